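#' @include AllClasses.R
NULL

#' Gene symbol of an object
#' @param x an object with a gene slot.
#' @return character scalar, the gene symbol.
#' @export
setGeneric("gene", function(x) standardGeneric("gene"))

#' @rdname gene
#' @export
setMethod("gene", "Haplotype", function(x) x@gene)
#' @rdname gene
#' @export
setMethod("gene", "Diplotype", function(x) x@gene)
#' @rdname gene
#' @export
setMethod("gene", "SimReadSet", function(x) x@gene)

#' Star components and copy multipliers of a haplotype
#' @param x a \code{\linkS4class{Haplotype}}.
#' @return \code{starComponents}: character vector of star names;
#'   \code{copyNumbers}: parallel integer vector of copy multipliers.
#' @export
setGeneric("starComponents", function(x) standardGeneric("starComponents"))
#' @rdname starComponents
#' @export
setMethod("starComponents", "Haplotype", function(x) x@stars)

#' @rdname starComponents
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))
#' @rdname starComponents
#' @export
setMethod("copyNumbers", "Haplotype", function(x) x@copies)

#' The two haplotypes of a diplotype
#' @param x a \code{\linkS4class{Diplotype}}.
#' @return list of the two \code{\linkS4class{Haplotype}} objects.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname haplotypes
#' @export
setMethod("haplotypes", "Diplotype", function(x) list(A = x@hapA, B = x@hapB))

#' Accessors for phasing results
#' @param x a \code{\linkS4class{PhaseResult}}.
#' @return \code{mecScore}: integer MEC score; \code{phaseBlocks}: list of
#'   site-index vectors; \code{phasedSites}: integer site positions;
#'   \code{hapAlleles}: 0/1 alleles on haplotype A.
#' @export
setGeneric("mecScore", function(x) standardGeneric("mecScore"))
#' @rdname mecScore
#' @export
setMethod("mecScore", "PhaseResult", function(x) x@mec)
#' @rdname mecScore
#' @export
setGeneric("phaseBlocks", function(x) standardGeneric("phaseBlocks"))
#' @rdname mecScore
#' @export
setMethod("phaseBlocks", "PhaseResult", function(x) x@blocks)
#' @rdname mecScore
#' @export
setGeneric("phasedSites", function(x) standardGeneric("phasedSites"))
#' @rdname mecScore
#' @export
setMethod("phasedSites", "PhaseResult", function(x) x@sites)
#' @rdname mecScore
#' @export
setGeneric("hapAlleles", function(x) standardGeneric("hapAlleles"))
#' @rdname mecScore
#' @export
setMethod("hapAlleles", "PhaseResult", function(x) x@hapA)

#' Reads of a simulated read set
#' @param x a \code{\linkS4class{SimReadSet}}.
#' @return data.frame of reads (see \code{\linkS4class{SimReadSet}}).
#' @export
setGeneric("simReads", function(x) standardGeneric("simReads"))
#' @rdname simReads
#' @export
setMethod("simReads", "SimReadSet", function(x) x@reads)

setMethod("show", "Haplotype", function(object) {
  cat("Haplotype <", object@gene, "> ", renderHaplotype(object), "\n", sep = "")
})

setMethod("show", "Diplotype", function(object) {
  cat("Diplotype <", object@gene, "> ", renderDiplotype(object), "\n", sep = "")
})

setMethod("show", "RegimeConfig", function(object) {
  cat("RegimeConfig", object@name, ": readLength", object@readLength,
    if (!is.na(object@fragmentLength))
      paste("fragmentLength", object@fragmentLength),
    "depth", object@depth, "errorRate", object@errorRate, "\n")
})

setMethod("show", "SimReadSet", function(object) {
  cat("SimReadSet <", object@gene, "> ", nrow(object@reads), " reads (",
    object@regime@name, " regime)\n", sep = "")
})

setMethod("show", "PhaseResult", function(object) {
  cat("PhaseResult [", object@method, "]: ", length(object@sites),
    " sites in ", length(object@blocks), " block(s), MEC ", object@mec,
    "\n", sep = "")
})

setMethod("show", "PgxCatalog", function(object) {
  cat("PgxCatalog: ", nrow(object@alleles), " star alleles, ",
    nrow(object@variants), " variant definitions, ",
    length(object@geneModels), " gene models (",
    paste(names(object@geneModels), collapse = ", "), ")\n", sep = "")
})
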