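#' @import methods
NULL

#' Catalog of star-allele definitions, gene models and scoring tables
#'
#' A \code{PgxCatalog} bundles everything the callers and scorers need to
#' know about the three packaged loci: per-gene star-allele tables (defining
#' variants, TA repeat lengths, activity values, function and acetylation
#' classes), variant definition tables, synthetic gene models (reference
#' sequence, repeat-locus anchors, paralog and junction geometry), the
#' diplotype-level activity override table, the phenotype threshold bands and
#' the population haplotype-frequency table used by statistical phasing.
#'
#' Construct one with \code{\link{loadCatalog}}; do not fill slots by hand.
#'
#' @slot alleles data.frame of star-allele definitions, one row per allele.
#' @slot variants data.frame of variant definitions, one row per variant.
#' @slot geneModels named list of gene models (see \code{\link{geneModel}}).
#' @slot overrides data.frame mapping canonical diplotype strings to activity
#'   scores for the non-additive diplotypes.
#' @slot bands named list of phenotype threshold bands per gene.
#' @slot frequencies data.frame of population haplotype frequencies used by
#'   \code{\link{phaseStatistical}}.
#'
#' @aliases PgxCatalog-class
#' @exportClass PgxCatalog
setClass("PgxCatalog",
  representation(
    alleles = "data.frame",
    variants = "data.frame",
    geneModels = "list",
    overrides = "data.frame",
    bands = "list",
    frequencies = "data.frame"
  )
)

#' One parental haplotype of a pharmacogene
#'
#' A haplotype is an ordered list of star-allele components with a positive
#' copy multiplier per component, so tandem arrangements such as
#' \code{*41,*68} and amplifications such as \code{*4 x 2,*68 x 2} can both
#' be represented.
#'
#' @slot gene gene symbol.
#' @slot stars character vector of star names (e.g. \code{"*41"}).
#' @slot copies integer vector, parallel to \code{stars}; copies >= 1.
#'
#' @aliases Haplotype-class
#' @exportClass Haplotype
setClass("Haplotype",
  representation(gene = "character", stars = "character", copies = "integer")
)

setValidity("Haplotype", function(object) {
  if (length(object@stars) == 0L) return("haplotype must have >= 1 component")
  if (length(object@copies) != length(object@stars))
    return("copies must be parallel to stars")
  if (any(object@copies < 1L)) return("copies must be >= 1")
  if (!all(grepl("^\\*", object@stars)))
    return("star names must start with '*'")
  TRUE
})

#' A diplotype: the pair of haplotypes of one individual at one gene
#'
#' @slot gene gene symbol.
#' @slot hapA,hapB the two \code{\linkS4class{Haplotype}} objects, stored in
#'   canonical order (see \code{\link{canonicalDiplotype}}).
#'
#' @aliases Diplotype-class
#' @exportClass Diplotype
setClass("Diplotype",
  representation(gene = "character", hapA = "Haplotype", hapB = "Haplotype")
)

setValidity("Diplotype", function(object) {
  if (object@hapA@gene != object@gene || object@hapB@gene != object@gene)
    return("haplotype genes must match diplotype gene")
  TRUE
})

#' Sequencing regime configuration
#'
#' Captures the handful of parameters that distinguish the short-read
#' (paired 2 x 150 bp, ~350 bp fragments, high depth, error < 1\%) and
#' long-read HiFi (single multi-kb reads, 15-30x, >= 99\% accuracy) regimes.
#'
#' @slot name \code{"SRS"} or \code{"LRS"}.
#' @slot readLength read length in bp.
#' @slot fragmentLength fragment length in bp (paired regime only; \code{NA}
#'   for the long-read regime).
#' @slot depth nominal diploid depth (x coverage).
#' @slot errorRate per-base substitution error rate in [0, 1).
#'
#' @aliases RegimeConfig-class
#' @exportClass RegimeConfig
setClass("RegimeConfig",
  representation(name = "character", readLength = "integer",
    fragmentLength = "integer", depth = "numeric", errorRate = "numeric")
)

setValidity("RegimeConfig", function(object) {
  if (!object@name %in% c("SRS", "LRS")) return("name must be SRS or LRS")
  if (object@readLength < 1L) return("readLength must be positive")
  if (object@depth <= 0) return("depth must be positive")
  if (object@errorRate < 0 || object@errorRate >= 1)
    return("errorRate must be in [0, 1)")
  if (object@name == "SRS" && (is.na(object@fragmentLength) ||
      object@fragmentLength < 2L * object@readLength))
    return("SRS fragmentLength must be >= 2 * readLength")
  TRUE
})

#' Simulated read set for one diploid sample at one gene
#'
#' Reads are emitted with their true haplotype of origin and true
#' haplotype-local coordinates; no aligner is run anywhere in the pipeline.
#' The per-haplotype segment maps (which haplotype interval corresponds to
#' which gene-model interval, plus structural junction records) play the role
#' an alignment would play downstream.
#'
#' @slot gene gene symbol.
#' @slot reads data.frame with columns \code{read_id}, \code{hap} ("A"/"B"),
#'   \code{start}, \code{end} (1-based haplotype-local, inclusive),
#'   \code{seq}, \code{fragment} (fragment id; equal for mates in the paired
#'   regime), \code{n_errors}.
#' @slot haps the materialized haplotypes as returned by
#'   \code{\link{materializeHaplotypes}} (sequences, segment maps, junctions).
#' @slot regime the \code{\linkS4class{RegimeConfig}} used.
#'
#' @aliases SimReadSet-class
#' @exportClass SimReadSet
setClass("SimReadSet",
  representation(gene = "character", reads = "data.frame", haps = "list",
    regime = "RegimeConfig")
)

setValidity("SimReadSet", function(object) {
  need <- c("read_id", "hap", "start", "end", "seq", "fragment", "n_errors")
  if (!all(need %in% names(object@reads)))
    return(paste("reads must have columns", paste(need, collapse = ", ")))
  if (nrow(object@reads) && !all(object@reads$hap %in% c("A", "B")))
    return("hap must be A or B")
  TRUE
})

#' Result of phasing a set of heterozygous sites
#'
#' Site assignments give the allele carried by haplotype A at each
#' heterozygous site (0 = ref, 1 = alt; haplotype B carries the complement).
#' Within a phase block the assignment is defined up to a global A/B swap;
#' sites in different blocks are not phased relative to each other.
#'
#' @slot sites integer vector of heterozygous site positions (gene-model
#'   coordinates), sorted.
#' @slot hapA integer vector (0/1), allele on haplotype A per site.
#' @slot blocks list of integer index vectors, each a maximal set of jointly
#'   phased site indices.
#' @slot mec minimum-error-correction score: the number of read base calls
#'   that had to be flipped for all reads to fit the two haplotypes.
#' @slot method \code{"direct"}, \code{"statistical"} or \code{"blockmodel"}.
#' @slot metadata list of extra information (e.g. \code{ambiguous_join}).
#'
#' @aliases PhaseResult-class
#' @exportClass PhaseResult
setClass("PhaseResult",
  representation(sites = "integer", hapA = "integer", blocks = "list",
    mec = "integer", method = "character", metadata = "list")
)

setValidity("PhaseResult", function(object) {
  if (length(object@hapA) != length(object@sites))
    return("hapA must be parallel to sites")
  if (length(object@sites) && is.unsorted(object@sites))
    return("sites must be sorted")
  idx <- sort(unlist(object@blocks))
  if (length(object@sites) && !identical(idx, seq_along(object@sites)))
    return("blocks must partition the site indices")
  if (object@mec < 0L) return("mec must be nonnegative")
  TRUE
})
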