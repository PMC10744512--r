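#' @include AllClasses.R catalog.R diplotype.R
NULL

asDiplotype <- function(cat, gene, d) {
  if (is(d, "Diplotype")) d else parseDiplotype(gene, d)
}

#' Activity score of a diplotype
#'
#' The default engine is additive: each haplotype contributes the sum of its
#' component activity values times their copy multipliers, hybrid tandem
#' components contributing their own (null) values. Diplotypes whose
#' published score is not additively consistent are resolved through the
#' catalog's override table and tagged accordingly. Any component with
#' unknown activity and no override yields an indeterminate phenotype.
#'
#' @param d a \code{\linkS4class{Diplotype}} or diplotype string.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol (needed when \code{d} is a string).
#' @return list with \code{activity_score}, \code{phenotype} and
#'   \code{source} (\code{"additive"} or \code{"override"}).
#' @examples
#' cat <- loadCatalog()
#' activityScore("*2 x 2/*41", cat, "CYP2D6")$activity_score  # 2.25
#' @export
activityScore <- function(d, cat, gene = NULL) {
  if (!is(d, "Diplotype")) d <- parseDiplotype(gene, d)
  gene <- d@gene
  key <- renderDiplotype(d)
  ov <- cat@overrides
  i <- which(ov$gene == gene & ov$diplotype == key)
  if (length(i)) {
    as <- ov$activity[i[1]]
    return(list(activity_score = as,
      phenotype = phenotypeFromScore(gene, as, cat), source = "override"))
  }
  hapValue <- function(h) {
    v <- vapply(h@stars, function(s) activityValue(cat, gene, s), 1.0)
    sum(v * h@copies)
  }
  as <- hapValue(d@hapA) + hapValue(d@hapB)
  if (is.na(as))
    return(list(activity_score = NA_real_, phenotype = "indeterminate",
      source = "additive"))
  list(activity_score = as, phenotype = phenotypeFromScore(gene, as, cat),
    source = "additive")
}

#' Metabolizer phenotype from an activity score
#'
#' Looks the score up in the gene's configured threshold bands
#' (PM/IM/NM/UM); bands cover the nonnegative half-line without overlap.
#'
#' @param gene gene symbol.
#' @param as activity score.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @return phenotype label.
#' @examples
#' cat <- loadCatalog()
#' phenotypeFromScore("CYP2D6", 1.0, cat)  # IM
#' @export
phenotypeFromScore <- function(gene, as, cat) {
  bands <- cat@bands[[gene]]
  if (is.null(bands)) stop("no phenotype bands configured for ", gene)
  for (b in bands) {
    lo <- if (b$lo_open) as > b$lo else as >= b$lo
    hi <- if (b$hi_open) as < b$hi else as <= b$hi
    if (lo && hi) return(b$label)
  }
  stop("activity score ", as, " not covered by the ", gene, " bands")
}

#' NAT2 acetylator status of a diplotype
#'
#' Counts the parental haplotypes carrying at least one slow-acetylator star
#' (*5, *6, *7, *14): zero slow haplotypes is a rapid acetylator (RA), one
#' an intermediate (IA), two a slow acetylator (SA). Unclassified stars
#' (*11) never count as slow.
#'
#' @param d a \code{\linkS4class{Diplotype}} or diplotype string.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol (default NAT2).
#' @return \code{"RA"}, \code{"IA"} or \code{"SA"}.
#' @examples
#' cat <- loadCatalog()
#' acetylatorStatus("*4/*6,*13", cat)  # IA
#' @export
acetylatorStatus <- function(d, cat, gene = "NAT2") {
  d <- asDiplotype(cat, gene, d)
  slow <- cat@bands$acetylator$slow
  nSlow <- sum(vapply(list(d@hapA, d@hapB),
    function(h) any(h@stars %in% slow), TRUE))
  c("RA", "IA", "SA")[nSlow + 1L]
}

#' Classify a NAT2 diplotype as ambiguous for statistical phasing
#'
#' A diplotype is ambiguous when it carries at least two distinct slow stars
#' whose core SNVs are heterozygous in the combined genotype and some pair
#' of those SNVs is separated by more than the fragment length — i.e. no
#' short-read fragment can phase them, so statistical inference has to
#' guess the configuration. Homozygous slow configurations are
#' non-ambiguous. The classification depends only on the combined genotype,
#' so it is invariant to haplotype order and to within-haplotype component
#' order.
#'
#' @param d a \code{\linkS4class{Diplotype}} or diplotype string.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param fragmentLength phasing reach of the short-read fragments in bp
#'   (default from the catalog configuration, 200 bp).
#' @param gene gene symbol (default NAT2).
#' @return list with \code{ambiguous} (logical) and \code{reason}.
#' @examples
#' cat <- loadCatalog()
#' classifyAmbiguity("*5,*11,*12/*6,*13", cat)$ambiguous  # TRUE
#' @export
classifyAmbiguity <- function(d, cat, fragmentLength = NULL,
    gene = "NAT2") {
  d <- asDiplotype(cat, gene, d)
  if (is.null(fragmentLength))
    fragmentLength <- cat@bands$ambiguity$fragment_length
  slow <- cat@bands$acetylator$slow
  inA <- d@hapA@stars; inB <- d@hapB@stars
  hetSlow <- union(setdiff(intersect(inA, slow), inB),
    setdiff(intersect(inB, slow), inA))
  if (length(hetSlow) < 2L)
    return(list(ambiguous = FALSE,
      reason = "fewer than two heterozygous slow stars"))
  pos <- vapply(hetSlow, function(s) coreCoord(cat, gene, s), 1L)
  maxd <- max(stats::dist(pos))
  list(ambiguous = maxd > fragmentLength,
    reason = sprintf("max pairwise slow-SNV distance %d bp vs fragment %d bp",
      as.integer(maxd), as.integer(fragmentLength)))
}
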