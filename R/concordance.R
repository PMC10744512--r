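#' @include AllClasses.R catalog.R diplotype.R scoring.R
NULL

truncatePct <- function(x) floor(x * 10) / 10
halfUpPct <- function(x) floor(x * 10 + 0.5) / 10

parseMarkers <- function(s) {
  if (is.na(s) || s == "-" || !nzchar(s)) return(character())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Compare two call sets for one sample at three levels
#'
#' Haplotype level: the multisets of star haplotypes of every gene, plus the
#' auxiliary marker genotypes, must agree (a no-call on one side is
#' discordant). Diplotype level: canonical diplotype string equality per
#' gene. Phenotype level: phenotype label equality per gene. A sample is
#' concordant at a level iff all genes agree at that level.
#'
#' @param a,b single-sample data.frames with columns \code{gene},
#'   \code{diplotype}, \code{phenotype}, \code{markers} (see
#'   \code{\link{readCallSets}}).
#' @return data.frame with columns \code{level}, \code{concordant},
#'   \code{detail} (first difference found, \code{""} if concordant).
#' @export
compareCallSets <- function(a, b) {
  if (!setequal(a$gene, b$gene) || nrow(a) != nrow(b))
    stop("call sets must cover the same genes")
  b <- b[match(a$gene, b$gene), , drop = FALSE]
  hapOk <- TRUE; dipOk <- TRUE; pheOk <- TRUE
  hapD <- dipD <- pheD <- ""
  for (i in seq_len(nrow(a))) {
    g <- a$gene[i]
    da <- parseDiplotype(g, a$diplotype[i])
    db <- parseDiplotype(g, b$diplotype[i])
    hapsA <- sort(c(renderHaplotype(da@hapA), renderHaplotype(da@hapB)))
    hapsB <- sort(c(renderHaplotype(db@hapA), renderHaplotype(db@hapB)))
    ma <- parseMarkers(a$markers[i]); mb <- parseMarkers(b$markers[i])
    srt <- function(m) if (length(m)) m[order(names(m))] else m
    mEq <- identical(srt(ma), srt(mb))
    if (hapOk && (!identical(hapsA, hapsB) || !mEq)) {
      hapOk <- FALSE
      hapD <- paste0(g, ": ", if (!identical(hapsA, hapsB))
        paste(paste(hapsA, collapse = "+"), "vs",
          paste(hapsB, collapse = "+")) else "marker genotypes differ")
    }
    if (dipOk && renderDiplotype(da) != renderDiplotype(db)) {
      dipOk <- FALSE
      dipD <- paste0(g, ": ", renderDiplotype(da), " vs ",
        renderDiplotype(db))
    }
    if (pheOk && a$phenotype[i] != b$phenotype[i]) {
      pheOk <- FALSE
      pheD <- paste0(g, ": ", a$phenotype[i], " vs ", b$phenotype[i])
    }
  }
  data.frame(level = c("haplotype", "diplotype", "phenotype"),
    concordant = c(hapOk, dipOk, pheOk), detail = c(hapD, dipD, pheD))
}

#' Compare two multi-sample call sets
#'
#' @param a,b data.frames as returned by \code{\link{readCallSets}}
#'   (columns \code{sample}, \code{gene}, \code{diplotype},
#'   \code{phenotype}, \code{markers}).
#' @param genes optional subset of genes to compare.
#' @return data.frame of per-sample records with columns \code{sample},
#'   \code{level}, \code{concordant}, \code{detail}.
#' @export
compareCohorts <- function(a, b, genes = NULL) {
  if (!is.null(genes)) {
    a <- a[a$gene %in% genes, , drop = FALSE]
    b <- b[b$gene %in% genes, , drop = FALSE]
  }
  samples <- unique(a$sample)
  out <- lapply(samples, function(s) {
    rec <- compareCallSets(a[a$sample == s, , drop = FALSE],
      b[b$sample == s, , drop = FALSE])
    cbind(sample = s, rec)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize concordance records into cohort percentages
#'
#' Percentages are truncated to one decimal, the convention of the published
#' totals (5/13 is reported as 38.4).
#'
#' @param records data.frame from \code{\link{compareCohorts}}.
#' @return data.frame with columns \code{level}, \code{n_concordant},
#'   \code{n_total}, \code{percentage}.
#' @export
summarizeConcordance <- function(records) {
  if (!nrow(records)) stop("no records to summarize")
  levels <- unique(records$level)
  out <- lapply(levels, function(l) {
    r <- records[records$level == l, , drop = FALSE]
    data.frame(level = l, n_concordant = sum(r$concordant),
      n_total = nrow(r),
      percentage = truncatePct(100 * sum(r$concordant) / nrow(r)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally a diplotype list into categories
#'
#' @param diplotypes character vector of diplotype strings.
#' @param classifier function mapping a diplotype string to a category
#'   label, or \code{NULL} when \code{categories} is given directly.
#' @param categories optional pre-assigned category per diplotype.
#' @param counts per-diplotype multiplicities (default 1).
#' @param denominator denominator for the percentages (default: total
#'   count). Percentages are rounded half-up to one decimal.
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{percentage}.
#' @export
tallySpread <- function(diplotypes, classifier = NULL, categories = NULL,
    counts = 1, denominator = NULL) {
  counts <- rep_len(counts, length(diplotypes))
  if (is.null(categories)) {
    if (is.null(classifier)) stop("need a classifier or categories")
    categories <- vapply(diplotypes, classifier, "", USE.NAMES = FALSE)
  }
  if (!length(diplotypes))
    return(data.frame(category = character(), count = integer(),
      percentage = numeric()))
  agg <- tapply(counts, categories, sum)
  if (is.null(denominator)) denominator <- sum(counts)
  res <- data.frame(category = names(agg), count = as.integer(agg),
    percentage = halfUpPct(100 * as.integer(agg) / denominator))
  rownames(res) <- NULL
  res[order(-res$count), , drop = FALSE]
}

#' Built-in spread classifiers
#'
#' \code{classifierDeletionPartner} classifies a deletion diplotype by the
#' clinical function of the haplotype partnered with the deletion allele
#' (\code{normal}, \code{decreased/none}, or \code{unknown});
#' \code{classifierAmbiguity} applies the NAT2 ambiguity rule of
#' \code{\link{classifyAmbiguity}}.
#'
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @return a classifier function usable with \code{\link{tallySpread}}.
#' @export
classifierDeletionPartner <- function(cat, gene = "CYP2D6") {
  function(s) {
    d <- parseDiplotype(gene, s)
    haps <- list(d@hapA, d@hapB)
    isDel <- vapply(haps, function(h) "*5" %in% h@stars, TRUE)
    if (!any(isDel)) stop("not a deletion diplotype: ", s)
    partner <- haps[[which(!isDel)[1]]]
    cls <- vapply(partner@stars, function(st) functionClass(cat, gene, st),
      "")
    if (any(cls == "normal")) "normal"
    else if (any(cls %in% c("decreased", "none"))) "decreased/none"
    else "unknown"
  }
}

#' @rdname classifierDeletionPartner
#' @export
classifierAmbiguity <- function(cat, gene = "NAT2") {
  function(s) {
    if (classifyAmbiguity(s, cat, gene = gene)$ambiguous) "ambiguous"
    else "non-ambiguous"
  }
}
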