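#' @include AllClasses.R catalog.R
NULL

# locus-window position of a variant coordinate (cDNA frames carry an offset)
locusPosition <- function(gm, coord) coord + gm$cds_offset

#' Extract per-fragment allele observations over heterozygous sites
#'
#' Projects each read onto the gene-model coordinate frame through its
#' haplotype's segment map and classifies the base at every covered site as
#' ref (0), alt (1) or missing (\code{NA}; bases matching neither allele are
#' treated as missing). Mates of the paired regime are merged into one
#' fragment-level observation. Fragments covering no site are dropped and
#' counted.
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param sites integer vector of heterozygous site coordinates (catalog
#'   variant frame), sorted.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @return list with \code{obs} (integer matrix, fragments x sites, values
#'   0/1/NA) and \code{dropped} (number of fragments covering no site).
#' @export
extractObservations <- function(rs, sites, cat) {
  gm <- geneModel(cat, rs@gene)
  if (is.unsorted(sites)) stop("sites must be sorted")
  v <- cat@variants[cat@variants$gene == rs@gene, , drop = FALSE]
  vi <- match(sites, v$coord)
  if (anyNA(vi)) stop("sites must be catalog variant coordinates")
  refb <- v$ref[vi]; altb <- v$alt[vi]
  pos <- locusPosition(gm, sites)

  reads <- rs@reads
  k <- length(sites)
  rows <- matrix(NA_integer_, nrow = nrow(reads), ncol = k)
  for (i in seq_len(nrow(reads))) {
    seg <- rs@haps[[reads$hap[i]]]$segments
    seg <- seg[seg$region == rs@gene, , drop = FALSE]
    for (j in seq_len(k)) {
      hit <- seg$region_start <= pos[j] &
        (seg$region_start + (seg$hap_end - seg$hap_start)) >= pos[j]
      if (!any(hit)) next
      hp <- seg$hap_start[hit] + (pos[j] - seg$region_start[hit])
      hp <- hp[hp >= reads$start[i] & hp <= reads$end[i]]
      if (!length(hp)) next
      b <- substr(reads$seq[i], hp[1] - reads$start[i] + 1L,
        hp[1] - reads$start[i] + 1L)
      rows[i, j] <- if (b == altb[j]) 1L else if (b == refb[j]) 0L else
        NA_integer_
    }
  }
  frag <- reads$fragment
  ufrag <- unique(frag)
  obs <- matrix(NA_integer_, nrow = length(ufrag), ncol = k,
    dimnames = list(ufrag, as.character(sites)))
  for (i in seq_len(nrow(reads))) {
    r <- match(frag[i], ufrag)
    take <- !is.na(rows[i, ]) & is.na(obs[r, ])
    obs[r, take] <- rows[i, take]
  }
  keep <- rowSums(!is.na(obs)) > 0L
  list(obs = obs[keep, , drop = FALSE], dropped = sum(!keep))
}

siteComponents <- function(obs) {
  k <- ncol(obs)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(obs))) {
    idx <- which(!is.na(obs[i, ]))
    if (length(idx) > 1L)
      for (j in idx[-1]) {
        a <- find(idx[1]); b <- find(j)
        if (a != b) parent[b] <- a
      }
  }
  roots <- vapply(seq_len(k), find, 1L)
  unname(split(seq_len(k), match(roots, unique(roots))))
}

mecCost <- function(obs, h) {
  # corrections needed for every fragment to fit haplotypes (h, 1-h)
  P <- (!is.na(obs)) & obs == 1L
  Q <- (!is.na(obs)) & obs == 0L
  m1 <- P %*% (1 - h) + Q %*% h
  m2 <- P %*% h + Q %*% (1 - h)
  sum(pmin(m1, m2))
}

exactMec <- function(obs) {
  m <- ncol(obs)
  P <- (!is.na(obs)) & obs == 1L
  Q <- (!is.na(obs)) & obs == 0L
  storage.mode(P) <- "numeric"; storage.mode(Q) <- "numeric"
  nA <- 2^(m - 1L)
  # assignments in lexicographic order, first site fixed to ref on hap A
  H <- matrix(0, nrow = m, ncol = nA)
  if (m > 1L) {
    combo <- as.matrix(expand.grid(rep(list(0:1), m - 1L)))
    # expand.grid varies the first factor fastest; reorder for lexicographic
    H[2:m, ] <- t(combo[order(apply(combo, 1L, paste, collapse = "")), ,
      drop = FALSE])
  }
  M1 <- P %*% (1 - H) + Q %*% H
  M2 <- P %*% H + Q %*% (1 - H)
  cost <- colSums(pmin(M1, M2))
  best <- which.min(cost)
  list(h = as.integer(H[, best]), mec = as.integer(cost[best]))
}

greedyMec <- function(obs) {
  m <- ncol(obs)
  # seed: chain sites by majority-vote relative phase
  h <- integer(m)
  rel <- matrix(0L, m, m)
  for (i in seq_len(nrow(obs))) {
    idx <- which(!is.na(obs[i, ]))
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      x <- idx[a]; y <- idx[a + 1L]
      d <- if (obs[i, x] == obs[i, y]) 1L else -1L
      rel[x, y] <- rel[x, y] + d
    }
  }
  for (j in 2:m) h[j] <- if (rel[j - 1L, j] >= 0L) h[j - 1L] else
    1L - h[j - 1L]
  # coordinate descent: reassign fragments, re-vote sites
  P <- (!is.na(obs)) & obs == 1L
  Q <- (!is.na(obs)) & obs == 0L
  storage.mode(P) <- "numeric"; storage.mode(Q) <- "numeric"
  descend <- function(h) {
    for (iter in 1:50) {
      m1 <- as.numeric(P %*% (1 - h) + Q %*% h)
      m2 <- as.numeric(P %*% h + Q %*% (1 - h))
      toA <- m1 <= m2
      hn <- integer(m)
      for (j in seq_len(m)) {
        alt1 <- sum(P[toA, j]) + sum(Q[!toA, j])
        ref1 <- sum(Q[toA, j]) + sum(P[!toA, j])
        hn[j] <- if (alt1 > ref1) 1L else 0L
      }
      if (hn[1] == 1L) hn <- 1L - hn
      if (identical(hn, h)) break
      h <- hn
    }
    h
  }
  h <- descend(h)
  # escape local optima: 1-opt over single-site flips (mis-phased sites)
  # and suffix flips (mis-joined chain links), re-descending after any gain
  repeat {
    cost <- mecCost(obs, h)
    improved <- FALSE
    for (j in seq_len(m)) {
      for (kind in 1:2) {
        hf <- h
        if (kind == 1L) hf[j] <- 1L - hf[j]
        else hf[j:m] <- 1L - hf[j:m]
        if (hf[1] == 1L) hf <- 1L - hf
        if (mecCost(obs, hf) < cost) {
          h <- descend(hf); improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(h = h, mec = as.integer(mecCost(obs, h)))
}

#' Read-backed phasing by minimum error correction
#'
#' Bipartitions the heterozygous sites into two haplotypes minimizing the
#' total number of read base calls that must be corrected (unweighted MEC).
#' Sites connected by no fragment fall into separate phase blocks and are
#' phased independently. Blocks with up to \code{maxExact} sites are solved
#' by exhaustive search over the \eqn{2^{k-1}} assignments; larger blocks use
#' a spanning-chain seed refined by coordinate descent. Ties are broken
#' toward the lexicographically smallest assignment with haplotype A carrying
#' the ref allele at the first site of each block.
#'
#' @param observations output of \code{\link{extractObservations}}, or a
#'   bare fragments x sites 0/1/NA matrix.
#' @param sites optional site coordinates (defaults to the matrix column
#'   names).
#' @param maxExact block size up to which the exact solver is used.
#' @return a \code{\linkS4class{PhaseResult}} (method \code{"direct"}).
#' @export
phaseDirect <- function(observations, sites = NULL, maxExact = 15L) {
  obs <- if (is.list(observations)) observations$obs else observations
  if (is.null(sites))
    sites <- as.integer(colnames(obs) %||% seq_len(ncol(obs)))
  k <- ncol(obs)
  if (k == 0L)
    return(new("PhaseResult", sites = integer(), hapA = integer(),
      blocks = list(), mec = 0L, method = "direct", metadata = list()))
  if (nrow(obs) == 0L) {
    warning("no informative observations; all sites left unphased")
    return(new("PhaseResult", sites = as.integer(sites),
      hapA = integer(k), blocks = as.list(seq_len(k)), mec = 0L,
      method = "direct", metadata = list()))
  }
  blocks <- siteComponents(obs)
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  hapA <- integer(k); mec <- 0L
  for (b in blocks) {
    sub <- obs[, b, drop = FALSE]
    sub <- sub[rowSums(!is.na(sub)) > 0L, , drop = FALSE]
    if (length(b) == 1L || nrow(sub) == 0L) next
    res <- if (length(b) <= maxExact) exactMec(sub) else greedyMec(sub)
    hapA[b] <- res$h
    mec <- mec + res$mec
  }
  new("PhaseResult", sites = as.integer(sites), hapA = hapA,
    blocks = blocks, mec = as.integer(mec), method = "direct",
    metadata = list())
}

#' Phase blocks attainable at a given read length
#'
#' Models which heterozygous sites can be phased jointly by reads of a given
#' length: a cut is introduced between adjacent sites separated by more than
#' the read length; adjacent sites separated by less are assumed phasable.
#' The number of blocks is non-increasing in read length.
#'
#' @param positions sorted heterozygous site positions (bp).
#' @param readLength read (or fragment) length in bp.
#' @return list of integer index vectors, one per block.
#' @examples
#' computePhaseBlocks(c(341, 481, 803), 200)  # {1,2} | {3}
#' @export
computePhaseBlocks <- function(positions, readLength) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (!length(positions)) return(list())
  cut <- which(diff(positions) > readLength)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(positions))
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

#' Switch and Hamming error of a phasing result against the truth
#'
#' Switch errors count adjacent in-block site pairs whose relative phase
#' disagrees with the truth; the Hamming error is the minimum number of
#' mis-assigned sites over a global A/B relabeling of each block.
#'
#' @param predicted a \code{\linkS4class{PhaseResult}}.
#' @param truth integer 0/1 vector: the true allele of haplotype A at each
#'   site of \code{predicted}, or a data.frame with columns \code{coord} and
#'   \code{A} (as in the truth matrix of
#'   \code{\link{materializeHaplotypes}}).
#' @return list with \code{switch_errors} and \code{hamming}.
#' @export
phaseErrors <- function(predicted, truth) {
  if (is.data.frame(truth)) {
    i <- match(predicted@sites, truth$coord)
    if (anyNA(i)) stop("site sets differ between prediction and truth")
    truth <- truth$A[i]
  }
  if (length(truth) != length(predicted@sites))
    stop("site sets differ between prediction and truth")
  sw <- 0L; ham <- 0L
  for (b in predicted@blocks) {
    p <- predicted@hapA[b]; t <- truth[b]
    mism <- sum(p != t)
    ham <- ham + min(mism, length(b) - mism)
    if (length(b) > 1L) {
      relp <- diff(p) != 0L; relt <- diff(t) != 0L
      sw <- sw + sum(relp != relt)
    }
  }
  list(switch_errors = sw, hamming = ham)
}

haplotypeFrequency <- function(freq, gene, key, floor = 1e-4) {
  i <- which(freq$gene == gene & freq$haplotype == key)
  if (length(i)) freq$freq[i[1]] else floor
}

#' Statistical phasing: frequency-driven joining of phase blocks
#'
#' Emulates population-frequency statistical phasing as used after
#' short-read sequencing: within each phase block the phase is fixed by the
#' read evidence supplied as input; across blocks, the relative orientation
#' is chosen to maximize the product of the population frequencies of the
#' two resulting star haplotypes. The result is deterministic given the
#' frequency table; exact ties are broken toward the canonically smallest
#' diplotype and flagged as ambiguous joins.
#'
#' @param phase a \code{\linkS4class{PhaseResult}} holding the within-block
#'   phase (e.g. from \code{\link{phaseDirect}} with blocks restricted by
#'   \code{\link{computePhaseBlocks}}).
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @param homVariants var_ids of homozygous-alt sites (carried by both
#'   haplotypes; they enter the frequency lookup but are not phased).
#' @param freq frequency table (defaults to the catalog's); columns
#'   \code{gene}, \code{haplotype}, \code{freq}.
#' @param floor frequency assigned to haplotypes absent from the table.
#' @return a \code{\linkS4class{PhaseResult}} (method \code{"statistical"})
#'   with metadata \code{ambiguous_join} and \code{score}.
#' @export
phaseStatistical <- function(phase, cat, gene, homVariants = character(),
    freq = NULL, floor = 1e-4) {
  if (is.null(freq)) freq <- cat@frequencies
  v <- cat@variants[cat@variants$gene == gene, , drop = FALSE]
  ids <- v$var_id[match(phase@sites, v$coord)]
  B <- length(phase@blocks)
  if (B <= 1L) {
    out <- phase
    out@method <- "statistical"
    out@metadata <- c(out@metadata, list(ambiguous_join = FALSE))
    return(out)
  }
  starKey <- function(varIds) paste(assignStars(varIds, cat, gene),
    collapse = ",")
  combos <- as.matrix(expand.grid(rep(list(0:1), B - 1L)))
  best <- NULL; bestScore <- -Inf; nbest <- 0L
  for (r in seq_len(nrow(combos))) {
    flip <- c(0L, as.integer(combos[r, ]))
    hapA <- phase@hapA
    for (b in seq_len(B)[flip == 1L])
      hapA[phase@blocks[[b]]] <- 1L - hapA[phase@blocks[[b]]]
    keyA <- starKey(c(ids[hapA == 1L], homVariants))
    keyB <- starKey(c(ids[hapA == 0L], homVariants))
    score <- haplotypeFrequency(freq, gene, keyA, floor) *
      haplotypeFrequency(freq, gene, keyB, floor)
    dipKey <- paste(sort(c(keyA, keyB)), collapse = "/")
    if (score > bestScore * (1 + 1e-12)) {
      bestScore <- score; best <- list(hapA = hapA, key = dipKey); nbest <- 1L
    } else if (abs(score - bestScore) <= bestScore * 1e-12) {
      nbest <- nbest + 1L
      if (dipKey < best$key) best <- list(hapA = hapA, key = dipKey)
    }
  }
  new("PhaseResult", sites = phase@sites, hapA = best$hapA,
    blocks = phase@blocks, mec = phase@mec, method = "statistical",
    metadata = list(ambiguous_join = nbest > 1L, score = bestScore))
}
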