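#' @include AllClasses.R catalog.R
NULL

#' Sequencing regime constructors
#'
#' \code{lrsRegime} models a HiFi-style long-read regime (multi-kb reads,
#' >= 99\% accuracy, 15-30x depth); \code{srsRegime} a paired-end short-read
#' regime (2 x 150 bp reads on ~350 bp fragments, high depth, < 1\% error).
#' Fragment length is fixed rather than drawn from a distribution.
#'
#' @param readLength read length in bp.
#' @param depth nominal diploid depth.
#' @param errorRate per-base substitution error rate.
#' @param fragmentLength fragment length in bp (paired regime).
#' @return a \code{\linkS4class{RegimeConfig}}.
#' @export
lrsRegime <- function(readLength = 4985L, depth = 30, errorRate = 0.01) {
  new("RegimeConfig", name = "LRS", readLength = as.integer(readLength),
    fragmentLength = NA_integer_, depth = depth, errorRate = errorRate)
}

#' @rdname lrsRegime
#' @export
srsRegime <- function(readLength = 150L, fragmentLength = 350L, depth = 100,
    errorRate = 0.005) {
  new("RegimeConfig", name = "SRS", readLength = as.integer(readLength),
    fragmentLength = as.integer(fragmentLength), depth = depth,
    errorRate = errorRate)
}

#' Draw a diplotype from a prevalence table
#'
#' @param gene gene symbol.
#' @param prevalence data.frame with columns \code{diplotype} and
#'   \code{count} (or \code{weight}), or a named numeric vector.
#' @param n number of draws.
#' @return list of \code{\linkS4class{Diplotype}} (a single object if
#'   \code{n = 1}).
#' @export
sampleDiplotype <- function(gene, prevalence, n = 1L) {
  if (is.numeric(prevalence))
    prevalence <- data.frame(diplotype = names(prevalence),
      count = unname(prevalence))
  w <- prevalence$count %||% prevalence$weight
  if (is.null(w) || !nrow(prevalence)) stop("empty prevalence table")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative, sum > 0")
  idx <- sample.int(nrow(prevalence), n, replace = TRUE, prob = w)
  out <- lapply(prevalence$diplotype[idx],
    function(s) parseDiplotype(gene, s))
  if (n == 1L) out[[1]] else out
}

applySnvs <- function(seq, coords, alts) {
  for (i in seq_along(coords)) substr(seq, coords[i], coords[i]) <- alts[i]
  seq
}

# variant substitutions implied by a set of star components (gene frame)
starVariantTable <- function(cat, gene, stars) {
  v <- cat@variants[cat@variants$gene == gene, , drop = FALSE]
  ids <- unique(unlist(lapply(stars, function(s)
    alleleRow(cat, gene, s)$defining_variants[[1]])))
  v[match(ids, v$var_id), , drop = FALSE]
}

materializeSnvHap <- function(cat, gm, hap) {
  v <- starVariantTable(cat, gm$gene, hap@stars)
  seq <- applySnvs(gm$reference_sequence, v$coord + gm$cds_offset, v$alt)
  list(seq = seq,
    segments = data.frame(hap_start = 1L, hap_end = nchar(seq),
      region = gm$gene, region_start = 1L),
    junctions = data.frame(pos = integer(), type = character()),
    variants = v$var_id)
}

materializeRepeatHap <- function(cat, gm, hap) {
  rl <- gm$repeat_locus
  repStars <- hap@stars[!is.na(vapply(hap@stars,
    function(s) taRepeatsOf(cat, gm$gene, s), 1L))]
  if (length(repStars) > 1L)
    stop("conflicting repeat-defined stars on one haplotype")
  units <- if (length(repStars)) taRepeatsOf(cat, gm$gene, repStars) else
    rl$ref_units
  v <- starVariantTable(cat, gm$gene, hap@stars)
  if (any(v$coord >= rl$position & v$coord < rl$position + 2L * rl$ref_units))
    stop("SNV inside the repeat locus is not supported")
  seq <- applySnvs(gm$reference_sequence, v$coord, v$alt)
  pre <- substr(seq, 1L, rl$position - 1L)
  post <- substr(seq, rl$position + 2L * rl$ref_units, nchar(seq))
  seq <- paste0(pre, strrep(rl$unit, units), post)
  repEnd <- rl$position + 2L * units - 1L
  list(seq = seq, ta_units = units,
    segments = data.frame(
      hap_start = c(1L, rl$position, repEnd + 1L),
      hap_end = c(rl$position - 1L, repEnd, nchar(seq)),
      region = c(gm$gene, "TA", gm$gene),
      region_start = c(1L, NA_integer_, rl$position + 2L * rl$ref_units)),
    junctions = data.frame(pos = integer(), type = character()),
    variants = v$var_id)
}

materializeStructuralHap <- function(cat, gm, hap) {
  par <- gm$paralog
  a <- cat@alleles[cat@alleles$gene == gm$gene, , drop = FALSE]
  typeOf <- function(s) a$allele_type[match(s, a$star)]
  types <- vapply(hap@stars, typeOf, "")
  fullIdx <- which(types %in% c("reference", "snv"))
  hybIdx <- which(types == "hybrid")
  delIdx <- which(types == "deletion")

  flankL <- randomBases(gm$flank, gm$seed * 1000L + 1L)
  flankR <- randomBases(gm$flank, gm$seed * 1000L + 2L)
  spacer <- randomBases(gm$spacer, gm$seed * 1000L + 3L)

  pieces <- character(); segs <- list(); juncs <- list()
  cursor <- 0L
  push <- function(piece, region, region_start) {
    pieces[[length(pieces) + 1L]] <<- piece
    segs[[length(segs) + 1L]] <<- data.frame(hap_start = cursor + 1L,
      hap_end = cursor + nchar(piece), region = region,
      region_start = region_start)
    cursor <<- cursor + nchar(piece)
  }
  push(flankL, "flank", NA_integer_)

  if (length(delIdx)) {
    if (length(fullIdx))
      stop("a haplotype cannot carry both a deletion and a full gene copy")
    juncs[[length(juncs) + 1L]] <- data.frame(pos = cursor, type = "deletion")
    push(flankR, "flank", NA_integer_)
  } else {
    nCopies <- sum(hap@copies[fullIdx])
    copyStars <- rep(hap@stars[fullIdx], hap@copies[fullIdx])
    if (!length(copyStars)) copyStars <- character()
    first <- TRUE
    for (s in copyStars) {
      if (!first) push(spacer, "spacer", NA_integer_)
      first <- FALSE
      v <- starVariantTable(cat, gm$gene, s)
      cp <- applySnvs(gm$reference_sequence, v$coord, v$alt)
      push(cp, gm$gene, 1L)
    }
    for (s in rep(hap@stars[hybIdx], hap@copies[hybIdx])) {
      push(spacer, "spacer", NA_integer_)
      hseq6 <- substr(gm$reference_sequence, 1L, par$junction)
      hseq7 <- substr(par$sequence, par$junction + 1L, par$length)
      push(hseq6, gm$gene, 1L)
      juncs[[length(juncs) + 1L]] <- data.frame(pos = cursor,
        type = "hybrid")
      push(hseq7, par$name, par$junction + 1L)
    }
    push(flankR, "flank", NA_integer_)
  }
  push(spacer, "spacer", NA_integer_)
  push(par$sequence, par$name, 1L)

  v <- starVariantTable(cat, gm$gene, hap@stars[fullIdx])
  list(seq = paste(pieces, collapse = ""),
    segments = do.call(rbind, segs),
    junctions = if (length(juncs)) do.call(rbind, juncs) else
      data.frame(pos = integer(), type = character()),
    variants = v$var_id,
    full_copies = if (length(delIdx)) 0L else
      sum(hap@copies[fullIdx]) %||% 0L,
    hybrid_copies = sum(hap@copies[hybIdx]))
}

#' Materialize the haplotype sequences of a diplotype
#'
#' Builds the two haplotype sequences implied by a diplotype under the
#' synthetic gene models: SNV stars substitute their alt bases into the
#' reference, repeat-defined stars set the promoter TA unit count between
#' the anchors, multi-copy haplotypes concatenate gene copies separated by a
#' fixed spacer, hybrid components splice paralog sequence downstream of the
#' junction, and the deletion allele fuses the flanking sequences (leaving a
#' deletion junction). Each haplotype carries a segment map (haplotype
#' interval -> gene-model interval) and junction records; these are what an
#' alignment would provide downstream.
#'
#' @param d a \code{\linkS4class{Diplotype}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @return list with elements \code{gene}, \code{diplotype}, \code{haps}
#'   (list \code{A}/\code{B}: \code{seq}, \code{segments}, \code{junctions},
#'   \code{ta_units} where applicable), \code{truth} (phased variant matrix:
#'   \code{var_id}, \code{coord}, \code{A}, \code{B}) and \code{cn}
#'   (copy-number profile, structural loci only).
#' @export
materializeHaplotypes <- function(d, cat) {
  gm <- geneModel(cat, d@gene)
  build <- function(h) {
    if (!is.null(gm$paralog)) materializeStructuralHap(cat, gm, h)
    else if (!is.null(gm$repeat_locus)) materializeRepeatHap(cat, gm, h)
    else materializeSnvHap(cat, gm, h)
  }
  hapA <- build(d@hapA); hapB <- build(d@hapB)
  v <- cat@variants[cat@variants$gene == d@gene, , drop = FALSE]
  A <- as.integer(v$var_id %in% hapA$variants)
  B <- as.integer(v$var_id %in% hapB$variants)
  keep <- A + B > 0L
  truth <- data.frame(var_id = v$var_id[keep], coord = v$coord[keep],
    A = A[keep], B = B[keep])
  truth <- truth[order(truth$coord), , drop = FALSE]
  rownames(truth) <- NULL
  cn <- NULL
  if (!is.null(gm$paralog))
    cn <- list(gene_copies = hapA$full_copies + hapB$full_copies,
      paralog_copies = 2L,
      hybrid_copies = hapA$hybrid_copies + hapB$hybrid_copies,
      deletion = nrow(hapA$junctions[hapA$junctions$type == "deletion", ]) +
        nrow(hapB$junctions[hapB$junctions$type == "deletion", ]) > 0L)
  list(gene = d@gene, diplotype = d, haps = list(A = hapA, B = hapB),
    truth = truth, cn = cn)
}

injectErrors <- function(seqs, rate) {
  if (rate <= 0) return(list(seqs = seqs, n = integer(length(seqs))))
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos],
      function(b) sample(setdiff(BASES, b), 1L), "", USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, n = nerr)
}

#' Simulate reads from a materialized diplotype
#'
#' Uniform start positions, per-base substitution errors at the configured
#' rate, haplotype of origin recorded as hidden truth. The paired regime
#' emits two reads per fragment, one at each fragment end. No aligner is run:
#' reads keep their true haplotype-local coordinates.
#'
#' @param mat output of \code{\link{materializeHaplotypes}}.
#' @param regime a \code{\linkS4class{RegimeConfig}}.
#' @param seed optional integer; when given, simulation is reproducible and
#'   leaves the caller's RNG state untouched.
#' @return a \code{\linkS4class{SimReadSet}}.
#' @export
simulateReads <- function(mat, regime, seed = NULL) {
  run <- function() {
    out <- list()
    for (h in c("A", "B")) {
      seq <- mat$haps[[h]]$seq
      L <- nchar(seq)
      rl <- regime@readLength
      if (rl > L)
        stop("read length ", rl, " exceeds haplotype length ", L)
      # starts are drawn from a window padded by one read length on each
      # side and reads are clipped to the locus, so that coverage is
      # uniform along the whole haplotype (the locus is embedded in a
      # larger captured region, as in real data)
      if (regime@name == "LRS") {
        n <- max(1L, round(regime@depth / 2 * (L + rl - 1L) / rl))
        starts0 <- sample.int(L + rl - 1L, n, replace = TRUE) - rl + 1L
        starts <- pmax(starts0, 1L)
        ends <- pmin(starts0 + rl - 1L, L)
        seqs <- substring(seq, starts, ends)
        err <- injectErrors(seqs, regime@errorRate)
        out[[h]] <- data.frame(
          read_id = sprintf("%s_%s_%04d", mat$gene, h, seq_len(n)),
          hap = h, start = starts, end = ends,
          seq = err$seqs, fragment = sprintf("%s_%s_f%04d", mat$gene, h,
            seq_len(n)), n_errors = err$n)
      } else {
        fl <- regime@fragmentLength
        if (fl > L) stop("fragment length exceeds haplotype length")
        nf <- max(1L, round(regime@depth / 2 * (L + fl - 1L) / (2 * rl)))
        fs <- sample.int(L + fl - 1L, nf, replace = TRUE) - fl + 1L
        starts0 <- c(fs, fs + fl - rl)
        starts <- pmax(starts0, 1L)
        ends <- pmin(starts0 + rl - 1L, L)
        keep <- ends - starts + 1L >= 30L  # drop mates clipped to stubs
        frag <- rep(sprintf("%s_%s_f%04d", mat$gene, h, seq_len(nf)), 2L)
        ids <- sprintf("%s_%s_%04d_%d", mat$gene, h,
          rep(seq_len(nf), 2L), rep(1:2, each = nf))
        seqs <- substring(seq, starts[keep], ends[keep])
        err <- injectErrors(seqs, regime@errorRate)
        out[[h]] <- data.frame(
          read_id = ids[keep], hap = h, start = starts[keep],
          end = ends[keep], seq = err$seqs, fragment = frag[keep],
          n_errors = err$n)
      }
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    new("SimReadSet", gene = mat$gene, reads = reads, haps = mat$haps,
      regime = regime)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a normalized depth / junction-read profile for a CN profile
#'
#' Models the copy-number signal of the structural locus directly: the
#' expected gene:paralog depth ratio is \code{n_gene / n_paralog} relative to
#' the 2/2 diploid baseline, hybrid junction reads are proportional to the
#' number of hybrid copies, and noise is multiplicative with configurable
#' coefficient of variation (\code{cv = 0} gives the noiseless expectation).
#'
#' @param cn integer vector \code{c(gene, paralog, hybrid)} copy numbers;
#'   paralog copies must be >= 1 (it is the normalizer).
#' @param regime a \code{\linkS4class{RegimeConfig}}.
#' @param cat a \code{\linkS4class{PgxCatalog}} (for junction geometry).
#' @param gene structural gene symbol.
#' @param cv coefficient of variation of the multiplicative depth noise
#'   (default 3\%, typical of normalized coverage between nearby regions in
#'   high-depth capture data).
#' @param seed optional integer seed.
#' @return list with \code{ratio} (normalized gene:paralog depth ratio) and
#'   \code{junction_reads}.
#' @export
simulateDepthProfile <- function(cn, regime, cat, gene = "CYP2D6", cv = 0.03,
    seed = NULL) {
  if (cn[2] < 1L) stop("paralog copies must be >= 1")
  gm <- geneModel(cat, gene)
  jexp <- regime@depth / 2 *
    (regime@readLength - 2 * gm$junction_flank) / regime@readLength
  run <- function() {
    ratio <- (cn[1] / cn[2]) * 2 / 2
    j <- cn[3] * jexp
    if (cv > 0) {
      ratio <- ratio * exp(stats::rnorm(1, 0, cv))
      j <- stats::rpois(1, j)
    }
    list(ratio = ratio, junction_reads = j)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
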