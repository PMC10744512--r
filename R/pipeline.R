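#' @include AllClasses.R catalog.R simulate.R phasing.R star_calling.R scoring.R
NULL

# genotype-calling constants: minimum depth per site, het allele-fraction band
MIN_SITE_DEPTH <- 8L
HET_AF <- c(0.15, 0.85)

#' Call genotypes at all catalog variant sites from simulated reads
#'
#' Projects every read onto the gene-model frame through the segment maps
#' and counts ref/alt bases at each catalog variant coordinate. Sites with
#' coverage below the minimum depth are no-calls; the allele fraction
#' decides ref / het / hom-alt. Note that multi-copy haplotypes shift het
#' allele fractions away from 1/2 (e.g. 2 alt copies of 3 give ~2/3), which
#' the het band accommodates.
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @return data.frame with columns \code{var_id}, \code{coord}, \code{cov},
#'   \code{nalt}, \code{af}, \code{gt} (ref/het/hom/nocall).
#' @export
callGenotypes <- function(rs, cat) {
  gm <- geneModel(cat, rs@gene)
  v <- cat@variants[cat@variants$gene == rs@gene, , drop = FALSE]
  pos <- locusPosition(gm, v$coord)
  cov <- nalt <- integer(length(pos))
  reads <- rs@reads
  segsByHap <- lapply(rs@haps, function(h) {
    s <- h$segments
    s[s$region == rs@gene, , drop = FALSE]
  })
  for (i in seq_len(nrow(reads))) {
    seg <- segsByHap[[reads$hap[i]]]
    for (j in seq_along(pos)) {
      hit <- which(seg$region_start <= pos[j] &
        (seg$region_start + (seg$hap_end - seg$hap_start)) >= pos[j])
      for (hs in hit) {
        hp <- seg$hap_start[hs] + (pos[j] - seg$region_start[hs])
        if (hp >= reads$start[i] && hp <= reads$end[i]) {
          b <- substr(reads$seq[i], hp - reads$start[i] + 1L,
            hp - reads$start[i] + 1L)
          if (b == v$alt[j]) { cov[j] <- cov[j] + 1L; nalt[j] <- nalt[j] + 1L }
          else if (b == v$ref[j]) cov[j] <- cov[j] + 1L
          # bases matching neither allele are sequencing errors: uncounted
        }
      }
    }
  }
  af <- ifelse(cov > 0L, nalt / cov, NA_real_)
  gt <- ifelse(cov < MIN_SITE_DEPTH, "nocall",
    ifelse(af >= HET_AF[2], "hom",
      ifelse(af >= HET_AF[1], "het", "ref")))
  data.frame(var_id = v$var_id, coord = v$coord, cov = cov, nalt = nalt,
    af = af, gt = gt)
}

phaseWithinBlocks <- function(obs, sites, blocks) {
  k <- length(sites)
  hapA <- integer(k); mec <- 0L; outBlocks <- list()
  for (b in blocks) {
    sub <- phaseDirect(obs[, b, drop = FALSE], sites = sites[b])
    hapA[b] <- sub@hapA
    mec <- mec + sub@mec
    for (sb in sub@blocks) outBlocks <- c(outBlocks, list(b[sb]))
  }
  new("PhaseResult", sites = as.integer(sites), hapA = hapA,
    blocks = outBlocks, mec = mec, method = "blockmodel", metadata = list())
}

#' Call a diplotype at a diploid SNV locus (NAT2-like)
#'
#' Genotypes the catalog sites, phases the heterozygous ones either directly
#' from reads (minimum error correction) or by the statistical emulation
#' (read-backed phase within fragment-reach blocks, frequency-driven joins
#' across blocks), and assigns star alleles per haplotype.
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param method \code{"direct"} or \code{"statistical"}.
#' @param blockLength phasing reach (bp) used by the statistical block model.
#' @return list with \code{diplotype}, \code{phase}, \code{genotypes},
#'   \code{status}.
#' @export
callSnvDiplotype <- function(rs, cat, method = c("direct", "statistical"),
    blockLength = 200L) {
  method <- match.arg(method)
  gene <- rs@gene
  gt <- callGenotypes(rs, cat)
  if (any(gt$gt == "nocall"))
    return(list(diplotype = NULL, phase = NULL, genotypes = gt,
      status = "no_call"))
  hets <- gt[gt$gt == "het", , drop = FALSE]
  homs <- gt[gt$gt == "hom", , drop = FALSE]
  ph <- NULL
  if (nrow(hets)) {
    ob <- extractObservations(rs, hets$coord, cat)
    if (method == "direct") {
      ph <- phaseDirect(ob, sites = hets$coord)
    } else {
      gm <- geneModel(cat, gene)
      blocks <- computePhaseBlocks(locusPosition(gm, hets$coord),
        blockLength)
      within <- phaseWithinBlocks(ob$obs, hets$coord, blocks)
      ph <- phaseStatistical(within, cat, gene, homVariants = homs$var_id)
    }
    idsA <- c(hets$var_id[ph@hapA == 1L], homs$var_id)
    idsB <- c(hets$var_id[ph@hapA == 0L], homs$var_id)
  } else {
    idsA <- idsB <- homs$var_id
  }
  d <- Diplotype(Haplotype(gene, assignStars(idsA, cat, gene)),
    Haplotype(gene, assignStars(idsB, cat, gene)))
  list(diplotype = d, phase = ph, genotypes = gt, status = "ok")
}

#' Call a diplotype at the promoter repeat locus (UGT1A1-like)
#'
#' Counts TA repeats from spanning reads, genotypes the distal promoter
#' marker SNVs, and labels each haplotype by its repeat allele — or by the
#' functional promoter SNV allele (*60) when present on a reference-length
#' (six TA) haplotype; the decreased-function repeat alleles take naming
#' precedence over the marker SNVs.
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param minReads minimum spanning reads per repeat mode.
#' @return list with \code{diplotype}, \code{ta}, \code{markers} (named
#'   genotype vector for the marker SNVs), \code{genotypes}, \code{status}.
#' @export
callRepeatDiplotype <- function(rs, cat, minReads = 3L) {
  gene <- rs@gene
  ta <- countTaRepeats(rs, cat, minReads)
  gt <- callGenotypes(rs, cat)
  markers <- stats::setNames(
    c(ref = "hom_ref", het = "het", hom = "hom_alt",
      nocall = "nocall")[gt$gt],
    vapply(gt$var_id, function(id)
      starForVariant(cat, gene, id), ""))
  if (ta$status != "ok")
    return(list(diplotype = NULL, ta = ta, markers = markers,
      genotypes = gt, status = "no_call"))
  labels <- ta$stars
  s60 <- gt[match("*60", names(markers)), , drop = FALSE]
  if (nrow(s60) && !is.na(s60$gt)) {
    if (s60$gt == "hom") {
      labels[labels == "*1"] <- "*60"
    } else if (s60$gt == "het") {
      u <- markerRepeatAllele(rs, cat, s60$coord)
      target <- if (!is.na(u) && u %in% ta$units) which(ta$units == u)[1L]
        else which(labels == "*1")[1L]
      if (!is.na(target) && labels[target] == "*1") labels[target] <- "*60"
    }
  }
  d <- Diplotype(Haplotype(gene, labels[1L]), Haplotype(gene, labels[2L]))
  list(diplotype = d, ta = ta, markers = markers, genotypes = gt,
    status = "ok")
}

starForVariant <- function(cat, gene, varId) {
  a <- cat@alleles[cat@alleles$gene == gene, , drop = FALSE]
  hit <- vapply(a$defining_variants, function(dv) identical(dv, varId), TRUE)
  if (any(hit)) a$star[hit][1L] else varId
}

# repeat-unit count carried by the haplotype bearing the alt allele at a
# marker SNV: majority unit count among alt-bearing repeat-spanning reads
markerRepeatAllele <- function(rs, cat, coord) {
  gm <- geneModel(cat, rs@gene)
  rl <- gm$repeat_locus
  v <- cat@variants[cat@variants$gene == rs@gene, , drop = FALSE]
  alt <- v$alt[v$coord == coord]
  pos <- locusPosition(gm, coord)
  units <- integer()
  for (i in seq_len(nrow(rs@reads))) {
    r <- rs@reads[i, ]
    if (r$start > pos || r$end < pos) next  # marker upstream of the repeat
    b <- substr(r$seq, pos - r$start + 1L, pos - r$start + 1L)
    if (b != alt) next
    hits <- matchWithMismatch(r$seq, rl$anchor_left, 1L)
    for (h in hits) {
      n <- countUnitsAt(r$seq, h + nchar(rl$anchor_left), rl$unit)
      raAt <- h + nchar(rl$anchor_left) + n * nchar(rl$unit)
      if (raAt + nchar(rl$anchor_right) - 1L > nchar(r$seq)) next
      units <- c(units, n)
      break
    }
  }
  if (!length(units)) return(NA_integer_)
  tab <- table(units)
  as.integer(names(tab)[which.max(tab)])
}

basesInWindow <- function(rs, region, window) {
  tot <- 0
  reads <- rs@reads
  for (i in seq_len(nrow(reads))) {
    seg <- rs@haps[[reads$hap[i]]]$segments
    seg <- seg[seg$region == region, , drop = FALSE]
    for (s in seq_len(nrow(seg))) {
      a <- max(reads$start[i], seg$hap_start[s])
      b <- min(reads$end[i], seg$hap_end[s])
      if (a > b) next
      ra <- seg$region_start[s] + (a - seg$hap_start[s])
      rb <- seg$region_start[s] + (b - seg$hap_start[s])
      ov <- min(rb, window[2]) - max(ra, window[1]) + 1L
      if (ov > 0L) tot <- tot + ov
    }
  }
  tot
}

junctionReadIndices <- function(rs, type, f = 100L) {
  reads <- rs@reads
  idx <- integer()
  for (i in seq_len(nrow(reads))) {
    j <- rs@haps[[reads$hap[i]]]$junctions
    j <- j[j$type == type, , drop = FALSE]
    if (!nrow(j)) next
    if (any(reads$start[i] <= j$pos - f + 1L & reads$end[i] >= j$pos + f))
      idx <- c(idx, i)
  }
  idx
}

# crossing-read support per individual junction record (both haplotypes)
junctionSupport <- function(rs, type, f = 100L) {
  reads <- rs@reads
  out <- integer()
  for (h in c("A", "B")) {
    j <- rs@haps[[h]]$junctions
    j <- j[j$type == type, , drop = FALSE]
    if (!nrow(j)) next
    sub <- reads[reads$hap == h, , drop = FALSE]
    for (p in j$pos)
      out <- c(out, sum(sub$start <= p - f + 1L & sub$end >= p + f))
  }
  out
}

#' Call a diplotype at the structural locus (CYP2D6-like)
#'
#' Estimates total gene copies from the normalized depth of the
#' paralog-discriminating windows, detects hybrid and deletion junction
#' reads, genotypes and phases the star tag SNVs, distributes copies across
#' the haplotypes from the allele fractions, and assembles the diplotype
#' (hybrid components are attached to the haplotype whose phased alleles the
#' junction-crossing reads carry).
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param depthRatio normalized gene:paralog depth ratio, typically from
#'   \code{\link{simulateDepthProfile}} (the depth signal of a high-depth
#'   normalized coverage track). When \code{NULL} it is recomputed from the
#'   read set's depth windows; note that at HiFi depths (15-30x) the
#'   read-sampling noise of a few dozen multi-kb reads makes that estimate
#'   far less stable than a normalized coverage track.
#' @return list with \code{diplotype}, \code{cn}, \code{phase},
#'   \code{genotypes}, \code{status}.
#' @export
callStructuralDiplotype <- function(rs, cat, depthRatio = NULL) {
  gene <- rs@gene
  gm <- geneModel(cat, gene)
  if (is.null(depthRatio)) {
    w6 <- gm$depth_window_gene; w7 <- gm$depth_window_paralog
    c6 <- basesInWindow(rs, gene, w6) / (w6[2] - w6[1] + 1)
    c7 <- basesInWindow(rs, gm$paralog$name, w7) / (w7[2] - w7[1] + 1)
    if (c7 <= 0) stop("no paralog coverage; cannot normalize depth")
    depthRatio <- c6 / c7
  }
  hybIdx <- junctionReadIndices(rs, "hybrid", gm$junction_flank)
  hybSup <- junctionSupport(rs, "hybrid", gm$junction_flank)
  delSup <- junctionSupport(rs, "deletion", gm$junction_flank)
  # each tandem hybrid copy contributes its own junction; copies are the
  # number of independently supported junctions, not a read-count ratio
  cn <- callCnStructure(depthRatio, sum(hybSup), sum(delSup),
    hybridCopies = sum(hybSup >= 3L))
  if (cn$status != "ok")
    return(list(diplotype = NULL, cn = cn, phase = NULL, genotypes = NULL,
      status = "no_call"))
  gt <- callGenotypes(rs, cat)
  hets <- gt[gt$gt == "het", , drop = FALSE]
  homs <- gt[gt$gt == "hom", , drop = FALSE]
  T <- cn$gene_copies

  if (cn$deletion) {
    ids <- c(hets$var_id, homs$var_id)
    prof <- if (length(ids)) assignStars(ids, cat, gene) else character()
    d <- assembleDiplotype(list(A = prof, B = character()),
      list(A = max(1L, T), B = 0L), cn, cat, gene)
    return(list(diplotype = d, cn = cn, phase = NULL, genotypes = gt,
      status = "ok"))
  }

  ph <- NULL; hybridHap <- "B"
  if (nrow(hets)) {
    ob <- extractObservations(rs, hets$coord, cat)
    ph <- phaseDirect(ob, sites = hets$coord)
    idsA <- hets$var_id[ph@hapA == 1L]
    idsB <- hets$var_id[ph@hapA == 0L]
    profA <- if (length(idsA) || nrow(homs))
      assignStars(c(idsA, homs$var_id), cat, gene) else character()
    profB <- if (length(idsB) || nrow(homs))
      assignStars(c(idsB, homs$var_id), cat, gene) else character()
    if (!length(idsA)) profA <- if (nrow(homs))
      assignStars(homs$var_id, cat, gene) else character()
    # copies from allele fractions at each haplotype's het sites
    est <- function(sel) {
      if (!any(sel)) return(NA_integer_)
      af <- mean(hets$af[sel])
      max(1L, min(T - 1L, as.integer(round(af * T))))
    }
    cA <- est(ph@hapA == 1L); cB <- est(ph@hapA == 0L)
    if (is.na(cA) && is.na(cB)) { cA <- 1L; cB <- T - 1L }
    else if (is.na(cA)) cA <- T - cB
    else if (is.na(cB)) cB <- T - cA
    # hybrid attachment: vote with junction reads that cover het sites
    if (cn$hybrid_copies > 0L && length(hybIdx)) {
      frag <- rs@reads$fragment[hybIdx]
      rows <- match(frag, rownames(ob$obs))
      vote <- 0L
      for (r in rows[!is.na(rows)]) {
        o <- ob$obs[r, ]
        nn <- !is.na(o)
        if (!any(nn)) next
        mA <- sum(o[nn] == ph@hapA[nn]); mB <- sum(nn) - mA
        vote <- vote + sign(mA - mB)
      }
      hybridHap <- if (vote > 0L) "A" else "B"
    }
    d <- assembleDiplotype(list(A = profA, B = profB),
      list(A = cA, B = cB), cn, cat, gene, hybridHap = hybridHap)
  } else {
    prof <- if (nrow(homs)) assignStars(homs$var_id, cat, gene) else
      character()
    d <- assembleDiplotype(list(A = prof, B = prof),
      list(A = 1L, B = max(1L, T - 1L)), cn, cat, gene,
      hybridHap = hybridHap)
  }
  list(diplotype = d, cn = cn, phase = ph, genotypes = gt, status = "ok")
}

#' Default sequencing regime for a gene
#'
#' Long-read defaults follow the study conditions: ~5 kb reads at 30x with
#' 1\% substitution error (a 4.5 kb read length at the 4 kb structural locus
#' keeps reads within its shorter haplotypes while staying in the 1-5 kb
#' HiFi range); short reads are paired 2 x 150 bp on 350 bp fragments at
#' high depth with <1\% error.
#'
#' @param gene gene symbol.
#' @param name \code{"LRS"} or \code{"SRS"}.
#' @return a \code{\linkS4class{RegimeConfig}}.
#' @export
defaultRegime <- function(gene, name = c("LRS", "SRS")) {
  name <- match.arg(name)
  if (name == "LRS") {
    if (gene == "CYP2D6") lrsRegime(readLength = 4500L) else lrsRegime()
  } else srsRegime()
}

#' Run the full simulate-phase-call-score pipeline for one sample
#'
#' Materializes a truth diplotype, simulates reads under the chosen regime,
#' calls the diplotype back with the locus-appropriate caller, and scores
#' the phenotype (activity score and metabolizer status, or acetylator
#' status for NAT2).
#'
#' @param gene gene symbol.
#' @param diplotype truth diplotype (string or
#'   \code{\linkS4class{Diplotype}}).
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param regime a \code{\linkS4class{RegimeConfig}} (default per gene).
#' @param method phasing method for SNV loci.
#' @param seed integer seed for the simulation.
#' @return list with \code{truth} and \code{called} canonical diplotype
#'   strings, \code{concordant}, \code{phenotype}, \code{call} (full caller
#'   output) and \code{readset}.
#' @examples
#' \donttest{
#' cat <- loadCatalog()
#' runPipeline("NAT2", "*4/*6,*13", cat, seed = 1)$called
#' }
#' @export
runPipeline <- function(gene, diplotype, cat, regime = NULL,
    method = "direct", seed = 1L) {
  d <- if (is(diplotype, "Diplotype")) diplotype else
    parseDiplotype(gene, diplotype)
  if (is.null(regime))
    regime <- defaultRegime(gene, if (method == "statistical") "SRS" else
      "LRS")
  mat <- materializeHaplotypes(d, cat)
  rs <- simulateReads(mat, regime, seed = seed)
  gm <- geneModel(cat, gene)
  call <- if (!is.null(gm$paralog)) {
    profile <- simulateDepthProfile(
      c(mat$cn$gene_copies, mat$cn$paralog_copies, mat$cn$hybrid_copies),
      regime, cat, gene = gene, seed = seed + 499979L)
    callStructuralDiplotype(rs, cat, depthRatio = profile$ratio)
  } else if (!is.null(gm$repeat_locus)) callRepeatDiplotype(rs, cat)
    else callSnvDiplotype(rs, cat, method = method)
  called <- if (!is.null(call$diplotype)) renderDiplotype(call$diplotype)
    else NA_character_
  phenotype <- if (is.null(call$diplotype)) NA_character_
    else if (gene == "NAT2") acetylatorStatus(call$diplotype, cat)
    else activityScore(call$diplotype, cat)$phenotype
  list(truth = renderDiplotype(d), called = called,
    concordant = identical(renderDiplotype(d), called),
    phenotype = phenotype, call = call, readset = rs)
}
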