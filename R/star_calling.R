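#' @include AllClasses.R catalog.R phasing.R
NULL

#' Assign star alleles to a phased haplotype variant set
#'
#' Returns every SNV-defined star whose defining variants are all present on
#' the haplotype (composite haplotypes yield multi-star labels such as
#' \code{*5,*11,*12}); an empty variant set yields the gene's reference
#' allele (\code{*4} for NAT2, \code{*1} otherwise). Components are sorted
#' by star number.
#'
#' @param varIds character vector of var_ids present on the haplotype.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @return character vector of star names.
#' @examples
#' cat <- loadCatalog()
#' assignStars(c("c.282C>T", "c.590G>A"), cat, "NAT2")  # *6, *13
#' @export
assignStars <- function(varIds, cat, gene) {
  a <- cat@alleles[cat@alleles$gene == gene, , drop = FALSE]
  hit <- vapply(seq_len(nrow(a)), function(i) {
    dv <- a$defining_variants[[i]]
    length(dv) > 0L && all(dv %in% varIds)
  }, TRUE)
  stars <- a$star[hit]
  if (!length(stars)) stars <- a$star[a$allele_type == "reference"]
  stars[order(starNumber(stars), stars)]
}

matchWithMismatch <- function(read, pattern, maxMismatch = 1L) {
  # positions where `pattern` occurs in `read` with <= maxMismatch edits
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(read),
    max.mismatch = maxMismatch, with.indels = FALSE)
  Biostrings::start(m)
}

countUnitsAt <- function(seq, from, unit) {
  n <- 0L; i <- from
  while (substr(seq, i, i + nchar(unit) - 1L) == unit) {
    n <- n + 1L; i <- i + nchar(unit)
  }
  n
}

#' Count promoter TA repeats from spanning reads
#'
#' For each read that fully spans the repeat locus (left anchor, repeat run,
#' right anchor; anchors located allowing one mismatch), counts consecutive
#' repeat units between the anchors. Reads whose run is not immediately
#' followed by the right anchor (e.g. reads ending inside the repeat, or
#' reads with an error inside the run) are excluded. Distinct unit counts
#' supported by at least \code{minReads} spanning reads form the allele
#' modes: one mode is a homozygous call, two modes a heterozygous call, zero
#' modes a no-call for absence of coverage, more than two a no-call with
#' diagnostics.
#'
#' @param rs a \code{\linkS4class{SimReadSet}} of the repeat locus.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param minReads minimum spanning reads per mode (default 3; below this a
#'   mode is considered unsupported, mirroring loci lost at ~3x depth).
#' @return list with \code{status} (\code{"ok"}/\code{"no_call"}),
#'   \code{reason}, \code{units} (the one or two unit counts), \code{stars}
#'   (mapped star names, \code{NA} for counts without a defined allele) and
#'   \code{support} (named vector of spanning-read counts per unit count).
#' @export
countTaRepeats <- function(rs, cat, minReads = 3L) {
  gm <- geneModel(cat, rs@gene)
  rl <- gm$repeat_locus
  if (is.null(rl)) stop("gene has no repeat locus")
  la <- rl$anchor_left; ra <- rl$anchor_right
  counts <- integer()
  for (i in seq_len(nrow(rs@reads))) {
    seq <- rs@reads$seq[i]
    hits <- matchWithMismatch(seq, la, 1L)
    ok <- FALSE
    for (h in hits) {
      from <- h + nchar(la)
      n <- countUnitsAt(seq, from, rl$unit)
      raAt <- from + n * nchar(rl$unit)
      if (raAt + nchar(ra) - 1L > nchar(seq)) next
      mm <- sum(strsplit(substr(seq, raAt, raAt + nchar(ra) - 1L),
        "")[[1]] != strsplit(ra, "")[[1]])
      if (mm <= 1L) { counts <- c(counts, n); ok <- TRUE; break }
    }
  }
  support <- table(counts)
  modes <- as.integer(names(support))[support >= minReads]
  if (length(modes) == 0L)
    return(list(status = "no_call", reason = "absence of coverage",
      units = integer(), stars = character(), support = support))
  if (length(modes) > 2L)
    return(list(status = "no_call", reason = "more than two repeat modes",
      units = modes, stars = character(), support = support))
  a <- cat@alleles[cat@alleles$gene == rs@gene, , drop = FALSE]
  units <- sort(modes)
  if (length(units) == 1L) units <- rep(units, 2L)
  stars <- a$star[match(units, a$ta_repeats)]
  list(status = "ok", reason = NULL, units = units, stars = stars,
    support = support)
}

#' Classify the structural form of the CYP2D6-like locus
#'
#' Converts a normalized gene:paralog depth ratio plus junction-read counts
#' into a copy-number profile and structural class. Gene copies are
#' \code{round(2 * ratio)}; a ratio further than \code{maxOffset} from the
#' nearest integer copy number is a no-call. Hybrid (and deletion) evidence
#' comes from junction reads: at least \code{minJunction} reads crossing the
#' hybrid (deletion) junction.
#'
#' @param ratio normalized gene:paralog depth ratio (1 = two diploid copies).
#' @param junctionReads hybrid junction read count.
#' @param delJunctionReads deletion junction read count.
#' @param jexp expected junction reads per hybrid copy (if known, hybrid
#'   copies are \code{round(junctionReads / jexp)}, at least 1).
#' @param minJunction junction-read threshold for structural evidence.
#' @param maxOffset maximum distance of \code{2 * ratio} from an integer.
#' @param hybridCopies optional externally determined hybrid copy count
#'   (e.g. the number of independently supported junction sites); it
#'   overrides the read-count-proportional estimate but still requires
#'   \code{minJunction} total junction reads.
#' @return list: \code{status}, \code{gene_copies}, \code{paralog_copies},
#'   \code{hybrid_copies}, \code{deletion}, \code{structural_form} (one of
#'   SNV/indel-only, deletion, duplication/multiplication, hybrid,
#'   composite), \code{ratio}.
#' @examples
#' callCnStructure(0.5, 0)$structural_form   # deletion
#' callCnStructure(1.0, 20)$structural_form  # hybrid
#' @export
callCnStructure <- function(ratio, junctionReads, delJunctionReads = 0,
    jexp = NULL, minJunction = 3L, maxOffset = 0.3, hybridCopies = NULL) {
  copies <- round(2 * ratio)
  if (abs(2 * ratio - copies) > maxOffset)
    return(list(status = "no_call", ratio = ratio,
      reason = "depth ratio between integer copy numbers"))
  hybrid <- if (junctionReads >= minJunction) {
    if (!is.null(hybridCopies)) as.integer(hybridCopies)
    else if (is.null(jexp)) 1L
    else max(1L, as.integer(round(junctionReads / jexp)))
  } else 0L
  deletion <- delJunctionReads >= minJunction
  form <-
    if (deletion && copies >= 2L) "composite"
    else if (deletion || copies < 2L) {
      if (hybrid > 0L) "composite" else "deletion"
    }
    else if (copies == 2L && hybrid == 0L) "SNV/indel-only"
    else if (copies == 2L && hybrid > 0L) "hybrid"
    else if (copies > 2L && hybrid == 0L) "duplication/multiplication"
    else "composite"
  list(status = "ok", gene_copies = as.integer(copies), paralog_copies = 2L,
    hybrid_copies = hybrid, deletion = deletion, structural_form = form,
    ratio = ratio)
}

#' Assemble a structural-locus diplotype from star profiles and CN evidence
#'
#' Distributes the total gene copies across the two haplotypes: with
#' deletion evidence, one haplotype is the deletion allele \code{*5} and the
#' partner carries all copies (the masking configuration that statistical
#' short-read callers miss); otherwise copies are attributed per haplotype
#' from the phased profiles, and hybrid components are appended in tandem
#' notation to their assigned haplotype.
#'
#' @param profiles list with components \code{A}, \code{B}: character
#'   vectors of star names per phased haplotype (may be empty).
#' @param copies list with components \code{A}, \code{B}: gene copies
#'   attributed to each haplotype.
#' @param cn output of \code{\link{callCnStructure}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @param hybridHap \code{"A"} or \code{"B"}: haplotype carrying the hybrid
#'   component(s), when any.
#' @param hybridStar star name used for hybrid junction evidence.
#' @return a \code{\linkS4class{Diplotype}}; attribute \code{unresolved} is
#'   set when CN and profile evidence conflict.
#' @export
assembleDiplotype <- function(profiles, copies, cn, cat, gene = "CYP2D6",
    hybridHap = "B", hybridStar = "*68") {
  ref <- cat@alleles$star[cat@alleles$gene == gene &
    cat@alleles$allele_type == "reference"]
  unresolved <- FALSE
  if (isTRUE(cn$deletion)) {
    stars <- unique(c(profiles$A, profiles$B))
    stars <- setdiff(stars, ref)
    if (!length(stars)) stars <- ref
    tot <- max(1L, cn$gene_copies)
    hap1 <- if (length(stars) == 1L) Haplotype(gene, stars, tot) else {
      unresolved <- TRUE
      Haplotype(gene, stars, 1L)
    }
    hap2 <- Haplotype(gene, "*5")
    d <- Diplotype(hap1, hap2)
  } else {
    mk <- function(h) {
      st <- profiles[[h]]; cp <- copies[[h]]
      if (!length(st)) st <- ref
      hyb <- if (cn$hybrid_copies > 0L && hybridHap == h)
        cn$hybrid_copies else 0L
      stars <- st
      cps <- rep(max(1L, cp), length(st))
      if (length(st) > 1L) cps <- rep(1L, length(st))
      if (hyb > 0L) { stars <- c(stars, hybridStar); cps <- c(cps, hyb) }
      Haplotype(gene, stars, cps)
    }
    if (copies$A + copies$B != cn$gene_copies) unresolved <- TRUE
    d <- Diplotype(mk("A"), mk("B"))
  }
  attr(d, "unresolved") <- unresolved
  d
}
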