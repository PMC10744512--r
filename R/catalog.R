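#' @include AllClasses.R diplotype.R
NULL

BASES <- c("A", "C", "G", "T")

#' Path to a packaged fixture file
#'
#' @param ... file name components under the package's \code{extdata}.
#' @return absolute file path.
#' @export
pgxFixture <- function(...) {
  p <- system.file("extdata", ..., package = "pgxphase", mustWork = TRUE)
  p
}

readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
    quote = "", stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = "NA")
}

randomBases <- function(n, seed) {
  withr::with_seed(seed, paste(sample(BASES, n, replace = TRUE),
    collapse = ""))
}

# Replace occurrences of `pattern` other than the one at `keep_at` so that
# anchors occur exactly once in the reference.
scrubExtraOccurrences <- function(seq, pattern, keep_at) {
  repeat {
    hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits != keep_at]
    if (!length(hits)) return(seq)
    i <- hits[1]
    old <- substr(seq, i, i)
    substr(seq, i, i) <- BASES[(match(old, BASES)) %% 4L + 1L]
  }
}

buildGeneModel <- function(gene, cfg, shared, variants) {
  gm <- list(gene = gene,
    locus_length = as.integer(cfg$locus_length),
    coordinate_frame = cfg$coordinate_frame,
    cds_offset = as.integer(cfg$cds_offset %||% 0L),
    seed = as.integer(cfg$seed),
    spacer = as.integer(shared$spacer),
    flank = as.integer(shared$flank),
    junction_flank = as.integer(shared$junction_flank))
  ref <- randomBases(gm$locus_length, gm$seed)

  if (!is.null(cfg$repeat_locus)) {
    rl <- cfg$repeat_locus
    rl$position <- as.integer(rl$position)
    rl$ref_units <- as.integer(rl$ref_units)
    la <- rl$anchor_left; ra <- rl$anchor_right
    units <- strrep(rl$unit, rl$ref_units)
    laStart <- rl$position - nchar(la)
    raStart <- rl$position + nchar(units)
    substr(ref, laStart, rl$position - 1L) <- la
    substr(ref, rl$position, raStart - 1L) <- units
    substr(ref, raStart, raStart + nchar(ra) - 1L) <- ra
    # anchors must be unique, and no stray TA unit may touch the planted run
    ref <- scrubExtraOccurrences(ref, la, laStart)
    ref <- scrubExtraOccurrences(ref, ra, raStart)
    gm$repeat_locus <- rl
  }

  if (!is.null(cfg$paralog)) {
    gm$paralog <- list(name = cfg$paralog$name,
      length = as.integer(cfg$paralog$length),
      junction = as.integer(cfg$paralog$junction),
      seed = as.integer(cfg$paralog$seed))
    gm$paralog$sequence <- randomBases(gm$paralog$length, gm$paralog$seed)
    gm$depth_window_gene <- as.integer(unlist(cfg$depth_window_gene))
    gm$depth_window_paralog <- as.integer(unlist(cfg$depth_window_paralog))
  }

  # force declared reference bases at variant positions
  v <- variants[variants$gene == gene, , drop = FALSE]
  if (nrow(v)) {
    pos <- v$coord + gm$cds_offset
    if (any(pos < 1L | pos > gm$locus_length))
      stop("variant coordinates outside the ", gene, " locus")
    for (i in seq_len(nrow(v))) substr(ref, pos[i], pos[i]) <- v$ref[i]
  }
  gm$reference_sequence <- ref
  gm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validateCatalog <- function(cat) {
  v <- cat@variants
  for (g in unique(v$gene)) {
    cd <- v$coord[v$gene == g]
    if (anyDuplicated(cd))
      stop("duplicate variant coordinate in gene ", g)
  }
  if (any(v$ref == v$alt)) stop("ref and alt base must differ")
  a <- cat@alleles
  for (i in seq_len(nrow(a))) {
    dv <- a$defining_variants[[i]]
    if (length(dv)) {
      known <- v$var_id[v$gene == a$gene[i]]
      miss <- setdiff(dv, known)
      if (length(miss))
        stop("star allele ", a$gene[i], a$star[i],
          " references undefined variant(s): ", paste(miss, collapse = ", "))
    }
    if (a$function_class[i] == "none" &&
        (is.na(a$activity[i]) || a$activity[i] != 0))
      stop("allele ", a$gene[i], a$star[i],
        " has function class 'none' but nonzero activity")
  }
  for (gm in cat@geneModels) {
    if (!is.null(gm$repeat_locus)) {
      for (anch in c(gm$repeat_locus$anchor_left,
                     gm$repeat_locus$anchor_right)) {
        n <- length(gregexpr(anch, gm$reference_sequence,
          fixed = TRUE)[[1]])
        if (n != 1L) stop("repeat anchor not unique in ", gm$gene)
      }
    }
    cd <- v$coord[v$gene == gm$gene]
    if (length(cd) && any(cd < 1L | cd > gm$locus_length))
      stop("variant coordinate outside [1, locus_length] in ", gm$gene)
  }
  ov <- cat@overrides
  for (i in seq_len(nrow(ov))) {
    d <- tryCatch(parseDiplotype(ov$gene[i], ov$diplotype[i]),
      error = function(e) stop("override key does not parse as a diplotype: ",
        ov$diplotype[i]))
    stars <- c(d@hapA@stars, d@hapB@stars)
    miss <- setdiff(stars, a$star[a$gene == ov$gene[i]])
    if (length(miss))
      stop("override key uses unknown star(s): ", paste(miss, collapse = ","))
  }
  invisible(cat)
}

#' Load the star-allele catalog
#'
#' Reads the allele and variant definition tables, the gene-model
#' configuration (reference sequences are generated deterministically from
#' the per-gene seeds), the phenotype threshold bands and activity override
#' table, and the population haplotype-frequency table, then validates all
#' cross-references eagerly: every defining variant must resolve, variant
#' coordinates must be unique per gene and fall inside the locus, repeat
#' anchors must occur exactly once in the reference, and override keys must
#' parse as diplotypes of known stars.
#'
#' @param dir directory holding the catalog files; defaults to the fixtures
#'   shipped with the package.
#' @return a validated \code{\linkS4class{PgxCatalog}}.
#' @examples
#' cat <- loadCatalog()
#' variantDistance(cat, "NAT2", "*13", "*6")
#' @export
loadCatalog <- function(dir = system.file("extdata", package = "pgxphase")) {
  pth <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing catalog file: ", p)
    p
  }
  variants <- readTsv(pth("variants.tsv"))
  variants$coord <- as.integer(variants$coord)
  alleles <- readTsv(pth("alleles.tsv"))
  alleles$defining_variants <- lapply(alleles$defining_variants,
    function(s) if (s == "-") character() else strsplit(s, ",")[[1]])
  alleles$core_variant[alleles$core_variant == "-"] <- NA_character_
  alleles$ta_repeats <- suppressWarnings(as.integer(alleles$ta_repeats))
  alleles$activity_class <- ifelse(alleles$activity == "unknown",
    "unknown", "known")
  alleles$activity <- suppressWarnings(as.numeric(alleles$activity))

  gmcfg <- yaml::read_yaml(pth("gene_models.yaml"))
  shared <- gmcfg[c("spacer", "flank", "junction_flank")]
  geneModels <- lapply(names(gmcfg$genes), function(g)
    buildGeneModel(g, gmcfg$genes[[g]], shared, variants))
  names(geneModels) <- names(gmcfg$genes)

  thr <- yaml::read_yaml(pth("thresholds.yaml"))
  ovl <- list()
  for (g in names(thr$overrides)) {
    o <- thr$overrides[[g]]
    ovl[[g]] <- data.frame(gene = g, diplotype = names(o),
      activity = as.numeric(unlist(o)), stringsAsFactors = FALSE)
  }
  overrides <- if (length(ovl)) do.call(rbind, ovl) else
    data.frame(gene = character(), diplotype = character(),
      activity = numeric())
  rownames(overrides) <- NULL
  bands <- thr$bands
  bands$acetylator <- thr$acetylator
  bands$ambiguity <- thr$ambiguity

  frequencies <- readTsv(pth("haplotype_frequencies.tsv"))

  cat <- new("PgxCatalog", alleles = alleles, variants = variants,
    geneModels = geneModels, overrides = overrides, bands = bands,
    frequencies = frequencies)
  validateCatalog(cat)
}

#' Write a catalog back to a directory of fixture files
#'
#' \code{loadCatalog(saveCatalog(cat, dir))} reproduces an identical catalog
#' (reference sequences are regenerated from the stored seeds).
#'
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly usable as input to \code{loadCatalog}.
#' @export
saveCatalog <- function(cat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cat@variants
  utils::write.table(v, file.path(dir, "variants.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  a <- cat@alleles
  a$defining_variants <- vapply(a$defining_variants,
    function(x) if (length(x)) paste(x, collapse = ",") else "-", "")
  a$core_variant[is.na(a$core_variant)] <- "-"
  a$activity <- ifelse(a$activity_class == "unknown", "unknown",
    as.character(a$activity))
  a$activity_class <- NULL
  utils::write.table(a, file.path(dir, "alleles.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  gm1 <- cat@geneModels[[1]]
  genes <- lapply(cat@geneModels, function(gm) {
    out <- list(locus_length = gm$locus_length,
      coordinate_frame = gm$coordinate_frame)
    if (gm$cds_offset) out$cds_offset <- gm$cds_offset
    out$seed <- gm$seed
    if (!is.null(gm$repeat_locus))
      out$repeat_locus <- gm$repeat_locus
    if (!is.null(gm$paralog)) {
      out$paralog <- gm$paralog[c("name", "length", "junction", "seed")]
      out$depth_window_gene <- gm$depth_window_gene
      out$depth_window_paralog <- gm$depth_window_paralog
    }
    out
  })
  yaml::write_yaml(list(spacer = gm1$spacer, flank = gm1$flank,
    junction_flank = gm1$junction_flank, genes = genes),
    file.path(dir, "gene_models.yaml"))
  ov <- split(cat@overrides, cat@overrides$gene)
  thr <- list(bands = cat@bands[setdiff(names(cat@bands),
      c("acetylator", "ambiguity"))],
    overrides = lapply(ov, function(d)
      as.list(stats::setNames(d$activity, d$diplotype))),
    acetylator = cat@bands$acetylator,
    ambiguity = cat@bands$ambiguity)
  yaml::write_yaml(thr, file.path(dir, "thresholds.yaml"))
  utils::write.table(cat@frequencies,
    file.path(dir, "haplotype_frequencies.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Gene model accessor
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @return the gene-model list (reference sequence, repeat locus, paralog,
#'   coordinate frame, simulation geometry).
#' @export
geneModel <- function(cat, gene) {
  gm <- cat@geneModels[[gene]]
  if (is.null(gm)) stop("unknown gene: ", gene)
  gm
}

alleleRow <- function(cat, gene, star) {
  i <- which(cat@alleles$gene == gene & cat@alleles$star == star)
  if (!length(i)) stop("unknown star allele: ", gene, " ", star)
  cat@alleles[i, , drop = FALSE]
}

#' Star-allele lookups
#'
#' \code{functionClass} returns the stored clinical function class of an
#' allele; \code{activityValue} its per-copy activity value (\code{NA} when
#' unknown); \code{acetylationClass} its acetylator class (NAT2);
#' \code{taRepeatsOf} its promoter TA unit count; \code{starAlleles} all star
#' names defined for a gene.
#'
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @param star star-allele name, e.g. \code{"*41"}.
#' @return see above; scalar per call.
#' @examples
#' cat <- loadCatalog()
#' functionClass(cat, "CYP2D6", "*41")
#' @export
functionClass <- function(cat, gene, star) alleleRow(cat, gene,
  star)$function_class

#' @rdname functionClass
#' @export
activityValue <- function(cat, gene, star) alleleRow(cat, gene, star)$activity

#' @rdname functionClass
#' @export
acetylationClass <- function(cat, gene, star) alleleRow(cat, gene,
  star)$acetylation_class

#' @rdname functionClass
#' @export
taRepeatsOf <- function(cat, gene, star) alleleRow(cat, gene,
  star)$ta_repeats

#' @rdname functionClass
#' @export
starAlleles <- function(cat, gene) cat@alleles$star[cat@alleles$gene == gene]

coreCoord <- function(cat, gene, star) {
  a <- alleleRow(cat, gene, star)
  if (is.na(a$core_variant))
    stop("star ", gene, " ", star, " has no core variant")
  v <- cat@variants
  v$coord[v$gene == gene & v$var_id == a$core_variant]
}

#' Distance between the core defining SNVs of two star alleles
#'
#' The physical separation (bp) of the single core SNVs that define two star
#' alleles in the same gene's coordinate frame. This is the quantity that
#' decides whether a short-read fragment can phase the two alleles directly.
#'
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @param starA,starB star names; each must have exactly one core SNV.
#' @return nonnegative integer distance in bp.
#' @examples
#' cat <- loadCatalog()
#' variantDistance(cat, "NAT2", "*13", "*6")  # 308
#' @export
variantDistance <- function(cat, gene, starA, starB) {
  abs(coreCoord(cat, gene, starA) - coreCoord(cat, gene, starB))
}

#' Read a packaged call-set or cohort-spread fixture
#'
#' \code{readCallSets} returns the transcribed 13-sample call set for one
#' method (\code{"SRS"} or \code{"LRS"}) as a data.frame with columns
#' \code{sample}, \code{gene}, \code{diplotype}, \code{phenotype},
#' \code{markers}. \code{readSpreadTable} returns a cohort diplotype spread
#' (\code{"cyp2d6"} or \code{"nat2"}) with columns \code{category}/
#' \code{type}, \code{diplotype}, \code{count}.
#'
#' @param method \code{"SRS"} or \code{"LRS"}.
#' @return data.frame; see above.
#' @export
readCallSets <- function(method = c("SRS", "LRS")) {
  method <- match.arg(method)
  f <- if (method == "SRS") "callsets_srs.tsv" else "callsets_lrs.tsv"
  readTsv(pgxFixture(f))
}

#' @rdname readCallSets
#' @param which \code{"cyp2d6"} or \code{"nat2"}.
#' @export
readSpreadTable <- function(which = c("cyp2d6", "nat2")) {
  which <- match.arg(which)
  readTsv(pgxFixture(paste0(which, "_spread.tsv")))
}
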