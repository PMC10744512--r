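#' @include AllClasses.R catalog.R simulate.R
NULL

#' Write simulated reads as FASTQ
#'
#' Long-read sets yield one file; paired sets yield two files with
#' \code{_R1}/\code{_R2} suffixes. Quality lines are a constant Q30
#' placeholder (the simulator's error model is substitution-only).
#'
#' @param rs a \code{\linkS4class{SimReadSet}}.
#' @param prefix output path prefix (without extension).
#' @return character vector of the files written, invisibly.
#' @export
writeReadsFastq <- function(rs, prefix) {
  writeOne <- function(df, path) {
    seqs <- Biostrings::DNAStringSet(df$seq)
    names(seqs) <- df$read_id
    quals <- Biostrings::BStringSet(strrep("?", nchar(df$seq)))
    qs <- Biostrings::QualityScaledDNAStringSet(seqs,
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(qs, path)
    path
  }
  if (rs@regime@name == "LRS") {
    invisible(writeOne(rs@reads, paste0(prefix, ".fastq")))
  } else {
    m1 <- grepl("_1$", rs@reads$read_id)
    invisible(c(writeOne(rs@reads[m1, ], paste0(prefix, "_R1.fastq")),
      writeOne(rs@reads[!m1, ], paste0(prefix, "_R2.fastq"))))
  }
}

#' Read a FASTQ file back as a data.frame
#'
#' @param path FASTQ file.
#' @return data.frame with columns \code{read_id}, \code{seq}.
#' @export
readReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x))
}

#' Write a gene's synthetic reference as FASTA
#'
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param gene gene symbol.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReferenceFasta <- function(cat, gene, path) {
  gm <- geneModel(cat, gene)
  x <- Biostrings::DNAStringSet(gm$reference_sequence)
  names(x) <- gene
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a truth variant matrix as a phased VCF
#'
#' Emits a minimal VCFv4.2 with phased genotypes (\code{|}) and a PS phase
#' set tag; positions are 1-based locus-window coordinates.
#'
#' @param mat output of \code{\link{materializeHaplotypes}}.
#' @param cat a \code{\linkS4class{PgxCatalog}}.
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @param seed optional integer recorded in the header for provenance.
#' @return \code{path}, invisibly.
#' @export
writeTruthVcf <- function(mat, cat, path, sample = "SAMPLE", seed = NULL) {
  gm <- geneModel(cat, mat$gene)
  v <- cat@variants[cat@variants$gene == mat$gene, , drop = FALSE]
  t <- mat$truth
  hdr <- c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", mat$gene, gm$locus_length),
    if (!is.null(seed)) sprintf("##simulation_seed=%d", as.integer(seed)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=PS,Number=1,Type=Integer,",
      "Description=\"Phase set\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample), collapse = "\t"))
  rows <- character(nrow(t))
  for (i in seq_len(nrow(t))) {
    vi <- match(t$var_id[i], v$var_id)
    rows[i] <- paste(c(mat$gene, locusPosition(gm, t$coord[i]),
      t$var_id[i], v$ref[vi], v$alt[vi], ".", "PASS", ".", "GT:PS",
      sprintf("%d|%d:1", t$A[i], t$B[i])), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a phased VCF back into a variant matrix
#'
#' Uses \pkg{VariantAnnotation} as the parser.
#'
#' @param path VCF file.
#' @return data.frame with columns \code{pos}, \code{var_id}, \code{A},
#'   \code{B}, \code{ps}.
#' @export
readPhasedVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  ps <- VariantAnnotation::geno(vcf)$PS[, 1L]
  al <- strsplit(gt, "|", fixed = TRUE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(pos = BiocGenerics::start(rr), var_id = names(rr),
    A = as.integer(vapply(al, `[`, "", 1L)),
    B = as.integer(vapply(al, `[`, "", 2L)), ps = as.integer(ps),
    row.names = NULL)
}

#' Write a phasing report as JSON
#'
#' @param phase a \code{\linkS4class{PhaseResult}}.
#' @param errors optional output of \code{\link{phaseErrors}}.
#' @param path output file.
#' @param seed optional integer recorded for provenance.
#' @return \code{path}, invisibly.
#' @export
writePhasingReport <- function(phase, path, errors = NULL, seed = NULL) {
  rep <- list(method = phase@method, sites = phase@sites,
    hapA = phase@hapA, blocks = phase@blocks, mec = phase@mec,
    metadata = phase@metadata)
  if (!is.null(errors)) rep$errors <- errors
  if (!is.null(seed)) rep$seed <- as.integer(seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
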