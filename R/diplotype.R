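#' @include AllClasses.R
NULL

starNumber <- function(star) {
  # numeric part of a star name; "*4N" -> 4, "*68" -> 68
  as.numeric(sub("^\\*([0-9]+).*$", "\\1", star))
}

#' Construct a haplotype
#'
#' @param gene gene symbol.
#' @param stars character vector of star names.
#' @param copies integer vector of per-component copy multipliers (recycled).
#' @return a \code{\linkS4class{Haplotype}} with components sorted by star
#'   number.
#' @examples
#' Haplotype("CYP2D6", c("*68", "*41"))
#' @export
Haplotype <- function(gene, stars, copies = 1L) {
  copies <- as.integer(rep_len(copies, length(stars)))
  ord <- order(starNumber(stars), stars)
  new("Haplotype", gene = gene, stars = stars[ord], copies = copies[ord])
}

#' Construct a diplotype from two haplotypes
#'
#' Haplotypes are stored in canonical order: by lowest star number, then by
#' fewer components, then by lower total copies, then by rendered string.
#'
#' @param hapA,hapB \code{\linkS4class{Haplotype}} objects of the same gene.
#' @return a \code{\linkS4class{Diplotype}}.
#' @export
Diplotype <- function(hapA, hapB) {
  stopifnot(hapA@gene == hapB@gene)
  key <- function(h) c(min(starNumber(h@stars)), length(h@stars),
    sum(h@copies))
  ka <- key(hapA); kb <- key(hapB)
  swap <- FALSE
  for (i in seq_along(ka)) {
    if (ka[i] != kb[i]) { swap <- ka[i] > kb[i]; break }
    if (i == length(ka)) swap <- renderHaplotype(hapA) > renderHaplotype(hapB)
  }
  if (swap) { tmp <- hapA; hapA <- hapB; hapB <- tmp }
  new("Diplotype", gene = hapA@gene, hapA = hapA, hapB = hapB)
}

#' Render a haplotype or diplotype as a string
#'
#' Machine output uses ASCII \code{" x N"} for copy multipliers; the Unicode
#' multiplication sign is accepted on input by \code{\link{parseDiplotype}}.
#'
#' @param h a \code{\linkS4class{Haplotype}}.
#' @return character scalar, e.g. \code{"*4 x 2,*68"}.
#' @export
renderHaplotype <- function(h) {
  paste0(h@stars, ifelse(h@copies > 1L, paste0(" x ", h@copies), ""),
    collapse = ",")
}

#' @rdname renderHaplotype
#' @param d a \code{\linkS4class{Diplotype}}.
#' @export
renderDiplotype <- function(d) {
  paste0(renderHaplotype(d@hapA), "/", renderHaplotype(d@hapB))
}

parseHaplotype <- function(gene, s) {
  s <- gsub("×", "x", s)            # unicode multiplication sign
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty haplotype string")
  stars <- character(length(parts)); copies <- integer(length(parts))
  for (i in seq_along(parts)) {
    m <- regmatches(parts[i],
      regexec("^(\\*?[0-9]+[A-Za-z]*)\\s*(?:x\\s*([0-9]+))?$", parts[i]))[[1]]
    if (!length(m)) stop("cannot parse haplotype component: ", parts[i])
    star <- m[2]
    if (!startsWith(star, "*")) star <- paste0("*", star)
    stars[i] <- star
    copies[i] <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  }
  Haplotype(gene, stars, copies)
}

#' Parse a diplotype string
#'
#' Accepts the table notation of the study, e.g. \code{"*2 x 2/*41"},
#' \code{"*2 × 2/*41"}, \code{"*5,*11,*12/*6,*13"}. Missing leading
#' \code{*} on a component (as in one printed table row) is tolerated.
#'
#' @param gene gene symbol.
#' @param s diplotype string \code{"hapA/hapB"}.
#' @return a canonical \code{\linkS4class{Diplotype}};
#'   \code{parse(render(d))} is the identity on canonical diplotypes.
#' @examples
#' renderDiplotype(parseDiplotype("CYP2D6", "*5/*2 × 2"))
#' @export
parseDiplotype <- function(gene, s) {
  halves <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("diplotype must be 'hapA/hapB': ", s)
  Diplotype(parseHaplotype(gene, halves[1]), parseHaplotype(gene, halves[2]))
}

#' Canonical string form of a diplotype
#'
#' @param gene gene symbol.
#' @param s diplotype string in any accepted notation.
#' @return the canonical rendering, suitable as a comparison or lookup key.
#' @export
canonicalDiplotype <- function(gene, s) {
  renderDiplotype(parseDiplotype(gene, s))
}
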