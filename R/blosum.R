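blosum_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 log-odds matrix (half-bit units), bundled as
#' a plain-text file so similarity scoring is bit-exact and reproducible
#' offline. Includes the ambiguity rows/columns `B`, `Z`, `X` and `*`.
#'
#' @return A 24 x 24 integer matrix with residue-letter dimnames.
#' @examples
#' blosum62()["L", "M"]
#' @export
blosum62 <- function() {
  if (is.null(blosum_cache$m)) {
    lines <- readLines(extdata_path("BLOSUM62.txt"))
    lines <- lines[!grepl("^#", lines)]
    header <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
    rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
    m <- t(vapply(rows, function(r) as.integer(r[-1]),
                  integer(length(header))))
    dimnames(m) <- list(vapply(rows, `[[`, "", 1L), header)
    blosum_cache$m <- m
  }
  blosum_cache$m
}
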