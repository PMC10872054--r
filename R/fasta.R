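#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings giving tibble in / tibble out semantics.
#' `read_fasta()` keeps only the first whitespace-delimited word of each
#' header as the record id. `write_fasta()` wraps sequence lines at 60
#' columns.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(ss), "[[:space:]]+"), `[[`, "", 1L),
    seq = unname(as.character(ss))
  )
}

#' @rdname read_fasta
#' @param records A tibble (or data frame) with columns `id` and `seq`.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  ss <- Biostrings::AAStringSet(records$seq)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
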