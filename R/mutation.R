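#' Extract substitutions from a wild type and its variants
#'
#' Variants must be length-matched to the wild type (substitutions only,
#' no indels). One substitution record is produced per position at which a
#' variant differs from the wild type; positions where either sequence has
#' the unknown letter `X` are skipped and tallied in the `skipped`
#' attribute.
#'
#' @param wild_type Normalized wild-type sequence string.
#' @param variants Tibble with columns `id`, `seq` (normalized), or a
#'   character vector of sequences.
#' @return A tibble with columns `variant_id`, `position` (1-based),
#'   `wt_residue`, `variant_residue`; attribute `skipped` counts
#'   X-containing mismatch positions that were dropped.
#' @export
extract_substitutions <- function(wild_type, variants) {
  if (is.character(variants)) {
    variants <- tibble::tibble(
      id = sprintf("variant_%d", seq_along(variants)), seq = variants
    )
  }
  wt <- str_chars(wild_type)
  skipped <- 0L
  out <- purrr::map2_dfr(variants$id, variants$seq, function(id, s) {
    if (nchar(s) != length(wt)) {
      abort_redalph(
        sprintf("variant '%s' length %d does not match wild type length %d",
                id, nchar(s), length(wt)),
        "redalph_validation_error"
      )
    }
    v <- str_chars(s)
    diff <- which(v != wt)
    has_x <- wt[diff] == AA_UNKNOWN | v[diff] == AA_UNKNOWN
    skipped <<- skipped + sum(has_x)
    diff <- diff[!has_x]
    tibble::tibble(
      variant_id = rep(id, length(diff)),
      position = diff,
      wt_residue = wt[diff],
      variant_residue = v[diff]
    )
  })
  attr(out, "skipped") <- skipped
  out
}

#' Can an alphabet distinguish a substitution from the wild type?
#'
#' A substitution is distinguishable under a reduced alphabet iff the
#' wild-type and variant residues map to different cluster indices; a
#' within-cluster substitution is encoded identically to the wild type and
#' is missed.
#'
#' @param wt_residue,variant_residue Standard residue letters (vectorized).
#' @param alphabet An `aa_alphabet` or built-in name.
#' @return Logical vector.
#' @examples
#' is_distinguishable("L", "V", "GBMR4") # FALSE: same cluster
#' is_distinguishable("G", "P", "GBMR4") # TRUE
#' @export
is_distinguishable <- function(wt_residue, variant_residue, alphabet) {
  alphabet <- as_alphabet(alphabet)
  rm <- residue_map(alphabet)
  stopifnot(all(wt_residue %in% AA_STANDARD),
            all(variant_residue %in% AA_STANDARD))
  unname(rm[wt_residue] != rm[variant_residue])
}

#' Alphabet error rate on a substitution set
#'
#' The error rate of an alphabet is the percentage of substitutions it
#' fails to distinguish from the wild type (both residues in the same
#' cluster). Substitutions are counted with multiplicity as they occur in
#' the input; set `unique_pairs = TRUE` to deduplicate to unique
#' (wild-type, variant) letter pairs first.
#'
#' @param substitutions Tibble from [extract_substitutions()] (needs
#'   columns `wt_residue`, `variant_residue`).
#' @param alphabet An `aa_alphabet` or built-in name.
#' @param unique_pairs Deduplicate to unique letter pairs before counting.
#' @return One-row tibble: `alphabet`, `n_pairs`, `n_missed`,
#'   `error_rate_percent`; attribute `missed_by_cluster` is a tibble of
#'   missed counts per cluster.
#' @export
error_rate <- function(substitutions, alphabet, unique_pairs = FALSE) {
  alphabet <- as_alphabet(alphabet)
  if (nrow(substitutions) == 0L) {
    abort_redalph("error rate is undefined on an empty substitution set",
                  "redalph_validation_error")
  }
  pairs <- substitutions
  if (unique_pairs) {
    pairs <- dplyr::distinct(pairs, .data$wt_residue, .data$variant_residue)
  }
  rm <- residue_map(alphabet)
  wt_idx <- unname(rm[pairs$wt_residue])
  missed <- !is_distinguishable(pairs$wt_residue, pairs$variant_residue,
                                alphabet)
  breakdown <- tibble::tibble(cluster_index = wt_idx[missed]) |>
    dplyr::count(.data$cluster_index, name = "n_missed") |>
    dplyr::mutate(
      letters = vapply(alphabet$clusters[.data$cluster_index + 1L],
                       paste, "", collapse = "")
    )
  out <- tibble::tibble(
    alphabet = alphabet$name,
    n_pairs = nrow(pairs),
    n_missed = sum(missed),
    error_rate_percent = 100 * mean(missed)
  )
  attr(out, "missed_by_cluster") <- breakdown
  out
}

#' Error rates across many alphabets
#'
#' @param substitutions Tibble of substitutions.
#' @param alphabets Character vector of built-in names or list of
#'   `aa_alphabet`s (default: all nine built-ins).
#' @param unique_pairs Passed to [error_rate()].
#' @return Tibble with one row per alphabet, sorted as given.
#' @export
error_rate_table <- function(substitutions, alphabets = builtin_alphabets(),
                             unique_pairs = FALSE) {
  if (is.character(alphabets)) alphabets <- lapply(alphabets, as_alphabet)
  purrr::map_dfr(alphabets, function(ab) {
    error_rate(substitutions, ab, unique_pairs = unique_pairs)
  })
}
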