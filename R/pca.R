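#' Embedding-trajectory PCA
#'
#' Projects per-token embedding snapshots taken during training into 2D,
#' one PCA per snapshot (centered, unscaled), with axis signs aligned
#' across consecutive snapshots (maximizing the coordinate correlation)
#' so token trajectories are visually continuous. Watching the 20 residue
#' embeddings drift apart stage by stage is how the systematic clustering
#' a language model discovers (hydrophobicity groups, singled-out
#' residues) is usually diagnosed.
#'
#' @param snapshots A fitted `masked_lm` (its recorded snapshots are
#'   used) or a list of `list(step, matrix)` entries; matrices must share
#'   dimensions, one row per vocabulary token, at least 2 columns.
#' @param labels Optional token labels (e.g. residue letters); defaults
#'   to rownames of the first snapshot, else `token_<i>`.
#' @return A tibble with columns `step`, `token` (0-based), `label`,
#'   `pc1`, `pc2`; attribute `explained_variance` is a tibble of
#'   per-snapshot variance fractions.
#' @export
embedding_pca_trajectory <- function(snapshots, labels = NULL) {
  if (inherits(snapshots, "masked_lm")) snapshots <- snapshots$snapshots
  stopifnot(length(snapshots) >= 1L)
  mats <- lapply(snapshots, `[[`, "matrix")
  steps <- vapply(snapshots, function(s) as.integer(s$step), 0L)
  d <- ncol(mats[[1L]])
  if (d < 2L) {
    abort_redalph("embedding dimension must be at least 2 for a 2D projection",
                  "redalph_validation_error")
  }
  v <- nrow(mats[[1L]])
  stopifnot(all(vapply(mats, nrow, 0L) == v),
            all(vapply(mats, ncol, 0L) == d))
  if (is.null(labels)) {
    labels <- rownames(mats[[1L]]) %||% sprintf("token_%d", seq_len(v) - 1L)
  }
  prev <- NULL
  coords <- vector("list", length(mats))
  ev <- matrix(0, length(mats), 2L)
  for (k in seq_along(mats)) {
    pc <- stats::prcomp(mats[[k]], center = TRUE, scale. = FALSE, rank. = 2L)
    sc <- pc$x
    if (ncol(sc) < 2L) sc <- cbind(sc, 0) # rank-deficient snapshot
    sc <- sc[, 1:2, drop = FALSE]
    if (!is.null(prev)) {
      for (j in 1:2) {
        r <- suppressWarnings(stats::cor(sc[, j], prev[, j]))
        if (!is.na(r) && r < 0) sc[, j] <- -sc[, j]
      }
    }
    prev <- sc
    coords[[k]] <- sc
    tot <- sum(pc$sdev^2)
    ev[k, ] <- if (tot > 0) (pc$sdev^2)[1:2] / tot else c(0, 0)
    ev[k, is.na(ev[k, ])] <- 0
  }
  out <- purrr::map2_dfr(seq_along(mats), coords, function(k, sc) {
    tibble::tibble(
      step = steps[k], token = seq_len(v) - 1L, label = labels,
      pc1 = sc[, 1L], pc2 = sc[, 2L]
    )
  })
  attr(out, "explained_variance") <- tibble::tibble(
    step = steps, pc1_frac = ev[, 1L], pc2_frac = ev[, 2L]
  )
  out
}
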