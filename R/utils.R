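# Internal helpers shared across modules.

#' @useDynLib redalph, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_UNKNOWN <- "X"
AA_VOCAB <- c(AA_STANDARD, AA_UNKNOWN)

abort_redalph <- function(msg, class) {
  rlang::abort(msg, class = c(class, "redalph_error"))
}

`%||%` <- rlang::`%||%`

# Split a sequence string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Derive a reproducible sub-seed for a named random stream from a run seed.
# Keeps results below 2^31 so they remain valid R integers.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}

# Evaluate an expression under a local RNG state seeded from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

extdata_path <- function(...) {
  system.file("extdata", ..., package = "redalph", mustWork = TRUE)
}
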