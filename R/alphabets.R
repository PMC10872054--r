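#' Reduced amino-acid alphabets
#'
#' A reduced amino-acid alphabet is an ordered partition of the 20 standard
#' residue letters into clusters, each cluster encoded by a single token.
#' The unknown residue `X` is never a cluster member: it is a reserved 21st
#' symbol present in every alphabet, so a K-cluster alphabet has a token
#' vocabulary of size K + 1. Cluster indices are 0-based (clusters are
#' numbered `0..K-1` in listed order, the unknown token gets index `K`) so
#' token ids are stable across runs and match the on-disk definition order.
#'
#' @param name Short identifier, e.g. `"MMSEQS12"`. If the name ends in
#'   digits, the numeric suffix is checked against the cluster count and a
#'   warning is raised on mismatch (the definition is kept as given).
#' @param spec Whitespace-separated cluster string, e.g.
#'   `"AST LM IV KR EQ ND FY C G H P W"`. Only the 20 standard residue
#'   letters are allowed; each must appear exactly once across all clusters.
#'
#' @return An object of class `aa_alphabet`: a list with fields `name`,
#'   `clusters` (ordered list of character vectors) and `unknown_token`
#'   (always `"X"`).
#'
#' @examples
#' ab <- parse_alphabet("MMSEQS12", "AST LM IV KR EQ ND FY C G H P W")
#' cluster_count(ab)
#' residue_map(ab)[c("L", "M", "X")]
#' @export
parse_alphabet <- function(name, spec) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(spec), length(spec) == 1L)
  groups <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  groups <- groups[nzchar(groups)]
  if (length(groups) == 0L) {
    abort_redalph("alphabet spec contains no clusters", "redalph_parse_error")
  }
  clusters <- lapply(groups, str_chars)
  letters_all <- unlist(clusters)
  bad <- setdiff(letters_all, AA_STANDARD)
  if (length(bad) > 0L) {
    abort_redalph(
      sprintf("non-standard residue letter(s) in alphabet spec: %s",
              paste(sort(unique(bad)), collapse = ", ")),
      "redalph_parse_error"
    )
  }
  dup <- unique(letters_all[duplicated(letters_all)])
  if (length(dup) > 0L) {
    abort_redalph(
      sprintf("duplicate residue letter(s) in alphabet spec: %s",
              paste(sort(dup), collapse = ", ")),
      "redalph_validation_error"
    )
  }
  missing <- setdiff(AA_STANDARD, letters_all)
  if (length(missing) > 0L) {
    abort_redalph(
      sprintf("alphabet spec is missing residue letter(s): %s",
              paste(sort(missing), collapse = ", ")),
      "redalph_validation_error"
    )
  }
  suffix <- regmatches(name, regexpr("[0-9]+$", name))
  if (length(suffix) == 1L && as.integer(suffix) != length(clusters)) {
    warning(sprintf(
      "alphabet '%s': name suffix %s does not match cluster count %d",
      name, suffix, length(clusters)
    ), call. = FALSE)
  }
  structure(
    list(name = name, clusters = clusters, unknown_token = AA_UNKNOWN),
    class = "aa_alphabet"
  )
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat(sprintf("<aa_alphabet> %s: %d clusters (+ unknown '%s')\n",
              x$name, cluster_count(x), x$unknown_token))
  cat(" ", alphabet_to_string(x), "\n")
  invisible(x)
}

#' Serialize an alphabet to its cluster-string form
#'
#' Inverse of [parse_alphabet()]: clusters joined by single spaces, letters
#' within a cluster concatenated, both in definition order.
#'
#' @param alphabet An `aa_alphabet`.
#' @return A single string such as `"AST LM IV KR EQ ND FY C G H P W"`.
#' @export
alphabet_to_string <- function(alphabet) {
  stopifnot(inherits(alphabet, "aa_alphabet"))
  paste(vapply(alphabet$clusters, paste, "", collapse = ""), collapse = " ")
}

#' Number of clusters in an alphabet
#'
#' Excludes the reserved unknown token, so this equals the numeric suffix
#' of the built-in alphabet names.
#'
#' @param alphabet An `aa_alphabet`.
#' @return Integer cluster count.
#' @export
cluster_count <- function(alphabet) {
  stopifnot(inherits(alphabet, "aa_alphabet"))
  length(alphabet$clusters)
}

#' Residue-to-cluster index map
#'
#' Total mapping from the 21-letter normalized vocabulary (20 standard
#' residues plus `X`) to 0-based cluster indices; `X` maps to the unknown
#' index `cluster_count(alphabet)`.
#'
#' @param alphabet An `aa_alphabet`.
#' @return Named integer vector of length 21.
#' @export
residue_map <- function(alphabet) {
  stopifnot(inherits(alphabet, "aa_alphabet"))
  k <- cluster_count(alphabet)
  idx <- integer(21L)
  names(idx) <- AA_VOCAB
  for (i in seq_len(k)) {
    idx[alphabet$clusters[[i]]] <- i - 1L
  }
  idx[AA_UNKNOWN] <- k
  idx
}

builtins_cache <- new.env(parent = emptyenv())

#' Built-in reduced alphabets
#'
#' The nine published alphabets bundled with the package: UNIPROT20 (the
#' full alphabet), UNIPROT18, HSDM17, WASS14, MMSEQS12, SDM12, GBMR7,
#' WWMJ5 and GBMR4. Definitions are read from the packaged alphabet file
#' (`inst/extdata/builtin_alphabets.tsv`) and cached.
#'
#' @return Named list of `aa_alphabet` objects, in definition-file order.
#' @examples
#' names(builtin_alphabets())
#' builtin_alphabets()[["GBMR4"]]
#' @export
builtin_alphabets <- function() {
  if (is.null(builtins_cache$alphabets)) {
    builtins_cache$alphabets <- read_alphabet_file(
      extdata_path("builtin_alphabets.tsv")
    )
  }
  builtins_cache$alphabets
}

#' Read alphabet definitions from file
#'
#' One alphabet per line, `NAME<TAB>cluster cluster ...`; lines starting
#' with `#` and blank lines are skipped.
#'
#' @param path Path to an alphabet definition file.
#' @return Named list of `aa_alphabet` objects.
#' @export
read_alphabet_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  defs <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(defs, function(d) {
    if (length(d) != 2L) {
      abort_redalph(
        "alphabet file lines must be 'NAME<TAB>cluster cluster ...'",
        "redalph_parse_error"
      )
    }
    parse_alphabet(d[[1]], d[[2]])
  })
  names(out) <- vapply(out, function(a) a$name, "")
  out
}

#' Write alphabet definitions to file
#'
#' @param alphabets A named list of `aa_alphabet` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alphabet_file <- function(alphabets, path) {
  if (inherits(alphabets, "aa_alphabet")) alphabets <- list(alphabets)
  lines <- vapply(alphabets, function(a) {
    paste0(a$name, "\t", alphabet_to_string(a))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Resolve an alphabet argument
#'
#' Accepts an `aa_alphabet` or the name of a built-in alphabet.
#'
#' @param alphabet An `aa_alphabet` object or built-in name.
#' @return An `aa_alphabet`.
#' @export
as_alphabet <- function(alphabet) {
  if (inherits(alphabet, "aa_alphabet")) return(alphabet)
  if (is.character(alphabet) && length(alphabet) == 1L) {
    ab <- builtin_alphabets()[[alphabet]]
    if (is.null(ab)) {
      abort_redalph(
        sprintf("unknown alphabet '%s'; built-ins: %s", alphabet,
                paste(names(builtin_alphabets()), collapse = ", ")),
        "redalph_validation_error"
      )
    }
    return(ab)
  }
  abort_redalph("alphabet must be an aa_alphabet or a built-in name",
                "redalph_validation_error")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an alphabet into one row per cluster
#'
#' @param x An `aa_alphabet`.
#' @param ... Unused.
#' @return A tibble with columns `alphabet`, `cluster_index` (0-based),
#'   `letters` (concatenated members) and `size`.
#' @method tidy aa_alphabet
#' @export
tidy.aa_alphabet <- function(x, ...) {
  tibble::tibble(
    alphabet = x$name,
    cluster_index = seq_along(x$clusters) - 1L,
    letters = vapply(x$clusters, paste, "", collapse = ""),
    size = lengths(x$clusters)
  )
}
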