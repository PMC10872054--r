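#' Normalize a raw protein sequence to the 21-letter vocabulary
#'
#' Non-standard residue codes are mapped the way large sequence databases
#' are preprocessed for language-model training: selenocysteine `U` becomes
#' cysteine `C`, pyrrolysine `O` becomes lysine `K`, and the ambiguity
#' codes `B` and `Z` (as well as `X` itself) become the unknown symbol
#' `X`. Lowercase input is uppercased; surrounding whitespace is stripped.
#' Any other character is an error naming the character and its position.
#'
#' @param raw A single sequence string.
#' @return A string over the 20 standard residue letters plus `X`.
#' @examples
#' normalize_sequence("UOX") # "CKX"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(s)) {
    abort_redalph("sequence is empty after whitespace stripping",
                  "redalph_validation_error")
  }
  ch <- str_chars(s)
  allowed <- c(AA_STANDARD, "U", "O", "B", "Z", "X")
  bad <- which(!(ch %in% allowed))
  if (length(bad) > 0L) {
    abort_redalph(
      sprintf("invalid character '%s' at position %d", ch[bad[1]], bad[1]),
      "redalph_parse_error"
    )
  }
  map <- c(U = "C", O = "K", B = "X", Z = "X")
  hit <- ch %in% names(map)
  ch[hit] <- map[ch[hit]]
  paste(ch, collapse = "")
}

#' Tokenize a normalized sequence under a reduced alphabet
#'
#' Each residue letter is replaced by its 0-based cluster index; `X` maps
#' to the unknown index `cluster_count(alphabet)`. This is the token
#' compression used to feed language models: residues of one cluster share
#' a token.
#'
#' @param seq A normalized sequence string (see [normalize_sequence()]).
#' @param alphabet An `aa_alphabet` or built-in alphabet name.
#' @return Integer vector of cluster indices, same length as `seq`.
#' @examples
#' tokenize("ALMS", "MMSEQS12") # 0 1 1 0
#' @export
tokenize <- function(seq, alphabet) {
  alphabet <- as_alphabet(alphabet)
  ch <- str_chars(seq)
  rm <- residue_map(alphabet)
  if (any(!(ch %in% names(rm)))) {
    abort_redalph("sequence is not normalized; run normalize_sequence() first",
                  "redalph_validation_error")
  }
  unname(rm[ch])
}

#' Tokenize records into a long tibble
#'
#' @param records A tibble with columns `id` and `seq` (normalized).
#' @param alphabet An `aa_alphabet` or built-in name.
#' @return A tibble with columns `id`, `position` (1-based), `residue`,
#'   `cluster_index`.
#' @export
tokenize_records <- function(records, alphabet) {
  alphabet <- as_alphabet(alphabet)
  purrr::map2_dfr(records$id, records$seq, function(id, s) {
    tibble::tibble(
      id = id,
      position = seq_len(nchar(s)),
      residue = str_chars(s),
      cluster_index = tokenize(s, alphabet)
    )
  })
}

#' Representative-residue schemes
#'
#' When a folding model needs a real amino-acid sequence, each cluster is
#' represented by one of its member letters, held fixed along the sequence.
#' Modes: `fixed_first` (first letter of each cluster as listed; the
#' deterministic default), `seeded_random` (one member drawn per cluster
#' from `seed`), `explicit` (user-supplied assignment), and
#' `per_position_random` (an independent member drawn at every position;
#' the stochastic variant of the same encoding family).
#'
#' @param alphabet An `aa_alphabet` or built-in name.
#' @param mode One of `"fixed_first"`, `"seeded_random"`, `"explicit"`,
#'   `"per_position_random"`.
#' @param assignment For `explicit` mode: character vector of one member
#'   letter per cluster (in cluster order, or named by cluster index).
#' @param seed Integer seed for the random modes.
#' @return An object of class `rep_scheme`.
#' @export
representative_scheme <- function(alphabet,
                                  mode = c("fixed_first", "seeded_random",
                                           "explicit", "per_position_random"),
                                  assignment = NULL, seed = NULL) {
  alphabet <- as_alphabet(alphabet)
  mode <- match.arg(mode)
  k <- cluster_count(alphabet)
  if (mode == "fixed_first") {
    assignment <- vapply(alphabet$clusters, `[[`, "", 1L)
  } else if (mode == "seeded_random") {
    if (is.null(seed)) {
      abort_redalph("seeded_random mode requires a seed",
                    "redalph_validation_error")
    }
    assignment <- with_seed(substream_seed(seed, "representatives"), {
      vapply(alphabet$clusters, function(cl) cl[sample.int(length(cl), 1L)], "")
    })
  } else if (mode == "explicit") {
    if (is.null(assignment) || length(assignment) != k) {
      abort_redalph(
        sprintf("explicit assignment must give one letter per cluster (%d)", k),
        "redalph_validation_error"
      )
    }
    ok <- vapply(seq_len(k), function(i) {
      assignment[[i]] %in% alphabet$clusters[[i]]
    }, NA)
    if (!all(ok)) {
      abort_redalph(
        sprintf("representative not a cluster member for cluster index %s",
                paste(which(!ok) - 1L, collapse = ", ")),
        "redalph_validation_error"
      )
    }
  } else { # per_position_random
    if (is.null(seed)) {
      abort_redalph("per_position_random mode requires a seed",
                    "redalph_validation_error")
    }
    assignment <- NULL
  }
  structure(
    list(alphabet = alphabet$name, mode = mode,
         assignment = unname(assignment), seed = seed),
    class = "rep_scheme"
  )
}

#' Translate a sequence to its representative-residue form
#'
#' Every residue is replaced by its cluster's representative letter; `X`
#' stays `X`. With any fixed scheme the translation is idempotent and
#' never changes cluster identity (tokenizing the translated sequence
#' equals tokenizing the original).
#'
#' @param seq Normalized sequence string.
#' @param alphabet An `aa_alphabet` or built-in name.
#' @param scheme A `rep_scheme`; defaults to the `fixed_first` scheme.
#' @return The translated sequence string, same length as `seq`.
#' @examples
#' to_representative_sequence("LM", "MMSEQS12") # "LL"
#' @export
to_representative_sequence <- function(seq, alphabet, scheme = NULL) {
  alphabet <- as_alphabet(alphabet)
  if (is.null(scheme)) scheme <- representative_scheme(alphabet)
  stopifnot(inherits(scheme, "rep_scheme"))
  if (!identical(scheme$alphabet, alphabet$name)) {
    abort_redalph("scheme was built for a different alphabet",
                  "redalph_validation_error")
  }
  idx <- tokenize(seq, alphabet)
  k <- cluster_count(alphabet)
  ch <- str_chars(seq)
  if (scheme$mode == "per_position_random") {
    out <- ch
    std <- which(idx < k)
    draws <- with_seed(substream_seed(scheme$seed, "per_position"), {
      runif(length(std))
    })
    sizes <- lengths(alphabet$clusters)
    for (j in seq_along(std)) {
      cl <- alphabet$clusters[[idx[std[j]] + 1L]]
      out[std[j]] <- cl[[1L + floor(draws[j] * length(cl))]]
    }
    return(paste(out, collapse = ""))
  }
  reps <- c(scheme$assignment, AA_UNKNOWN) # index k+1 = unknown
  paste(reps[idx + 1L], collapse = "")
}

#' Enumerate all explicit representative assignments
#'
#' Walks the Cartesian product of per-cluster member choices in
#' lexicographic order (clusters vary slowest to fastest in listed order,
#' members in within-cluster order), stopping after `cap` assignments.
#' The total number of assignments (the product of cluster sizes) is
#' attached whether or not it exceeds `cap`.
#'
#' @param alphabet An `aa_alphabet` or built-in name.
#' @param cap Maximum number of assignments to materialize (>= 1).
#' @return A tibble with columns `assignment_id` and `representatives`
#'   (list-column of per-cluster letter vectors), with attribute
#'   `total_assignments`.
#' @examples
#' enumerate_representative_assignments("GBMR4", cap = 5)
#' @export
enumerate_representative_assignments <- function(alphabet, cap = 1000L) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(cap >= 1L)
  sizes <- lengths(alphabet$clusters)
  total <- prod(sizes)
  n <- min(cap, total)
  k <- length(sizes)
  # mixed-radix counter, last cluster fastest
  out <- vector("list", n)
  digits <- rep(1L, k)
  for (i in seq_len(n)) {
    out[[i]] <- vapply(seq_len(k), function(j) {
      alphabet$clusters[[j]][[digits[j]]]
    }, "")
    j <- k
    while (j >= 1L) {
      digits[j] <- digits[j] + 1L
      if (digits[j] <= sizes[j]) break
      digits[j] <- 1L
      j <- j - 1L
    }
  }
  res <- tibble::tibble(
    assignment_id = seq_len(n),
    representatives = out
  )
  attr(res, "total_assignments") <- total
  res
}

#' Positionwise identity and BLOSUM62 similarity
#'
#' Translation is length-preserving, so the original and translated
#' sequences are compared position by position with no alignment step.
#' Identity is the percentage of positions with equal letters; similarity
#' is the percentage of positions whose BLOSUM62 substitution score is
#' strictly positive (the EMBOSS convention). Positions involving `X` are
#' kept in the denominator and scored through the matrix's `X` row; the
#' convention is recorded in the output so users can recompute under the
#' complementary one.
#'
#' @param original,translated Equal-length sequence strings over the
#'   21-letter vocabulary.
#' @return A one-row tibble: `identity`, `similarity` (both percent),
#'   `n_positions`, `convention`.
#' @examples
#' identity_and_similarity("LL", "MM") # identity 0, similarity 100
#' @export
identity_and_similarity <- function(original, translated) {
  if (nchar(original) != nchar(translated)) {
    abort_redalph("sequences differ in length; translation is length-preserving",
                  "redalph_validation_error")
  }
  a <- str_chars(original)
  b <- str_chars(translated)
  m <- blosum62()
  if (any(!(a %in% rownames(m))) || any(!(b %in% rownames(m)))) {
    abort_redalph("sequences contain letters outside the BLOSUM62 alphabet",
                  "redalph_validation_error")
  }
  scores <- m[cbind(a, b)]
  tibble::tibble(
    identity = 100 * mean(a == b),
    similarity = 100 * mean(scores > 0),
    n_positions = length(a),
    convention = "similar iff BLOSUM62 > 0; X positions counted via X row"
  )
}

#' Translate a set of records and score them against the originals
#'
#' Convenience wrapper reproducing the sequence-fidelity table: each
#' record is translated to its representative form under each alphabet
#' and scored with [identity_and_similarity()].
#'
#' @param records Tibble with `id`, `seq` (normalized).
#' @param alphabets Character vector of built-in names or list of
#'   `aa_alphabet`s (default: all built-ins).
#' @param scheme_mode,seed Passed to [representative_scheme()].
#' @return Tibble: `alphabet`, `id`, `identity`, `similarity`, `n_positions`.
#' @export
translation_fidelity <- function(records, alphabets = builtin_alphabets(),
                                 scheme_mode = "fixed_first", seed = NULL) {
  if (is.character(alphabets)) alphabets <- lapply(alphabets, as_alphabet)
  purrr::map_dfr(alphabets, function(ab) {
    ab <- as_alphabet(ab)
    sch <- representative_scheme(ab, mode = scheme_mode, seed = seed)
    purrr::map2_dfr(records$id, records$seq, function(id, s) {
      tr <- to_representative_sequence(s, ab, sch)
      dplyr::mutate(
        dplyr::select(identity_and_similarity(s, tr), -"convention"),
        alphabet = ab$name, id = id, .before = 1L
      )
    })
  })
}
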