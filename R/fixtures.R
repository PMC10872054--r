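#' Default residue composition for synthetic corpora
#'
#' Average amino-acid frequencies over a large curated protein
#' knowledgebase (bundled as a plain-text table), normalized to sum to 1.
#' Used as the default composition of [generate_corpus()] so synthetic
#' corpora have a realistic, non-uniform residue usage.
#'
#' @return Named numeric vector over the 20 standard letters, summing to 1.
#' @export
default_composition <- function() {
  tab <- utils::read.delim(extdata_path("aa_frequencies.tsv"),
                           comment.char = "#")
  p <- tab$percent
  names(p) <- tab$residue
  p <- p[AA_STANDARD]
  p / sum(p)
}

#' Specification for a synthetic sequence corpus
#'
#' The generator emulates the statistical shape of a protein-sequence
#' corpus at desk scale: iid residues from a realistic composition, with
#' an optional planted motif that gives a bidirectional model learnable
#' context. Defaults define the package's standard desk-scale study
#' corpus: 5000 sequences of length 30-50 with a 16-residue motif planted
#' in every sequence.
#'
#' @param n_sequences Number of sequences.
#' @param length_min,length_max Sequence length range (uniform).
#' @param composition Named probability vector over the 20 standard
#'   letters; default [default_composition()].
#' @param motif Optional motif string (standard letters) planted verbatim
#'   at a uniformly random valid offset; `NULL` for none.
#' @param motif_prob Probability that a given sequence carries the motif.
#' @param seed Integer seed; the same spec and seed reproduce the corpus
#'   byte for byte.
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_sequences = 5000L, length_min = 30L,
                        length_max = 50L, composition = default_composition(),
                        motif = "CWHPDKQYFMENRGST", motif_prob = 1,
                        seed = 1L) {
  stopifnot(n_sequences >= 1L, length_min >= 1L, length_max >= length_min,
            motif_prob >= 0, motif_prob <= 1)
  composition <- composition / sum(composition)
  stopifnot(setequal(names(composition), AA_STANDARD))
  if (!is.null(motif)) {
    stopifnot(all(str_chars(motif) %in% AA_STANDARD))
    if (nchar(motif) > length_min) {
      abort_redalph("motif is longer than the minimum sequence length",
                    "redalph_validation_error")
    }
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         length_min = as.integer(length_min),
         length_max = as.integer(length_max),
         composition = composition, motif = motif,
         motif_prob = motif_prob, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Generate a synthetic protein corpus
#'
#' @param spec A [corpus_spec()].
#' @return A tibble with columns `id` and `seq` (standard letters only).
#' @examples
#' generate_corpus(corpus_spec(n_sequences = 3, seed = 7))
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(substream_seed(spec$seed, "corpus"), {
    len_range <- seq(spec$length_min, spec$length_max)
    lens <- len_range[sample.int(length(len_range), spec$n_sequences,
                                 replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(names(spec$composition), L, replace = TRUE,
                   prob = spec$composition), collapse = "")
    }, "")
    if (!is.null(spec$motif)) {
      ml <- nchar(spec$motif)
      has <- runif(spec$n_sequences) < spec$motif_prob
      off <- floor(runif(spec$n_sequences) * (lens - ml + 1L))
      for (i in which(has)) {
        substr(seqs[i], off[i] + 1L, off[i] + ml) <- spec$motif
      }
    }
    tibble::tibble(id = sprintf("seq_%05d", seq_along(seqs)), seq = seqs)
  })
}

#' Generate a synthetic variant set
#'
#' Emulates a deep-mutational-scanning substitution set: a wild type drawn
#' from the default composition and variants differing from it at exactly
#' `n_substitutions` positions, with substitute letters drawn uniformly
#' from the 19 other standard residues.
#'
#' @param wild_type_length Length of the wild-type sequence.
#' @param n_variants Number of variants.
#' @param n_substitutions Substitutions per variant (Hamming distance).
#' @param seed Integer seed.
#' @return A list with `wild_type` (string) and `variants` (tibble with
#'   `id`, `seq`).
#' @export
generate_variant_set <- function(wild_type_length = 50L, n_variants = 100L,
                                 n_substitutions = 1L, seed = 1L) {
  stopifnot(n_substitutions <= wild_type_length, n_substitutions >= 0L)
  comp <- default_composition()
  with_seed(substream_seed(seed, "variants"), {
    wt <- paste(sample(names(comp), wild_type_length, replace = TRUE,
                       prob = comp), collapse = "")
    wt_ch <- str_chars(wt)
    vs <- vapply(seq_len(n_variants), function(i) {
      v <- wt_ch
      if (n_substitutions > 0L) {
        pos <- sample.int(wild_type_length, n_substitutions)
        for (p in pos) {
          v[p] <- sample(setdiff(AA_STANDARD, wt_ch[p]), 1L)
        }
      }
      paste(v, collapse = "")
    }, "")
    list(
      wild_type = wt,
      variants = tibble::tibble(
        id = sprintf("var_%04d", seq_len(n_variants)), seq = vs
      )
    )
  })
}

#' Specification for a synthetic structure pair
#'
#' Toy structures are ideal alpha-helical Calpha traces (rise 1.5 A per
#' residue, radius 2.3 A, 100 degrees of turn per residue). A helix keeps
#' the 15 A inclusion radius non-trivial at 10-30 residues: residues a few
#' turns apart re-approach the axis, unlike a random coil or a straight
#' chain.
#'
#' @param n_residues Number of residues.
#' @param noise_sd Isotropic Gaussian displacement (A) per coordinate
#'   applied to the perturbed copy; 0 reproduces the ideal geometry.
#' @param rigid_transform Apply a random rigid rotation + translation to
#'   the perturbed copy (LDDT is superposition-free, so this must not
#'   change scores).
#' @param seed Integer seed.
#' @return A `structure_spec` object.
#' @export
structure_spec <- function(n_residues = 20L, noise_sd = 0,
                           rigid_transform = FALSE, seed = 1L) {
  stopifnot(n_residues >= 2L, noise_sd >= 0)
  structure(
    list(n_residues = as.integer(n_residues), noise_sd = noise_sd,
         rigid_transform = rigid_transform, seed = as.integer(seed)),
    class = "structure_spec"
  )
}

#' Ideal alpha-helix Calpha trace
#'
#' @param n_residues Number of residues.
#' @param chain_id Chain identifier.
#' @return A [ca_trace()] with residues numbered from 1.
#' @export
ideal_helix <- function(n_residues, chain_id = "A") {
  i <- seq_len(n_residues) - 1L
  theta <- i * 100 * pi / 180
  ca_trace(
    tibble::tibble(
      resno = i + 1L,
      x = 2.3 * cos(theta),
      y = 2.3 * sin(theta),
      z = 1.5 * i
    ),
    chain_id = chain_id
  )
}

#' Generate a reference/perturbed structure pair
#'
#' @param spec A [structure_spec()].
#' @return List with `reference` and `model`, both [ca_trace()] objects.
#' @examples
#' pair <- generate_structure_pair(structure_spec(noise_sd = 0.5, seed = 3))
#' @export
generate_structure_pair <- function(spec) {
  stopifnot(inherits(spec, "structure_spec"))
  ref <- ideal_helix(spec$n_residues)
  with_seed(substream_seed(spec$seed, "structure"), {
    xyz <- as.matrix(ref$residues[, c("x", "y", "z")])
    if (spec$noise_sd > 0) {
      xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$noise_sd),
                          ncol = 3L)
    }
    if (isTRUE(spec$rigid_transform)) {
      rot <- random_rotation()
      shift <- runif(3L, -20, 20)
      xyz <- xyz %*% rot + matrix(shift, nrow(xyz), 3L, byrow = TRUE)
    }
    model <- ref
    model$residues$x <- xyz[, 1L]
    model$residues$y <- xyz[, 2L]
    model$residues$z <- xyz[, 3L]
    list(reference = ref, model = model)
  })
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
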