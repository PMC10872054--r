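#' Calpha trace objects
#'
#' A `ca_trace` holds one chain's per-residue Calpha coordinates, the unit
#' of LDDT-Calpha scoring. Residues are identified by author residue
#' number plus insertion code; identifiers must be unique within the
#' chain and coordinates finite.
#'
#' @param residues Tibble (or data frame) with columns `resno`, `x`, `y`,
#'   `z` and optionally `ins` (insertion code, default `""`).
#' @param chain_id Chain identifier.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(residues, chain_id = "A") {
  residues <- tibble::as_tibble(residues)
  stopifnot(all(c("resno", "x", "y", "z") %in% names(residues)))
  if (!("ins" %in% names(residues))) residues$ins <- ""
  residues$ins[is.na(residues$ins)] <- ""
  residues <- residues[, c("resno", "ins", "x", "y", "z")]
  key <- paste0(residues$resno, residues$ins)
  if (anyDuplicated(key)) {
    abort_redalph("duplicate residue identifiers in trace",
                  "redalph_validation_error")
  }
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    abort_redalph("non-finite coordinates in trace",
                  "redalph_validation_error")
  }
  structure(list(chain_id = chain_id, residues = residues),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> chain %s: %d residues (resno %s..%s)\n",
              x$chain_id, nrow(x$residues),
              x$residues$resno[1], x$residues$resno[nrow(x$residues)]))
  invisible(x)
}

trace_keys <- function(trace) {
  paste0(trace$residues$resno, trace$residues$ins)
}

trace_xyz <- function(trace) {
  as.matrix(trace$residues[, c("x", "y", "z")])
}

#' Read a Calpha trace from a PDB or mmCIF file
#'
#' Uses bio3d to parse the structure, keeping one Calpha per residue.
#' Alternate locations are resolved to the highest-occupancy copy (first
#' on ties, in file order); residues without a Calpha atom are skipped and
#' counted in the `n_skipped` attribute (with a message).
#'
#' @param path Path to a `.pdb`, `.cif` or `.mmcif` file.
#' @param chain Chain selector; `NULL` takes the first chain present.
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(path, chain = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    abort_redalph("no ATOM records in structure file", "redalph_parse_error")
  }
  if (is.null(chain)) chain <- atoms$chain[[1]]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    abort_redalph(sprintf("no atoms for chain '%s'", chain),
                  "redalph_validation_error")
  }
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste0(atoms$resno, ins)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  n_skipped <- length(unique(key)) - length(unique(key[atoms$elety == "CA"]))
  if (nrow(ca) == 0L) {
    abort_redalph(sprintf("chain '%s' has no Calpha atoms", chain),
                  "redalph_validation_error")
  }
  ca_ins <- ca$insert
  ca_ins[is.na(ca_ins)] <- ""
  ca_key <- paste0(ca$resno, ca_ins)
  occ <- ca$o
  occ[is.na(occ)] <- 1
  # highest occupancy wins within a residue; stable sort keeps file order
  ord <- order(match(ca_key, unique(ca_key)), -occ)
  ca <- ca[ord, , drop = FALSE]
  keep <- !duplicated(ca_key[ord])
  ca <- ca[keep, , drop = FALSE]
  if (n_skipped > 0L) {
    message(sprintf("read_ca_trace: %d residue(s) without a Calpha skipped",
                    n_skipped))
  }
  ins2 <- ca$insert
  ins2[is.na(ins2)] <- ""
  out <- ca_trace(
    tibble::tibble(resno = ca$resno, ins = ins2,
                   x = ca$x, y = ca$y, z = ca$z),
    chain_id = chain
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a Calpha-only PDB file
#'
#' Writes one fixed-width ATOM record per residue (residue name ALA,
#' occupancy 1.00). Intended for synthetic fixtures and round-tripping
#' traces to external tools.
#'
#' @param trace A [ca_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(trace, path) {
  r <- trace$residues
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), substr(trace$chain_id, 1, 1), r$resno,
    ifelse(nzchar(r$ins), r$ins, " "), r$x, r$y, r$z, 1, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Domain ranges
#'
#' A domain range selects a chain plus a set of inclusive author-numbered
#' residue intervals, the convention used to crop predicted structures to
#' the scored segment of a target.
#'
#' @param chain_id Chain identifier.
#' @param intervals Two-column matrix or data frame of inclusive
#'   `(start, end)` residue numbers; must be ascending and
#'   non-overlapping.
#' @return A `domain_range` object.
#' @export
domain_range <- function(chain_id, intervals) {
  intervals <- as.matrix(intervals)
  stopifnot(ncol(intervals) == 2L, nrow(intervals) >= 1L)
  storage.mode(intervals) <- "integer"
  if (any(intervals[, 2L] < intervals[, 1L])) {
    abort_redalph("interval end before start", "redalph_validation_error")
  }
  if (nrow(intervals) > 1L) {
    o <- order(intervals[, 1L])
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals[-1L, 1L] <= intervals[-nrow(intervals), 2L])) {
      abort_redalph("domain intervals overlap", "redalph_validation_error")
    }
  }
  colnames(intervals) <- c("start", "end")
  structure(list(chain_id = chain_id, intervals = intervals),
            class = "domain_range")
}

#' Parse a domain-range string
#'
#' Accepts the `CHAIN:START-END[,START-END...]` form, e.g. `"A:10-120"`
#' or `"A:1-5,90-95"`.
#'
#' @param x Domain string.
#' @return A [domain_range()].
#' @export
parse_domain_range <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):(.+)$", x))[[1]]
  if (length(m) != 3L) {
    abort_redalph("domain string must be 'CHAIN:START-END[,START-END...]'",
                  "redalph_parse_error")
  }
  parts <- strsplit(m[[3]], ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    se <- regmatches(p, regexec("^(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
    if (length(se) != 3L) {
      abort_redalph(sprintf("bad interval '%s'", p), "redalph_parse_error")
    }
    as.integer(se[2:3])
  }, integer(2L)))
  domain_range(m[[2]], iv)
}

#' Crop a trace to a domain range
#'
#' Retains residues whose author numbers fall inside any interval
#' (inclusive ends), preserving order. Scoring a cropped pair recomputes
#' the distance-pair inclusion set on the cropped residues.
#'
#' @param trace A [ca_trace()].
#' @param range A [domain_range()] or domain string.
#' @return A cropped [ca_trace()].
#' @export
crop_to_domain <- function(trace, range) {
  if (is.character(range)) range <- parse_domain_range(range)
  stopifnot(inherits(range, "domain_range"))
  if (!identical(range$chain_id, trace$chain_id)) {
    abort_redalph(
      sprintf("domain chain '%s' does not match trace chain '%s'",
              range$chain_id, trace$chain_id),
      "redalph_validation_error"
    )
  }
  keep <- rep(FALSE, nrow(trace$residues))
  for (i in seq_len(nrow(range$intervals))) {
    keep <- keep | (trace$residues$resno >= range$intervals[i, 1L] &
                    trace$residues$resno <= range$intervals[i, 2L])
  }
  if (!any(keep)) {
    abort_redalph(
      sprintf("no residues fall inside interval(s) %s",
              paste(sprintf("[%d,%d]", range$intervals[, 1L],
                            range$intervals[, 2L]), collapse = ", ")),
      "redalph_validation_error"
    )
  }
  out <- trace
  out$residues <- trace$residues[keep, , drop = FALSE]
  out
}

#' LDDT parameters
#'
#' Defaults follow the standard local distance difference test: reference
#' Calpha pairs closer than a 15 A inclusion radius, preservation
#' thresholds 0.5/1/2/4 A, same-residue pairs excluded.
#'
#' @param inclusion_radius Inclusion radius R0 in Angstrom.
#' @param thresholds Ascending positive difference cutoffs in Angstrom;
#'   must all be below `inclusion_radius`.
#' @param exclude_same_residue Exclude pairs within one residue (always
#'   true for a Calpha-only trace; kept for interface completeness).
#' @return An `lddt_params` object.
#' @export
lddt_params <- function(inclusion_radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        exclude_same_residue = TRUE) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds, strictly = TRUE),
            inclusion_radius > max(thresholds))
  structure(
    list(inclusion_radius = inclusion_radius, thresholds = thresholds,
         exclude_same_residue = exclude_same_residue),
    class = "lddt_params"
  )
}

#' LDDT-Calpha score of a model against a reference
#'
#' Superposition-free structure similarity: the pair set is all reference
#' Calpha pairs from different residues with reference distance below the
#' inclusion radius (the reference defines the pair set — arguments are
#' not symmetric). A pair is preserved at threshold t if the model
#' reproduces its distance within t; pairs touching residues absent from
#' the model count as not preserved. The global score is the mean over
#' thresholds of the preserved fraction, on a 0-100 scale; the
#' per-residue profile applies the same rule to the pairs touching each
#' residue. Model residues are matched to reference residues by author
#' residue number + insertion code, not by alignment.
#'
#' @param reference,model [ca_trace()] objects.
#' @param params An [lddt_params()].
#' @return An object of class `lddt_result` with fields `global` (0-100),
#'   `per_residue` (tibble: `resno`, `ins`, `in_model`, `n_pairs`,
#'   `score`), `n_pairs`, `n_reference`, `n_matched`, `params`. `tidy()`
#'   returns the per-residue profile, `glance()` the one-row summary.
#' @examples
#' helix <- ideal_helix(15)
#' lddt_ca(helix, helix)$global # 100
#' @export
lddt_ca <- function(reference, model, params = lddt_params()) {
  stopifnot(inherits(reference, "ca_trace"), inherits(model, "ca_trace"),
            inherits(params, "lddt_params"))
  rk <- trace_keys(reference)
  mk <- trace_keys(model)
  pos <- match(rk, mk)
  if (sum(!is.na(pos)) < 2L) {
    abort_redalph("fewer than 2 model residues match the reference",
                  "redalph_validation_error")
  }
  xr <- trace_xyz(reference)
  xm_all <- trace_xyz(model)
  n <- nrow(xr)
  d_ref <- as.matrix(stats::dist(xr))
  include <- d_ref < params$inclusion_radius
  diag(include) <- FALSE
  present <- !is.na(pos)
  xm <- matrix(NA_real_, n, 3L)
  xm[present, ] <- xm_all[pos[present], , drop = FALSE]
  d_mod <- matrix(NA_real_, n, n)
  d_mod[present, present] <- as.matrix(stats::dist(xm[present, , drop = FALSE]))
  dd <- abs(d_ref - d_mod)
  n_th <- length(params$thresholds)
  pres_count <- matrix(0L, n, n)
  for (t in params$thresholds) {
    p <- !is.na(dd) & dd < t
    pres_count <- pres_count + p
  }
  pres_count[!include] <- 0L
  total_pairs <- sum(include) / 2
  if (total_pairs == 0) {
    abort_redalph("no reference pairs inside the inclusion radius",
                  "redalph_validation_error")
  }
  global <- 100 * sum(pres_count[upper.tri(pres_count) & include]) /
    (n_th * total_pairs)
  touch_pairs <- rowSums(include)
  touch_pres <- rowSums(pres_count)
  per_res_score <- ifelse(touch_pairs > 0,
                          100 * touch_pres / (n_th * touch_pairs), NA_real_)
  res <- structure(
    list(
      global = global,
      per_residue = tibble::tibble(
        resno = reference$residues$resno,
        ins = reference$residues$ins,
        in_model = present,
        n_pairs = unname(touch_pairs),
        score = unname(per_res_score)
      ),
      n_pairs = total_pairs,
      n_reference = n,
      n_matched = sum(present),
      params = params
    ),
    class = "lddt_result"
  )
  res
}

#' @export
print.lddt_result <- function(x, ...) {
  cat(sprintf("<lddt_result> global LDDT-Ca %.1f (%d pairs, %d/%d residues matched)\n",
              x$global, x$n_pairs, x$n_matched, x$n_reference))
  invisible(x)
}

#' @rdname lddt_ca
#' @param x An `lddt_result`.
#' @param ... Unused.
#' @method tidy lddt_result
#' @export
tidy.lddt_result <- function(x, ...) x$per_residue

#' @rdname lddt_ca
#' @method glance lddt_result
#' @export
glance.lddt_result <- function(x, ...) {
  tibble::tibble(
    lddt_ca = x$global, n_pairs = x$n_pairs,
    n_reference = x$n_reference, n_matched = x$n_matched
  )
}

#' Compare predictions from several alphabet encodings against one target
#'
#' Scores each prediction with [lddt_ca()] and reports the delta against
#' the full-alphabet baseline, flagging alphabets whose improvement meets
#' the margin (default 1 LDDT point). The best-over-alphabets summary is
#' attached as attribute `best`.
#'
#' @param reference Reference [ca_trace()].
#' @param predictions Named list of [ca_trace()] predictions; must include
#'   `baseline`.
#' @param params An [lddt_params()].
#' @param baseline Name of the full-alphabet baseline prediction.
#' @param margin Improvement margin (LDDT points) for flagging.
#' @return Tibble: `alphabet`, `lddt_ca`, `delta`, `improved`.
#' @export
compare_alphabet_predictions <- function(reference, predictions,
                                         params = lddt_params(),
                                         baseline = "UNIPROT20",
                                         margin = 1) {
  if (!baseline %in% names(predictions)) {
    abort_redalph(
      sprintf("predictions must include the baseline '%s'", baseline),
      "redalph_validation_error"
    )
  }
  scores <- vapply(predictions, function(p) {
    lddt_ca(reference, p, params)$global
  }, 0)
  out <- tibble::tibble(
    alphabet = names(predictions),
    lddt_ca = unname(scores),
    delta = unname(scores - scores[[baseline]]),
    improved = unname(scores - scores[[baseline]] >= margin)
  )
  best <- out[which.max(out$lddt_ca), ]
  attr(out, "best") <- best
  out
}
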