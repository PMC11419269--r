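#' Kyte-Doolittle hydropathy scale
#'
#' The canonical Kyte-Doolittle hydropathy index for the 20 standard amino
#' acids. Positive values are hydrophobic (maximum +4.5 at isoleucine),
#' negative values hydrophilic (minimum -4.5 at arginine); no residue sits
#' exactly at zero, so the binary hydrophobicity sign is always defined.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @examples
#' kd_hydropathy()[c("I", "R", "G", "W")]
#' @export
kd_hydropathy <- function() {
  c(I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
    E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

validate_scale <- function(scale) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  if (!all(aa %in% names(scale)) || length(scale) != 20L)
    stop("hydropathy scale must cover exactly the 20 standard residues")
  if (any(scale == 0))
    stop("hydropathy scale has residues with index 0; binary sign undefined")
  scale
}

#' Build a hydropathy profile from a protein sequence
#'
#' Converts a residue string into per-residue hydropathy indices and a
#' binary (+/-) hydrophobicity map under the given scale. The profile keeps
#' track of the 1-based position of its first residue in the full precursor
#' (`offset`), so that windows of a sub-sequence (for example an Ig domain)
#' report coordinates in precursor numbering.
#'
#' @param sequence Residue string (one-letter codes, standard 20 only).
#' @param id Sequence identifier.
#' @param scale Named hydropathy scale, default [kd_hydropathy()].
#' @param offset 1-based precursor position of the first residue.
#' @return An object of class `hydropathy_profile`: list with `sequence_id`,
#'   `residues` (character vector), `indices` (numeric), `signs`
#'   (`"+"`/`"-"`), `offset`.
#' @examples
#' hydropathy_profile("IRGW", id = "toy")$signs
#' @export
hydropathy_profile <- function(sequence, id = "seq", scale = kd_hydropathy(),
                               offset = 1L) {
  scale <- validate_scale(scale)
  if (length(sequence) != 1L || !is.character(sequence) || nchar(sequence) < 1L)
    stop("'sequence' must be a single non-empty string")
  if (offset < 1L) stop("'offset' must be >= 1")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% names(scale)))
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d of '%s'",
                 res[bad[1L]], bad[1L], id))
  idx <- unname(scale[res])
  structure(list(sequence_id = id, residues = res, indices = idx,
                 signs = ifelse(idx > 0, "+", "-"),
                 offset = as.integer(offset)),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %s: %d residues (precursor %d-%d)\n",
              x$sequence_id, length(x$residues), x$offset,
              x$offset + length(x$residues) - 1L))
  cat(" signs:", paste(utils::head(x$signs, 40), collapse = ""),
      if (length(x$signs) > 40) "...\n" else "\n")
  invisible(x)
}

#' @export
length.hydropathy_profile <- function(x) length(x$residues)

# Slice a profile to precursor coordinates [start, end]
profile_window <- function(profile, start, end, id = profile$sequence_id) {
  i <- start - profile$offset + 1L
  j <- end - profile$offset + 1L
  if (i < 1L || j > length(profile$residues) || i > j)
    stop(sprintf("window %d-%d outside '%s' (%d-%d)", start, end,
                 profile$sequence_id, profile$offset,
                 profile$offset + length(profile$residues) - 1L))
  structure(list(sequence_id = id, residues = profile$residues[i:j],
                 indices = profile$indices[i:j], signs = profile$signs[i:j],
                 offset = as.integer(start)),
            class = "hydropathy_profile")
}

#' Percent match between two binary hydrophobicity maps
#'
#' The percentage of aligned positions whose hydrophobicity signs are
#' complementary (one `+`, one `-`), out of all aligned pairs.
#'
#' @param motif_signs,window_signs Equal-length character vectors of
#'   `"+"`/`"-"`, or `hydropathy_profile` objects.
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_match(c("+", "-", "+"), c("-", "+", "-"))  # 100
#' @export
percent_match <- function(motif_signs, window_signs) {
  a <- if (inherits(motif_signs, "hydropathy_profile")) motif_signs$signs else motif_signs
  b <- if (inherits(window_signs, "hydropathy_profile")) window_signs$signs else window_signs
  if (length(a) != length(b) || length(a) < 1L)
    stop("sign vectors must have equal positive length")
  if (!all(c(a, b) %in% c("+", "-"))) stop("signs must be '+' or '-'")
  100 * sum(a != b) / length(a)
}

#' Degree of complementary hydropathy
#'
#' Normalized mean absolute difference of hydropathy indices between two
#' aligned segments: `C = sum(|H(i) - H'(i)|) / (L * 9)`, where 9 is the
#' full span of the Kyte-Doolittle scale. `C` ranges from 0 (identical
#' hydropathy at every position) to 1 (every pair is maximally opposed,
#' i.e. Ile against Arg), and is symmetric in its arguments.
#'
#' @param motif_indices,window_indices Equal-length numeric vectors of
#'   hydropathy indices, or `hydropathy_profile` objects.
#' @param scale_span Index span used for normalization; 9 for Kyte-Doolittle.
#' @return Complementarity in \[0, 1\].
#' @examples
#' complementarity(rep(4.5, 3), rep(-4.5, 3))  # 1
#' @export
complementarity <- function(motif_indices, window_indices, scale_span = 9) {
  h1 <- if (inherits(motif_indices, "hydropathy_profile")) motif_indices$indices else motif_indices
  h2 <- if (inherits(window_indices, "hydropathy_profile")) window_indices$indices else window_indices
  if (length(h1) != length(h2) || length(h1) < 1L)
    stop("index vectors must have equal positive length")
  sum(abs(h1 - h2)) / (length(h1) * scale_span)
}
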