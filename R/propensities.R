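# Per-residue propensity scales behind the surrogate scorers.
#
# Amyloidogenicity surrogate: Chou-Fasman beta-sheet propensity multiplied by
# Kyte-Doolittle hydropathy shifted to be non-negative -- beta-prone
# hydrophobics (I, V, F, ...) land high, charged/turn residues low.
# Disorder surrogate: the TOP-IDP disorder propensity scale (Campen et al.
# 2008), high for P/E/K/S/Q, low for W/F/Y/I.
# Both tables are min-max scaled to [0, 1] over their 20-residue range, so a
# fixed decision threshold is portable across sequences.

CHOU_FASMAN_BETA <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
)

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

TOP_IDP <- c(
  A = 0.06, R = 0.180, N = 0.007, D = 0.192, C = 0.02, Q = 0.318,
  E = 0.736, G = 0.166, H = 0.303, I = -0.486, L = -0.326, K = 0.586,
  M = -0.397, F = -0.697, P = 0.987, S = 0.341, T = 0.059, W = -0.884,
  Y = -0.510, V = -0.121
)

scale01 <- function(x) (x - min(x)) / (max(x) - min(x))

#' Residue propensity tables used by the surrogate scorers
#'
#' `amylo_propensity()` returns the scaled amyloidogenicity propensity per
#' residue (Chou-Fasman beta-sheet propensity times shifted Kyte-Doolittle
#' hydropathy, min-max scaled to `[0, 1]` over the 20 residues).
#' `disorder_propensity()` returns the scaled TOP-IDP disorder propensity.
#' The sliding-window means of these tables are the surrogate score tracks,
#' so the tables fully determine the scorers.
#'
#' @return A named numeric vector over the 20 standard amino acids, values
#'   in `[0, 1]`.
#' @export
#' @examples
#' amylo_propensity()[c("I", "V", "G", "E")]
amylo_propensity <- function() {
  scale01(CHOU_FASMAN_BETA * (KYTE_DOOLITTLE + 4.5))
}

#' @rdname amylo_propensity
#' @export
disorder_propensity <- function() {
  scale01(TOP_IDP)
}

# sliding-window mean with the window truncated at the termini
window_mean <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  L <- length(x)
  if (L == 0L) return(numeric(0))
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

propensity_track <- function(sequence, table, window) {
  chars <- split_chars(sequence)
  if (length(chars) == 0L) return(numeric(0))
  check_protein_alphabet(chars)
  vals <- unname(table[chars])
  vals[chars == "X"] <- mean(table)  # unknown residue scored as neutral
  window_mean(vals, window)
}

#' Surrogate per-residue amyloidogenicity and disorder scores
#'
#' Built-in stand-ins for external amyloid and disorder predictors: the
#' per-residue propensity (see [amylo_propensity()]) is smoothed by a
#' sliding-window mean (window truncated at the termini). Scores are in
#' `[0, 1]` on a scale fixed by the propensity table, not per sequence, so
#' the downstream decision thresholds apply uniformly. These scorers are
#' surrogates: they reproduce the *shape* of predictor output (one score per
#' residue, fixed threshold), not the predictions of any published tool.
#'
#' @param sequence A single protein sequence string (20 standard residues;
#'   `X` allowed and scored as neutral).
#' @param window Odd window width in residues (default 21, a typical
#'   disorder-predictor smoothing scale).
#' @return Numeric vector of per-residue scores in `[0, 1]`, same length as
#'   the sequence.
#' @seealso [surrogate_scores()] for the data-frame interface.
#' @export
#' @examples
#' surrogate_amylo_score(strrep("G", 30))
surrogate_amylo_score <- function(sequence, window = 21L) {
  propensity_track(sequence, amylo_propensity(), window)
}

#' @rdname surrogate_amylo_score
#' @export
surrogate_disorder_score <- function(sequence, window = 21L) {
  propensity_track(sequence, disorder_propensity(), window)
}

#' Score every sequence of a family with the surrogate predictors
#'
#' @param sequences Data frame with columns `id` and `sequence`.
#' @param window Odd sliding-window width passed to the scorers.
#' @return A tibble with one row per residue: `id`, `position` (1-based),
#'   `residue`, `amylo_score`, `disorder_score`.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = "p1", sequence = "MKNIIFGGGSIIII")
#' surrogate_scores(seqs, window = 5)
surrogate_scores <- function(sequences, window = 21L) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  purrr::map2_dfr(sequences$id, sequences$sequence, function(id, seq) {
    chars <- split_chars(seq)
    tibble(
      id = id,
      position = seq_along(chars),
      residue = chars,
      amylo_score = surrogate_amylo_score(seq, window),
      disorder_score = surrogate_disorder_score(seq, window)
    )
  })
}
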