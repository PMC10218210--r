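AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Derive a reproducible sub-seed for a pipeline stage
#'
#' Every stochastic stage draws from its own stream so that adding or
#' reordering stages never perturbs the draws of another. The stream seed is
#' a 31-bit polynomial hash of the master seed, a stage label and a
#' replicate index.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"sample"`).
#' @param index Replicate or item index (default 0).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "sample", 3)
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  h <- (h * 31 + as.numeric(index)) %% m
  as.integer(h)
}

# maximal runs of TRUE -> tibble(start, end); NA breaks runs
runs_to_intervals <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

#' Jaccard index between two column sets
#'
#' Overlap measure used to compare a called conserved region with the column
#' span of a planted motif: size of the intersection over size of the union.
#'
#' @param a,b Integer vectors of (alignment column) positions.
#' @return A number in `[0, 1]`; 0 when both sets are empty.
#' @export
#' @examples
#' jaccard_columns(1:10, 6:15)
jaccard_columns <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# FNV-1a 32-bit content hash, reported in run manifests; arithmetic kept in
# doubles (exact below 2^53), the xor only ever touches the low byte
fnv1a32 <- function(x) {
  stopifnot(is.character(x))
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32x24-bit product overflows 2^53, so multiply in 16-bit halves
    h <- ((h %% 65536) * 16777619 +
            ((h %/% 65536 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

assert_positive_scalar <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number.",
                  name, if (allow_zero) "non-negative" else "positive"))
  }
  invisible(x)
}

assert_unit_scalar <- function(x, name) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!ok) abort(sprintf("`%s` must be a single number in [0, 1].", name))
  invisible(x)
}

split_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

check_protein_alphabet <- function(chars, id = "sequence", allow_x = TRUE) {
  ok <- chars %in% AA20 | (allow_x & chars == "X")
  if (!all(ok)) {
    bad <- unique(chars[!ok])
    abort(sprintf("%s contains non-amino-acid characters: %s",
                  id, paste(bad, collapse = ", ")))
  }
  invisible(chars)
}
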