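# File formats shared by the pipeline. Sequences travel as FASTA (via
# Biostrings), tabular results as TSV with a "# coordinates: 1-based closed"
# comment header. All intervals in the package are 1-based and closed.

#' Read and write protein FASTA as a tibble
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(id = names(x), sequence = as.character(x))
}

#' @rdname read_fasta
#' @param sequences Data frame with `id` and `sequence` columns (aligned or
#'   not).
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  x <- Biostrings::AAStringSet(setNames(sequences$sequence, sequences$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a tabular result as TSV with a coordinate-convention header
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(x, path) {
  writeLines("# coordinates: 1-based closed", path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a per-residue score track TSV
#'
#' Expects header columns `id`, `position` (1-based, contiguous from 1 per
#' id), `amylo_score` and optionally `disorder_score`; extra columns are
#' kept. This is the import path for output of external amyloidogenicity /
#' disorder predictors. A missing `disorder_score` column defaults to 1
#' everywhere (fully disordered) with a warning.
#'
#' @param path TSV file; lines starting with `#` are ignored.
#' @return Tibble `id`, `position`, `amylo_score`, `disorder_score` (+ any
#'   extra columns).
#' @export
read_score_track <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("id", "position", "amylo_score")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("score track is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"disorder_score" %in% names(x)) {
    warn("no `disorder_score` column; defaulting to 1 (fully disordered).")
    x$disorder_score <- 1
  }
  x <- as_tibble(x)
  validate_score_track(x, source = path)
  x
}

validate_score_track <- function(x, source = "score track") {
  for (col in c("amylo_score", "disorder_score")) {
    bad <- which(!is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1))
    if (length(bad)) {
      abort(sprintf("%s: `%s` outside [0, 1] at line %d",
                    source, col, bad[1] + 1L))
    }
    if (anyNA(x[[col]])) {
      abort(sprintf("%s: missing `%s` at line %d",
                    source, col, which(is.na(x[[col]]))[1] + 1L))
    }
  }
  x$.line <- seq_len(nrow(x)) + 1L   # header is line 1
  split_rows <- split(seq_len(nrow(x)), x$id)
  for (rows in split_rows) {
    pos <- x$position[rows]
    expect <- seq_along(pos)
    bad <- which(pos != expect)
    if (length(bad)) {
      abort(sprintf(
        "%s: positions for '%s' must be contiguous from 1; first problem at line %d (position %s, expected %d)",
        source, x$id[rows[1]], x$.line[rows[bad[1]]], pos[bad[1]], expect[bad[1]]))
    }
  }
  invisible(x)
}

#' Convert interval-formatted predictor output to a per-residue track
#'
#' Some amyloid predictors report candidate intervals with one score per
#' candidate rather than per-residue values. Each residue receives the
#' maximum score of any candidate covering it (0 where none does), which
#' preserves "at least one candidate above threshold" semantics at every
#' residue.
#'
#' @param intervals Data frame with `id`, `start`, `end` (1-based closed)
#'   and `score`.
#' @param lengths Named integer vector: sequence length per id (every id in
#'   `intervals` must be present; ids without intervals get an all-zero
#'   track).
#' @param disorder_value Constant disorder score for the returned track.
#' @return Score-track tibble: `id`, `position`, `amylo_score`,
#'   `disorder_score`.
#' @export
#' @examples
#' iv <- tibble::tibble(id = "p", start = c(2, 4), end = c(5, 6),
#'                      score = c(0.7, 0.9))
#' intervals_to_track(iv, c(p = 8))
intervals_to_track <- function(intervals, lengths, disorder_value = 1) {
  stopifnot(is.data.frame(intervals),
            all(c("id", "start", "end", "score") %in% names(intervals)),
            !is.null(names(lengths)))
  bad <- setdiff(unique(intervals$id), names(lengths))
  if (length(bad)) {
    abort(sprintf("no length given for ids: %s", paste(bad, collapse = ", ")))
  }
  assert_unit_scalar(disorder_value, "disorder_value")
  purrr::map_dfr(names(lengths), function(id) {
    L <- as.integer(lengths[[id]])
    amylo <- numeric(L)
    iv <- intervals[intervals$id == id, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      if (iv$start[k] < 1 || iv$end[k] > L || iv$start[k] > iv$end[k]) {
        abort(sprintf("interval [%s, %s] out of bounds for '%s' (length %d)",
                      iv$start[k], iv$end[k], id, L))
      }
      span <- iv$start[k]:iv$end[k]
      amylo[span] <- pmax(amylo[span], iv$score[k])
    }
    tibble(id = id, position = seq_len(L), amylo_score = amylo,
           disorder_score = disorder_value)
  })
}

#' @rdname read_score_track
#' @param scores Data frame of per-residue scores to export.
#' @export
write_score_track <- function(scores, path) {
  stopifnot(is.data.frame(scores),
            all(c("id", "position", "amylo_score", "disorder_score") %in%
                  names(scores)))
  write_scan_tsv(scores, path)
}
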