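# Projection of per-residue amyloid information onto alignment columns and
# the per-column statistics:
#   Gaps -- fraction of rows with a gap at the column;
#   AAC  -- amino acid conservation, rate of the most frequent residue;
#   CAP  -- conservation of amyloidogenic properties, fraction of rows whose
#           residue at the column lies inside a called amyloidogenic region.
# Gap cells carry NA (never a 0), mirroring the NA-padded rearranged score
# table; the default denominators for AAC and CAP are the non-gap rows, with
# a switch to divide by all rows instead.

#' Project residue-level scores and region calls onto alignment columns
#'
#' Each alignment cell receives the residue's amyloid score and its
#' in-region flag through the residue-to-column map; gap cells are `NA` in
#' every projected field.
#'
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @param scores Per-residue score table (`id`, `position`, `amylo_score`,
#'   ...); the ungapped length of every alignment row must equal its track
#'   length.
#' @param regions Region table from [call_amyloid_regions()] (may have zero
#'   rows).
#' @return Tibble with one row per alignment cell: `id`, `column`,
#'   `residue`, `amylo_score`, `in_region` (`NA` at gaps).
#' @export
project_scores <- function(alignment, scores, regions) {
  stopifnot(is.data.frame(alignment),
            all(c("id", "aligned") %in% names(alignment)),
            is.data.frame(scores), is.data.frame(regions))
  n_col <- nchar(alignment$aligned[1])
  purrr::map_dfr(seq_len(nrow(alignment)), function(i) {
    id <- alignment$id[i]
    chars <- split_chars(alignment$aligned[i])
    map <- which(chars != "-")
    tr <- scores[scores$id == id, , drop = FALSE]
    if (nrow(tr) != length(map)) {
      abort(sprintf(
        "track length (%d) does not match ungapped row length (%d) for '%s'",
        nrow(tr), length(map), id))
    }
    tr <- tr[order(tr$position), , drop = FALSE]
    in_reg <- rep(FALSE, nrow(tr))
    iv <- regions[regions$id == id, , drop = FALSE]
    for (k in seq_len(nrow(iv))) in_reg[iv$start[k]:iv$end[k]] <- TRUE

    residue <- rep(NA_character_, n_col)
    amylo <- rep(NA_real_, n_col)
    flag <- rep(NA, n_col)
    residue[map] <- chars[map]
    amylo[map] <- tr$amylo_score
    flag[map] <- in_reg
    tibble(id = id, column = seq_len(n_col), residue = residue,
           amylo_score = amylo, in_region = flag)
  })
}

#' Per-column Gaps / AAC / CAP statistics
#'
#' @param projected Projected cell table from [project_scores()].
#' @param cap_denominator,aac_denominator `"nongap"` (default) divides by
#'   the non-gap rows of the column; `"all"` divides by all rows. Columns
#'   with no non-gap cell report `NA` for AAC and CAP under the `"nongap"`
#'   denominators.
#' @return Tibble of class `amyloscan_metrics`: `column`, `n_rows`,
#'   `n_nongap`, `gaps_fraction`, `aac`, `cap`, plus the convenience track
#'   `cap_minus_aac` (how much property conservation exceeds sequence
#'   conservation at the column).
#' @export
column_metrics <- function(projected,
                           cap_denominator = c("nongap", "all"),
                           aac_denominator = c("nongap", "all")) {
  cap_denominator <- match.arg(cap_denominator)
  aac_denominator <- match.arg(aac_denominator)
  stopifnot(is.data.frame(projected),
            all(c("id", "column", "residue", "in_region") %in%
                  names(projected)))
  n_rows <- dplyr::n_distinct(projected$id)
  out <- projected |>
    group_by(.data$column) |>
    summarise(
      n_rows = n_rows,
      n_nongap = sum(!is.na(.data$residue)),
      gaps_fraction = 1 - n_nongap / n_rows,
      top_count = if (n_nongap == 0L) NA_integer_ else
        max(table(.data$residue[!is.na(.data$residue)])),
      in_region_count = sum(.data$in_region, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      aac = .data$top_count /
        switch(aac_denominator, nongap = .data$n_nongap, all = n_rows),
      cap = dplyr::if_else(
        .data$n_nongap == 0L & cap_denominator == "nongap",
        NA_real_,
        .data$in_region_count /
          switch(cap_denominator, nongap = .data$n_nongap, all = n_rows)
      )
    ) |>
    mutate(aac = dplyr::if_else(.data$n_nongap == 0L &
                                  aac_denominator == "nongap",
                                NA_real_, .data$aac)) |>
    mutate(cap_minus_aac = .data$cap - .data$aac) |>
    select("column", "n_rows", "n_nongap", "gaps_fraction", "aac", "cap",
           "cap_minus_aac") |>
    arrange(.data$column)
  structure(out, class = c("amyloscan_metrics", class(out)))
}

#' Call conserved amyloidogenic regions from column metrics
#'
#' A conserved region is a maximal run of at least `min_length` consecutive
#' columns with `cap >= cap_min` and `gaps_fraction <= gaps_max`. Columns
#' with `NA` metrics (e.g. all-gap columns) break runs. When the metrics
#' table carries a `replicate` column, regions are called per replicate.
#'
#' @param metrics Metrics table from [column_metrics()] (optionally with a
#'   `replicate` column).
#' @param cap_min Minimum CAP (default 0.5).
#' @param gaps_max Maximum gap fraction (default 0.25).
#' @param min_length Minimum region length in columns (default 10).
#' @return Tibble of class `amyloscan_conserved`: (`replicate`,) `start`,
#'   `end`, `length`, `mean_cap`, `mean_gaps`.
#' @export
call_conserved_regions <- function(metrics, cap_min = 0.5, gaps_max = 0.25,
                                   min_length = 10L) {
  assert_unit_scalar(cap_min, "cap_min")
  assert_unit_scalar(gaps_max, "gaps_max")
  assert_positive_scalar(min_length, "min_length")
  stopifnot(is.data.frame(metrics),
            all(c("column", "gaps_fraction", "cap") %in% names(metrics)))
  call_one <- function(d) {
    d <- arrange(d, .data$column)
    ok <- !is.na(d$cap) & d$cap >= cap_min &
      !is.na(d$gaps_fraction) & d$gaps_fraction <= gaps_max
    iv <- runs_to_intervals(ok)
    iv <- iv[iv$end - iv$start + 1L >= min_length, , drop = FALSE]
    if (nrow(iv) == 0L) {
      return(tibble(start = integer(), end = integer(), length = integer(),
                    mean_cap = numeric(), mean_gaps = numeric()))
    }
    # runs_to_intervals works in row indices of d; translate to column labels
    iv |>
      mutate(
        length = .data$end - .data$start + 1L,
        mean_cap = purrr::map2_dbl(.data$start, .data$end,
                                   function(s, e) mean(d$cap[s:e])),
        mean_gaps = purrr::map2_dbl(.data$start, .data$end,
                                    function(s, e) mean(d$gaps_fraction[s:e])),
        start = d$column[.data$start],
        end = d$column[.data$end]
      )
  }
  out <- if ("replicate" %in% names(metrics)) {
    metrics |>
      group_by(.data$replicate) |>
      dplyr::group_modify(function(d, key) call_one(d)) |>
      ungroup()
  } else {
    call_one(metrics)
  }
  structure(out, class = c("amyloscan_conserved", class(out)))
}

#' Summarise column metrics across sampling replicates
#'
#' Each replicate has its own alignment, hence its own column axis, so
#' per-column values are never merged across replicates. Instead each
#' replicate's curve is reduced to scalar summaries, and those scalars are
#' averaged.
#'
#' @param metrics Metrics table with a `replicate` column (concatenated
#'   per-replicate [column_metrics()] tables).
#' @return List of class `amyloscan_aggregate` with elements
#'   `per_replicate` (tibble: `replicate`, `n_columns`, `mean_gaps`,
#'   `mean_aac`, `mean_cap`) and `overall` (tibble: `metric`, `mean`, `sd`
#'   over replicates).
#' @export
aggregate_replicates <- function(metrics) {
  stopifnot(is.data.frame(metrics),
            all(c("replicate", "gaps_fraction", "aac", "cap") %in%
                  names(metrics)))
  if (nrow(metrics) == 0L) abort("`metrics` must be non-empty.")
  per <- metrics |>
    group_by(.data$replicate) |>
    summarise(n_columns = n(),
              mean_gaps = mean(.data$gaps_fraction, na.rm = TRUE),
              mean_aac = mean(.data$aac, na.rm = TRUE),
              mean_cap = mean(.data$cap, na.rm = TRUE),
              .groups = "drop")
  overall <- per |>
    tidyr::pivot_longer(c("mean_gaps", "mean_aac", "mean_cap"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value),
              sd = if (n() > 1L) stats::sd(.data$value) else 0,
              .groups = "drop")
  structure(list(per_replicate = per, overall = overall),
            class = "amyloscan_aggregate")
}

#' @export
print.amyloscan_aggregate <- function(x, ...) {
  cat(sprintf("<amyloscan_aggregate> %d replicates\n",
              nrow(x$per_replicate)))
  print(x$overall)
  invisible(x)
}
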