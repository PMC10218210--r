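# broom-style accessors for the pipeline result and the smaller result
# objects, so everything drops straight into dplyr/ggplot workflows.

#' Tidy a pipeline run
#'
#' Returns the conserved-region table (one row per called region per
#' replicate) -- the headline result of a run.
#'
#' @param x An `amyloscan_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble: `replicate`, `start`, `end`, `length`, `mean_cap`,
#'   `mean_gaps`.
#' @export
tidy.amyloscan_run <- function(x, ...) {
  as_tibble(x$conserved)
}

#' Glance at a pipeline run
#'
#' @param x An `amyloscan_run`.
#' @param ... Unused.
#' @return One-row tibble: sequence/replicate/region counts, the fraction
#'   of proteins called potential amyloids, and mean CAP across replicates.
#' @export
glance.amyloscan_run <- function(x, ...) {
  mean_cap <- if (!is.null(x$aggregate)) {
    x$aggregate$overall$mean[x$aggregate$overall$metric == "mean_cap"]
  } else NA_real_
  tibble(
    n_sequences = x$manifest$n_sequences,
    n_classes_kept = x$manifest$n_classes_kept,
    n_replicates = x$manifest$n_replicates,
    n_conserved_regions = nrow(x$conserved),
    prop_potential_amyloid = mean(x$calls$potential_amyloid),
    mean_cap = mean_cap
  )
}

#' @export
tidy.amyloscan_aggregate <- function(x, ...) x$per_replicate

#' @export
glance.amyloscan_aggregate <- function(x, ...) {
  tidyr::pivot_wider(x$overall, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' @export
tidy.amyloscan_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.amyloscan_comparison <- function(x, ...) {
  tibble(p_value = x$p_value, significant = x$significant,
         alpha = attr(x, "alpha"))
}
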