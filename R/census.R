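# Per-taxon amyloid census and the aggregation-assay comparison statistics.

#' Per-taxon census of potential amyloids
#'
#' Counts, for every taxon at the requested level (and per gene if a `gene`
#' column is present in `calls`), how many proteins were analysed and how
#' many are potential amyloids.
#'
#' @param calls Data frame with `id` and logical `potential_amyloid`
#'   (see [is_potential_amyloid()]); an optional `gene` column stratifies
#'   the census.
#' @param taxonomy Data frame with `id` and the taxon columns (`kingdom`,
#'   `phylum`, `class`, `species`); every id in `calls` must appear.
#' @param group_level Taxon column to group by (default `"phylum"`).
#' @return Tibble of class `amyloscan_census`: (`gene`,) the level column,
#'   `n_proteins`, `n_amyloid`, `proportion`. Taxa with no proteins are
#'   absent.
#' @export
#' @examples
#' calls <- tibble::tibble(id = c("a", "b", "c", "d"),
#'                         potential_amyloid = c(TRUE, TRUE, TRUE, FALSE))
#' tax <- tibble::tibble(id = c("a", "b", "c", "d"),
#'                       phylum = c("P1", "P1", "P1", "P1"))
#' census(calls, tax)
census <- function(calls, taxonomy, group_level = "phylum") {
  stopifnot(is.data.frame(calls),
            all(c("id", "potential_amyloid") %in% names(calls)),
            is.data.frame(taxonomy), "id" %in% names(taxonomy))
  if (!group_level %in% names(taxonomy)) {
    abort(sprintf("`taxonomy` has no column '%s'.", group_level))
  }
  missing <- setdiff(calls$id, taxonomy$id)
  if (length(missing)) {
    abort(sprintf("proteins missing taxonomy records: %s",
                  paste(missing, collapse = ", ")))
  }
  joined <- calls |>
    left_join(select(taxonomy, "id", dplyr::all_of(group_level)), by = "id")
  keys <- c(intersect("gene", names(calls)), group_level)
  out <- joined |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(n_proteins = n(),
              n_amyloid = sum(.data$potential_amyloid),
              proportion = n_amyloid / n_proteins,
              .groups = "drop")
  structure(out, class = c("amyloscan_census", class(out)),
            group_level = group_level)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass method (the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table) and the
#' sample odds ratio `(a*d)/(b*c)`. A zero row or column margin makes every
#' admissible table equally extreme, so p is 1 by convention (a message is
#' emitted).
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`. A 2x2
#'   matrix may be given as `a`.
#' @return One-row tibble: `odds_ratio` (`Inf` when `b*c == 0` with
#'   `a*d > 0`, `NA` when both products are 0), `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(10, 90, 10, 90)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("cell counts must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("at least one cell must be positive.")
  or <- if (b * c == 0 && a * d == 0) NA_real_
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  zero_margin <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  if (zero_margin) {
    inform("a table margin is zero; p = 1 by convention.")
    return(tibble(odds_ratio = or, p_value = 1))
  }
  p <- stats::fisher.test(rbind(c(a, b), c(c, d)))$p.value
  tibble(odds_ratio = or, p_value = min(1, p))
}

#' Compare two aggregation-assay proportions
#'
#' Given pooled counts of cells with aggregates (`k`) out of all scored
#' cells (`n`) for two strains/conditions, reports both proportions with
#' two standard errors each -- the Wald SE `sqrt(p(1-p)/n)` (zero at k = 0)
#' and an Agresti-Coull adjusted SE (add 2 successes and 2 failures; never
#' zero) -- plus the two-sided Fisher exact p-value on the pooled 2x2 table
#' and a significance flag at `alpha`.
#'
#' @param k_a,n_a Counts for the first group (`k_a <= n_a`, `n_a > 0`).
#' @param k_b,n_b Counts for the second group.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble of class `amyloscan_comparison`: `p1`, `p2`,
#'   `se1_wald`, `se2_wald`, `se1_adjusted`, `se2_adjusted`, `odds_ratio`,
#'   `p_value`, `significant`.
#' @export
#' @examples
#' compare_aggregation(10, 100, 1, 100)
compare_aggregation <- function(k_a, n_a, k_b, n_b, alpha = 0.05) {
  for (x in list(k_a, n_a, k_b, n_b)) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        x != round(x)) {
      abort("counts must be single non-negative integers.")
    }
  }
  if (n_a == 0 || n_b == 0) abort("`n_a` and `n_b` must be positive.")
  if (k_a > n_a || k_b > n_b) abort("`k` must not exceed `n`.")
  assert_unit_scalar(alpha, "alpha")

  wald <- function(k, n) { p <- k / n; sqrt(p * (1 - p) / n) }
  adjusted <- function(k, n) {
    p <- (k + 2) / (n + 4)
    sqrt(p * (1 - p) / (n + 4))
  }
  ft <- fisher_exact_2x2(k_a, n_a - k_a, k_b, n_b - k_b)
  out <- tibble(
    p1 = k_a / n_a, p2 = k_b / n_b,
    se1_wald = wald(k_a, n_a), se2_wald = wald(k_b, n_b),
    se1_adjusted = adjusted(k_a, n_a), se2_adjusted = adjusted(k_b, n_b),
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value,
    significant = ft$p_value < alpha
  )
  structure(out, class = c("amyloscan_comparison", class(out)),
            alpha = alpha)
}
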