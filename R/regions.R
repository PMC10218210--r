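# The amyloid-call rule: a residue belongs to an amyloidogenic region when
# its amyloidogenicity score is strictly above the amyloid threshold AND its
# disorder score is strictly above the disorder threshold (a beta-arch
# candidate only counts inside an unstructured stretch). Maximal runs of
# such residues form the called intervals.

#' Call amyloidogenic regions from per-residue score tracks
#'
#' A residue is in-region iff `amylo_score > amylo_threshold` and
#' `disorder_score > disorder_threshold` (both strict, so a residue exactly
#' at a threshold is excluded). Maximal runs of in-region residues become
#' 1-based closed intervals.
#'
#' @param scores Data frame with columns `id`, `position` (1-based,
#'   contiguous from 1 per id), `amylo_score`, `disorder_score`.
#' @param amylo_threshold Amyloidogenicity cutoff (default 0.575).
#' @param disorder_threshold Disorder cutoff (default 0.3). Set to `NULL`
#'   to call on the amyloid score alone, ignoring disorder.
#' @return Tibble of class `amyloscan_regions` with columns `id`, `start`,
#'   `end`; ids with no region contribute no rows. Thresholds are stored in
#'   the `thresholds` attribute.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   id = "p1", position = 1:30, residue = "A",
#'   amylo_score = c(rep(0.2, 9), rep(0.6, 12), rep(0.2, 9)),
#'   disorder_score = 1
#' )
#' call_amyloid_regions(scores)
call_amyloid_regions <- function(scores,
                                 amylo_threshold = 0.575,
                                 disorder_threshold = 0.3) {
  stopifnot(is.data.frame(scores),
            all(c("id", "position", "amylo_score", "disorder_score") %in%
                  names(scores)))
  assert_unit_scalar(amylo_threshold, "amylo_threshold")
  if (!is.null(disorder_threshold)) {
    assert_unit_scalar(disorder_threshold, "disorder_threshold")
  }
  validate_score_track(scores, source = "scores")

  out <- scores |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      flag <- d$amylo_score > amylo_threshold
      if (!is.null(disorder_threshold)) {
        flag <- flag & d$disorder_score > disorder_threshold
      }
      runs_to_intervals(flag[order(d$position)])
    }) |>
    dplyr::ungroup()
  structure(out,
            class = c("amyloscan_regions", class(out)),
            thresholds = list(amylo = amylo_threshold,
                              disorder = disorder_threshold))
}

#' Per-protein potential-amyloid calls
#'
#' A protein is a potential amyloid iff it has at least one called
#' amyloidogenic region.
#'
#' @param regions Region table from [call_amyloid_regions()].
#' @param ids Character vector of all protein ids to report (needed so that
#'   proteins with zero regions appear as `FALSE`); defaults to the ids
#'   present in `regions`.
#' @return Tibble `id`, `n_regions`, `potential_amyloid`.
#' @export
is_potential_amyloid <- function(regions, ids = NULL) {
  stopifnot(is.data.frame(regions), all(c("id") %in% names(regions)))
  ids <- ids %||% unique(regions$id)
  counts <- regions |> dplyr::count(.data$id, name = "n_regions")
  tibble(id = ids) |>
    left_join(counts, by = "id") |>
    mutate(n_regions = dplyr::coalesce(.data$n_regions, 0L),
           potential_amyloid = .data$n_regions > 0L)
}
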