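# End-to-end orchestration: score -> call -> sample -> align -> project ->
# column metrics -> conserved regions -> census, with one validated config
# object, a manifest, and optional TSV/FASTA export of every stage.

#' Pipeline configuration
#'
#' One validated record holding every tunable of the pipeline. Validation
#' happens here, before any stage runs.
#'
#' @param amylo_threshold,disorder_threshold Amyloid-call cutoffs (strict
#'   `>`), defaults 0.575 and 0.3.
#' @param use_disorder If `FALSE`, the amyloid call and hence CAP use the
#'   amyloid score alone (score-only mode).
#' @param min_class_size,max_class_size,replicates Taxon-balanced sampling
#'   rule (defaults 3, 10, 10).
#' @param gap_open,gap_extend,matrix Aligner parameters (see
#'   [alignment_params()]).
#' @param cap_min,gaps_max,min_length Conserved-region rule (defaults 0.5,
#'   0.25, 10 columns).
#' @param cap_denominator,aac_denominator Column-metric denominators, see
#'   [column_metrics()].
#' @param predictor_mode `"surrogate"` scores sequences with the built-in
#'   scorers; `"external"` requires a `scores` table to be supplied to
#'   [run_pipeline()].
#' @param window Surrogate scorer window.
#' @param seed Master seed; all stage streams derive from it.
#' @return List of class `amyloscan_config`.
#' @export
run_config <- function(amylo_threshold = 0.575,
                       disorder_threshold = 0.3,
                       use_disorder = TRUE,
                       min_class_size = 3L,
                       max_class_size = 10L,
                       replicates = 10L,
                       gap_open = 10,
                       gap_extend = 0.5,
                       matrix = "BLOSUM62",
                       cap_min = 0.5,
                       gaps_max = 0.25,
                       min_length = 10L,
                       cap_denominator = "nongap",
                       aac_denominator = "nongap",
                       predictor_mode = c("surrogate", "external"),
                       window = 21L,
                       seed = 1L) {
  assert_unit_scalar(amylo_threshold, "amylo_threshold")
  assert_unit_scalar(disorder_threshold, "disorder_threshold")
  assert_unit_scalar(cap_min, "cap_min")
  assert_unit_scalar(gaps_max, "gaps_max")
  assert_positive_scalar(min_length, "min_length")
  assert_positive_scalar(replicates, "replicates")
  stopifnot(min_class_size >= 1L, max_class_size >= min_class_size,
            window >= 1L, window %% 2L == 1L)
  predictor_mode <- match.arg(predictor_mode)
  cap_denominator <- match.arg(cap_denominator, c("nongap", "all"))
  aac_denominator <- match.arg(aac_denominator, c("nongap", "all"))
  structure(list(
    amylo_threshold = amylo_threshold,
    disorder_threshold = disorder_threshold,
    use_disorder = isTRUE(use_disorder),
    min_class_size = as.integer(min_class_size),
    max_class_size = as.integer(max_class_size),
    replicates = as.integer(replicates),
    gap_open = gap_open,
    gap_extend = gap_extend,
    matrix = matrix,
    cap_min = cap_min,
    gaps_max = gaps_max,
    min_length = as.integer(min_length),
    cap_denominator = cap_denominator,
    aac_denominator = aac_denominator,
    predictor_mode = predictor_mode,
    window = as.integer(window),
    seed = as.integer(seed)
  ), class = "amyloscan_config")
}

stage_abort <- function(stage, parent) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage,
                conditionMessage(parent)))
}

#' Run the full conserved-amyloid-region pipeline
#'
#' Executes, in order: per-residue scoring (surrogate scorers, or the
#' supplied external `scores`), amyloid-region calling, the per-protein
#' census, taxon-balanced subsampling, per-replicate progressive alignment,
#' projection of calls onto columns, per-column Gaps/AAC/CAP metrics,
#' conserved-region calling, and replicate aggregation. Fully deterministic
#' given (sequences, taxonomy, scores, config).
#'
#' @param sequences Data frame with `id`, `sequence` and (unless `taxonomy`
#'   is given separately) the taxon columns.
#' @param taxonomy Optional data frame `id`, `kingdom`, `phylum`, `class`,
#'   `species`; defaults to the taxon columns of `sequences`.
#' @param scores Optional per-residue score table (`id`, `position`,
#'   `amylo_score`, `disorder_score`); required when
#'   `config$predictor_mode == "external"`, e.g. imported predictor output
#'   or [synthesize_score_tracks()] tracks.
#' @param config An [run_config()] object.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as TSV (plus aligned FASTA per replicate and a YAML manifest).
#' @return List of class `amyloscan_run` with elements `scores`, `regions`,
#'   `calls`, `census`, `subsamples`, `alignments` (list per replicate),
#'   `metrics` (per replicate x column), `conserved` (called regions),
#'   `aggregate`, `config`, `manifest`.
#' @export
run_pipeline <- function(sequences, taxonomy = NULL, scores = NULL,
                         config = run_config(), out_dir = NULL) {
  if (!inherits(config, "amyloscan_config")) {
    abort("`config` must be created by run_config().")
  }
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  if (is.null(taxonomy)) {
    if (!"class" %in% names(sequences)) {
      abort("supply `taxonomy` or include taxon columns in `sequences`.")
    }
    taxonomy <- select(sequences, -"sequence")
  }
  if (!all(c("id", "class") %in% names(taxonomy))) {
    abort("`taxonomy` needs at least `id` and `class` columns.")
  }

  # -- score ---------------------------------------------------------------
  if (config$predictor_mode == "external") {
    if (is.null(scores)) abort("predictor_mode 'external' requires `scores`.")
  } else if (is.null(scores)) {
    scores <- tryCatch(surrogate_scores(sequences, window = config$window),
                       error = function(e) stage_abort("score", e))
  }
  tryCatch(validate_score_track(scores, "scores"),
           error = function(e) stage_abort("score", e))

  # -- call ----------------------------------------------------------------
  regions <- tryCatch(
    call_amyloid_regions(
      scores,
      amylo_threshold = config$amylo_threshold,
      disorder_threshold = if (config$use_disorder) config$disorder_threshold
                           else NULL),
    error = function(e) stage_abort("call", e))
  calls <- is_potential_amyloid(regions, ids = sequences$id)

  # -- census --------------------------------------------------------------
  census_tbl <- tryCatch(
    if ("phylum" %in% names(taxonomy)) census(calls, taxonomy, "phylum")
    else NULL,
    error = function(e) stage_abort("census", e))

  # -- sample --------------------------------------------------------------
  members <- left_join(select(sequences, "id", "sequence"),
                       taxonomy, by = "id")
  subsamples <- tryCatch(
    filter_and_sample(members,
                      replicates = config$replicates,
                      seed = config$seed,
                      min_class_size = config$min_class_size,
                      max_class_size = config$max_class_size),
    error = function(e) stage_abort("sample", e))

  params <- alignment_params(config$matrix, config$gap_open,
                             config$gap_extend)
  alignments <- list()
  metrics_all <- list()
  reps <- unique(subsamples$replicate)
  for (r in reps) {
    sub <- filter(subsamples, .data$replicate == r)
    aln <- tryCatch(progressive_msa(sub, params),
                    error = function(e) stage_abort("align", e))
    proj <- tryCatch(project_scores(aln, scores, regions),
                     error = function(e) stage_abort("project", e))
    met <- tryCatch(column_metrics(proj,
                                   cap_denominator = config$cap_denominator,
                                   aac_denominator = config$aac_denominator),
                    error = function(e) stage_abort("metrics", e))
    alignments[[as.character(r)]] <- aln
    metrics_all[[as.character(r)]] <- mutate(met, replicate = r, .before = 1)
  }
  metrics <- bind_rows(metrics_all)

  conserved <- if (nrow(metrics)) {
    tryCatch(call_conserved_regions(metrics,
                                    cap_min = config$cap_min,
                                    gaps_max = config$gaps_max,
                                    min_length = config$min_length),
             error = function(e) stage_abort("regions", e))
  } else {
    tibble(replicate = integer(), start = integer(), end = integer(),
           length = integer(), mean_cap = numeric(), mean_gaps = numeric())
  }
  aggregate <- if (nrow(metrics)) aggregate_replicates(metrics) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("amyloscan")),
    config = unclass(config),
    seed_scheme = "derive_seed(seed, stage, index)",
    input_digest = fnv1a32(paste(sequences$id, sequences$sequence)),
    n_sequences = nrow(sequences),
    n_classes_kept = dplyr::n_distinct(subsamples$class),
    classes_dropped = attr(subsamples, "dropped_classes"),
    n_replicates = length(reps),
    n_conserved_regions = nrow(conserved)
  )

  result <- structure(list(
    scores = as_tibble(scores),
    regions = regions,
    calls = calls,
    census = census_tbl,
    subsamples = subsamples,
    alignments = alignments,
    metrics = metrics,
    conserved = conserved,
    aggregate = aggregate,
    config = config,
    manifest = manifest
  ), class = "amyloscan_run")

  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  write_scan_tsv(result$scores, file.path(out_dir, "scores.tsv"))
  write_scan_tsv(result$regions, file.path(out_dir, "amyloid_regions.tsv"))
  write_scan_tsv(result$calls, file.path(out_dir, "calls.tsv"))
  if (!is.null(result$census)) {
    write_scan_tsv(result$census, file.path(out_dir, "census.tsv"))
  }
  write_scan_tsv(result$subsamples |> select(-dplyr::any_of("sequence")),
                 file.path(out_dir, "subsamples.tsv"))
  write_scan_tsv(result$metrics, file.path(out_dir, "column_metrics.tsv"))
  write_scan_tsv(result$conserved, file.path(out_dir, "conserved_regions.tsv"))
  for (r in names(result$alignments)) {
    export_alignment(result$alignments[[r]],
                     file.path(out_dir, sprintf("alignment_rep%s.afa", r)))
  }
  invisible(out_dir)
}

#' @export
print.amyloscan_run <- function(x, ...) {
  cat(sprintf(
    "<amyloscan_run> %d sequences | %d replicates | %d conserved region(s)\n",
    x$manifest$n_sequences, x$manifest$n_replicates,
    nrow(x$conserved)))
  if (nrow(x$conserved)) print(as_tibble(x$conserved))
  invisible(x)
}
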