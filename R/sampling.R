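# Taxon-balanced subsampling: classes with fewer than `min_class_size`
# members are dropped, classes up to `max_class_size` are kept whole, larger
# classes contribute exactly `max_class_size` members drawn uniformly
# without replacement, independently per replicate.

#' Filter classes and draw taxon-balanced replicates
#'
#' @param members Data frame with one row per sequence, containing at least
#'   `id` and `class`; other columns are carried through.
#' @param replicates Number of independent subsampling replicates
#'   (default 10).
#' @param seed Master seed; replicate `r` draws from the stream
#'   `derive_seed(seed, "sample", r)`, so replicates are independent and the
#'   whole set is reproducible.
#' @param min_class_size,max_class_size Class-size window (defaults 3 and
#'   10): smaller classes are excluded entirely, larger ones downsampled to
#'   `max_class_size`.
#' @return Tibble with columns `replicate`, then the columns of `members`,
#'   one row per selected sequence. Attributes: `dropped_classes` (labels
#'   excluded by the size filter) and `manifest` (rule parameters and seed).
#'   If no class survives filtration the result has zero rows and a warning
#'   is raised.
#' @export
#' @examples
#' members <- tibble::tibble(
#'   id = paste0("s", 1:12),
#'   class = rep(c("A", "B"), c(2, 10))
#' )
#' subs <- filter_and_sample(members, replicates = 2, seed = 1)
#' table(subs$replicate, subs$class)
filter_and_sample <- function(members, replicates = 10L, seed = 1L,
                              min_class_size = 3L, max_class_size = 10L) {
  stopifnot(is.data.frame(members),
            all(c("id", "class") %in% names(members)))
  if (nrow(members) == 0L) abort("`members` must be non-empty.")
  if (anyDuplicated(members$id)) abort("sequence ids must be unique.")
  stopifnot(replicates >= 1L, min_class_size >= 1L,
            max_class_size >= min_class_size)

  sizes <- members |> dplyr::count(.data$class, name = "class_size")
  kept <- sizes$class[sizes$class_size >= min_class_size]
  dropped <- setdiff(sizes$class, kept)
  if (length(kept) == 0L) {
    warn("no class satisfies the size filter; returning an empty subsample set.")
    out <- members[0, , drop = FALSE] |>
      mutate(replicate = integer(0), .before = 1)
    return(structure(as_tibble(out),
                     dropped_classes = dropped,
                     manifest = sampling_manifest(replicates, seed,
                                                  min_class_size,
                                                  max_class_size)))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  reps <- purrr::map_dfr(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, "sample", r))
    picked <- purrr::map(sort(kept), function(cl) {
      ids <- sort(members$id[members$class == cl])
      if (length(ids) > max_class_size) {
        sort(sample(ids, max_class_size))
      } else ids
    })
    members |>
      filter(.data$id %in% unlist(picked)) |>
      mutate(replicate = r, .before = 1)
  })
  structure(as_tibble(reps),
            dropped_classes = dropped,
            manifest = sampling_manifest(replicates, seed, min_class_size,
                                         max_class_size))
}

sampling_manifest <- function(replicates, seed, min_class_size,
                              max_class_size) {
  list(replicates = as.integer(replicates),
       seed = as.integer(seed),
       seed_scheme = "derive_seed(seed, 'sample', replicate)",
       min_class_size = as.integer(min_class_size),
       max_class_size = as.integer(max_class_size))
}
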