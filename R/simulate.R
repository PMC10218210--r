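# Ortholog-family simulator: a taxonomy-shaped phylogeny (root -> class
# ancestors -> species, star within each class), sequences diverged by
# substitutions and indels, and one planted motif evolving under a reduced
# substitution rate with indels excluded, so its coordinates stay exactly
# trackable. The planted motif doubles as the true amyloidogenic region for
# the synthetic score tracks.

#' Configuration for simulating one ortholog family
#'
#' The defaults describe the simulation conditions used throughout the
#' package's validation: a 160-residue ancestor with a 40-residue motif at
#' positions 61--100 evolving five times slower than the background.
#'
#' @param ancestral_length Length of the ancestral protein, residues.
#' @param motif_start,motif_end 1-based closed interval of the planted
#'   motif; must lie within the ancestor.
#' @param background_sub_rate Expected substitutions per site per unit
#'   branch time outside the motif.
#' @param motif_sub_rate Same, inside the motif; must not exceed
#'   `background_sub_rate`.
#' @param indel_rate Expected indel events per site per unit branch time.
#' @param indel_length_mean Mean indel length, residues (geometric lengths).
#' @param branch_length_range Length-2 numeric; branch times are drawn
#'   uniformly from this range (arbitrary time units).
#' @param allow_motif_indels If `FALSE` (default) indel events never touch
#'   the motif interval, so the motif survives in every descendant.
#' @param seed Integer seed; the family is reproducible given
#'   (taxonomy, config).
#' @return A validated list of class `family_config`.
#' @export
#' @examples
#' family_config(seed = 42)
family_config <- function(ancestral_length = 160L,
                          motif_start = 61L,
                          motif_end = 100L,
                          background_sub_rate = 0.3,
                          motif_sub_rate = 0.06,
                          indel_rate = 0.01,
                          indel_length_mean = 3,
                          branch_length_range = c(0.4, 1),
                          allow_motif_indels = FALSE,
                          seed = 1L) {
  assert_positive_scalar(ancestral_length, "ancestral_length")
  assert_positive_scalar(background_sub_rate, "background_sub_rate",
                         allow_zero = TRUE)
  assert_positive_scalar(motif_sub_rate, "motif_sub_rate", allow_zero = TRUE)
  assert_positive_scalar(indel_rate, "indel_rate", allow_zero = TRUE)
  assert_positive_scalar(indel_length_mean, "indel_length_mean")
  if (motif_start < 1L || motif_end > ancestral_length ||
      motif_start > motif_end) {
    abort("motif interval must be a closed interval inside [1, ancestral_length].")
  }
  if (motif_sub_rate > background_sub_rate) {
    abort("`motif_sub_rate` must not exceed `background_sub_rate`.")
  }
  stopifnot(length(branch_length_range) == 2L,
            branch_length_range[1] > 0,
            branch_length_range[1] <= branch_length_range[2])
  structure(list(
    ancestral_length = as.integer(ancestral_length),
    motif_start = as.integer(motif_start),
    motif_end = as.integer(motif_end),
    background_sub_rate = background_sub_rate,
    motif_sub_rate = motif_sub_rate,
    indel_rate = indel_rate,
    indel_length_mean = indel_length_mean,
    branch_length_range = as.numeric(branch_length_range),
    allow_motif_indels = isTRUE(allow_motif_indels),
    seed = as.integer(seed)
  ), class = "family_config")
}

#' Build a taxonomy table for simulation
#'
#' One row per taxonomic class with the number of species to simulate in it.
#'
#' @param n_species Integer vector, species per class; names used as class
#'   labels (defaults `ClassA`, `ClassB`, ...).
#' @param phylum Phylum label per class (recycled; default splits classes
#'   over two phyla).
#' @param kingdom Single kingdom label.
#' @return Tibble with columns `kingdom`, `phylum`, `class`, `n_species`.
#' @export
#' @examples
#' taxonomy_spec(c(4, 7, 12))
taxonomy_spec <- function(n_species,
                          phylum = NULL,
                          kingdom = "Kingdom1") {
  stopifnot(is.numeric(n_species), all(n_species >= 1))
  k <- length(n_species)
  cls <- names(n_species) %||% paste0("Class", LETTERS[seq_len(k)])
  if (anyDuplicated(cls)) abort("class labels must be unique.")
  if (is.null(phylum)) {
    # first half of the classes in Phylum1, the rest in Phylum2
    phylum <- paste0("Phylum", ((seq_len(k) - 1L) %/% max(1L, ceiling(k / 2))) + 1L)
  }
  tibble(kingdom = kingdom,
         phylum = rep_len(phylum, k),
         class = cls,
         n_species = as.integer(n_species))
}

# -- internal evolution helpers ---------------------------------------------

# state: list(chars, motif = c(start, end) or NULL)
evolve_branch <- function(state, t, config) {
  chars <- state$chars
  motif <- state$motif
  L <- length(chars)

  # substitutions: per-site Poisson process => at least one event with
  # probability 1 - exp(-rate * t); replacement uniform over the other 19
  in_motif <- rep(FALSE, L)
  if (!is.null(motif)) in_motif[motif[1]:motif[2]] <- TRUE
  p <- ifelse(in_motif,
              1 - exp(-config$motif_sub_rate * t),
              1 - exp(-config$background_sub_rate * t))
  hit <- runif(L) < p
  if (any(hit)) {
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
    }
  }

  # indels: Poisson event count over the branch, geometric lengths,
  # excluded from the motif unless allowed
  n_events <- rpois(1L, config$indel_rate * L * t)
  for (e in seq_len(n_events)) {
    len <- rgeom(1L, 1 / config$indel_length_mean) + 1L
    L <- length(chars)
    if (runif(1) < 0.5) {                     # insertion after position pos
      pos <- sample(0:L, 1L)
      if (!config$allow_motif_indels && !is.null(motif) &&
          pos >= motif[1] && pos < motif[2]) next
      ins <- sample(AA20, len, replace = TRUE)
      chars <- append(chars, ins, after = pos)
      if (!is.null(motif) && pos < motif[1]) motif <- motif + len
    } else {                                  # deletion of [pos, pos+len-1]
      if (L <= len) next
      pos <- sample(seq_len(L - len + 1L), 1L)
      del <- c(pos, pos + len - 1L)
      if (!is.null(motif) && del[1] <= motif[2] && del[2] >= motif[1]) {
        if (!config$allow_motif_indels) next
        # truncate the motif by the overlap, in post-deletion coordinates
        keep <- setdiff(motif[1]:motif[2], del[1]:del[2])
        motif <- if (length(keep) == 0L) NULL else {
          range(vapply(keep, function(p) p - sum(del[1]:del[2] < p), 1L))
        }
        chars <- chars[-(del[1]:del[2])]
        next
      }
      chars <- chars[-(del[1]:del[2])]
      if (!is.null(motif) && del[2] < motif[1]) motif <- motif - len
    }
  }
  list(chars = chars, motif = motif)
}

#' Simulate an ortholog family with a planted conserved motif
#'
#' Generates one protein sequence per species under a taxonomy-shaped
#' phylogeny: the root sequence evolves independently into one ancestor per
#' class, and each class ancestor into its species (a star tree within the
#' class). Substitutions follow a per-site Poisson process (uniform
#' replacement among the 19 alternatives); indels follow a per-branch
#' Poisson count with geometric lengths and by default never touch the
#' planted motif, whose coordinates are tracked exactly into every
#' descendant.
#'
#' @param taxonomy Data frame as returned by [taxonomy_spec()].
#' @param config A [family_config()].
#' @return A list of class `ortholog_family`:
#'   \describe{
#'     \item{sequences}{tibble `id`, `kingdom`, `phylum`, `class`,
#'       `species`, `sequence`}
#'     \item{truth}{tibble `id`, `start`, `end`, `kind` giving the planted
#'       motif in current coordinates (1-based closed); sequences in which
#'       the motif was deleted have no row}
#'   }
#' @export
#' @examples
#' fam <- simulate_family(taxonomy_spec(c(3, 4)), family_config(seed = 7))
#' fam$sequences$id
simulate_family <- function(taxonomy, config = family_config()) {
  stopifnot(is.data.frame(taxonomy),
            all(c("kingdom", "phylum", "class", "n_species") %in%
                  names(taxonomy)))
  if (anyDuplicated(taxonomy$class)) abort("class labels must be unique.")
  if (any(taxonomy$n_species < 1)) abort("species counts must be >= 1.")
  if (!inherits(config, "family_config")) abort("`config` must be a family_config().")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "simulate"))

  root <- list(chars = sample(AA20, config$ancestral_length, replace = TRUE),
               motif = c(config$motif_start, config$motif_end))
  blr <- config$branch_length_range

  seq_rows <- list()
  truth_rows <- list()
  for (ci in seq_len(nrow(taxonomy))) {
    cls <- taxonomy$class[ci]
    anc <- evolve_branch(root, runif(1, blr[1], blr[2]), config)
    for (si in seq_len(taxonomy$n_species[ci])) {
      tip <- evolve_branch(anc, runif(1, blr[1], blr[2]), config)
      id <- sprintf("%s_sp%02d", cls, si)
      seq_rows[[length(seq_rows) + 1L]] <- tibble(
        id = id,
        kingdom = taxonomy$kingdom[ci],
        phylum = taxonomy$phylum[ci],
        class = cls,
        species = id,
        sequence = paste(tip$chars, collapse = "")
      )
      if (!is.null(tip$motif)) {
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          id = id, start = tip$motif[1], end = tip$motif[2], kind = "motif"
        )
      }
    }
  }
  out <- list(sequences = bind_rows(seq_rows), truth = bind_rows(truth_rows))
  if (nrow(out$truth) == 0L) {
    out$truth <- tibble(id = character(), start = integer(),
                        end = integer(), kind = character())
  }
  class(out) <- "ortholog_family"
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat(sprintf("<ortholog_family> %d sequences, %d classes, motif tracked in %d\n",
              nrow(x$sequences), dplyr::n_distinct(x$sequences$class),
              nrow(x$truth)))
  invisible(x)
}

#' Paint synthetic per-residue score tracks from ground truth
#'
#' Produces score tracks of the shape downstream stages expect: residues
#' inside the true amyloidogenic intervals get mean `in_motif_score`, all
#' others `background_score`, plus Gaussian noise clipped to `[0, 1]`. The
#' disorder track is a constant (default 1: fully disordered), so the
#' amyloid-call rule is driven by the amyloid score alone unless the caller
#' lowers it.
#'
#' @param sequences Data frame with `id` and `sequence` columns.
#' @param truth Data frame of true intervals (`id`, `start`, `end`), e.g.
#'   `simulate_family()$truth`. Ids without intervals get flat background.
#' @param in_motif_score,background_score Mean scores inside/outside the
#'   true intervals, in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param disorder_value Constant disorder score, in `[0, 1]`.
#' @param seed Integer seed for the noise stream.
#' @return Tibble `id`, `position`, `residue`, `amylo_score`,
#'   `disorder_score`, one row per residue.
#' @export
#' @examples
#' fam <- simulate_family(taxonomy_spec(c(3, 3)), family_config(seed = 7))
#' tracks <- synthesize_score_tracks(fam$sequences, fam$truth)
synthesize_score_tracks <- function(sequences, truth,
                                    in_motif_score = 0.8,
                                    background_score = 0.2,
                                    noise_sd = 0,
                                    disorder_value = 1,
                                    seed = 1L) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  assert_unit_scalar(in_motif_score, "in_motif_score")
  assert_unit_scalar(background_score, "background_score")
  assert_unit_scalar(disorder_value, "disorder_value")
  assert_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  if (nrow(sequences) == 0L) {
    return(tibble(id = character(), position = integer(),
                  residue = character(), amylo_score = numeric(),
                  disorder_score = numeric()))
  }
  bad <- setdiff(unique(truth$id), sequences$id)
  if (length(bad)) {
    abort(sprintf("truth refers to unknown sequence ids: %s",
                  paste(bad, collapse = ", ")))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "tracks"))

  purrr::map2_dfr(sequences$id, sequences$sequence, function(id, seq) {
    chars <- split_chars(seq)
    L <- length(chars)
    amylo <- rep(background_score, L)
    iv <- truth[truth$id == id, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      if (iv$start[k] < 1L || iv$end[k] > L || iv$start[k] > iv$end[k]) {
        abort(sprintf("truth interval [%d, %d] out of bounds for '%s' (length %d)",
                      iv$start[k], iv$end[k], id, L))
      }
      amylo[iv$start[k]:iv$end[k]] <- in_motif_score
    }
    if (noise_sd > 0) amylo <- pmin(1, pmax(0, amylo + rnorm(L, 0, noise_sd)))
    tibble(id = id, position = seq_len(L), residue = chars,
           amylo_score = amylo, disorder_score = disorder_value)
  })
}

#' Column span of the planted motif in an alignment
#'
#' Maps every sequence's true motif interval through the alignment and
#' returns the columns where at least `min_fraction` of the rows place a
#' motif residue -- the ground-truth column set used to judge recovered
#' conserved regions.
#'
#' @param alignment Alignment tibble (`id`, `aligned`) as produced by
#'   [progressive_msa()].
#' @param truth Ground-truth interval table (`id`, `start`, `end`).
#' @param min_fraction Minimum fraction of rows supporting a column.
#' @return Sorted integer vector of alignment columns (possibly empty).
#' @export
motif_column_span <- function(alignment, truth, min_fraction = 0.5) {
  stopifnot(is.data.frame(alignment),
            all(c("id", "aligned") %in% names(alignment)))
  n_col <- nchar(alignment$aligned[1])
  votes <- numeric(n_col)
  for (i in seq_len(nrow(alignment))) {
    id <- alignment$id[i]
    iv <- truth[truth$id == id, , drop = FALSE]
    if (nrow(iv) == 0L) next
    map <- residue_to_column(alignment, id)
    for (k in seq_len(nrow(iv))) {
      pos <- iv$start[k]:iv$end[k]
      pos <- pos[pos <= length(map)]
      votes[map[pos]] <- votes[map[pos]] + 1
    }
  }
  which(votes / nrow(alignment) >= min_fraction)
}
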