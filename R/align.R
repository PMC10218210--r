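# Progressive multiple sequence alignment. A deliberately simple,
# deterministic stand-in for production aligners: global affine-gap pairwise
# alignment (compiled Gotoh core), guide tree by average-linkage clustering
# of 1 - fractional identity, then profile-profile progressive merging
# (profiles are per-column residue frequency vectors scored against the same
# substitution matrix; once a gap, always a gap; no refinement pass). An
# import path accepts externally computed alignments so the downstream
# column statistics can also run on alignments from any other tool.

#' Alignment parameters
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open Gap opening penalty (>= 0); the first position of a gap
#'   costs `gap_open + gap_extend`.
#' @param gap_extend Gap extension penalty (>= 0) per gapped position.
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  assert_positive_scalar(gap_open, "gap_open", allow_zero = TRUE)
  assert_positive_scalar(gap_extend, "gap_extend", allow_zero = TRUE)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, submat = load_submat(matrix)),
            class = "alignment_params")
}

load_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(get(name, envir = e))
}

seq_to_idx <- function(sequence, submat, id = "sequence") {
  chars <- split_chars(sequence)
  idx <- match(chars, rownames(submat))
  if (anyNA(idx)) {
    abort(sprintf("%s contains characters absent from the substitution matrix: %s",
                  id, paste(unique(chars[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment maximising
#' `sum(matrix) - gaps`, end gaps penalised. Ties are broken
#' deterministically: residue-residue pairing is preferred over a gap in
#' `a`, which is preferred over a gap in `b`.
#'
#' @param a,b Protein sequence strings (non-empty).
#' @param params An [alignment_params()].
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   and `identity` (matches / alignment length).
#' @export
#' @examples
#' pairwise_align("HEAGAWGHEE", "PAWHEAE")$score
pairwise_align <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty.")
  sm <- params$submat
  ai <- seq_to_idx(a, sm, "a")
  bi <- seq_to_idx(b, sm, "b")
  cell <- sm[ai, bi, drop = FALSE]
  res <- gotoh_align_cpp(cell, params$gap_open, params$gap_extend)
  ac <- split_chars(a); bc <- split_chars(b)
  ga <- ifelse(res$a_path == 0L, "-", ac[pmax(res$a_path, 1L)])
  gb <- ifelse(res$b_path == 0L, "-", bc[pmax(res$b_path, 1L)])
  matches <- sum(ga == gb & ga != "-")
  list(aligned_a = paste(ga, collapse = ""),
       aligned_b = paste(gb, collapse = ""),
       score = res$score,
       identity = matches / length(ga))
}

#' Guide tree for progressive alignment
#'
#' Pairwise distances are `1 - identity` from global pairwise alignments;
#' clustering is average linkage. Sequences are sorted by id first, which
#' fixes the join order when distances tie.
#'
#' @param sequences Data frame with `id` and `sequence`.
#' @param params An [alignment_params()].
#' @return An [stats::hclust] object with sequence ids as labels (a single
#'   sequence yields a degenerate one-leaf tree represented as a list with
#'   `labels`).
#' @export
build_guide_tree <- function(sequences, params = alignment_params()) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  if (anyDuplicated(sequences$id)) abort("sequence ids must be unique.")
  sequences <- arrange(sequences, .data$id)
  n <- nrow(sequences)
  if (n == 1L) {
    return(structure(list(labels = sequences$id), class = "amyloscan_leaf"))
  }
  d <- matrix(0, n, n, dimnames = list(sequences$id, sequences$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pa <- pairwise_align(sequences$sequence[i], sequences$sequence[j],
                           params)
      d[i, j] <- d[j, i] <- 1 - pa$identity
    }
  }
  hclust(as.dist(d), method = "average")
}

#' Export a guide tree as newick
#'
#' @param tree An [stats::hclust] guide tree from [build_guide_tree()].
#' @param path Output file.
#' @export
write_guide_tree <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# per-column residue frequency profile of a gapped character matrix,
# over the alphabet of the substitution matrix; gaps contribute no mass
profile_of <- function(mat, alphabet) {
  n <- nrow(mat)
  apply(mat, 2L, function(col) {
    tabulate(match(col, alphabet), nbins = length(alphabet)) / n
  })
}

#' Progressive multiple sequence alignment
#'
#' Aligns the sequences along the guide tree by repeated profile-profile
#' alignment (sum-of-pairs expected score under the substitution matrix;
#' same affine gap penalties as the pairwise stage). Gap columns, once
#' introduced, are never removed. Input order does not matter: sequences
#' are sorted by id before the guide tree is built.
#'
#' @param sequences Data frame with `id` and `sequence` (>= 1 row).
#' @param params An [alignment_params()].
#' @return Tibble of class `amyloscan_msa` with columns `id`, `aligned`
#'   (equal-length gapped strings), rows ordered by id. Ungapping any row
#'   reproduces its input sequence.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = c("s1", "s2"), sequence = c("ACDE", "ACE"))
#' progressive_msa(seqs)
progressive_msa <- function(sequences, params = alignment_params()) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  if (nrow(sequences) == 0L) abort("`sequences` must be non-empty.")
  sequences <- arrange(sequences, .data$id)
  if (nrow(sequences) == 1L) {
    out <- tibble(id = sequences$id, aligned = sequences$sequence)
    return(structure(out, class = c("amyloscan_msa", class(out))))
  }
  sm <- params$submat
  alphabet <- rownames(sm)
  tree <- build_guide_tree(sequences, params)

  # cluster state: gapped character matrix with rownames = ids
  leaf_mat <- function(i) {
    chars <- split_chars(sequences$sequence[i])
    check_idx <- seq_to_idx(sequences$sequence[i], sm, sequences$id[i])
    matrix(chars, nrow = 1L, dimnames = list(sequences$id[i], NULL))
  }
  clusters <- vector("list", nrow(tree$merge))
  get_cluster <- function(k) {
    if (k < 0L) leaf_mat(-k) else clusters[[k]]
  }
  for (step in seq_len(nrow(tree$merge))) {
    A <- get_cluster(tree$merge[step, 1L])
    B <- get_cluster(tree$merge[step, 2L])
    pA <- profile_of(A, alphabet)
    pB <- profile_of(B, alphabet)
    cell <- crossprod(sm %*% pA, pB)          # t(pA) S pB, nA x nB
    path <- gotoh_align_cpp(cell, params$gap_open, params$gap_extend)
    newA <- matrix("-", nrow(A), length(path$a_path),
                   dimnames = list(rownames(A), NULL))
    newB <- matrix("-", nrow(B), length(path$b_path),
                   dimnames = list(rownames(B), NULL))
    newA[, path$a_path != 0L] <- A[, path$a_path[path$a_path != 0L],
                                   drop = FALSE]
    newB[, path$b_path != 0L] <- B[, path$b_path[path$b_path != 0L],
                                   drop = FALSE]
    clusters[[step]] <- rbind(newA, newB)
  }
  final <- clusters[[nrow(tree$merge)]]
  final <- final[order(rownames(final)), , drop = FALSE]
  out <- tibble(id = rownames(final),
                aligned = unname(apply(final, 1L, paste, collapse = "")))
  structure(out, class = c("amyloscan_msa", class(out)))
}

#' Import / export an alignment as aligned FASTA
#'
#' @param path Aligned FASTA file (all rows equal length).
#' @param expected_ids Optional character vector; the file must contain
#'   exactly these ids.
#' @return `import_alignment()`: an alignment tibble (`id`, `aligned`),
#'   rows sorted by id.
#' @export
import_alignment <- function(path, expected_ids = NULL) {
  x <- read_fasta(path)
  if (nrow(x) == 0L) abort("alignment file contains no sequences.")
  widths <- nchar(x$sequence)
  if (length(unique(widths)) != 1L) {
    abort("ragged alignment: rows have unequal lengths.")
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, x$id)
    extra <- setdiff(x$id, expected_ids)
    if (length(missing) || length(extra)) {
      abort(sprintf("alignment ids do not match: missing [%s], extra [%s]",
                    paste(missing, collapse = ", "),
                    paste(extra, collapse = ", ")))
    }
  }
  out <- tibble(id = x$id, aligned = x$sequence) |> arrange(.data$id)
  structure(out, class = c("amyloscan_msa", class(out)))
}

#' @rdname import_alignment
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @export
export_alignment <- function(alignment, path) {
  stopifnot(is.data.frame(alignment),
            all(c("id", "aligned") %in% names(alignment)))
  write_fasta(dplyr::rename(alignment, sequence = "aligned"), path)
}

#' Residue/column coordinate maps of an alignment row
#'
#' `residue_to_column()` maps each residue position (1-based, ungapped) of
#' one row to its alignment column; `column_to_residue()` is the inverse,
#' with `NA` at gap columns.
#'
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @param id Sequence id of the row.
#' @return Integer vector (strictly increasing for `residue_to_column()`).
#' @export
#' @examples
#' aln <- tibble::tibble(id = "s1", aligned = "-AC-G")
#' residue_to_column(aln, "s1")
residue_to_column <- function(alignment, id) {
  row <- alignment$aligned[match(id, alignment$id)]
  if (is.na(row)) abort(sprintf("unknown sequence id '%s'", id))
  which(split_chars(row) != "-")
}

#' @rdname residue_to_column
#' @export
column_to_residue <- function(alignment, id) {
  row <- alignment$aligned[match(id, alignment$id)]
  if (is.na(row)) abort(sprintf("unknown sequence id '%s'", id))
  chars <- split_chars(row)
  out <- rep(NA_integer_, length(chars))
  out[chars != "-"] <- seq_len(sum(chars != "-"))
  out
}

#' Sum-of-pairs score of an alignment
#'
#' Scores every pair of rows with the substitution matrix and affine gap
#' penalties (a gap run against residues costs
#' `gap_open + gap_extend * length`; columns where both rows gap are
#' skipped), then sums over pairs. Used to sanity-check that the
#' progressive result beats naive stacking.
#'
#' @param alignment Alignment tibble (`id`, `aligned`).
#' @param params An [alignment_params()].
#' @return A single number.
#' @export
sum_of_pairs_score <- function(alignment, params = alignment_params()) {
  sm <- params$submat
  rows <- lapply(alignment$aligned, split_chars)
  n <- length(rows)
  total <- 0
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      a <- rows[[i]]; b <- rows[[j]]
      keep <- !(a == "-" & b == "-")
      a <- a[keep]; b <- b[keep]
      both <- a != "-" & b != "-"
      if (any(both)) total <- total + sum(sm[cbind(a[both], b[both])])
      for (gapped in list(a == "-", b == "-")) {
        if (any(gapped)) {
          r <- rle(gapped)
          runs <- r$lengths[r$values]
          total <- total - sum(params$gap_open + params$gap_extend * runs)
        }
      }
    }
  }
  total
}
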