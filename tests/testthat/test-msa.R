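params <- alignment_params()

test_that("self-alignment has no gaps and scores the matrix diagonal", {
  s <- "MKNLAFIVGHEE"
  pa <- pairwise_align(s, s, params)
  expect_equal(pa$aligned_a, s)
  expect_equal(pa$aligned_b, s)
  expect_equal(pa$identity, 1)
  chars <- strsplit(s, "")[[1]]
  expect_equal(pa$score, sum(params$submat[cbind(chars, chars)]))
})

test_that("empty or invalid sequences are rejected", {
  expect_error(pairwise_align("A", "", params), "non-empty")
  expect_error(pairwise_align("", "A", params), "non-empty")
  expect_error(pairwise_align("AC1", "AC", params), "absent from")
})

test_that("pairwise scores equal the brute-force affine oracle on random pairs", {
  set.seed(11)
  for (k in 1:30) {
    a <- random_protein(sample(1:12, 1))
    b <- random_protein(sample(1:12, 1))
    got <- pairwise_align(a, b, params)$score
    want <- oracle_affine_score(a, b, params$submat,
                                params$gap_open, params$gap_extend)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("score(%s, %s)", a, b))
  }
})

test_that("guide tree joins identical sequences first and ties break lexicographically", {
  seqs <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    sequence = c("ACDEFGHIKL", "ACDEFGHIKL", "WWWWWWWWWW"))
  tree <- build_guide_tree(seqs, params)
  expect_s3_class(tree, "hclust")
  expect_equal(sort(tree$merge[1, ]), c(-2L, -1L))  # the identical pair
  expect_setequal(tree$labels, seqs$id)

  # all pairwise distances equal: first join is the lexicographically
  # smallest pair of ids
  eq <- tibble::tibble(id = c("b", "c", "a"),
                       sequence = c("C", "D", "A"))
  t2 <- build_guide_tree(eq, params)
  expect_equal(sort(t2$merge[1, ]), c(-2L, -1L))    # labels sorted: a, b
  expect_equal(t2$labels[1:2], c("a", "b"))

  nw <- withr::local_tempfile(fileext = ".nwk")
  write_guide_tree(tree, nw)
  phy <- ape::read.tree(nw)
  expect_setequal(phy$tip.label, seqs$id)
})

test_that("progressive alignment handles identical sequences and single indels", {
  same <- tibble::tibble(id = paste0("s", 1:5),
                         sequence = rep("MKVLAGHEE", 5))
  aln <- progressive_msa(same, params)
  expect_false(any(grepl("-", aln$aligned, fixed = TRUE)))
  expect_equal(nchar(aln$aligned), rep(9L, 5))

  pair <- tibble::tibble(id = c("s1", "s2"), sequence = c("ACDE", "ACE"))
  a2 <- progressive_msa(pair, params)
  expect_equal(a2$aligned[a2$id == "s1"], "ACDE")
  expect_equal(a2$aligned[a2$id == "s2"], "AC-E")
})

test_that("ungapping any alignment row recovers its input sequence", {
  set.seed(3)
  seqs <- tibble::tibble(id = sprintf("q%02d", 1:6),
                         sequence = replicate(6, random_protein(sample(20:40, 1))))
  aln <- progressive_msa(seqs, params)
  expect_length(unique(nchar(aln$aligned)), 1L)
  ungapped <- gsub("-", "", aln$aligned, fixed = TRUE)
  expect_equal(ungapped[match(seqs$id, aln$id)], seqs$sequence)
})

test_that("progressive alignment is input-order independent and beats naive stacking", {
  set.seed(8)
  base <- random_protein(35)
  mutate_seq <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), 4)
    ch[i] <- sample(c("A", "G", "S", "V"), 4, replace = TRUE)
    paste(ch[-sample(seq_along(ch), 2)], collapse = "")
  }
  seqs <- tibble::tibble(id = sprintf("r%d", 1:5),
                         sequence = c(base, replicate(4, mutate_seq(base))))
  a1 <- progressive_msa(seqs, params)
  a2 <- progressive_msa(seqs[sample(1:5), ], params)
  expect_identical(as.data.frame(a1), as.data.frame(a2))

  # naive stack-and-pad alignment of the same sequences
  w <- max(nchar(seqs$sequence))
  stacked <- dplyr::mutate(seqs, aligned = paste0(
    sequence, strrep("-", w - nchar(sequence))))
  expect_gte(sum_of_pairs_score(a1, params),
             sum_of_pairs_score(stacked, params))
})

test_that("aligned-FASTA import validates shape and round-trips", {
  aln <- progressive_msa(tibble::tibble(
    id = c("x", "y", "z"),
    sequence = c("ACDEFGHIKL", "ACDEGHIKL", "ACDEFGHKL")), params)
  path <- withr::local_tempfile(fileext = ".afa")
  export_alignment(aln, path)
  back <- import_alignment(path, expected_ids = c("x", "y", "z"))
  expect_equal(as.data.frame(back), as.data.frame(aln))

  expect_error(import_alignment(path, expected_ids = c("x", "y")),
               "extra \\[z\\]")
  ragged <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">a", "AC-DE", ">b", "ACDE"), ragged)
  expect_error(import_alignment(ragged), "ragged")
})

test_that("residue/column maps are mutually inverse", {
  aln <- tibble::tibble(id = c("s1", "s2"),
                        aligned = c("-AC-G", "TACQG"))
  expect_equal(residue_to_column(aln, "s1"), c(2L, 3L, 5L))
  expect_equal(residue_to_column(aln, "s2"), 1:5)
  c2r <- column_to_residue(aln, "s1")
  expect_equal(c2r, c(NA, 1L, 2L, NA, 3L))
  map <- residue_to_column(aln, "s1")
  expect_equal(c2r[map], seq_along(map))
  expect_error(residue_to_column(aln, "nope"), "unknown sequence id")
})
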