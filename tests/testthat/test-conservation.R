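test_that("projection carries scores through the column map and NA-fills gaps", {
  aln <- tibble::tibble(id = c("s1", "s2"),
                        aligned = c("AC", "-A"))
  scores <- dplyr::bind_rows(
    make_track(c(0.9, 0.1), id = "s1"),
    make_track(0.9, id = "s2"))
  regions <- call_amyloid_regions(scores)
  proj <- project_scores(aln, scores, regions)
  expect_equal(nrow(proj), 4L)

  s2 <- proj[proj$id == "s2", ]
  expect_true(is.na(s2$residue[1]))
  expect_true(is.na(s2$amylo_score[1]))
  expect_true(is.na(s2$in_region[1]))
  expect_equal(s2$amylo_score[2], 0.9)
  expect_true(s2$in_region[2])

  # NA count per row equals the gap count of that row
  na_counts <- tapply(is.na(proj$residue), proj$id, sum)
  gap_counts <- vapply(aln$aligned, function(s)
    lengths(regmatches(s, gregexpr("-", s, fixed = TRUE))), 1L)
  expect_equal(as.vector(na_counts[aln$id]), as.vector(gap_counts))

  # gapless alignment projects with zero NA cells
  aln2 <- tibble::tibble(id = c("s1", "s2"), aligned = c("AC", "CA"))
  scores2 <- dplyr::bind_rows(make_track(c(0.9, 0.1), id = "s1"),
                              make_track(c(0.2, 0.3), id = "s2"))
  proj2 <- project_scores(aln2, scores2, call_amyloid_regions(scores2))
  expect_false(anyNA(proj2$amylo_score))

  # mismatched track length is a named data error
  expect_error(project_scores(aln, scores2, regions), "s2")
})

test_that("column metrics match direct counts on a constructed column", {
  # 10 rows: 4 gaps, 6 x F all inside a called region
  ids <- sprintf("r%02d", 1:10)
  aligned <- c(rep("F", 6), rep("-", 4))
  aln <- tibble::tibble(id = ids, aligned = aligned)
  scores <- dplyr::bind_rows(lapply(ids[1:6], function(i)
    make_track(0.9, id = i)))
  proj <- project_scores(aln, scores, call_amyloid_regions(scores))
  m <- column_metrics(proj)
  expect_equal(m$gaps_fraction, 0.4)
  expect_equal(m$aac, 1)
  expect_equal(m$cap, 1)
  expect_equal(m$n_nongap, 6L)
  expect_equal(m$cap_minus_aac, m$cap - m$aac)

  # 6 non-gap cells, 3 in-region -> CAP 0.5
  scores3 <- dplyr::bind_rows(lapply(seq_len(6), function(k)
    make_track(if (k <= 3) 0.9 else 0.1, id = ids[k])))
  proj3 <- project_scores(aln, scores3, call_amyloid_regions(scores3))
  expect_equal(column_metrics(proj3)$cap, 0.5)

  # identical fully in-region sequences: every column 0 / 1 / 1
  aln4 <- tibble::tibble(id = c("a", "b", "c"),
                         aligned = rep("IVIV", 3))
  scores4 <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(i)
    make_track(rep(0.9, 4), id = i)))
  m4 <- column_metrics(project_scores(aln4, scores4,
                                      call_amyloid_regions(scores4)))
  expect_true(all(m4$gaps_fraction == 0))
  expect_true(all(m4$aac == 1))
  expect_true(all(m4$cap == 1))
})

test_that("metric identities and denominator switches hold on random columns", {
  set.seed(5)
  ids <- sprintf("r%02d", 1:8)
  rows <- replicate(8, paste(sample(c("A", "V", "-"), 12, replace = TRUE,
                                    prob = c(.4, .4, .2)), collapse = ""))
  aln <- tibble::tibble(id = ids, aligned = rows)
  scores <- dplyr::bind_rows(lapply(seq_along(ids), function(k) {
    L <- nchar(gsub("-", "", rows[k], fixed = TRUE))
    make_track(runif(L), id = ids[k])
  }))
  scores <- scores[scores$position >= 1, ]
  proj <- project_scores(aln, scores, call_amyloid_regions(scores))
  m <- column_metrics(proj)
  # gaps_fraction + n_nongap/n_rows == 1
  expect_equal(m$gaps_fraction + m$n_nongap / m$n_rows, rep(1, nrow(m)))
  # AAC >= 1/min(20, n_nongap) whenever defined
  def <- !is.na(m$aac)
  expect_true(all(m$aac[def] >= 1 / pmin(20, m$n_nongap[def])))
  # CAP invariant under row permutation
  perm <- aln[sample(seq_len(nrow(aln))), ]
  m2 <- column_metrics(project_scores(perm, scores,
                                      call_amyloid_regions(scores)))
  expect_equal(m2$cap, m$cap)
  # "all" denominators divide by all rows instead
  mall <- column_metrics(proj, cap_denominator = "all",
                         aac_denominator = "all")
  expect_equal(mall$cap * m$n_rows,
               dplyr::coalesce(m$cap, 0) * m$n_nongap)
})

test_that("all-gap columns yield NA metrics and break region runs", {
  aln <- tibble::tibble(id = c("a", "b"),
                        aligned = c("VV-VV", "VV-VV"))
  # build from an imported-style alignment where column 3 is all gaps
  scores <- dplyr::bind_rows(make_track(rep(.9, 4), id = "a"),
                             make_track(rep(.9, 4), id = "b"))
  m <- column_metrics(project_scores(aln, scores,
                                     call_amyloid_regions(scores)))
  expect_true(is.na(m$cap[3]))
  expect_true(is.na(m$aac[3]))
  regs <- call_conserved_regions(m, cap_min = 0.5, gaps_max = 0.25,
                                 min_length = 2)
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$start, c(1L, 4L))
  expect_equal(regs$end, c(2L, 5L))
})

test_that("conserved-region calling respects thresholds and minimum length", {
  m <- tibble::tibble(column = 1:30, n_rows = 10L, n_nongap = 10L,
                      gaps_fraction = 0, aac = 1, cap = 1)
  class(m) <- c("amyloscan_metrics", class(m))
  r <- call_conserved_regions(m, cap_min = 0.5, gaps_max = 0.25,
                              min_length = 5)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1L, 30L))
  expect_equal(r$mean_cap, 1)
  expect_equal(r$mean_gaps, 0)

  low <- dplyr::mutate(m, cap = 0.4)
  expect_equal(nrow(call_conserved_regions(low)), 0L)

  short <- dplyr::mutate(m, cap = ifelse(column %in% 10:15, 1, 0))
  expect_equal(nrow(call_conserved_regions(short, min_length = 10)), 0L)
  expect_equal(nrow(call_conserved_regions(short, min_length = 6)), 1L)
})

test_that("raising cap_min or lowering gaps_max never lengthens the call set", {
  set.seed(9)
  m <- tibble::tibble(column = 1:80, n_rows = 10L, n_nongap = 10L,
                      gaps_fraction = runif(80, 0, 0.5),
                      aac = runif(80), cap = runif(80))
  total <- function(cap_min, gaps_max) {
    r <- call_conserved_regions(m, cap_min = cap_min, gaps_max = gaps_max,
                                min_length = 3)
    sum(r$length)
  }
  lens <- vapply(seq(0.1, 0.9, by = 0.1), total, 1, gaps_max = 0.4)
  expect_true(all(diff(lens) <= 0))
  lens2 <- vapply(seq(0.5, 0.05, by = -0.05), total, 1, cap_min = 0.3)
  expect_true(all(diff(lens2) <= 0))
})

test_that("replicate aggregation reports scalars without merging column axes", {
  m1 <- tibble::tibble(replicate = 1L, column = 1:5, n_rows = 4L,
                       n_nongap = 4L, gaps_fraction = 0.1,
                       aac = 0.8, cap = 0.6)
  agg1 <- aggregate_replicates(m1)
  expect_equal(agg1$per_replicate$mean_cap, 0.6)
  expect_equal(agg1$overall$sd, rep(0, 3))

  two <- dplyr::bind_rows(m1, dplyr::mutate(m1, replicate = 2L))
  agg2 <- aggregate_replicates(two)
  expect_equal(nrow(agg2$per_replicate), 2L)
  expect_equal(agg2$overall$sd, rep(0, 3))

  three <- dplyr::bind_rows(two, dplyr::mutate(m1, replicate = 3L, cap = 0.9))
  agg3 <- aggregate_replicates(three)
  caps <- agg3$per_replicate$mean_cap
  ov <- agg3$overall$mean[agg3$overall$metric == "mean_cap"]
  expect_gte(ov, min(caps))
  expect_lte(ov, max(caps))
  g <- glance(agg3)
  expect_equal(g$mean_mean_cap, mean(caps))
  expect_error(aggregate_replicates(m1[0, ]), "non-empty")
})
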