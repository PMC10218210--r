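test_that("surrogate scores are length-preserving, bounded and constant on homopolymers", {
  polyg <- strrep("G", 30)
  s <- surrogate_amylo_score(polyg)
  expect_length(s, 30)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(abs(s - amylo_propensity()[["G"]]) < 1e-12))

  set.seed(42)
  rnd <- random_protein(57)
  sr <- surrogate_amylo_score(rnd)
  expect_length(sr, 57)
  expect_true(all(sr >= 0 & sr <= 1))
  expect_error(surrogate_amylo_score("ACB1"), "non-amino-acid")
})

test_that("a high-propensity block flanked by glycine peaks at the block center", {
  # 12 G | 7 I | 12 G, window 5: hand-compute the window means from the
  # shipped propensity table
  seq31 <- paste0(strrep("G", 12), strrep("I", 7), strrep("G", 12))
  s <- surrogate_amylo_score(seq31, window = 5)
  tab <- amylo_propensity()
  pI <- tab[["I"]]; pG <- tab[["G"]]
  expect_equal(s[16], pI)                        # window 14..18, all I
  expect_equal(s[14], (pI * 4 + pG) / 5)         # window 12..16
  expect_equal(s[2], pG)                         # all-G window
  # windows fully inside the block (15..17) share the maximum
  expect_equal(s[15:17], rep(pI, 3))
  expect_true(all(s[-(15:17)] < pI - 1e-9))
  expect_gt(pI, 0.575)                           # block scores amyloidogenic
  expect_lt(pG, 0.575)
})

test_that("disorder surrogate separates charged from bulky hydrophobic runs", {
  tabd <- disorder_propensity()
  e <- surrogate_disorder_score(strrep("E", 30))
  w <- surrogate_disorder_score(strrep("W", 30))
  expect_true(all(abs(e - tabd[["E"]]) < 1e-12))
  expect_true(all(abs(w - tabd[["W"]]) < 1e-12))
  expect_gt(e[1], 0.3)
  expect_lt(w[1], 0.3)
  expect_length(surrogate_disorder_score(""), 0)
})

test_that("score-track TSV round-trips and rejects malformed files", {
  scores <- surrogate_scores(
    tibble::tibble(id = c("a", "b"), sequence = c("ACDEFG", "MKLVI")),
    window = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(scores, path)
  back <- read_score_track(path)
  expect_equal(as.data.frame(back), as.data.frame(scores))

  gap <- make_track(c(0.1, 0.2, 0.3))
  gap$position <- c(1L, 2L, 4L)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(gap, p2)
  expect_error(read_score_track(p2), "line 4")

  dup <- make_track(c(0.1, 0.2, 0.3))
  dup$position <- c(1L, 2L, 2L)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(dup, p3)
  expect_error(read_score_track(p3), "contiguous")

  oob <- make_track(c(0.1, 1.5, 0.3))
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(oob, p4)
  expect_error(read_score_track(p4), "outside \\[0, 1\\] at line 3")

  nodis <- make_track(c(0.1, 0.2))
  nodis$disorder_score <- NULL
  p5 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(nodis, p5)
  expect_warning(back5 <- read_score_track(p5), "disorder_score")
  expect_true(all(back5$disorder_score == 1))
})

test_that("interval-formatted predictor output converts by max cover", {
  iv <- tibble::tibble(id = "p", start = c(2L, 4L), end = c(5L, 6L),
                       score = c(0.7, 0.9))
  tr <- intervals_to_track(iv, c(p = 8L, q = 3L))
  p <- tr[tr$id == "p", ]
  expect_equal(p$amylo_score, c(0, 0.7, 0.7, 0.9, 0.9, 0.9, 0, 0))
  expect_equal(tr$amylo_score[tr$id == "q"], c(0, 0, 0))
  expect_error(intervals_to_track(iv, c(p = 4L)), "out of bounds")
  expect_error(intervals_to_track(iv, c(q = 9L)), "no length")
})

test_that("amyloid-call rule: both thresholds strict, runs become intervals", {
  expect_equal(nrow(call_amyloid_regions(make_track(rep(0, 25)))), 0L)

  amylo <- rep(0.2, 30); amylo[10:20] <- 0.6
  r <- call_amyloid_regions(make_track(amylo))
  expect_equal(r$start, 10L)
  expect_equal(r$end, 20L)

  # high amyloid score inside an ordered (non-disordered) stretch: no call
  ordered <- make_track(rep(0.6, 30), disorder = 0.1)
  expect_equal(nrow(call_amyloid_regions(ordered)), 0L)

  # boundary residues exactly at the thresholds are excluded
  bnd <- make_track(c(0.575, 0.5751, 0.575), disorder = 1)
  rb <- call_amyloid_regions(bnd)
  expect_equal(rb$start, 2L)
  expect_equal(rb$end, 2L)
  at_dis <- make_track(rep(0.9, 5), disorder = 0.3)
  expect_equal(nrow(call_amyloid_regions(at_dis)), 0L)
})

test_that("region calling is idempotent and monotone in the amyloid threshold", {
  set.seed(7)
  tr <- make_track(runif(200), disorder = runif(200))
  r1 <- call_amyloid_regions(tr)
  r2 <- call_amyloid_regions(tr)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  cover <- function(regions) {
    if (nrow(regions) == 0) integer(0)
    else unlist(Map(seq, regions$start, regions$end))
  }
  prev <- cover(call_amyloid_regions(tr, amylo_threshold = 0.2))
  for (th in c(0.4, 0.575, 0.7, 0.9)) {
    cur <- cover(call_amyloid_regions(tr, amylo_threshold = th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("per-protein amyloid calls require at least one region", {
  amylo <- rep(0.2, 30); amylo[10:20] <- 0.9
  regions <- call_amyloid_regions(
    dplyr::bind_rows(make_track(amylo, id = "hit"),
                     make_track(rep(0.1, 30), id = "miss")))
  calls <- is_potential_amyloid(regions, ids = c("hit", "miss"))
  expect_equal(calls$potential_amyloid, c(TRUE, FALSE))
  expect_equal(calls$n_regions, c(1L, 0L))

  many <- rep(0.2, 50); many[c(5:8, 15:18, 25:28)] <- 0.9
  r3 <- call_amyloid_regions(make_track(many, id = "multi"))
  expect_equal(nrow(r3), 3L)
  expect_true(is_potential_amyloid(r3)$potential_amyloid)
})
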