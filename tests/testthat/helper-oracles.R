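# Independent oracles and small fixture builders shared by the tests.

# Brute-force affine-gap global alignment score: plain recursion with
# memoization over (i, j, state). state 0 = last move was a residue pair (or
# start), 1 = gap in a, 2 = gap in b. Entering a gap state from any other
# state costs gap_open + gap_extend, staying costs gap_extend. Kept
# deliberately independent of the package's DP.
oracle_affine_score <- function(a, b, sm, gap_open, gap_extend) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  memo <- array(NA_real_, dim = c(n + 1L, m + 1L, 3L))
  rec <- function(i, j, s) {
    if (i > n && j > m) return(0)
    if (!is.na(memo[i, j, s + 1L])) return(memo[i, j, s + 1L])
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sm[ac[i], bc[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (j <= m) {  # gap in a, consume b[j]
      cost <- gap_extend + if (s == 1L) 0 else gap_open
      best <- max(best, rec(i, j + 1L, 1L) - cost)
    }
    if (i <= n) {  # gap in b, consume a[i]
      cost <- gap_extend + if (s == 2L) 0 else gap_open
      best <- max(best, rec(i + 1L, j, 2L) - cost)
    }
    memo[i, j, s + 1L] <<- best
    best
  }
  rec(1L, 1L, 0L)
}

# Exhaustive two-sided Fisher p: enumerate every 2x2 table with the observed
# margins, sum hypergeometric probabilities <= that of the observed table
# (1e-7 relative slack for floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 - (n - c1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  p <- exp(logp)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

# one-id score track builder
make_track <- function(amylo, disorder = 1, id = "p1") {
  tibble::tibble(id = id, position = seq_along(amylo),
                 residue = rep("A", length(amylo)),
                 amylo_score = amylo,
                 disorder_score = rep_len(disorder, length(amylo)))
}

# random protein string
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# simulate a family plus noiseless painted tracks at the package defaults
simulated_fixture <- function(n_species, seed, motif_present = TRUE) {
  cfg <- if (motif_present) {
    family_config(seed = seed)
  } else {
    family_config(motif_sub_rate = 0.3, seed = seed)
  }
  fam <- simulate_family(taxonomy_spec(n_species), cfg)
  tracks <- synthesize_score_tracks(
    fam$sequences, fam$truth,
    in_motif_score = if (motif_present) 0.8 else 0.2,
    background_score = 0.2, noise_sd = 0, seed = seed)
  list(family = fam, tracks = tracks)
}

# best Jaccard between any called region of a run and the per-replicate
# motif column span
best_recovery_jaccard <- function(run, truth) {
  if (nrow(run$conserved) == 0L) return(0)
  best <- 0
  for (r in unique(run$conserved$replicate)) {
    aln <- run$alignments[[as.character(r)]]
    span <- motif_column_span(aln, truth)
    regs <- run$conserved[run$conserved$replicate == r, , drop = FALSE]
    for (k in seq_len(nrow(regs))) {
      j <- jaccard_columns(span, regs$start[k]:regs$end[k])
      best <- max(best, j)
    }
  }
  best
}
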