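test_that("mismatch scoring weights wobbles as half", {
  expect_equal(score_mismatches(rep("WC", 22))$total, 0)
  one_gu <- make_states(22, gu = 5)
  expect_equal(score_mismatches(one_gu)$total, 0.5)
  mix <- make_states(22, open = c(3, 15), gu = 8)
  sm <- score_mismatches(mix)
  expect_equal(sm$total, 2.5)
  expect_equal(sm$scores[c(3, 8, 15)], c(1, 0.5, 1))
  expect_error(score_mismatches(c("WC", "xx")), "WC, GU or open")
})

test_that("each rule flips exactly at its boundary", {
  ok <- list(mfe_duplex = -30, mfe_perfect = -30)
  rr <- function(states, mfe_d = -30, mfe_p = -30)
    apply_rules(states, mfe_duplex = mfe_d, mfe_perfect = mfe_p)
  # rule 1: total 4 passes, 4.5 fails (mismatches kept outside 1-12 runs)
  r <- rr(make_states(22, open = c(13, 15, 17, 19)))
  expect_true(r$r1); expect_true(r$verdict)
  r <- rr(make_states(22, open = c(13, 15, 17, 19), gu = 21))
  expect_false(r$r1); expect_false(r$verdict)
  expect_equal(r$mismatch_total, 4.5)
  # rule 2: run of 2 passes, run of 3 fails
  expect_true(rr(make_states(22, open = c(14, 15)))$r2)
  r <- rr(make_states(22, open = c(14, 15, 16)))
  expect_false(r$r2); expect_false(r$verdict)
  # rule 3: adjacency inside positions 2-12
  r <- rr(make_states(22, open = c(5, 6)))
  expect_false(r$r3)
  expect_true(rr(make_states(22, open = c(5, 7)))$r3)
  # rule 4: any mismatch at position 10 or 11
  r <- rr(make_states(22, open = 10))
  expect_false(r$r4); expect_false(r$verdict)
  r <- rr(make_states(22, gu = 11))
  expect_false(r$r4)
  # rule 5: 2.5 in positions 1-12 passes, 3 fails
  expect_true(rr(make_states(22, open = c(2, 4), gu = 6))$r5)
  r <- rr(make_states(22, open = c(2, 4, 6)))
  expect_false(r$r5)
  # rule 6: MFE ratio 0.75 passes, 0.74 fails
  expect_true(rr(rep("WC", 22), mfe_d = -18.75, mfe_p = -25)$r6)
  r <- rr(rep("WC", 22), mfe_d = -18.5, mfe_p = -25)
  expect_false(r$r6); expect_false(r$verdict)
  expect_equal(r$mfe_ratio, 0.74)
})

test_that("G:U lenient mode relaxes the presence rules but not the sums", {
  states <- make_states(22, gu = c(10, 11))
  strict <- apply_rules(states, mfe_duplex = -30, mfe_perfect = -30)
  lenient <- apply_rules(states, mfe_duplex = -30, mfe_perfect = -30,
                         gu_strict = FALSE)
  expect_false(strict$r4)
  expect_true(lenient$r4)
  expect_equal(strict$mismatch_total, lenient$mismatch_total)
})

test_that("perfect-complement duplexes always pass all six rules", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_rna(sample(18:24, 1))
    d <- duplex_hybridize(m, revcomp(m))
    rep <- apply_rules(d)
    expect_true(rep$verdict, label = m)
    expect_equal(rep$mfe_ratio, 1)
  }
})

test_that("repairing a mismatch never flips the verdict to false", {
  set.seed(99)
  repair <- function(s, i) {
    s[i] <- c(open = "GU", GU = "WC", WC = "WC")[s[i]]
    s
  }
  for (trial in 1:200) {
    L <- 22
    s <- sample(c("WC", "GU", "open"), L, replace = TRUE,
                prob = c(0.7, 0.15, 0.15))
    before <- apply_rules(s, mfe_duplex = -30, mfe_perfect = -30)$verdict
    i <- sample(L, 1)
    after <- apply_rules(repair(s, i), mfe_duplex = -30,
                         mfe_perfect = -30)$verdict
    if (before) expect_true(after)
  }
})

test_that("transcript scanning finds planted sites and matches the window oracle", {
  set.seed(55)
  m <- random_rna(22)
  backbone <- random_rna(300)
  tr <- paste0(substr(backbone, 1, 120), revcomp(m),
               substr(backbone, 121, 300))
  sites <- scan_transcript(m, tr)
  expect_equal(nrow(sites), 1)
  expect_true(sites$start <= 120 && sites$end >= 120 + 22)
  expect_equal(sites$mismatch_total, 0)

  # oracle: evaluate every window through the full per-duplex interface
  oracle_windows <- function(m, tr, pad = 3L) {
    L <- nchar(m); Tn <- nchar(tr)
    pcm <- perfect_complement_mfe(m)
    wlen <- min(L + pad, Tn)
    pass <- integer()
    for (s0 in 0:(Tn - (L - pad))) {
      e0 <- min(Tn, s0 + wlen)
      if (e0 - s0 < L - pad) next
      d <- duplex_hybridize(m, substr(tr, s0 + 1, e0))
      if (apply_rules(d, mfe_perfect = pcm)$verdict) pass <- c(pass, s0)
    }
    pass
  }
  raw <- scan_transcript(m, tr, merge_overlaps = FALSE)
  expect_equal(raw$start, oracle_windows(m, tr))

  # a random miRNA against a random transcript agrees too
  m2 <- random_rna(20)
  tr2 <- random_rna(250)
  raw2 <- scan_transcript(m2, tr2, merge_overlaps = FALSE)
  expect_equal(raw2$start, oracle_windows(m2, tr2))

  # transcript shorter than the miRNA
  expect_equal(nrow(scan_transcript(m, "ACGU")), 0)
})

test_that("target prediction totals include zero-site miRNAs and scale with UTRs", {
  set.seed(66)
  m1 <- random_rna(22)
  m2 <- random_rna(22)
  utr <- paste0(random_rna(60), revcomp(m1), random_rna(60))
  mirnas <- tibble::tibble(id = c("m1", "m2"), mature = c(m1, m2))
  utrs <- tibble::tibble(id = "u1", sequence = utr)
  tp <- predict_targets(mirnas, utrs)
  expect_equal(tp$totals$n_sites[tp$totals$mirna == "m1"], 1L)
  expect_true("m2" %in% tp$totals$mirna)
  doubled <- predict_targets(mirnas,
                             tibble::tibble(id = c("u1", "u2"),
                                            sequence = c(utr, utr)))
  expect_equal(doubled$totals$n_sites[doubled$totals$mirna == "m1"], 2L)
})
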