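test_that("matching scores: closed forms and scan oracle", {
  # uniform PWM forces every score to k/4 exactly
  s <- candidate_seq("u", "ACGUACGUAC")
  sc <- scan_matching_scores(s, uniform_pwm(4))
  expect_length(sc, 7L)
  expect_identical(sc, rep(1, 7))

  # perfect match sums to k
  expect_equal(scan_matching_scores(candidate_seq("x", "AC"),
                                    consensus_pwm("AC")), 2)

  # L < k errors
  expect_error(scan_matching_scores(candidate_seq("x", "AC"), uniform_pwm(4)),
               "shorter than the motif")

  # explicit small case against per-position summation
  p <- pwm(matrix(c(.7, .1, .1, .1,
                    .1, .7, .1, .1), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, c("A", "C", "G", "U"))), id = "ac")
  sc2 <- scan_matching_scores(candidate_seq("x", "ACGU"), p)
  expect_equal(sc2, naive_scan("ACGU", p$freq))
  expect_equal(sc2[1], 1.4)

  # N contributes 0.25 at any motif position
  scn <- scan_matching_scores(candidate_seq("n", "ANGU"), p)
  expect_equal(scn[1], .7 + .25)

  # 50 random instances vs the naive oracle
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    L <- sample((k + 1):40, 1)
    sq <- random_seq(L, comp = c(A = .3, C = .2, G = .2, U = .3))
    pw <- generate_pwm(k, concentration = 0.5, seed = i)
    got <- scan_matching_scores(sq, pw)
    expect_equal(got, naive_scan(sq$bases, pw$freq), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= k + 1e-12))
  }
})

test_that("select_top_sites ranks, tie-breaks leftmost, and pads", {
  out <- select_top_sites(c(5, 3, 9, 9, 1), n = 2)
  expect_equal(out$start, c(2L, 3L))
  expect_equal(out$ms, c(9, 9))

  out2 <- select_top_sites(rep(1, 4), n = 10)
  expect_equal(sum(out2$padded), 6L)
  expect_equal(out2$ms[5:10], rep(0, 6))
  expect_equal(out2$rank, 1:10)

  expect_error(select_top_sites(numeric(0)), "empty")

  # brute-force sort oracle on random scores
  set.seed(9)
  for (i in 1:5) {
    sc <- round(runif(30), 2)
    got <- select_top_sites(sc, n = 10)
    ord <- order(-sc, seq_along(sc))[1:10]
    expect_equal(got$start, ord - 1L)
    expect_equal(got$ms, sc[ord])
    expect_true(all(diff(got$ms) <= 0)) # MS non-increasing in rank
  }
})

test_that("clustering score follows the rank-weighted peak rule", {
  site <- list(start = 10L, padded = FALSE)
  # all-zero profile: single plateau, peak value 0
  expect_equal(clustering_score(rep(0, 30), site, k = 4), 0)

  # one isolated local maximum p in the window -> CS = p/2
  sc <- rep(0, 30); sc[11] <- 6
  expect_equal(clustering_score(sc, site, k = 4), 3)

  # peaks {8,4,2}: CS = 8/2 + 4/4 + 2/8
  sc <- rep(0, 40); sc[6] <- 8; sc[16] <- 4; sc[26] <- 2
  expect_equal(clustering_score(sc, list(start = 15L, padded = FALSE), k = 4),
               5.25)

  # more than five peaks: only the top five count
  sc <- rep(0, 40)
  sc[seq(2, 38, by = 4)] <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)[1:10]
  cs <- clustering_score(sc, list(start = 18L, padded = FALSE), k = 2,
                         window_nt = 100)
  expect_equal(cs, 10 / 2 + 9 / 4 + 8 / 8 + 7 / 16 + 6 / 32)

  # geometric-weight bounds
  set.seed(21)
  for (i in 1:20) {
    sc <- runif(60, 0, 5)
    st <- list(start = sample(0:50, 1), padded = FALSE)
    cs <- clustering_score(sc, st, k = 5)
    k <- 5
    mid <- st$start + k / 2
    lo <- max(0, mid - 25); hi <- min(64, mid + 25)
    win <- sc[which((seq_along(sc) - 1) >= lo - 1e-9 &
                    (seq_along(sc) - 1) + k <= hi + 1e-9)]
    expect_lte(cs, (31 / 32) * max(win) + 1e-12)
    expect_gte(cs, 0.5 * max(win) - 1e-12) # global max in window is a peak
  }

  # padded sites contribute nothing
  expect_equal(clustering_score(runif(20), list(start = NA, padded = TRUE),
                                k = 4), 0)
})

test_that("conservation score averages ten positions, clamped", {
  tr <- 0:19
  s <- candidate_seq("c", paste(rep("A", 20), collapse = ""), track = tr)
  expect_equal(conservation_score(s, list(start = 0L, padded = FALSE)),
               mean(0:9))
  # constant track -> that constant
  s2 <- candidate_seq("c2", paste(rep("A", 15), collapse = ""),
                      track = rep(1, 15))
  expect_equal(conservation_score(s2, list(start = 3L, padded = FALSE)), 1)
  # clamped at the end: mean over available positions
  expect_equal(conservation_score(s, list(start = 15L, padded = FALSE)),
               mean(15:19))
  # no track, and padded sites -> 0
  s3 <- candidate_seq("c3", "ACGUACGUACGU")
  expect_equal(conservation_score(s3, list(start = 0L, padded = FALSE)), 0)
  expect_equal(conservation_score(s, list(start = NA, padded = TRUE)), 0)
})

test_that("featurize produces the 40-vector with the documented structure", {
  fx_seq <- random_seq(80, "f1")
  set.seed(5)
  pw <- generate_pwm(5, 0.2, seed = 31)
  fv <- featurize(fx_seq, pw)
  expect_length(fv, 40L)
  expect_equal(names(fv)[c(1, 11, 21, 31)], c("MS1", "CS1", "Gacc1", "Csrv1"))
  expect_true(all(is.finite(fv)))
  expect_true(all(diff(fv[1:10]) <= 1e-12)) # MS non-increasing

  # uniform PWM + poly-A + no track: forced degenerate values
  pa <- candidate_seq("pa", paste(rep("A", 20), collapse = ""))
  fv2 <- featurize(pa, uniform_pwm(4))
  expect_equal(unname(fv2[1:10]), rep(1, 10))        # MS = k/4
  expect_equal(unname(fv2[11:20]), rep(0.5, 10))     # one plateau peak of 1
  expect_equal(unname(fv2[21:30]), rep(0, 10))       # poly-A never pairs
  expect_equal(unname(fv2[31:40]), rep(0, 10))       # no track
})

test_that("featurize agrees with an independent naive reimplementation", {
  # small instances so the enumeration folding oracle is feasible
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    L <- sample((k + 4):20, 1)
    sq <- random_seq(L, paste0("nf", i))
    if (runif(1) < 0.5) sq$track <- round(rnorm(L), 2)
    pw <- generate_pwm(k, concentration = 0.3, seed = 1000 + i)
    got <- featurize(sq, pw)
    want <- naive_featurize(sq$bases, pw$freq, sq$track)
    expect_equal(as.numeric(got), want, tolerance = 1e-10)
  }
})

test_that("planted strong-motif sequence: MS1 equals brute-force best window sum", {
  spec <- synthetic_spec(k = 7, concentration = 0.05, n_pos = 3, n_neg = 1,
                         seq_length = 120, seed = 7)
  pos <- generate_positive_set(spec)
  for (s in pos$seqs) {
    sc <- naive_scan(s$bases, spec$pwm$freq)
    fv <- featurize(s, spec$pwm)
    expect_equal(unname(fv["MS1"]), max(sc))
  }
})
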