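# The planted-motif fixtures here are intentionally small (n = 24-60,
# short sequences) so the whole file runs in seconds; the full-size
# parameter-recovery run lives in test-acceptance.R.

test_that("specific model separates planted-motif data; permuted labels do not", {
  fx <- make_planted_dataset(seed = 301, n_pos = 30, n_neg = 30,
                             seq_length = 160, k = 7)
  m <- train_specific(fx$ds, n_trees = 200, seed = 11)
  oob <- oob_scores(m)
  usable <- !is.na(oob)
  auc <- roc_auc(fx$ds$labels[usable], oob[usable])
  expect_gte(auc, 0.85)
  expect_equal(m$summary$oob_auc, auc)

  # permuted labels: no signal
  perm <- fx$ds
  perm$labels <- rbpforest:::with_seed(11, sample(perm$labels))
  mp <- train_specific(perm, n_trees = 200, seed = 11)
  expect_true(mp$summary$oob_auc > 0.3 && mp$summary$oob_auc < 0.7)
})

test_that("training is deterministic and validates its input", {
  fx <- make_planted_dataset(seed = 302, n_pos = 12, n_neg = 12,
                             seq_length = 60, k = 5)
  m1 <- train_specific(fx$ds, n_trees = 50, seed = 4)
  m2 <- train_specific(fx$ds, n_trees = 50, seed = 4)
  expect_identical(oob_scores(m1), oob_scores(m2))
  expect_identical(rbpforest:::rf_predict(m1$forest, fx$ds$x),
                   rbpforest:::rf_predict(m2$forest, fx$ds$x))
  m3 <- train_specific(fx$ds, n_trees = 50, seed = 5)
  expect_false(identical(oob_scores(m1), oob_scores(m3)))

  single <- fx$ds
  single$labels <- rep(1L, length(single$labels))
  expect_error(train_specific(single, seed = 1), "both classes")
  tiny <- fx$ds
  keep <- c(which(tiny$labels == 1)[1:5], which(tiny$labels == 0))
  tiny$x <- tiny$x[keep, ]; tiny$labels <- tiny$labels[keep]
  tiny$ids <- tiny$ids[keep]
  expect_error(train_specific(tiny, seed = 1), "at least 10")
})

test_that("OOB bookkeeping matches bootstrap-exclusion expectations", {
  fx <- make_planted_dataset(seed = 303, n_pos = 25, n_neg = 25,
                             seq_length = 60, k = 5)
  # one tree: about 1/e of rows are out-of-bag
  m1 <- train_specific(fx$ds, n_trees = 1, seed = 9)
  frac <- mean(!is.na(oob_scores(m1)))
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.55)
  # OOB fraction counted directly from the stored in-bag matrix
  expect_equal(unname(which(!is.na(oob_scores(m1)))),
               unname(which(m1$forest$inbag[, 1] == 0)))

  # many trees: every row eventually out-of-bag, scores within [0,1]
  m <- train_specific(fx$ds, n_trees = 200, seed = 9)
  s <- oob_scores(m)
  expect_false(anyNA(s))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(oob_scores(structure(list(forest = list()),
                                    class = "binding_model")),
               "out-of-bag")
})

test_that("general model pools standardized data at the requested ratio", {
  sets <- list()
  for (r in 1:3) {
    fx <- make_planted_dataset(seed = 310 + r, n_pos = 25, n_neg = 60,
                               seq_length = 120, k = 6)
    bgspec <- synthetic_spec(pwm = fx$pwm, n_neg = 30, seq_length = 120,
                             seed = 400 + r)
    st <- compute_background_stats(generate_negative_set(bgspec), fx$pwm)
    sets[[r]] <- labeled_dataset(z_transform(fx$pos_features, st),
                                 z_transform(fx$neg_features, st))
  }
  g <- train_general(sets, neg_ratio = 2, n_trees = 100, seed = 21)
  expect_equal(g$kind, "general")
  expect_true(g$standardized)
  expect_equal(g$summary$n_pos, 75L)
  expect_equal(g$summary$n_neg, 150L) # 1:2 ratio arithmetic
  expect_length(g$pwm_id, 3L)

  # raw datasets are rejected
  raw <- make_planted_dataset(seed = 320, n_pos = 12, n_neg = 12,
                              seq_length = 60, k = 5)$ds
  expect_error(train_general(list(raw, sets[[1]]), seed = 1),
               "standardized")
  # mismatched stats provenance is rejected
  bad <- sets[[1]]
  bad$stats_pwm_id <- "someone-else"
  expect_error(train_general(list(bad, sets[[2]]), seed = 1), "stats for")
  # ratio must be positive; needs >= 2 distinct PWMs
  expect_error(train_general(sets, neg_ratio = 0, seed = 1), "positive")
  expect_error(train_general(sets[1], seed = 1), "2 distinct")
})

test_that("predict_binding enforces contracts and threshold semantics", {
  fx <- make_planted_dataset(seed = 330, n_pos = 20, n_neg = 20,
                             seq_length = 120, k = 6)
  m <- train_specific(fx$ds, n_trees = 100, seed = 3)
  rec <- predict_binding(m, fx$pos_features)
  expect_equal(nrow(rec), 20L)
  expect_gte(median(rec$vote_fraction), 0.5) # separable training positives
  expect_true(all(rec$binding_call == (rec$vote_fraction >= 0.5)))
  expect_true(all(rec$best_site_start >= 1 &
                  rec$best_site_start <= 120 - 6 + 1))

  # threshold beyond 1: no positive calls
  rec2 <- predict_binding(m, fx$pos_features, call_threshold = 1.01)
  expect_false(any(rec2$binding_call))

  # raw-vs-standardized mismatch, and non-feature input
  bg <- generate_negative_set(synthetic_spec(pwm = fx$pwm, n_neg = 15,
                                             seq_length = 120, seed = 9))
  st <- compute_background_stats(bg, fx$pwm)
  expect_error(predict_binding(m, z_transform(fx$pos_features, st)),
               "standardization mismatch")
  expect_error(predict_binding(m, matrix(0, 1, 40)), "featurize_set")
})

test_that("feature importance finds the planted signal and is deterministic", {
  # only sequence signal planted (no tracks): MS/CS features carry it
  fx <- make_planted_dataset(seed = 340, n_pos = 30, n_neg = 30,
                             seq_length = 160, k = 7)
  m <- train_specific(fx$ds, n_trees = 200, seed = 13)
  imp <- feature_importance(m)
  expect_equal(dim(imp), c(40L, 2L))
  expect_true(grepl("^(MS|CS)", imp$feature[1]))
  # pure-noise features (conservation never planted) center near 0
  expect_lt(abs(mean(imp$importance[grepl("^Csrv", imp$feature)])), 0.02)
  # same seed twice: identical ranking
  expect_identical(feature_importance(m, seed = 77),
                   feature_importance(m, seed = 77))
})

test_that("cross-RBP prediction requires standardization and behaves sanely", {
  mk <- function(seed) {
    fx <- make_planted_dataset(seed = seed, n_pos = 25, n_neg = 25,
                               seq_length = 140, k = 6)
    st <- compute_background_stats(
      generate_negative_set(synthetic_spec(pwm = fx$pwm, n_neg = 30,
                                           seq_length = 140,
                                           seed = seed + 5000)),
      fx$pwm)
    list(fx = fx,
         z = labeled_dataset(z_transform(fx$pos_features, st),
                             z_transform(fx$neg_features, st)))
  }
  a <- mk(350); b <- mk(360)
  ma <- train_specific(a$z, n_trees = 200, seed = 17)
  auc_ab <- cross_predict(ma, b$z)
  expect_gt(auc_ab, 0.6) # transfer across distinct PWMs in z-space

  # optimism: a model scores its own training data at least as well as OOB
  expect_gte(cross_predict(ma, a$z), ma$summary$oob_auc)

  # label flip symmetry
  flip <- b$z
  flip$labels <- 1L - flip$labels
  expect_equal(cross_predict(ma, flip), 1 - auc_ab, tolerance = 1e-12)

  # raw features refused on either side
  expect_error(cross_predict(ma, b$fx$ds), "standardized")
  mraw <- train_specific(a$fx$ds, n_trees = 50, seed = 17)
  expect_error(cross_predict(mraw, b$z), "standardized")
})
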