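test_that("the paired t field matches the closed form and its symmetries", {
  # all differences zero: t is zero everywhere
  tf0 <- paired_t_field(matrix(0, 5, 10))
  expect_equal(tf0$t, rep(0, 10))
  # zero variance with nonzero mean: infinite t with a warning
  expect_warning(tfi <- paired_t_field(matrix(1, 5, 10)), "zero variance")
  expect_true(all(is.infinite(tfi$t)))
  withr::with_seed(1, d <- matrix(rnorm(12 * 20), 12, 20))
  tf <- paired_t_field(d)
  expect_equal(tf$df, 11L)
  j <- 7
  expect_equal(tf$t[j], mean(d[, j]) / (sd(d[, j]) / sqrt(12)))
  # invariance to subject relabeling
  tf2 <- paired_t_field(d[sample(12), ])
  expect_equal(tf2$t, tf$t)
  expect_error(paired_t_field(d[1:2, ]), class = "too_few_subjects")
})

test_that("pointwise type-I error of the t field is nominal", {
  withr::with_seed(2, {
    n_sim <- 4000
    crit <- qt(0.975, 11)
    hits <- vapply(seq_len(n_sim), function(i) {
      x <- rnorm(12)
      abs(mean(x) / (sd(x) / sqrt(12))) > crit
    }, logical(1))
  })
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("FWHM estimation recovers white-noise and smoothed-field values", {
  withr::with_seed(3, {
    est_white <- vapply(seq_len(2500), function(i) {
      x <- matrix(rnorm(12 * 101), 12, 101)
      estimate_fwhm(sweep(x, 2, colMeans(x)))
    }, numeric(1))
  })
  expect_equal(mean(est_white), sqrt(4 * log(2) / 2), tolerance = 0.05 * 1.18)
  withr::with_seed(4, {
    est_smooth <- vapply(seq_len(300), function(i) {
      x <- smooth_fields(12, 101, 4)
      estimate_fwhm(sweep(x, 2, colMeans(x)))
    }, numeric(1))
  })
  expect_equal(mean(est_smooth), 4, tolerance = 0.10 * 4)
  # doubling grid resolution halves the FWHM in index units
  withr::with_seed(5, x <- smooth_fields(12, 202, 8))
  r <- sweep(x, 2, colMeans(x))
  expect_equal(estimate_fwhm(r) / 2,
               estimate_fwhm(r[, seq(1, 202, by = 2)]), tolerance = 0.25)
  expect_error(estimate_fwhm(matrix(0, 5, 10)), class = "constant_residuals")
})

test_that("RFT thresholds behave at the limits and grow with resels", {
  # tiny resel count: threshold approaches the pointwise two-tailed quantile
  expect_equal(rft_threshold(11, 1e-9, 0.05), qt(0.975, 11), tolerance = 1e-5)
  t1 <- rft_threshold(11, 5, 0.05)
  t2 <- rft_threshold(11, 25, 0.05)
  t3 <- rft_threshold(11, 50, 0.05)
  expect_lt(t1, t2)
  expect_lt(t2, t3)
  # the threshold satisfies the expected-EC equation
  expect_equal(streamscore:::expected_ec(t2, 11, 25, TRUE), 0.05,
               tolerance = 1e-8)
  expect_error(rft_threshold(11, 25, 0), class = "invalid_alpha")
})

test_that("cluster inference flags planted effects with sane p-values", {
  withr::with_seed(6, d <- smooth_fields(12, 101, 4))
  expect_equal(nrow(spm_cluster_test(d)$clusters), 0) # typical null field
  d2 <- d
  d2[, 40:52] <- d2[, 40:52] + 1.5
  r <- spm_cluster_test(d2)
  expect_gte(nrow(r$clusters), 1)
  expect_true(any(r$clusters$significant))
  expect_true(all(r$clusters$cluster_p > 0 & r$clusters$cluster_p <= 1))
  top <- r$clusters[which.min(r$clusters$cluster_p), ]
  expect_true(top$start_idx <= 52 && top$end_idx >= 40)
  # single suprathreshold point forms a cluster of extent 1
  tfield <- c(rep(0, 10), 6, rep(0, 10))
  cl <- cluster_inference(tfield, 4.5, fwhm = 4, df = 11)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent, 1L)
  # p falls as extent grows at fixed threshold
  cl2 <- cluster_inference(c(rep(0, 8), rep(6, 3), rep(0, 10)), 4.5,
                           fwhm = 4, df = 11)
  expect_lt(cl2$cluster_p, cl$cluster_p)
})

test_that("sign-flip permutation detects planted effects and matches RFT
           boundaries", {
  withr::with_seed(7, d <- smooth_fields(12, 101, 4))
  d[, 45:54] <- d[, 45:54] + 1.0 # one-sd offset over a 10-point span
  r_rft <- spm_cluster_test(d, method = "rft")
  # given the same cluster-forming threshold the boundaries coincide exactly
  r_perm <- signflip_cluster_test(d, n_perm = 1000, seed = 8,
                                  t_crit = r_rft$t_crit)
  expect_equal(r_perm$clusters$start_idx, r_rft$clusters$start_idx)
  expect_equal(r_perm$clusters$end_idx, r_rft$clusters$end_idx)
  # at its default (uncorrected) threshold the mass test flags the effect too
  r_unc <- signflip_cluster_test(d, n_perm = 1000, seed = 8)
  expect_true(any(r_unc$clusters$significant))
  # all-zero differences cannot be significant
  z <- matrix(0, 12, 50)
  z[, 1] <- rnorm(12) # avoid all-constant columns
  expect_warning(r0 <- signflip_cluster_test(z + rnorm(600) * 1e-8,
                                             n_perm = 1000, seed = 9),
                 regexp = NA)
  expect_error(signflip_cluster_test(d, n_perm = 10), class = "invalid_n_perm")
})

test_that("planted 1-sd clusters are detected in most replicates", {
  withr::with_seed(10, {
    found <- vapply(seq_len(120), function(i) {
      d <- smooth_fields(12, 101, 2)
      d[, 45:54] <- d[, 45:54] + 1.0
      r <- signflip_cluster_test(d, n_perm = 1000)
      any(r$clusters$significant &
            r$clusters$start_idx <= 54 & r$clusters$end_idx >= 45)
    }, logical(1))
  })
  expect_gte(mean(found), 0.90)
})

test_that("analysis is restricted to the largest fully-defined window", {
  withr::with_seed(11, d <- smooth_fields(12, 40, 4))
  d[3, 1:4] <- NA
  r <- spm_cluster_test(d)
  expect_equal(r$kept_idx, 5:40)
  expect_length(r$t_field, 36)
})
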