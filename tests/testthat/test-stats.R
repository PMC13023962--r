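test_that("per-subject exponents carry within-subject uncertainty", {
  fs <- 200
  base <- noise_powerlaw(4000, fs, beta = 2, seed = 1, subject_id = "s1",
                         region = "r1", channel_id = "c1")
  dup <- base; dup$channel_id <- "c2"
  solo <- noise_powerlaw(4000, fs, beta = 2, seed = 2, subject_id = "s2",
                         region = "r1", channel_id = "c3")
  truth <- data.frame(subject_id = c("s1", "s1", "s2"), region = "r1",
                      channel_id = c("c1", "c2", "c3"),
                      age = c(30, 30, 40), sex = "F")
  co <- manual_cohort(list(base, dup, solo), truth)
  recs <- per_subject_betas(co, bd = band_low(), filter = filter_spec("lowpass"))
  # identical channels within a subject: SE exactly 0
  expect_identical(recs$within_se[recs$subject_id == "s1"], 0)
  # single-channel subject: SE 0 with one channel flagged
  expect_identical(recs$within_se[recs$subject_id == "s2"], 0)
  expect_identical(recs$n_channels[recs$subject_id == "s2"], 1L)
})

test_that("two-group region ANOVA reduces to the squared pooled t statistic", {
  recs <- simulate_beta_records(c(x = 2, y = 2.4), n_subjects = 12,
                                between_sd = 0.3, seed = 4)
  av <- region_anova(recs)
  tt <- t.test(beta_hat ~ region, data = recs, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(av$p_value, tt$p.value, tolerance = 1e-9)
  expect_identical(av$df_between, 1L)
  expect_identical(av$df_within, 22L)
})

test_that("ANOVA input validation excludes tiny regions and degenerate layouts", {
  recs <- simulate_beta_records(c(a = 2, b = 2, c = 2), n_subjects = 5, seed = 5)
  lone <- recs[recs$region != "c" | recs$subject_id == "c_s01", ]
  expect_warning(av <- region_anova(lone), "excluding")
  expect_identical(av$df_between, 1L)
  one <- recs[recs$region == "a", ]
  expect_error(suppressWarnings(region_anova(one)), "2 regions")
  expect_error(region_anova(data.frame(x = 1)), "records")
})

test_that("Tukey HSD enumerates pairs and flags exactly the shifted region", {
  recs <- simulate_beta_records(c(a = 2, b = 2, c = 2, d = 2, e = 2),
                                n_subjects = 6, seed = 6)
  tk <- tukey_hsd(recs)
  expect_identical(nrow(tk), 10L)
  expect_named(tk, c("region_i", "region_j", "diff", "lwr", "upr",
                     "p_adj", "significant"))

  # one region displaced by 5 pooled SDs: all and only its pairs significant
  hits <- vapply(1:40, function(i) {
    r <- simulate_beta_records(c(a = 2, b = 2, c = 2 + 5 * 0.3, d = 2),
                               n_subjects = 8, between_sd = 0.3,
                               within_sd = 0, seed = 600 + i)
    tk <- tukey_hsd(r)
    inv_c <- tk$region_i == "c" | tk$region_j == "c"
    all(tk$significant[inv_c]) && !any(tk$significant[!inv_c])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ANOVA and Tukey agree with a permutation reference on small cohorts", {
  set.seed(7)
  agree <- vapply(1:40, function(i) {
    shift <- sample(c(0, 0.25, 0.5), 1)
    r <- simulate_beta_records(c(a = 2, b = 2 + shift, c = 2),
                               n_subjects = 6, between_sd = 0.25,
                               seed = 700 + i)
    p_aov <- region_anova(r)$p_value
    p_perm <- perm_anova_p(r$beta_hat, r$region, nperm = 399)
    (p_aov < 0.05) == (p_perm < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("exponent-gamma correlation matches the closed form and rejects degeneracy", {
  b <- c(1.2, 1.9, 2.4, 3.0, 3.8)
  g <- c(0.11, 0.09, 0.13, 0.10, 0.12)
  ct <- beta_gamma_correlation(b, g)
  r_hand <- sum((b - mean(b)) * (g - mean(g))) /
    sqrt(sum((b - mean(b))^2) * sum((g - mean(g))^2))
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_identical(ct$n, 5L)

  lin <- beta_gamma_correlation(1:6, 2 * (1:6) + 3)
  expect_equal(lin$r, 1, tolerance = 1e-12)
  expect_lt(lin$p_value, 1e-10)

  expect_error(beta_gamma_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(beta_gamma_correlation(1:2, 1:2), "3 paired")
})

test_that("null exponent-gamma correlations are calibrated", {
  set.seed(8)
  sims <- t(replicate(500, {
    ct <- beta_gamma_correlation(rnorm(37, 2.5, 0.4), rnorm(37, 0.1, 0.02))
    c(ct$r, ct$p_value)
  }))
  expect_lt(mean(abs(sims[, 1])), 0.2)
  expect_gt(ks.test(sims[, 2], "punif")$p.value, 0.01)
})

test_that("exponent-age regression recovers exact trends and rejects bad input", {
  d <- data.frame(beta_hat = 2 + 0.01 * (20:40), age = 20:40)
  ar <- beta_age_regression(d)
  expect_equal(ar$slope, 0.01, tolerance = 1e-12)
  expect_equal(diff(ar$slope_ci), 0, tolerance = 1e-9)

  expect_error(beta_age_regression(data.frame(beta_hat = 1:2, age = 1:2)),
               "3 subjects")
  expect_error(beta_age_regression(data.frame(beta_hat = 1:5, age = rep(30, 5))),
               "identical")

  # slope CI covers zero for age-independent exponents at the nominal rate
  set.seed(9)
  cover <- vapply(1:500, function(i) {
    d <- data.frame(beta_hat = rnorm(15, 2.5, 0.3), age = runif(15, 20, 60))
    ci <- beta_age_regression(d)$slope_ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("the parameter sweep enumerates the grid deterministically and skips impossible configs", {
  spec <- data.frame(region = c("r1", "r2"), beta_low = 2, beta_high = 2)
  co <- simulate_cohort(spec, n_subjects = 2, n_channels = 1,
                        duration_s = 15, seed = 10)
  sw <- robustness_sweep(co, bands = list(band_low()),
                         nffts = c(256, 1024), orders = 7)
  # 2 cutoffs x 1 order x 2 nfft = 4 configs x 2 regions
  expect_identical(nrow(sw$table), 8L)
  expect_identical(sort(unique(sw$table$cutoff)), c(4, 8))
  sw2 <- robustness_sweep(co, bands = list(band_low()),
                          nffts = c(256, 1024), orders = 7)
  expect_identical(sw$table, sw2$table)

  w <- testthat::capture_warnings(
    sw3 <- robustness_sweep(co, bands = list(band_low()), orders = 7,
                            nffts = c(1024, 8192)))
  expect_true(all(grepl("exceeds signal length", w)))
  expect_identical(sort(unique(sw3$table$nfft)), 1024)
})
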