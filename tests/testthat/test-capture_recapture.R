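# Closed-population log-linear estimation: incidence conversion, history
# tabulation, analytic-oracle equivalences, model selection, and the
# full estimation pipeline.

test_that("to_incidence binarises pooled per-timepoint detection", {
  recs <- rbind(is_rec(pos = 1, timepoint = 12, reads = 5),
                is_rec(pos = 1, timepoint = 48, reads = 2),
                is_rec(pos = 2, timepoint = 48, reads = 7))
  x <- to_incidence(build_matrix(recs), "TN")
  expect_equal(unname(unclass(x)),
               matrix(c(1L, 0L, 1L, 1L), 2), ignore_attr = TRUE)
  expect_true(all(rowSums(x) >= 1))
  expect_error(to_incidence(build_matrix(is_rec()), "TN"),
               ">= 2 timepoints")
})

test_that("capture histories and frequencies add up", {
  x <- matrix(c(1, 0, 1,
                0, 1, 1,
                1, 1, 1), nrow = 3, byrow = TRUE)
  h <- capture_histories(x)
  expect_equal(h$n_obs, 3)
  expect_equal(sum(h$counts), h$n_obs)
  expect_equal(unname(h$f), c(0, 2, 1))
  expect_equal(h$counts[rownames(h$histories) == "111"], 1L)
  # t = 2 enumeration from the module contract
  h2 <- history_counts(c("10" = 1, "01" = 1, "11" = 1))
  expect_equal(unname(h2$f), c(2, 1))
  # conservation on random incidence matrices
  set.seed(40)
  for (i in 1:5) {
    r <- matrix(rbinom(60, 1, 0.5), ncol = 3)
    r <- r[rowSums(r) > 0, , drop = FALSE]
    hh <- capture_histories(r)
    expect_equal(sum(hh$f), nrow(r))
    expect_equal(sum(hh$counts), nrow(r))
  }
  expect_error(capture_histories(matrix(c(0, 1, 0, 1), 2)), "all-zero")
})

test_that("t=2 Mt fit reproduces Lincoln-Petersen exactly", {
  h <- history_counts(c("10" = 90, "01" = 90, "11" = 10))
  f <- fit_closedp(h, "Mt")
  expect_equal(f$N_hat, 100 * 100 / 10)
  # delta-method SE equals the Lincoln-Petersen variance
  expect_equal(f$SE, sqrt(100 * 100 * 90 * 90 / 10^3))
  # saturated overlap: no unseen mass
  f2 <- fit_closedp(history_counts(c("11" = 10, "10" = 0, "01" = 0)), "Mt")
  expect_equal(f2$N_hat, 10, tolerance = 1e-6)
  # zero overlap: infinite abundance reported as such
  f3 <- fit_closedp(history_counts(c("10" = 5, "01" = 8, "11" = 0)), "Mt")
  expect_true(is.infinite(f3$N_hat))
})

test_that("Mh-Chao log-linear equals the analytic Chao lower bound", {
  # f1=50, f2=25, f3=25 -> 100 + (2/3) * 50^2 / 50 = 133.33
  h <- history_counts(c("100" = 17, "010" = 17, "001" = 16,
                        "110" = 9, "101" = 8, "011" = 8, "111" = 25))
  expect_equal(unname(h$f), c(50, 25, 25))
  f <- fit_closedp(h, "Mh_Chao")
  expect_equal(f$N_hat, chao_lower_bound(h), tolerance = 1e-6)
  expect_equal(f$N_hat, 100 + 2 / 3 * 50^2 / 50, tolerance = 1e-6)
  # degenerate f2 = 0: bias-corrected convention (f2 := 1), flagged
  h0 <- history_counts(c("100" = 10, "010" = 10, "001" = 10, "111" = 2))
  f0 <- fit_closedp(h0, "Mh_Chao")
  expect_true(f0$degenerate)
  expect_equal(f0$N_hat, 32 + 2 / 3 * 30^2 / 2)
  expect_error(fit_closedp(history_counts(c("10" = 3, "01" = 3, "11" = 3)),
                           "Mh_Chao"), ">= 3")
})

test_that("fits conserve observed mass and never report N < n_obs", {
  set.seed(50)
  for (i in 1:8) {
    x <- matrix(rbinom(900, 1, runif(1, 0.2, 0.6)), ncol = 3)
    x <- x[rowSums(x) > 0, , drop = FALSE]
    h <- capture_histories(x)
    for (mod in c("M0", "Mt", "Mh_Chao", "Mth_Chao")) {
      f <- fit_closedp(h, mod)
      expect_gte(f$N_hat, f$n_obs)
      # Poisson GLM with intercept: fitted history means sum to n_obs
      expect_equal(sum(f$fitted), h$n_obs, tolerance = 1e-6)
      # Chao heterogeneity terms are constrained non-negative
      if (!is.null(f$coefficients)) {
        etas <- grep("^eta", names(f$coefficients), value = TRUE)
        expect_true(all(is.na(f$coefficients[etas]) |
                          f$coefficients[etas] >= 0))
      }
    }
  }
})

test_that("model selection takes lowest BIC then smallest N", {
  h <- capture_histories({
    set.seed(60)
    x <- matrix(rbinom(600, 1, 0.4), ncol = 3)
    x[rowSums(x) > 0, , drop = FALSE]
  })
  fits <- fit_closedp_all(h)
  sel <- select_model(fits)
  bics <- vapply(fits, `[[`, 0, "BIC")
  expect_equal(sel$BIC, min(bics))
  expect_identical(select_model(fits["Mt"])$model, "Mt")
  # tolerance band: among near-tied fits the smaller estimate wins
  wide <- select_model(fits, bic_tol = Inf)
  expect_equal(wide$N_hat, min(vapply(fits, `[[`, 0, "N_hat")))
})

test_that("estimate_ltlp runs the full pipeline and refuses t < 3", {
  cfg <- sim_config(n_patients = 1, n_clones_per_patient = 800,
                    compartments = "TN", contamination_rate = 0, seed = 70)
  m <- build_matrix(simulate_cohort(cfg, tcr = FALSE)$is_table)
  est <- estimate_ltlp(m, "TN")
  expect_setequal(est$model, c("M0", "Mt", "Mh_Chao", "Mth_Chao"))
  expect_equal(sum(est$selected), 1)
  expect_true(all(est$N_hat >= max(colSums(unclass(m) > 0))))
  # two timepoints: explicit refusal
  cfg2 <- sim_config(n_patients = 1, n_clones_per_patient = 200,
                     timepoints = c(12L, 48L),
                     capture_prob_per_timepoint = c(0.2, 0.2),
                     compartments = "TN", contamination_rate = 0, seed = 71)
  m2 <- build_matrix(simulate_cohort(cfg2, tcr = FALSE)$is_table)
  expect_error(estimate_ltlp(m2, "TN", patient = "P1"), "refused")
  expect_error(estimate_ltlp(m2, "TN"), "refused")
})

test_that("homogeneous capture is recovered essentially unbiased", {
  res <- vapply(1:10, function(s) {
    cfg <- sim_config(n_patients = 1, n_clones_per_patient = 3000,
                      output_rate_dispersion = 0, compartments = "TN",
                      contamination_rate = 0, seed = 200 + s)
    m <- build_matrix(simulate_cohort(cfg, tcr = FALSE)$is_table)
    est <- estimate_ltlp(m, "TN")
    sel <- est[est$selected, ]
    c(sel$N_hat, sel$SE)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 3000) / 3000, 0.05)
  expect_gte(mean(abs(res[1, ] - 3000) <= 2 * res[2, ]), 0.8)
})

test_that("Chao models resist heterogeneity better than M0", {
  # directional property: under heterogeneous capture, the Chao lower
  # bound sits above the homogeneous-model estimate (which collapses
  # toward the observed count), and at or below truth plus noise
  diffs <- vapply(1:6, function(s) {
    cfg <- sim_config(n_patients = 1, n_clones_per_patient = 1500,
                      output_rate_dispersion = 0.8, compartments = "TN",
                      contamination_rate = 0, seed = 100 + s)
    m <- build_matrix(simulate_cohort(cfg, tcr = FALSE)$is_table)
    h <- capture_histories(to_incidence(m, "TN"))
    c(chao = fit_closedp(h, "Mh_Chao")$N_hat,
      m0 = fit_closedp(h, "M0")$N_hat)
  }, numeric(2))
  expect_gt(mean(diffs["chao", ]), mean(diffs["m0", ]))
  expect_lt(mean(diffs["chao", ]), 1500 * 1.05)
})
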