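# Synthetic cohort generator: determinism, contamination semantics,
# closed-form capture expectations, and ground-truth conservation.

test_that("config validation rejects impossible parameter sets", {
  expect_error(sim_config(bipotent_fraction = 1.4), "probabilities")
  expect_error(sim_config(n_clones_per_patient = 0), ">= 1")
  expect_error(sim_config(timepoints = c(12, 24),
                          capture_prob_per_timepoint = c(0.1)),
               "match timepoints")
  expect_error(sim_config(compartments = c("TSCM")), "TN")
})

test_that("same config and seed give byte-identical tables", {
  cfg <- sim_config(n_clones_per_patient = 150, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$is_table, b$is_table)
  expect_identical(a$tcr_table, b$tcr_table)
  expect_identical(a$truth, b$truth)
  # skipping the TCR branch must not perturb the IS table or the truth
  c <- simulate_cohort(cfg, tcr = FALSE)
  expect_identical(a$is_table, c$is_table)
  expect_null(c$tcr_table)
})

test_that("zero contamination forces patient-unique IS coordinates", {
  co <- simulate_cohort(sim_config(n_clones_per_patient = 300,
                                   contamination_rate = 0, seed = 7))
  key <- with(co$is_table, paste(chrom, pos, strand))
  by_key <- tapply(co$is_table$patient, key,
                   function(p) length(unique(p)))
  expect_true(all(by_key == 1L))
})

test_that("contamination rows are cross-patient copies at <= 1/10 reads", {
  co <- simulate_cohort(sim_config(n_clones_per_patient = 800,
                                   contamination_rate = 0.05, seed = 11))
  tab <- co$is_table
  contam <- tab[tab$origin == "contamination", , drop = FALSE]
  expect_gt(nrow(contam), 0)
  for (i in seq_len(nrow(contam))) {
    src <- tab[tab$origin == "clone" &
                 tab$clone_id == contam$clone_id[i] &
                 tab$compartment == contam$compartment[i] &
                 tab$timepoint_months == contam$timepoint_months[i], ]
    expect_true(all(src$patient != contam$patient[i]))
    expect_lte(contam$reads[i], max(src$reads) / 10)
  }
})

test_that("observed distinct clones match the binomial closed form", {
  # homogeneous rates: each clone seen in TN with prob 1 - (1 - p)^t
  cfg <- sim_config(n_patients = 1, n_clones_per_patient = 3000,
                    output_rate_dispersion = 0,
                    capture_prob_per_timepoint = c(0.05, 0.05, 0.05),
                    compartments = "TN", contamination_rate = 0, seed = 5)
  co <- simulate_cohort(cfg, tcr = FALSE)
  q <- 1 - (1 - 0.05)^3
  expected <- 3000 * q                      # ~ 428
  mc_sd <- sqrt(3000 * q * (1 - q))
  observed <- length(unique(co$is_table$pos))
  expect_lt(abs(observed - expected), 3 * mc_sd)
})

test_that("every output row traces to one truth clone or contamination", {
  co <- simulate_cohort(sim_config(n_clones_per_patient = 200,
                                   contamination_rate = 0.05, seed = 3),
                        tcr = FALSE)
  truth_key <- with(co$truth, paste(clone_id, chrom, pos, strand))
  row_key <- with(co$is_table, paste(clone_id, chrom, pos, strand))
  expect_true(all(row_key %in% truth_key))
  own <- co$is_table$origin == "clone"
  truth_pat <- co$truth$patient[match(co$is_table$clone_id,
                                      co$truth$clone_id)]
  expect_true(all(co$is_table$patient[own] == truth_pat[own]))
  expect_true(all(co$is_table$patient[!own] != truth_pat[!own]))
  expect_equal(nrow(co$truth), 200 * co$config$n_patients)
})

test_that("raising capture probability never lowers expected richness", {
  distinct_tn <- function(p, seed) {
    cfg <- sim_config(n_patients = 1, n_clones_per_patient = 600,
                      capture_prob_per_timepoint = rep(p, 3),
                      compartments = "TN", contamination_rate = 0,
                      seed = seed)
    length(unique(simulate_cohort(cfg, tcr = FALSE)$is_table$pos))
  }
  seeds <- 1:5
  lo <- mean(vapply(seeds, function(s) distinct_tn(0.05, s), numeric(1)))
  mid <- mean(vapply(seeds, function(s) distinct_tn(0.15, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) distinct_tn(0.4, s), numeric(1)))
  expect_true(lo <= mid && mid <= hi)
})

test_that("NK rows come only from bipotent clones", {
  co <- simulate_cohort(sim_config(n_clones_per_patient = 400, seed = 9),
                        tcr = FALSE)
  nk <- co$is_table[co$is_table$compartment == "NK" &
                      co$is_table$origin == "clone", ]
  expect_gt(nrow(nk), 0)
  expect_true(all(co$truth$bipotent[match(nk$clone_id,
                                          co$truth$clone_id)]))
})

test_that("TN clonotypes turn over while memory clonotypes persist", {
  cfg <- sim_config(n_patients = 1, n_clones_per_patient = 400,
                    capture_prob_per_timepoint = c(0.3, 0.3, 0.3),
                    contamination_rate = 0, qc_fail_rate = 0, seed = 13)
  co <- simulate_cohort(cfg)
  tn <- tcr_recapture(co$tcr_table, "TN")
  tcm <- tcr_recapture(co$tcr_table, "TCM")
  expect_lt(max(tn$percent_recaptured), 5)   # fresh rearrangements
  expect_gt(mean(tcm$percent_recaptured), mean(tn$percent_recaptured))
})

test_that("save_cohort round-trips the IS table through the TSV dialect", {
  co <- simulate_cohort(sim_config(n_clones_per_patient = 60, seed = 2),
                        tcr = FALSE)
  dir <- tempfile("cohort_")
  paths <- save_cohort(co, dir)
  back <- read_is_table(paths[["is_table"]])
  expect_equal(back[, names(co$is_table)], co$is_table,
               ignore_attr = TRUE)
  expect_true(file.exists(paths[["config"]]))
})
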