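# TCR repertoire: QC filtering, diversity, sharing, recapture, and the
# CDR3 window distance.

tcr_rec <- function(patient = "P1", compartment = "TN", timepoint = 12L,
                    cdr3 = "ACGTACGTACGT", v = "TRBV1", j = "TRBJ1",
                    reads = 5L, qc = "ok") {
  data.frame(patient = patient, compartment = compartment,
             timepoint_months = as.integer(timepoint), locus = "TRB",
             v_gene = v, j_gene = j, cdr3_nt = cdr3,
             window50 = cdr3_window50(cdr3), reads = as.integer(reads),
             qc_label = qc, stringsAsFactors = FALSE)
}

test_that("QC filtering removes labelled rearrangements and counts them", {
  cl <- do.call(rbind, lapply(1:10, function(i) {
    tcr_rec(cdr3 = strrep("AC", 20 + i))
  }))
  cl$qc_label[c(3, 7)] <- "no CD3 detected"
  kept <- filter_qc(cl)
  expect_equal(nrow(kept), 8)
  expect_equal(attr(kept, "n_removed"), 2)
  clean <- filter_qc(kept)
  expect_equal(nrow(clean), 8)
  expect_equal(attr(clean, "n_removed"), 0)
})

test_that("TCR tables round-trip and reject rows without a CDR3", {
  cl <- rbind(tcr_rec(), tcr_rec(cdr3 = strrep("GT", 26)))
  path <- tempfile(fileext = ".tsv")
  write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_tcr_table(path)
  expect_equal(back, cl, ignore_attr = TRUE)
  cl$cdr3_nt[2] <- ""
  write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tcr_table(path), "missing CDR3.*line\\(s\\) 3")
})

test_that("per-sample TCR diversity matches the closed forms", {
  cl <- rbind(tcr_rec(cdr3 = "AAAAACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA"),
              tcr_rec(cdr3 = "CCCCACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA"),
              tcr_rec(cdr3 = "GGGGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA"),
              tcr_rec(cdr3 = "TTTTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA"))
  cl$reads <- c(1L, 1L, 1L, 1L)
  d <- tcr_diversity(cl)
  expect_equal(d$n_clonotypes, 4)
  expect_equal(d$shannon, log(4))
  cl$reads <- c(2L, 1L, 1L, 1L)
  d2 <- tcr_diversity(cl[1:3, ])
  expect_equal(d2$shannon, shannon(c(2, 1, 1)))
  # duplicate rows of one clonotype are pooled
  d3 <- tcr_diversity(rbind(tcr_rec(reads = 3L), tcr_rec(reads = 4L)))
  expect_equal(d3$n_clonotypes, 1)
  expect_equal(d3$shannon, 0)
})

test_that("TCR recapture enumerates shared clonotypes between timepoints", {
  mk <- function(tp, seqs) {
    do.call(rbind, lapply(seqs, function(s) {
      tcr_rec(timepoint = tp, cdr3 = s)
    }))
  }
  seqs1 <- vapply(1:20, function(i) strrep(c("AC", "GT", "CA", "TG")[i %% 4 + 1],
                                           23 + i %% 5), character(1))
  seqs1 <- paste0(seqs1, sprintf("%02d", 1:20))  # unique tails
  cl <- rbind(mk(12L, seqs1), mk(48L, c(seqs1[1], paste0(seqs1[2:20], "X"))))
  rec <- tcr_recapture(cl, "TN")
  expect_equal(rec$n_shared, 1)
  expect_equal(rec$percent_recaptured, 5)       # 1 of 20
  # identical and disjoint repertoires
  same <- rbind(mk(12L, seqs1[1:5]), mk(48L, seqs1[1:5]))
  expect_equal(tcr_recapture(same, "TN")$percent_recaptured, 100)
  disj <- rbind(mk(12L, seqs1[1:5]), mk(48L, seqs1[6:10]))
  expect_equal(tcr_recapture(disj, "TN")$percent_recaptured, 0)
  # symmetric variant is exchangeable in the two timepoints
  asym <- rbind(mk(12L, seqs1[1:10]), mk(48L, seqs1[6:20]))
  fwd <- tcr_recapture(asym, "TN")
  swapped <- asym
  swapped$timepoint_months <- ifelse(asym$timepoint_months == 12L, 48L, 12L)
  bwd <- tcr_recapture(swapped, "TN")
  expect_equal(fwd$percent_symmetric, bwd$percent_symmetric)
  expect_error(tcr_recapture(mk(12L, seqs1[1:3]), "TN"), ">= 2 timepoints")
})

test_that("CDR3 windows are centred, padded, and Hamming is a metric", {
  expect_equal(nchar(cdr3_window50(c(strrep("A", 45), strrep("C", 60)))),
               c(50L, 50L))
  w60 <- cdr3_window50(strrep("ACGTA", 12))       # 60 -> central 50
  expect_equal(nchar(w60), 50L)
  short <- cdr3_window50("ACGT")
  expect_equal(nchar(gsub("-", "", short)), 4L)
  # identical windows at distance 0; known mismatch count
  a <- strrep("A", 50); b <- paste0(strrep("A", 47), "CCC")
  d <- cdr3_distance_matrix(c(a, a, b))
  expect_equal(d[1, 2], 0L)
  expect_equal(d[1, 3], 3L)
  # padding never fabricates agreement with real sequence
  expect_equal(cdr3_distance_matrix(c(strrep("A", 50),
                                      cdr3_window50(strrep("A", 40))))[1, 2],
               10L)
  # metric properties on random triples
  set.seed(80)
  w <- vapply(1:9, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  }, character(1))
  dm <- cdr3_distance_matrix(w)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    expect_lte(dm[i, k], dm[i, j] + dm[j, k])
  }
})

test_that("memory subsets share clonotypes more than naive cells do", {
  cfg <- sim_config(n_patients = 1, n_clones_per_patient = 300,
                    capture_prob_per_timepoint = c(0.3, 0.3, 0.3),
                    contamination_rate = 0, qc_fail_rate = 0, seed = 90)
  net <- tcr_sharing_network(simulate_cohort(cfg)$tcr_table)
  edge_r <- function(a, b) {
    e <- net[(net$from == a & net$to == b) | (net$from == b & net$to == a), ]
    mean(e$r, na.rm = TRUE)
  }
  expect_gt(edge_r("TCM", "TEM"), max(0, edge_r("TEM", "TN"), na.rm = TRUE))
})
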