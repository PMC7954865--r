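# In-code fixtures shared across test files.

# IS record rows with defaults filled in.
is_rec <- function(patient = "P1", compartment = "TN", timepoint = 12L,
                   chrom = "chr1", pos = 100L, strand = "+", reads = 10L) {
  data.frame(patient = patient, compartment = compartment,
             timepoint_months = as.integer(timepoint), chrom = chrom,
             pos = as.integer(pos), strand = strand,
             reads = as.integer(reads), stringsAsFactors = FALSE)
}

# Small abundance matrix from (is, sample, reads) triples.
toy_matrix <- function(...) {
  build_matrix(do.call(rbind, list(...)))
}

# Random IS record table for property tests.
random_records <- function(n = 60, n_patients = 3, seed = 1) {
  set.seed(seed)
  is_rec(patient = sample(sprintf("P%d", 1:n_patients), n, TRUE),
         compartment = sample(c("TN", "TCM", "TEM"), n, TRUE),
         timepoint = sample(c(12L, 24L, 48L), n, TRUE),
         chrom = sample(c("chr1", "chr2"), n, TRUE),
         pos = sample.int(500L, n, TRUE),  # deliberate cross-patient reuse
         strand = sample(c("+", "-"), n, TRUE),
         reads = sample.int(200L, n, TRUE))
}

# Gene annotation fixture: BED6 written to a temp file (0-based half-open).
write_test_bed <- function(lines = c(
  "chr1\t999\t2000\tGENEA\t0\t+",
  "chr1\t4999\t6000\tGENEB\t0\t+",
  "chr2\t9999\t20000\tLMO2\t0\t-"
)) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
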