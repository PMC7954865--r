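# Synthetic clonal-hematopoiesis simulator.
#
# A fixed pool of vector-marked long-term lymphoid progenitor (LtLP) clones,
# each tagged by a unique integration site (IS), feeds naive T (TN) cell
# production over a series of sampling timepoints. A subset of clones is
# bipotent and also produces NK cells; memory compartments (TSCM/TCM/TEM)
# re-observe TN-derived IS. TN cells carry freshly rearranged TCRs at every
# timepoint while their IS persists, which is the signature the downstream
# sharing/recapture statistics are designed to detect.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a cohort in the regime the estimators target: thousands of
#' marked clones per patient sampled at three late timepoints with modest
#' per-occasion capture probability and moderate clone-output heterogeneity.
#'
#' @param n_patients number of patients in the cohort.
#' @param n_clones_per_patient true number of marked LtLP clones per patient
#'   (the ground-truth abundance the capture-recapture module estimates).
#' @param bipotent_fraction probability that a clone has dual T/NK potential.
#' @param output_rate_dispersion log-normal sigma of the per-clone output
#'   rate. Rates multiply into capture probability as
#'   `p = 1 - (1 - p_t)^rate`, inducing the capture heterogeneity the Chao
#'   lower-bound models account for; 0 gives homogeneous capture.
#' @param timepoints sampling timepoints in months since gene therapy.
#' @param capture_prob_per_timepoint per-timepoint baseline capture
#'   probability for a unit-rate clone in TN; same length as `timepoints`.
#' @param compartments compartment labels to simulate. TN is always the
#'   production compartment; TSCM/TCM/TEM re-observe IS at
#'   `memory_carryover` times the TN baseline; NK draws only from bipotent
#'   clones at the same reduced baseline.
#' @param memory_carryover scaling in (0, 1] applied to the capture
#'   probability of memory and NK compartments; also the per-clonotype
#'   probability that a memory compartment re-expresses a persistent memory
#'   TCR at a given timepoint.
#' @param tcr_per_clone_per_timepoint number of fresh TCR clonotypes a
#'   TN-captured clone contributes per timepoint (also the size of each
#'   clone's persistent memory clonotype pool).
#' @param contamination_rate probability that an IS row is copied into
#'   another patient at low read count (cross-sample contamination, the
#'   event the 10-fold collision filter removes).
#' @param read_depth mean sequencing reads for a captured unit-rate IS.
#' @param qc_fail_rate fraction of TCR rows labelled `"no CD3 detected"` by
#'   the upstream caller, removed by [filter_qc()].
#' @param seed integer seed; a given (config, seed) pair yields
#'   byte-identical tables on every run.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 2L,
                       n_clones_per_patient = 3000L,
                       bipotent_fraction = 0.3,
                       output_rate_dispersion = 0.5,
                       timepoints = c(60L, 100L, 140L),
                       capture_prob_per_timepoint = c(0.12, 0.10, 0.08),
                       compartments = c("TN", "TSCM", "TCM", "TEM", "NK"),
                       memory_carryover = 0.35,
                       tcr_per_clone_per_timepoint = 2L,
                       contamination_rate = 0.002,
                       read_depth = 100,
                       qc_fail_rate = 0.02,
                       seed = 20210312L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_clones_per_patient = as.integer(n_clones_per_patient),
    bipotent_fraction = bipotent_fraction,
    output_rate_dispersion = output_rate_dispersion,
    timepoints = as.integer(timepoints),
    capture_prob_per_timepoint = capture_prob_per_timepoint,
    compartments = compartments,
    memory_carryover = memory_carryover,
    tcr_per_clone_per_timepoint = as.integer(tcr_per_clone_per_timepoint),
    contamination_rate = contamination_rate,
    read_depth = read_depth,
    qc_fail_rate = qc_fail_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$bipotent_fraction, cfg$capture_prob_per_timepoint,
             cfg$memory_carryover, cfg$contamination_rate, cfg$qc_fail_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_patients < 1L || cfg$n_clones_per_patient < 1L ||
      cfg$tcr_per_clone_per_timepoint < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (cfg$output_rate_dispersion < 0 || cfg$read_depth <= 0) {
    stop("output_rate_dispersion must be >= 0 and read_depth > 0",
         call. = FALSE)
  }
  if (length(cfg$capture_prob_per_timepoint) != length(cfg$timepoints)) {
    stop("capture_prob_per_timepoint must match timepoints in length",
         call. = FALSE)
  }
  if (!"TN" %in% cfg$compartments) {
    stop("compartments must include TN, the production compartment",
         call. = FALSE)
  }
  unknown <- setdiff(cfg$compartments, is_compartments())
  if (length(unknown) > 0) {
    stop("unknown compartment(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Toy genome: 3 chromosomes x 1e8 bp. IS positions are drawn without
# replacement over the concatenated genome so coordinates are unique within
# a patient by construction; cross-patient coincidences are so improbable
# (N^2/3e8) that any cross-patient duplicate in practice is an injected
# contamination event.
.sim_genome <- list(chroms = c("chr1", "chr2", "chr3"), chrom_len = 1e8)

.random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate an IS/TCR cohort with known ground truth
#'
#' Generates, for each patient, a fixed clone pool with unique IS
#' coordinates, heterogeneous per-clone output rates
#' (log-normal(0, sigma^2)), and per-timepoint Bernoulli capture with
#' probability `1 - (1 - p_t * s_compartment)^rate`, where the compartment
#' scaling `s` is 1 for TN and `memory_carryover` for memory/NK
#' compartments. Captured IS receive `1 + NegBin(mean = read_depth * rate,
#' size = 2)` reads. TN rows at each timepoint carry freshly generated CDR3
#' clonotypes; memory compartments re-express a persistent per-clone
#' clonotype pool. With positive `contamination_rate`, IS rows with at least
#' 10 reads may be copied into another patient with at most one tenth of
#' the source reads, so the collision filter has real work to do.
#'
#' @param config a [sim_config()] object.
#' @param tcr if `FALSE`, skip TCR table generation (the IS table and truth
#'   are unchanged for a given seed; useful for capture-recapture
#'   simulation studies).
#' @return A list of class `sim_cohort` with elements `is_table` (data frame
#'   in the [read_is_table()] dialect plus an `origin` provenance column),
#'   `tcr_table` (data frame in the [read_tcr_table()] dialect, or `NULL`),
#'   `truth` (per-clone ground truth: patient, clone_id, chrom, pos, strand,
#'   bipotent, rate) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_clones_per_patient = 200, seed = 1))
#' head(cohort$is_table)
#' @export
simulate_cohort <- function(config = sim_config(), tcr = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  patients <- sprintf("P%d", seq_len(config$n_patients))
  n <- config$n_clones_per_patient
  genome_len <- length(.sim_genome$chroms) * .sim_genome$chrom_len

  ## -- phase 1: clone pools and IS capture (RNG order fixed; the TCR phase
  ##    comes strictly after so `tcr = FALSE` cannot perturb the IS table)
  truth_list <- vector("list", length(patients))
  is_list <- list()
  for (pi in seq_along(patients)) {
    pat <- patients[pi]
    flat <- sample.int(genome_len, n)           # unique within patient
    chrom <- .sim_genome$chroms[(flat - 1L) %/% .sim_genome$chrom_len + 1L]
    pos <- as.integer((flat - 1L) %% .sim_genome$chrom_len + 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rate <- stats::rlnorm(n, 0, config$output_rate_dispersion)
    bipotent <- stats::runif(n) < config$bipotent_fraction
    truth_list[[pi]] <- data.frame(
      patient = pat, clone_id = sprintf("%s_c%04d", pat, seq_len(n)),
      chrom = chrom, pos = pos, strand = strand,
      bipotent = bipotent, rate = rate,
      stringsAsFactors = FALSE
    )
    for (ti in seq_along(config$timepoints)) {
      p_t <- config$capture_prob_per_timepoint[ti]
      for (comp in config$compartments) {
        s <- if (comp == "TN") 1 else config$memory_carryover
        eligible <- if (comp == "NK") bipotent else rep(TRUE, n)
        p_clone <- 1 - (1 - p_t * s)^rate
        captured <- which(stats::runif(n) < p_clone & eligible)
        if (length(captured) == 0) next
        reads <- 1L + stats::rnbinom(length(captured), size = 2,
                                     mu = config$read_depth * rate[captured])
        is_list[[length(is_list) + 1L]] <- data.frame(
          patient = pat, compartment = comp,
          timepoint_months = config$timepoints[ti],
          chrom = chrom[captured], pos = pos[captured],
          strand = strand[captured], reads = reads,
          origin = "clone", clone_id = truth_list[[pi]]$clone_id[captured],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  truth <- do.call(rbind, truth_list)
  is_table <- do.call(rbind, is_list)
  rownames(is_table) <- NULL

  ## -- phase 2: cross-patient contamination at <= 1/10 of source reads
  if (config$contamination_rate > 0 && config$n_patients > 1L) {
    can_seed <- is_table$reads >= 10L
    hit <- which(can_seed & stats::runif(nrow(is_table)) < config$contamination_rate)
    if (length(hit) > 0) {
      contam <- is_table[hit, , drop = FALSE]
      others <- vapply(contam$patient, function(p) {
        sample(setdiff(patients, p), 1L)
      }, character(1))
      contam$patient <- others
      max_r <- contam$reads %/% 10L
      contam$reads <- vapply(max_r, function(m) sample.int(m, 1L), integer(1))
      contam$origin <- "contamination"
      is_table <- rbind(is_table, contam)
      rownames(is_table) <- NULL
    }
  }

  ## -- phase 3: TCR tables (TN fresh clonotypes, memory persistent pool)
  tcr_table <- NULL
  if (tcr) {
    tcr_table <- .simulate_tcr(config, truth, is_table)
  }

  structure(list(is_table = is_table, tcr_table = tcr_table,
                 truth = truth, config = config),
            class = "sim_cohort")
}

# Memory compartments share one persistent clonotype pool per clone; TN
# clonotypes are minted fresh at every timepoint. A clone's memory progeny
# enter a given blood draw together, so whenever a clone's memory pool is
# sampled at a timepoint each memory compartment expresses pool clonotypes
# at its own rate (TCM/TEM more readily than TSCM) from the SAME pool —
# reproducing the memory-biased TCR sharing structure of sorted subsets
# while fresh TN rearrangements stay private to their timepoint.
.simulate_tcr <- function(config, truth, is_table) {
  k <- config$tcr_per_clone_per_timepoint
  mem_comps <- intersect(config$compartments, c("TSCM", "TCM", "TEM"))
  reexpr <- c(TSCM = 0.4, TCM = 0.7, TEM = 0.7)
  vs <- sprintf("TRBV%d", 1:30)
  js <- sprintf("TRBJ%d", 1:6)
  rate_of <- stats::setNames(truth$rate, truth$clone_id)
  pool <- list()   # clone_id -> pool clonotypes, created on first use
  rows <- list()
  emit <- function(pat, comp, tp, cid, cdr3, v, j) {
    m <- length(cdr3)
    reads <- 1L + stats::rnbinom(m, size = 2,
                                 mu = config$read_depth * rate_of[[cid]])
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = pat, compartment = comp, timepoint_months = tp,
      locus = "TRB", v_gene = v, j_gene = j, cdr3_nt = cdr3,
      window50 = cdr3_window50(cdr3), reads = reads, qc_label = "ok",
      clone_id = cid, stringsAsFactors = FALSE)
  }

  # TN: one batch of fresh clonotypes per captured clone per timepoint
  tn <- is_table[is_table$origin == "clone" &
                   is_table$compartment == "TN", , drop = FALSE]
  for (i in seq_len(nrow(tn))) {
    emit(tn$patient[i], "TN", tn$timepoint_months[i], tn$clone_id[i],
         .random_dna(sample(45:60, k, replace = TRUE)),
         sample(vs, k, replace = TRUE), sample(js, k, replace = TRUE))
  }

  # memory: a clone sampled in any memory compartment at a timepoint has
  # its shared pool drawn into each sorted memory subset independently
  if (length(mem_comps) > 0) {
    mem <- is_table[is_table$origin == "clone" &
                      is_table$compartment %in% mem_comps, , drop = FALSE]
    ev <- unique(mem[, c("patient", "clone_id", "timepoint_months")])
    ev <- ev[order(ev$patient, ev$clone_id, ev$timepoint_months), ,
             drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      cid <- ev$clone_id[i]
      if (is.null(pool[[cid]])) {
        pool[[cid]] <- list(
          cdr3 = .random_dna(sample(45:60, k, replace = TRUE)),
          v = sample(vs, k, replace = TRUE),
          j = sample(js, k, replace = TRUE))
      }
      for (comp in mem_comps) {
        use <- which(stats::runif(k) < reexpr[[comp]])
        if (length(use) == 0) next
        emit(ev$patient[i], comp, ev$timepoint_months[i], cid,
             pool[[cid]]$cdr3[use], pool[[cid]]$v[use],
             pool[[cid]]$j[use])
      }
    }
  }
  tcr <- do.call(rbind, rows)
  if (is.null(tcr)) return(NULL)
  rownames(tcr) <- NULL
  if (config$qc_fail_rate > 0) {
    fail <- stats::runif(nrow(tcr)) < config$qc_fail_rate
    tcr$qc_label[fail] <- "no CD3 detected"
  }
  tcr
}

#' Write a simulated cohort to disk
#'
#' Writes the IS table, TCR table (if present) and ground truth as TSV and
#' the configuration as JSON, in the dialects read back by
#' [read_is_table()] and [read_tcr_table()].
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
save_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(is_table = file.path(dir, "is_table.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.json"))
  write_is_table(cohort$is_table, paths[["is_table"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$tcr_table)) {
    paths[["tcr_table"]] <- file.path(dir, "tcr_table.tsv")
    utils::write.table(cohort$tcr_table, paths[["tcr_table"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
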