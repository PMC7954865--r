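# End-to-end orchestration: simulate or ingest, filter, build the matrix,
# and run every analysis stage, writing TSV artefacts plus a run manifest.

#' Pipeline run configuration
#'
#' @param is_table path to an IS table TSV, or `NULL` to simulate.
#' @param tcr_table path to a TCR table TSV (optional).
#' @param gene_bed path to a BED6 gene annotation (required when the
#'   annotation stage is enabled).
#' @param sim a [sim_config()] used when `is_table` is `NULL`.
#' @param out_dir output directory for artefacts.
#' @param stages character vector of stages to run, a subset of
#'   `c("filter", "matrix", "diversity", "sharing", "estimate", "tcr",
#'   "annotate")`.
#' @param fold collision-filter dominance ratio.
#' @param bubble_pct strict abundance threshold (percent) for
#'   [top_clones()].
#' @param noise_floor sequencing noise floor (percent) for [track_clone()].
#' @param oncogene_loci gene names watched by [flag_oncogenes()].
#' @param seed seed applied to the simulation branch.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(is_table = NULL, tcr_table = NULL, gene_bed = NULL,
                       sim = sim_config(), out_dir = tempfile("istrack_run_"),
                       stages = c("filter", "matrix", "diversity", "sharing",
                                  "estimate", "tcr", "annotate"),
                       fold = 10, bubble_pct = 0.01, noise_floor = 1e-4,
                       oncogene_loci = c("LMO2", "MECOM", "CCND2"),
                       seed = NULL) {
  all_stages <- c("filter", "matrix", "diversity", "sharing", "estimate",
                  "tcr", "annotate")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  for (p in c(is_table, tcr_table, gene_bed)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  if ("annotate" %in% stages && is.null(gene_bed)) {
    stop("config field gene_bed is required when the annotate stage is ",
         "enabled", call. = FALSE)
  }
  if (fold <= 1 || bubble_pct <= 0 || noise_floor <= 0) {
    stop("thresholds must be positive (and fold > 1)", call. = FALSE)
  }
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(is_table = is_table, tcr_table = tcr_table,
                 gene_bed = gene_bed, sim = sim, out_dir = out_dir,
                 stages = stages, fold = fold, bubble_pct = bubble_pct,
                 noise_floor = noise_floor, oncogene_loci = oncogene_loci),
            class = "run_config")
}

#' Run the clonal-tracking pipeline
#'
#' Executes, in order: collision filter, abundance matrix, diversity,
#' sharing/recapture statistics, closed-population abundance estimation,
#' TCR branch, and nearest-gene annotation, writing every stage artefact
#' as TSV under `config$out_dir` together with `manifest.json` (inputs,
#' parameters, artefact list, package version, seed). The run is a pure
#' function of (inputs, config, seed): re-running a simulation config with
#' the same seed reproduces every artefact byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`records`,
#'   `collision_report`, `matrix`, `diversity`, `sharing`, `estimates`,
#'   `tcr`, `annotation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artefacts <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artefacts[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  ## ingest or simulate
  tcr_raw <- NULL
  if (is.null(config$is_table)) {
    cohort <- stage("simulate",
                    simulate_cohort(config$sim,
                                    tcr = "tcr" %in% config$stages))
    records <- cohort$is_table
    tcr_raw <- cohort$tcr_table
    emit(cohort$truth, "sim_truth")
  } else {
    records <- stage("ingest", read_is_table(config$is_table))
    if (!is.null(config$tcr_table)) {
      tcr_raw <- stage("ingest", read_tcr_table(config$tcr_table))
    }
  }
  n_in <- nrow(records)

  if ("filter" %in% config$stages) {
    fl <- stage("filter", collision_filter(records, fold = config$fold))
    records <- fl$records
    res$collision_report <- fl$report
    emit(fl$report, "collision_report")
    message(sprintf("collision filter: %d -> %d rows (%d collision IS)",
                    n_in, nrow(records), nrow(fl$report)))
  }
  res$records <- records
  emit(records, "is_records_filtered")

  m <- NULL
  if ("matrix" %in% config$stages) {
    m <- stage("matrix", build_matrix(records))
    res$matrix <- m
    emit(data.frame(is_key = rownames(m), unclass(m), check.names = FALSE),
         "abundance_matrix")
  }

  if ("diversity" %in% config$stages && !is.null(m)) {
    res$diversity <- stage("diversity", diversity_table(m))
    emit(res$diversity, "diversity")
  }

  if ("sharing" %in% config$stages && !is.null(m)) {
    info <- sample_info(m)
    tsub <- intersect(c("TSCM", "TCM", "TEM", "TEMRA"), info$compartment)
    sh <- stage("sharing", sharing_fraction(m, "TN", tsub))
    rec <- stage("sharing", recapture_fraction(m, "TN"))
    pp <- stage("sharing", pairwise_pearson(m))
    res$sharing <- list(tn_vs_memory = sh, tn_recapture = rec,
                        network = pp$edges)
    emit(sh, "sharing_tn_vs_memory")
    emit(rec, "recapture_tn")
    emit(pp$edges, "sharing_network_edges")
    if ("NK" %in% info$compartment) {
      res$sharing$nk <- stage("sharing", nk_t_sharing(m))
      emit(res$sharing$nk, "sharing_nk_vs_t")
    }
  }

  if ("estimate" %in% config$stages && !is.null(m)) {
    res$estimates <- stage("estimate", estimate_ltlp(m, "TN"))
    emit(res$estimates, "ltlp_estimates")
  }

  if ("tcr" %in% config$stages && !is.null(tcr_raw)) {
    tc <- stage("tcr", filter_qc(tcr_raw))
    res$tcr <- list(clones = tc,
                    diversity = stage("tcr", tcr_diversity(tc)),
                    network = stage("tcr", tcr_sharing_network(tc)))
    emit(res$tcr$diversity, "tcr_diversity")
    emit(res$tcr$network, "tcr_network_edges")
  }

  if ("annotate" %in% config$stages && !is.null(m)) {
    genes <- stage("annotate", read_gene_bed(config$gene_bed))
    ann <- stage("annotate", nearest_gene(is_info(m), genes))
    res$annotation <- list(
      nearest = cbind(data.frame(is_key = rownames(m)), ann),
      oncogenes = stage("annotate",
                        flag_oncogenes(m, genes,
                                       loci = config$oncogene_loci))
    )
    emit(res$annotation$nearest, "nearest_gene")
    emit(res$annotation$oncogenes, "oncogene_flags")
  }

  manifest <- list(
    package = "istrack",
    version = as.character(utils::packageVersion("istrack")),
    inputs = list(is_table = config$is_table, tcr_table = config$tcr_table,
                  gene_bed = config$gene_bed,
                  simulated = is.null(config$is_table),
                  seed = if (is.null(config$is_table)) config$sim$seed),
    parameters = list(fold = config$fold, bubble_pct = config$bubble_pct,
                      noise_floor = config$noise_floor,
                      oncogene_loci = config$oncogene_loci,
                      stages = config$stages),
    artefacts = as.list(artefacts)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Headline cohort statistics
#'
#' Computes, from an IS table (and optionally a TCR table), the summary
#' quantities a clonal-tracking study reports: unique IS count, NK IS
#' count, retained TCR rearrangement count, the per-patient range of
#' TN-vs-memory sharing and TN recapture, NK-vs-TN / NK-vs-T sharing
#' maxima, and per-patient clone abundance estimates where >= 3 TN
#' timepoints exist.
#'
#' @param is_records IS record data frame (pre collision filter).
#' @param tcr_records optional TCR clone data frame (pre QC filter).
#' @param fold collision-filter dominance ratio.
#' @return Named list of scalar statistics and the underlying estimate
#'   table (`estimates`).
#' @export
reproduce_cohort_stats <- function(is_records, tcr_records = NULL,
                                   fold = 10) {
  fl <- collision_filter(is_records, fold = fold)
  m <- build_matrix(fl$records)
  info <- sample_info(m)
  out <- list(n_unique_is = nrow(m))
  nk_cols <- .cols_for(m, compartment = "NK")
  out$n_nk_is <- if (length(nk_cols) > 0) {
    sum(rowSums(m[, nk_cols, drop = FALSE] > 0) > 0)
  } else 0L
  tsub <- intersect(c("TSCM", "TCM", "TEM", "TEMRA"), info$compartment)
  if (length(tsub) > 0 && "TN" %in% info$compartment) {
    sh <- sharing_fraction(m, "TN", tsub)
    out$tn_memory_sharing_min <- min(sh$percent_shared)
    out$tn_memory_sharing_max <- max(sh$percent_shared)
  }
  multi_tn <- unique(info$patient[info$compartment == "TN"])
  multi_tn <- Filter(function(p) {
    length(unique(info$timepoint_months[info$patient == p &
                                          info$compartment == "TN"])) >= 2L
  }, multi_tn)
  if (length(multi_tn) > 0) {
    rec <- recapture_fraction(m, "TN", patient = multi_tn)
    out$tn_recapture_min <- min(rec$percent_recaptured)
    out$tn_recapture_max <- max(rec$percent_recaptured)
  }
  if ("NK" %in% info$compartment) {
    nk <- nk_t_sharing(m)
    out$nk_vs_tn_sharing_max <-
      max(nk$percent_shared[nk$comparison == "NK vs. TN"])
    out$nk_vs_t_sharing_max <-
      max(nk$percent_shared[nk$comparison == "NK vs. T"])
  }
  if (!is.null(tcr_records)) {
    out$n_tcr_retained <- nrow(filter_qc(tcr_records))
  }
  est_pats <- Filter(function(p) {
    length(unique(info$timepoint_months[info$patient == p &
                                          info$compartment == "TN"])) >= 3L
  }, unique(info$patient[info$compartment == "TN"]))
  if (length(est_pats) > 0) {
    est <- estimate_ltlp(m, "TN", patient = est_pats)
    sel <- est[est$selected, , drop = FALSE]
    out$ltlp_nhat_min <- min(sel$N_hat)
    out$ltlp_nhat_max <- max(sel$N_hat)
    out$estimates <- est
  }
  out
}
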