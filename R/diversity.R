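# Clonal diversity indices over abundance-matrix columns and their
# longitudinal trends.

.check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("diversity undefined for all-zero counts", call. = FALSE)
  }
  counts
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` with `p_i = count_i / sum(counts)`. Zero
#' counts are ignored. Reported in nats by default; pass `base = 2` for
#' bits.
#'
#' @param counts non-negative clone sizes (reads), at least one positive.
#' @param base logarithm base; `exp(1)` (nats) by default.
#' @return Shannon entropy H.
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  p <- .check_counts(counts)
  p <- p / sum(p)
  -sum(p * log(p)) / log(base)
}

#' Simpson concentration index
#'
#' `D = sum(p_i^2)`, the probability that two reads drawn at random belong
#' to the same clone; 1 for a monoclonal sample, 1/S for S equally abundant
#' clones.
#'
#' @inheritParams shannon
#' @return Simpson index D in (0, 1].
#' @export
simpson <- function(counts) {
  p <- .check_counts(counts)
  p <- p / sum(p)
  sum(p^2)
}

#' Inverse Simpson index
#'
#' `1/D`, the effective number of equally abundant clones.
#'
#' @inheritParams shannon
#' @return Inverse Simpson index, in [1, S].
#' @export
inverse_simpson <- function(counts) 1 / simpson(counts)

.diversity_row <- function(sample_key, counts) {
  data.frame(sample = sample_key,
             n_clones = sum(counts > 0),
             shannon = shannon(counts),
             simpson = simpson(counts),
             inverse_simpson = inverse_simpson(counts),
             stringsAsFactors = FALSE)
}

#' Per-sample diversity table
#'
#' One row per non-empty matrix column: clone richness S, Shannon (nats),
#' Simpson and inverse Simpson, computed on read counts.
#'
#' @param m an [build_matrix()] abundance matrix.
#' @return Data frame with columns `sample`, `patient`, `compartment`,
#'   `timepoint_months`, `n_clones`, `shannon`, `simpson`,
#'   `inverse_simpson`.
#' @export
diversity_table <- function(m) {
  keep <- which(colSums(m) > 0)
  res <- do.call(rbind, lapply(keep, function(j) {
    .diversity_row(colnames(m)[j], m[, j])
  }))
  cbind(sample_info(m)[keep, , drop = FALSE], res[, -1, drop = FALSE],
        row.names = NULL)
}

#' Diversity time course for one compartment
#'
#' Diversity indices at each timepoint at which the compartment was
#' sampled, in time order — the longitudinal trend whose stability
#' distinguishes homeostatic polyclonal output from clonal selection.
#'
#' @param m an abundance matrix.
#' @param compartment compartment label, e.g. `"TN"`.
#' @param patient optional patient filter.
#' @return Time-ordered data frame as [diversity_table()].
#' @export
diversity_timecourse <- function(m, compartment, patient = NULL) {
  if (!compartment %in% sample_info(m)$compartment) {
    stop("compartment not present in matrix: ", compartment, call. = FALSE)
  }
  cols <- .cols_for(m, compartment = compartment, patient = patient)
  res <- diversity_table(m[, cols, drop = FALSE])
  res[order(res$patient, res$timepoint_months), , drop = FALSE]
}

#' Clones above a relative-abundance threshold
#'
#' Returns the IS whose relative abundance in the given sample strictly
#' exceeds `threshold_pct` percent, most abundant first (the clone set
#' drawn in per-timepoint bubble plots).
#'
#' @param m an abundance matrix.
#' @param compartment compartment label.
#' @param timepoint timepoint in months.
#' @param patient optional patient filter.
#' @param threshold_pct strict lower threshold in percent; default 0.01.
#' @return Data frame `is_key`, `reads`, `abundance_pct`, descending.
#' @export
top_clones <- function(m, compartment, timepoint, patient = NULL,
                       threshold_pct = 0.01) {
  cols <- .cols_for(m, compartment = compartment, patient = patient,
                    timepoint = timepoint)
  if (length(cols) == 0) {
    stop("no sample for the requested compartment/timepoint", call. = FALSE)
  }
  counts <- rowSums(m[, cols, drop = FALSE])
  pct <- if (sum(counts) > 0) 100 * counts / sum(counts) else counts * 0
  keep <- which(pct > threshold_pct)
  out <- data.frame(is_key = rownames(m)[keep], reads = counts[keep],
                    abundance_pct = pct[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$abundance_pct), , drop = FALSE]
}
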