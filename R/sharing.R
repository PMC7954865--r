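# IS sharing fractions, recapture-over-time fractions, and
# Pearson-correlation sharing networks.

#' Fraction of focal-compartment IS shared with comparator compartments
#'
#' The focal IS set is the union over all the focal compartment's samples
#' (all timepoints) per patient; an IS counts as shared when it is detected
#' (any read count >= 1) in at least one comparator sample. High TN-vs-
#' memory sharing is the signature of ongoing naive-to-memory
#' differentiation from common progenitors.
#'
#' @param m an [build_matrix()] abundance matrix.
#' @param focal_compartment focal compartment label, e.g. `"TN"`.
#' @param comparator_compartments character vector of comparator labels.
#' @param patient optional patient filter; by default one result row per
#'   patient having focal samples.
#' @param exclude_timepoints if `TRUE`, an IS only counts as shared when it
#'   is found in a comparator sample from a timepoint at which the focal
#'   compartment did not carry it (independently sampled material).
#' @return Data frame: `patient`, `focal`, `comparators`, `n_focal`,
#'   `n_shared`, `percent_shared`.
#' @export
sharing_fraction <- function(m, focal_compartment, comparator_compartments,
                             patient = NULL, exclude_timepoints = FALSE) {
  info <- sample_info(m)
  pats <- if (is.null(patient)) unique(info$patient) else patient
  res <- lapply(pats, function(pat) {
    fcols <- .cols_for(m, compartment = focal_compartment, patient = pat)
    if (length(fcols) == 0) {
      stop("no samples for focal compartment ", focal_compartment,
           " in patient ", pat, call. = FALSE)
    }
    ccols <- .cols_for(m, compartment = comparator_compartments,
                       patient = pat)
    fsub <- m[, fcols, drop = FALSE] > 0
    focal_rows <- which(rowSums(fsub) > 0)
    if (length(ccols) == 0 || length(focal_rows) == 0) {
      shared <- logical(length(focal_rows))
    } else if (!exclude_timepoints) {
      shared <- rowSums(m[focal_rows, ccols, drop = FALSE] > 0) > 0
    } else {
      ftp <- info$timepoint_months[fcols]
      ctp <- info$timepoint_months[ccols]
      shared <- vapply(focal_rows, function(r) {
        seen_at <- ftp[fsub[r, ]]
        ok <- ccols[!ctp %in% seen_at]
        length(ok) > 0 && any(m[r, ok, drop = FALSE] > 0)
      }, logical(1))
    }
    data.frame(patient = pat, focal = focal_compartment,
               comparators = paste(comparator_compartments, collapse = ","),
               n_focal = length(focal_rows), n_shared = sum(shared),
               percent_shared = if (length(focal_rows) > 0) {
                 100 * sum(shared) / length(focal_rows)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fraction of a compartment's IS recaptured across timepoints
#'
#' Percent of the compartment's IS (union over its samples, per patient)
#' detected at two or more distinct timepoints. Persistent recapture of
#' naive T cell IS over years is the direct evidence for long-lived
#' progenitor clones feeding the compartment.
#'
#' @param m an abundance matrix.
#' @param compartment compartment label.
#' @param patient optional patient filter.
#' @return Data frame: `patient`, `compartment`, `n_timepoints`, `n_is`,
#'   `n_recaptured`, `percent_recaptured`.
#' @export
recapture_fraction <- function(m, compartment, patient = NULL) {
  info <- sample_info(m)
  pats <- if (is.null(patient)) {
    unique(info$patient[info$compartment == compartment])
  } else patient
  res <- lapply(pats, function(pat) {
    cols <- .cols_for(m, compartment = compartment, patient = pat)
    tps <- unique(info$timepoint_months[cols])
    if (length(tps) < 2L) {
      stop("recapture_fraction needs >= 2 timepoints for ", compartment,
           " in patient ", pat, call. = FALSE)
    }
    det <- vapply(sort(tps), function(tp) {
      cc <- .cols_for(m, compartment = compartment, patient = pat,
                      timepoint = tp)
      rowSums(m[, cc, drop = FALSE] > 0) > 0
    }, logical(nrow(m)))
    det <- matrix(det, nrow = nrow(m))
    n_tp_detected <- rowSums(det)
    present <- which(n_tp_detected > 0)
    data.frame(patient = pat, compartment = compartment,
               n_timepoints = length(tps), n_is = length(present),
               n_recaptured = sum(n_tp_detected[present] >= 2L),
               percent_recaptured =
                 100 * sum(n_tp_detected[present] >= 2L) / length(present),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise Pearson correlation of sample profiles (sharing network)
#'
#' For each pair of samples, Pearson's r is computed over the union of IS
#' detected in either sample, on relative abundances with 0 for absences
#' (or on 0/1 incidence with `method = "incidence"`). Edges with r > 0 are
#' flagged as retained — the edges drawn in sharing network plots. Pairs
#' whose profile is constant over the union (r undefined) are reported as
#' `NA`, not 0.
#'
#' @param m an abundance matrix.
#' @param method `"relative"` (default) or `"incidence"`.
#' @return A list with `r`: the symmetric correlation matrix (unit diagonal
#'   where defined), and `edges`: a data frame `from`, `to`, `r`,
#'   `retained`.
#' @export
pairwise_pearson <- function(m, method = c("relative", "incidence")) {
  method <- match.arg(method)
  if (ncol(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  x <- if (method == "relative") relative_abundance(m) else (unclass(m) > 0) * 1
  n <- ncol(x)
  r <- matrix(NA_real_, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      rows <- which(x[, i] > 0 | x[, j] > 0)
      if (length(rows) >= 2L &&
          stats::sd(x[rows, i]) > 0 && stats::sd(x[rows, j]) > 0) {
        r[i, j] <- r[j, i] <- stats::cor(x[rows, i], x[rows, j])
      } else if (i == j && length(rows) >= 1L) {
        r[i, j] <- 1
      }
    }
  }
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(from = colnames(x)[pairs[, 1L]],
                      to = colnames(x)[pairs[, 2L]],
                      r = r[pairs],
                      retained = !is.na(r[pairs]) & r[pairs] > 0,
                      stringsAsFactors = FALSE)
  list(r = r, edges = edges, method = method)
}

#' NK versus T-cell IS sharing
#'
#' Percent of each patient's NK IS shared with naive T cells (NK vs. TN)
#' and with any T-cell subtype (NK vs. T). With
#' `independent_timepoints = TRUE` (default) only comparator samples from
#' timepoints at which NK did not carry the IS are counted, which rules out
#' same-library cross-contamination as the source of sharing; substantial
#' sharing under this restriction implies common T/NK progenitors.
#'
#' @param m an abundance matrix.
#' @param t_compartments labels counted as T-cell subtypes.
#' @param patient optional patient filter.
#' @param independent_timepoints restrict comparators to other timepoints.
#' @return Data frame with one `NK vs. TN` and one `NK vs. T` row per
#'   patient (columns as [sharing_fraction()] plus `comparison`).
#' @export
nk_t_sharing <- function(m, t_compartments = c("TN", "TSCM", "TCM", "TEM",
                                               "TEMRA"),
                         patient = NULL, independent_timepoints = TRUE) {
  info <- sample_info(m)
  if (!"NK" %in% info$compartment) stop("no NK samples in matrix",
                                        call. = FALSE)
  pats <- if (is.null(patient)) unique(info$patient[info$compartment == "NK"])
          else patient
  vs_tn <- sharing_fraction(m, "NK", "TN", patient = pats,
                            exclude_timepoints = independent_timepoints)
  vs_t <- sharing_fraction(m, "NK",
                           intersect(t_compartments, info$compartment),
                           patient = pats,
                           exclude_timepoints = independent_timepoints)
  vs_tn$comparison <- "NK vs. TN"
  vs_t$comparison <- "NK vs. T"
  rbind(vs_tn, vs_t)
}
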