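# Closed-population log-linear capture-recapture estimation of clone
# abundance.
#
# Each sampling timepoint is a capture occasion; a clone's 0/1 detection
# pattern across occasions is its capture history. Counts of the 2^t - 1
# observable histories are modelled as independent Poisson with a
# log-linear mean structure; the intercept extrapolates to the unobserved
# all-zero history, so Nhat = n_obs + exp(beta0). The Chao variants add
# non-negative heterogeneity terms for histories with >= 3 captures, which
# turns the estimate into a lower bound that is robust to unequal
# catchability across clones — the realistic regime for clones with
# heterogeneous output rates.

#' Binarise an abundance matrix into a per-timepoint incidence matrix
#'
#' Pools the compartment's samples per timepoint (an IS is "captured" at a
#' timepoint when any pooled sample has reads > 0) and keeps the IS
#' observed at least once.
#'
#' @param m an [build_matrix()] abundance matrix.
#' @param compartment compartment label (capture occasions are its
#'   timepoints).
#' @param patient optional patient filter (recommended: occasions should
#'   come from one closed population).
#' @return 0/1 integer matrix of class `incidence_matrix`, one column per
#'   timepoint (time-ordered, named by month), every row with >= 1 one.
#' @export
to_incidence <- function(m, compartment, patient = NULL) {
  info <- sample_info(m)
  cols <- .cols_for(m, compartment = compartment, patient = patient)
  tps <- sort(unique(info$timepoint_months[cols]))
  if (length(tps) < 2L) {
    stop("to_incidence needs >= 2 timepoints for compartment ",
         compartment, call. = FALSE)
  }
  x <- vapply(tps, function(tp) {
    cc <- .cols_for(m, compartment = compartment, patient = patient,
                    timepoint = tp)
    as.integer(rowSums(m[, cc, drop = FALSE] > 0) > 0)
  }, integer(nrow(m)))
  x <- matrix(x, nrow = nrow(m), dimnames = list(rownames(m), tps))
  x <- x[rowSums(x) > 0L, , drop = FALSE]
  class(x) <- c("incidence_matrix", class(x))
  x
}

#' Tabulate capture histories and capture frequencies
#'
#' @param x an [to_incidence()] incidence matrix (or any 0/1 matrix with
#'   t >= 2 columns and no all-zero row).
#' @return A list of class `capture_histories`: `t`, `n_obs`, `histories`
#'   (the 2^t - 1 nonzero 0/1 patterns, one per row), `counts` (clones per
#'   history), and `f` (f_k: clones captured exactly k times, k = 1..t).
#' @export
capture_histories <- function(x) {
  x <- unclass(x)
  t <- ncol(x)
  if (t < 2L) stop("need >= 2 capture occasions", call. = FALSE)
  if (!all(x %in% c(0L, 1L))) stop("incidence must be 0/1", call. = FALSE)
  if (any(rowSums(x) == 0L)) {
    stop("all-zero capture history is unobservable", call. = FALSE)
  }
  H <- as.matrix(expand.grid(rep(list(0:1), t))[-1L, , drop = FALSE])
  dimnames(H) <- list(apply(H, 1L, paste, collapse = ""),
                      paste0("occ", seq_len(t)))
  obs <- apply(x, 1L, paste, collapse = "")
  counts <- as.integer(table(factor(obs, levels = rownames(H))))
  k <- rowSums(H)
  f <- vapply(seq_len(t), function(kk) sum(counts[k == kk]), numeric(1))
  structure(list(t = t, n_obs = nrow(x), histories = H, counts = counts,
                 f = stats::setNames(f, paste0("f", seq_len(t)))),
            class = "capture_histories")
}

#' Capture histories from explicit history counts
#'
#' Convenience constructor for analytic test cases and frequency-only data.
#'
#' @param counts named vector of history counts, names being 0/1 strings of
#'   equal length t (e.g. `c("10" = 90, "01" = 90, "11" = 10)`); omitted
#'   histories count 0.
#' @return A `capture_histories` object.
#' @export
history_counts <- function(counts) {
  t <- unique(nchar(names(counts)))
  if (length(t) != 1L || t < 2L) {
    stop("history names must be 0/1 strings of one common length >= 2",
         call. = FALSE)
  }
  H <- as.matrix(expand.grid(rep(list(0:1), t))[-1L, , drop = FALSE])
  dimnames(H) <- list(apply(H, 1L, paste, collapse = ""),
                      paste0("occ", seq_len(t)))
  if (!all(names(counts) %in% rownames(H))) {
    stop("unknown capture history: ",
         paste(setdiff(names(counts), rownames(H)), collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(numeric(nrow(H)), rownames(H))
  full[names(counts)] <- counts
  k <- rowSums(H)
  f <- vapply(seq_len(t), function(kk) sum(full[k == kk]), numeric(1))
  structure(list(t = t, n_obs = sum(full), histories = H,
                 counts = as.numeric(full),
                 f = stats::setNames(f, paste0("f", seq_len(t)))),
            class = "capture_histories")
}

#' Analytic Chao lower bound
#'
#' `S + ((t - 1) / t) * f1^2 / (2 * f2)`: the closed-form moment version of
#' the Chao heterogeneity lower bound, used as the independent oracle for
#' the log-linear Chao fits.
#'
#' @param h a `capture_histories` object.
#' @return Lower-bound abundance estimate (numeric).
#' @export
chao_lower_bound <- function(h) {
  f1 <- h$f[["f1"]]; f2 <- h$f[["f2"]]
  if (f2 == 0) f2 <- 1   # bias-corrected convention for degenerate f2
  h$n_obs + (h$t - 1) / h$t * f1^2 / (2 * f2)
}

.closedp_models <- c("M0", "Mt", "Mh_Chao", "Mth_Chao")

.design_closedp <- function(h, model) {
  H <- h$histories
  k <- rowSums(H)
  eta <- NULL
  if (model %in% c("Mh_Chao", "Mth_Chao") && h$t >= 3L) {
    eta <- vapply(3:h$t, function(kk) as.numeric(k == kk), numeric(nrow(H)))
    colnames(eta) <- paste0("eta", 3:h$t)
  }
  switch(model,
    M0 = cbind(k = k),
    Mt = H,
    Mh_Chao = cbind(cbind(k = k), eta),
    Mth_Chao = cbind(H, eta))
}

#' Fit a closed-population log-linear model to capture histories
#'
#' Fits the Poisson log-linear model for the chosen capture-probability
#' structure: `M0` (constant), `Mt` (occasion effects), `Mh_Chao`
#' (heterogeneity lower bound: a capture-count slope plus non-negative
#' eta terms for histories captured >= 3 times) or `Mth_Chao` (occasion
#' effects plus the same eta terms). Non-negativity of the eta coefficients
#' — what makes the Chao fits lower bounds — is enforced by dropping
#' negative eta terms and refitting (active constraints at zero).
#'
#' The abundance estimate is `Nhat = n_obs + exp(beta0)` and its standard
#' error comes from the delta method with a Poisson term for the unseen
#' cell: `SE^2 = exp(2 beta0) Var(beta0) + exp(beta0)`. AIC/BIC are
#' computed from the Poisson log-likelihood with `BIC = -2 logLik +
#' k log(n_obs)`.
#'
#' @param h a `capture_histories` object ([capture_histories()] or
#'   [history_counts()]).
#' @param model one of `"M0"`, `"Mt"`, `"Mh_Chao"`, `"Mth_Chao"`. Chao
#'   models need t >= 3.
#' @return A list of class `closedp_fit`: `model`, `N_hat`, `SE`,
#'   `coefficients`, `deviance`, `df`, `AIC`, `BIC`, `n_obs`, `t`,
#'   `converged`, `degenerate` (TRUE when the f2 = 0 analytic fallback was
#'   used).
#' @export
fit_closedp <- function(h, model = c("Mt", "M0", "Mh_Chao", "Mth_Chao")) {
  model <- match.arg(model, .closedp_models)
  stopifnot(inherits(h, "capture_histories"))
  if (model %in% c("Mh_Chao", "Mth_Chao") && h$t < 3L) {
    stop(model, " requires >= 3 capture occasions", call. = FALSE)
  }

  # Degenerate cases handled analytically rather than through a divergent
  # GLM: no overlap at t = 2 (unseen mass unbounded), f2 = 0 for Chao.
  if (h$t == 2L && h$counts[rownames(h$histories) == "11"] == 0) {
    return(.closedp_degenerate(h, model, N_hat = Inf,
                               reason = "no recaptured clones at t = 2"))
  }
  if (model %in% c("Mh_Chao", "Mth_Chao") && h$f[["f2"]] == 0) {
    return(.closedp_degenerate(h, model, N_hat = chao_lower_bound(h),
                               reason = "f2 = 0; Chao bound with f2 := 1"))
  }

  X <- .design_closedp(h, model)
  keep <- colnames(X)
  repeat {
    g <- suppressWarnings(
      stats::glm(h$counts ~ X[, keep, drop = FALSE],
                 family = stats::poisson())
    )
    cf <- stats::coef(g)
    names(cf) <- c("(Intercept)", keep)
    etas <- grep("^eta", keep, value = TRUE)
    neg <- etas[!is.na(cf[etas]) & cf[etas] < 0]
    if (length(neg) == 0) break
    keep <- setdiff(keep, neg[which.min(cf[neg])])  # most negative first
  }
  est <- cf[!is.na(cf)]
  b0 <- est[["(Intercept)"]]
  v <- stats::vcov(g)
  vb0 <- v["(Intercept)", "(Intercept)"]
  n_par <- length(est)
  ll <- as.numeric(stats::logLik(g))
  structure(list(
    model = model,
    N_hat = h$n_obs + exp(b0),
    SE = sqrt(exp(2 * b0) * vb0 + exp(b0)),
    coefficients = cf,
    deviance = stats::deviance(g),
    df = stats::df.residual(g),
    AIC = -2 * ll + 2 * n_par,
    BIC = -2 * ll + n_par * log(h$n_obs),
    n_obs = h$n_obs, t = h$t,
    converged = isTRUE(g$converged) && all(is.finite(est)),
    degenerate = FALSE,
    fitted = stats::fitted(g)
  ), class = "closedp_fit")
}

.closedp_degenerate <- function(h, model, N_hat, reason) {
  structure(list(model = model, N_hat = N_hat, SE = NA_real_,
                 coefficients = NULL, deviance = NA_real_, df = NA_integer_,
                 AIC = NA_real_, BIC = NA_real_, n_obs = h$n_obs, t = h$t,
                 converged = FALSE, degenerate = TRUE, reason = reason),
            class = "closedp_fit")
}

#' @export
print.closedp_fit <- function(x, ...) {
  cat(sprintf("%s closed-population fit: N = %.1f (SE %.1f), n_obs = %d, BIC = %.2f%s\n",
              x$model, x$N_hat, x$SE, x$n_obs, x$BIC,
              if (x$degenerate) paste0(" [degenerate: ", x$reason, "]") else ""))
  invisible(x)
}

#' Fit the standard model set to one set of capture histories
#'
#' @param h a `capture_histories` object.
#' @param models subset of the model family; Chao models are skipped
#'   automatically when t < 3.
#' @return Named list of `closedp_fit` objects.
#' @export
fit_closedp_all <- function(h, models = .closedp_models) {
  models <- intersect(models, .closedp_models)
  if (h$t < 3L) models <- setdiff(models, c("Mh_Chao", "Mth_Chao"))
  stats::setNames(lapply(models, function(mo) fit_closedp(h, mo)), models)
}

#' Select the reported model: lowest BIC, then most conservative
#'
#' Among the converged fits whose BIC lies within `bic_tol` of the minimum,
#' returns the fit with the smallest abundance estimate — the most
#' conservative of the best-supported models.
#'
#' @param fits list of `closedp_fit` objects ([fit_closedp_all()]).
#' @param bic_tol BIC tolerance band; 0 keeps only the strict minimum set.
#' @return The selected `closedp_fit`, with a `ranking` attribute (data
#'   frame of all candidate fits ordered by BIC).
#' @export
select_model <- function(fits, bic_tol = 0) {
  ok <- Filter(function(f) f$converged && is.finite(f$BIC), fits)
  if (length(ok) == 0) stop("no converged closed-population fit",
                            call. = FALSE)
  tab <- data.frame(model = vapply(ok, `[[`, "", "model"),
                    N_hat = vapply(ok, `[[`, 0, "N_hat"),
                    SE = vapply(ok, `[[`, 0, "SE"),
                    BIC = vapply(ok, `[[`, 0, "BIC"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$BIC, tab$N_hat), , drop = FALSE]
  cand <- tab[tab$BIC <= min(tab$BIC) + bic_tol, , drop = FALSE]
  sel <- ok[[cand$model[which.min(cand$N_hat)]]]
  attr(sel, "ranking") <- tab
  sel
}

#' Estimate active long-term lymphoid progenitor clone abundance
#'
#' Full pipeline for one compartment (naive T cells by default):
#' binarise the abundance matrix into per-timepoint incidence, tabulate
#' capture histories, fit the closed-population model family and select
#' the reported fit by lowest BIC / most conservative estimate. Estimation
#' is refused for patients sampled at fewer than 3 timepoints, for which
#' the heterogeneity models that make the estimate credible cannot be fit.
#'
#' @param m an [build_matrix()] abundance matrix (collision-filtered).
#' @param compartment compartment whose recapture pattern is modelled.
#' @param patient patients to estimate; default: all with >= 3 timepoints
#'   (patients with fewer are listed in the `refused` attribute). Naming a
#'   patient with < 3 timepoints explicitly is an error.
#' @param bic_tol BIC tolerance band for [select_model()].
#' @return Data frame with one row per patient x model (`patient`, `model`,
#'   `N_hat`, `SE`, `deviance`, `df`, `AIC`, `BIC`, `selected`), with
#'   attributes `fits` (per-patient `closedp_fit` lists) and `refused`
#'   (patients skipped, with reasons).
#' @export
estimate_ltlp <- function(m, compartment = "TN", patient = NULL,
                          bic_tol = 0) {
  info <- sample_info(m)
  all_pats <- unique(info$patient[info$compartment == compartment])
  n_tp <- vapply(all_pats, function(p) {
    length(unique(info$timepoint_months[info$patient == p &
                                          info$compartment == compartment]))
  }, integer(1))
  if (!is.null(patient)) {
    missing_p <- setdiff(patient, all_pats)
    if (length(missing_p) > 0) {
      stop("no ", compartment, " samples for patient(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    short <- patient[n_tp[match(patient, all_pats)] < 3L]
    if (length(short) > 0) {
      stop("abundance estimation refused for ",
           paste(short, collapse = ", "), ": fewer than 3 ", compartment,
           " timepoints (heterogeneity models need >= 3 capture occasions)",
           call. = FALSE)
    }
    pats <- patient
  } else {
    pats <- all_pats[n_tp >= 3L]
  }
  refused <- data.frame(
    patient = all_pats[n_tp < 3L],
    reason = sprintf("only %d %s timepoint(s); >= 3 required",
                     n_tp[n_tp < 3L], compartment),
    stringsAsFactors = FALSE
  )
  if (length(pats) == 0) {
    stop("no patient with >= 3 ", compartment,
         " timepoints; abundance estimation refused", call. = FALSE)
  }
  fits_by_pat <- list()
  rows <- list()
  for (pat in pats) {
    h <- capture_histories(to_incidence(m, compartment, patient = pat))
    fits <- fit_closedp_all(h)
    sel <- select_model(fits, bic_tol = bic_tol)
    fits_by_pat[[pat]] <- fits
    rows[[pat]] <- data.frame(
      patient = pat,
      model = vapply(fits, `[[`, "", "model"),
      N_hat = vapply(fits, `[[`, 0, "N_hat"),
      SE = vapply(fits, function(f) as.numeric(f$SE), 0),
      deviance = vapply(fits, function(f) as.numeric(f$deviance), 0),
      df = vapply(fits, function(f) as.integer(f$df), 0L),
      AIC = vapply(fits, function(f) as.numeric(f$AIC), 0),
      BIC = vapply(fits, function(f) as.numeric(f$BIC), 0),
      selected = vapply(fits, `[[`, "", "model") == sel$model,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits_by_pat
  attr(out, "refused") <- refused
  out
}
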