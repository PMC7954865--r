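# TCR repertoire diversity, sharing, longitudinal recapture, and CDR3
# window distances.

.tcr_required_cols <- c("patient", "compartment", "timepoint_months",
                        "locus", "v_gene", "j_gene", "cdr3_nt", "window50",
                        "reads", "qc_label")

#' Read a TCR rearrangement table
#'
#' Tab-separated export of an upstream V(D)J caller, one row per
#' rearrangement per sample. Required columns: `patient`, `compartment`,
#' `timepoint_months`, `locus`, `v_gene`, `j_gene`, `cdr3_nt`, `window50`,
#' `reads`, `qc_label`. Rows with a missing CDR3 are rejected with their
#' line numbers; a missing or short `window50` is rebuilt/padded from
#' `cdr3_nt` with [cdr3_window50()].
#'
#' @param path path to a TSV file with header.
#' @return A data frame of typed TCR clone records.
#' @export
read_tcr_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(.tcr_required_cols, "window50"), names(df))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L
  bad <- is.na(df$cdr3_nt) | df$cdr3_nt == ""
  if (any(bad)) {
    stop(path, ": missing CDR3 sequence on line(s) ",
         paste(utils::head(line[bad], 5L), collapse = ", "), call. = FALSE)
  }
  df$reads <- as.integer(df$reads)
  if (any(is.na(df$reads) | df$reads < 1L)) {
    stop(path, ": reads must be >= 1", call. = FALSE)
  }
  if (is.null(df$window50) || anyNA(df$window50)) {
    df$window50 <- cdr3_window50(df$cdr3_nt)
  } else {
    fix <- nchar(df$window50) != 50L
    df$window50[fix] <- cdr3_window50(df$window50[fix])
  }
  df
}

#' Remove rearrangements failing upstream QC
#'
#' Drops clones carrying the upstream caller's QC failure label
#' (`"no CD3 detected"` by default, i.e. no productive CDR3 call) and
#' reports how many were removed.
#'
#' @param clones TCR clone data frame.
#' @param label QC label marking rows to remove (exact match).
#' @return The retained clones, with attribute `n_removed`.
#' @export
filter_qc <- function(clones, label = "no CD3 detected") {
  drop <- !is.na(clones$qc_label) & clones$qc_label == label
  out <- clones[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Clonotype identity keys
#'
#' Default identity is (locus, CDR3 nucleotide sequence, V, J); `cdr3_only`
#' collapses to (locus, CDR3).
#'
#' @param clones TCR clone data frame.
#' @param cdr3_only ignore V/J calls in the identity.
#' @return Character vector of identity keys, one per row.
#' @export
tcr_identity <- function(clones, cdr3_only = FALSE) {
  if (cdr3_only) paste(clones$locus, clones$cdr3_nt, sep = "|")
  else paste(clones$locus, clones$cdr3_nt, clones$v_gene, clones$j_gene,
             sep = "|")
}

.tcr_sample_split <- function(clones) {
  split(clones, paste(clones$patient, clones$compartment,
                      clones$timepoint_months, sep = "|"))
}

#' Per-sample TCR diversity
#'
#' Shannon diversity of clonotype read counts per (patient, compartment,
#' timepoint) sample, with richness and Simpson indices.
#'
#' @param clones TCR clone data frame (normally after [filter_qc()]).
#' @param cdr3_only identity option, see [tcr_identity()].
#' @return Data frame: `patient`, `compartment`, `timepoint_months`,
#'   `n_clonotypes`, `shannon`, `simpson`, `inverse_simpson`.
#' @export
tcr_diversity <- function(clones, cdr3_only = FALSE) {
  groups <- .tcr_sample_split(clones)
  res <- lapply(names(groups), function(g) {
    cl <- groups[[g]]
    counts <- rowsum(cl$reads, tcr_identity(cl, cdr3_only))[, 1L]
    parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
    data.frame(patient = parts[1L], compartment = parts[2L],
               timepoint_months = as.integer(parts[3L]),
               n_clonotypes = length(counts),
               shannon = shannon(counts),
               simpson = simpson(counts),
               inverse_simpson = inverse_simpson(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$patient, out$compartment, out$timepoint_months), ,
      drop = FALSE]
}

#' TCR sharing network between T-cell subtypes
#'
#' For every patient and timepoint, pairwise Pearson correlation between
#' compartments over the union of clonotypes detected in either, on
#' relative clonotype abundances (absent = 0). Positive edges are
#' retained; memory-to-memory edges dominating naive-to-memory edges is
#' the expected signature when the naive pool turns over while memory
#' persists.
#'
#' @param clones TCR clone data frame.
#' @param cdr3_only identity option.
#' @return Edge data frame: `patient`, `timepoint_months`, `from`, `to`,
#'   `r`, `retained`.
#' @export
tcr_sharing_network <- function(clones, cdr3_only = FALSE) {
  groups <- split(clones, paste(clones$patient, clones$timepoint_months,
                                sep = "|"))
  res <- lapply(names(groups), function(g) {
    cl <- groups[[g]]
    comps <- sort(unique(cl$compartment))
    if (length(comps) < 2L) return(NULL)
    ids <- tcr_identity(cl, cdr3_only)
    counts <- tapply(cl$reads, list(factor(ids),
                                    factor(cl$compartment, comps)), sum,
                     default = 0)
    pct <- sweep(counts, 2L, pmax(colSums(counts), 1), "/") * 100
    pairs <- utils::combn(comps, 2L)
    parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
    rr <- apply(pairs, 2L, function(pr) {
      rows <- pct[, pr[1L]] > 0 | pct[, pr[2L]] > 0
      a <- pct[rows, pr[1L]]; b <- pct[rows, pr[2L]]
      if (sum(rows) >= 2L && stats::sd(a) > 0 && stats::sd(b) > 0) {
        stats::cor(a, b)
      } else NA_real_
    })
    data.frame(patient = parts[1L],
               timepoint_months = as.integer(parts[2L]),
               from = pairs[1L, ], to = pairs[2L, ], r = rr,
               retained = !is.na(rr) & rr > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Longitudinal TCR recapture between two timepoints
#'
#' Percent of the clonotypes detected in a compartment at one timepoint
#' that are re-detected at a second timepoint. The directed fraction uses
#' the earlier timepoint as denominator; the symmetric variant divides the
#' shared set by the union (exchangeable in the two timepoints). A low TN
#' recapture with preserved IS recapture is the signature of fresh TCR
#' rearrangement on persistent progenitor clones.
#'
#' @param clones TCR clone data frame.
#' @param compartment compartment label.
#' @param patient optional patient filter (default: each patient with the
#'   compartment at >= 2 timepoints).
#' @param cdr3_only identity option.
#' @return Data frame per patient and consecutive timepoint pair:
#'   `patient`, `compartment`, `t1`, `t2`, `n_t1`, `n_t2`, `n_shared`,
#'   `percent_recaptured` (directed, of t1), `percent_symmetric` (of the
#'   union).
#' @export
tcr_recapture <- function(clones, compartment, patient = NULL,
                          cdr3_only = FALSE) {
  cl <- clones[clones$compartment == compartment, , drop = FALSE]
  pats <- if (is.null(patient)) unique(cl$patient) else patient
  res <- lapply(pats, function(pat) {
    cc <- cl[cl$patient == pat, , drop = FALSE]
    tps <- sort(unique(cc$timepoint_months))
    if (length(tps) < 2L) {
      stop("tcr_recapture needs >= 2 timepoints for ", compartment,
           " in patient ", pat, call. = FALSE)
    }
    do.call(rbind, lapply(seq_len(length(tps) - 1L), function(i) {
      s1 <- unique(tcr_identity(cc[cc$timepoint_months == tps[i], ],
                                cdr3_only))
      s2 <- unique(tcr_identity(cc[cc$timepoint_months == tps[i + 1L], ],
                                cdr3_only))
      sh <- length(intersect(s1, s2))
      data.frame(patient = pat, compartment = compartment,
                 t1 = tps[i], t2 = tps[i + 1L],
                 n_t1 = length(s1), n_t2 = length(s2), n_shared = sh,
                 percent_recaptured = 100 * sh / length(s1),
                 percent_symmetric = 100 * sh / length(union(s1, s2)),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, res)
}

#' Extract or pad the 50-bp CDR3 window
#'
#' Takes the central 50 bases of each sequence; sequences shorter than the
#' window are centre-padded with `pad` on both sides. The pad character
#' mismatches every nucleotide in [cdr3_distance_matrix()], so padding
#' never fabricates sequence agreement.
#'
#' @param x character vector of nucleotide sequences.
#' @param width window width (50).
#' @param pad single pad character.
#' @return Character vector of fixed-width windows.
#' @export
cdr3_window50 <- function(x, width = 50L, pad = "-") {
  n <- nchar(x)
  out <- character(length(x))
  long <- n >= width
  if (any(long)) {
    start <- (n[long] - width) %/% 2L + 1L
    out[long] <- substr(x[long], start, start + width - 1L)
  }
  if (any(!long)) {
    left <- (width - n[!long]) %/% 2L
    out[!long] <- paste0(strrep(pad, left), x[!long],
                         strrep(pad, width - n[!long] - left))
  }
  out
}

#' Pairwise Hamming distances between CDR3 windows
#'
#' Per-position mismatch count between the fixed-width 50-bp windows of
#' every clone pair: a symmetric, zero-diagonal metric whose 2-D embedding
#' renders repertoire spread. Clones whose window cannot be built are
#' excluded (with a message).
#'
#' @param clones TCR clone data frame with a `window50` column, or a
#'   character vector of windows.
#' @return Symmetric integer matrix of Hamming distances.
#' @export
cdr3_distance_matrix <- function(clones) {
  w <- if (is.character(clones)) clones else clones$window50
  ok <- !is.na(w) & nchar(w) > 0
  if (any(!ok)) {
    message(sum(!ok), " clone(s) without a usable CDR3 window excluded")
    w <- w[ok]
  }
  w <- cdr3_window50(w)
  n <- length(w)
  chars <- matrix(unlist(strsplit(w, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      dij <- sum(chars[i, ] != chars[j, ])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}
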