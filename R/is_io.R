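# IS table ingestion, the cross-patient collision (contamination) filter,
# and construction of the IS x sample abundance matrix M.

#' Recognised compartment labels
#' @return Character vector of valid compartment labels.
#' @export
is_compartments <- function() {
  c("TN", "TSCM", "TCM", "TEM", "TEMRA", "NK", "PB", "Twhole")
}

# IS identity key: exact (chrom, pos, strand). Coordinates are 1-based in
# IS tables throughout; 0-based half-open appears only at BED boundaries.
is_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

.parse_is_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             strand = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

.sample_key <- function(patient, compartment, timepoint) {
  paste(patient, compartment, timepoint, sep = "|")
}

.parse_sample_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(patient = vapply(parts, `[`, "", 1L),
             compartment = vapply(parts, `[`, "", 2L),
             timepoint_months = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

.is_required_cols <- c("patient", "compartment", "timepoint_months",
                       "chrom", "pos", "strand", "reads")

.validate_is_records <- function(df, context = "IS table") {
  missing_cols <- setdiff(.is_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(context, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df$timepoint_months <- as.integer(df$timepoint_months)
  df$reads <- as.integer(df$reads)
  line <- seq_len(nrow(df)) + 1L   # +1 for the header line
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(context, ": ", what, " on line(s) ",
           paste(utils::head(line[cond], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad(is.na(df$reads) | df$reads < 1L, "reads must be >= 1")
  bad(is.na(df$timepoint_months) | df$timepoint_months < 0L,
      "timepoint_months must be >= 0")
  bad(is.na(df$pos) | df$pos < 1L, "pos must be a 1-based coordinate")
  bad(!df$strand %in% c("+", "-"), "strand must be '+' or '-'")
  bad(!df$compartment %in% is_compartments(),
      paste0("compartment must be one of ",
             paste(is_compartments(), collapse = "/")))
  df
}

#' Read an IS table
#'
#' Reads a tab-separated integration-site table with one row per IS
#' detection per sample. Required columns: `patient`, `compartment`,
#' `timepoint_months`, `chrom`, `pos` (1-based), `strand`, `reads`.
#' Extra columns are preserved. Malformed rows abort with their line
#' numbers.
#'
#' @param path path to a TSV file with a header line.
#' @return A data frame of typed IS records.
#' @export
read_is_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  .validate_is_records(df, context = path)
}

#' Write an IS table
#'
#' @param records IS record data frame.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_is_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cross-patient collision filter (10-fold rule)
#'
#' An IS coordinate observed in more than one patient is presumed to be a
#' cross-sample contamination ("collision") and is resolved by read
#' dominance: reads are summed per patient over all of that patient's
#' samples, and if the top patient's total is at least `fold` times every
#' other patient's total the IS is assigned uniquely to the top patient
#' (rows elsewhere removed); otherwise the IS is dropped from all patients.
#' Sharing of an IS across compartments or timepoints *within* a patient is
#' biological signal and is never altered. Ties at exactly `fold`-fold keep
#' the IS in the top patient.
#'
#' @param records IS record data frame (any number of patients).
#' @param fold dominance ratio, > 1; default 10.
#' @return A list with `records` (the filtered table) and `report`, a data
#'   frame with one row per cross-patient IS: `is_key`, `patients`
#'   (comma-separated, read-dominant first), `reads` (matching totals),
#'   `outcome` (`"assigned"`/`"dropped"`) and `assigned_to`.
#' @export
collision_filter <- function(records, fold = 10) {
  records <- .validate_is_records(records, context = "collision_filter input")
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  key <- is_key(records$chrom, records$pos, records$strand)
  tot <- rowsum(records$reads, group = paste(key, records$patient, sep = "\r"))
  kp <- strsplit(rownames(tot), "\r", fixed = TRUE)
  kp_key <- vapply(kp, `[`, "", 1L)
  kp_pat <- vapply(kp, `[`, "", 2L)
  multi <- names(which(table(kp_key) > 1L))
  if (length(multi) == 0) {
    return(list(records = records,
                report = data.frame(is_key = character(),
                                    patients = character(),
                                    reads = character(),
                                    outcome = character(),
                                    assigned_to = character(),
                                    stringsAsFactors = FALSE)))
  }
  report <- lapply(multi, function(k) {
    idx <- which(kp_key == k)
    ord <- order(tot[idx], decreasing = TRUE)
    pats <- kp_pat[idx][ord]
    rds <- tot[idx][ord]
    win <- rds[1] >= fold * max(rds[-1])
    data.frame(is_key = k,
               patients = paste(pats, collapse = ","),
               reads = paste(rds, collapse = ","),
               outcome = if (win) "assigned" else "dropped",
               assigned_to = if (win) pats[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  drop <- logical(nrow(records))
  for (i in seq_len(nrow(report))) {
    k <- report$is_key[i]
    if (report$outcome[i] == "assigned") {
      drop <- drop | (key == k & records$patient != report$assigned_to[i])
    } else {
      drop <- drop | (key == k)
    }
  }
  list(records = records[!drop, , drop = FALSE], report = report)
}

#' Build the IS x sample abundance matrix M
#'
#' Rows are IS identities (one per distinct `chrom:pos:strand`), columns are
#' samples (`patient|compartment|timepoint`), entries are summed sequencing
#' reads. Rows are ordered genomically (chrom, then position, then strand),
#' columns by patient, compartment and timepoint; the result is invariant
#' to the input row order.
#'
#' @param records IS record data frame, normally collision-filtered.
#' @return An integer matrix of class `abundance_matrix` with `row_info` and
#'   `col_info` attributes (parsed row/column keys).
#' @export
build_matrix <- function(records) {
  records <- .validate_is_records(records, context = "build_matrix input")
  if (nrow(records) == 0) {
    m <- matrix(integer(), 0, 0)
    class(m) <- c("abundance_matrix", class(m))
    return(m)
  }
  rk <- is_key(records$chrom, records$pos, records$strand)
  ck <- .sample_key(records$patient, records$compartment,
                    records$timepoint_months)
  row_levels <- unique(data.frame(chrom = records$chrom, pos = records$pos,
                                  strand = records$strand,
                                  stringsAsFactors = FALSE))
  row_levels <- row_levels[order(row_levels$chrom, row_levels$pos,
                                 row_levels$strand), , drop = FALSE]
  col_levels <- unique(data.frame(patient = records$patient,
                                  compartment = records$compartment,
                                  timepoint_months = records$timepoint_months,
                                  stringsAsFactors = FALSE))
  col_levels <- col_levels[order(col_levels$patient, col_levels$compartment,
                                 col_levels$timepoint_months), , drop = FALSE]
  rlev <- is_key(row_levels$chrom, row_levels$pos, row_levels$strand)
  clev <- .sample_key(col_levels$patient, col_levels$compartment,
                      col_levels$timepoint_months)
  m <- matrix(0L, nrow = length(rlev), ncol = length(clev),
              dimnames = list(rlev, clev))
  agg <- rowsum(records$reads, group = paste(rk, ck, sep = "\r"))
  idx <- strsplit(rownames(agg), "\r", fixed = TRUE)
  ri <- match(vapply(idx, `[`, "", 1L), rlev)
  ci <- match(vapply(idx, `[`, "", 2L), clev)
  m[cbind(ri, ci)] <- as.integer(agg[, 1L])
  rownames(row_levels) <- NULL
  rownames(col_levels) <- NULL
  attr(m, "row_info") <- row_levels
  attr(m, "col_info") <- col_levels
  class(m) <- c("abundance_matrix", class(m))
  m
}

#' Relative abundance view of an abundance matrix
#'
#' Scales every column to percent of its read total, so that non-empty
#' columns sum to 100. Columns with zero total (possible after subsetting)
#' are returned all-zero.
#'
#' @param m an [build_matrix()] abundance matrix (or any numeric matrix).
#' @return A numeric matrix of per-column percentages, same dimnames.
#' @export
relative_abundance <- function(m) {
  if (ncol(m) == 0 || nrow(m) == 0) return(m * 0)
  totals <- colSums(m)
  totals[totals == 0] <- Inf    # empty column -> all zeros, not NaN
  sweep(unclass(m), 2L, totals, "/") * 100
}

#' Column metadata of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return Data frame with `patient`, `compartment`, `timepoint_months`.
#' @export
sample_info <- function(m) {
  ci <- attr(m, "col_info")
  if (is.null(ci)) ci <- .parse_sample_key(colnames(m))
  ci
}

#' Row metadata of an abundance matrix
#' @param m an `abundance_matrix`.
#' @return Data frame with `chrom`, `pos`, `strand`.
#' @export
is_info <- function(m) {
  ri <- attr(m, "row_info")
  if (is.null(ri)) ri <- .parse_is_key(rownames(m))
  ri
}

# column selection helpers used across modules
.cols_for <- function(m, compartment = NULL, patient = NULL,
                      timepoint = NULL) {
  info <- sample_info(m)
  keep <- rep(TRUE, nrow(info))
  if (!is.null(compartment)) keep <- keep & info$compartment %in% compartment
  if (!is.null(patient)) keep <- keep & info$patient %in% patient
  if (!is.null(timepoint)) keep <- keep & info$timepoint_months %in% timepoint
  which(keep)
}

#' Export an abundance matrix as TSV
#'
#' Rows are keyed `chrom:pos:strand`, columns `patient|compartment|months`.
#'
#' @param m an `abundance_matrix`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(is_key = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d IS x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  if (ncol(x) > 0) {
    cat("samples:", paste(utils::head(colnames(x), 6L), collapse = ", "),
        if (ncol(x) > 6L) "..." else "", "\n")
  }
  invisible(x)
}
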