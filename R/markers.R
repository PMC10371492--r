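# ---- allele-dosage / allele-ratio marker matrices -------------------------
#
# Dosage matrices are individuals x markers, integer values 0..ploidy (a
# diploid has 3 admissible classes, a tetraploid 5: nulliplex..quadruplex),
# NA for missing. Ratio matrices hold reals in [0, 1]. Mean imputation
# produces real-valued dosages, which all G constructions accept.

as_marker_matrix <- function(M) {
  if (is.data.frame(M)) M <- as.matrix(M)
  if (!is.matrix(M) || !is.numeric(M))
    stop_format("marker data must be a numeric matrix (individuals x markers)")
  if (is.null(rownames(M))) rownames(M) <- paste0("ind", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(ncol(M)))
  M
}

#' Validate an allele-dosage matrix
#'
#' Checks that every non-missing value is an integer dosage in `0..ploidy`
#' (exactly `ploidy + 1` admissible genotype classes). The first offending
#' entry is reported with its marker and individual.
#'
#' @param M individuals x markers matrix (NA = missing).
#' @param ploidy even integer ploidy.
#' @param allow_real accept non-integer values inside `[0, ploidy]` (as
#'   produced by mean imputation).
#' @return `M`, invisibly, on success.
#' @export
validate_dosage <- function(M, ploidy, allow_real = FALSE) {
  M <- as_marker_matrix(M)
  v <- as.vector(M)
  bad <- !is.na(v) & (v < 0 | v > ploidy | (!allow_real & v != round(v)))
  if (any(bad)) {
    k <- which(bad)[1]
    i <- (k - 1L) %% nrow(M) + 1L
    j <- (k - 1L) %/% nrow(M) + 1L
    stop_validation(sprintf(
      "invalid dosage %s at marker %s, individual %s: admissible classes for ploidy %d are 0..%d",
      format(v[k]), colnames(M)[j], rownames(M)[i], ploidy, ploidy))
  }
  invisible(M)
}

#' Per-marker summary statistics
#'
#' Computes, over non-missing entries only: the reference-allele frequency
#' `p` (mean dosage / ploidy), the minor-allele frequency `maf = min(p, 1-p)`,
#' the call rate, the observed heterozygosity (fraction of dosages not in
#' `{0, ploidy}`), and a monomorphic flag (zero variance). Markers with no
#' observed calls get `call_rate` 0 and `NA` statistics.
#'
#' @inheritParams validate_dosage
#' @return data.frame with one row per marker.
#' @export
marker_stats <- function(M, ploidy) {
  M <- as_marker_matrix(M)
  n_obs <- colSums(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / ploidy
  p[n_obs == 0L] <- NA_real_
  het <- apply(M, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(x != 0 & x != ploidy)
  })
  mono <- apply(M, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA)
    length(unique(x)) == 1L
  })
  data.frame(marker = colnames(M),
             p = unname(p),
             maf = unname(pmin(p, 1 - p)),
             call_rate = unname(n_obs / nrow(M)),
             het_obs = unname(het),
             monomorphic = unname(mono),
             n_obs = unname(n_obs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter markers on frequency, call rate, heterozygosity and monomorphism
#'
#' A marker is dropped iff `maf < maf_min`, `call_rate < callrate_min`,
#' `het_obs > het_max`, `het_obs < het_min`, or it is monomorphic and
#' `drop_monomorphic` is set. Markers with zero observed calls are always
#' dropped (reason `no_data`). Individuals are never dropped.
#'
#' @inheritParams validate_dosage
#' @param maf_min,callrate_min,het_max,het_min thresholds in `[0, 1]`. The
#'   heterozygosity filter is primarily an upper bound (`het_max`), the use
#'   case being highly inbred breeding lines; `het_min` defaults to 0.
#' @param drop_monomorphic drop zero-variance markers.
#' @return list with the filtered `matrix` and a `report` data.frame
#'   (marker, kept, reasons) carrying threshold and count attributes.
#' @export
filter_markers <- function(M, ploidy, maf_min = 0, callrate_min = 0,
                           het_max = 1, het_min = 0, drop_monomorphic = FALSE) {
  M <- as_marker_matrix(M)
  for (th in c(maf_min, callrate_min, het_max, het_min))
    if (!is.numeric(th) || is.na(th) || th < 0 || th > 1)
      stop_parameter("filter thresholds must lie in [0, 1]")
  st <- marker_stats(M, ploidy)
  reasons <- vector("list", nrow(st))
  for (k in seq_len(nrow(st))) {
    r <- character(0)
    if (st$n_obs[k] == 0L) r <- c(r, "no_data")
    else {
      if (st$maf[k] < maf_min) r <- c(r, "maf")
      if (st$call_rate[k] < callrate_min) r <- c(r, "call_rate")
      if (st$het_obs[k] > het_max) r <- c(r, "het_high")
      if (st$het_obs[k] < het_min) r <- c(r, "het_low")
      if (drop_monomorphic && isTRUE(st$monomorphic[k])) r <- c(r, "monomorphic")
    }
    reasons[[k]] <- r
  }
  kept <- lengths(reasons) == 0L
  if (!any(kept))
    stop_validation("all markers were dropped by the requested filters; G would be undefined")
  report <- data.frame(marker = st$marker, kept = kept,
                       reasons = vapply(reasons, paste, character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  counts <- table(unlist(reasons))
  attr(report, "thresholds") <- list(maf_min = maf_min, callrate_min = callrate_min,
                                     het_max = het_max, het_min = het_min,
                                     drop_monomorphic = drop_monomorphic)
  attr(report, "counts") <- counts
  class(report) <- c("qc_report", "data.frame")
  list(matrix = M[, kept, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers: %d kept, %d dropped\n",
              nrow(x), sum(x$kept), sum(!x$kept)))
  cts <- attr(x, "counts")
  if (length(cts)) for (nm in names(cts)) cat(sprintf("  %-12s %d\n", nm, cts[[nm]]))
  invisible(x)
}

#' Write a QC report to a per-marker TSV
#' @param report a `qc_report` from [filter_markers()].
#' @param file output path.
#' @export
write_qc_report <- function(report, file) {
  utils::write.table(as.data.frame(report), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Impute missing dosages by column mean or mode
#'
#' Mean imputation fills each missing entry with the column mean of the
#' observed dosages (real-valued; accepted by all G constructions). Mode
#' imputation uses the most frequent observed dosage, ties broken toward the
#' smaller dosage. Observed entries are never altered. A marker with no
#' observed values cannot be imputed and must be filtered first.
#'
#' @inheritParams validate_dosage
#' @param method `"mean"` or `"mode"`.
#' @return the completed matrix (numeric for `"mean"`).
#' @export
impute_markers <- function(M, method = c("mean", "mode")) {
  M <- as_marker_matrix(M)
  method <- match.arg(method)
  all_missing <- colSums(!is.na(M)) == 0L
  if (any(all_missing))
    stop_validation(sprintf(
      "marker(s) with no observed values cannot be imputed (filter first): %s",
      paste(utils::head(colnames(M)[all_missing], 5), collapse = ", ")))
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (!any(miss)) next
    x <- M[!miss, j]
    fill <- if (method == "mean") mean(x) else {
      tab <- table(x)
      vals <- as.numeric(names(tab))
      min(vals[tab == max(tab)])  # tie toward the smaller dosage
    }
    M[miss, j] <- fill
  }
  M
}
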