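# ---- readers / writers and matrix post-processing -------------------------

#' Read an allele-dosage (or ratio) matrix from CSV/TSV
#'
#' First column = individual label, header row = marker names; the
#' delimiter is sniffed. Missing tokens (default `"NA"` and empty) become
#' `NA`.
#'
#' @param file path to a delimited text file.
#' @param missing_codes tokens treated as missing.
#' @return numeric matrix, individuals x markers.
#' @export
read_dosage <- function(file, missing_codes = c("NA", "")) {
  if (!file.exists(file)) stop_format(sprintf("dosage file not found: %s", file))
  dt <- data.table::fread(file, header = TRUE, data.table = FALSE,
                          na.strings = missing_codes)
  if (ncol(dt) < 2L) stop_format("dosage file needs an id column plus markers")
  ids <- as.character(dt[[1]])
  M <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' Write a dosage matrix to CSV
#' @param M individuals x markers matrix.
#' @param file output path.
#' @export
write_dosage <- function(M, file) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a relationship matrix
#'
#' `dense` writes a labelled square CSV (full precision by default, so a
#' round trip is exact to well below 1e-12). `long` writes the lower
#' triangle including the diagonal as TSV `(row_label, col_label, value)` —
#' `n(n+1)/2` rows — the layout mixed-model and GWAS software ingests; with
#' `index_dialect = TRUE` integer 1-based codes replace the labels for tools
#' that require them. A metadata sidecar (`<file>.meta`) records kind,
#' method, ploidy and construction parameters as key=value lines.
#'
#' @param x a [relmat].
#' @param file output path.
#' @param format `"dense"` or `"long"`.
#' @param digits significant digits (`NA` = full precision).
#' @param index_dialect long format with integer codes instead of labels.
#' @param metadata also write the `<file>.meta` sidecar.
#' @return `file`, invisibly.
#' @export
write_relmat <- function(x, file, format = c("dense", "long"), digits = NA,
                         index_dialect = FALSE, metadata = FALSE) {
  format <- match.arg(format)
  vals <- rel_values(x)
  fmt_num <- function(v) {
    if (is.na(digits)) sprintf("%.17g", v) else formatC(v, digits = digits, format = "g")
  }
  if (format == "dense") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(c("id", colnames(vals)), collapse = ","), con)
    for (i in seq_len(nrow(vals)))
      writeLines(paste(c(rownames(vals)[i], fmt_num(vals[i, ])), collapse = ","), con)
  } else {
    n <- nrow(vals)
    lt <- which(lower.tri(vals, diag = TRUE), arr.ind = TRUE)
    lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
    df <- data.frame(
      row_label = if (index_dialect) lt[, 1] else rownames(vals)[lt[, 1]],
      col_label = if (index_dialect) lt[, 2] else colnames(vals)[lt[, 2]],
      value = fmt_num(vals[lt]),
      stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (metadata) {
    meta <- c(kind = rel_kind(x), method = attr(x, "method") %||% "",
              ploidy = rel_ploidy(x), n = nrow(vals))
    pars <- rel_params(x)
    scal <- pars[vapply(pars, function(p) is.atomic(p) && length(p) == 1L, logical(1))]
    meta <- c(meta, unlist(scal))
    writeLines(sprintf("%s=%s", names(meta), as.character(meta)),
               paste0(file, ".meta"))
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a relationship matrix written by [write_relmat()]
#'
#' @param file path; the format (dense square CSV vs three-column long TSV)
#'   is detected from the header.
#' @param kind,ploidy metadata to attach (the sidecar, if present, wins).
#' @return a [relmat].
#' @export
read_relmat <- function(file, kind = "A_additive", ploidy = 2) {
  if (!file.exists(file)) stop_format(sprintf("matrix file not found: %s", file))
  meta_file <- paste0(file, ".meta")
  if (file.exists(meta_file)) {
    kv <- strsplit(readLines(meta_file), "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                   character(1)),
                            vapply(kv, `[[`, character(1), 1))
    if (!is.na(meta["kind"])) kind <- meta[["kind"]]
    if (!is.na(meta["ploidy"])) ploidy <- as.integer(meta[["ploidy"]])
  }
  first <- readLines(file, n = 1L)
  is_long <- grepl("\t", first) && length(strsplit(first, "\t")[[1]]) == 3L
  if (is_long) {
    df <- data.table::fread(file, header = TRUE, data.table = FALSE)
    labs <- unique(c(as.character(df[[1]]), as.character(df[[2]])))
    n <- length(labs)
    M <- matrix(0, n, n, dimnames = list(labs, labs))
    i <- match(as.character(df[[1]]), labs)
    j <- match(as.character(df[[2]]), labs)
    M[cbind(i, j)] <- df[[3]]
    M[cbind(j, i)] <- df[[3]]
  } else {
    dt <- data.table::fread(file, header = TRUE, data.table = FALSE)
    labs <- as.character(dt[[1]])
    M <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    dimnames(M) <- list(labs, colnames(M))
  }
  relmat(M, rownames(M), kind = kind, ploidy = ploidy)
}

#' Import allele dosages from a VCF
#'
#' Counts ALT alleles in the GT field of biallelic records (or rounds the
#' DS field when `use_ds = TRUE`). Multi-allelic records and records whose
#' GT ploidy differs from every sample's expectation are handled per the
#' contract: multi-allelic records are skipped with a logged count, and a
#' GT whose ploidy is inconsistent with `ploidy` raises an error naming the
#' record.
#'
#' @param path VCF file (plain or gzipped).
#' @param ploidy expected GT ploidy.
#' @param use_ds read the DS (dosage) FORMAT field instead of GT.
#' @return dosage matrix, individuals x markers; attribute
#'   `skipped_multiallelic` counts skipped records.
#' @export
read_vcf_dosage <- function(path, ploidy = 2, use_ds = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_format("read_vcf_dosage requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- sprintf("rec%d", which(is.na(ids)))
  multi <- grepl(",", alt)
  n_skip <- sum(multi)
  if (n_skip) message(sprintf("skipped %d multi-allelic record(s)", n_skip))
  if (use_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    M <- t(ds[!multi, , drop = FALSE])
    M <- round(M)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    ids_kept <- ids[!multi]
    count_alt <- function(g, rec) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      al <- al[al != "."]
      if (length(al) != ploidy)
        stop_validation(sprintf(
          "record %s: GT ploidy %d inconsistent with expected ploidy %d",
          rec, length(al), ploidy))
      sum(al != "0")
    }
    M <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), ids_kept))
    for (r in seq_len(nrow(gt)))
      M[, r] <- vapply(gt[r, ], count_alt, numeric(1), rec = ids_kept[r])
  }
  if (!use_ds) colnames(M) <- ids[!multi]
  attr(M, "skipped_multiallelic") <- n_skip
  M
}

#' Invert a relationship matrix
#'
#' Numerically inverts (for software that ingests A or H inverses). If the
#' matrix is singular and `bend_if_needed` is set, it is first bent with
#' diagonal jitter at `eps`; otherwise a singularity error is raised. The
#' inverse is checked to satisfy `max |M M^-1 - I| < 1e-6`.
#'
#' @param x a [relmat].
#' @param bend_if_needed bend before inverting if necessary.
#' @param eps bending eigenvalue floor.
#' @return the inverse as a [relmat] (same kind, `inverse = TRUE` in
#'   params).
#' @export
invert_relmat <- function(x, bend_if_needed = FALSE, eps = 1e-8) {
  vals <- rel_values(x)
  inv <- tryCatch(solve(vals), error = function(e) NULL)
  bad <- is.null(inv) || max(abs(vals %*% inv - diag(nrow(vals)))) >= 1e-6
  if (bad) {
    if (!bend_if_needed)
      stop_numeric("matrix is singular (or too ill-conditioned to invert); set bend_if_needed = TRUE")
    message(sprintf("bending with diagonal jitter (eps = %g) before inversion", eps))
    xb <- ensure_positive_definite(x, method = "diagonal_jitter", eps = eps)
    vals <- rel_values(xb)
    inv <- solve(vals)
  }
  inv <- (inv + t(inv)) / 2
  relmat(inv, rel_labels(x), kind = rel_kind(x), ploidy = rel_ploidy(x),
         method = attr(x, "method"),
         params = c(rel_params(x), list(inverse = TRUE, bended = bad)))
}
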