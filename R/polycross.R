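#' Expected relationship matrix for non-deterministic (polycross) pedigrees
#'
#' Handles mating designs where offspring arise from a group of equally
#' possible parents (e.g. seed harvested in bulk from a polycross block), so
#' parentage is probabilistic rather than recorded. The expected additive
#' relationship is obtained by averaging the tabular recursion over equally
#' likely draws of two distinct parents from the candidate set: an offspring
#' with candidate set C contributes weight `1/|C|` to each candidate's row,
#' so its expected relatedness to a non-inbred, mutually unrelated candidate
#' is `1/|C|` (1/3 for a group of three). With `fixed = TRUE` the first
#' parent column is a known parent (e.g. the mother in a polycross of pollen
#' donors): the offspring row is `0.5` times the known parent's row plus
#' `0.5/n` times each of the n candidates' rows, giving relatedness 0.5 to
#' the known parent and `0.5/n` to each candidate under the same
#' assumptions. All diagonals are set to 1 (the construction assumes no
#' inbreeding). Deterministic records (exactly two listed parents, no fixed
#' parent) reduce to the ordinary 0.5/0.5 cross and may be freely mixed in.
#'
#' @param pedigree data.frame in wide format: column 1 = individual id,
#'   remaining columns = possible parents (unknown coded 0/NA/empty). Parent
#'   labels never listed as individuals are appended as founders.
#' @param fixed if `TRUE`, column 2 holds the known parent and columns 3+
#'   the candidate set.
#' @return a [relmat] of kind `A_additive` (diploid scale, no inbreeding).
#' @examples
#' ped <- data.frame(id = c("P1", "P2", "P3", "bulk1"),
#'                   par1 = c(0, 0, 0, "P1"), par2 = c(0, 0, 0, "P2"),
#'                   par3 = c(0, 0, 0, "P3"))
#' Amatrix_polycross(ped)["bulk1", "P1"]  # 1/3
#' @export
Amatrix_polycross <- function(pedigree, fixed = FALSE) {
  df <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop_format("polycross pedigree needs an id column and >= 2 parent columns")
  codes <- c("0", "NA", "")
  for (j in seq_len(ncol(df))) {
    v <- trimws(as.character(df[[j]]))
    if (j > 1L) v[is.na(v) | v %in% codes | tolower(v) %in% tolower(codes)] <- NA_character_
    df[[j]] <- v
  }
  id <- df[[1]]
  if (anyDuplicated(id))
    stop_validation(sprintf("duplicate polycross record(s): %s",
                            paste(unique(id[duplicated(id)]), collapse = ", ")))
  pmat <- as.matrix(df[, -1, drop = FALSE])

  # append never-defined parents as founders
  all_parents <- unique(stats::na.omit(as.vector(pmat)))
  extra <- setdiff(all_parents, id)
  if (length(extra)) {
    warning(sprintf("%d parent label(s) appended as founders", length(extra)))
    id <- c(extra, id)
    pmat <- rbind(matrix(NA_character_, length(extra), ncol(pmat)), pmat)
  }
  n <- length(id)

  parent_weights <- function(i) {
    ps <- stats::na.omit(pmat[i, ])
    if (fixed && !is.na(pmat[i, 1])) {
      f <- pmat[i, 1]
      cand <- unique(setdiff(ps[-1], NA))
      if (f %in% cand)
        stop_validation(sprintf("fixed parent of %s also listed among candidates", id[i]))
      if (!length(cand)) return(stats::setNames(0.5, f))
      w <- c(0.5, rep(0.5 / length(cand), length(cand)))
      return(stats::setNames(w, c(f, cand)))
    }
    ps <- unique(as.character(ps))
    if (!length(ps)) return(stats::setNames(numeric(0), character(0)))
    if (length(ps) == 1L) return(stats::setNames(0.5, ps))  # one known, one unknown parent
    stats::setNames(rep(1 / length(ps), length(ps)), ps)
  }

  # topological ordering: all listed parents must precede the offspring
  placed <- logical(n)
  ord <- integer(0)
  remaining <- seq_len(n)
  idx <- function(lbl) match(lbl, id)
  repeat {
    progressed <- FALSE
    keep <- logical(length(remaining))
    for (r in seq_along(remaining)) {
      i <- remaining[r]
      ps <- stats::na.omit(pmat[i, ])
      if (all(placed[idx(ps)])) {
        ord <- c(ord, i); placed[i] <- TRUE; progressed <- TRUE
      } else keep[r] <- TRUE
    }
    remaining <- remaining[keep]
    if (!length(remaining)) break
    if (!progressed)
      stop_cycle(sprintf("polycross pedigree contains a cycle involving: %s",
                         paste(id[remaining[1]], collapse = ", ")))
  }

  A <- matrix(0, n, n, dimnames = list(id, id))
  pos <- match(seq_len(n), ord)
  for (k in seq_len(n)) {
    i <- ord[k]
    wts <- parent_weights(i)
    if (length(wts)) {
      contrib <- drop(wts %*% A[idx(names(wts)), , drop = FALSE])
      A[i, ] <- contrib
      A[, i] <- contrib
    }
    A[i, i] <- 1
  }
  relmat(A, id, kind = "A_additive", ploidy = 2L, method = "polycross",
         params = list(fixed = fixed, assumes_no_inbreeding = TRUE))
}
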