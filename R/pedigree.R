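#' Read and validate a three-column pedigree table
#'
#' Pedigrees are recorded as three columns: individual id, parent 1,
#' parent 2. Parent assignment carries no sex distinction and is orderless.
#' Unknown parents are coded by any of the `unknown_codes` sentinels
#' (matched case-insensitively for alphabetic codes) or a true `NA`.
#' Parent labels that never appear in the id column are appended as founder
#' records (unknown x unknown) with a warning. Duplicate records with
#' identical parent sets are deduplicated; duplicates with conflicting
#' parents are an error.
#'
#' @param x a file path (CSV/TSV, delimiter sniffed) or a data.frame with at
#'   least three columns (id, parent1, parent2; extra columns are ignored
#'   with a warning).
#' @param unknown_codes sentinels treated as "parent unknown".
#' @param header `"auto"`, `TRUE` or `FALSE`. Under `"auto"` a first file row
#'   whose fields look like column names (id/individual/parent/sire/dam/...)
#'   is treated as a header.
#' @return a data.frame of class `pedigree_table` with character columns
#'   `id`, `parent1`, `parent2` (`NA` = unknown) and attribute
#'   `appended_founders` (how many parent-only labels were appended).
#' @export
read_pedigree <- function(x, unknown_codes = c("0", "NA", ""), header = "auto") {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_format(sprintf("pedigree file not found: %s", x))
    dt <- data.table::fread(x, header = FALSE, colClasses = "character",
                            data.table = FALSE, strip.white = TRUE, fill = TRUE)
    if (identical(header, "auto")) {
      hdr_words <- c("id", "ind", "individual", "genotype", "name", "progeny",
                     "parent", "parent1", "parent2", "sire", "dam", "mother", "father", "p1", "p2")
      first <- tolower(trimws(as.character(dt[1, ])))
      header <- any(first %in% hdr_words)
    }
    if (isTRUE(header)) dt <- dt[-1, , drop = FALSE]
    df <- dt
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    stop_format("pedigree input must be a file path or a data.frame")
  }
  if (ncol(df) < 3L)
    stop_format(sprintf("pedigree needs >= 3 columns (id, parent1, parent2); got %d", ncol(df)))
  if (ncol(df) > 3L) {
    warning(sprintf("ignoring %d extra pedigree column(s)", ncol(df) - 3L))
    df <- df[, 1:3, drop = FALSE]
  }
  names(df) <- c("id", "parent1", "parent2")
  for (j in 1:3) df[[j]] <- trimws(as.character(df[[j]]))

  is_unknown <- function(v) {
    is.na(v) | v %in% unknown_codes | tolower(v) %in% tolower(unknown_codes)
  }
  df$parent1[is_unknown(df$parent1)] <- NA_character_
  df$parent2[is_unknown(df$parent2)] <- NA_character_
  if (any(is_unknown(df$id)))
    stop_validation("individual id may not be missing or equal to an unknown sentinel")

  # deduplicate; conflicting duplicates are an error
  key <- vapply(seq_len(nrow(df)), function(i) {
    ps <- sort(c(df$parent1[i], df$parent2[i]), na.last = TRUE)
    paste(df$id[i], ps[1], ps[2], sep = "\r")
  }, character(1))
  df <- df[!duplicated(key), , drop = FALSE]
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop_validation(sprintf("conflicting duplicate pedigree record(s) for: %s",
                            paste(dup, collapse = ", ")))

  parents <- unique(stats::na.omit(c(df$parent1, df$parent2)))
  missing_parents <- setdiff(parents, df$id)
  if (length(missing_parents)) {
    warning(sprintf("%d parent label(s) absent from the id column appended as founders: %s",
                    length(missing_parents),
                    paste(utils::head(missing_parents, 5), collapse = ", ")))
    df <- rbind(data.frame(id = missing_parents, parent1 = NA_character_,
                           parent2 = NA_character_, stringsAsFactors = FALSE),
                df)
  }
  rownames(df) <- NULL
  structure(df,
            appended_founders = length(missing_parents),
            unknown_codes = unknown_codes,
            class = c("pedigree_table", "data.frame"))
}

as_pedigree_table <- function(x, ...) {
  if (inherits(x, "pedigree_table")) x else read_pedigree(x, ...)
}

#' Topologically order a pedigree
#'
#' Reorders records so that every parent precedes its offspring and assigns
#' indices 1..N. The ordering pass scans the remaining records repeatedly in
#' input order, placing each record as soon as both its parents are placed,
#' so an already-valid pedigree is returned untouched (and the sort is
#' idempotent) and ties are broken stably by input order. Self-parenting and
#' ancestry cycles are rejected with an error naming one cycle.
#'
#' @param ped a `pedigree_table`, data.frame, or file path (passed through
#'   [read_pedigree()]); an `ordered_pedigree` is returned unchanged.
#' @return an object of class `ordered_pedigree`: a list with `labels`
#'   (ordered ids), integer parent indices `sire` and `dam` (0 = unknown),
#'   `n`, and flag `reordered`.
#' @export
order_pedigree <- function(ped) {
  if (inherits(ped, "ordered_pedigree")) return(ped)
  ped <- as_pedigree_table(ped)
  n <- nrow(ped)
  id <- ped$id
  self <- which(!is.na(ped$parent1) & ped$parent1 == id |
                !is.na(ped$parent2) & ped$parent2 == id)
  if (length(self))
    stop_cycle(sprintf("individual(s) recorded as their own parent: %s",
                       paste(id[self], collapse = ", ")))

  p1i <- match(ped$parent1, id)  # NA = unknown (parents all resolvable after parsing)
  p2i <- match(ped$parent2, id)
  placed <- logical(n)
  ord <- integer(n)
  k <- 0L
  remaining <- seq_len(n)
  repeat {
    placed_this_pass <- 0L
    keep <- logical(length(remaining))
    for (r in seq_along(remaining)) {
      i <- remaining[r]
      ok1 <- is.na(p1i[i]) || placed[p1i[i]]
      ok2 <- is.na(p2i[i]) || placed[p2i[i]]
      if (ok1 && ok2) {
        k <- k + 1L
        ord[k] <- i
        placed[i] <- TRUE
        placed_this_pass <- placed_this_pass + 1L
      } else keep[r] <- TRUE
    }
    remaining <- remaining[keep]
    if (!length(remaining)) break
    if (placed_this_pass == 0L) {
      # name one cycle: walk parent pointers within the stuck set
      stuck <- remaining[1]
      path <- integer(0)
      cur <- stuck
      while (!(cur %in% path)) {
        path <- c(path, cur)
        nxt <- if (!is.na(p1i[cur]) && !placed[p1i[cur]]) p1i[cur] else p2i[cur]
        cur <- nxt
      }
      cyc <- path[which(path == cur)[1]:length(path)]
      stop_cycle(sprintf("pedigree contains an ancestry cycle: %s -> %s",
                         paste(id[cyc], collapse = " -> "), id[cur]))
    }
  }
  labels <- id[ord]
  pos <- match(seq_len(n), ord)           # original row -> new position
  sire <- ifelse(is.na(p1i[ord]), 0L, pos[p1i[ord]])
  dam  <- ifelse(is.na(p2i[ord]), 0L, pos[p2i[ord]])
  structure(list(labels = labels, sire = as.integer(sire), dam = as.integer(dam),
                 n = n, reordered = !identical(ord, seq_len(n))),
            class = "ordered_pedigree")
}

#' Convert an ordered pedigree back to a three-column table
#' @param x an `ordered_pedigree`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `id`, `parent1`, `parent2` (NA = unknown).
#' @export
as.data.frame.ordered_pedigree <- function(x, row.names = NULL, optional = FALSE, ...) {
  lab_at <- function(idx) {
    out <- rep(NA_character_, length(idx))
    out[idx > 0L] <- x$labels[idx[idx > 0L]]
    out
  }
  data.frame(id = x$labels, parent1 = lab_at(x$sire), parent2 = lab_at(x$dam),
             stringsAsFactors = FALSE)
}

#' @export
print.ordered_pedigree <- function(x, ...) {
  cat(sprintf("<ordered_pedigree> %d individuals (%d founders)%s\n",
              x$n, sum(x$sire == 0L & x$dam == 0L),
              if (x$reordered) ", input order corrected" else ""))
  invisible(x)
}

#' Append new records to an ordered pedigree
#'
#' Extends an [order_pedigree()] result with new crosses. Existing
#' individuals keep their indices 1..N; new individuals are appended (in
#' corrected chronological order) as N+1, N+2, ... The result is identical
#' to ordering the concatenated table in one pass.
#'
#' @param ped an `ordered_pedigree`.
#' @param new a data.frame / `pedigree_table` of new records. Every parent
#'   must be unknown, already present in `ped`, or defined within `new`;
#'   unresolvable parent labels are an error (founders are not silently
#'   appended here).
#' @return an `ordered_pedigree` covering old and new individuals.
#' @export
append_pedigree <- function(ped, new) {
  ped <- order_pedigree(ped)
  if (is.null(new) || NROW(new) == 0L) return(ped)
  new <- as.data.frame(new, stringsAsFactors = FALSE)
  if (ncol(new) < 3L) stop_format("new pedigree records need >= 3 columns")
  new <- new[, 1:3, drop = FALSE]
  names(new) <- c("id", "parent1", "parent2")
  codes <- c("0", "NA", "")
  for (j in 1:3) new[[j]] <- trimws(as.character(new[[j]]))
  for (j in 2:3) {
    v <- new[[j]]
    v[is.na(v) | v %in% codes | tolower(v) %in% tolower(codes)] <- NA_character_
    new[[j]] <- v
  }
  key <- vapply(seq_len(nrow(new)), function(i) {
    ps <- sort(c(new$parent1[i], new$parent2[i]), na.last = TRUE)
    paste(new$id[i], ps[1], ps[2], sep = "\r")
  }, character(1))
  new <- new[!duplicated(key), , drop = FALSE]
  if (any(duplicated(new$id)))
    stop_validation(sprintf("conflicting duplicate new record(s): %s",
                            paste(unique(new$id[duplicated(new$id)]), collapse = ", ")))
  clash <- intersect(new$id, ped$labels)
  if (length(clash))
    stop_validation(sprintf("new record(s) redefine existing individual(s): %s",
                            paste(clash, collapse = ", ")))
  all_ids <- c(ped$labels, new$id)
  bad <- setdiff(stats::na.omit(c(new$parent1, new$parent2)), all_ids)
  if (length(bad))
    stop_validation(sprintf("new record(s) reference unresolvable parent label(s): %s",
                            paste(bad, collapse = ", ")))

  old_df <- as.data.frame(ped)
  concat <- data.frame(
    id = all_ids,
    parent1 = c(old_df$parent1, new$parent1),
    parent2 = c(old_df$parent2, new$parent2),
    stringsAsFactors = FALSE)
  out <- order_pedigree(structure(concat, appended_founders = 0L,
                                  class = c("pedigree_table", "data.frame")))
  if (!identical(out$labels[seq_len(ped$n)], ped$labels))
    stop_validation("internal: existing individuals did not keep their indices") # nocov
  out
}
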