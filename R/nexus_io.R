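## Weighted split sets and SplitsTree-compatible NEXUS output.

#' Construct a weighted split set
#'
#' A split is a bipartition of the taxon set, stored as the sorted vector
#' of taxon indices on one side (the side not containing taxon 1, i.e.
#' the canonical side, except for the trivial split of taxon 1 itself).
#'
#' @param taxa Character vector of taxon labels.
#' @param splits List of integer vectors (taxon indices, 1-based).
#' @param weights Non-negative numeric vector, one per split.
#' @param support Optional numeric vector in `[0, 1]`, one per split.
#' @param cycle Optional circular ordering of taxon indices (NeighborNet
#'   output is circular).
#' @return Object of class `split_set`.
#' @export
split_set <- function(taxa, splits, weights, support = NULL, cycle = NULL) {
  stopifnot(length(splits) == length(weights))
  if (any(weights < 0)) stop("split weights must be >= 0")
  n <- length(taxa)
  splits <- lapply(splits, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) == 0L || length(s) >= n) stop("split side must be a proper subset")
    if (any(s < 1L | s > n)) stop("split references unknown taxon index")
    if (1L %in% s && length(s) > 1L) s <- sort(setdiff(seq_len(n), s))
    s
  })
  if (!is.null(support)) {
    stopifnot(length(support) == length(splits), all(support >= 0 & support <= 1))
  }
  structure(list(taxa = taxa, splits = splits, weights = as.numeric(weights),
                 support = support, cycle = cycle), class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("split_set:", length(x$splits), "splits over", length(x$taxa), "taxa\n")
  if (length(x$splits)) {
    show <- utils::head(order(-x$weights), 10L)
    for (k in show) {
      cat(sprintf("  %-30s w=%.5g%s\n",
                  paste(x$taxa[x$splits[[k]]], collapse = ","),
                  x$weights[k],
                  if (!is.null(x$support)) sprintf(" support=%.2f", x$support[k]) else ""))
    }
    if (length(x$splits) > 10L) cat("  ...\n")
  }
  invisible(x)
}

## canonical string key of a split (side not containing taxon 1)
.split_key <- function(s, n) {
  if (1L %in% s) s <- sort(setdiff(seq_len(n), s))
  paste(s, collapse = ",")
}

#' Write a split set as a NEXUS file with TAXA and SPLITS blocks
#'
#' The output round-trips through [read_nexus_splits()] and is readable by
#' SplitsTree.
#'
#' @param splits A [split_set()].
#' @param path Output path.
#' @export
write_nexus_splits <- function(splits, path) {
  stopifnot(inherits(splits, "split_set"))
  n <- length(splits$taxa)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN TAXA;")
  w("DIMENSIONS ntax=", n, ";")
  w("TAXLABELS")
  for (t in splits$taxa) w("  '", t, "'")
  w(";")
  w("END;")
  w("BEGIN SPLITS;")
  w("DIMENSIONS ntax=", n, " nsplits=", length(splits$splits), ";")
  w("FORMAT labels=no weights=yes confidences=",
    if (is.null(splits$support)) "no" else "yes", ";")
  if (!is.null(splits$cycle)) w("CYCLE ", paste(splits$cycle, collapse = " "), ";")
  w("MATRIX")
  for (k in seq_along(splits$splits)) {
    conf <- if (is.null(splits$support)) "" else
      paste0(" ", format(splits$support[k], digits = 10))
    w("  ", format(splits$weights[k], digits = 15), conf, "\t",
      paste(splits$splits[[k]], collapse = " "), ",")
  }
  w(";")
  w("END;")
  invisible(path)
}

#' Read a NEXUS splits file written by [write_nexus_splits()]
#'
#' @param path NEXUS file path.
#' @return A [split_set()].
#' @export
read_nexus_splits <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || toupper(lines[1L]) != "#NEXUS") stop("not a NEXUS file")
  up <- toupper(lines)
  tx0 <- grep("^TAXLABELS", up)
  if (!length(tx0)) stop("no TAXLABELS found")
  taxa <- character(0)
  i <- tx0[1L] + 1L
  while (i <= length(lines) && lines[i] != ";") {
    taxa <- c(taxa, gsub("^'|'$", "", lines[i]))
    i <- i + 1L
  }
  has_conf <- any(grepl("confidences=yes", lines, ignore.case = TRUE))
  cyc_line <- grep("^CYCLE", up, value = FALSE)
  cycle <- NULL
  if (length(cyc_line)) {
    cycle <- as.integer(strsplit(gsub("^CYCLE\\s*|;\\s*$", "",
                                      lines[cyc_line[1L]], ignore.case = TRUE),
                                 "\\s+")[[1L]])
  }
  m0 <- grep("^MATRIX$", up)
  sp_block <- grep("BEGIN SPLITS", up)
  if (!length(sp_block)) stop("no SPLITS block")
  m0 <- m0[m0 > sp_block[1L]][1L]
  splits <- list(); weights <- numeric(0); support <- numeric(0)
  i <- m0 + 1L
  while (i <= length(lines) && lines[i] != ";") {
    row <- sub(",\\s*$", "", lines[i])
    toks <- strsplit(row, "\\s+")[[1L]]
    weights <- c(weights, as.numeric(toks[1L]))
    if (has_conf) {
      support <- c(support, as.numeric(toks[2L]))
      side <- as.integer(toks[-(1:2)])
    } else side <- as.integer(toks[-1L])
    splits <- c(splits, list(side))
    i <- i + 1L
  }
  split_set(taxa, splits, weights,
            support = if (has_conf) support else NULL, cycle = cycle)
}
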