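## NeighborNet split networks and column-bootstrap supports.
##
## The agglomeration and non-negative least-squares split weighting are
## delegated to phangorn::neighborNet (an established implementation of
## the published algorithm); this module normalizes its output into the
## package's split_set container, applies the weight threshold, and adds
## column-bootstrap supports computed from the package's own
## ambiguity-averaged distances.

#' NeighborNet split network from a distance matrix
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [distance_matrix()]).
#' @param threshold Splits with weight below this are dropped
#'   (default 1e-6, suppressing numerical-noise splits).
#' @return A [split_set()] with the circular ordering in `$cycle`.
#' @export
neighbor_net <- function(d, threshold = 1e-6) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
    stop("distance matrix must be symmetric")
  }
  taxa <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- length(taxa)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    return(split_set(taxa, list(2L), d[1L, 2L], cycle = 1:2))
  }
  if (n == 3L) {
    ## only trivial splits exist; three-point split weights
    w <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    w <- pmax(w, 0)
    keep <- which(w >= threshold)
    return(split_set(taxa, as.list(keep), w[keep], cycle = 1:3))
  }
  nn <- phangorn::neighborNet(stats::as.dist(d))
  sp <- nn$splits
  if (is.null(sp)) sp <- phangorn::as.splits(nn)  # degenerate (tree/star) case
  labs <- attr(sp, "labels")
  wts <- attr(sp, "weights")
  if (is.null(wts)) wts <- rep(1, length(sp))
  idx_map <- match(labs, taxa)
  sides <- lapply(sp, function(s) sort(idx_map[s]))
  full <- lengths(sides) %in% c(0L, n)  # improper splits (whole taxon set)
  keep <- which(wts >= threshold & !full)
  cyc <- attr(sp, "cycle")
  cycle <- if (!is.null(cyc)) idx_map[cyc] else NULL
  split_set(taxa, sides[keep], wts[keep], cycle = cycle)
}

#' Column-bootstrap supports for NeighborNet splits
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate's distance matrix and NeighborNet are recomputed, and the
#' support of a split of the full-data network is the fraction of
#' replicates whose network contains that exact bipartition.
#'
#' @param aln An [aligned_set()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed (results are deterministic given the seed).
#' @param method Distance method, `"p"` or `"k2p"`.
#' @param threshold Split weight threshold.
#' @return The full-data [split_set()] with `$support` filled in.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              method = "p", threshold = 1e-6) {
  stopifnot(n_reps >= 1L)
  base <- neighbor_net(distance_matrix(aln, method), threshold)
  n <- length(base$taxa)
  keys <- vapply(base$splits, .split_key, "", n = n)
  hits <- stats::setNames(numeric(length(keys)), keys)
  valid <- 0L
  rec <- aln$records
  chars <- do.call(rbind, strsplit(rec$seq, "", fixed = TRUE))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (r in seq_len(n_reps)) {
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    seqs <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    rep_aln <- aligned_set(seq_records(rec$id, seqs, rec$group, rec$role))
    sp <- tryCatch(
      neighbor_net(distance_matrix(rep_aln, method), threshold),
      error = function(e) NULL)
    if (is.null(sp)) next
    valid <- valid + 1L
    rep_keys <- unique(vapply(sp$splits, .split_key, "", n = n))
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  if (valid == 0L) stop("all bootstrap replicates failed")
  base$support <- unname(hits / valid)
  base
}
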