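## Pairwise distances with IUPAC ambiguity averaging, group identity
## summaries and ribotype delimitation.
##
## All distances use pairwise gap deletion: a column enters a pair's
## comparison only when both sequences carry an informative (non-gap,
## non-N) state there. Ambiguities are handled as averages over their
## uniform resolutions, matching the "ambiguities handled as average"
## convention of split-network software.

## per-pair expected transition/transversion/mismatch fractions,
## computed from integer code vectors via the 16 x 16 lookup tables
.pair_PQ <- function(ca, cb) .pq_stats(ca, cb)

#' Uncorrected p distance with ambiguity averaging
#'
#' Mean over comparable columns (pairwise gap/N deletion) of the expected
#' mismatch probability `1 - |Sa  ^  Sb| / (|Sa| * |Sb|)` where `Sa`, `Sb`
#' are the expanded IUPAC state sets.
#'
#' @param a,b Sequence strings of equal length (or single-row
#'   `seq_records`).
#' @return Fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- if (inherits(a, "seq_records")) a$seq[1L] else .normalize_seq(a)
  b <- if (inherits(b, "seq_records")) b$seq[1L] else .normalize_seq(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  st <- .pair_PQ(.seq_codes(a), .seq_codes(b))
  if (st$n == 0L) stop("no comparable columns (all gaps/N)")
  st$mism / st$n
}

#' Kimura 2-parameter distance with ambiguity averaging
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with transition fraction
#' `P` and transversion fraction `Q` computed as expectations over uniform
#' resolutions of IUPAC ambiguities, under pairwise gap deletion.
#'
#' @param a,b Sequence strings of equal length.
#' @return Non-negative distance; saturated pairs (non-positive log
#'   argument) are an error rather than `Inf`.
#' @export
k2p_distance <- function(a, b) {
  a <- if (inherits(a, "seq_records")) a$seq[1L] else .normalize_seq(a)
  b <- if (inherits(b, "seq_records")) b$seq[1L] else .normalize_seq(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  st <- .pair_PQ(.seq_codes(a), .seq_codes(b))
  if (st$n == 0L) stop("no comparable columns (all gaps/N)")
  P <- st$P / st$n; Q <- st$Q / st$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated: K2P distance undefined for this pair")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln An [aligned_set()].
#' @param method `"p"` (uncorrected, default) or `"k2p"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = record
#'   ids.
#' @export
distance_matrix <- function(aln, method = c("p", "k2p")) {
  method <- match.arg(method)
  rec <- aln$records
  n <- nrow(rec)
  sets <- lapply(rec$seq, .seq_codes)
  d <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  f <- function(i, j) {
    st <- .pair_PQ(sets[[i]], sets[[j]])
    if (st$n == 0L) stop("no comparable columns between ", rec$id[i],
                         " and ", rec$id[j])
    if (method == "p") return(st$mism / st$n)
    P <- st$P / st$n; Q <- st$Q / st$n
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      stop("saturated pair: ", rec$id[i], " / ", rec$id[j])
    }
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) d[i, j] <- d[j, i] <- f(i, j)
  d
}

#' Mean genetic identity within or between groups
#'
#' Identity of a pair is `1 - p_distance`; the group summary is the
#' unweighted mean over all qualifying pairs, reported rounded half-up to
#' 3 decimals (the convention of published identity tables).
#'
#' @param aln An [aligned_set()].
#' @param groups Character vector: one group for `level = "within"`, two
#'   for `level = "between"`.
#' @param level `"within"` or `"between"`.
#' @param digits Decimal places for half-up rounding; `NULL` for the raw
#'   mean.
#' @return Mean identity.
#' @export
group_identity <- function(aln, groups, level = c("within", "between"),
                           digits = 3L) {
  level <- match.arg(level)
  rec <- aln$records
  if (level == "within") {
    stopifnot(length(groups) == 1L)
    idx <- which(rec$group %in% groups)
    if (length(idx) < 2L) stop("'within' needs at least 2 sequences in the group")
    prs <- utils::combn(idx, 2L)
  } else {
    stopifnot(length(groups) == 2L)
    ia <- which(rec$group %in% groups[1L]); ib <- which(rec$group %in% groups[2L])
    if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
    prs <- rbind(rep(ia, each = length(ib)), rep(ib, times = length(ia)))
  }
  sets <- lapply(rec$seq, .seq_codes)
  ident <- apply(prs, 2L, function(ij) {
    st <- .pair_PQ(sets[[ij[1L]]], sets[[ij[2L]]])
    if (st$n == 0L) stop("no comparable columns for a pair")
    1 - st$mism / st$n
  })
  m <- mean(ident)
  if (is.null(digits)) m else .round_half_up(m, digits)
}

.round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Delimit ribotypes (distinct sequence variants)
#'
#' Two sequences belong to the same ribotype iff they are identical at
#' every column where both are non-gap. By default `N` matches nothing,
#' so a sequence with an `N` differs from everything (including another
#' `N`) at that column; set `permissive_n = TRUE` to let `N` match any
#' base.
#'
#' @param aln An [aligned_set()] (or `seq_records` of equal lengths).
#' @param permissive_n Logical; see above.
#' @return data.frame of class `ribotypes`: `ribotype` (R1, R2, ... in
#'   order of first appearance), `representative` id, `members`
#'   (comma-separated ids), `multiplicity`.
#' @export
delimit_ribotypes <- function(aln, permissive_n = FALSE) {
  rec <- if (inherits(aln, "aligned_set")) aln$records else aln
  m <- do.call(rbind, strsplit(rec$seq, "", fixed = TRUE))
  n <- nrow(m)
  same <- function(i, j) {
    a <- m[i, ]; b <- m[j, ]
    cmp <- a != "-" & b != "-"
    a <- a[cmp]; b <- b[cmp]
    if (permissive_n) {
      ok <- a == b | a == "N" | b == "N"
    } else {
      ok <- a == b & a != "N"
    }
    all(ok)
  }
  assign <- integer(n); reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in seq_along(reps)) if (same(i, reps[r])) { hit <- r; break }
    if (hit) assign[i] <- hit else { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  out <- data.frame(
    ribotype = paste0("R", seq_along(reps)),
    representative = rec$id[reps],
    members = vapply(seq_along(reps), function(r)
      paste(rec$id[assign == r], collapse = ","), ""),
    multiplicity = as.integer(tabulate(assign, length(reps))),
    stringsAsFactors = FALSE)
  attr(out, "assignment") <- stats::setNames(paste0("R", assign), rec$id)
  class(out) <- c("ribotypes", "data.frame")
  out
}
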