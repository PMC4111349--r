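## IUPAC nucleotide ambiguity machinery. All sequence logic in the package
## funnels through these tables so that "ambiguities handled as average"
## means the same thing everywhere.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_CHARS <- c(names(.IUPAC), "-")

## reverse lookup: sorted base set -> minimal IUPAC code
.IUPAC_REV <- local({
  keys <- vapply(.IUPAC, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC), keys)
})

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param base Single IUPAC character (case-insensitive; `U` is treated as
#'   `T`). Gap (`-`) and `N` handling is controlled by `gap_n`.
#' @param gap_n How to expand gap and `N`: `"empty"` (default) returns an
#'   empty set, i.e. the position carries no state information; `"full"`
#'   returns all four bases for `N` (gap is always empty).
#' @return Character vector, a subset of `c("A","C","G","T")`.
#' @examples
#' expand_ambiguity("R")   # A G
#' expand_ambiguity("Y")   # C T
#' expand_ambiguity("N")   # character(0)
#' @export
expand_ambiguity <- function(base, gap_n = c("empty", "full")) {
  gap_n <- match.arg(gap_n)
  stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
  b <- toupper(base)
  if (b == "U") b <- "T"
  if (b == "-") return(character(0))
  if (!b %in% names(.IUPAC)) {
    stop("not an IUPAC nucleotide code: '", base, "'")
  }
  if (b == "N" && gap_n == "empty") return(character(0))
  .IUPAC[[b]]
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector of bases from `A`, `C`, `G`, `T`.
#' @return Single IUPAC character; `"-"` for an empty set.
#' @examples
#' iupac_code(c("C", "T"))  # "Y"
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  bases[bases == "U"] <- "T"
  if (length(bases) == 0L) return("-")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be A/C/G/T, got: ", paste(bases, collapse = ","))
  }
  .IUPAC_REV[[paste(sort(bases), collapse = "")]]
}

## Expand every character of a sequence string into a list of base sets.
## Internal workhorse; gaps and N give empty sets by default.
.expand_seq <- function(seq, gap_n = "empty") {
  ch <- .seq_chars(seq)
  out <- unname(.IUPAC[ch])
  empty <- ch == "-" | (ch == "N" & gap_n == "empty")
  if (any(empty)) out[empty] <- list(character(0))
  out
}

## Integer coding of IUPAC characters for vectorized pairwise statistics.
## Codes 1..15 are the IUPAC letters, 16 is the gap.
.seq_codes <- function(seq) {
  idx <- match(.seq_chars(seq), .IUPAC_CHARS)
  if (anyNA(idx)) stop("non-IUPAC character in sequence")
  idx
}

## 16 x 16 lookup tables of expected pairwise statistics under uniform
## resolution of ambiguities; gap and N are non-comparable.
.pair_tables <- (function() {
  k <- length(.IUPAC_CHARS)
  comp <- matrix(FALSE, k, k)
  mism <- ti <- tv <- matrix(0, k, k)
  sets <- c(.IUPAC, list("-" = character(0)))
  sets$N <- character(0)  # N treated as missing for distances
  purine <- c("A", "G")
  for (x in seq_len(k)) for (y in seq_len(k)) {
    A <- sets[[x]]; B <- sets[[y]]
    if (!length(A) || !length(B)) next
    comp[x, y] <- TRUE
    tot <- length(A) * length(B)
    nti <- 0L; ntv <- 0L
    for (a in A) for (b in B) {
      if (a == b) next
      if ((a %in% purine) == (b %in% purine)) nti <- nti + 1L else ntv <- ntv + 1L
    }
    ti[x, y] <- nti / tot
    tv[x, y] <- ntv / tot
    mism[x, y] <- (nti + ntv) / tot
  }
  list(comp = comp, mism = mism, ti = ti, tv = tv)
})()
.M_COMP <- .pair_tables$comp
.M_MISM <- .pair_tables$mism
.M_TI <- .pair_tables$ti
.M_TV <- .pair_tables$tv

## vectorized pairwise statistics from integer code vectors
.pq_stats <- function(ca, cb) {
  idx <- cbind(ca, cb)
  list(n = sum(.M_COMP[idx]), P = sum(.M_TI[idx]), Q = sum(.M_TV[idx]),
       mism = sum(.M_MISM[idx]))
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

## Validate + normalize a raw sequence string: upper case, U->T.
## Errors name the 1-based offending position.
.normalize_seq <- function(seq, id = "?") {
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  ch <- .seq_chars(s)
  bad <- which(!ch %in% .IUPAC_CHARS)
  if (length(bad)) {
    stop("sequence '", id, "' has non-IUPAC character '", ch[bad[1L]],
         "' at position ", bad[1L])
  }
  s
}

## Per-column expected match probability between two IUPAC characters,
## uniform over joint resolutions; NA when either side is uninformative.
.match_prob <- function(sa, sb) {
  if (length(sa) == 0L || length(sb) == 0L) return(NA_real_)
  length(intersect(sa, sb)) / (length(sa) * length(sb))
}
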