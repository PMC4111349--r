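## Polymorphic-site detection with IUPAC semantics, ITS region annotation,
## GC content, hybrid additivity classification and consensus calling.
##
## A column is polymorphic iff the union of expanded IUPAC states across
## the selected sequences (gaps and N excluded) contains two or more
## bases; a single intra-individual ambiguity (one Y in one sequence)
## therefore suffices. Columns varying only by gaps are not polymorphic.

## default motif anchors used for motif-based region annotation; the 5.8S
## is taken to start at M1 and end at M3 (both configurable)
.DEFAULT_MOTIFS <- list(
  ITS1_angiosperm = "GGCRYnnnnGYGYCAAGGAA",  # 4-7 n spacer, see check_motifs
  M1 = "CGATGAAGAACGYAGC",
  M2 = "GAATTGCAGAATCC",
  M3 = "TTTGAAYGCA"
)

#' Annotate ITS1 / 5.8S / ITS2 regions on an alignment
#'
#' Either pass explicit column spans (`spans`), which are validated and
#' returned verbatim, or anchor the 5.8S by locating the conserved 5.8S
#' motifs M1 (start) and M3 (end) on a reference sequence: ITS1 is then
#' everything before M1 and ITS2 everything after the end of M3.
#'
#' @param aln An [aligned_set()].
#' @param spans Optional named list `list(ITS1 = c(s,e), r5.8S = c(s,e),
#'   ITS2 = c(s,e))`, 1-based inclusive alignment columns.
#' @param motifs Named list of IUPAC motif patterns with entries `M1` and
#'   `M3` (defaults are the conserved angiosperm 5.8S motifs).
#' @param max_mismatch Mismatch budget for motif location (default 1).
#' @param reference Id of the sequence used to locate motifs (default:
#'   first sequence).
#' @return Object of class `region_annotation`: named list of spans.
#' @export
annotate_regions <- function(aln, spans = NULL, motifs = .DEFAULT_MOTIFS,
                             max_mismatch = 1L, reference = NULL) {
  if (!is.null(spans)) {
    need <- c("ITS1", "r5.8S", "ITS2")
    if (!all(need %in% names(spans))) {
      stop("spans must name regions: ", paste(need, collapse = ", "))
    }
    spans <- spans[need]
    v <- unlist(spans)
    if (any(v < 1L) || any(v > aln$L)) stop("span outside alignment columns")
    if (!(spans$ITS1[2L] < spans$`r5.8S`[1L] &&
          spans$`r5.8S`[2L] < spans$ITS2[1L])) {
      stop("regions must be ordered ITS1 < 5.8S < ITS2 without overlap")
    }
    if (spans$ITS1[2L] < spans$ITS1[1L] || spans$ITS2[2L] < spans$ITS2[1L]) {
      stop("ITS1 and ITS2 must have positive length")
    }
    return(structure(spans, class = "region_annotation"))
  }
  ref_id <- reference %||% aln$records$id[1L]
  seq <- aln$records$seq[match(ref_id, aln$records$id)]
  m1 <- .find_motif(seq, motifs$M1, max_mismatch)
  m3 <- .find_motif(seq, motifs$M3, max_mismatch)
  if (m1$n_mismatches > max_mismatch) {
    stop("M1 motif not found within ", max_mismatch, " mismatches; best hit at ",
         m1$start, " with ", m1$n_mismatches, " mismatches")
  }
  if (m3$n_mismatches > max_mismatch) {
    stop("M3 motif not found within ", max_mismatch, " mismatches; best hit at ",
         m3$start, " with ", m3$n_mismatches, " mismatches")
  }
  s58 <- m1$start; e58 <- m3$end
  if (s58 <= 1L || e58 >= nchar(seq) || s58 >= e58) {
    stop("motif anchors give an impossible 5.8S span (", s58, "-", e58, ")")
  }
  structure(list(ITS1 = c(1L, s58 - 1L), `r5.8S` = c(s58, e58),
                 ITS2 = c(e58 + 1L, nchar(seq))),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  for (r in names(x)) {
    cat(sprintf("%-6s %d-%d (%d columns)\n", r, x[[r]][1L], x[[r]][2L],
                x[[r]][2L] - x[[r]][1L] + 1L))
  }
  invisible(x)
}

## region of an alignment column; NA if outside all spans
.region_of <- function(column, regions) {
  for (r in names(regions)) {
    if (column >= regions[[r]][1L] && column <= regions[[r]][2L]) return(r)
  }
  NA_character_
}

## IUPAC-aware motif scan: best hit of pattern in seq, ignoring gaps in
## seq. A position matches iff the observed base set is a subset of the
## pattern code's set; 'n'/'N' in the pattern matches anything. Returns
## 1-based start/end in original (gapped) coordinates.

## SUBSET[obs, pat]: observed state set contained in pattern state set
.MOTIF_SUBSET <- (function() {
  codes <- names(.IUPAC)
  sub <- matrix(FALSE, length(codes), length(codes),
                dimnames = list(codes, codes))
  for (o in codes) for (p in codes) {
    sub[o, p] <- all(.IUPAC[[o]] %in% .IUPAC[[p]])
  }
  sub
})()

.find_motif <- function(seq, pattern, max_mismatch = 0L) {
  ch <- .seq_chars(seq)
  keep <- which(ch != "-")
  s <- ch[keep]
  p <- .seq_chars(toupper(gsub("U", "T", pattern)))
  np <- length(p); ns <- length(s)
  best <- list(start = NA_integer_, end = NA_integer_, n_mismatches = np + 1L)
  if (ns < np || np == 0L) return(best)
  oi <- match(s, names(.IUPAC))
  pi <- match(p, names(.IUPAC))
  if (anyNA(pi)) stop("non-IUPAC character in motif pattern: ", pattern)
  for (off in 0:(ns - np)) {
    mm <- np - sum(.MOTIF_SUBSET[cbind(oi[off + seq_len(np)], pi)])
    if (mm < best$n_mismatches) {
      best <- list(start = keep[off + 1L], end = keep[off + np],
                   n_mismatches = mm)
    }
    if (best$n_mismatches == 0L) break
  }
  best
}

#' GC content of a region of a sequence
#'
#' Computed as the expected fraction of G or C over non-gap, non-N
#' positions of the span: unambiguous G/C/S contribute 1, A/T/W 0, and
#' other ambiguity codes their expected GC fraction (e.g. R contributes
#' 0.5).
#'
#' @param seq Sequence string (or a single-row `seq_records`).
#' @param regions A `region_annotation` (or `NULL` to use the whole
#'   sequence).
#' @param which Region name from `regions` (ignored when `regions` is
#'   `NULL`).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq, regions = NULL, which = "ITS1") {
  if (inherits(seq, "seq_records")) seq <- seq$seq[1L]
  seq <- .normalize_seq(seq)
  if (!is.null(regions)) {
    sp <- regions[[which]]
    if (is.null(sp)) stop("unknown region: ", which)
    if (sp[2L] > nchar(seq)) stop("region span outside sequence")
    seq <- substr(seq, sp[1L], sp[2L])
  }
  sets <- .expand_seq(seq)
  informative <- lengths(sets) > 0L
  if (!any(informative)) stop("region is all gaps/N; GC content undefined")
  gcfrac <- vapply(sets[informative], function(s)
    mean(s %in% c("G", "C")), 0)
  mean(gcfrac)
}

#' Find polymorphic alignment columns
#'
#' @param aln An [aligned_set()].
#' @param groups Optional character vector restricting the scan to records
#'   whose `group` is in this set.
#' @param regions Optional `region_annotation` used to label each site.
#' @return data.frame of class `polymorphic_sites` with one row per
#'   polymorphic column: `column`, `region`, `states` (comma-separated
#'   union of expanded bases) and one `states.<group>` column per group
#'   present.
#' @export
find_polymorphic_sites <- function(aln, groups = NULL, regions = NULL) {
  rec <- aln$records
  if (!is.null(groups)) {
    rec <- rec[rec$group %in% groups, , drop = FALSE]
    if (!nrow(rec)) stop("no sequences in the selected groups")
  }
  m <- do.call(rbind, strsplit(rec$seq, "", fixed = TRUE))
  cols <- integer(0); states <- character(0); region <- character(0)
  grs <- unique(rec$group[!is.na(rec$group)])
  per_group <- stats::setNames(rep(list(character(0)), length(grs)), grs)
  for (j in seq_len(ncol(m))) {
    u <- .column_states(m[, j])
    if (length(u) >= 2L) {
      cols <- c(cols, j)
      states <- c(states, paste(u, collapse = ","))
      region <- c(region,
                  if (is.null(regions)) NA_character_ else .region_of(j, regions))
      for (g in grs) {
        gu <- .column_states(m[rec$group %in% g, j])
        per_group[[g]] <- c(per_group[[g]], paste(gu, collapse = ","))
      }
    }
  }
  out <- data.frame(column = cols, region = region, states = states,
                    stringsAsFactors = FALSE)
  for (g in grs) out[[paste0("states.", g)]] <- per_group[[g]]
  class(out) <- c("polymorphic_sites", "data.frame")
  out
}

## union of expanded states over a character vector (one alignment column)
.column_states <- function(chars) {
  u <- character(0)
  for (b in chars) {
    if (b == "-" || b == "N") next
    u <- union(u, .IUPAC[[b]])
    if (length(u) == 4L) break
  }
  sort(u)
}

#' Classify hybrid additivity at a polymorphic site
#'
#' Given the expanded state sets of the maternal parent, paternal parent
#' and hybrid at one column, assigns one of:
#' \describe{
#'   \item{additive_combination}{the hybrid carries at least one
#'     maternal-specific and one paternal-specific state, i.e. it combines
#'     contributions unique to each parent;}
#'   \item{parental_shared}{the hybrid's states equal a polymorphism
#'     already present within a single parent (or within both);}
#'   \item{maternal_only / paternal_only}{hybrid states fall exclusively
#'     inside one parent's states, and that parent is not polymorphic for
#'     the hybrid's full state set;}
#'   \item{novel}{the hybrid carries a state absent from both parents.}
#' }
#'
#' @param maternal,paternal,hybrid Character vectors of expanded bases
#'   (e.g. from the `states.*` columns of [find_polymorphic_sites()]; a
#'   comma-separated string is also accepted).
#' @return Single classification string.
#' @export
classify_additivity <- function(maternal, paternal, hybrid) {
  tostate <- function(x) {
    if (length(x) == 1L && grepl(",", x)) x <- strsplit(x, ",")[[1L]]
    sort(unique(toupper(x)))
  }
  mat <- tostate(maternal); pat <- tostate(paternal); hyb <- tostate(hybrid)
  if (!length(hyb)) stop("hybrid group has no states at this column")
  if (!length(mat) || !length(pat)) stop("both parental groups must be present")
  if (length(setdiff(hyb, union(mat, pat)))) return("novel")
  mat_specific <- setdiff(mat, pat)
  pat_specific <- setdiff(pat, mat)
  if (length(intersect(hyb, mat_specific)) && length(intersect(hyb, pat_specific))) {
    return("additive_combination")
  }
  if (length(hyb) >= 2L &&
      (all(hyb %in% mat) && length(mat) >= 2L && setequal(hyb, mat) ||
       all(hyb %in% pat) && length(pat) >= 2L && setequal(hyb, pat))) {
    return("parental_shared")
  }
  if (all(hyb %in% mat) && !all(hyb %in% pat)) return("maternal_only")
  if (all(hyb %in% pat) && !all(hyb %in% mat)) return("paternal_only")
  ## remaining case: hyb subset of both parents' union and of each --
  ## i.e. states shared by both parents
  "parental_shared"
}

#' Classify additivity for every informative site of an alignment
#'
#' Convenience wrapper running [find_polymorphic_sites()] on the union of
#' the three groups and [classify_additivity()] per site (sites where any
#' of the three groups is absent are dropped).
#'
#' @param aln An [aligned_set()].
#' @param maternal,paternal,hybrid Group labels.
#' @param regions Optional `region_annotation`.
#' @return `polymorphic_sites` data.frame with an `additivity` column.
#' @export
additivity_table <- function(aln, maternal, paternal, hybrid, regions = NULL) {
  sites <- find_polymorphic_sites(aln, groups = c(maternal, paternal, hybrid),
                                  regions = regions)
  cols <- paste0("states.", c(maternal, paternal, hybrid))
  if (!all(cols %in% names(sites))) stop("missing group in alignment")
  keep <- rep(TRUE, nrow(sites))
  cls <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    st <- lapply(cols, function(cn) sites[[cn]][i])
    if (any(!nzchar(unlist(st)))) { keep[i] <- FALSE; next }
    cls[i] <- classify_additivity(st[[1L]], st[[2L]], st[[3L]])
  }
  out <- sites[keep, , drop = FALSE]
  out$additivity <- cls[keep]
  out
}

#' Call a direct-sequencing style consensus over a copy pool
#'
#' Emulates direct Sanger sequencing of a multi-copy template: per column,
#' expanded base states with frequency at or above `minor_threshold` are
#' collected and encoded as the minimal IUPAC code covering them;
#' below-threshold minor variants disappear, which is why direct
#' sequencing detects fewer polymorphic sites than cloning.
#'
#' @param copies `seq_records` or `aligned_set` of aligned copies.
#' @param minor_threshold Minimum state frequency to be retained
#'   (default 0.25, roughly the level below which a secondary Sanger peak
#'   goes uncalled); must lie in `(0, 0.5)`.
#' @param id Identifier for the consensus record.
#' @return Single-row `seq_records`.
#' @export
call_consensus <- function(copies, minor_threshold = 0.25, id = "consensus") {
  if (inherits(copies, "aligned_set")) copies <- copies$records
  if (!nrow(copies)) stop("empty copy set")
  stopifnot(minor_threshold > 0, minor_threshold < 0.5)
  L <- unique(nchar(copies$seq))
  if (length(L) != 1L) stop("copies must be aligned (equal length)")
  m <- do.call(rbind, strsplit(copies$seq, "", fixed = TRUE))
  cons <- vapply(seq_len(L), function(j) {
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    n_inf <- 0L
    for (b in m[, j]) {
      s <- if (b == "-" || b == "N") character(0) else .IUPAC[[b]]
      if (!length(s)) next
      counts[s] <- counts[s] + 1 / length(s)
      n_inf <- n_inf + 1L
    }
    if (n_inf == 0L) return("-")
    keep <- names(counts)[counts / n_inf >= minor_threshold]
    if (!length(keep)) keep <- names(counts)[which.max(counts)]
    iupac_code(keep)
  }, "")
  seq_records(id, paste(cons, collapse = ""))
}
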