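## Secondary-structure-aware substitution classification and clone QC.
##
## Substitutions at helical (paired) template positions are classified by
## what they do to the base-pair bond: a compensatory base change (CBC)
## mutates both partners while retaining the bond (G-C -> A-U); a
## hemi-CBC mutates one partner while retaining the bond (G-C -> G-U);
## a non-compensatory change destroys the bond; positions outside helices
## are "unpaired". G-U wobble counts as a bond by default.

.BONDS_WOBBLE <- c("AT", "TA", "GC", "CG", "GT", "TG")
.BONDS_STRICT <- c("AT", "TA", "GC", "CG")

.is_bond <- function(x, y, wobble = TRUE) {
  paste0(x, y) %in% (if (wobble) .BONDS_WOBBLE else .BONDS_STRICT)
}

#' Classify a substitution against a structure template
#'
#' @param template A [structure_template()].
#' @param column 1-based template position of the (possibly) mutated base.
#' @param from_base,to_base Base at `column` before/after the change.
#' @param partner_from,partner_to Base at the partner position
#'   before/after; must be `NULL` for unpaired columns (supplying a
#'   partner state for an unpaired column is an error). For unpaired
#'   columns the classification is `"unpaired"`.
#' @param wobble Count G-U as a bond (default `TRUE`).
#' @return List of class `base_change` with `column`, `partner`,
#'   `from_pair`, `to_pair` and `klass` in `CBC`, `hCBC`,
#'   `non_compensatory`, `unpaired`, `silent`.
#' @export
classify_base_change <- function(template, column, from_base, to_base,
                                 partner_from = NULL, partner_to = NULL,
                                 wobble = TRUE) {
  L <- nchar(template$seq)
  if (column < 1L || column > L) stop("column outside template")
  partner <- template$partner[column]
  norm <- function(b) if (is.null(b)) NULL else {
    b <- toupper(b); if (b == "U") "T" else b
  }
  from_base <- norm(from_base); to_base <- norm(to_base)
  partner_from <- norm(partner_from); partner_to <- norm(partner_to)
  if (partner == 0L) {
    if (!is.null(partner_from) || !is.null(partner_to)) {
      stop("column ", column, " is unpaired but a partner state was supplied")
    }
    klass <- if (identical(from_base, to_base)) "silent" else "unpaired"
    out <- list(column = column, partner = NA_integer_,
                from_pair = from_base, to_pair = to_base, klass = klass)
    class(out) <- "base_change"
    return(out)
  }
  if (is.null(partner_from)) partner_from <- substr(template$seq, partner, partner)
  if (is.null(partner_to)) partner_to <- partner_from
  changed1 <- from_base != to_base
  changed2 <- partner_from != partner_to
  bonded_after <- .is_bond(to_base, partner_to, wobble)
  klass <- if (!changed1 && !changed2) "silent"
  else if (!bonded_after) "non_compensatory"
  else if (changed1 && changed2) "CBC"
  else "hCBC"
  out <- list(column = column, partner = partner,
              from_pair = paste0(from_base, partner_from),
              to_pair = paste0(to_base, partner_to), klass = klass)
  class(out) <- "base_change"
  out
}

#' @export
print.base_change <- function(x, ...) {
  cat(sprintf("position %d%s: %s -> %s  [%s]\n", x$column,
              if (is.na(x$partner)) " (unpaired)" else
                sprintf(" ~ %d", x$partner),
              x$from_pair, x$to_pair, x$klass))
  invisible(x)
}

## severity order for multi-state sites: CBC > non_compensatory > hCBC >
## unpaired > silent
.KLASS_SEVERITY <- c(CBC = 4L, non_compensatory = 3L, hCBC = 2L,
                     unpaired = 1L, silent = 0L)

#' Per-site substitution class for a table of polymorphic sites
#'
#' Each polymorphic site is assigned one class: the maximal-severity
#' class (CBC > non-compensatory > hCBC > unpaired) over all single-base
#' variants observed at the site, evaluated with the template base at the
#' partner position (and, when the partner column is itself polymorphic,
#' also over joint variants of the pair, which is how a CBC can be
#' observed). Sites must already be in template coordinates.
#'
#' @param sites `polymorphic_sites` data.frame (from
#'   [find_polymorphic_sites()]); only `column` and `states` are used.
#' @param template A [structure_template()].
#' @param wobble Count G-U as a bond.
#' @return The sites with a `klass` column, plus a `counts` attribute:
#'   class counts per region (matrix class x region) when sites carry a
#'   `region` column.
#' @export
summarize_change_classes <- function(sites, template, wobble = TRUE) {
  L <- nchar(template$seq)
  if (any(sites$column < 1L | sites$column > L)) {
    stop("site outside template coordinates")
  }
  tch <- .seq_chars(template$seq)
  site_states <- function(col) {
    hit <- which(sites$column == col)
    if (length(hit)) strsplit(sites$states[hit[1L]], ",")[[1L]] else
      substr(template$seq, col, col)
  }
  klass <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    col <- sites$column[i]
    ref <- tch[col]
    obs <- setdiff(strsplit(sites$states[i], ",")[[1L]], ref)
    if (!length(obs)) { klass[i] <- "silent"; next }
    partner <- template$partner[col]
    if (partner == 0L) { klass[i] <- "unpaired"; next }
    pref <- tch[partner]
    pobs <- site_states(partner)
    best <- 0L; best_k <- "unpaired"
    for (a in obs) {
      for (pb in pobs) {
        bc <- classify_base_change(template, col, ref, a, pref, pb,
                                   wobble = wobble)
        if (.KLASS_SEVERITY[[bc$klass]] > best) {
          best <- .KLASS_SEVERITY[[bc$klass]]; best_k <- bc$klass
        }
      }
    }
    klass[i] <- best_k
  }
  out <- sites
  out$klass <- klass
  if (!is.null(sites$region)) {
    attr(out, "counts") <- table(factor(klass, names(.KLASS_SEVERITY)),
                                 sites$region)
  }
  attr(out, "class_counts") <- table(factor(klass, names(.KLASS_SEVERITY)))
  out
}

#' Check conserved ITS motifs in a sequence
#'
#' Scans for the conserved angiosperm ITS1 motif
#' `GGCRY(4-7n)GYGYCAAGGAA` (all spacer lengths 4-7 are tried and the
#' best kept) and the three conserved 5.8S motifs M1-M3. Matching is
#' IUPAC-aware: a pattern position with code R matches an observed base
#' whose state set is contained in `{A,G}`. A motif passes with 0
#' mismatches at the best position.
#'
#' @param seq Sequence string or single-row `seq_records`.
#' @param regions Optional `region_annotation`; when given, each motif is
#'   searched only in its home region (ITS1 motif in ITS1, M1-M3 in the
#'   5.8S) and a missing region reports a failed check rather than an
#'   error.
#' @param motifs Named list of IUPAC patterns; the ITS1 motif may contain
#'   a literal `(4-7n)` style spacer written as `nnnn` (minimum length),
#'   extended up to 3 extra `n`s during the scan.
#' @return data.frame of class `motif_checks`: motif, expected, observed,
#'   start, n_mismatches, pass.
#' @export
check_motifs <- function(seq, regions = NULL, motifs = .DEFAULT_MOTIFS) {
  if (inherits(seq, "seq_records")) seq <- seq$seq[1L]
  seq <- .normalize_seq(seq)
  home <- c(ITS1_angiosperm = "ITS1", M1 = "r5.8S", M2 = "r5.8S", M3 = "r5.8S")
  rows <- lapply(names(motifs), function(mn) {
    sub_seq <- seq; offset <- 0L
    if (!is.null(regions) && mn %in% names(home)) {
      sp <- regions[[home[[mn]]]]
      if (is.null(sp)) {
        return(data.frame(motif = mn, expected = motifs[[mn]],
                          observed = NA_character_, start = NA_integer_,
                          n_mismatches = NA_integer_, pass = FALSE,
                          stringsAsFactors = FALSE))
      }
      sub_seq <- substr(seq, sp[1L], sp[2L]); offset <- sp[1L] - 1L
    }
    pat <- motifs[[mn]]
    cands <- if (grepl("nnnn", pat, fixed = TRUE)) {
      vapply(0:3, function(k) sub("nnnn", strrep("n", 4L + k), pat, fixed = TRUE), "")
    } else pat
    best <- NULL
    for (p in cands) {
      hit <- .find_motif(sub_seq, p, max_mismatch = nchar(p))
      if (is.null(best) || (!is.na(hit$start) &&
                            hit$n_mismatches < best$n_mismatches)) best <- hit
    }
    obs <- if (is.na(best$start)) NA_character_ else
      substr(seq, best$start + offset, best$end + offset)
    data.frame(motif = mn, expected = pat,
               observed = obs,
               start = if (is.na(best$start)) NA_integer_ else best$start + offset,
               n_mismatches = best$n_mismatches,
               pass = !is.na(best$start) && best$n_mismatches == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_checks", "data.frame")
  out
}

#' Screen a clone library for putative non-functional ITS copies
#'
#' Each clone is compared to the library's reference (the direct-sequence
#' consensus or a majority-rule consensus). Diagnostics per clone:
#' substitutions in the 5.8S (strictly conserved in functional copies),
#' conserved-motif failures, per-region GC z-scores against the library,
#' methylation-type substitutions (C->T, G->A relative to the reference)
#' and whether the clone's variants are singletons in the library.
#' Verdicts: `putative_nonfunctional` iff any 5.8S substitution, any
#' failed motif, or a GC z-score below `gc_z`; otherwise
#' `putative_artifact` for clones whose variants are all singletons and
#' (when a template is given) all non-compensatory; otherwise `ok`.
#'
#' @param library `aligned_set` of clones (one clone library).
#' @param consensus Reference sequence (string or single-row
#'   `seq_records`), aligned to the library columns.
#' @param regions `region_annotation` covering the alignment (the 5.8S
#'   span is required).
#' @param template Optional [structure_template()] enabling the
#'   non-compensatory singleton-artifact rule.
#' @param gc_z GC z-score cutoff (default -3).
#' @param motifs Motif patterns for [check_motifs()].
#' @param wobble Count G-U as a bond.
#' @return data.frame of class `clone_qc`: one row per clone with columns
#'   id, n_58S_subs, n_motif_fails, gc_ITS1, gc_58S, gc_ITS2, gc_z_min,
#'   n_methylation_type_subs, n_subs, is_singleton_variant, verdict.
#' @export
screen_pseudogenes <- function(library, consensus, regions, template = NULL,
                               gc_z = -3, motifs = .DEFAULT_MOTIFS,
                               wobble = TRUE) {
  if (is.null(regions[["r5.8S"]])) stop("5.8S span missing from regions")
  cons <- if (inherits(consensus, "seq_records")) consensus$seq[1L] else
    .normalize_seq(consensus)
  rec <- library$records
  if (nchar(cons) != library$L) stop("consensus not aligned to library columns")
  cch <- .seq_chars(cons)
  mm <- .aln_matrix(library)
  s58 <- regions[["r5.8S"]]
  in58 <- seq(s58[1L], s58[2L])
  ## substitution = clone has an unambiguous informative base differing
  ## from every base covered by the reference state at that column
  subs_of <- function(i) {
    ch <- mm[i, ]
    idx <- which(ch != "-" & ch != "N" & cch != "-" & cch != "N")
    idx[vapply(idx, function(j) {
      length(intersect(.IUPAC[[ch[j]]], .IUPAC[[cch[j]]])) == 0L
    }, TRUE)]
  }
  all_subs <- lapply(seq_len(nrow(rec)), subs_of)
  ## singleton variant: a (column, state) carried by exactly one clone
  n <- nrow(rec)
  gc_reg <- function(i, rg) tryCatch(gc_content(rec$seq[i], regions, rg),
                                     error = function(e) NA_real_)
  gcs <- cbind(ITS1 = vapply(seq_len(n), gc_reg, 0, rg = "ITS1"),
               `r5.8S` = vapply(seq_len(n), gc_reg, 0, rg = "r5.8S"),
               ITS2 = vapply(seq_len(n), gc_reg, 0, rg = "ITS2"))
  zs <- scale(gcs)  # per-region z-scores within the library
  zs[is.nan(zs)] <- 0
  rows <- lapply(seq_len(n), function(i) {
    subs <- all_subs[[i]]
    n58 <- sum(subs %in% in58)
    mot <- check_motifs(rec$seq[i], regions, motifs)
    nmf <- sum(!mot$pass)
    meth <- sum(vapply(subs, function(j) {
      (cch[j] == "C" && mm[i, j] == "T") || (cch[j] == "G" && mm[i, j] == "A")
    }, TRUE))
    singleton <- length(subs) > 0L && all(vapply(subs, function(j) {
      sum(mm[, j] == mm[i, j]) == 1L
    }, TRUE))
    noncomp_only <- FALSE
    if (!is.null(template) && length(subs)) {
      kl <- vapply(subs, function(j) {
        classify_base_change(template, j, cch[j], mm[i, j],
                             wobble = wobble)$klass
      }, "")
      noncomp_only <- all(kl == "non_compensatory")
    }
    zmin <- suppressWarnings(min(zs[i, ], na.rm = TRUE))
    verdict <- if (n58 >= 1L || nmf >= 1L || (is.finite(zmin) && zmin < gc_z)) {
      "putative_nonfunctional"
    } else if (singleton && (is.null(template) || noncomp_only) &&
               length(subs) > 0L) {
      "putative_artifact"
    } else "ok"
    data.frame(id = rec$id[i], n_58S_subs = n58, n_motif_fails = nmf,
               gc_ITS1 = gcs[i, 1L], gc_58S = gcs[i, 2L], gc_ITS2 = gcs[i, 3L],
               gc_z_min = zmin, n_methylation_type_subs = meth,
               n_subs = length(subs), is_singleton_variant = singleton,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("clone_qc", "data.frame")
  out
}

#' Maximum chi-square scan for chimeric (recombinant) clones
#'
#' At informative sites (columns where the two parents carry different
#' unambiguous bases) the query is assigned to parent A or B; the scan
#' maximizes the 2x2 chi-square statistic (left-of-breakpoint vs right,
#' A-like vs B-like) over all breakpoints, and calibrates significance by
#' permuting the site assignments.
#'
#' @param query,parent_a,parent_b Aligned sequences (strings or
#'   single-row `seq_records`) of equal length.
#' @param n_perm Permutation replicates for calibration (default 999).
#' @param seed Integer seed (required for reproducibility).
#' @param alpha Significance level (default 0.05).
#' @param min_informative Minimum informative sites (default 4); fewer
#'   returns `NULL` with a warning.
#' @return `NULL` if no significant breakpoint (or too few informative
#'   sites), else a list of class `chimera_hit`: `breakpoint_column`
#'   (alignment position after which the origin switches),
#'   `breakpoint_site` (index among informative sites), `chi_square`,
#'   `p_value`, `informative_columns`, `assignment`.
#' @export
chimera_scan <- function(query, parent_a, parent_b, n_perm = 999L, seed = 1L,
                         alpha = 0.05, min_informative = 4L) {
  g <- function(x) if (inherits(x, "seq_records")) x$seq[1L] else .normalize_seq(x)
  q <- .seq_chars(g(query)); a <- .seq_chars(g(parent_a)); b <- .seq_chars(g(parent_b))
  if (length(unique(c(length(q), length(a), length(b)))) != 1L) {
    stop("query and parents must be aligned to equal length")
  }
  plain <- function(ch) ch %in% c("A", "C", "G", "T")
  inf <- which(plain(a) & plain(b) & a != b)
  if (!length(inf)) stop("parents are identical: no informative sites")
  usable <- inf[plain(q[inf]) & (q[inf] == a[inf] | q[inf] == b[inf])]
  if (length(usable) < min_informative) {
    warning("only ", length(usable), " informative sites; chimera scan skipped")
    return(NULL)
  }
  z <- as.integer(q[usable] == a[usable])  # 1 = A-like, 0 = B-like
  max_chi <- function(z) {
    m <- length(z)
    best <- 0; at <- NA_integer_
    cs <- cumsum(z)
    tot1 <- cs[m]; tot0 <- m - tot1
    for (k in seq_len(m - 1L)) {
      l1 <- cs[k]; l0 <- k - l1
      r1 <- tot1 - l1; r0 <- tot0 - l0
      E <- outer(c(k, m - k), c(tot1, tot0)) / m
      O <- matrix(c(l1, r1, l0, r0), 2L)
      chi <- sum((O - E)^2 / E)
      if (is.finite(chi) && chi > best) { best <- chi; at <- k }
    }
    list(chi = best, at = at)
  }
  obs <- max_chi(z)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  exceed <- 0L
  for (r in seq_len(n_perm)) {
    if (max_chi(sample(z))$chi >= obs$chi) exceed <- exceed + 1L
  }
  p <- (exceed + 1L) / (n_perm + 1L)
  if (p > alpha) return(NULL)
  structure(list(breakpoint_column = usable[obs$at],
                 breakpoint_site = obs$at,
                 chi_square = obs$chi, p_value = p,
                 informative_columns = usable,
                 assignment = z), class = "chimera_hit")
}

#' @export
print.chimera_hit <- function(x, ...) {
  cat(sprintf(
    "chimera breakpoint after column %d (informative site %d/%d), chi^2 = %.2f, p = %.4g\n",
    x$breakpoint_column, x$breakpoint_site, length(x$informative_columns),
    x$chi_square, x$p_value))
  invisible(x)
}
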