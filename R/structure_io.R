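## RNA secondary-structure templates: CT and Vienna dot-bracket parsing,
## plus a constructor used by the synthetic module. Positions are 1-based;
## each position pairs with at most one partner.

#' Construct a structure template
#'
#' @param seq Template sequence (RNA or DNA; stored with `U` as `T`).
#' @param pairs Two-column integer matrix of base pairs `(i, j)`, 1-based.
#'   Stored with `i < j`, deduplicated.
#' @param region_spans Optional named list mapping region names (e.g.
#'   `ITS1`, `r5.8S`, `ITS2`) to `c(start, end)`, inclusive.
#' @return Object of class `structure_template` with fields `seq`,
#'   `pairs`, `partner` (integer vector, 0 = unpaired) and `region_spans`.
#' @export
structure_template <- function(seq, pairs, region_spans = NULL) {
  seq <- .normalize_seq(seq, "template")
  L <- nchar(seq)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    if (any(pairs < 1L | pairs > L)) stop("pair index out of range 1..", L)
    if (any(pairs[, 1L] == pairs[, 2L])) stop("position paired with itself")
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  partner <- integer(L)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (partner[i] || partner[j]) {
      stop("position ", if (partner[i]) i else j, " appears in more than one pair")
    }
    partner[i] <- j; partner[j] <- i
  }
  structure(list(seq = seq, pairs = pairs, partner = partner,
                 region_spans = region_spans),
            class = "structure_template")
}

#' @export
print.structure_template <- function(x, ...) {
  cat("structure_template:", nchar(x$seq), "nt,", nrow(x$pairs), "base pairs\n")
  if (!is.null(x$region_spans)) {
    for (r in names(x$region_spans)) {
      cat("  ", r, ": ", x$region_spans[[r]][1L], "-", x$region_spans[[r]][2L],
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Read a secondary-structure template
#'
#' Supports the 6-column CT format (partner index 0 = unpaired) and Vienna
#' dot-bracket strings. Pseudoknot bracket tiers `[]`, `{}`, `<>` are
#' accepted and parsed as ordinary pairs.
#'
#' @param path File path. For `dotbracket`, the file holds the sequence on
#'   one line and the bracket string on the next (an optional leading
#'   `>` header line is skipped).
#' @param dialect `"ct"` or `"dotbracket"`.
#' @return A [structure_template()].
#' @export
read_structure <- function(path, dialect = c("ct", "dotbracket")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty structure file: ", path)
  if (dialect == "ct") .parse_ct(lines) else {
    lines <- lines[!grepl("^>", lines)]
    if (length(lines) < 2L) stop("dot-bracket file needs sequence and bracket lines")
    structure_template(trimws(lines[1L]),
                       .parse_dotbracket(trimws(lines[2L])))
  }
}

.parse_ct <- function(lines) {
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
  if (is.na(n)) stop("CT header does not start with a position count")
  body <- lines[-1L][seq_len(n)]
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) < 5L)) stop("CT rows need at least 5 columns")
  idx <- vapply(fields, function(f) as.integer(f[1L]), 1L)
  base <- vapply(fields, `[`, "", 2L)
  part <- vapply(fields, function(f) as.integer(f[5L]), 1L)
  if (!identical(idx, seq_len(n))) stop("CT position column is not 1..n")
  if (any(part < 0L | part > n)) {
    stop("CT partner index out of range at position ", idx[which(part < 0L | part > n)[1L]])
  }
  paired <- which(part > 0L)
  bad <- paired[part[part[paired]] != paired]
  if (length(bad)) stop("CT pairing not symmetric at position ", bad[1L])
  pr <- cbind(paired, part[paired])
  pr <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]
  structure_template(paste(base, collapse = ""), pr)
}

.parse_dotbracket <- function(db) {
  ch <- .seq_chars(db)
  open <- c("(", "[", "{", "<"); close <- c(")", "]", "}", ">")
  ok <- ch %in% c(open, close, ".")
  if (!all(ok)) stop("unexpected character '", ch[which(!ok)[1L]],
                     "' in dot-bracket string")
  pairs <- matrix(integer(0), ncol = 2L)
  for (t in seq_along(open)) {
    stack <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == open[t]) stack <- c(stack, i)
      else if (ch[i] == close[t]) {
        if (!length(stack)) stop("unbalanced brackets: unmatched '",
                                 close[t], "' at position ", i)
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced brackets: unmatched '", open[t],
                            "' at position ", stack[1L])
  }
  pairs
}

#' Write a structure template as dot-bracket
#'
#' Nested pairs use `()`; crossing pairs fall back to `[]`, `{}`, `<>`
#' tiers (rarely needed for the templates used here).
#'
#' @param template A [structure_template()].
#' @param path Output path.
#' @export
write_structure <- function(template, path) {
  L <- nchar(template$seq)
  ch <- rep(".", L)
  tiers <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  placed <- matrix(numeric(0), ncol = 2L)
  tier_of <- integer(nrow(template$pairs))
  ord <- order(template$pairs[, 1L])
  for (k in ord) {
    i <- template$pairs[k, 1L]; j <- template$pairs[k, 2L]
    t <- 1L
    repeat {
      same <- which(tier_of == t)
      crossing <- FALSE
      for (m in same) {
        a <- template$pairs[m, 1L]; b <- template$pairs[m, 2L]
        if ((a < i & i < b & b < j) || (i < a & a < j & j < b)) crossing <- TRUE
      }
      if (!crossing) break
      t <- t + 1L
      if (t > 4L) stop("structure too deeply pseudoknotted for dot-bracket")
    }
    tier_of[k] <- t
    ch[i] <- tiers[[t]][1L]; ch[j] <- tiers[[t]][2L]
  }
  writeLines(c(template$seq, paste(ch, collapse = "")), path)
  invisible(path)
}
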