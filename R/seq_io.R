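## Sequence containers and flat-file I/O (FASTA, label sidecar TSV).
##
## A "record set" is a data.frame with columns id, seq, group, role; an
## aligned_set additionally guarantees equal sequence lengths and carries
## the column count L. Group/role labels live in a sidecar table rather
## than in FASTA headers, because database headers are unstructured.

.ROLES <- c("maternal", "paternal", "hybrid", "clone", "unknown")

#' Construct a sequence record set
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of IUPAC DNA sequences (gaps allowed).
#' @param group Optional group labels (e.g. taxon or clone library).
#' @param role Optional roles, from `maternal`, `paternal`, `hybrid`,
#'   `clone`, `unknown`.
#' @return A `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, seq, group = NA_character_, role = "unknown") {
  stopifnot(length(id) == length(seq), length(id) >= 1L)
  if (anyDuplicated(id)) stop("duplicate record ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for id ",
                              id[which(!nzchar(seq))[1L]])
  seq <- mapply(.normalize_seq, seq, id, USE.NAMES = FALSE)
  role <- rep_len(as.character(role), length(id))
  role[is.na(role)] <- "unknown"
  if (!all(role %in% .ROLES)) {
    stop("role must be one of: ", paste(.ROLES, collapse = ", "))
  }
  out <- data.frame(id = as.character(id), seq = seq,
                    group = rep_len(as.character(group), length(id)),
                    role = role, stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Bundle records into an alignment
#'
#' @param records A `seq_records` object (or data.frame with the same
#'   columns) whose sequences all have equal length.
#' @return An object of class `aligned_set`: the records plus the column
#'   count `L`.
#' @export
aligned_set <- function(records) {
  if (!inherits(records, "seq_records")) {
    records <- seq_records(records$id, records$seq,
                           records$group %||% NA_character_,
                           records$role %||% "unknown")
  }
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records")
  L <- unique(nchar(records$seq))
  if (length(L) != 1L) {
    stop("sequences have unequal lengths: ", paste(L, collapse = ", "))
  }
  structure(list(records = records, L = L), class = "aligned_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", nrow(x$records), "sequences x", x$L, "columns\n")
  gr <- table(x$records$group, useNA = "ifany")
  if (length(gr)) {
    cat("groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "), "\n")
  }
  invisible(x)
}

## alignment as a character matrix (rows = sequences, named by id)
.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$records$seq, "", fixed = TRUE))
  rownames(m) <- aln$records$id
  m
}

#' Read sequences from a FASTA file
#'
#' Characters are upper-cased and `U` is mapped to `T`. Non-IUPAC
#' characters raise an error naming the offending position. Labels, if
#' supplied, are merged by longest id prefix match (so `N01` picks up the
#' labels of the `N` library entry if no exact match exists).
#'
#' @param path FASTA file path.
#' @param labels Optional label table as returned by [read_labels()], or a
#'   data.frame with columns `id`, `group`, `role`.
#' @return A `seq_records` object.
#' @export
read_fasta <- function(path, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA: first non-blank line is not a header")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    stop("FASTA entry without sequence data in ", path)
  }
  rec <- seq_records(ids, unname(gsub("\\s", "", seqs)))
  if (!is.null(labels)) rec <- merge_labels(rec, labels)
  rec
}

#' Write a record set to FASTA
#'
#' @param records `seq_records` object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sidecar label table
#'
#' Tab-separated with header columns `id`, `group`, `role` (extra columns
#' kept as-is).
#'
#' @param path TSV file path.
#' @return data.frame of labels.
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "group")
  if (!all(need %in% names(lab))) {
    stop("label table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(lab$role)) lab$role <- "unknown"
  lab
}

#' Attach group/role labels to records by id prefix match
#'
#' @param records `seq_records` object.
#' @param labels data.frame with `id`, `group` and optionally `role`.
#' @return The records with `group`/`role` filled where a label id equals
#'   the record id or is a prefix of it (longest prefix wins).
#' @export
merge_labels <- function(records, labels) {
  if (is.null(labels$role)) labels$role <- "unknown"
  for (i in seq_len(nrow(records))) {
    hit <- which(labels$id == records$id[i])
    if (!length(hit)) {
      pref <- labels$id[startsWith(records$id[i], labels$id)]
      if (length(pref)) hit <- which(labels$id == pref[which.max(nchar(pref))])
    }
    if (length(hit)) {
      records$group[i] <- labels$group[hit[1L]]
      records$role[i] <- labels$role[hit[1L]]
    }
  }
  records
}

#' Fetch nucleotide records from GenBank (optional, needs network)
#'
#' Downloads the given accessions in FASTA format through NCBI E-utilities
#' and reads them with [read_fasta()]. This is a convenience for
#' reproducing published datasets; everything else in the package works
#' offline.
#'
#' @param accessions Character vector of accession numbers.
#' @param dest Optional file to keep the downloaded FASTA.
#' @param timeout Seconds before the download attempt is abandoned.
#' @return A `seq_records` object.
#' @export
fetch_genbank <- function(accessions, dest = tempfile(fileext = ".fasta"),
                          timeout = 60) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=fasta&retmode=text&id=",
    paste(accessions, collapse = ","))
  old <- options(timeout = timeout)
  on.exit(options(old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("GenBank fetch failed (no network access?): ",
                length(accessions), " accessions requested")
  read_fasta(dest)
}

#' Expand an accession range like "KF671968-KF672035"
#'
#' @param range Single string `PREFIXnnn-PREFIXmmm`.
#' @return Character vector of accessions.
#' @export
accession_range <- function(range) {
  parts <- strsplit(range, "-", fixed = TRUE)[[1L]]
  stopifnot(length(parts) == 2L)
  pref <- sub("[0-9]+$", "", parts[1L])
  lo <- as.integer(sub("^[A-Za-z]+", "", parts[1L]))
  hi <- as.integer(sub("^[A-Za-z]+", "", parts[2L]))
  sprintf("%s%0*d", pref, nchar(sub("^[A-Za-z]+", "", parts[1L])), lo:hi)
}
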