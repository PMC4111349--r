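## TPS landmark file I/O. The dialect understood here: repeated blocks of
##   LM=<k>
##   x y            (k coordinate lines)
##   [IMAGE=...]
##   [ID=...]
##   [SCALE=s]      (applied multiplicatively to the coordinates)

#' Construct a landmark configuration
#'
#' @param id Specimen identifier.
#' @param coords Numeric k x 2 matrix of landmark coordinates.
#' @param group Optional group label.
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(id, coords, group = NA_character_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, all(is.finite(coords)))
  structure(list(id = as.character(id), group = as.character(group),
                 coords = unname(coords)), class = "landmark_config")
}

#' Read 2D landmark configurations from a TPS file
#'
#' @param path TPS file path.
#' @param n_landmarks Expected landmark count per configuration
#'   (default 14, the leaf-outline scheme used throughout the package).
#' @param strict If `TRUE` (default), a configuration whose `LM=` count
#'   differs from `n_landmarks` is an error; if `FALSE`, any count is
#'   accepted.
#' @return List of [landmark_config()] objects.
#' @export
read_tps <- function(path, n_landmarks = 14L, strict = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty TPS file: ", path)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= line found in ", path)
  if (starts[1L] != 1L) stop("TPS file must start with an LM= line")
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1L], ignore.case = TRUE))
    if (is.na(k) || k < 1L) stop("bad LM= count in block ", b)
    coord_lines <- block[-1L][!grepl("=", block[-1L], fixed = TRUE)]
    if (length(coord_lines) != k) {
      stop("block ", b, ": LM=", k, " but ", length(coord_lines),
           " coordinate lines")
    }
    if (strict && k != n_landmarks) {
      stop("block ", b, ": expected ", n_landmarks, " landmarks, got ", k,
           " (use strict = FALSE to accept)")
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (ncol(xy) != 2L || anyNA(xy)) stop("block ", b, ": malformed coordinates")
    kv <- block[grepl("=", block, fixed = TRUE)][-1L]
    getv <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), kv, ignore.case = TRUE, value = TRUE)
      if (length(hit)) sub("^[^=]*=\\s*", "", hit[1L]) else NA_character_
    }
    sc <- suppressWarnings(as.numeric(getv("SCALE")))
    if (!is.na(sc)) xy <- xy * sc
    id <- getv("ID")
    if (is.na(id)) id <- getv("IMAGE")
    if (is.na(id)) id <- paste0("config", b)
    out[[b]] <- landmark_config(id, xy)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' @param configs List of [landmark_config()] objects.
#' @param path Output path.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(paste0("LM=", nrow(cf$coords)), con)
    writeLines(apply(cf$coords, 1L, function(p)
      paste(format(p, digits = 12, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines(paste0("ID=", cf$id), con)
  }
  invisible(path)
}
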