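## Landmark geometric morphometrics: generalized Procrustes analysis,
## bilateral symmetrization, relative warps (PCA of aligned coordinates),
## group mean shapes, Procrustes distances and permutation tests.
##
## Conventions: configurations are k x 2 matrices; aligned shapes have
## centroid at the origin and unit centroid size; rotations never include
## reflection (leaves are oriented objects).

.centroid_size <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  sqrt(sum(xc^2))
}

.center_scale <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  s <- sqrt(sum(xc^2))
  if (s < 1e-12) stop("degenerate configuration: all landmarks coincide")
  list(x = xc / s, size = s)
}

## optimal rotation (no reflection) of x onto y, both centered
.opt_rotation <- function(x, y) {
  sv <- svd(crossprod(x, y))
  s <- diag(c(1, det(sv$u %*% t(sv$v))))
  sv$u %*% s %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition: every configuration is centered, scaled to
#' unit centroid size and rotated (without reflection) onto the running
#' consensus; the consensus is the coordinate-wise mean re-standardized
#' to unit size. Iteration stops when the consensus changes by less than
#' `tol` (root-sum-of-squares).
#'
#' @param configs List of k x 2 matrices, or of [landmark_config()]
#'   objects, or an n x k x 2 array.
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap.
#' @return Object of class `gpa_shapes`: `coords` (n x k x 2 array of
#'   aligned configurations), `consensus` (k x 2), `centroid_sizes`,
#'   `ids`, `groups`, `rss` (residual sum of squares about the
#'   consensus), `iterations`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 200L) {
  prep <- .as_config_list(configs)
  n <- length(prep$coords)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  k <- nrow(prep$coords[[1L]])
  if (any(vapply(prep$coords, nrow, 1L) != k)) {
    stop("configurations must share the landmark count")
  }
  std <- lapply(prep$coords, .center_scale)
  X <- lapply(std, `[[`, "x")
  sizes <- vapply(std, `[[`, 0, "size")
  ## initial consensus: first configuration
  cons <- X[[1L]]
  it <- 0L
  repeat {
    it <- it + 1L
    X <- lapply(X, function(x) x %*% .opt_rotation(x, cons))
    new_cons <- Reduce(`+`, X) / n
    new_cons <- .center_scale(new_cons)$x
    delta <- sqrt(sum((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol || it >= max_iter) break
  }
  coords <- array(NA_real_, c(n, k, 2L))
  for (i in seq_len(n)) coords[i, , ] <- X[[i]]
  rss <- sum(vapply(X, function(x) sum((x - cons)^2), 0))
  structure(list(coords = coords, consensus = cons, centroid_sizes = sizes,
                 ids = prep$ids, groups = prep$groups, rss = rss,
                 iterations = it),
            class = "gpa_shapes")
}

.as_config_list <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    n <- dim(configs)[1L]
    return(list(coords = lapply(seq_len(n), function(i) configs[i, , ]),
                ids = paste0("config", seq_len(n)),
                groups = rep(NA_character_, n)))
  }
  stopifnot(is.list(configs), length(configs) >= 1L)
  if (inherits(configs[[1L]], "landmark_config")) {
    list(coords = lapply(configs, `[[`, "coords"),
         ids = vapply(configs, `[[`, "", "id"),
         groups = vapply(configs, `[[`, "", "group"))
  } else {
    list(coords = lapply(configs, function(x) unname(as.matrix(x))),
         ids = names(configs) %||% paste0("config", seq_along(configs)),
         groups = rep(NA_character_, length(configs)))
  }
}

#' @export
print.gpa_shapes <- function(x, ...) {
  cat("gpa_shapes:", dim(x$coords)[1L], "configurations,",
      dim(x$coords)[2L], "landmarks; residual SS =",
      format(x$rss, digits = 6), "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Bilateral symmetrization of a landmark configuration
#'
#' Averages the configuration with its reflected and relabeled copy
#' (object-symmetry correction): the copy is reflected across the y axis,
#' paired landmark labels are swapped, the copy is optimally aligned
#' (translation + rotation) onto the original, and the two are averaged.
#' The result is exactly invariant under the same reflection-relabel map,
#' and the operation is idempotent.
#'
#' @param config k x 2 matrix or [landmark_config()].
#' @param pairing Two-column integer matrix of (left, right) landmark
#'   index pairs.
#' @param midline Integer indices of unpaired (midline) landmarks.
#' @return Symmetrized configuration (same class as the input coords, a
#'   k x 2 matrix; for a `landmark_config` input, the object with coords
#'   replaced).
#' @export
symmetrize <- function(config, pairing, midline) {
  is_lc <- inherits(config, "landmark_config")
  x <- if (is_lc) config$coords else unname(as.matrix(config))
  k <- nrow(x)
  pairing <- matrix(as.integer(pairing), ncol = 2L)
  covered <- sort(c(pairing, as.integer(midline)))
  if (!identical(covered, seq_len(k))) {
    stop("pairing plus midline must cover every landmark exactly once")
  }
  perm <- seq_len(k)
  perm[pairing[, 1L]] <- pairing[, 2L]
  perm[pairing[, 2L]] <- pairing[, 1L]
  xc <- sweep(x, 2L, colMeans(x))
  refl <- xc %*% diag(c(-1, 1))     # reflect across the y axis
  refl <- refl[perm, , drop = FALSE]  # swap paired labels
  rot <- .opt_rotation(refl, xc)
  sym <- (xc + refl %*% rot) / 2
  if (is_lc) { config$coords <- sym; config } else sym
}

#' Relative warps (principal components of aligned shape coordinates)
#'
#' PCA of the flattened Procrustes-aligned coordinates with no
#' bending-energy weighting (alpha = 0), so relative warps are ordinary
#' principal components of shape.
#'
#' @param aligned A `gpa_shapes` object.
#' @return Object of class `relative_warps`: `scores` (n x k), ordered
#'   non-increasing `variance_fractions`, `loadings`, `ids`, `groups`.
#' @export
relative_warps <- function(aligned) {
  stopifnot(inherits(aligned, "gpa_shapes"))
  n <- dim(aligned$coords)[1L]
  if (n <= 2L) stop("relative warps need more than 2 configurations")
  flat <- matrix(aligned$coords, nrow = n)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > 1e-14 * max(ev)
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 variance_fractions = ev[keep] / sum(ev),
                 loadings = pc$rotation[, keep, drop = FALSE],
                 ids = aligned$ids, groups = aligned$groups),
            class = "relative_warps")
}

#' @export
print.relative_warps <- function(x, ...) {
  vf <- x$variance_fractions
  cat("relative_warps:", ncol(x$scores), "warps;",
      sprintf("RW1 = %.2f%%, RW2 = %.2f%%\n", 100 * vf[1L],
              if (length(vf) > 1L) 100 * vf[2L] else 0))
  invisible(x)
}

#' Mean shape of a group of aligned configurations
#'
#' @param aligned A `gpa_shapes` object.
#' @param group Group label (uses `aligned$groups`), or an integer/logical
#'   index vector selecting configurations.
#' @return k x 2 mean configuration, re-standardized to centroid at the
#'   origin and unit centroid size.
#' @export
group_mean_shape <- function(aligned, group) {
  stopifnot(inherits(aligned, "gpa_shapes"))
  idx <- if (is.character(group)) which(aligned$groups %in% group) else group
  if (is.logical(idx)) idx <- which(idx)
  if (!length(idx)) stop("empty group: ", paste(group, collapse = ","))
  m <- apply(aligned$coords[idx, , , drop = FALSE], c(2L, 3L), mean)
  .center_scale(m)$x
}

#' Procrustes distance between two configurations
#'
#' After centering and scaling both shapes to unit centroid size and
#' rotating (no reflection) B onto A: the full Procrustes distance is
#' `sin(rho)`, the partial Procrustes distance `2 sin(rho/2)`, and
#' `rho` itself the Procrustes (Riemannian) distance, where
#' `cos(rho)` is the sum of singular values of the cross-product matrix
#' (sign-corrected to exclude reflection).
#'
#' @param a,b k x 2 matrices (or `landmark_config`s) with equal k.
#' @param type `"full"` (default), `"partial"` or `"riemannian"`.
#' @return Non-negative distance; symmetric in its arguments.
#' @export
procrustes_distance <- function(a, b, type = c("full", "partial", "riemannian")) {
  type <- match.arg(type)
  if (inherits(a, "landmark_config")) a <- a$coords
  if (inherits(b, "landmark_config")) b <- b$coords
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  if (nrow(a) != nrow(b)) stop("landmark counts differ")
  xa <- .center_scale(a)$x
  xb <- .center_scale(b)$x
  sv <- svd(crossprod(xb, xa))
  cr <- sum(sv$d) - 2 * sv$d[length(sv$d)] * (det(sv$u %*% t(sv$v)) < 0)
  cr <- min(1, max(-1, cr))
  rho <- acos(cr)
  switch(type,
         full = sin(rho),
         partial = 2 * sin(rho / 2),
         riemannian = rho)
}

#' Two-group permutation test on relative-warp scores
#'
#' Test statistic: Euclidean distance between the two groups' mean score
#' vectors on the first `n_warps` relative warps. Group labels are
#' permuted `n_perm` times; the p-value is `(b + 1) / (n_perm + 1)` where
#' `b` counts permutations with a statistic at least as large as
#' observed.
#'
#' @param scores_a,scores_b Numeric matrices of RW scores (rows =
#'   specimens), both with at least 2 rows.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param n_warps Number of leading warps used (default 12, capped at the
#'   available columns).
#' @return List of class `perm_test`: `statistic`, `p_value`, `n_perm`,
#'   `n_warps_used`.
#' @export
permutation_test <- function(scores_a, scores_b, n_perm = 9999L, seed = 1L,
                             n_warps = 12L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  scores_a <- as.matrix(scores_a); scores_b <- as.matrix(scores_b)
  if (nrow(scores_a) < 2L || nrow(scores_b) < 2L) {
    stop("both groups need at least 2 specimens")
  }
  w <- min(n_warps, ncol(scores_a), ncol(scores_b))
  A <- scores_a[, seq_len(w), drop = FALSE]
  B <- scores_b[, seq_len(w), drop = FALSE]
  pooled <- rbind(A, B)
  na <- nrow(A); ntot <- nrow(pooled)
  stat <- function(ia) {
    sqrt(sum((colMeans(pooled[ia, , drop = FALSE]) -
              colMeans(pooled[-ia, , drop = FALSE]))^2))
  }
  obs <- stat(seq_len(na))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  b <- 0L
  for (r in seq_len(n_perm)) {
    if (stat(sample.int(ntot, na)) >= obs - 1e-12) b <- b + 1L
  }
  structure(list(statistic = obs, p_value = (b + 1L) / (n_perm + 1L),
                 n_perm = n_perm, n_warps_used = w), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("two-group permutation test: D = %.5g, p = %.5g (%d permutations, %d warps)\n",
              x$statistic, x$p_value, x$n_perm, x$n_warps_used))
  invisible(x)
}

#' Tangent-space adequacy check
#'
#' Compares pairwise Procrustes (Riemannian) distances with Euclidean
#' distances in the aligned coordinate (tangent) space. For small shape
#' variation the relationship is linear with slope and correlation near
#' 1, validating linear multivariate analysis of the aligned coordinates.
#'
#' @param aligned A `gpa_shapes` object with at least 3 configurations.
#' @return List: `correlation`, `slope` (regression through the origin of
#'   tangent on Procrustes distances), `n_pairs`. Both are `NA` when all
#'   shapes are identical.
#' @export
tangent_check <- function(aligned) {
  stopifnot(inherits(aligned, "gpa_shapes"))
  n <- dim(aligned$coords)[1L]
  if (n < 3L) stop("tangent check needs at least 3 configurations")
  prs <- utils::combn(n, 2L)
  proc <- apply(prs, 2L, function(ij)
    procrustes_distance(aligned$coords[ij[1L], , ],
                        aligned$coords[ij[2L], , ], type = "riemannian"))
  tang <- apply(prs, 2L, function(ij)
    sqrt(sum((aligned$coords[ij[1L], , ] - aligned$coords[ij[2L], , ])^2)))
  if (stats::sd(proc) < 1e-12) {
    return(list(correlation = NA_real_, slope = NA_real_, n_pairs = ncol(prs)))
  }
  list(correlation = stats::cor(proc, tang),
       slope = sum(proc * tang) / sum(proc^2),
       n_pairs = ncol(prs))
}
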