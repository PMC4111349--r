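## Statistical parsimony: the connection limit and the haplotype network.
##
## The connection limit is the largest number of observed differences j
## for which the probability that those differences arose from exactly j
## substitutions (no superimposed changes) still reaches `prob`. The
## probability model: substitutions per site on the path between two
## haplotypes are Poisson with mean mu, base changes follow the
## equal-rates (Jukes-Cantor) chain, and mu is calibrated so that the
## expected fraction of visibly different sites equals the observed j/L.
## Independence across the j differing sites gives
##   P(parsimony | j) = r(mu)^j,  r(mu) = mu e^-mu / ((3/4)(1 - e^(-4mu/3))).

## probability that a differing site reflects exactly one substitution
.single_hit_prob <- function(mu) {
  if (mu <= 0) return(1)
  mu * exp(-mu) / (0.75 * (1 - exp(-4 * mu / 3)))
}

## mu such that expected visible divergence per site equals q (JC inverse)
.mu_from_q <- function(q) {
  if (q <= 0) return(0)
  if (q >= 0.75) stop("divergence at or beyond saturation (q >= 0.75)")
  -0.75 * log(1 - 4 * q / 3)
}

#' Probability that j observed differences are non-homoplastic
#'
#' @param j Number of observed differences (steps).
#' @param L Alignment length in comparable columns.
#' @return Probability in `(0, 1]`.
#' @export
parsimony_probability <- function(j, L) {
  stopifnot(j >= 0, L >= 1)
  if (j == 0) return(1)
  mu <- .mu_from_q(j / L)
  .single_hit_prob(mu)^j
}

#' Statistical-parsimony connection limit
#'
#' Largest step count `j` whose non-homoplasy probability
#' [parsimony_probability()] is at least `prob`. Haplotypes separated by
#' more steps than this are not connected in the network.
#'
#' @param L Alignment length (comparable columns).
#' @param prob Parsimony probability, conventionally 0.95.
#' @return Integer step limit (at least 1 for any realistic `L`).
#' @export
parsimony_limit <- function(L, prob = 0.95) {
  stopifnot(L >= 1, prob > 0, prob < 1)
  j <- 0L
  while (j + 1L < 0.75 * L && parsimony_probability(j + 1L, L) >= prob) {
    j <- j + 1L
  }
  j
}

## absolute differences between two aligned sequences on columns where
## both carry an unambiguous-comparable (non-gap, non-N) state
.abs_diff <- function(a, b) {
  cmp <- a != "-" & b != "-" & a != "N" & b != "N"
  sum(a[cmp] != b[cmp])
}

#' Build a statistical-parsimony (TCS-style) haplotype network
#'
#' Ribotypes are delimited, pairwise absolute differences computed on
#' shared non-gap columns, and components agglomerated by ascending
#' distance: an edge is added between two ribotypes at `d` steps iff they
#' are not already connected through strictly shorter edges and
#' `d <= limit`; ties at the same distance are evaluated simultaneously
#' against the pre-tie components. Multi-step edges materialize `d - 1`
#' unlabeled intermediate nodes. Disconnected components are allowed.
#'
#' @param aln An [aligned_set()] (clones or ribotype representatives).
#' @param limit Step limit; default computed by [parsimony_limit()] from
#'   the alignment length.
#' @param prob Parsimony probability used when `limit` is `NULL`.
#' @param permissive_n Passed to [delimit_ribotypes()].
#' @return Object of class `haplotype_network` with `nodes` (id, kind
#'   observed/inferred, multiplicity, members, group), `edges` (from, to,
#'   steps; between observed ribotypes), `expanded_edges` (unit-step edges
#'   including intermediates), `limit`, `ribotypes`.
#' @export
build_parsimony_network <- function(aln, limit = NULL, prob = 0.95,
                                    permissive_n = FALSE) {
  rib <- delimit_ribotypes(aln, permissive_n = permissive_n)
  rec <- aln$records
  reps <- match(rib$representative, rec$id)
  m <- do.call(rbind, strsplit(rec$seq[reps], "", fixed = TRUE))
  n <- nrow(rib)
  if (is.null(limit)) limit <- parsimony_limit(aln$L, prob)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- .abs_diff(m[i, ], m[j, ])
    }
  }
  comp <- seq_len(n)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  lv <- sort(unique(d[upper.tri(d)]))
  lv <- lv[lv > 0L & lv <= limit]
  for (s in lv) {
    pre <- comp
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (d[i, j] == s && pre[i] != pre[j]) {
        edges <- rbind(edges, data.frame(from = rib$ribotype[i],
                                         to = rib$ribotype[j],
                                         steps = s, stringsAsFactors = FALSE))
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  ## group label of a ribotype: groups of its member sequences
  assign <- attr(rib, "assignment")
  grp <- vapply(rib$ribotype, function(r) {
    g <- unique(rec$group[assign[rec$id] == r])
    paste(g[!is.na(g)], collapse = "+")
  }, "")
  nodes <- data.frame(id = rib$ribotype, kind = "observed",
                      multiplicity = rib$multiplicity,
                      members = rib$members, group = grp,
                      stringsAsFactors = FALSE)
  ## expand multi-step edges through inferred intermediates
  exp_edges <- data.frame(from = character(0), to = character(0),
                          stringsAsFactors = FALSE)
  n_int <- 0L
  for (k in seq_len(nrow(edges))) {
    s <- edges$steps[k]
    chain <- edges$from[k]
    if (s > 1L) {
      ints <- paste0("i", n_int + seq_len(s - 1L))
      n_int <- n_int + s - 1L
      nodes <- rbind(nodes, data.frame(id = ints, kind = "inferred",
                                       multiplicity = 0L, members = "",
                                       group = "", stringsAsFactors = FALSE))
      chain <- c(chain, ints)
    }
    chain <- c(chain, edges$to[k])
    exp_edges <- rbind(exp_edges,
                       data.frame(from = chain[-length(chain)],
                                  to = chain[-1L], stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges, expanded_edges = exp_edges,
                 limit = limit, ribotypes = rib),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  n_obs <- sum(x$nodes$kind == "observed")
  comp <- .hapnet_components(x)
  cat("haplotype_network:", n_obs, "ribotypes,",
      nrow(x$edges), "connections (limit", x$limit, "steps),",
      length(unique(comp)), "component(s)\n")
  invisible(x)
}

## component labels over observed ribotypes
.hapnet_components <- function(net) {
  ids <- net$ribotypes$ribotype
  comp <- stats::setNames(seq_along(ids), ids)
  for (k in seq_len(nrow(net$edges))) {
    a <- comp[net$edges$from[k]]; b <- comp[net$edges$to[k]]
    comp[comp == b] <- a
  }
  comp
}

#' Export a haplotype network as Graphviz DOT
#'
#' @param net A `haplotype_network`.
#' @param path Output path.
#' @export
write_dot <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph haplotypes {", con)
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    if (nd$kind == "observed") {
      writeLines(sprintf('  "%s" [label="%s (%d)"];', nd$id, nd$id,
                         nd$multiplicity), con)
    } else {
      writeLines(sprintf('  "%s" [shape=point];', nd$id), con)
    }
  }
  for (k in seq_len(nrow(net$expanded_edges))) {
    writeLines(sprintf('  "%s" -- "%s";', net$expanded_edges$from[k],
                       net$expanded_edges$to[k]), con)
  }
  writeLines("}", con)
  invisible(path)
}
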