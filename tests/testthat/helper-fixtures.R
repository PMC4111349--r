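# Shared fixtures and independent oracles used across the suite.

# write lines to a temp file, return the path
tmpfile <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# random unambiguous DNA string
rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

# --- oracle: p distance by explicit enumeration of ambiguity resolutions ---
# expands both sequences into all joint resolutions column-wise and averages
# the mismatch indicator; gaps/N excluded pairwise
oracle_p_distance <- function(a, b) {
  expand <- function(ch) {
    sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"))
    sets[[ch]]
  }
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  num <- 0; den <- 0
  for (j in seq_along(ca)) {
    if (ca[j] %in% c("-", "N") || cb[j] %in% c("-", "N")) next
    A <- expand(ca[j]); B <- expand(cb[j])
    den <- den + 1
    mm <- 0
    for (x in A) for (y in B) mm <- mm + (x != y)
    num <- num + mm / (length(A) * length(B))
  }
  if (den == 0) stop("no comparable columns")
  num / den
}

# --- oracle: K2P closed form from given P and Q fractions ---
oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# --- oracle: minimum spanning network over haplotype difference counts ---
# edge (i, j) belongs to the MSN iff i and j are not connected by the graph
# of all pairs at strictly smaller distance; limit caps edge lengths
oracle_msn <- function(d, limit) {
  n <- nrow(d)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- d[i, j]
    if (dij == 0 || dij > limit) next
    # connectivity using all pairs with distance < dij (and <= limit)
    adj <- d > 0 & d < dij & d <= limit
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (u in seq_len(n - 1)) for (v in (u + 1):n) {
        if (adj[u, v] && comp[u] != comp[v]) {
          comp[comp == max(comp[u], comp[v])] <- min(comp[u], comp[v])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (comp[i] != comp[j]) edges <- rbind(edges, c(i, j, dij))
  }
  edges
}

# --- oracle: parsimony probability by series enumeration ---
# substitutions per site Poisson(mu); P(visible change | k hits) follows the
# equal-rates base-change chain; single-hit probability given a visible
# difference, independent across the j differing sites
oracle_parsimony_prob <- function(j, L, kmax = 300) {
  if (j == 0) return(1)
  q <- j / L
  mu <- -0.75 * log(1 - 4 * q / 3)
  k <- seq_len(kmax)
  p_diff_k <- 0.75 * (1 - (-1 / 3)^k)
  p_diff <- sum(dpois(k, mu) * p_diff_k)
  r <- dpois(1, mu) * 1 / p_diff
  r^j
}

# --- random additive tree metric via ape ---
random_tree_metric <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = cophenetic(tr))
}

# splits of a phylo tree as canonical keys over given taxa order
tree_split_keys <- function(tr, taxa) {
  n <- length(taxa)
  keys <- character(0)
  wts <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    kid <- tr$edge[e, 2]
    tips <- if (kid <= length(tr$tip.label)) tr$tip.label[kid] else
      ape::extract.clade(tr, kid)$tip.label
    side <- sort(match(tips, taxa))
    if (length(side) == 0 || length(side) == n) next
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    keys <- c(keys, paste(side, collapse = ","))
    wts <- c(wts, tr$edge.length[e])
  }
  # a root bipartition can appear twice (once per child edge); merge weights
  tapply(wts, keys, sum)
}

# canonical key of a split_set entry
split_keys <- function(ss) {
  n <- length(ss$taxa)
  vapply(ss$splits, function(s) {
    if (1 %in% s) s <- sort(setdiff(seq_len(n), s))
    paste(s, collapse = ",")
  }, "")
}

# small deterministic aligned fixture with groups
demo_alignment <- function() {
  aligned_set(seq_records(
    id = c("mat1", "mat2", "pat1", "pat2", "hyb1", "hyb2"),
    seq = c("ACGTACGTAC",
            "ACGTACGTAC",
            "ACGTTCGGAC",
            "ACGTTCGGAC",
            "ACGTWCGKAC",
            "ACGTWCGKAC"),
    group = c("mat", "mat", "pat", "pat", "hyb", "hyb"),
    role = c("maternal", "maternal", "paternal", "paternal",
             "hybrid", "hybrid")))
}
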