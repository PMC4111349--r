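test_that("p distance matches the enumeration oracle, with and without ambiguities", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("A", "R"), 0.5)  # resolutions {A, G}
  set.seed(11)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "-")
  for (rep in 1:20) {
    a <- paste(sample(alphabet, 40, TRUE, prob = c(rep(5, 4), rep(1, 12))),
               collapse = "")
    b <- paste(sample(alphabet, 40, TRUE, prob = c(rep(5, 4), rep(1, 12))),
               collapse = "")
    expect_equal(p_distance(a, b), oracle_p_distance(a, b), tolerance = 1e-12)
  }
  expect_error(p_distance("---", "AAA"), "comparable")
})

test_that("K2P matches the closed form to 1e-10 and errors at saturation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # P = 0.25, Q = 0
  expect_equal(k2p_distance("ACGT", "GCGT"), oracle_k2p(0.25, 0),
               tolerance = 1e-10)
  expect_equal(k2p_distance("ACGT", "GCGT"), 0.34657359, tolerance = 1e-5)
  # Q = 0.5 -> 1 - 2Q = 0: saturated
  expect_error(k2p_distance("AAGG", "CCGG"), "saturated")
  # random unambiguous pairs against counted P and Q
  set.seed(13)
  for (rep in 1:10) {
    a <- rand_dna(200)
    b <- strsplit(a, "")[[1]]
    sub <- sample(200, 12)
    for (j in sub) b[j] <- setdiff(c("A", "C", "G", "T"), b[j])[sample(3, 1)]
    b <- paste(b, collapse = "")
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    purine <- c("A", "G")
    ti <- sum(ca != cb & (ca %in% purine) == (cb %in% purine))
    tv <- sum(ca != cb) - ti
    expect_equal(k2p_distance(a, b), oracle_k2p(ti / 200, tv / 200),
                 tolerance = 1e-10)
  }
})

test_that("K2P and p agree to first order as divergence shrinks", {
  set.seed(17)
  for (rep in 1:10) {
    a <- rand_dna(500)
    b <- strsplit(a, "")[[1]]
    for (j in sample(500, 4)) b[j] <- setdiff(c("A", "C", "G", "T"), b[j])[1]
    b <- paste(b, collapse = "")
    p <- p_distance(a, b)
    k <- k2p_distance(a, b)
    expect_lt(abs(k - p), 3 * p^2)
  }
})

test_that("ambiguity-free distances agree with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(23)
  base <- strsplit(rand_dna(300), "")[[1]]
  seqs <- vapply(1:5, function(i) {
    x <- base
    for (j in sample(300, 20)) {
      x[j] <- setdiff(c("A", "C", "G", "T"), x[j])[sample(3, 1)]
    }
    paste(x, collapse = "")
  }, "")
  aln <- aligned_set(seq_records(paste0("s", 1:5), seqs))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  rownames(bin) <- paste0("s", 1:5)
  d_raw <- as.matrix(ape::dist.dna(bin, model = "raw"))
  d_k80 <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unname(distance_matrix(aln, "p")), unname(d_raw),
               tolerance = 1e-12)
  expect_equal(unname(distance_matrix(aln, "k2p")), unname(d_k80),
               tolerance = 1e-12)
})

test_that("group identity averages pairs and rounds half-up to 3 decimals", {
  aln <- demo_alignment()
  expect_equal(group_identity(aln, "mat", "within"), 1.000)
  # identical groups at p = 0.2 apart -> between identity 0.8
  aln2 <- aligned_set(seq_records(
    c("a1", "a2", "b1"), c("AAAAA", "AAAAA", "AAACC"),
    group = c("A", "A", "B")))
  expect_equal(group_identity(aln2, c("A", "B"), "between"), 0.6, tolerance = 1e-9)
  expect_error(group_identity(aln2, "B", "within"), "at least 2")
  # within = 1.000 iff the library is a single ribotype
  rib <- delimit_ribotypes(aligned_set(seq_records(
    c("x", "y"), c("AAAAA", "AAAAA"), group = "g")))
  expect_equal(nrow(rib), 1L)
})

test_that("ribotype delimitation: identity over shared non-gap columns, N distinct", {
  rec <- seq_records(c("s1", "s2", "s3", "s4", "s5"),
                     c("ACGT", "ACGT", "ACTT", "AC-T", "ACNT"))
  rib <- delimit_ribotypes(aligned_set(rec))
  asg <- attr(rib, "assignment")
  expect_equal(unname(asg["s1"]), unname(asg["s2"]))  # identical
  expect_false(asg["s3"] == asg["s1"])                # real difference
  expect_equal(unname(asg["s4"]), unname(asg["s1"]))  # gap column ignored
  expect_false(asg["s5"] == asg["s1"])                # N matches nothing
  # permissive N mode lets N match any base
  rib2 <- delimit_ribotypes(aligned_set(rec), permissive_n = TRUE)
  asg2 <- attr(rib2, "assignment")
  expect_equal(unname(asg2["s5"]), unname(asg2["s1"]))
  # all-distinct input yields n ribotypes
  set.seed(3)
  rec3 <- seq_records(paste0("d", 1:6), replicate(6, rand_dna(30)))
  expect_equal(nrow(delimit_ribotypes(aligned_set(rec3))), 6L)
})

test_that("parsimony probability matches the series-enumeration oracle", {
  for (L in c(100L, 501L, 1000L)) {
    for (j in 1:20) {
      expect_equal(parsimony_probability(j, L),
                   oracle_parsimony_prob(j, L), tolerance = 1e-10)
    }
  }
})

test_that("parsimony limit: >= 1 for realistic lengths, monotone in prob and L", {
  for (L in c(50L, 100L, 501L, 1000L)) {
    expect_gte(parsimony_limit(L, 0.95), 1L)
  }
  # limit equals the largest j with oracle probability >= 0.95
  for (L in c(100L, 501L, 1000L)) {
    lim <- parsimony_limit(L, 0.95)
    expect_gte(oracle_parsimony_prob(lim, L), 0.95)
    expect_lt(oracle_parsimony_prob(lim + 1L, L), 0.95)
  }
  # non-increasing as prob grows
  lims <- vapply(c(0.9, 0.95, 0.99), function(p) parsimony_limit(501L, p), 1L)
  expect_true(all(diff(lims) <= 0))
  # longer alignments tolerate more steps
  expect_gte(parsimony_limit(1000L, 0.95), parsimony_limit(100L, 0.95))
})

test_that("parsimony network equals the brute-force MSN on small cases", {
  # A-B one step -> single edge
  aln <- aligned_set(seq_records(c("A", "B"), c("AAAA", "AAAT")))
  net <- build_parsimony_network(aln, limit = 5L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 1L)
  expect_equal(nrow(net$expanded_edges), 1L)

  # A-B two steps -> one inferred intermediate
  aln2 <- aligned_set(seq_records(c("A", "B"), c("AAAA", "AATT")))
  net2 <- build_parsimony_network(aln2, limit = 5L)
  expect_equal(net2$edges$steps, 2L)
  expect_equal(sum(net2$nodes$kind == "inferred"), 1L)
  expect_equal(nrow(net2$expanded_edges), 2L)

  # beyond the limit -> disconnected
  net3 <- build_parsimony_network(aln2, limit = 1L)
  expect_equal(nrow(net3$edges), 0L)

  # randomized haplotype sets vs exhaustive MSN oracle
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    L <- 30L
    base <- strsplit(rand_dna(L), "")[[1]]
    seqs <- vapply(seq_len(n), function(i) {
      x <- base
      for (j in sample(L, sample(0:4, 1))) {
        x[j] <- setdiff(c("A", "C", "G", "T"), x[j])[sample(3, 1)]
      }
      paste(x, collapse = "")
    }, "")
    if (anyDuplicated(seqs)) next
    aln_r <- aligned_set(seq_records(paste0("h", 1:n), seqs))
    limit <- 4L
    net_r <- build_parsimony_network(aln_r, limit = limit)
    ch <- do.call(rbind, strsplit(seqs, ""))
    d <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(ch[i, ] != ch[j, ])
    }
    oracle <- oracle_msn(d, limit)
    got <- net_r$edges
    rib_of <- attr(net_r$ribotypes, "assignment")
    got_pairs <- sort(apply(got, 1, function(e)
      paste(sort(c(match(e["from"], net_r$ribotypes$ribotype),
                   match(e["to"], net_r$ribotypes$ribotype))), collapse = "-")))
    ora_pairs <- if (is.null(oracle)) character(0) else
      sort(apply(oracle, 1, function(e) paste(sort(e[1:2]), collapse = "-")))
    expect_equal(got_pairs, ora_pairs)
    expect_true(all(net_r$edges$steps <= limit))
  }
})

test_that("NeighborNet recovers splits and branch lengths of additive trees", {
  skip_if_not_installed("ape")
  for (case in 1:6) {
    n <- sample(4:8, 1)
    tm <- random_tree_metric(n, seed = 100 + case)
    nn <- neighbor_net(tm$d)
    expected <- tree_split_keys(tm$tree, rownames(tm$d))
    got <- split_keys(nn)
    expect_setequal(got, names(expected))
    w <- nn$weights[match(names(expected), got)]
    expect_equal(unname(w), unname(as.numeric(expected)), tolerance = 1e-6)
  }
})

test_that("NeighborNet handles the documented edge cases", {
  # additive 4-taxon tree: internal split {c,d} with its branch length
  d4 <- matrix(c(0, 2, 5, 5,
                 2, 0, 5, 5,
                 5, 5, 0, 2,
                 5, 5, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nn <- neighbor_net(d4)
  keys <- split_keys(nn)
  expect_true("3,4" %in% keys)
  expect_equal(nn$weights[keys == "3,4"], 3, tolerance = 1e-6)
  # ultrametric ((a,b),(c,d)): split {a,b}|{c,d} has positive weight
  du <- matrix(c(0, 1, 4, 4,
                 1, 0, 4, 4,
                 4, 4, 0, 1,
                 4, 4, 1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nnu <- neighbor_net(du)
  expect_gt(nnu$weights[split_keys(nnu) == "3,4"], 0)
  # all-equal distances -> only pendant splits, all equal weight
  de <- matrix(1, 5, 5) - diag(5)
  dimnames(de) <- list(letters[1:5], letters[1:5])
  nne <- neighbor_net(de)
  expect_true(all(lengths(nne$splits) %in% c(1L, 4L)))
  expect_equal(var(nne$weights), 0, tolerance = 1e-12)
  # n = 3: trivial splits from the three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nn3 <- neighbor_net(d3)
  expect_equal(sort(nn3$weights), c(1, 1, 2))
  expect_error(neighbor_net(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded, and certain for duplicated signal", {
  # alignment whose only variation is one diagnostic column, duplicated:
  # every bootstrap replicate contains it with probability ~1
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
            c = "TTTTTAAAAA", d = "TTTTTAAAAA")
  aln <- aligned_set(seq_records(names(seqs), unname(seqs),
                                 group = names(seqs)))
  bs <- bootstrap_support(aln, n_reps = 30L, seed = 4L)
  key <- split_keys(bs)
  diag_split <- bs$support[key == "3,4"]
  expect_equal(diag_split, 1.0)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  bs2 <- bootstrap_support(aln, n_reps = 30L, seed = 4L)
  expect_identical(bs$support, bs2$support)
  # random data: supports stay in [0, 1]
  set.seed(41)
  aln_r <- aligned_set(seq_records(paste0("t", 1:5), replicate(5, rand_dna(60))))
  bs3 <- bootstrap_support(aln_r, n_reps = 20L, seed = 9L)
  expect_true(all(bs3$support >= 0 & bs3$support <= 1))
})
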