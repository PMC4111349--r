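## Synthetic data with the statistical structure the analysis assumes:
## parental ribotype pools with intragenomic variants, dosage-weighted
## hybrid copy mixtures, clone libraries with PCR/cloning artifacts and
## planted pseudogenized copies, direct-sequencing consensus records, a
## matching secondary-structure template, and leaf landmark datasets.
## Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a two-parent hybridization
#' design in a buttercup-like ITS system: ITS1/5.8S/ITS2 lengths
#' 241/164/212, between-parent divergence 2%, triploid dosage 2 maternal
#' : 1 paternal, 20 clones per library, low-frequency intragenomic
#' variants, and a small per-site cloning/PCR error rate with a C->T /
#' G->A (deamination-type) bias.
#'
#' @param seed Integer master seed; all generator randomness derives
#'   from it.
#' @param L_its1,L_58S,L_its2 Region lengths (columns).
#' @param divergence Expected per-site p-distance between the two
#'   parental consensus sequences.
#' @param n_parental_variants Distinct ITS copy variants per parental
#'   genome (one dominant + minor variants).
#' @param intragenomic_poly_rate Per-site substitution rate of a minor
#'   intragenomic variant relative to its genome's consensus.
#' @param minor_variant_freq Copy-pool frequency of each minor variant.
#' @param pool_size Number of ITS copies represented per genome pool.
#' @param dosage Integer pair: (maternal, paternal) genome copies
#'   contributed to the hybrid, e.g. `c(2, 1)` for a triploid from a
#'   tetraploid mother and diploid father.
#' @param n_clones Clones sequenced per library.
#' @param clone_error_rate Per-site PCR/cloning error probability per
#'   clone.
#' @param methylation_bias Fraction of errors at C/G that are
#'   deamination-type (C->T, G->A).
#' @param pseudogene_rate Fraction of clones carrying a pseudogenized
#'   copy (5.8S substitutions + lowered GC).
#' @param n_58S_subs Possible numbers of planted 5.8S substitutions per
#'   pseudogenized clone (sampled uniformly).
#' @param gc_shift Target GC-content drop in ITS1+ITS2 of a pseudogenized
#'   copy (fraction of spacer sites converted G/C -> A/T).
#' @param kappa Transition/transversion rate bias of all substitutions.
#' @param minor_threshold Consensus-calling threshold for
#'   [call_consensus()].
#' @param n_chimeras Chimeric clones spliced into a library (only
#'   libraries whose pool mixes parental origins).
#' @param landmark_n Integer vector of group sizes for the landmark
#'   generator (defaults 28, 26, 41 for paternal species, synthetic
#'   hybrid and natural apomict).
#' @param landmark_sigma Isotropic landmark noise SD on unit-centroid-
#'   size shapes.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       L_its1 = 241L, L_58S = 164L, L_its2 = 212L,
                       divergence = 0.02,
                       n_parental_variants = 5L,
                       intragenomic_poly_rate = 0.0015,
                       minor_variant_freq = 0.05,
                       pool_size = 30L,
                       dosage = c(2L, 1L),
                       n_clones = 20L,
                       clone_error_rate = 1e-4,
                       methylation_bias = 0.5,
                       pseudogene_rate = 0.16,
                       n_58S_subs = 1:2,
                       gc_shift = 0.015,
                       kappa = 2,
                       minor_threshold = 0.25,
                       n_chimeras = 0L,
                       landmark_n = c(notabilis = 28L, hybrid = 26L,
                                      variabilis = 41L),
                       landmark_sigma = 0.02) {
  stopifnot(L_its1 > 0, L_58S > 0, L_its2 > 0,
            divergence >= 0, divergence <= 1,
            intragenomic_poly_rate >= 0, intragenomic_poly_rate <= 1,
            clone_error_rate >= 0, clone_error_rate <= 1,
            pseudogene_rate >= 0, pseudogene_rate <= 1,
            length(dosage) == 2L, all(dosage >= 0), sum(dosage) > 0,
            minor_threshold > 0, minor_threshold < 0.5,
            landmark_sigma >= 0)
  cfg <- as.list(environment())
  cfg$L <- L_its1 + L_58S + L_its2
  class(cfg) <- "sim_config"
  cfg
}

#' The buttercup study preset: two parents, divergence 0.02, dosage 2:1,
#' 20 clones per library, pseudogene rate 0.2
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
ranunculus_preset <- function(seed = 1L, ...) {
  sim_config(seed = seed, pseudogene_rate = 0.2, ...)
}

## run expr under a derived seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## substitute a base under transition bias kappa
.mutate_base <- function(base, kappa) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(c("A", "C", "G", "T"), base)
  tv <- setdiff(others, ti[[base]])
  p <- c(kappa, 1, 1) / (kappa + 2)
  sample(c(ti[[base]], tv), 1L, prob = p)
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

## motif realizations planted in every synthetic template
.SIM_MOTIFS <- list(ITS1_angiosperm = "GGCGCGATCGGCGTCAAGGAA",
                    M1 = "CGATGAAGAACGTAGC",
                    M2 = "GAATTGCAGAATCC",
                    M3 = "TTTGAACGCA")

#' Generate the ancestral ITS template (sequence + secondary structure)
#'
#' Builds a random ancestor with conserved motifs planted (the ITS1
#' angiosperm motif inside ITS1; M1/M2/M3 at the start, middle and end of
#' the 5.8S) and a hairpin layout whose paired positions are
#' Watson-Crick complementary in the ancestor: 6 ITS1 hairpins, 3 5.8S
#' helices and 4 ITS2 hairpins, giving roughly the paired fractions seen
#' in ITS transcripts (about 58% of ITS1, 72% of ITS2).
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List: `ancestor` (string), `template`
#'   ([structure_template()] with region spans), `regions`
#'   (`region_annotation`), `protected` (motif columns, never mutated by
#'   the generators).
#' @export
gen_its_template <- function(cfg, seed = cfg$seed * 1000L) {
  .with_seed(seed, {
    L1 <- cfg$L_its1; L58 <- cfg$L_58S; L2 <- cfg$L_its2
    L <- L1 + L58 + L2
    base_freq <- c(A = 0.21, C = 0.29, G = 0.29, T = 0.21)
    ch <- sample(names(base_freq), L, replace = TRUE, prob = base_freq)
    plant <- function(ch, motif, at) {
      m <- .seq_chars(motif)
      ch[at:(at + length(m) - 1L)] <- m
      ch
    }
    ## motif anchor positions (template coordinates)
    pos <- list(
      ITS1_angiosperm = max(1L, L1 - 60L),
      M1 = L1 + 1L,
      M2 = L1 + max(17L, L58 %/% 2L - 7L),
      M3 = L1 + L58 - 9L)
    for (mn in names(.SIM_MOTIFS)) ch <- plant(ch, .SIM_MOTIFS[[mn]], pos[[mn]])
    protected <- sort(unlist(lapply(names(.SIM_MOTIFS), function(mn)
      seq(pos[[mn]], pos[[mn]] + nchar(.SIM_MOTIFS[[mn]]) - 1L))))
    ## hairpin blocks (start, stem, loop) per region, avoiding motifs
    hp <- function(start, stem, loop = 4L) {
      i <- start + seq_len(stem) - 1L
      j <- start + 2L * stem + loop - seq_len(stem)
      cbind(i, j)
    }
    blocks <- list()
    add <- function(start, stem) blocks[[length(blocks) + 1L]] <<- hp(start, stem)
    ## ITS1: 5 hairpins before the motif, 1 after (stems of 12 = 28 nt)
    for (b in 0:4) add(3L + b * 32L, 12L)
    add(min(L1 - 28L, pos$ITS1_angiosperm + 23L), 12L)
    ## 5.8S: 3 short helices between the motifs (stems of 8 = 20 nt)
    add(L1 + 20L, 8L); add(L1 + 44L, 8L); add(L1 + 118L, 8L)
    ## ITS2: 4 hairpins (stems of 19 = 42 nt)
    for (b in 0:3) add(L1 + L58 + 4L + b * 46L, 19L)
    pairs <- do.call(rbind, blocks)
    stopifnot(max(pairs) <= L)
    ## make every pair complementary, preferring to edit non-protected side
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (j %in% protected) ch[i] <- .COMPLEMENT[[ch[j]]]
      else ch[j] <- .COMPLEMENT[[ch[i]]]
    }
    seq <- paste(ch, collapse = "")
    spans <- list(ITS1 = c(1L, L1), `r5.8S` = c(L1 + 1L, L1 + L58),
                  ITS2 = c(L1 + L58 + 1L, L))
    tpl <- structure_template(seq, pairs, region_spans = spans)
    list(ancestor = seq, template = tpl,
         regions = structure(spans, class = "region_annotation"),
         protected = protected)
  })
}

## mutate a sequence at n random non-protected sites; returns list(seq,
## columns actually changed)
.mutate_seq <- function(seq, n, protected, kappa) {
  ch <- .seq_chars(seq)
  eligible <- setdiff(seq_along(ch), protected)
  n <- min(n, length(eligible))
  if (n == 0L) return(list(seq = seq, columns = integer(0)))
  at <- sample(eligible, n)
  for (j in at) ch[j] <- .mutate_base(ch[j], kappa)
  list(seq = paste(ch, collapse = ""), columns = sort(at))
}

#' Generate the two parental copy pools
#'
#' A common ancestor is mutated into a maternal and a paternal consensus
#' (each lineage at rate `divergence / 2`, so the expected between-parent
#' p-distance is `divergence`); each genome then carries
#' `n_parental_variants - 1` minor intragenomic variants at frequency
#' `minor_variant_freq` in a pool of `pool_size` copies.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List of class `sim_parents`: `maternal`, `paternal`
#'   (`seq_records` pools, groups "maternal" / "paternal"),
#'   `consensus_maternal`, `consensus_paternal` (strings), `template`,
#'   `regions`, `protected`, and `truth` (divergent columns, per-parent
#'   intragenomic variant columns).
#' @export
gen_parents <- function(cfg, seed = cfg$seed * 1000L + 1L) {
  tpl <- gen_its_template(cfg)
  .with_seed(seed, {
    L <- cfg$L
    ## functional copies evolve only in the spacers: the 5.8S is under
    ## purifying selection and stays conserved, as observed in direct
    ## sequences of functional ITS arrays
    frozen <- union(tpl$protected,
                    seq(tpl$regions[["r5.8S"]][1L], tpl$regions[["r5.8S"]][2L]))
    mk_cons <- function() {
      n <- stats::rbinom(1L, L, cfg$divergence / 2)
      .mutate_seq(tpl$ancestor, n, frozen, cfg$kappa)
    }
    mat <- mk_cons(); pat <- mk_cons()
    mk_pool <- function(cons, prefix, group, role) {
      n_minor <- cfg$n_parental_variants - 1L
      per <- max(1L, round(cfg$minor_variant_freq * cfg$pool_size))
      n_dom <- cfg$pool_size - n_minor * per
      stopifnot(n_dom >= 1L)
      var_cols <- list()
      seqs <- rep(cons$seq, n_dom)
      for (v in seq_len(n_minor)) {
        nm <- max(1L, stats::rpois(1L, cfg$intragenomic_poly_rate * L))
        mv <- .mutate_seq(cons$seq, nm, frozen, cfg$kappa)
        var_cols[[v]] <- mv$columns
        seqs <- c(seqs, rep(mv$seq, per))
      }
      rec <- seq_records(sprintf("%s%02d", prefix, seq_along(seqs)), seqs,
                         group = group, role = role)
      list(rec = rec, var_cols = var_cols)
    }
    m <- mk_pool(mat, "M", "maternal", "maternal")
    p <- mk_pool(pat, "P", "paternal", "paternal")
    div_cols <- which(.seq_chars(mat$seq) != .seq_chars(pat$seq))
    structure(list(
      maternal = m$rec, paternal = p$rec,
      consensus_maternal = mat$seq, consensus_paternal = pat$seq,
      template = tpl$template, regions = tpl$regions,
      protected = tpl$protected,
      truth = list(divergent_columns = div_cols,
                   maternal_variant_columns = m$var_cols,
                   paternal_variant_columns = p$var_cols)),
      class = "sim_parents")
  })
}

#' Generate a dosage-weighted hybrid copy pool
#'
#' The hybrid pool mixes maternal and paternal copies at the dosage
#' ratio (e.g. 2:1 for a triploid), sampling whole copies from each
#' parental pool so every parent-differentiating column is additive in
#' the pool by construction.
#'
#' @param parents A `sim_parents` object.
#' @param cfg The [sim_config()].
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List of class `sim_hybrid`: `pool` (`seq_records`, group
#'   "hybrid"), `origin` (per-copy "maternal"/"paternal"), `truth`
#'   (differentiating columns, dosage).
#' @export
gen_hybrid <- function(parents, cfg, seed = cfg$seed * 1000L + 2L) {
  if (sum(cfg$dosage) == 0) stop("dosage (0,0) is not a genome")
  .with_seed(seed, {
    n_m <- round(cfg$pool_size * cfg$dosage[1L] / sum(cfg$dosage))
    n_p <- cfg$pool_size - n_m
    pick <- function(pool, n) pool$seq[sample.int(nrow(pool), n, replace = TRUE)]
    seqs <- c(pick(parents$maternal, n_m),
              if (n_p > 0L) pick(parents$paternal, n_p))
    origin <- c(rep("maternal", n_m), rep("paternal", n_p))
    rec <- seq_records(sprintf("H%02d", seq_along(seqs)), seqs,
                       group = "hybrid", role = "hybrid")
    structure(list(pool = rec, origin = origin,
                   truth = list(
                     differentiating_columns = parents$truth$divergent_columns,
                     dosage = cfg$dosage, n_maternal = n_m, n_paternal = n_p)),
              class = "sim_hybrid")
  })
}

#' Generate a clone library from a copy pool
#'
#' `n_clones` copies are drawn from the pool with replacement; each clone
#' acquires per-site PCR/cloning errors at `clone_error_rate` (with a
#' deamination C->T / G->A bias at C/G sites); a `pseudogene_rate`
#' fraction of clones is pseudogenized (1-2 substitutions planted in the
#' 5.8S plus a GC-lowering shift in the spacers); optionally chimeric
#' clones are spliced between copies of different parental origin at a
#' random breakpoint.
#'
#' @param pool `seq_records` copy pool (e.g. `parents$maternal` or
#'   `hybrid$pool`).
#' @param cfg The [sim_config()].
#' @param regions `region_annotation` for the pool columns.
#' @param origin Optional per-copy origin labels (required for
#'   `n_chimeras > 0`).
#' @param library Library name used for ids/groups (default "lib").
#' @param protected Columns never touched by pseudogenization (motifs).
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List of class `sim_library`: `clones` (`seq_records`), and
#'   `truth` (`source_index`, `pseudogene_ids`, `chimera` data.frame with
#'   id/breakpoint_column, `error_columns`).
#' @export
gen_clone_library <- function(pool, cfg, regions, origin = NULL,
                              library = "lib", protected = integer(0),
                              seed = cfg$seed * 1000L + 3L) {
  .with_seed(seed, {
    L <- nchar(pool$seq[1L])
    n <- cfg$n_clones
    src <- sample.int(nrow(pool), n, replace = TRUE)
    ch <- strsplit(pool$seq[src], "", fixed = TRUE)
    err_cols <- vector("list", n)
    for (i in seq_len(n)) {
      ne <- stats::rbinom(1L, L, cfg$clone_error_rate)
      if (ne > 0L) {
        at <- sample.int(L, ne)
        for (j in at) {
          b <- ch[[i]][j]
          ch[[i]][j] <- if (b %in% c("C", "G") &&
                            stats::runif(1) < cfg$methylation_bias) {
            if (b == "C") "T" else "A"
          } else .mutate_base(b, cfg$kappa)
        }
        err_cols[[i]] <- sort(at)
      } else err_cols[[i]] <- integer(0)
    }
    ## pseudogenize a fixed fraction of clones
    n_pseudo <- round(cfg$pseudogene_rate * n)
    pseudo_idx <- if (n_pseudo > 0L) sort(sample.int(n, n_pseudo)) else integer(0)
    s58 <- regions[["r5.8S"]]
    sp_cols <- c(seq(regions$ITS1[1L], regions$ITS1[2L]),
                 seq(regions$ITS2[1L], regions$ITS2[2L]))
    sp_cols <- setdiff(sp_cols, protected)
    for (i in pseudo_idx) {
      k58 <- sample(cfg$n_58S_subs, 1L)
      at58 <- sample(setdiff(seq(s58[1L], s58[2L]), protected), k58)
      for (j in at58) ch[[i]][j] <- .mutate_base(ch[[i]][j], cfg$kappa)
      gc_here <- sp_cols[ch[[i]][sp_cols] %in% c("G", "C")]
      k_gc <- min(length(gc_here), round(cfg$gc_shift * length(sp_cols)))
      if (k_gc > 0L) {
        for (j in sample(gc_here, k_gc)) {
          ch[[i]][j] <- sample(c("A", "T"), 1L)
        }
      }
    }
    ## splice chimeras between copies of different parental origin
    chim <- data.frame(id = character(0), breakpoint_column = integer(0),
                       stringsAsFactors = FALSE)
    if (cfg$n_chimeras > 0L) {
      if (is.null(origin) || length(unique(origin)) < 2L) {
        stop("chimeras need a pool with mixed parental origin")
      }
      avail <- setdiff(seq_len(n), pseudo_idx)
      ci <- sample(avail, min(cfg$n_chimeras, length(avail)))
      for (i in ci) {
        a <- sample(which(origin == "maternal"), 1L)
        b <- sample(which(origin == "paternal"), 1L)
        bp <- sample(seq(round(L * 0.25), round(L * 0.75)), 1L)
        ch[[i]] <- c(strsplit(pool$seq[a], "")[[1L]][1:bp],
                     strsplit(pool$seq[b], "")[[1L]][(bp + 1L):L])
        chim <- rbind(chim, data.frame(
          id = sprintf("%s%02d", library, i), breakpoint_column = bp,
          stringsAsFactors = FALSE))
      }
    }
    ids <- sprintf("%s%02d", library, seq_len(n))
    clones <- seq_records(ids, vapply(ch, paste, "", collapse = ""),
                          group = library, role = "clone")
    structure(list(clones = clones,
                   truth = list(source_index = src,
                                pseudogene_ids = ids[pseudo_idx],
                                chimera = chim,
                                error_columns = stats::setNames(err_cols, ids))),
              class = "sim_library")
  })
}

#' Direct-sequencing consensus record of a copy pool
#'
#' Applies [call_consensus()] at the configured minor-variant threshold,
#' emulating what direct Sanger sequencing of the multi-copy template
#' reports (minor variants below the threshold vanish).
#'
#' @param pool `seq_records` copy pool.
#' @param cfg The [sim_config()].
#' @param id Record id.
#' @return Single-row `seq_records` with IUPAC ambiguities.
#' @export
gen_direct_record <- function(pool, cfg, id = "direct") {
  call_consensus(pool, cfg$minor_threshold, id = id)
}

#' Landmark pairing scheme of the 14-landmark leaf
#'
#' @return List with `pairing` (6 x 2 matrix of left/right landmark
#'   indices) and `midline` (apex and base indices).
#' @export
leaf_pairing <- function() {
  list(pairing = cbind(c(2L, 4L, 6L, 8L, 10L, 12L),
                       c(3L, 5L, 7L, 9L, 11L, 13L)),
       midline = c(1L, 14L))
}

## bilaterally symmetric 14-landmark group mean shapes (unit centroid
## size): apex, 6 left/right pairs (lobe tips and sinuses), leaf base.
.leaf_mean_shapes <- function() {
  mk <- function(apex, p2, p4, p6, p8, p10, p12, base) {
    pts <- rbind(apex,
                 c(-p2[1], p2[2]), p2,
                 c(-p4[1], p4[2]), p4,
                 c(-p6[1], p6[2]), p6,
                 c(-p8[1], p8[2]), p8,
                 c(-p10[1], p10[2]), p10,
                 c(-p12[1], p12[2]), p12,
                 base)
    .center_scale(unname(pts))$x
  }
  list(
    notabilis = mk(c(0, 1.00), c(0.55, 0.72), c(0.33, 0.45), c(0.85, 0.22),
                   c(0.44, -0.02), c(0.72, -0.38), c(0.20, -0.62),
                   c(0, -0.85)),
    hybrid = mk(c(0, 1.048), c(0.617, 0.777), c(0.207, 0.403), c(0.945, 0.182),
                c(0.279, -0.077), c(0.796, -0.437), c(0.105, -0.696),
                c(0, -0.879)),
    variabilis = mk(c(0, 0.908), c(0.486, 0.646), c(0.440, 0.514),
                    c(0.749, 0.257), c(0.569, 0.035), c(0.628, -0.306),
                    c(0.310, -0.528), c(0, -0.786)))
}

#' Generate a landmark dataset of leaf shapes
#'
#' Per group, configurations are the group mean shape plus isotropic
#' Gaussian landmark noise, pushed through a random similarity transform
#' (rotation, scale, translation) so that the raw data carry nuisance
#' position/size/orientation exactly as digitized specimens do. Group
#' mean shapes are bilaterally symmetric under [leaf_pairing()].
#'
#' @param cfg A [sim_config()] (`landmark_n`, `landmark_sigma`).
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List of class `sim_landmarks`: `configs` (list of
#'   [landmark_config()]), `truth` (`means` in unit size, `pairing`,
#'   `midline`, `sigma`, true pairwise full Procrustes distances).
#' @export
gen_landmarks <- function(cfg, seed = cfg$seed * 1000L + 5L) {
  if (cfg$landmark_sigma <= 0) stop("landmark noise sigma must be positive")
  if (length(cfg$landmark_n) < 2L) stop("need at least 2 landmark groups")
  shapes <- .leaf_mean_shapes()
  gn <- names(cfg$landmark_n) %||% names(shapes)[seq_along(cfg$landmark_n)]
  if (is.null(names(cfg$landmark_n))) names(cfg$landmark_n) <- gn
  if (!all(gn %in% names(shapes))) {
    stop("unknown landmark group(s): ",
         paste(setdiff(gn, names(shapes)), collapse = ", "))
  }
  .with_seed(seed, {
    configs <- list()
    for (g in gn) {
      mu <- shapes[[g]]
      for (i in seq_len(cfg$landmark_n[[g]])) {
        x <- mu + matrix(stats::rnorm(28L, 0, cfg$landmark_sigma), 14L, 2L)
        th <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        s <- exp(stats::runif(1, log(0.5), log(2)))
        tr <- stats::runif(2, -5, 5)
        x <- sweep(s * (x %*% R), 2L, tr, `+`)
        configs[[length(configs) + 1L]] <-
          landmark_config(sprintf("%s_%02d", g, i), x, group = g)
      }
    }
    pr <- leaf_pairing()
    used <- shapes[gn]
    cmb <- utils::combn(length(gn), 2L)
    truth_d <- apply(cmb, 2L, function(ij)
      procrustes_distance(used[[ij[1L]]], used[[ij[2L]]]))
    names(truth_d) <- apply(cmb, 2L, function(ij)
      paste(gn[ij[1L]], gn[ij[2L]], sep = "-"))
    structure(list(configs = configs,
                   truth = list(means = used, pairing = pr$pairing,
                                midline = pr$midline,
                                sigma = cfg$landmark_sigma,
                                mean_distances = truth_d)),
              class = "sim_landmarks")
  })
}
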