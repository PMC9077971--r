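#' @importFrom stats rnorm runif rpois rexp setNames approx quantile median
NULL

COMP_RES <- 1e5  # compartment truth is defined on a 100-kb ancestral grid

#' Generate a seeded multi-species synthetic world
#'
#' Builds a toy vertebrate-like universe with known ground truth: a shared
#' ancestral karyotype whose chromosome lengths are rescaled per species
#' (synteny preserved; rearrangements are out of scope), an ultrametric
#' phylogeny with divergence times in MYA, single-copy orthologs spaced
#' along each chromosome, and planted structure — per-species contact-decay
#' exponents, A/B compartment signs on a 100-kb grid, and TAD intervals —
#' that evolves along the tree: each structure element changes state on a
#' branch with probability proportional to branch length, scaled so that
#' `conserved_fraction = 1` means no divergence at all.
#'
#' @param n_species number of species (>= 2).
#' @param chrom_count_range integer pair; the ancestral chromosome count is
#'   drawn from this range once and shared by all species.
#' @param chrom_len_range bp pair for ancestral chromosome lengths.
#' @param seed integer seed; the world is a deterministic function of its
#'   arguments and this seed.
#' @param conserved_fraction in (0, 1]; fraction of compartment/TAD
#'   structure expected to survive from root to leaf.
#' @param root_age root depth of the phylogeny in MYA.
#' @param ps_exponent_range planted contact-decay exponents are drawn
#'   uniformly from this (negative) range.
#' @param trans_tau length scale (bp) of the inter-chromosomal affinity
#'   decay with chromosome-length difference.
#' @param trans_frac expected fraction of contacts that are
#'   inter-chromosomal.
#' @param tad_len_range bp pair for planted TAD lengths.
#' @param gene_spacing bp between consecutive ortholog genes.
#' @param length_coupling couple decay to length: species with longer
#'   genomes get exponents from the steep end of `ps_exponent_range`, and
#'   within a species each chromosome's exponent is shifted by
#'   `-chrom_coupling * (len - mean len) / 50 Mb` (longer chromosomes
#'   decay steeper, i.e. have fewer long-range contacts).
#' @param chrom_coupling per-chromosome exponent shift scale (default
#'   0.15 per 50 Mb of length difference).
#' @param tree optional `ape::phylo` tree to use instead of a random
#'   coalescent (tip labels become species ids).
#' @return an object of class `SpeciesWorld` with elements `species`,
#'   `genomes`, `phylogeny`, `orthologs` and `planted`.
#' @export
make_world <- function(n_species = 3,
                       chrom_count_range = c(2L, 5L),
                       chrom_len_range = c(5e6, 5e7),
                       seed = 1,
                       conserved_fraction = 0.8,
                       root_age = 100,
                       ps_exponent_range = c(-0.45, -0.23),
                       trans_tau = 3e7,
                       trans_frac = 0.35,
                       tad_len_range = c(4e5, 1.2e6),
                       gene_spacing = 2e5,
                       length_coupling = TRUE,
                       chrom_coupling = 0.15,
                       tree = NULL) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (any(chrom_count_range < 1) || chrom_count_range[1] > chrom_count_range[2])
    stop("invalid chrom_count_range")
  if (any(chrom_len_range <= 0) || chrom_len_range[1] > chrom_len_range[2])
    stop("invalid chrom_len_range")
  if (conserved_fraction <= 0 || conserved_fraction > 1)
    stop("conserved_fraction must be in (0, 1]")
  set.seed(seed)

  species <- paste0("sp", seq_len(n_species))
  if (is.null(tree)) {
    tree <- ape::rcoal(n_species, tip.label = species)
  } else {
    species <- tree$tip.label
  }
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * root_age / max(depths[seq_len(n_species)])

  n_chrom <- if (chrom_count_range[1] == chrom_count_range[2])
    chrom_count_range[1] else
    sample(seq(chrom_count_range[1], chrom_count_range[2]), 1)
  anc_len <- sort(runif(n_chrom, chrom_len_range[1], chrom_len_range[2]),
                  decreasing = TRUE)
  anc_len <- round(anc_len / COMP_RES) * COMP_RES
  names(anc_len) <- paste0("chr", seq_len(n_chrom))

  # per-species, per-chromosome linear scale factors
  scales <- lapply(species, function(s) {
    sf <- runif(1, 0.85, 1.15)
    setNames(sf * runif(n_chrom, 0.95, 1.05), names(anc_len))
  })
  names(scales) <- species
  genomes <- lapply(scales, function(sc)
    round(anc_len * sc / 1e4) * 1e4)

  # planted per-species decay exponents; with length coupling, longer
  # genomes sit at the steep end of the range (vertebrate-like pattern)
  if (length_coupling) {
    mlen <- vapply(genomes, mean, numeric(1))
    u <- if (diff(range(mlen)) > 0)
      (mlen - min(mlen)) / diff(range(mlen)) else rep(0.5, n_species)
    lo <- min(ps_exponent_range); hi <- max(ps_exponent_range)
    ps_exponent <- setNames(hi + u * (lo - hi) +
                              rnorm(n_species, 0, 0.005), species)
  } else {
    ps_exponent <- setNames(runif(n_species, ps_exponent_range[1],
                                  ps_exponent_range[2]), species)
  }
  # per-chromosome exponents: longer chromosomes decay steeper
  chrom_exponent <- lapply(species, function(s) {
    len <- genomes[[s]]
    ps_exponent[[s]] - chrom_coupling * (len - mean(len)) / 5e7
  })
  names(chrom_exponent) <- species

  # ancestral compartment signs: alternating blocks of ~1 Mb on 100-kb grid
  anc_sign <- lapply(names(anc_len), function(ch) {
    nb <- anc_len[[ch]] / COMP_RES
    s <- integer(0); cur <- sample(c(-1, 1), 1)
    while (length(s) < nb) {
      blk <- max(3, stats::rgeom(1, 1 / 10) + 1)
      s <- c(s, rep(cur, blk)); cur <- -cur
    }
    s[seq_len(nb)]
  })
  names(anc_sign) <- names(anc_len)

  flip_rate <- (1 - conserved_fraction) / root_age
  comp_leaf <- lapply(anc_sign, function(s)
    evolve_signs(tree, s, flip_rate))

  # ancestral TAD boundaries and their evolution
  anc_bounds <- lapply(names(anc_len), function(ch) {
    len <- anc_len[[ch]]
    b <- numeric(0); pos <- 0
    repeat {
      pos <- pos + runif(1, tad_len_range[1], tad_len_range[2])
      if (pos >= len - tad_len_range[1] / 2) break
      b <- c(b, round(pos / 2e4) * 2e4)
    }
    b
  })
  names(anc_bounds) <- names(anc_len)
  bound_leaf <- lapply(anc_bounds, function(b)
    evolve_boundaries(tree, b, flip_rate))

  # ortholog genes on the ancestral grid, mapped into each species
  orth <- list(); og <- 0
  for (ch in names(anc_len)) {
    pos <- seq(gene_spacing / 2, anc_len[[ch]] - gene_spacing / 2,
               by = gene_spacing)
    glen <- round(runif(length(pos), 2e3, 2e4))
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    for (k in seq_along(pos)) {
      og <- og + 1
      id <- sprintf("og%05d", og)
      for (s in species) {
        sc <- scales[[s]][[ch]]
        st <- round(pos[k] * sc)
        orth[[length(orth) + 1]] <- data.frame(
          og = id, species = s, gene = paste0(id, "_", s),
          chrom = ch, start = st, end = st + glen[k], strand = strand[k],
          anc_pos = pos[k], stringsAsFactors = FALSE)
      }
    }
  }
  orthologs <- do.call(rbind, orth)

  # gene annotations: ortholog genes plus extra genes whose density is
  # enriched in the ancestral A compartment (gene positions are shared
  # across species, as gene order is conserved in this world)
  extra <- list(); gid <- 0
  for (ch in names(anc_len)) {
    nb <- anc_len[[ch]] / COMP_RES
    lam <- ifelse(anc_sign[[ch]] > 0, 1.6, 0.4)
    cnt <- rpois(nb, lam)
    for (bb in which(cnt > 0)) for (r in seq_len(cnt[bb])) {
      gid <- gid + 1
      pos <- (bb - 1) * COMP_RES + runif(1, 0, COMP_RES - 2e4)
      extra[[length(extra) + 1]] <- data.frame(
        chrom = ch, anc_start = pos, anc_end = pos + runif(1, 2e3, 2e4),
        gene = sprintf("g%05d", gid),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  extra <- do.call(rbind, extra)
  genes <- do.call(rbind, lapply(species, function(s) {
    sc <- scales[[s]]
    og <- orthologs[orthologs$species == s, ]
    rbind(
      data.frame(species = s, gene = og$gene, chrom = og$chrom,
                 start = og$start, end = og$end, strand = og$strand,
                 stringsAsFactors = FALSE),
      data.frame(species = s, gene = paste0(extra$gene, "_", s),
                 chrom = extra$chrom,
                 start = round(extra$anc_start * sc[extra$chrom]),
                 end = round(extra$anc_end * sc[extra$chrom]),
                 strand = extra$strand, stringsAsFactors = FALSE))
  }))

  planted <- structure(list(
    ps_exponent = ps_exponent,
    chrom_exponent = chrom_exponent,
    comp_anc = anc_sign,
    comp_leaf = comp_leaf,          # per chrom: matrix anc-bin x species
    bound_leaf = bound_leaf,        # per chrom: list per species
    anc_len = anc_len,
    scales = scales,
    trans_affinity = list(tau = trans_tau, trans_frac = trans_frac),
    tad_len_range = tad_len_range,
    conserved_fraction = conserved_fraction,
    comp_strength = 0.4,
    tad_boost = 1.0
  ), class = "PlantedTruth")

  structure(list(species = species, genomes = genomes, phylogeny = tree,
                 orthologs = orthologs, genes = genes, planted = planted,
                 seed = seed),
            class = "SpeciesWorld")
}

#' @export
print.SpeciesWorld <- function(x, ...) {
  cat(sprintf("SpeciesWorld: %d species, %d chromosomes, conserved_fraction %.2f, seed %d\n",
              length(x$species), length(x$planted$anc_len),
              x$planted$conserved_fraction, x$seed))
  invisible(x)
}

# evolve a vector of +/-1 states down the tree; returns anc-bin x species
# matrix of leaf states. Flip probability per element per branch is
# min(0.5, rate * branch length).
evolve_signs <- function(tree, root_state, rate) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", max(tree$edge))
  states[[root]] <- root_state
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    p <- min(0.5, rate * ord$edge.length[e])
    s <- states[[parent]]
    flip <- runif(length(s)) < p
    s[flip] <- -s[flip]
    states[[child]] <- s
  }
  out <- do.call(cbind, states[seq_len(ntip)])
  colnames(out) <- tree$tip.label
  out
}

# evolve a set of boundary positions (ancestral bp) down the tree; a mutated
# boundary is deleted (p 0.3) or shifted (N(0, 100 kb)); new boundaries
# arise at rate `rate` per existing boundary per branch.
evolve_boundaries <- function(tree, bounds, rate) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", max(tree$edge))
  states[[root]] <- bounds
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    p <- min(0.5, rate * ord$edge.length[e])
    b <- states[[parent]]
    if (length(b)) {
      mut <- runif(length(b)) < p
      del <- mut & runif(length(b)) < 0.3
      shift <- mut & !del
      b[shift] <- b[shift] + round(rnorm(sum(shift), 0, 1e5) / 2e4) * 2e4
      b <- sort(b[!del])
      n_new <- rpois(1, p * length(bounds))
      if (n_new > 0 && length(bounds) > 1)
        b <- sort(unique(c(b, round(runif(n_new, min(bounds), max(bounds)) /
                                      2e4) * 2e4)))
    }
    states[[child]] <- b
  }
  out <- states[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Planted TAD intervals of one species
#'
#' Boundary positions evolved on the ancestral frame, rescaled into the
#' species' own coordinates; domains tile each chromosome between
#' consecutive boundaries.
#'
#' @param world a `SpeciesWorld`.
#' @param species species id.
#' @return data.frame (chrom, start, end), sorted, non-overlapping.
#' @export
planted_tads <- function(world, species) {
  stopifnot(species %in% world$species)
  sc <- world$planted$scales[[species]]
  out <- lapply(names(world$genomes[[species]]), function(ch) {
    len <- world$genomes[[species]][[ch]]
    anc_len <- world$planted$anc_len[[ch]]
    min_sep <- world$planted$tad_len_range[1]
    # filter and enforce the minimum TAD width on the ancestral frame, so
    # identical ancestral boundaries give identical TADs in every species
    b <- sort(unique(world$planted$bound_leaf[[ch]][[species]]))
    b <- b[b >= min_sep & b <= anc_len - min_sep]
    keep <- numeric(0)
    for (pos in b)
      if (!length(keep) || pos - keep[length(keep)] >= min_sep)
        keep <- c(keep, pos)
    keep <- round(keep * sc[[ch]] / 2e4) * 2e4
    keep <- keep[keep > 0 & keep < len]
    edges <- c(0, keep, len)
    data.frame(chrom = ch, start = edges[-length(edges)], end = edges[-1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Planted compartment sign track of one species
#'
#' @param world a `SpeciesWorld`.
#' @param species species id.
#' @param resolution bin width (bp) of the requested track.
#' @return integer vector of +/-1 aligned to
#'   `make_bins(world$genomes[[species]], resolution)`.
#' @export
planted_comp_sign <- function(world, species, resolution = COMP_RES) {
  stopifnot(species %in% world$species)
  bins <- make_bins(world$genomes[[species]], resolution)
  sc <- world$planted$scales[[species]]
  mid <- (bins$start + bins$end) / 2
  anc <- mid / sc[bins$chrom]
  idx <- pmin(floor(anc / COMP_RES) + 1,
              world$planted$anc_len[bins$chrom] / COMP_RES)
  vapply(seq_len(nrow(bins)), function(i)
    world$planted$comp_leaf[[bins$chrom[i]]][idx[i], species], numeric(1))
}

#' Simulate a Hi-C contact matrix for one species
#'
#' Intra-chromosomal expected counts follow the planted power-law decay
#' `s^exponent`, modulated multiplicatively by the planted compartment
#' checkerboard (same-sign bins enriched) and planted TADs (intra-TAD
#' enrichment); inter-chromosomal expected counts decay with the absolute
#' chromosome-length difference. Observed counts are independent Poisson
#' draws around the expectation, scaled so the expected total equals
#' `depth`.
#'
#' @param world a `SpeciesWorld`.
#' @param species species id.
#' @param resolution bin width in bp.
#' @param depth expected total contact count (> 0).
#' @param seed integer seed.
#' @param expected_only return the expectation matrix instead of Poisson
#'   draws (used by oracle tests).
#' @return a `ContactMatrix`.
#' @export
simulate_hic <- function(world, species, resolution = 2e4, depth = 1e5,
                         seed = 1, expected_only = FALSE) {
  if (!species %in% world$species)
    stop(sprintf("species '%s' not in world", species))
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  genome <- world$genomes[[species]]
  bins <- make_bins(genome, resolution)
  n <- nrow(bins)
  alpha_ch <- world$planted$chrom_exponent[[species]]
  if (is.null(alpha_ch))
    alpha_ch <- setNames(rep(world$planted$ps_exponent[[species]],
                             length(genome)), names(genome))
  cs <- world$planted$comp_strength
  tb <- world$planted$tad_boost
  sign_track <- planted_comp_sign(world, species, resolution)
  tads <- planted_tads(world, species)

  chroms <- names(genome)
  # --- intra-chromosomal expectations
  blocks <- list()
  block_sums <- numeric(length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    alpha <- alpha_ch[[ch]]
    idx <- which(bins$chrom == ch)
    nb <- length(idx)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    sg <- sign_track[idx]
    # the compartment plaid is a long-range feature: its modulation ramps
    # in quadratically up to 2 Mb so that short-range structure is owned
    # by the distance decay and the TADs
    ramp <- pmin(d * resolution / 2e6, 1)^2
    Fmod <- 1 + cs * outer(sg, sg) * ramp
    tad_ch <- tads[tads$chrom == ch, ]
    mid <- (bins$start[idx] + bins$end[idx]) / 2
    tid <- findInterval(mid, tad_ch$start)
    Fmod <- Fmod * (1 + tb * outer(tid, tid, "=="))
    # normalize the modulation per diagonal so the marginal decay stays
    # exactly s^alpha (the planted exponent is the mean contact decay)
    dmean <- vapply(seq_len(nb - 1), function(dd) {
      ix <- seq_len(nb - dd)
      mean(Fmod[cbind(ix, ix + dd)])
    }, numeric(1))
    E <- ifelse(d == 0, 0, d^alpha) * Fmod / c(1, dmean)[d + 1]
    diag(E) <- 0
    blocks[[ch]] <- E
    block_sums[ci] <- sum(E) / 2
  }
  cis_total <- depth * (1 - world$planted$trans_affinity$trans_frac)
  scale_cis <- cis_total / sum(block_sums)

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (ch in chroms) {
    idx <- which(bins$chrom == ch)
    E <- blocks[[ch]] * scale_cis
    up <- upper.tri(E)
    if (expected_only) {
      x <- E[up]
    } else {
      x <- rpois(sum(up), E[up])
    }
    keep <- x > 0
    ii <- row(E)[up][keep]; jj <- col(E)[up][keep]
    trip_i <- c(trip_i, idx[ii]); trip_j <- c(trip_j, idx[jj])
    trip_x <- c(trip_x, x[keep])
  }

  # --- inter-chromosomal expectations: uniform within a chromosome pair,
  # pair weight proportional to bin-count product times length affinity
  tau <- world$planted$trans_affinity$tau
  if (length(chroms) > 1) {
    pairs <- utils::combn(chroms, 2)
    w <- apply(pairs, 2, function(pr) {
      na <- sum(bins$chrom == pr[1]); nb <- sum(bins$chrom == pr[2])
      na * nb * exp(-abs(genome[[pr[1]]] - genome[[pr[2]]]) / tau)
    })
    lam <- depth * world$planted$trans_affinity$trans_frac * w / sum(w)
    for (pc in seq_len(ncol(pairs))) {
      ia <- which(bins$chrom == pairs[1, pc])
      ib <- which(bins$chrom == pairs[2, pc])
      if (expected_only) {
        per <- lam[pc] / (length(ia) * length(ib))
        gi <- rep(ia, times = length(ib)); gj <- rep(ib, each = length(ia))
        trip_i <- c(trip_i, gi); trip_j <- c(trip_j, gj)
        trip_x <- c(trip_x, rep(per, length(gi)))
      } else {
        tot <- rpois(1, lam[pc])
        if (tot > 0) {
          gi <- sample(ia, tot, replace = TRUE)
          gj <- sample(ib, tot, replace = TRUE)
          key <- paste(gi, gj)
          tab <- table(key)
          ij <- matrix(as.integer(unlist(strsplit(names(tab), " "))),
                       ncol = 2, byrow = TRUE)
          trip_i <- c(trip_i, ij[, 1]); trip_j <- c(trip_j, ij[, 2])
          trip_x <- c(trip_x, as.numeric(tab))
        }
      }
    }
  }
  cts <- Matrix::sparseMatrix(i = c(trip_i, trip_j), j = c(trip_j, trip_i),
                              x = c(trip_x, trip_x), dims = c(n, n))
  contact_matrix(cts, bins, resolution)
}

#' Simulate annotation tracks for one species
#'
#' Emits CTCF-like motifs (orientation-biased convergent inward at planted
#' TAD borders), TE annotations whose SINE/LINE densities track the planted
#' compartment sign, CNEs depleted near planted boundaries, a gene-by-
#' replicate TPM matrix in which genes sharing a planted TAD are
#' co-expressed, and enhancer intervals preferentially placed on SINE-rich
#' bins.
#'
#' @param world a `SpeciesWorld`.
#' @param species species id.
#' @param seed integer seed.
#' @param convergence_bias in `[0, 1]`: 0 gives unoriented border motifs
#'   (3DR approx. 1); 1 gives fully convergent borders.
#' @param sine_effect,line_effect additive coverage effect of the planted
#'   compartment sign on SINE/LINE density (set 0 to null the association).
#' @param coexpr_r target Pearson correlation of same-TAD gene pairs
#'   across replicates.
#' @param n_reps number of expression replicates.
#' @param motif_bg_rate background motifs per 100 kb.
#' @param cne_rate CNEs per 100 kb of TAD interior (boundary +/- 1 bin gets
#'   30% of this rate).
#' @return list with elements `motifs`, `tes`, `cnes`, `expression`
#'   (matrix, genes x replicates), `enhancers`.
#' @export
simulate_tracks <- function(world, species, seed = 1,
                            convergence_bias = 0.9,
                            sine_effect = 0.08, line_effect = -0.08,
                            coexpr_r = 0.7, n_reps = 3,
                            motif_bg_rate = 2, cne_rate = 3) {
  if (!species %in% world$species)
    stop(sprintf("species '%s' not in world", species))
  set.seed(seed)
  genome <- world$genomes[[species]]
  tads <- planted_tads(world, species)

  # --- motifs
  mot <- list()
  for (ch in names(genome)) {
    len <- genome[[ch]]
    nbg <- rpois(1, len / 1e5 * motif_bg_rate)
    if (nbg > 0)
      mot[[length(mot) + 1]] <- data.frame(
        chrom = ch, start = st <- sort(round(runif(nbg, 0, len - 20))),
        end = st + 19, name = "CTCF", score = runif(nbg),
        strand = sample(c("+", "-"), nbg, replace = TRUE),
        stringsAsFactors = FALSE)
    td <- tads[tads$chrom == ch, ]
    if (nrow(td)) {
      conv_strand <- function(target, n) {
        ok <- runif(n) < (1 + convergence_bias) / 2
        out <- ifelse(ok, target, sample(c("+", "-"), n, replace = TRUE))
        out
      }
      ls <- pmin(td$start + round(runif(nrow(td), 0, 2e4)), len - 20)
      rs <- pmax(td$end - round(runif(nrow(td), 20, 2e4)), 0)
      mot[[length(mot) + 1]] <- data.frame(
        chrom = ch, start = c(ls, rs), end = c(ls, rs) + 19, name = "CTCF",
        score = runif(2 * nrow(td), 0.7, 1),
        strand = c(conv_strand("+", nrow(td)), conv_strand("-", nrow(td))),
        stringsAsFactors = FALSE)
    }
  }
  motifs <- do.call(rbind, mot)
  motifs <- motifs[order(motifs$chrom, motifs$start), ]
  rownames(motifs) <- NULL

  # --- TEs on a 20-kb grid, coverage coupled to compartment sign
  bins20 <- make_bins(genome, 2e4)
  sg <- planted_comp_sign(world, species, 2e4)
  nb <- nrow(bins20)
  cov <- list(
    SINE = pmin(pmax(0.12 + sine_effect * sg + rnorm(nb, 0, 0.03), 0.01), 0.6),
    LINE = pmin(pmax(0.20 + line_effect * sg + rnorm(nb, 0, 0.03), 0.01), 0.6),
    LTR  = pmin(pmax(0.08 + rnorm(nb, 0, 0.02), 0.01), 0.4),
    DNA  = pmin(pmax(0.05 + rnorm(nb, 0, 0.015), 0.01), 0.4))
  tes <- do.call(rbind, lapply(names(cov), function(fam) {
    w <- bins20$end - bins20$start
    L <- pmin(round(cov[[fam]] * w), w)
    off <- floor(runif(nb) * (w - L))
    data.frame(chrom = bins20$chrom, start = bins20$start + off,
               end = bins20$start + off + L, family = fam,
               stringsAsFactors = FALSE)
  }))
  # a few records with uncertain classification (must be discarded downstream)
  nu <- max(2, round(nb * 0.005))
  ub <- sample(nb, nu)
  tes <- rbind(tes, data.frame(chrom = bins20$chrom[ub],
                               start = bins20$start[ub],
                               end = bins20$start[ub] + 500,
                               family = "Unknown", stringsAsFactors = FALSE))
  tes <- tes[tes$end > tes$start, ]
  rownames(tes) <- NULL

  # --- CNEs: depleted in boundary +/- 1 bin (20 kb) zones
  cne <- list()
  for (k in seq_len(nrow(tads))) {
    td <- tads[k, ]
    inner <- c(td$start + 2e4, td$end - 2e4)
    if (inner[2] > inner[1]) {
      ni <- rpois(1, (inner[2] - inner[1]) / 1e5 * cne_rate)
      if (ni > 0)
        cne[[length(cne) + 1]] <- data.frame(
          chrom = td$chrom, start = st <- round(runif(ni, inner[1], inner[2] - 600)),
          stringsAsFactors = FALSE)
    }
    nb_ <- rpois(1, 4e4 / 1e5 * cne_rate * 0.3)
    if (nb_ > 0)
      cne[[length(cne) + 1]] <- data.frame(
        chrom = td$chrom,
        start = round(runif(nb_, max(0, td$start - 2e4),
                            min(td$start + 2e4, genome[[td$chrom]] - 600))),
        stringsAsFactors = FALSE)
  }
  cnes <- do.call(rbind, cne)
  cnes <- cnes[order(cnes$chrom, cnes$start), , drop = FALSE]
  cnes$end <- cnes$start + round(runif(nrow(cnes), 150, 600))
  cnes$score <- round(runif(nrow(cnes), 0.90, 1.0), 4)
  rownames(cnes) <- NULL

  # --- expression: shared TAD factor induces co-expression
  genes <- world$orthologs[world$orthologs$species == species, ]
  genes <- genes[order(genes$chrom, genes$start), ]
  mid <- (genes$start + genes$end) / 2
  tad_id <- vapply(seq_len(nrow(genes)), function(i) {
    td <- tads[tads$chrom == genes$chrom[i], ]
    paste(genes$chrom[i], findInterval(mid[i], td$start))
  }, character(1))
  utads <- unique(tad_id)
  Fmat <- matrix(rnorm(length(utads) * n_reps), length(utads), n_reps,
                 dimnames = list(utads, NULL))
  base <- rnorm(nrow(genes), 2.5, 2)
  z <- sqrt(coexpr_r) * Fmat[tad_id, , drop = FALSE] +
    sqrt(1 - coexpr_r) * matrix(rnorm(nrow(genes) * n_reps),
                                nrow(genes), n_reps)
  tpm <- 2^(base + z)
  rownames(tpm) <- genes$gene
  colnames(tpm) <- paste0("rep", seq_len(n_reps))

  # --- enhancers on SINE-rich bins; density ~15 per Mb (vertebrate-like)
  p <- cov$SINE^2; p <- p / sum(p)
  ne <- max(5, round(nb * 0.3))
  eb <- sample(nb, ne, prob = p)
  w <- bins20$end[eb] - bins20$start[eb]
  el <- pmin(round(runif(ne, 1e3, 5e3)), w)
  eo <- floor(runif(ne) * (w - el))
  enhancers <- data.frame(chrom = bins20$chrom[eb],
                          start = bins20$start[eb] + eo,
                          end = bins20$start[eb] + eo + el,
                          stringsAsFactors = FALSE)
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ]
  rownames(enhancers) <- NULL

  list(motifs = motifs, tes = tes, cnes = cnes, expression = tpm,
       enhancers = enhancers, tad_of_gene = setNames(tad_id, genes$gene))
}

#' Ortholog-anchored coordinate map between two species
#'
#' Uses ortholog gene midpoints as anchors (plus the chromosome ends) and
#' maps positions by piecewise-linear interpolation, standing in for a
#' whole-genome liftOver chain.
#'
#' @param world a `SpeciesWorld`.
#' @param from,to species ids.
#' @return object of class `anchor_map`; use [map_position()] with it.
#' @export
build_anchor_map <- function(world, from, to) {
  stopifnot(from %in% world$species, to %in% world$species)
  of <- world$orthologs[world$orthologs$species == from, ]
  ot <- world$orthologs[world$orthologs$species == to, ]
  m <- merge(of, ot, by = "og", suffixes = c(".f", ".t"))
  maps <- lapply(unique(m$chrom.f), function(ch) {
    mm <- m[m$chrom.f == ch & m$chrom.t == ch, ]
    xf <- (mm$start.f + mm$end.f) / 2
    xt <- (mm$start.t + mm$end.t) / 2
    o <- order(xf)
    list(x = c(0, xf[o], world$genomes[[from]][[ch]]),
         y = c(0, xt[o], world$genomes[[to]][[ch]]))
  })
  names(maps) <- unique(m$chrom.f)
  structure(list(maps = maps, from = from, to = to), class = "anchor_map")
}

#' Map positions through an ortholog anchor map
#'
#' @param amap an `anchor_map` from [build_anchor_map()].
#' @param chrom,pos vectors of source chromosome and position (bp).
#' @return numeric vector of target positions (NA for unmappable chroms).
#' @export
map_position <- function(amap, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    mp <- amap$maps[[chrom[i]]]
    if (is.null(mp)) return(NA_real_)
    approx(mp$x, mp$y, xout = pos[i], rule = 2, ties = "ordered")$y
  }, numeric(1))
}

#' Per-bin gene density of one species
#'
#' Number of annotated genes whose midpoint falls in each bin; in this
#' world gene density is enriched in the ancestral A compartment, as in
#' real genomes.
#'
#' @param world a `SpeciesWorld`.
#' @param species species id.
#' @param bins bin table from [make_bins()].
#' @return integer vector of gene counts per bin.
#' @export
gene_density <- function(world, species, bins) {
  g <- world$genes[world$genes$species == species, ]
  b <- pos_to_bin(bins, g$chrom, pmin((g$start + g$end) / 2,
                                      matrix_genome_of(world, species, g$chrom) - 1))
  tabulate(b[!is.na(b)], nrow(bins))
}

matrix_genome_of <- function(world, species, chrom) {
  as.numeric(world$genomes[[species]][chrom])
}
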