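test_that("worlds and simulations are deterministic for a fixed seed", {
  w1 <- make_world(n_species = 3, seed = 11, chrom_count_range = c(2, 2),
                   chrom_len_range = c(8e6, 1.2e7))
  w2 <- make_world(n_species = 3, seed = 11, chrom_count_range = c(2, 2),
                   chrom_len_range = c(8e6, 1.2e7))
  expect_identical(w1$genomes, w2$genomes)
  expect_identical(w1$planted$comp_leaf, w2$planted$comp_leaf)
  expect_identical(w1$orthologs, w2$orthologs)
  m1 <- simulate_hic(w1, "sp1", 1e5, 1e5, seed = 7)
  m2 <- simulate_hic(w2, "sp1", 1e5, 1e5, seed = 7)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  t1 <- simulate_tracks(w1, "sp2", seed = 5)
  t2 <- simulate_tracks(w2, "sp2", seed = 5)
  expect_identical(t1$motifs, t2$motifs)
  expect_identical(t1$expression, t2$expression)
})

test_that("generator rejects invalid parameters", {
  expect_error(make_world(n_species = 1), "n_species")
  expect_error(make_world(chrom_count_range = c(5, 2)), "chrom_count_range")
  expect_error(make_world(chrom_len_range = c(-1, 1e7)), "chrom_len_range")
  w <- small_world()
  expect_error(simulate_hic(w, "nosuch", 1e5, 1e5), "not in world")
  expect_error(simulate_hic(w, "sp1", 1e5, 0), "depth")
  expect_error(simulate_tracks(w, "nosuch"), "not in world")
})

test_that("full conservation gives identical planted TADs after mapping", {
  w <- make_world(n_species = 2, conserved_fraction = 1, seed = 5,
                  chrom_count_range = c(2, 2), chrom_len_range = c(8e6, 1.2e7))
  t1 <- planted_tads(w, "sp1")
  t2 <- planted_tads(w, "sp2")
  expect_identical(nrow(t1), nrow(t2))
  amap <- build_anchor_map(w, "sp1", "sp2")
  mapped <- map_position(amap, t1$chrom, t1$end)
  # boundaries land on the same 20-kb grid position up to rounding
  expect_true(all(abs(mapped - t2$end) <= 2e4))
})

test_that("planted compartment agreement decays with divergence time", {
  # oracle: direct counting of planted sign agreement on the ancestral frame
  w <- make_world(n_species = 10, seed = 4, chrom_count_range = c(2, 2),
                  chrom_len_range = c(1e7, 1.5e7), conserved_fraction = 0.7)
  signs <- do.call(rbind, w$planted$comp_leaf)
  agree <- crossprod(signs) / nrow(signs)
  div <- ape::cophenetic.phylo(w$phylogeny)[colnames(signs),
                                            colnames(signs)] / 2
  up <- upper.tri(agree)
  expect_lt(cor(agree[up], div[up]), 0)
})

test_that("intra-chromosomal expectation follows the planted decay", {
  # oracle: independent log-log least squares on the expectation function
  w <- make_world(n_species = 2, seed = 5, chrom_count_range = c(3, 3),
                  chrom_len_range = c(3e7, 5e7))
  me <- simulate_hic(w, "sp1", 1e5, 1e6, seed = 1, expected_only = TRUE)
  ps <- ps_curve(me, balanced = FALSE)
  expect_lt(abs(ps$slope - w$planted$ps_exponent[["sp1"]]), 0.005)
})

test_that("trans expectation decreases with chromosome-length difference", {
  w <- make_world(n_species = 2, seed = 9, chrom_count_range = c(4, 4),
                  chrom_len_range = c(8e6, 4e7))
  me <- simulate_hic(w, "sp1", 5e5, 1e6, seed = 1, expected_only = TRUE)
  genome <- matrix_genome(me)
  pairs <- utils::combn(names(genome), 2)
  stats_per_pair <- vapply(seq_len(ncol(pairs)), function(k) {
    ia <- which(me$bins$chrom == pairs[1, k])
    ib <- which(me$bins$chrom == pairs[2, k])
    c(abs(genome[[pairs[1, k]]] - genome[[pairs[2, k]]]),
      mean(as.matrix(me$counts[ia, ib])))
  }, numeric(2))
  dlen <- stats_per_pair[1, ]; mcount <- stats_per_pair[2, ]
  # most similar pair has strictly higher per-pair expectation than the
  # most dissimilar pair
  expect_gt(mcount[which.min(dlen)], mcount[which.max(dlen)])
  expect_lt(cor(dlen, mcount), 0)
})

test_that("generated motifs are convergent at borders, neutral without bias", {
  trk <- small_tracks()
  pt <- planted_tads(small_world(), "sp1")
  borders <- data.frame(chrom = pt$chrom, start = pmax(0, pt$end - 2e4),
                        end = pt$end + 2e4)
  r_border <- compute_3dr(trk$motifs, regions = borders)$ratio_3dr
  r_genome <- compute_3dr(trk$motifs)$ratio_3dr
  expect_gt(r_border, r_genome)
  expect_gt(r_genome, 1)
  # unbiased limit: pool two seeds for a stable estimate
  r0 <- vapply(c(8, 9), function(sd)
    compute_3dr(simulate_tracks(small_world(), "sp1", seed = sd,
                                convergence_bias = 0)$motifs)$ratio_3dr,
    numeric(1))
  expect_gt(mean(r0), 0.5)
  expect_lt(mean(r0), 2)
})

test_that("TE coverage tracks compartment sign only when an effect is planted", {
  w <- small_world()
  bins20 <- make_bins(w$genomes[["sp1"]], 2e4)
  sg <- planted_comp_sign(w, "sp1", 2e4)
  cov <- te_coverage(small_tracks()$tes, bins20)
  r <- te_ab_correlation(cov, sg)
  expect_gt(r$r[r$family == "SINE"], 0.5)
  expect_lt(r$r[r$family == "LINE"], -0.5)
  cov0 <- te_coverage(simulate_tracks(w, "sp1", seed = 8, sine_effect = 0,
                                      line_effect = 0)$tes, bins20)
  r0 <- te_ab_correlation(cov0, sg)
  expect_lt(abs(r0$r[r0$family == "SINE"]), 0.1)
})

test_that("same-TAD genes are co-expressed at the configured strength", {
  w <- small_world()
  trk <- simulate_tracks(w, "sp1", seed = 2, coexpr_r = 0.95)
  g <- w$orthologs[w$orthologs$species == "sp1", ]
  co <- coexpression_by_distance(
    trk$expression,
    data.frame(gene = g$gene, chrom = g$chrom, start = g$start, end = g$end),
    planted_tads(w, "sp1"), r_cutoff = 0.9, max_d = 1)
  expect_true(all(co$frac_same_tad > co$frac_all))
})

test_that("ortholog anchor maps interpolate and invert consistently", {
  w <- small_world()
  a12 <- build_anchor_map(w, "sp1", "sp2")
  a21 <- build_anchor_map(w, "sp2", "sp1")
  pos <- c(1e6, 5e6, 9e6)
  there <- map_position(a12, rep("chr1", 3), pos)
  back <- map_position(a21, rep("chr1", 3), there)
  expect_true(all(abs(back - pos) < 5e4))
  expect_true(is.na(map_position(a12, "chrX", 1e6)))
})
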