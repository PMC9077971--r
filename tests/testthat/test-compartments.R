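test_that("compartment calling recovers the planted checkerboard", {
  w <- small_world()
  m100 <- small_m100()
  gd <- gene_density(w, "sp1", m100$bins)
  tr <- call_compartments(m100, gd)
  planted <- planted_comp_sign(w, "sp1", 1e5)
  expect_gte(mean(sign(tr$pc1) == planted, na.rm = TRUE), 0.95)
  expect_equal(tr$ab_label[which(tr$pc1 > 0)[1]], "A")
  # deterministic: a second call gives identical output
  tr2 <- call_compartments(m100, gd)
  expect_identical(tr$pc1, tr2$pc1)
})

test_that("degenerate matrices give flat low-confidence PC1", {
  M <- matrix(1, 40, 40); diag(M) <- 0
  m <- toy_matrix(M, 1e5)
  tr <- call_compartments(m, rep(1, 40))
  expect_true(all(tr$low_confidence))
  expect_lt(stats::sd(tr$pc1, na.rm = TRUE), 1e-6)
})

test_that("AB index matches hand evaluation and its boundary cases", {
  # 4 fine bins; coarse labels A,A,B,B; hand-chosen counts
  M <- matrix(0, 4, 4)
  M[1, 2] <- 8            # bin 1 contacts only A-labeled bins
  M[2, 3] <- 2; M[2, 4] <- 2  # bin 2: meanA (8/2=4) vs meanB (2+2)/2=2
  M <- M + t(M)
  bins20 <- make_bins(c(c1 = 8e4), 2e4)
  m <- contact_matrix(M, bins20, 2e4)
  labels <- c("A", "A", "B", "B")
  coarse <- make_bins(c(c1 = 8e4), 2e4)
  abi <- ab_index(m, labels, coarse)
  expect_equal(abi[1], 1)                      # only-A contact
  # bin 2: meanA = (0+8)/2 = 4, meanB = (2+2)/2 = 2 -> (4-2)/6
  expect_equal(abi[2], (4 - 2) / (4 + 2))
  # equal contact with both classes -> 0
  M2 <- matrix(0, 4, 4); M2[1, 3] <- 5; M2[1, 2] <- 5; M2 <- M2 + t(M2)
  abi2 <- ab_index(contact_matrix(M2, bins20, 2e4), labels, coarse)
  expect_equal(abi2[1], (2.5 - 2.5) / 5)
  expect_true(all(abs(abi[!is.na(abi)]) <= 1))
  # antisymmetric under swapping the A/B labels
  swapped <- ab_index(m, c("B", "B", "A", "A"), coarse)
  expect_equal(swapped, -abi)
})

test_that("AB index correlates with the planted sign at 20 kb", {
  w <- small_world()
  tr <- call_compartments(small_m100(), gene_density(w, "sp1",
                                                     small_m100()$bins))
  abi <- ab_index(small_m20(), tr)
  planted <- planted_comp_sign(w, "sp1", 2e4)
  expect_gt(mean(sign(abi) == planted, na.rm = TRUE), 0.9)
})

test_that("insulation score dips at planted TAD boundaries", {
  w <- small_world()
  ist <- insulation_score(small_m20())
  pt <- planted_tads(w, "sp1")
  bnd <- pt[pt$end < stats::ave(pt$end, pt$chrom, FUN = max), ]
  prof <- insulation_profile(ist, data.frame(chrom = bnd$chrom,
                                             mid = bnd$end), flank = 2e5)
  offs <- as.numeric(rownames(prof))
  expect_equal(offs[which.min(prof[, 1])], 0)
})

test_that("state grouping obeys the cosine threshold and classifies signs", {
  # two tight clusters whose means have cosine just under 0.85 stay apart
  set.seed(1)
  c1 <- c(1, 0.1); c2 <- c(0.773, 0.642)  # cos = cos(34 deg) = 0.829
  expect_lt(sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2)), 0.85)
  X <- rbind(matrix(rep(c1, 60), ncol = 2, byrow = TRUE),
             matrix(rep(c2, 60), ncol = 2, byrow = TRUE)) +
    matrix(rnorm(240, 0, 0.005), ncol = 2)
  st <- cluster_states(X, K = 2, seed = 1)
  expect_equal(length(unique(st$state_group)), 2)
  # both clusters all-positive in both species -> two CA groups
  expect_true(all(st$state_class == "CA"))
  expect_equal(st$groups$pct[st$groups$class == "CA"], 100)
  # ... and two clusters with cosine above the threshold merge
  c3 <- c(1, 1); c4 <- c(1, 0.8)  # cos = 0.9965
  Y <- rbind(matrix(rep(c3, 60), ncol = 2, byrow = TRUE),
             matrix(rep(c4, 60), ncol = 2, byrow = TRUE)) +
    matrix(rnorm(240, 0, 0.005), ncol = 2)
  st2 <- cluster_states(Y, K = 2, seed = 1)
  expect_equal(length(unique(st2$state_group)), 1)
  expect_error(cluster_states(X[1:3, ], K = 10), "distinct")
})

test_that("conserved-state percentages recover the planted truth", {
  w <- make_world(n_species = 5, chrom_count_range = c(3, 3),
                  chrom_len_range = c(1.5e7, 2.5e7), seed = 11,
                  conserved_fraction = 0.75)
  sg <- do.call(rbind, w$planted$comp_leaf)
  planted_pct <- 100 * table(planted_classes(w)) / nrow(sg)
  al <- sg + matrix(rnorm(length(sg), 0, 0.25), nrow(sg))
  st <- cluster_states(al, K = 30, seed = 1)
  got <- stats::setNames(st$groups$pct, st$groups$class)
  for (cl in c("CA", "CB", "NC"))
    expect_lt(abs(got[[cl]] - planted_pct[[cl]]), 5)
})

test_that("group summary reproduces the printed percentages", {
  mb <- c(CA = 272.99, CB = 333.02, NC = 243.73)
  gs <- group_summary(mb, total_mb = 849.74)
  expect_equal(gs$pct[gs$class == "CA"], round(100 * 272.99 / 849.74, 2))
  expect_equal(gs$pct[gs$class == "NC"], 28.68)
  is_mb <- c(CHI = 184.80, CLI = 183.77)
  gi <- group_summary(is_mb, total_mb = 849.74)
  expect_equal(gi$pct[gi$class == "CHI"], 21.75)
  expect_equal(group_summary(c(X = 5))$pct, 100)
  expect_error(group_summary(c(a = 10, b = 10), total_mb = 15), "exceed")
})

test_that("cross-tissue consistency separates shared from shuffled tracks", {
  w <- make_world(n_species = 4, chrom_count_range = c(2, 2),
                  chrom_len_range = c(1.5e7, 2e7), seed = 6,
                  conserved_fraction = 0.85)
  sg <- do.call(rbind, w$planted$comp_leaf)
  al <- sg + matrix(rnorm(length(sg), 0, 0.2), nrow(sg))
  st <- cluster_states(al, K = 12, seed = 1)
  base <- sg[, 1]
  # identical track retains every conserved state
  same <- cross_tissue_consistency(st, list(t1 = base), n_perm = 10, seed = 1)
  expect_equal(unname(same$observed), 1)
  # tissues sharing 80% of signs beat their permutation controls
  set.seed(2)
  tissues <- lapply(1:6, function(i) {
    v <- base
    fl <- sample(length(v), round(0.2 * length(v)))
    v[fl] <- -v[fl]
    v
  })
  cc <- cross_tissue_consistency(st, tissues, n_perm = 20, seed = 3)
  expect_true(all(cc$observed > apply(cc$control, 2, max)))
  expect_lt(cc$p_value, 0.05)
  expect_warning(cross_tissue_consistency(st, tissues, n_perm = 5, seed = 1),
                 "unstable")
})

test_that("similarity versus divergence: hand cosines, NA cases, planted drift", {
  # hand vectors: cosine values match dot-product arithmetic
  tracks <- cbind(a = c(1, 0, 1), b = c(1, 1, 0), c = c(0, 1, 1))
  tree <- ape::read.tree(text = "((a:10,b:10):20,c:30);")
  sv <- similarity_vs_divergence(tracks, tree)
  expect_equal(unname(sv$similarity["a", "b"]), 1 / 2)  # 1 / (sqrt2*sqrt2)
  expect_equal(unname(sv$similarity["a", "c"]), 1 / 2)
  # identical tracks -> similarity 1 everywhere, correlation undefined
  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(is.na(similarity_vs_divergence(same, tree)$r))
  # planted phylogenetic drift -> negative correlation (sign test)
  rs <- vapply(1:5, function(sd) {
    w <- make_world(n_species = 6, chrom_count_range = c(2, 2),
                    chrom_len_range = c(1e7, 1.5e7), seed = sd,
                    conserved_fraction = 0.7)
    sg <- do.call(rbind, w$planted$comp_leaf)
    al <- sg + matrix(rnorm(length(sg), 0, 0.3), nrow(sg))
    similarity_vs_divergence(al, w$phylogeny)$r
  }, numeric(1))
  expect_gte(sum(rs < 0), 4)
})
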