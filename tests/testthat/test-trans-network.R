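# exact upper-tail binomial by log-space pmf summation (independent of
# pbinom, which the implementation uses)
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  terms <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

test_that("binomial tail p-values match the exact-summation oracle", {
  cases <- expand.grid(k = c(0, 1, 3, 10, 50), n = c(20, 100, 1000),
                       p = c(0.001, 0.01, 0.2))
  cases <- cases[cases$k <= cases$n, ]
  for (r in seq_len(nrow(cases))) {
    got <- stats::pbinom(cases$k[r] - 1, cases$n[r], cases$p[r],
                         lower.tail = FALSE)
    expect_lt(abs(got - binom_tail_oracle(cases$k[r], cases$n[r],
                                          cases$p[r])), 1e-12)
  }
  # printed worked case
  expect_equal(stats::pbinom(2, 100, 0.01, lower.tail = FALSE),
               binom_tail_oracle(3, 100, 0.01))
  expect_lt(abs(binom_tail_oracle(3, 100, 0.01) - 0.0794), 5e-4)
})

test_that("trans significance respects the binomial contract and q normalization", {
  w <- small_world()
  mt <- simulate_hic(w, "sp1", 5e5, 2e5, seed = 3)
  tests <- trans_significance(mt)
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_true(all(tests$m_norm > 0 & tests$m_norm < 1))
  expect_true(all(tests$k <= tests$n))
  # k = 0 pairs have p exactly 1
  expect_true(all(tests$p_value[tests$k == 0] == 1))
  # BH monotonicity within each chromosome-pair family
  fam <- paste(tests$chromA, tests$chromB)
  for (f in unique(fam)) {
    tf <- tests[fam == f, ]
    ord <- order(tf$p_value)
    expect_true(!is.unsorted(tf$q_value[ord]))
  }
  # the two chromosomes here are the two longest: q_norm == q
  genome <- matrix_genome(mt)
  top2 <- names(sort(genome, decreasing = TRUE))[1:2]
  sel <- tests$chromA %in% top2 & tests$chromB %in% top2
  expect_equal(tests$q_norm[sel], tests$q_value[sel])
})

test_that("bin network construction thresholds q_norm as specified", {
  tests <- data.frame(chromA = "c1", binA = 1:5, chromB = "c2", binB = 11:15,
                      k = 5, n = 100, m_norm = 0.01, p_value = 0.5,
                      q_value = 0.5,
                      q_norm = c(1e-8, 1e-7, 1e-3, 0.2, 0.9))
  attr(tests, "bins") <- make_bins(c(c1 = 5e5 * 5, c2 = 5e5 * 10), 5e5)
  expect_equal(igraph::ecount(build_bin_network(tests, 1e-6)$graph), 2)
  expect_equal(igraph::ecount(build_bin_network(tests, 0)$graph), 0)
  expect_equal(igraph::ecount(build_bin_network(tests, 1.0)$graph), 5)
})

test_that("network statistics match hand-computed graphs", {
  star <- igraph::make_star(5, mode = "undirected")
  st <- network_stats(star)
  expect_equal(st$network_variance, 1.8 / 1.6)  # degrees {4,1,1,1,1}
  expect_equal(st$average_degree, 1.6)
  expect_equal(network_stats(igraph::make_ring(3))$clustering_coefficient, 1)
  expect_equal(network_stats(
    igraph::make_ring(3, circular = FALSE))$clustering_coefficient, 0)
  expect_error(network_stats(igraph::make_empty_graph(3, directed = FALSE)),
               "zero mean degree")
})

test_that("randomization conserves counts, varies with seed, raises transitivity", {
  g <- igraph::sample_gnm(30, 45)
  r1 <- randomize_network(g, seed = 1)
  r2 <- randomize_network(g, seed = 2)
  expect_equal(igraph::ecount(r1$graph), 45)
  expect_equal(igraph::vcount(r1$graph), 30)
  expect_false(identical(igraph::as_edgelist(r1$graph),
                         igraph::as_edgelist(r2$graph)))
  # switching phase never decreases transitivity relative to the raw
  # geometric graph built from the same seed
  r0 <- randomize_network(g, seed = 1, switch_factor = 0)
  expect_gte(igraph::transitivity(r1$graph), igraph::transitivity(r0$graph))
  expect_error(randomize_network(igraph::make_empty_graph(5, directed = FALSE)),
               "no edges")
})

test_that("observed synthetic BINs are far from random controls", {
  w <- small_world()
  mt <- simulate_hic(w, "sp1", 5e5, 1e6, seed = 3)
  net <- build_bin_network(trans_significance(mt), q_cutoff = 1e-4)
  obs <- network_stats(net)$network_variance
  rand <- vapply(1:5, function(sd)
    network_stats(randomize_network(net, seed = sd))$network_variance,
    numeric(1))
  # one-sided empirical comparison: observed exceeds every control
  expect_true(all(obs > rand))
  expect_gt(obs / mean(rand), 1)
})

test_that("gene network similarity is 1 for identical inputs", {
  w <- small_world()
  mt <- simulate_hic(w, "sp1", 5e5, 3e5, seed = 1)
  net <- build_bin_network(trans_significance(mt), q_cutoff = 1e-4)
  og <- w$orthologs[w$orthologs$species == "sp1", ]
  og2 <- og; og2$species <- "sp9"
  sim <- gene_network_similarity(list(sp1 = net, sp9 = net),
                                 rbind(og, og2))
  expect_equal(unname(sim$similarity["sp1", "sp9"]), 1)
})

test_that("contact ratio matches hand cases and a recount oracle", {
  bins <- make_bins(c(c1 = 2e5, c2 = 1e5), 1e5)
  M <- matrix(0, 3, 3)
  M[1, 3] <- 4            # bin 1: only trans
  M[2, 3] <- 5; M[2, 1] <- 5  # bin 2: equal intra and inter
  M <- M + t(M)
  m <- contact_matrix(M, bins, 1e5)
  cr <- contact_ratio_profile(m)
  expect_equal(cr[1], 4 / 9)   # 4 trans / (4 trans + 5 intra)
  expect_equal(cr[2], 0.5)
  only_trans <- matrix(0, 2, 2); only_trans[1, 2] <- 3
  m2 <- contact_matrix(only_trans + t(only_trans),
                       make_bins(c(a = 1e5, b = 1e5), 1e5), 1e5)
  expect_equal(contact_ratio_profile(m2), c(1, 1))
  # full profile vs independent recount from the triplet file
  w <- small_world()
  mt <- simulate_hic(w, "sp1", 5e5, 2e5, seed = 8)
  tf <- tempfile(fileext = ".tsv")
  write_contacts(mt, tf)
  trip <- read.table(tf, header = TRUE)
  bins <- mt$bins
  first <- tapply(bins$bin, bins$chrom, min)
  gi <- as.integer(first[trip$chromA]) + trip$binA
  gj <- as.integer(first[trip$chromB]) + trip$binB
  tot <- numeric(nrow(bins)); intra <- numeric(nrow(bins))
  for (r in seq_len(nrow(trip))) {
    tot[gi[r]] <- tot[gi[r]] + trip$count[r]
    if (gi[r] != gj[r]) tot[gj[r]] <- tot[gj[r]] + trip$count[r]
    if (trip$chromA[r] == trip$chromB[r]) {
      intra[gi[r]] <- intra[gi[r]] + trip$count[r]
      if (gi[r] != gj[r]) intra[gj[r]] <- intra[gj[r]] + trip$count[r]
    }
  }
  oracle <- ifelse(tot > 0, (tot - intra) / tot, NA_real_)
  expect_equal(contact_ratio_profile(mt), oracle)
})
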