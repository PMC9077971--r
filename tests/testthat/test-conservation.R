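test_that("3DR matches brute-force pair enumeration on toy motifs", {
  mt <- data.frame(chrom = "c", start = c(0, 10, 20, 25),
                   end = c(0, 10, 20, 25),
                   strand = c("+", "-", "+", "-"), score = 1)
  sp <- compute_3dr(mt, score_quantile = 0)
  expect_equal(sort(sp$convergent), c(5, 10))
  expect_equal(sp$divergent, 10)
  expect_equal(sp$ratio_3dr, 0.75)
  # alternating strands at equal spacing -> 3DR = 1
  alt <- data.frame(chrom = "c", start = seq(0, 90, 10),
                    end = seq(0, 90, 10),
                    strand = rep(c("+", "-"), 5), score = 1)
  expect_equal(compute_3dr(alt, score_quantile = 0)$ratio_3dr, 1)
  # no divergent pair -> undefined
  conv_only <- data.frame(chrom = "c", start = c(0, 10), end = c(0, 10),
                          strand = c("+", "-"), score = 1)
  expect_error(compute_3dr(conv_only, score_quantile = 0), "undefined")
})

test_that("3DR is invariant to translation, relabeling and scaling", {
  set.seed(3)
  mt <- data.frame(chrom = "c", start = sort(sample(1e6, 200)),
                   strand = sample(c("+", "-"), 200, TRUE),
                   score = runif(200))
  mt$end <- mt$start + 19
  base <- compute_3dr(mt)$ratio_3dr
  shifted <- mt; shifted$start <- mt$start + 5e5; shifted$end <- mt$end + 5e5
  expect_equal(compute_3dr(shifted)$ratio_3dr, base)
  renamed <- mt; renamed$chrom <- "other"
  expect_equal(compute_3dr(renamed)$ratio_3dr, base)
  scaled <- mt; scaled$start <- mt$start * 7; scaled$end <- mt$end * 7
  expect_equal(compute_3dr(scaled)$ratio_3dr, base)
})

test_that("3DR score filtering drops the sub-quantile motifs", {
  mt <- data.frame(chrom = "c", start = c(0, 10, 20, 30, 40, 50),
                   end = c(0, 10, 20, 30, 40, 50),
                   strand = c("+", "-", "+", "-", "+", "-"),
                   score = c(1, 1, 0.1, 0.1, 1, 1))
  sp <- compute_3dr(mt, score_quantile = 0.5)
  expect_equal(sp$n_motifs, 4)
})

test_that("CNE profile assigns the worked single-CNE example once", {
  tads <- data.frame(chrom = "c1", start = 0, end = 2000)
  cnes <- data.frame(chrom = "c1", start = 100, end = 350, score = 0.99)
  cp <- cne_profile(tads, cnes, min_len = 200, min_tad_bp = 100)
  expect_equal(cp$total_assigned, 1)
  # midpoint 225 -> interior bin 3 of 20 -> overall bin 13 (after 10 flanks)
  expect_equal(which(cp$profile > 0), 13)
  # zero CNEs -> all-zero profile
  cp0 <- cne_profile(tads, cnes[0, ], min_tad_bp = 100)
  expect_true(all(cp0$profile == 0))
})

test_that("CNE profile separates interiors from flanks by construction", {
  set.seed(5)
  tads <- data.frame(chrom = "c1", start = c(1e6, 3e6, 5e6),
                     end = c(1.8e6, 3.9e6, 5.7e6))
  inner <- do.call(rbind, lapply(seq_len(nrow(tads)), function(k)
    data.frame(chrom = "c1",
               start = round(runif(40, tads$start[k], tads$end[k] - 300)))))
  inner$end <- inner$start + 250
  inner$score <- 0.99
  cp <- cne_profile(tads, inner)
  expect_gt(cp$interior_mean, cp$flank_mean)
  # filters: low scores and short CNEs are discarded
  weak <- inner; weak$score <- 0.5
  expect_equal(cne_profile(tads, weak)$total_assigned, 0)
  short <- inner; short$end <- short$start + 100
  expect_equal(cne_profile(tads, short)$total_assigned, 0)
})

test_that("TAD conservation scores: hand count and identity case", {
  # 2 TADs; genes A,B in TAD1 and C in TAD2; target preserves A,B
  ref_tads <- data.frame(chrom = "c1", start = c(0, 1e6), end = c(1e6, 2e6))
  orth <- rbind(
    data.frame(og = c("g1", "g2", "g3"), species = "ref",
               gene = c("A", "B", "C"), chrom = "c1",
               start = c(1e5, 5e5, 1.5e6), end = c(1.1e5, 5.1e5, 1.51e6)),
    data.frame(og = c("g1", "g2", "g3"), species = "tgt",
               gene = c("A2", "B2", "C2"), chrom = "c1",
               start = c(1e5, 5e5, 1.5e6), end = c(1.1e5, 5.1e5, 1.51e6)))
  tgt_tads <- data.frame(chrom = "c1", start = c(0, 1e6), end = c(1e6, 2e6))
  sc <- tad_conservation_scores(ref_tads, tgt_tads, orth, "ref", "tgt")
  expect_equal(sc$intra_score, 50)  # 1 of 2 TADs has a conserved pair
  # identical worlds: every TAD with >= 2 genes is intra-conserved
  w <- small_world()
  pt1 <- planted_tads(w, "sp1"); pt2 <- planted_tads(w, "sp2")
  full <- tad_conservation_scores(pt1, pt2, w$orthologs, "sp1", "sp2")
  expect_gt(full$intra_score, 80)
  expect_true(full$intra_score <= 100 && full$inter_score <= 100)
})

test_that("shuffling target TADs degrades intra-TAD conservation", {
  w <- small_world()
  pt1 <- planted_tads(w, "sp1")
  pt2 <- planted_tads(w, "sp2")
  true_score <- tad_conservation_scores(pt1, pt2, w$orthologs,
                                        "sp1", "sp2")$intra_score
  set.seed(7)
  # destroy the target TAD frame: random small domains over the genome
  shuf <- do.call(rbind, lapply(names(w$genomes[["sp2"]]), function(ch) {
    len <- w$genomes[["sp2"]][[ch]]
    starts <- sort(sample(seq(0, len - 3e5, by = 2e4), 8))
    data.frame(chrom = ch, start = starts, end = starts + 1e5)
  }))
  shuf_score <- tad_conservation_scores(pt1, shuf, w$orthologs,
                                        "sp1", "sp2")$intra_score
  expect_gt(true_score, shuf_score)
})

test_that("co-expression stratification enforces its preconditions and rules", {
  expr <- matrix(rnorm(8), 4, 2,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
  genes <- data.frame(gene = c("a", "b", "c", "d"), chrom = "c1",
                      start = c(1, 2, 3, 4) * 1e5,
                      end = c(1, 2, 3, 4) * 1e5 + 1e4)
  tads <- data.frame(chrom = "c1", start = 0, end = 1e6)
  expect_error(coexpression_by_distance(expr, genes, tads),
               "3 replicates")
  # pair straddling a TAD boundary is never counted as same-TAD
  expr3 <- matrix(rnorm(12), 4, 3,
                  dimnames = list(c("a", "b", "c", "d"), NULL))
  split_tads <- data.frame(chrom = "c1", start = c(0, 2.5e5),
                           end = c(2.5e5, 1e6))
  co <- coexpression_by_distance(expr3, genes, split_tads, max_d = 0)
  expect_equal(co$n_same_tad, 2)  # (b,c) straddles; (a,b) and (c,d) do not
})
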