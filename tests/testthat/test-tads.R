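test_that("directionality index follows the chi-square-style formula", {
  # A = 10 upstream, B = 20 downstream -> DI = +10/3
  M <- matrix(0, 3, 3); M[1, 2] <- 10; M[2, 3] <- 20; M <- M + t(M)
  di <- directionality_index(toy_matrix(M, 2e4), window = 4e4)
  expect_equal(di$di[2], 10 / 3)
  # symmetry: A = B -> 0
  Ms <- matrix(0, 3, 3); Ms[1, 2] <- 10; Ms[2, 3] <- 10; Ms <- Ms + t(Ms)
  expect_equal(directionality_index(toy_matrix(Ms, 2e4), window = 4e4)$di[2], 0)
  expect_error(directionality_index(toy_matrix(Ms, 2e4), window = 2e4),
               "twice the resolution")
})

test_that("mirroring the matrix negates the directionality index", {
  m <- small_m20()
  idx <- which(m$bins$chrom == "chr1")
  M <- chrom_block(m, "chr1")
  rev_idx <- rev(seq_len(nrow(M)))
  mm <- toy_matrix(M[rev_idx, rev_idx], 2e4)
  di_f <- directionality_index(toy_matrix(M, 2e4))$di
  di_r <- directionality_index(mm)$di
  expect_equal(di_r, -rev(di_f), tolerance = 1e-10)
})

test_that("zero DI yields zero domains and all-unorganized chromatin", {
  bins <- make_bins(c(c1 = 2e6), 2e4)
  di <- structure(list(bins = bins, resolution = 2e4, window = 2e6,
                       di = rep(0, nrow(bins))), class = "DITrack")
  ts <- call_tads(di)
  expect_equal(nrow(ts$domains), 0)
  expect_equal(nrow(ts$boundaries), 0)
  expect_equal(ts$unorganized$end, 2e6)
})

test_that("TAD calling recovers planted boundaries and is scale invariant", {
  w <- small_world()
  ts <- small_tads()
  rec <- boundary_recovery(ts, planted_tads(w, "sp1"))
  expect_gte(rec, 0.75)
  di <- directionality_index(small_m20())
  di10 <- di; di10$di <- di$di * 10
  ts10 <- call_tads(di10, seed = 1)
  expect_identical(ts$domains, ts10$domains)
  expect_identical(ts$boundaries$mid, ts10$boundaries$mid)
})

test_that("domains, boundaries and unorganized gaps partition each chromosome", {
  ts <- small_tads()
  for (ch in unique(ts$domains$chrom)) {
    d <- ts$domains[ts$domains$chrom == ch, ]
    expect_true(all(d$end > d$start))
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    # covered length = domains + gaps (boundary intervals + unorganized)
    len <- max(small_m20()$bins$end[small_m20()$bins$chrom == ch])
    gap_bp <- sum(ts$unorganized$end[ts$unorganized$chrom == ch] -
                    ts$unorganized$start[ts$unorganized$chrom == ch])
    b <- ts$boundaries[ts$boundaries$chrom == ch, ]
    # boundary intervals lie between domains (never exceed the gap rule)
    expect_true(all(b$end - b$start < 4e5))
    expect_gte(len, sum(d$end - d$start) + gap_bp)
  }
})

test_that("larger genomes with the same TAD size distribution hold more TADs", {
  count_for <- function(lo, hi, sd) {
    w <- make_world(n_species = 2, chrom_count_range = c(2, 2),
                    chrom_len_range = c(lo, hi), seed = sd)
    m <- suppressWarnings(iterative_correction(
      simulate_hic(w, "sp1", 2e4, 1e6, seed = sd + 1)))
    nrow(call_tads(directionality_index(m), seed = 1)$domains)
  }
  wins <- vapply(1:3, function(sd)
    count_for(1.6e7, 2e7, sd) > count_for(8e6, 1e7, sd), logical(1))
  expect_gte(sum(wins), 2)
})

test_that("insulation profiles separate planted strong and weak boundaries", {
  # constructed IS track: dips of known depth at known positions
  bins <- make_bins(c(c1 = 4e6), 2e4)
  is_val <- rep(0, nrow(bins))
  strong <- c(50, 150); weak <- c(100, 180)
  for (b in strong) is_val[b + (-2:2)] <- c(-0.5, -1, -2, -1, -0.5)
  for (b in weak) is_val[b + (-2:2)] <- pmin(is_val[b + (-2:2)],
                                             c(-0.2, -0.4, -0.8, -0.4, -0.2))
  ist <- structure(list(bins = bins, resolution = 2e4, is_value = is_val),
                   class = "ISTrack")
  bd <- data.frame(chrom = "c1",
                   mid = (c(strong, weak) - 0.5) * 2e4,
                   class = rep(c("conserved", "gained"), each = 2))
  prof <- insulation_profile(ist, bd, flank = 1e5)
  expect_equal(as.numeric(rownames(prof))[which.min(prof[, "conserved"])], 0)
  expect_lt(min(prof[, "conserved"]), min(prof[, "gained"]))
  # flat track -> flat profile
  flat <- structure(list(bins = bins, resolution = 2e4,
                         is_value = rep(0.3, nrow(bins))), class = "ISTrack")
  pf <- insulation_profile(flat, bd, flank = 1e5)
  expect_true(all(abs(pf - 0.3) < 1e-12))
  expect_warning(insulation_profile(ist, data.frame(chrom = character(0),
                                                    mid = numeric(0),
                                                    class = character(0))),
                 "no boundaries")
})

test_that("TSS density peaks at boundary midpoints when planted there", {
  set.seed(3)
  bd <- data.frame(chrom = "c1", mid = c(1e6, 2e6, 3e6))
  tss <- data.frame(chrom = "c1",
                    pos = rep(bd$mid, each = 30) +
                      round(runif(90, 0, 8e3)))
  prof <- tss_enrichment(bd, tss, flank = 1e5, bin = 1e4)
  expect_equal(prof$offset[which.max(prof$density)], 5e3)
  # uniform TSS -> roughly flat
  set.seed(1)
  uni <- data.frame(chrom = "c1", pos = runif(3000, 0, 4e6))
  pu <- tss_enrichment(bd, uni, flank = 1e5, bin = 1e4)
  expect_lt(max(pu$density) / mean(pu$density), 2)
  expect_warning(
    out <- tss_enrichment(bd[0, ], tss), "no boundaries")
  expect_equal(nrow(out), 0)
  expect_error(tss_enrichment(bd, tss[0, ]), "empty")
})

test_that("boundary conservation labels follow the 40/100 kb rules", {
  mk_tadset <- function(mids) {
    structure(list(domains = data.frame(chrom = "c1",
                                        start = c(0, mids),
                                        end = c(mids, 1e7)),
                   boundaries = data.frame(chrom = "c1", start = mids,
                                           end = mids, mid = mids),
                   unorganized = data.frame(), resolution = 2e4),
              class = "TadSet")
  }
  identity_map <- structure(list(maps = list(c1 = list(x = c(0, 1e7),
                                                       y = c(0, 1e7))),
                                 from = "q", to = "t"), class = "anchor_map")
  all_tads <- list(q = mk_tadset(c(1e6, 2e6, 3e6)),
                   t1 = mk_tadset(c(1e6 + 3e4, 2e6 + 4e4, 3e6 + 2e5)),
                   t2 = mk_tadset(c(1e6 - 2e4, 2e6 + 2e5, 3e6 + 3e5)))
  maps <- list(t1 = identity_map, t2 = identity_map)
  bc <- classify_boundaries("q", all_tads, maps)
  # boundary 1: 30 kb and 20 kb away -> conserved in both
  expect_equal(bc$labels$label[1], "conserved")
  # boundary 2: exactly 40 kb (strict <) and 200 kb -> unknown overall
  expect_equal(bc$labels$label[2], "unknown")
  # boundary 3: >100 kb in every other species -> gained
  expect_equal(bc$labels$label[3], "gained")
})

test_that("a fully conserved world yields only conserved boundary labels", {
  w <- make_world(n_species = 3, conserved_fraction = 1, seed = 5,
                  chrom_count_range = c(2, 2), chrom_len_range = c(8e6, 1.2e7))
  tads <- lapply(w$species, function(s) {
    pt <- planted_tads(w, s)
    bnd <- pt[pt$end < stats::ave(pt$end, pt$chrom, FUN = max), ]
    structure(list(domains = pt,
                   boundaries = data.frame(chrom = bnd$chrom,
                                           start = bnd$end, end = bnd$end,
                                           mid = bnd$end),
                   unorganized = data.frame(), resolution = 2e4),
              class = "TadSet")
  })
  names(tads) <- w$species
  maps <- lapply(setdiff(w$species, "sp1"), function(t)
    build_anchor_map(w, "sp1", t))
  names(maps) <- setdiff(w$species, "sp1")
  bc <- classify_boundaries("sp1", tads, maps)
  expect_true(all(bc$labels$label == "conserved"))
  expect_equal(nrow(bc$lost), 0)
})
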