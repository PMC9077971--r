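TE_FAMILIES <- c("SINE", "LINE", "LTR", "DNA")

te_granges <- function(tes, family) {
  sel <- tes[tes$family == family, , drop = FALSE]
  GenomicRanges::reduce(GenomicRanges::GRanges(
    sel$chrom, IRanges::IRanges(sel$start + 1, sel$end)))
}

#' Per-bin TE coverage fractions by family
#'
#' Records within a family are merged before computing coverage (so
#' overlapping annotations are not double counted); records whose family
#' is not one of SINE/LINE/LTR/DNA are discarded.
#'
#' @param tes data.frame with `chrom`, `start`, `end`, `family`.
#' @param bins bin table from [make_bins()].
#' @return numeric matrix, bins x family, coverage fraction in `[0, 1]`.
#' @export
te_coverage <- function(tes, bins) {
  out <- matrix(0, nrow(bins), length(TE_FAMILIES),
                dimnames = list(NULL, TE_FAMILIES))
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start + 1, bins$end))
  for (fam in TE_FAMILIES) {
    gr <- te_granges(tes, fam)
    if (!length(gr)) next
    hits <- GenomicRanges::findOverlaps(gr_bins, gr)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      gr_bins[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
    bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(bp))
    out[idx, fam] <- as.numeric(bp) / (bins$end[idx] - bins$start[idx])
  }
  out
}

#' Correlation between TE coverage and AB index
#'
#' Per family Pearson correlation between per-bin coverage and the AB
#' index, over bins where both are defined.
#'
#' @param cov coverage matrix from [te_coverage()].
#' @param ab AB-index vector aligned to the same bins.
#' @param min_bins minimum usable bins (default 30; fewer is an error).
#' @return data.frame with `family`, `r`, `p` (NA for zero-variance
#'   coverage).
#' @export
te_ab_correlation <- function(cov, ab, min_bins = 30) {
  use <- !is.na(ab) & stats::complete.cases(cov)
  if (sum(use) < min_bins)
    stop(sprintf("only %d usable bins (< %d)", sum(use), min_bins))
  do.call(rbind, lapply(colnames(cov), function(fam) {
    x <- cov[use, fam]; y <- ab[use]
    if (stats::sd(x) == 0)
      return(data.frame(family = fam, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    data.frame(family = fam, r = unname(ct$estimate), p = ct$p.value)
  }))
}

#' Filter intra-chromosomal bin pairs by contact frequency
#'
#' Two-sided filter on raw intra-chromosomal contact frequencies (CI):
#' the lower threshold is the mean CI over inter-domain bin pairs (pairs
#' whose bins lie in different TADs, zero pairs included), and pairs below
#' it are dropped; then, scanning integer frequency levels from the top
#' downward in steps of 1, levels represented by fewer than `min_pairs`
#' bin pairs are removed, ensuring every retained level has enough pairs
#' to estimate a mean TE proportion.
#'
#' @param m a `ContactMatrix` (raw counts used).
#' @param tads a `TadSet` or domain data.frame on the same genome.
#' @param min_pairs minimum bin pairs per retained frequency level
#'   (default 100).
#' @return object of class `CiFilterSpec`: list with `lower`, `retained`
#'   (data.frame binA, binB, chrom, ci), `removed_fraction`,
#'   `removed_levels`.
#' @export
filter_bin_pairs <- function(m, tads, min_pairs = 100) {
  stopifnot(inherits(m, "ContactMatrix"))
  domains <- if (inherits(tads, "TadSet")) tads$domains else tads
  bins <- m$bins
  mid <- (bins$start + bins$end) / 2
  tad_of <- locate_tad(domains, bins$chrom, mid)
  inter_sum <- 0; inter_n <- 0
  pr_i <- integer(0); pr_j <- integer(0); pr_x <- numeric(0)
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    blk <- methods::as(Matrix::triu(m$counts[idx, idx, drop = FALSE], k = 1),
                       "TsparseMatrix")
    ti <- tad_of[idx]
    nb <- length(idx)
    n_pairs <- nb * (nb - 1) / 2
    tt <- table(ti[!is.na(ti)])
    bi <- blk@i + 1L; bj <- blk@j + 1L
    # bins outside any domain have NA TAD; their pairs count as inter-domain
    inter_pair <- is.na(ti[bi]) | is.na(ti[bj]) | ti[bi] != ti[bj]
    same <- sum(tt * (tt - 1) / 2)
    inter_n <- inter_n + (n_pairs - same)
    inter_sum <- inter_sum + sum(blk@x[inter_pair])
    pr_i <- c(pr_i, idx[bi]); pr_j <- c(pr_j, idx[bj])
    pr_x <- c(pr_x, blk@x)
  }
  if (inter_n == 0) stop("no inter-domain pairs; lower threshold undefined")
  lower <- inter_sum / inter_n
  keep <- pr_x >= lower
  if (!any(keep)) {
    warning("all pairs below the lower threshold; empty retention")
    return(structure(list(lower = lower,
                          retained = data.frame(binA = integer(),
                                                binB = integer(),
                                                ci = numeric()),
                          removed_fraction = NA_real_,
                          removed_levels = integer()),
                     class = "CiFilterSpec"))
  }
  ci <- round(pr_x[keep])
  bi <- pr_i[keep]; bj <- pr_j[keep]
  lev <- table(ci)
  bad <- as.integer(names(lev)[lev < min_pairs])
  drop <- ci %in% bad
  structure(list(lower = lower,
                 retained = data.frame(binA = bi[!drop], binB = bj[!drop],
                                       ci = ci[!drop]),
                 removed_fraction = mean(drop),
                 removed_levels = bad),
            class = "CiFilterSpec")
}

#' Correlation between TE proportion and contact frequency of bin pairs
#'
#' Per bin pair, the family TE proportion is the mean of the two bins'
#' coverage fractions; per family, the Pearson correlation of that
#' proportion with the pair's contact frequency.
#'
#' @param cov coverage matrix from [te_coverage()] (aligned to the matrix
#'   bins used for filtering).
#' @param pairs `CiFilterSpec` (or its `retained` data.frame).
#' @return data.frame with `family`, `r`, `p` (NA with < 2 pairs or zero
#'   variance).
#' @export
te_contact_correlation <- function(cov, pairs) {
  ret <- if (inherits(pairs, "CiFilterSpec")) pairs$retained else pairs
  do.call(rbind, lapply(colnames(cov), function(fam) {
    if (nrow(ret) < 2)
      return(data.frame(family = fam, r = NA_real_, p = NA_real_))
    x <- (cov[ret$binA, fam] + cov[ret$binB, fam]) / 2
    if (stats::sd(x) == 0 || stats::sd(ret$ci) == 0)
      return(data.frame(family = fam, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, ret$ci)
    data.frame(family = fam, r = unname(ct$estimate), p = ct$p.value)
  }))
}

#' TE enrichment in enhancer versus non-enhancer regions
#'
#' Per family fold change: mean TE coverage within enhancer bp divided by
#' mean coverage in all other regions, with a seeded bootstrap CI over
#' enhancer intervals. When the enhancer set tiles the whole genome the
#' fold is 1 by convention (no complement to compare against).
#'
#' @param tes TE table (`chrom`, `start`, `end`, `family`).
#' @param enhancers data.frame of intervals (`chrom`, `start`, `end`).
#' @param genome named numeric vector of chromosome lengths.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame with `family`, `fold`, `ci_lo`, `ci_hi`.
#' @export
enhancer_enrichment <- function(tes, enhancers, genome, n_boot = 1000,
                                seed = 1) {
  if (!nrow(enhancers)) stop("empty enhancer set")
  set.seed(seed)
  gr_enh <- GenomicRanges::reduce(GenomicRanges::GRanges(
    enhancers$chrom, IRanges::IRanges(enhancers$start + 1, enhancers$end)))
  enh_bp <- sum(IRanges::width(gr_enh))
  tot_bp <- sum(genome)
  out_bp <- tot_bp - enh_bp
  fam_gr <- lapply(TE_FAMILIES, function(f) te_granges(tes, f))
  names(fam_gr) <- TE_FAMILIES
  fam_bp <- vapply(fam_gr, function(g) sum(IRanges::width(g)), numeric(1))
  in_bp <- vapply(fam_gr, function(g)
    sum(IRanges::width(GenomicRanges::intersect(g, gr_enh))), numeric(1))
  fold_of <- function(inb, enhb) {
    if (out_bp <= 0) return(rep(1, length(inb)))
    dens_in <- inb / enhb
    dens_out <- (fam_bp - inb) / out_bp
    ifelse(dens_out > 0, dens_in / dens_out, NA_real_)
  }
  fold <- fold_of(in_bp, enh_bp)
  # bootstrap over enhancer intervals
  gr_all <- GenomicRanges::GRanges(enhancers$chrom,
                                   IRanges::IRanges(enhancers$start + 1,
                                                    enhancers$end))
  per_int <- vapply(TE_FAMILIES, function(f) {
    g <- fam_gr[[f]]
    if (!length(g)) return(numeric(nrow(enhancers)))
    hits <- GenomicRanges::findOverlaps(gr_all, g)
    bp <- numeric(nrow(enhancers))
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        gr_all[S4Vectors::queryHits(hits)], g[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
      bp[as.integer(names(agg))] <- agg
    }
    bp
  }, numeric(nrow(enhancers)))
  per_int <- matrix(per_int, nrow = nrow(enhancers),
                    dimnames = list(NULL, TE_FAMILIES))
  widths <- enhancers$end - enhancers$start
  boots <- replicate(n_boot, {
    s <- sample.int(nrow(enhancers), replace = TRUE)
    fold_of(colSums(per_int[s, , drop = FALSE]), sum(widths[s]))
  })
  boots <- matrix(boots, nrow = length(TE_FAMILIES))
  data.frame(family = TE_FAMILIES, fold = fold,
             ci_lo = apply(boots, 1, quantile, 0.025, na.rm = TRUE),
             ci_hi = apply(boots, 1, quantile, 0.975, na.rm = TRUE),
             row.names = NULL)
}

#' Per-ortholog TE coverage within enhancers
#'
#' For each ortholog gene of one species, the bp of family TEs falling in
#' enhancers within a window around the gene, normalized by window size;
#' the per-species vectors (ortholog x family, flattened) feed
#' [te_similarity_vs_divergence()].
#'
#' @param tes TE table.
#' @param enhancers enhancer intervals.
#' @param orthologs ortholog rows for one species.
#' @param window one-sided window around the gene midpoint (default
#'   100 kb).
#' @return matrix, orthologs x family, rownames = ortholog-group ids.
#' @export
ortholog_enhancer_te <- function(tes, enhancers, orthologs, window = 1e5) {
  gr_enh <- GenomicRanges::reduce(GenomicRanges::GRanges(
    enhancers$chrom, IRanges::IRanges(enhancers$start + 1, enhancers$end)))
  mid <- (orthologs$start + orthologs$end) / 2
  gr_win <- GenomicRanges::GRanges(
    orthologs$chrom,
    IRanges::IRanges(pmax(1, mid - window), mid + window))
  out <- matrix(0, nrow(orthologs), length(TE_FAMILIES),
                dimnames = list(orthologs$og, TE_FAMILIES))
  for (fam in TE_FAMILIES) {
    g <- GenomicRanges::intersect(te_granges(tes, fam), gr_enh)
    if (!length(g)) next
    hits <- GenomicRanges::findOverlaps(gr_win, g)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      gr_win[S4Vectors::queryHits(hits)], g[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg)), fam] <- agg / (2 * window)
  }
  out
}

#' Cross-species TE-coverage similarity versus divergence time
#'
#' Pairwise Spearman correlation of per-ortholog enhancer TE-coverage
#' vectors between species, then Pearson correlation of similarity versus
#' divergence time (half cophenetic distance).
#'
#' @param cov_list named list (per species) of matrices from
#'   [ortholog_enhancer_te()].
#' @param tree dated `ape::phylo`.
#' @return list with `similarity`, `r`, `p`.
#' @export
te_similarity_vs_divergence <- function(cov_list, tree) {
  sp <- names(cov_list)
  if (length(sp) < 3) stop("need >= 3 species")
  ns <- length(sp)
  sim <- matrix(1, ns, ns, dimnames = list(sp, sp))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (b <= a) next
    shared <- intersect(rownames(cov_list[[a]]), rownames(cov_list[[b]]))
    va <- as.vector(cov_list[[a]][shared, ])
    vb <- as.vector(cov_list[[b]][shared, ])
    sim[a, b] <- sim[b, a] <-
      suppressWarnings(stats::cor(va, vb, method = "spearman"))
  }
  div <- ape::cophenetic.phylo(tree)[sp, sp] / 2
  up <- upper.tri(sim)
  if (anyNA(sim[up]) || stats::sd(sim[up]) == 0)
    return(list(similarity = sim, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(sim[up], div[up])
  list(similarity = sim, r = unname(ct$estimate), p = ct$p.value)
}
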