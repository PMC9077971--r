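#' Call A/B compartments from a balanced contact matrix
#'
#' Per chromosome: the balanced intra-chromosomal map is converted to
#' observed/expected (each diagonal divided by its mean), a Pearson
#' correlation matrix is computed, and PCA is run on it. The PC1 sign is
#' oriented so that Spearman correlation between PC1 and gene density is
#' positive, and positive PC1 defines compartment A. The first 3 PCs are
#' retained for diagnostics.
#'
#' @param m a balanced `ContactMatrix` (typically 100 kb).
#' @param gene_density numeric vector aligned to `m$bins` (genes per bin).
#' @param min_bins chromosomes with fewer usable bins are skipped with a
#'   warning (default 20).
#' @return object of class `CompartmentTrack`: list with `bins`,
#'   `resolution`, `pc1`, `ab_label` ("A"/"B"/NA), `pcs` (3-column
#'   matrix), `low_confidence` (named logical per chromosome).
#' @export
call_compartments <- function(m, gene_density, min_bins = 20) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (length(gene_density) != nrow(m$bins))
    stop("gene_density must align with the bin table")
  n <- nrow(m$bins)
  pc1 <- rep(NA_real_, n)
  pcs <- matrix(NA_real_, n, 3)
  lowconf <- logical(0)
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    M <- chrom_block(m, ch, balanced = TRUE)
    use <- which(rowSums(M) > 0)
    if (length(use) < min_bins) {
      warning(sprintf("chromosome '%s': %d usable bins (< %d); skipped",
                      ch, length(use), min_bins))
      next
    }
    M <- M[use, use, drop = FALSE]
    nb <- nrow(M)
    # observed / expected by diagonal
    for (d in 1:(nb - 1)) {
      ix <- seq_len(nb - d)
      v <- M[cbind(ix, ix + d)]
      mu <- mean(v)
      if (mu > 0) {
        M[cbind(ix, ix + d)] <- v / mu
        M[cbind(ix + d, ix)] <- v / mu
      }
    }
    diag(M) <- 1  # neutral self-interaction in observed/expected units
    C <- suppressWarnings(stats::cor(M))
    # a chromosome with no variance in its O/E map has no compartment
    # signal at all: report a flat PC1 rather than an arbitrary direction
    degenerate <- !any(is.finite(C[upper.tri(C)]))
    C[!is.finite(C)] <- 0
    if (degenerate) {
      k <- 3
      sc <- matrix(0, nb, 3)
      v1 <- sc[, 1]
    } else {
      pr <- stats::prcomp(C, center = TRUE, scale. = FALSE)
      k <- min(3, ncol(pr$x))
      sc <- pr$x[, seq_len(k), drop = FALSE]
      v1 <- sc[, 1]
    }
    rho <- suppressWarnings(stats::cor(v1, gene_density[idx[use]],
                                       method = "spearman"))
    flagged <- degenerate || is.na(rho) || rho == 0 ||
      stats::sd(v1) < 1e-10
    if (!is.na(rho) && rho < 0) {
      v1 <- -v1
      sc[, 1] <- v1
    }
    pc1[idx[use]] <- v1
    pcs[idx[use], seq_len(k)] <- sc
    lowconf[ch] <- flagged
  }
  lab <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
  structure(list(bins = m$bins, resolution = m$resolution, pc1 = pc1,
                 ab_label = lab, pcs = pcs, low_confidence = lowconf),
            class = "CompartmentTrack")
}

#' AB index at fine resolution against coarse A/B labels
#'
#' For each fine bin, the relative likelihood of interacting with A- versus
#' B-labeled coarse regions on its chromosome:
#' `(meanA - meanB) / (meanA + meanB)`, where meanA (meanB) is the mean
#' normalized contact of the bin with all fine bins inside A-labeled
#' (B-labeled) coarse bins. Bounded in `[-1, 1]`; positive values classify
#' the bin as compartment A. Bins with zero contact to both classes are
#' masked.
#'
#' @param m a balanced `ContactMatrix` at fine resolution (typically
#'   20 kb).
#' @param track a `CompartmentTrack` called at coarse resolution on the
#'   same genome (or a character vector of "A"/"B" labels aligned to a
#'   coarse bin table given as `coarse_bins`).
#' @param coarse_bins coarse bin table when `track` is a bare label vector.
#' @return numeric vector aligned to `m$bins`.
#' @export
ab_index <- function(m, track, coarse_bins = NULL) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (inherits(track, "CompartmentTrack")) {
    labels <- track$ab_label
    coarse_bins <- track$bins
  } else labels <- track
  if (is.null(coarse_bins)) stop("coarse bin table required")
  mid <- (m$bins$start + m$bins$end) / 2
  fine_lab <- labels[pos_to_bin(coarse_bins, m$bins$chrom, mid)]
  out <- rep(NA_real_, nrow(m$bins))
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    M <- chrom_block(m, ch, balanced = TRUE)
    isA <- which(fine_lab[idx] == "A")
    isB <- which(fine_lab[idx] == "B")
    if (!length(isA) || !length(isB)) next
    mA <- rowMeans(M[, isA, drop = FALSE])
    mB <- rowMeans(M[, isB, drop = FALSE])
    tot <- mA + mB
    out[idx] <- ifelse(tot > 0, (mA - mB) / tot, NA_real_)
  }
  out
}

#' Sliding-square insulation score
#'
#' For each bin, the mean contact in the square window spanning `window`
#' upstream x `window` downstream of the bin, log2-scaled relative to the
#' chromosome mean of those window values. Minima mark insulating
#' boundaries.
#'
#' @param m a balanced `ContactMatrix` (typically 20 kb).
#' @param window one-sided window in bp (default 500 kb).
#' @return object of class `ISTrack`: list with `bins`, `resolution`,
#'   `is_value` (NA near chromosome edges and for empty windows).
#' @export
insulation_score <- function(m, window = 5e5) {
  stopifnot(inherits(m, "ContactMatrix"))
  w <- round(window / m$resolution)
  if (w < 1) stop("window smaller than one bin")
  val <- rep(NA_real_, nrow(m$bins))
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    M <- chrom_block(m, ch, balanced = TRUE)
    nb <- nrow(M)
    if (nb < 2 * w + 1) next
    raw <- rep(NA_real_, nb)
    for (i in (w + 1):(nb - w))
      raw[i] <- mean(M[(i - w):(i - 1), (i + 1):(i + w)])
    mu <- mean(raw[raw > 0], na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) next
    val[idx] <- ifelse(!is.na(raw) & raw > 0, log2(raw / mu), NA_real_)
  }
  structure(list(bins = m$bins, resolution = m$resolution, is_value = val),
            class = "ISTrack")
}

cosine_sim <- function(a, b) {
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# k-means++ seeding with fixed RNG state
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- numeric(K)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - X[rep(centers[1], n), , drop = FALSE])^2)
  for (k in 2:K) {
    p <- d2 / sum(d2)
    centers[k] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums((X - X[rep(centers[k], n), , drop = FALSE])^2))
  }
  X[centers, , drop = FALSE]
}

#' Cluster aligned multi-species tracks into conserved-state groups
#'
#' K-means (k-means++ seeding, fixed seed) on per-bin cross-species value
#' vectors, followed by merging of states whose mean vectors are mutually
#' similar: a state joins the first existing group in state-index order
#' for which ALL pairwise cosine similarities with the group's member
#' states are >= `cos_threshold` (strict threshold: 0.84 stays separate).
#' Groups are classified by sign pattern of the member-state means:
#' with `mode = "ab"`, CA if positive in every species, CB if negative,
#' else NC; with `mode = "is"`, values are first centered on the
#' per-species median and classes are CHI / CLI / AI.
#'
#' @param aligned numeric matrix, aligned bins x species.
#' @param K number of states (default 30).
#' @param seed integer seed.
#' @param cos_threshold cosine similarity required within a group
#'   (default 0.85).
#' @param mode "ab" (compartment sign) or "is" (insulation level).
#' @param bin_mb size of one aligned bin in Mb (default 0.1).
#' @return object of class `StateAssignment`: list with `state` (per-bin
#'   state id), `centers`, `state_group`, `state_class`, `bin_class`,
#'   `groups` (per-class Mb and percentage), `mode`, `bin_mb`.
#' @export
cluster_states <- function(aligned, K = 30, seed = 1, cos_threshold = 0.85,
                           mode = c("ab", "is"), bin_mb = 0.1) {
  mode <- match.arg(mode)
  aligned <- as.matrix(aligned)
  if (K < 1) stop("K must be >= 1")
  X <- aligned
  if (mode == "is")
    X <- sweep(X, 2, apply(X, 2, stats::median, na.rm = TRUE))
  keep <- stats::complete.cases(X)
  Xc <- X[keep, , drop = FALSE]
  if (nrow(unique(Xc)) < K)
    stop("K exceeds the number of distinct aligned bins")
  set.seed(seed)
  km <- stats::kmeans(Xc, centers = kmeanspp_centers(Xc, K), iter.max = 100)
  centers <- km$centers
  # greedy cosine grouping in state-index order
  groups <- list()
  state_group <- integer(K)
  for (s in seq_len(K)) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(vapply(groups[[gi]], function(t)
        cosine_sim(centers[s, ], centers[t, ]) >= cos_threshold,
        logical(1)))) {
        groups[[gi]] <- c(groups[[gi]], s)
        state_group[s] <- gi
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- s
      state_group[s] <- length(groups)
    }
  }
  pos_lab <- if (mode == "ab") "CA" else "CHI"
  neg_lab <- if (mode == "ab") "CB" else "CLI"
  amb_lab <- if (mode == "ab") "NC" else "AI"
  group_class <- vapply(groups, function(members) {
    gm <- centers[members, , drop = FALSE]
    if (all(gm > 0)) pos_lab else if (all(gm < 0)) neg_lab else amb_lab
  }, character(1))
  state_class <- group_class[state_group]
  state <- rep(NA_integer_, nrow(aligned))
  state[keep] <- km$cluster
  bin_class <- rep(NA_character_, nrow(aligned))
  bin_class[keep] <- state_class[km$cluster]
  mb <- vapply(c(pos_lab, neg_lab, amb_lab), function(cl)
    sum(bin_class == cl, na.rm = TRUE) * bin_mb, numeric(1))
  gr <- data.frame(class = names(mb), mb = as.numeric(mb),
                   pct = round(100 * as.numeric(mb) / sum(mb), 2))
  structure(list(state = state, centers = centers,
                 state_group = state_group, state_class = state_class,
                 bin_class = bin_class, groups = gr, mode = mode,
                 bin_mb = bin_mb, note = "state grouping by K-means + cosine similarity"),
            class = "StateAssignment")
}

#' Percentage summary of conserved-state groups
#'
#' @param x a `StateAssignment`, or a named numeric vector of Mb totals.
#' @param total_mb denominator in Mb (defaults to the sum of group Mb).
#' @return data.frame with `class`, `mb`, `pct` (2 decimal places).
#' @export
group_summary <- function(x, total_mb = NULL) {
  mb <- if (inherits(x, "StateAssignment"))
    setNames(x$groups$mb, x$groups$class) else x
  if (is.null(total_mb)) total_mb <- sum(mb)
  if (sum(mb) > total_mb * (1 + 1e-9))
    stop("group Mb totals exceed total_mb")
  data.frame(class = names(mb), mb = as.numeric(mb),
             pct = round(100 * as.numeric(mb) / total_mb, 2),
             row.names = NULL)
}

#' Consistency of conserved states with independent tracks
#'
#' For each additional track (e.g. another tissue's AB index or insulation
#' score), computes the fraction of conserved-positive bins (CA or CHI)
#' with positive track values and conserved-negative bins (CB or CLI) with
#' negative values, compares to a permutation control in which track
#' values are randomly reassigned across bins, and tests observed versus
#' control fractions with a two-sided Wilcoxon rank-sum test.
#'
#' @param conserved a `StateAssignment`.
#' @param other_tracks list of numeric vectors aligned to the assignment's
#'   bins.
#' @param n_perm permutations per track (warning below 10).
#' @param seed integer seed.
#' @return list with `observed` (per track), `control` (per track x perm),
#'   `p_value`.
#' @export
cross_tissue_consistency <- function(conserved, other_tracks, n_perm = 20,
                                     seed = 1) {
  stopifnot(inherits(conserved, "StateAssignment"))
  if (n_perm < 10) warning("n_perm < 10: permutation p-value is unstable")
  set.seed(seed)
  pos_lab <- if (conserved$mode == "ab") "CA" else "CHI"
  neg_lab <- if (conserved$mode == "ab") "CB" else "CLI"
  pos <- which(conserved$bin_class == pos_lab)
  neg <- which(conserved$bin_class == neg_lab)
  retention <- function(v) {
    ok <- c(v[pos] > 0, v[neg] < 0)
    mean(ok, na.rm = TRUE)
  }
  observed <- vapply(other_tracks, retention, numeric(1))
  control <- sapply(other_tracks, function(v)
    vapply(seq_len(n_perm), function(i) retention(sample(v)), numeric(1)))
  p <- stats::wilcox.test(observed, as.numeric(control), exact = FALSE)$p.value
  list(observed = observed, control = control, p_value = p)
}

#' Cross-species track similarity versus divergence time
#'
#' Pairwise cosine similarity between per-species track vectors, an
#' average-linkage clustering tree on 1 - similarity, and the Pearson
#' correlation between pairwise similarity and divergence time (half the
#' cophenetic distance on the dated phylogeny).
#'
#' @param tracks numeric matrix, bins x species (columns named by tip
#'   label).
#' @param tree `ape::phylo` with branch lengths in MYA.
#' @return list with `similarity`, `hclust`, `r`, `p` (`r` is NA when all
#'   similarities are equal).
#' @export
similarity_vs_divergence <- function(tracks, tree) {
  tracks <- as.matrix(tracks)
  sp <- colnames(tracks)
  if (length(sp) < 3) stop("need >= 3 species")
  keep <- stats::complete.cases(tracks)
  X <- tracks[keep, , drop = FALSE]
  ns <- length(sp)
  sim <- matrix(1, ns, ns, dimnames = list(sp, sp))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (b <= a) next
    sim[a, b] <- sim[b, a] <- cosine_sim(X[, a], X[, b])
  }
  div <- ape::cophenetic.phylo(tree)[sp, sp] / 2
  up <- upper.tri(sim)
  r <- NA_real_; p <- NA_real_
  if (stats::sd(sim[up]) > 0 && stats::sd(div[up]) > 0) {
    ct <- stats::cor.test(sim[up], div[up])
    r <- unname(ct$estimate); p <- ct$p.value
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  list(similarity = sim, hclust = hc, r = r, p = p)
}
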