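#' Iterative correction (matrix balancing) of a contact matrix
#'
#' Sinkhorn-style iterative correction: low-coverage bins (bottom
#' `low_coverage_quantile` of nonzero marginals, plus zero-marginal bins)
#' are masked, then per-bin weights are iterated until every retained row's
#' balanced marginal equals the mean marginal within `tol` relative
#' tolerance. Masked bins get weight NA and are excluded from all
#' downstream statistics.
#'
#' @param m a `ContactMatrix` with nonnegative counts.
#' @param max_iter maximum number of iterations.
#' @param tol relative tolerance on marginal flatness (> 0).
#' @param low_coverage_quantile fraction of lowest-coverage nonzero bins to
#'   mask (default 0.02, standard ICE practice).
#' @return the matrix with `weights` set; attribute `converged` is FALSE
#'   (with a warning) if `max_iter` was exhausted.
#' @export
iterative_correction <- function(m, max_iter = 200, tol = 1e-4,
                                 low_coverage_quantile = 0.02) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (tol <= 0) stop("tol must be positive")
  marg <- Matrix::rowSums(m$counts)
  mask <- marg == 0
  nz <- marg[!mask]
  if (low_coverage_quantile > 0 && length(nz)) {
    cut <- quantile(nz, low_coverage_quantile)
    mask <- mask | marg < cut
  }
  w <- ifelse(mask, 0, 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cts <- m$counts
    cts@x <- cts@x * (w[cts@i + 1L] * w[rep.int(seq_len(ncol(cts)), diff(cts@p))])
    s <- Matrix::rowSums(cts)
    sk <- s[!mask]
    mu <- mean(sk)
    dev <- max(abs(sk - mu) / mu)
    if (dev < tol) { converged <- TRUE; break }
    adj <- rep(1, length(w))
    adj[!mask] <- sk / mu
    w <- w / sqrt(adj)
  }
  if (!converged)
    warning(sprintf("iterative correction did not converge in %d iterations (dev %.2g)",
                    max_iter, dev))
  w[mask] <- NA
  out <- m
  out$weights <- w
  attr(out, "converged") <- converged
  out
}

#' Distance-stratified quantile normalization across samples
#'
#' For every intra-chromosomal genomic-distance stratum (one stratum per
#' resolution step), the nonzero contact values of each sample are replaced
#' by the rank-matched mean quantile across samples, so samples become
#' comparable without disturbing the distance decay. Inter-chromosomal
#' counts are normalized as a single stratum.
#'
#' @param samples list of >= 2 `ContactMatrix` objects with identical bin
#'   tables.
#' @return list of normalized `ContactMatrix` objects.
#' @export
quantile_normalize <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 samples to quantile-normalize")
  ref <- samples[[1]]
  for (s in samples[-1])
    if (!same_bin_table(ref, s)) stop("bin tables differ between samples")
  res <- ref$resolution
  trips <- lapply(samples, function(s) {
    tt <- methods::as(Matrix::triu(s$counts), "TsparseMatrix")
    d <- ifelse(s$bins$chrom[tt@i + 1L] == s$bins$chrom[tt@j + 1L],
                tt@j - tt@i, -1L)
    list(i = tt@i + 1L, j = tt@j + 1L, x = tt@x, d = d)
  })
  strata <- sort(unique(unlist(lapply(trips, `[[`, "d"))))
  for (d in strata) {
    vals <- lapply(trips, function(t) t$x[t$d == d])
    if (all(lengths(vals) == 0)) next
    norm <- quantile_match(vals)
    for (k in seq_along(trips))
      trips[[k]]$x[trips[[k]]$d == d] <- norm[[k]]
  }
  lapply(seq_along(samples), function(k) {
    t <- trips[[k]]
    off <- t$i != t$j
    n <- nrow(ref$bins)
    cts <- Matrix::sparseMatrix(i = c(t$i, t$j[off]), j = c(t$j, t$i[off]),
                                x = c(t$x, t$x[off]), dims = c(n, n))
    contact_matrix(cts, ref$bins, res)
  })
}

# replace each sample's values by the mean quantile across samples at the
# same plotting position (rank - 0.5)/n; with equal counts this is exactly
# the mean of order statistics.
quantile_match <- function(vals) {
  nz <- which(lengths(vals) > 0)
  lapply(seq_along(vals), function(k) {
    v <- vals[[k]]
    if (!length(v)) return(v)
    p <- (rank(v, ties.method = "average") - 0.5) / length(v)
    cols <- vapply(nz, function(t)
      quantile(vals[[t]], probs = p, type = 5, names = FALSE),
      numeric(length(v)))
    if (length(v) == 1) mean(cols) else rowMeans(matrix(cols, nrow = length(v)))
  })
}

#' Stratum-adjusted correlation coefficient (SCC) between two contact maps
#'
#' Reproducibility measure for Hi-C: per chromosome, both matrices are
#' smoothed with a (2h+1)-bin mean filter, contacts are stratified by
#' genomic distance up to `max_dist`, a Pearson correlation is computed per
#' stratum, and the SCC is the stratum-size-and-variance weighted average
#' of the stratum correlations. The aggregate is the median across
#' chromosomes.
#'
#' @param a,b `ContactMatrix` objects on the same bin table.
#' @param h half-width (bins) of the smoothing window (default 1).
#' @param max_dist maximum genomic separation (bp) to include.
#' @return list with `per_chrom` (named vector of per-chromosome SCC) and
#'   `aggregate` (median).
#' @export
scc <- function(a, b, h = 1, max_dist = 5e6) {
  stopifnot(inherits(a, "ContactMatrix"), inherits(b, "ContactMatrix"))
  if (!same_bin_table(a, b)) stop("bin tables differ")
  res <- a$resolution
  dmax <- floor(max_dist / res)
  chroms <- unique(a$bins$chrom)
  per <- vapply(chroms, function(ch) {
    A <- smooth2d(chrom_block(a, ch, balanced = FALSE), h)
    B <- smooth2d(chrom_block(b, ch, balanced = FALSE), h)
    nb <- nrow(A)
    ds <- seq_len(min(dmax, nb - 2))
    num <- 0; den <- 0
    for (d in ds) {
      ix <- seq_len(nb - d)
      x <- A[cbind(ix, ix + d)]
      y <- B[cbind(ix, ix + d)]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- stats::cor(x, y)
      w <- length(x) * sqrt(stats::var(x) * stats::var(y))
      num <- num + w * r
      den <- den + w
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  names(per) <- chroms
  if (all(is.na(per))) stop("no usable distance strata for SCC")
  list(per_chrom = per, aggregate = median(per, na.rm = TRUE))
}

# (2h+1) x (2h+1) box mean filter via integral image; windows are
# truncated (and renormalized) at matrix edges
smooth2d <- function(M, h) {
  if (h <= 0) return(M)
  n <- nrow(M)
  CS <- matrix(0, n + 1, n + 1)
  CS[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  I1 <- pmax(seq_len(n) - h, 1)
  I2 <- pmin(seq_len(n) + h, n)
  num <- CS[I2 + 1, I2 + 1] - CS[I1, I2 + 1] - CS[I2 + 1, I1] + CS[I1, I1]
  num / outer(I2 - I1 + 1, I2 - I1 + 1)
}

#' Contact-decay curve P(s) and its log-log slope
#'
#' Mean normalized contact frequency per genomic-distance stratum (one
#' stratum per resolution step), normalized per chromosome so P sums to 1
#' over strata, then averaged across all chromosomes. The slope is the
#' least-squares slope of log10 P versus log10 s within `fit_range`.
#'
#' @param m a `ContactMatrix` (balanced if weights present).
#' @param fit_range bp pair, default 1-10 Mb (the long-range window).
#' @param balanced use balancing weights if present.
#' @return object of class `PsCurve`: list with `distances` (bp,
#'   stratum midpoints), `probability`, `fit_range`, `slope`.
#' @export
ps_curve <- function(m, fit_range = c(1e6, 1e7), balanced = TRUE) {
  stopifnot(inherits(m, "ContactMatrix"))
  res <- m$resolution
  chroms <- unique(m$bins$chrom)
  dmax <- max(table(m$bins$chrom)) - 1
  acc <- matrix(0, dmax, length(chroms))
  for (ci in seq_along(chroms)) {
    M <- chrom_block(m, chroms[ci], balanced = balanced)
    nb <- nrow(M)
    if (nb < 3) next
    pd <- vapply(seq_len(nb - 1), function(d)
      mean(M[cbind(seq_len(nb - d), seq_len(nb - d) + d)]), numeric(1))
    tot <- sum(pd)
    if (tot > 0) acc[seq_len(nb - 1), ci] <- pd / tot
  }
  p <- rowMeans(acc, na.rm = TRUE)
  s <- seq_len(dmax) * res
  inr <- which(s >= fit_range[1] & s <= fit_range[2] & p > 0)
  if (length(inr) < 5)
    stop("fewer than 5 usable strata in fit range; slope undefined")
  fit <- stats::lm(log10(p[inr]) ~ log10(s[inr]))
  structure(list(distances = s, probability = p, fit_range = fit_range,
                 slope = unname(stats::coef(fit)[2])), class = "PsCurve")
}

#' @export
print.PsCurve <- function(x, ...) {
  cat(sprintf("PsCurve: %d strata, fit %g-%g bp, slope %.4f\n",
              length(x$distances), x$fit_range[1], x$fit_range[2], x$slope))
  invisible(x)
}

#' Summarize a genome's chromosome lengths
#'
#' Per-chromosome lengths (Mb), the mean autosome length, and all pairwise
#' longer/shorter length ratios rounded to 2 decimal places.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @return list with `lengths_mb`, `mean_mb` and a `ratios` data.frame
#'   (chromA = longer, chromB = shorter, ratio >= 1).
#' @export
genome_summary <- function(genome) {
  if (!length(genome)) stop("empty genome")
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  mb <- genome / 1e6
  ratios <- NULL
  if (length(genome) > 1) {
    pr <- utils::combn(names(genome), 2)
    ratios <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      a <- pr[1, k]; b <- pr[2, k]
      if (mb[[a]] < mb[[b]]) { tmp <- a; a <- b; b <- tmp }
      data.frame(chromA = a, chromB = b,
                 ratio = round(mb[[a]] / mb[[b]], 2),
                 stringsAsFactors = FALSE)
    }))
  }
  list(lengths_mb = mb, mean_mb = mean(mb), ratios = ratios)
}
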