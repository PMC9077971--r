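#' 3D convex hull volume and surface area
#'
#' Incremental convex hull of a 3D point cloud. Returns the hull's volume,
#' surface area and the indices of its vertices. Requires at least 4
#' non-coplanar points.
#'
#' @param pts numeric matrix (n x 3) of point coordinates.
#' @return list with `volume`, `surface`, `vertices` (row indices of hull
#'   vertices), `faces` (matrix of vertex-index triples).
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("points must be n x 3")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) stop("need >= 4 distinct points for a 3D hull")
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  if (scale == 0) stop("degenerate point cloud (all points identical)")
  tol <- 1e-9 * scale^2

  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])

  # initial tetrahedron: farthest point pairs, then max area, then max volume
  d1 <- which.max(rowSums((pts - pts[rep(1, n), ])^2))
  d2 <- which.max(rowSums((pts - pts[rep(d1, n), ])^2))
  ab <- pts[d2, ] - pts[d1, ]
  areas <- vapply(seq_len(n), function(i)
    sum(cross3(ab, pts[i, ] - pts[d1, ])^2), numeric(1))
  d3 <- which.max(areas)
  if (areas[d3] <= tol^2) stop("degenerate hull: points are collinear")
  nrm <- cross3(ab, pts[d3, ] - pts[d1, ])
  vols <- abs(as.vector(sweep(pts, 2, pts[d1, ]) %*% nrm))
  d4 <- which.max(vols)
  if (vols[d4] <= tol * scale) stop("degenerate hull: points are coplanar")

  c0 <- colMeans(pts[c(d1, d2, d3, d4), ])
  orient <- function(f) {
    v1 <- pts[f[1], ]; nf <- cross3(pts[f[2], ] - v1, pts[f[3], ] - v1)
    if (sum(nf * (c0 - v1)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(rbind(c(d1, d2, d3), c(d1, d2, d4),
                         c(d1, d3, d4), c(d2, d3, d4)), 1, orient))

  face_normal <- function(f) {
    v1 <- pts[f[1], ]
    cross3(pts[f[2], ] - v1, pts[f[3], ] - v1)
  }
  rest <- setdiff(seq_len(n), c(d1, d2, d3, d4))
  for (p in rest) {
    vis <- vapply(seq_len(nrow(faces)), function(k) {
      f <- faces[k, ]
      sum(face_normal(f) * (pts[p, ] - pts[f[1], ])) > tol
    }, logical(1))
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    ed <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horizon <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newf <- t(apply(horizon, 1, function(e) orient(c(e[1], e[2], p))))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
  }

  vol <- 0; surf <- 0
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    v1 <- pts[f[1], ] - c0; v2 <- pts[f[2], ] - c0; v3 <- pts[f[3], ] - c0
    nf <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    surf <- surf + sqrt(sum(nf^2)) / 2
    vol <- vol + abs(sum(v1 * cross3(v2, v3))) / 6
  }
  list(volume = vol, surface = surf, vertices = sort(unique(as.vector(faces))),
       faces = faces)
}

#' Embed one chromosome in 3D from its contact map
#'
#' Converts balanced contacts to distances `d_ij = c_ij^(-alpha)` for
#' nonzero contacts, completes missing distances by shortest paths, and
#' embeds the distance matrix in 3D by classical metric multidimensional
#' scaling. Contacts are rescaled by a single genome-wide mean
#' (`contact_scale`), so models of different chromosomes from the same
#' matrix share one contact-to-distance calibration and their territory
#' metrics are comparable. The returned model is centered at the origin.
#'
#' @param m a balanced `ContactMatrix`.
#' @param chrom chromosome name.
#' @param alpha contact-to-distance exponent (> 0, default 0.25).
#' @param min_bins minimum number of bins with signal (default 10).
#' @param contact_scale reference contact level mapping to unit distance;
#'   defaults to the mean nonzero balanced intra-chromosomal contact of
#'   the whole matrix.
#' @return object of class `ChromosomeModel`: list with `coords`
#'   (bins x 3 matrix in genomic order), `chrom`, `length_mb`, `bins_used`.
#' @export
embed_chromosome <- function(m, chrom, alpha = 0.25, min_bins = 10,
                             contact_scale = NULL) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (alpha <= 0) stop("alpha must be positive (degenerate distance map)")
  if (is.null(contact_scale)) {
    vals <- unlist(lapply(unique(m$bins$chrom), function(ch) {
      B <- chrom_block(m, ch, balanced = TRUE)
      B[B > 0]
    }))
    contact_scale <- mean(vals)
  }
  M <- chrom_block(m, chrom, balanced = TRUE)
  use <- which(rowSums(M) > 0)
  if (length(use) < min_bins)
    stop(sprintf("chromosome '%s' has %d bins with signal (< %d)",
                 chrom, length(use), min_bins))
  M <- M[use, use, drop = FALSE]
  nb <- nrow(M)
  cmean <- contact_scale
  D <- matrix(NA_real_, nb, nb)
  nz <- M > 0
  D[nz] <- (M[nz] / cmean)^(-alpha)
  diag(D) <- 0
  # shortest-path completion for unobserved pairs
  if (any(is.na(D))) {
    idx <- which(nz & upper.tri(nz), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = idx[, 1], to = idx[, 2], weight = D[idx]),
      directed = FALSE, vertices = data.frame(name = seq_len(nb)))
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    ord <- as.integer(igraph::V(g)$name)
    sp <- sp[order(ord), order(ord)]
    if (any(is.infinite(sp))) {
      comp <- igraph::components(g)
      small <- which(comp$membership != which.max(comp$csize))
      stop(sprintf("contact graph of '%s' is disconnected; isolated segment at bins %s",
                   chrom, paste(ord[small][seq_len(min(5, length(small)))],
                                collapse = ", ")))
    }
    D[is.na(D)] <- sp[is.na(D)]
  }
  xyz <- stats::cmdscale(stats::as.dist(D), k = 3)
  if (ncol(xyz) < 3)
    xyz <- cbind(xyz, matrix(0, nrow(xyz), 3 - ncol(xyz)))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  len_mb <- (max(m$bins$end[m$bins$chrom == chrom])) / 1e6
  structure(list(coords = xyz, chrom = chrom, length_mb = len_mb,
                 bins_used = use),
            class = "ChromosomeModel")
}

#' Chromosome territory metrics from a 3D model
#'
#' Convex-hull volume and surface of the model, the volume-to-surface
#' ratio (VSR) and volume per Mb (VpM), and their reciprocals: stretchiness
#' (1/VSR; a sphere minimizes surface for fixed volume, so higher values
#' mean a more stretched territory) and condensation (1/VpM; higher values
#' mean more condensed chromatin).
#'
#' @param model a `ChromosomeModel`, or a bare n x 3 coordinate matrix plus
#'   `length_mb`.
#' @param length_mb chromosome length in Mb (taken from the model if
#'   omitted).
#' @return list with `volume`, `surface`, `vsr`, `vpm`, `stretchiness`,
#'   `condensation`, `chrom`, `length_mb`.
#' @export
ct_metrics <- function(model, length_mb = NULL) {
  if (inherits(model, "ChromosomeModel")) {
    pts <- model$coords
    if (is.null(length_mb)) length_mb <- model$length_mb
    chrom <- model$chrom
  } else {
    pts <- as.matrix(model)
    chrom <- NA_character_
    if (is.null(length_mb)) stop("length_mb required for bare coordinates")
  }
  hull <- convex_hull_3d(pts)
  vsr <- hull$volume / hull$surface
  vpm <- hull$volume / length_mb
  list(volume = hull$volume, surface = hull$surface, vsr = vsr, vpm = vpm,
       stretchiness = 1 / vsr, condensation = 1 / vpm,
       chrom = chrom, length_mb = length_mb)
}

#' Correlate chromosome length with territory metrics
#'
#' Spearman correlation of chromosome length versus stretchiness (expected
#' negative: longer chromosomes are less stretched) and versus condensation
#' (expected positive), with p-values.
#'
#' @param models list of `ChromosomeModel` objects (>= 3), or a data.frame
#'   with columns `length_mb`, `stretchiness`, `condensation`.
#' @return list with `table` and `stretchiness` / `condensation`
#'   sublists (`rho`, `p`), NA when undefined (e.g. zero variance).
#' @export
length_scaling <- function(models) {
  tab <- if (is.data.frame(models)) models else
    do.call(rbind, lapply(models, function(mod) {
      met <- ct_metrics(mod)
      data.frame(chrom = met$chrom, length_mb = met$length_mb,
                 stretchiness = met$stretchiness,
                 condensation = met$condensation)
    }))
  if (nrow(tab) < 3) stop("need >= 3 chromosomes")
  cor_or_na <- function(y) {
    if (stats::sd(tab$length_mb) == 0 || stats::sd(y) == 0)
      return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(tab$length_mb, y,
                                           method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(table = tab,
       stretchiness = cor_or_na(tab$stretchiness),
       condensation = cor_or_na(tab$condensation))
}
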