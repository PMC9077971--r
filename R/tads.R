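#' Directionality index of a contact matrix
#'
#' For each bin, with A the contact sum to the upstream window and B the
#' contact sum to the downstream window (each `window` bp wide, truncated
#' at chromosome ends) and E = (A+B)/2, the directionality index is
#' `DI = sign(B - A) * ((A-E)^2/E + (B-E)^2/E)`, and 0 when A = B
#' (including the empty case). Positive DI marks downstream bias (domain
#' starts), negative DI upstream bias (domain ends).
#'
#' @param m a balanced `ContactMatrix` (typically 20 kb).
#' @param window one-sided window in bp (default 2 Mb).
#' @return object of class `DITrack`: list with `bins`, `resolution`,
#'   `window`, `di`.
#' @export
directionality_index <- function(m, window = 2e6) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (window < 2 * m$resolution)
    stop("window must be at least twice the resolution")
  w <- round(window / m$resolution)
  di <- rep(0, nrow(m$bins))
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    M <- chrom_block(m, ch, balanced = TRUE)
    nb <- nrow(M)
    for (i in seq_len(nb)) {
      # windows truncated symmetrically near chromosome ends, so edge bins
      # are not biased toward the longer side
      we <- min(w, i - 1, nb - i)
      if (we < 1) { di[idx[i]] <- 0; next }
      A <- sum(M[i, seq(i - we, i - 1)])
      B <- sum(M[i, seq(i + 1, i + we)])
      E <- (A + B) / 2
      di[idx[i]] <- if (E == 0 || A == B) 0 else
        sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
  }
  structure(list(bins = m$bins, resolution = m$resolution, window = window,
                 di = di), class = "DITrack")
}

run_lengths <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Call TADs from a directionality-index track
#'
#' A 3-state Gaussian-emission HMM (downstream-bias / none / upstream-bias)
#' is fitted to the DI by EM with several restarts and decoded by Viterbi.
#' Runs of fewer than `min_run` consecutive biased bins are treated as
#' unbiased (noise guard). A domain runs from the start of a
#' downstream-bias run to the end of the following upstream-bias run.
#' Gaps between consecutive domains shorter than `gap_threshold` are
#' topological boundaries; longer gaps are unorganized chromatin.
#'
#' @param di a `DITrack`.
#' @param min_run minimum consecutive biased bins to open/close a domain
#'   (default 2).
#' @param gap_threshold bp separating boundaries from unorganized chromatin
#'   (default 400 kb).
#' @param seed integer seed for the EM restarts.
#' @return object of class `TadSet`: list with `domains`, `boundaries`
#'   (with midpoints), `unorganized`, `resolution`.
#' @export
call_tads <- function(di, min_run = 2, gap_threshold = 4e5, seed = 1) {
  stopifnot(inherits(di, "DITrack"))
  bins <- di$bins
  res <- di$resolution
  chroms <- unique(bins$chrom)
  empty <- function()
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  if (stats::sd(di$di) == 0) {
    return(structure(list(domains = empty(),
                          boundaries = cbind(empty(), mid = numeric()),
                          unorganized = do.call(rbind, lapply(chroms, function(ch)
                            data.frame(chrom = ch, start = 0,
                                       end = max(bins$end[bins$chrom == ch])))),
                          resolution = res),
                     class = "TadSet"))
  }
  # classify on a signed-log transform standardized by the MAD: compresses
  # the chi-square-like heavy tails of the DI so the Gaussian emissions
  # separate by sign, and makes the call exactly invariant to global
  # rescaling of the DI
  scale0 <- stats::mad(di$di[di$di != 0])
  if (!is.finite(scale0) || scale0 == 0) scale0 <- stats::sd(di$di)
  tf <- function(x) sign(x) * log1p(abs(x) / scale0)
  seqs <- lapply(chroms, function(ch) tf(di$di[bins$chrom == ch]))
  fit <- fit_gaussian_hmm(seqs, n_states = 3, seed = seed)
  ord <- order(fit$mu)  # 1 = upstream-bias (lowest mu), 3 = downstream-bias
  state_of <- integer(3); state_of[ord] <- c(-1L, 0L, 1L)
  domains <- list(); extra <- list()
  for (ch in chroms) {
    x <- tf(di$di[bins$chrom == ch])
    st <- state_of[hmm_viterbi(x, fit)]
    runs <- run_lengths(st)
    runs$value[runs$value != 0 & runs$length < min_run] <- 0L
    runs <- runs[runs$value != 0, , drop = FALSE]
    # a domain opens at a downstream-bias run and closes at the end of the
    # last upstream-bias run before the next downstream onset (upstream
    # bias near a TAD end is often split into several runs by noise)
    open_start <- NA_integer_; last_u_end <- NA_integer_
    close_domain <- function() {
      if (!is.na(open_start) && !is.na(last_u_end))
        domains[[length(domains) + 1]] <<- data.frame(
          chrom = ch, start = (open_start - 1) * res,
          end = last_u_end * res, stringsAsFactors = FALSE)
    }
    if (nrow(runs)) for (k in seq_len(nrow(runs))) {
      if (runs$value[k] == 1L) {
        if (!is.na(last_u_end)) {
          close_domain()
          open_start <- runs$start[k]; last_u_end <- NA_integer_
        } else if (is.na(open_start)) open_start <- runs$start[k]
      } else if (!is.na(open_start)) last_u_end <- runs$end[k]
      else extra[[length(extra) + 1]] <- data.frame(
        chrom = ch, mid = runs$end[k] * res)  # orphan upstream run: its end marks a boundary with a missed downstream onset
    }
    if (!is.na(open_start) && is.na(last_u_end))
      extra[[length(extra) + 1]] <- data.frame(
        chrom = ch, mid = (open_start - 1) * res)  # unclosed domain: keep its start edge
    close_domain()
  }
  domains <- if (length(domains)) do.call(rbind, domains) else empty()
  boundaries <- list(); unorg <- list()
  for (ch in chroms) {
    len <- max(bins$end[bins$chrom == ch])
    dch <- domains[domains$chrom == ch, , drop = FALSE]
    if (nrow(dch) == 0) {
      unorg[[length(unorg) + 1]] <- data.frame(chrom = ch, start = 0, end = len)
      next
    }
    gs <- c(0, dch$end); ge <- c(dch$start, len)
    for (k in seq_along(gs)) {
      w <- ge[k] - gs[k]
      between <- k > 1 && k < length(gs)
      if (w < gap_threshold && (between || w > 0)) {
        boundaries[[length(boundaries) + 1]] <- data.frame(
          chrom = ch, start = gs[k], end = ge[k],
          mid = if (between && w > 0)
            refine_boundary(di, ch, gs[k], ge[k]) else (gs[k] + ge[k]) / 2)
      } else if (w > 0) {
        unorg[[length(unorg) + 1]] <- data.frame(
          chrom = ch, start = gs[k], end = ge[k])
        # domain edges facing unorganized chromatin are boundaries too
        if (k > 1)
          boundaries[[length(boundaries) + 1]] <- data.frame(
            chrom = ch, start = gs[k], end = gs[k], mid = gs[k])
        if (k < length(gs))
          boundaries[[length(boundaries) + 1]] <- data.frame(
            chrom = ch, start = ge[k], end = ge[k], mid = ge[k])
      }
    }
  }
  bnd <- if (length(boundaries)) do.call(rbind, boundaries) else
    cbind(empty(), mid = numeric())
  if (length(extra)) {
    ex <- do.call(rbind, extra)
    # keep only orphan boundaries not already represented within one bin
    novel <- vapply(seq_len(nrow(ex)), function(i) {
      near <- bnd$mid[bnd$chrom == ex$chrom[i]]
      !length(near) || min(abs(near - ex$mid[i])) > res
    }, logical(1))
    if (any(novel))
      bnd <- rbind(bnd, data.frame(chrom = ex$chrom[novel],
                                   start = ex$mid[novel], end = ex$mid[novel],
                                   mid = ex$mid[novel]))
    bnd <- bnd[order(bnd$chrom, bnd$mid), ]
    rownames(bnd) <- NULL
  }
  structure(list(
    domains = domains,
    boundaries = bnd,
    unorganized = if (length(unorg)) do.call(rbind, unorg) else empty(),
    resolution = res), class = "TadSet")
}

#' @export
print.TadSet <- function(x, ...) {
  cat(sprintf("TadSet: %d domains (mean %.0f kb), %d boundaries, %d unorganized gaps\n",
              nrow(x$domains),
              if (nrow(x$domains)) mean(x$domains$end - x$domains$start) / 1e3 else 0,
              nrow(x$boundaries), nrow(x$unorganized)))
  invisible(x)
}

# place the boundary at the best DI sign changepoint inside an
# inter-domain gap: upstream bias (DI < 0) belongs to the left domain,
# downstream bias (DI > 0) to the right one
refine_boundary <- function(di, ch, lo, hi) {
  res <- di$resolution
  i0 <- round(lo / res); i1 <- round(hi / res)
  idx <- which(di$bins$chrom == ch)
  x <- di$di[idx]
  cands <- i0:i1
  score <- vapply(cands, function(p) {
    left <- if (p > i0) x[(i0 + 1):p] else numeric(0)
    right <- if (p < i1) x[(p + 1):i1] else numeric(0)
    sum(left < 0) + sum(right > 0)
  }, numeric(1))
  cands[which.max(score)] * res
}

#' Mean insulation profile around boundary classes
#'
#' For each boundary class, the mean insulation score per offset bin in a
#' +/- `flank` window around boundary midpoints.
#'
#' @param is_track an `ISTrack`.
#' @param boundaries data.frame with columns `chrom`, `mid` and optionally
#'   `class` (single class assumed if absent).
#' @param flank one-sided flank in bp (multiple of the track resolution).
#' @return matrix offsets x classes of mean insulation score.
#' @export
insulation_profile <- function(is_track, boundaries, flank = 3e5) {
  stopifnot(inherits(is_track, "ISTrack"))
  res <- is_track$resolution
  if (flank %% res != 0) stop("flank must be a multiple of the resolution")
  if (!nrow(boundaries)) {
    warning("no boundaries; empty profile")
    return(matrix(numeric(0), 0, 0))
  }
  if (is.null(boundaries$class)) boundaries$class <- "all"
  offs <- seq(-flank, flank, by = res)
  classes <- unique(boundaries$class)
  out <- matrix(NA_real_, length(offs), length(classes),
                dimnames = list(offs, classes))
  for (cl in classes) {
    bd <- boundaries[boundaries$class == cl, , drop = FALSE]
    if (!nrow(bd)) { warning(sprintf("class '%s' has no boundaries", cl)); next }
    vals <- sapply(seq_len(nrow(bd)), function(i) {
      b <- pos_to_bin(is_track$bins, rep(bd$chrom[i], length(offs)),
                      bd$mid[i] + offs)
      ifelse(is.na(b), NA_real_, is_track$is_value[b])
    })
    out[, cl] <- rowMeans(matrix(vals, nrow = length(offs)), na.rm = TRUE)
  }
  out
}

#' TSS density profile around boundary midpoints
#'
#' @param boundaries data.frame with `chrom` and `mid` columns.
#' @param tss data.frame with `chrom` and `pos` columns (TSS coordinates).
#' @param flank one-sided flank in bp (default 500 kb).
#' @param bin profile bin width in bp (default 10 kb).
#' @return data.frame with `offset` (bin center relative to boundary) and
#'   `density` (TSS per bin per boundary); zero rows when there are no
#'   boundaries (with a warning).
#' @export
tss_enrichment <- function(boundaries, tss, flank = 5e5, bin = 1e4) {
  if (!nrow(tss)) stop("TSS list is empty")
  if (!nrow(boundaries)) {
    warning("no boundaries; empty profile")
    return(data.frame(offset = numeric(), density = numeric()))
  }
  edges <- seq(-flank, flank, by = bin)
  counts <- numeric(length(edges) - 1)
  for (i in seq_len(nrow(boundaries))) {
    d <- tss$pos[tss$chrom == boundaries$chrom[i]] - boundaries$mid[i]
    d <- d[d >= -flank & d < flank]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges), length(edges) - 1)
  }
  data.frame(offset = edges[-length(edges)] + bin / 2,
             density = counts / nrow(boundaries))
}

#' Cross-species conservation of TAD boundaries
#'
#' Each boundary of the query species is mapped into every other species
#' through ortholog-anchor coordinate maps and compared to the nearest
#' called boundary there: a pair is conserved when the distance is below
#' `conserved_dist` (default 40 kb, 2 bins), non-conserved above
#' `nonconserved_dist` (default 100 kb, 5 bins), otherwise unknown.
#' A query boundary is conserved when conserved in all mappable species
#' and gained when non-conserved in all of them. Boundaries conserved in
#' more than `lost_majority` of species but non-conserved in one species
#' are reported as lost in that species.
#'
#' @param query_species species id whose boundaries are classified.
#' @param all_tads named list of `TadSet` per species.
#' @param coord_maps named list of `anchor_map` from the query species to
#'   each other species.
#' @param conserved_dist,nonconserved_dist distance thresholds in bp.
#' @param lost_majority fraction of species required for the lost call.
#' @return object of class `BoundaryConservation`: list with `labels`
#'   (data.frame chrom, mid, label), `distances` (boundary x species),
#'   `lost` (data.frame boundary index, species).
#' @export
classify_boundaries <- function(query_species, all_tads, coord_maps,
                                conserved_dist = 4e4, nonconserved_dist = 1e5,
                                lost_majority = 0.5) {
  if (length(all_tads) < 3) stop("need TADs for >= 3 species")
  others <- setdiff(names(all_tads), query_species)
  qb <- all_tads[[query_species]]$boundaries
  if (!nrow(qb))
    return(structure(list(labels = data.frame(), distances = NULL,
                          lost = data.frame()), class = "BoundaryConservation"))
  dist_mat <- matrix(NA_real_, nrow(qb), length(others),
                     dimnames = list(NULL, others))
  for (t in others) {
    tb <- all_tads[[t]]$boundaries
    mapped <- map_position(coord_maps[[t]], qb$chrom, qb$mid)
    for (i in seq_len(nrow(qb))) {
      cand <- tb$mid[tb$chrom == qb$chrom[i]]
      if (!is.na(mapped[i]) && length(cand))
        dist_mat[i, t] <- min(abs(cand - mapped[i]))
    }
  }
  pair_label <- ifelse(is.na(dist_mat), "unknown",
                ifelse(dist_mat < conserved_dist, "conserved",
                ifelse(dist_mat > nonconserved_dist, "non-conserved",
                       "unknown")))
  label <- apply(pair_label, 1, function(pl) {
    mappable <- pl != "unknown"
    if (!any(mappable)) return("unknown")
    if (all(pl[mappable] == "conserved")) return("conserved")
    if (all(pl == "non-conserved")) return("gained")
    "unknown"
  })
  n_sp <- length(all_tads)
  lost <- do.call(rbind, lapply(seq_len(nrow(qb)), function(i) {
    cons <- sum(pair_label[i, ] == "conserved") + 1  # query itself counts
    if (cons / n_sp <= lost_majority) return(NULL)
    bad <- others[pair_label[i, ] == "non-conserved"]
    if (!length(bad)) return(NULL)
    data.frame(boundary = i, species = bad, stringsAsFactors = FALSE)
  }))
  structure(list(labels = data.frame(chrom = qb$chrom, mid = qb$mid,
                                     label = label, stringsAsFactors = FALSE),
                 distances = dist_mat,
                 lost = if (is.null(lost)) data.frame() else lost),
            class = "BoundaryConservation")
}
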