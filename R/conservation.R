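#' CTCF motif orientation ratio (3DR)
#'
#' Motifs below the score quantile are dropped; optionally only motifs
#' inside `regions` are kept. Per chromosome, every pair of contiguous
#' surviving motifs is classified by strand: (+,-) is convergent, (-,+)
#' divergent; like-strand (tandem) pairs contribute to neither. The 3DR is
#' the ratio of the median convergent distance to the median divergent
#' distance; values well above 1 indicate loop-compatible convergent
#' spacing.
#'
#' @param motifs data.frame with `chrom`, `start`, `end`, `strand`,
#'   `score`.
#' @param regions optional data.frame of intervals (`chrom`, `start`,
#'   `end`); motifs outside them are discarded before pairing.
#' @param score_quantile quantile threshold on motif score (default 0.7).
#' @return object of class `MotifSpacing`: list with `convergent`,
#'   `divergent` (distance vectors), `ratio_3dr`, `n_motifs`.
#' @export
compute_3dr <- function(motifs, regions = NULL, score_quantile = 0.7) {
  stopifnot(all(c("chrom", "start", "strand") %in% names(motifs)))
  keep <- motifs
  if (score_quantile > 0 && !is.null(keep$score)) {
    cut <- quantile(keep$score, score_quantile)
    keep <- keep[keep$score >= cut, , drop = FALSE]
  }
  if (!is.null(regions)) {
    gr_m <- GenomicRanges::GRanges(keep$chrom,
                                   IRanges::IRanges(keep$start + 1, keep$end))
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1,
                                                    regions$end))
    keep <- keep[IRanges::overlapsAny(gr_m, gr_r), , drop = FALSE]
  }
  conv <- numeric(0); div <- numeric(0)
  for (ch in unique(keep$chrom)) {
    mm <- keep[keep$chrom == ch, , drop = FALSE]
    mm <- mm[order(mm$start), , drop = FALSE]
    if (nrow(mm) < 2) next
    pos <- (mm$start + mm$end) / 2
    s1 <- mm$strand[-nrow(mm)]; s2 <- mm$strand[-1]
    d <- diff(pos)
    conv <- c(conv, d[s1 == "+" & s2 == "-"])
    div <- c(div, d[s1 == "-" & s2 == "+"])
  }
  if (!length(conv) || !length(div))
    stop("no convergent or no divergent contiguous pair; 3DR undefined")
  structure(list(convergent = conv, divergent = div,
                 ratio_3dr = median(conv) / median(div),
                 n_motifs = nrow(keep)), class = "MotifSpacing")
}

#' @export
print.MotifSpacing <- function(x, ...) {
  cat(sprintf("MotifSpacing: %d motifs, %d convergent / %d divergent pairs, 3DR = %.3f\n",
              x$n_motifs, length(x$convergent), length(x$divergent),
              x$ratio_3dr))
  invisible(x)
}

#' CNE density profile across scaled TADs
#'
#' CNEs are filtered (score >= `min_score`, length > `min_len`), each TAD
#' is enlarged by 50% of its length on each side and the enlarged region is
#' partitioned into 40 equal bins: 10 flank bins per side and 20 interior
#' bins. Each CNE is assigned to the bin holding its midpoint, and counts
#' are averaged across TADs.
#'
#' @param tads a `TadSet` or data.frame of domains (`chrom`, `start`,
#'   `end`).
#' @param cnes data.frame with `chrom`, `start`, `end`, `score`.
#' @param min_score phastCons-style score threshold (default 0.95).
#' @param min_len minimum CNE length in bp, exclusive (default 200).
#' @param min_tad_bp TADs shorter than this are skipped with a message
#'   (default 20 kb: one bin per interior bin at 1 kb).
#' @return object of class `CneProfile`: list with `profile` (mean count
#'   per bin, length 40), `interior_mean`, `flank_mean`, `n_tads`,
#'   `total_assigned`.
#' @export
cne_profile <- function(tads, cnes, min_score = 0.95, min_len = 200,
                        min_tad_bp = 2e4) {
  domains <- if (inherits(tads, "TadSet")) tads$domains else tads
  keep <- cnes[cnes$score >= min_score & (cnes$end - cnes$start) > min_len, ,
               drop = FALSE]
  nb_flank <- 10L; nb_int <- 20L
  nb_tot <- nb_int + 2L * nb_flank
  acc <- matrix(0, 0, nb_tot)
  skipped <- 0
  for (k in seq_len(nrow(domains))) {
    td <- domains[k, ]
    L <- td$end - td$start
    if (L < min_tad_bp) { skipped <- skipped + 1; next }
    lo <- td$start - L / 2
    binw <- 2 * L / nb_tot  # = L / 20
    mid <- (keep$start + keep$end) / 2
    sel <- keep$chrom == td$chrom & mid >= lo & mid < lo + 2 * L
    counts <- tabulate(floor((mid[sel] - lo) / binw) + 1, nb_tot)
    acc <- rbind(acc, counts)
  }
  if (skipped)
    message(sprintf("%d TADs shorter than %g bp skipped", skipped, min_tad_bp))
  if (!nrow(acc))
    stop("no usable TADs for the CNE profile")
  prof <- colMeans(acc)
  interior <- seq(nb_flank + 1, nb_flank + nb_int)
  structure(list(profile = prof,
                 interior_mean = mean(prof[interior]),
                 flank_mean = mean(prof[-interior]),
                 n_tads = nrow(acc),
                 total_assigned = sum(acc)), class = "CneProfile")
}

locate_tad <- function(domains, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    hit <- which(domains$chrom == chrom[i] & domains$start <= pos[i] &
                   domains$end > pos[i])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Intra- and inter-TAD conservation scores between two species
#'
#' Gene pairs are consecutive single-copy orthologs in reference gene
#' order (per chromosome). A pair is intra-conserved when both genes share
#' one TAD in the reference AND share one TAD in the target; the
#' intra-TAD score is the percentage of reference TADs containing at least
#' one such pair. A pair is inter-conserved when its genes lie in
#' different reference TADs but on a single chromosome in both species;
#' the inter-TAD score is the percentage of reference TADs participating
#' in at least one such pair.
#'
#' @param ref_tads,target_tads `TadSet` (or domain data.frame) for the
#'   reference and target species.
#' @param orthologs ortholog table (columns `og`, `species`, `gene`,
#'   `chrom`, `start`, `end`) covering both species.
#' @param ref_species,target_species species ids as used in `orthologs`.
#' @param mode "consecutive" pairs (default) or "all" within-chromosome
#'   pairs.
#' @return object of class `TadConservationScore`: list with
#'   `intra_score`, `inter_score` (percent), `n_tads`, `n_pairs`.
#' @export
tad_conservation_scores <- function(ref_tads, target_tads, orthologs,
                                    ref_species, target_species,
                                    mode = c("consecutive", "all")) {
  mode <- match.arg(mode)
  ref_dom <- if (inherits(ref_tads, "TadSet")) ref_tads$domains else ref_tads
  tgt_dom <- if (inherits(target_tads, "TadSet")) target_tads$domains else
    target_tads
  ro <- orthologs[orthologs$species == ref_species, ]
  to <- orthologs[orthologs$species == target_species, ]
  shared <- intersect(ro$og, to$og)
  ro <- ro[match(shared, ro$og), ]
  to <- to[match(shared, to$og), ]
  ro$mid <- (ro$start + ro$end) / 2
  to$mid <- (to$start + to$end) / 2
  ro$tad <- locate_tad(ref_dom, ro$chrom, ro$mid)
  to$tad <- locate_tad(tgt_dom, to$chrom, to$mid)
  intra_tads <- integer(0); inter_tads <- integer(0); n_pairs <- 0
  for (ch in unique(ro$chrom)) {
    idx <- which(ro$chrom == ch)
    if (length(idx) < 2) next
    idx <- idx[order(ro$mid[idx])]
    prs <- if (mode == "consecutive")
      cbind(idx[-length(idx)], idx[-1]) else
      t(utils::combn(idx, 2))
    n_pairs <- n_pairs + nrow(prs)
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1]; j <- prs[r, 2]
      ti <- ro$tad[i]; tj <- ro$tad[j]
      if (is.na(ti) || is.na(tj)) next
      same_ref <- ti == tj
      same_tgt <- !is.na(to$tad[i]) && !is.na(to$tad[j]) &&
        to$tad[i] == to$tad[j]
      if (same_ref && same_tgt) intra_tads <- c(intra_tads, ti)
      if (!same_ref && to$chrom[i] == to$chrom[j])
        inter_tads <- c(inter_tads, ti, tj)
    }
  }
  n_tads <- nrow(ref_dom)
  if (!n_tads) stop("reference has no TADs")
  structure(list(intra_score = 100 * length(unique(intra_tads)) / n_tads,
                 inter_score = 100 * length(unique(inter_tads)) / n_tads,
                 n_tads = n_tads, n_pairs = n_pairs),
            class = "TadConservationScore")
}

#' Co-expression of gene pairs stratified by TAD co-residence
#'
#' Computes the Pearson correlation over replicates for all gene pairs at
#' each gene-count distance d (d = 0 means immediately adjacent genes in
#' chromosome order) and, per d, the fraction of same-TAD pairs with
#' r > `r_cutoff` versus the fraction among all pairs. Pairs straddling a
#' TAD boundary are never counted as same-TAD.
#'
#' @param expr numeric matrix, genes x replicates (>= 3 replicates).
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`, ordered
#'   or orderable by position.
#' @param tads a `TadSet` or domain data.frame.
#' @param r_cutoff correlation threshold (default 0.9).
#' @param max_d maximum gene-count distance (default 5).
#' @return data.frame with `d`, `frac_same_tad`, `frac_all`,
#'   `n_same_tad`, `n_all`.
#' @export
coexpression_by_distance <- function(expr, genes, tads, r_cutoff = 0.9,
                                     max_d = 5) {
  if (ncol(expr) < 3)
    stop("at least 3 replicates are required for co-expression analysis")
  domains <- if (inherits(tads, "TadSet")) tads$domains else tads
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$mid <- (genes$start + genes$end) / 2
  genes$tad <- locate_tad(domains, genes$chrom, genes$mid)
  res <- lapply(0:max_d, function(d) {
    same <- logical(0); hi <- logical(0)
    for (ch in unique(genes$chrom)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      n <- nrow(g)
      if (n < d + 2) next
      i <- seq_len(n - d - 1); j <- i + d + 1
      r <- vapply(seq_along(i), function(k)
        suppressWarnings(stats::cor(expr[g$gene[i[k]], ],
                                    expr[g$gene[j[k]], ])), numeric(1))
      st <- !is.na(g$tad[i]) & !is.na(g$tad[j]) & g$tad[i] == g$tad[j]
      same <- c(same, st)
      hi <- c(hi, !is.na(r) & r > r_cutoff)
    }
    data.frame(d = d,
               frac_same_tad = if (any(same)) mean(hi[same]) else NA_real_,
               frac_all = if (length(hi)) mean(hi) else NA_real_,
               n_same_tad = sum(same), n_all = length(hi))
  })
  do.call(rbind, res)
}
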