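#' Binomial significance of inter-chromosomal bin pairs
#'
#' For every pair of bins on different chromosomes, tests whether the
#' observed contact count k exceeds expectation under a binomial model:
#' n is the total read-pair count between the two chromosomes and the
#' background probability `m_norm` is the product of the two bins' fragment
#' counts divided by the product of the two chromosomes' fragment counts.
#' The upper-tail p-value is `P(X >= k)`, Benjamini-Hochberg adjusted
#' separately within each chromosome-pair family, and q-values are
#' length-normalized: `q_norm = q * lenA*lenB / (L1*L2)` with L1, L2 the
#' two longest chromosomes.
#'
#' Fragment counts per bin are proxied by the number of fixed-size sub-bins
#' (`frag_size`), since only the ratio structure of `m_norm` matters.
#'
#' @param m a `ContactMatrix` (typically at 500 kb).
#' @param frag_size sub-bin width (bp) used as the fragment-count proxy.
#' @return data.frame of class `trans_tests` with columns `chromA`,
#'   `binA`, `chromB`, `binB` (global bin indices), `k`, `n`, `m_norm`,
#'   `p_value`, `q_value`, `q_norm`; bin table and genome attached as
#'   attributes.
#' @export
trans_significance <- function(m, frag_size = 5e3) {
  stopifnot(inherits(m, "ContactMatrix"))
  genome <- matrix_genome(m)
  if (length(genome) < 2) stop("need >= 2 chromosomes for trans tests")
  bins <- m$bins
  frags <- ceiling((bins$end - bins$start) / frag_size)
  Ltop <- sort(genome, decreasing = TRUE)[1:2]
  chroms <- names(genome)
  out <- list()
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    ia <- which(bins$chrom == chroms[a])
    ib <- which(bins$chrom == chroms[b])
    blk <- as.matrix(m$counts[ia, ib, drop = FALSE])
    n <- round(sum(blk))
    if (n == 0) {
      message(sprintf("no contacts between %s and %s; pair skipped",
                      chroms[a], chroms[b]))
      next
    }
    FA <- sum(frags[ia]); FB <- sum(frags[ib])
    mn <- outer(frags[ia], frags[ib]) / (FA * FB)
    k <- round(as.vector(blk))
    p <- stats::pbinom(k - 1, n, as.vector(mn), lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    qn <- q * (genome[[chroms[a]]] * genome[[chroms[b]]]) / prod(Ltop)
    out[[length(out) + 1]] <- data.frame(
      chromA = chroms[a], binA = rep(ia, times = length(ib)),
      chromB = chroms[b], binB = rep(ib, each = length(ia)),
      k = k, n = n, m_norm = as.vector(mn),
      p_value = p, q_value = q, q_norm = qn,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no testable chromosome pairs")
  res <- do.call(rbind, out)
  attr(res, "bins") <- bins
  attr(res, "genome") <- genome
  class(res) <- c("trans_tests", "data.frame")
  res
}

#' Build an inter-chromosomal bin interaction network (BIN)
#'
#' Nodes are all bins with at least one test; edges are bin pairs whose
#' length-normalized q-value falls below the cutoff.
#'
#' @param tests output of [trans_significance()].
#' @param q_cutoff threshold on `q_norm` (default 1e-6).
#' @return object of class `BinNetwork`: list with `graph` (igraph),
#'   `edges` (data.frame of significant pairs), `nodes`, `bins`, `genome`.
#' @export
build_bin_network <- function(tests, q_cutoff = 1e-6) {
  nodes <- sort(unique(c(tests$binA, tests$binB)))
  sig <- tests[tests$q_norm < q_cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sig$binA), to = as.character(sig$binB)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  g <- igraph::simplify(g)
  structure(list(graph = g, edges = sig, nodes = nodes,
                 bins = attr(tests, "bins"), genome = attr(tests, "genome")),
            class = "BinNetwork")
}

#' @export
print.BinNetwork <- function(x, ...) {
  cat(sprintf("BinNetwork: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Randomized control for a bin interaction network
#'
#' Generates a random geometric control with the same node and edge counts:
#' nodes are placed uniformly in the unit cube, the |E| closest pairs by
#' Euclidean distance become edges, and then 10*|E| degree-preserving edge
#' switches between neighbors are attempted, each accepted only if it
#' increases the network transitivity (which, with degrees fixed, reduces
#' to increasing the triangle count).
#'
#' @param net a `BinNetwork` (or bare igraph).
#' @param seed integer seed.
#' @param switch_factor number of switch attempts as a multiple of |E|
#'   (default 10; 0 skips the switching phase).
#' @return a `BinNetwork` with the randomized graph.
#' @export
randomize_network <- function(net, seed = 1, switch_factor = 10) {
  g <- if (inherits(net, "BinNetwork")) net$graph else net
  ne <- igraph::ecount(g)
  nv <- igraph::vcount(g)
  if (ne < 1) stop("network has no edges")
  rg <- random_geometric_switched(nv, ne, seed, switch_factor)
  out <- list(graph = rg,
              edges = igraph::as_data_frame(rg, "edges"),
              nodes = seq_len(nv),
              bins = if (inherits(net, "BinNetwork")) net$bins else NULL,
              genome = if (inherits(net, "BinNetwork")) net$genome else NULL)
  class(out) <- "BinNetwork"
  out
}

# unit-cube geometric graph on nv nodes with the ne closest pairs as edges,
# then 10*ne transitivity-increasing double-edge switches
random_geometric_switched <- function(nv, ne, seed, switch_factor = 10) {
  set.seed(seed)
  pts <- matrix(runif(nv * 3), nv, 3)
  dm <- as.matrix(stats::dist(pts))
  dm[lower.tri(dm, diag = TRUE)] <- Inf
  ord <- order(dm)[seq_len(ne)]
  ei <- row(dm)[ord]; ej <- col(dm)[ord]
  edges <- cbind(ei, ej)
  adj <- vector("list", nv)
  for (k in seq_len(ne)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  tri <- function(u, v) length(intersect(adj[[u]], adj[[v]]))
  has_edge <- function(u, v) v %in% adj[[u]]
  for (att in seq_len(switch_factor * ne)) {
    pick <- sample.int(ne, 2)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # propose replacing (a,b),(c,d) with (a,c),(b,d)
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (has_edge(a, c_) || has_edge(b, d)) next
    t_old <- tri(a, b) + tri(c_, d)
    adj[[a]] <- setdiff(adj[[a]], b); adj[[b]] <- setdiff(adj[[b]], a)
    adj[[c_]] <- setdiff(adj[[c_]], d); adj[[d]] <- setdiff(adj[[d]], c_)
    t_new <- tri(a, c_) + tri(b, d)
    if (t_new > t_old) {
      adj[[a]] <- c(adj[[a]], c_); adj[[c_]] <- c(adj[[c_]], a)
      adj[[b]] <- c(adj[[b]], d); adj[[d]] <- c(adj[[d]], b)
      edges[pick[1], ] <- c(a, c_); edges[pick[2], ] <- c(b, d)
    } else {
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      adj[[c_]] <- c(adj[[c_]], d); adj[[d]] <- c(adj[[d]], c_)
    }
  }
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  igraph::add_edges(g, t(edges))
}

#' Basic network statistics of a bin interaction network
#'
#' Network variance is the sample variance (n-1 denominator) of node
#' degrees divided by the mean degree; it is close to 1 for Poisson-like
#' random graphs and greater when the network deviates from random
#' expectation. The clustering coefficient is the mean of the per-node
#' local coefficient `C_n = 2 e_n / (k_n (k_n - 1))`, with nodes having
#' fewer than two neighbors set to 0. The characteristic path length is
#' the mean shortest path within the largest connected component, and the
#' degree power-law slope is the least-squares slope of log10 count versus
#' log10 degree over the nonzero-degree histogram.
#'
#' @param net a `BinNetwork` (or bare igraph).
#' @return list with `network_variance`, `clustering_coefficient`,
#'   `average_degree`, `characteristic_path_length`,
#'   `degree_powerlaw_slope`.
#' @export
network_stats <- function(net) {
  g <- if (inherits(net, "BinNetwork")) net$graph else net
  if (igraph::vcount(g) < 2) stop("need >= 2 nodes")
  deg <- igraph::degree(g)
  if (mean(deg) == 0) stop("zero mean degree; network variance undefined")
  nv <- stats::var(deg) / mean(deg)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- mean(cc_local)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  cpl <- igraph::mean_distance(sub, directed = FALSE)
  tab <- table(deg[deg > 0])
  slope <- if (length(tab) >= 2) {
    unname(stats::coef(stats::lm(log10(as.numeric(tab)) ~
                                   log10(as.numeric(names(tab)))))[2])
  } else NA_real_
  list(network_variance = nv, clustering_coefficient = cc,
       average_degree = mean(deg), characteristic_path_length = cpl,
       degree_powerlaw_slope = slope)
}

#' Cross-species similarity of gene interaction networks (GINs)
#'
#' Per species, each single-copy ortholog's trans-contact propensity is the
#' summed contact frequency of its significant inter-chromosomal edges
#' (edges of the BIN incident to bins overlapping the gene). Species are
#' compared by Spearman correlation over shared orthologs, and clustered by
#' average linkage on 1 - similarity.
#'
#' @param nets named list of `BinNetwork` per species.
#' @param orthologs ortholog table with columns `og`, `species`, `chrom`,
#'   `start`, `end` (as in a `SpeciesWorld`).
#' @param min_shared minimum shared orthologs per pair (default 10); pairs
#'   below it are reported NA.
#' @return list with `similarity` (species x species Spearman matrix) and
#'   `tree` (hclust, average linkage on 1 - similarity).
#' @export
gene_network_similarity <- function(nets, orthologs, min_shared = 10) {
  if (length(nets) < 2) stop("need >= 2 species")
  sp <- names(nets)
  prop <- lapply(sp, function(s) {
    net <- nets[[s]]
    strength <- numeric(nrow(net$bins))
    if (nrow(net$edges)) {
      for (col in c("binA", "binB")) {
        agg <- tapply(net$edges$k, net$edges[[col]], sum)
        strength[as.integer(names(agg))] <-
          strength[as.integer(names(agg))] + agg
      }
    }
    og <- orthologs[orthologs$species == s, ]
    val <- vapply(seq_len(nrow(og)), function(i) {
      b <- pos_to_bin(net$bins, rep(og$chrom[i], 2),
                      c(og$start[i], og$end[i] - 1))
      sum(strength[unique(b[!is.na(b)])])
    }, numeric(1))
    setNames(val, og$og)
  })
  names(prop) <- sp
  sim <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  diag(sim) <- 1
  for (a in seq_along(sp)) for (b in seq_along(sp)) {
    if (b <= a) next
    shared <- intersect(names(prop[[a]]), names(prop[[b]]))
    if (length(shared) < min_shared) next
    r <- suppressWarnings(stats::cor(prop[[a]][shared], prop[[b]][shared],
                                     method = "spearman"))
    sim[a, b] <- sim[b, a] <- r
  }
  d <- stats::as.dist(1 - sim)
  tree <- if (!anyNA(d)) stats::hclust(d, method = "average") else NULL
  list(similarity = sim, tree = tree, propensity = prop)
}

#' Per-bin inter-chromosomal contact ratio
#'
#' Ratio of inter-chromosomal contacts to the sum of intra- and
#' inter-chromosomal contacts aligned to each bin; bins with no coverage
#' are masked (NA).
#'
#' @param m a `ContactMatrix`.
#' @return numeric vector in `[0, 1]` aligned to `m$bins`, NA where
#'   undefined.
#' @export
contact_ratio_profile <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  total <- Matrix::rowSums(m$counts)
  intra <- numeric(nrow(m$bins))
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    intra[idx] <- Matrix::rowSums(m$counts[idx, idx, drop = FALSE])
  }
  inter <- total - intra
  out <- ifelse(total > 0, inter / total, NA_real_)
  out
}
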