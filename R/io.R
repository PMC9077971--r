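#' @importFrom utils read.table write.table
NULL

#' Write / read a chrom.sizes table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#' @param genome named numeric vector of chromosome lengths.
#' @param path file path.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), as.integer(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}

#' Write / read a sparse contact triplet file
#'
#' TSV with header `chromA binA chromB binB count`, one row per nonzero
#' upper-triangle entry; `binA`/`binB` are 0-based bin indices within their
#' chromosome.
#'
#' @param m a `ContactMatrix`.
#' @param path file path.
#' @export
write_contacts <- function(m, path) {
  cts <- methods::as(Matrix::triu(m$counts), "TsparseMatrix")
  i <- cts@i + 1L; j <- cts@j + 1L
  first <- tapply(m$bins$bin, m$bins$chrom, min)
  df <- data.frame(chromA = m$bins$chrom[i],
                   binA = m$bins$bin[i] - as.integer(first[m$bins$chrom[i]]),
                   chromB = m$bins$chrom[j],
                   binB = m$bins$bin[j] - as.integer(first[m$bins$chrom[j]]),
                   count = cts@x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contacts
#' @param genome named numeric vector of chromosome lengths.
#' @param resolution bin width in bp.
#' @export
read_contacts <- function(path, genome, resolution) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "character",
                                  "integer", "numeric"))
  bins <- make_bins(genome, resolution)
  first <- tapply(bins$bin, bins$chrom, min)
  i <- as.integer(first[df$chromA]) + df$binA
  j <- as.integer(first[df$chromB]) + df$binB
  n <- nrow(bins)
  cts <- Matrix::sparseMatrix(i = c(i, j[i != j]), j = c(j, i[i != j]),
                              x = c(df$count, df$count[i != j]),
                              dims = c(n, n))
  contact_matrix(cts, bins, resolution)
}

#' Write / read BED-style interval tables
#'
#' Plain TSV without header. `write_bed` emits whichever of the optional
#' columns (`name`, `score`, `strand`, extras) are present, in BED column
#' order; extra columns (e.g. TE family) follow the first six.
#'
#' @param df data.frame with at least `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  lead <- c("chrom", "start", "end", "name", "score", "strand")
  cols <- c(intersect(lead, names(df)), setdiff(names(df), lead))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param extra_cols names for columns beyond the first six, if any.
#' @export
read_bed <- function(path, extra_cols = character()) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  lead <- c("chrom", "start", "end", "name", "score", "strand")
  n_lead <- min(ncol(df), 6L)
  names(df) <- c(lead[seq_len(n_lead)],
                 if (ncol(df) > 6L) {
                   if (length(extra_cols) == ncol(df) - 6L) extra_cols
                   else paste0("extra", seq_len(ncol(df) - 6L))
                 })
  df
}

#' Write a per-bin signed track as bedGraph
#'
#' @param bins bin table from [make_bins()].
#' @param values numeric vector, one per bin (NA rows dropped).
#' @param path file path.
#' @export
write_bedgraph <- function(bins, values, path) {
  keep <- !is.na(values)
  write.table(data.frame(bins$chrom[keep], bins$start[keep], bins$end[keep],
                         signif(values[keep], 6)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a gene-by-replicate TPM matrix
#'
#' TSV with a `gene` column followed by one column per replicate.
#' @param tpm numeric matrix, rownames = gene ids.
#' @param path file path.
#' @export
write_tpm <- function(tpm, path) {
  write.table(data.frame(gene = rownames(tpm), tpm, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tpm
#' @export
read_tpm <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Export a bin network as an edge-list TSV
#'
#' Columns: binA, binB (global bin indices), and the test statistics carried
#' on the edges (k, n, m_norm, p, q, q_norm).
#' @param net a `BinNetwork` (see [build_bin_network()]).
#' @param path file path.
#' @export
write_edges <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a bin network as GraphML
#'
#' @param net a `BinNetwork` (or bare igraph).
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  g <- if (inherits(net, "BinNetwork")) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
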