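#' @importFrom Matrix sparseMatrix forceSymmetric rowSums t diag
#' @importFrom methods as is
NULL

#' Tile a genome into fixed-width bins
#'
#' Coordinates are 0-based half-open (BED convention); the last bin of each
#' chromosome is truncated at the chromosome end so that bins tile each
#' chromosome without gaps.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @return data.frame with columns `chrom`, `start`, `end` and a global
#'   1-based `bin` index in genome order.
#' @export
make_bins <- function(genome, resolution) {
  stopifnot(length(genome) >= 1, !is.null(names(genome)))
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  pieces <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  bins
}

#' Map genomic positions to bin indices
#'
#' @param bins bin table from [make_bins()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of global bin indices (NA when off-chromosome).
#' @export
pos_to_bin <- function(bins, chrom, pos) {
  res <- bins$end[1] - bins$start[1]
  first <- tapply(bins$bin, bins$chrom, min)
  nper <- tapply(bins$bin, bins$chrom, length)
  idx <- floor(pos / res)
  out <- as.integer(first[chrom] + idx)
  bad <- is.na(out) | idx < 0 | idx >= nper[chrom]
  out[bad] <- NA_integer_
  out
}

#' Construct a ContactMatrix
#'
#' A binned Hi-C contact map: a symmetric sparse count matrix over a genome
#' bin table, optionally carrying per-bin balancing weights (NA marks masked
#' bins excluded from downstream statistics).
#'
#' @param counts square matrix (dense or sparse) of contact counts; it is
#'   symmetrised by averaging with its transpose if not already symmetric.
#' @param bins bin table from [make_bins()].
#' @param resolution bin width in bp.
#' @param weights optional per-bin balancing weights.
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, bins, resolution, weights = NULL) {
  if (nrow(counts) != nrow(bins) || ncol(counts) != nrow(bins))
    stop("counts dimension does not match bin table")
  counts <- methods::as(counts, "CsparseMatrix")
  if (!Matrix::isSymmetric(counts))
    counts <- (counts + Matrix::t(counts)) / 2
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, bins = bins, resolution = resolution,
                 weights = weights),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins @ %d bp, %d chromosomes, total %.3g contacts%s\n",
              nrow(x$bins), x$resolution, length(unique(x$bins$chrom)),
              sum(x$counts) , if (is.null(x$weights)) "" else " (balanced)"))
  invisible(x)
}

#' Balanced (normalized) counts of a ContactMatrix
#'
#' Applies the stored balancing weights: `K_ij = M_ij * w_i * w_j`.
#' Rows/columns of masked bins (weight NA) are zeroed.
#'
#' @param m a `ContactMatrix`.
#' @return sparse symmetric matrix of normalized counts.
#' @export
balanced_counts <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (is.null(m$weights)) return(m$counts)
  w <- m$weights
  w[is.na(w)] <- 0
  out <- m$counts
  out@x <- out@x * (w[out@i + 1L] * w[rep.int(seq_len(ncol(out)), diff(out@p))])
  Matrix::drop0(out)
}

#' Extract the intra-chromosomal block of one chromosome as a dense matrix
#'
#' @param m a `ContactMatrix`.
#' @param chrom chromosome name.
#' @param balanced use balancing weights if present.
#' @return dense numeric matrix.
#' @export
chrom_block <- function(m, chrom, balanced = TRUE) {
  idx <- which(m$bins$chrom == chrom)
  if (!length(idx)) stop(sprintf("chromosome '%s' not in bin table", chrom))
  cts <- if (balanced) balanced_counts(m) else m$counts
  as.matrix(cts[idx, idx, drop = FALSE])
}

#' Per-chromosome genome vector of a ContactMatrix
#' @param m a `ContactMatrix`.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
matrix_genome <- function(m) {
  ends <- tapply(m$bins$end, m$bins$chrom, max)
  out <- as.numeric(ends)
  names(out) <- names(ends)
  out[unique(m$bins$chrom)]
}

same_bin_table <- function(a, b) {
  identical(a$bins$chrom, b$bins$chrom) &&
    identical(a$bins$start, b$bins$start) &&
    identical(a$bins$end, b$bins$end)
}
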