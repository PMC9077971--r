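# lazily built fixtures shared across test files (one build per run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_world <- function() fixture("small_world", function()
  make_world(n_species = 3, chrom_count_range = c(2, 2),
             chrom_len_range = c(1e7, 1.5e7), seed = 3))

small_m20 <- function() fixture("small_m20", function()
  suppressWarnings(iterative_correction(
    simulate_hic(small_world(), "sp1", 2e4, 1e6, seed = 4))))

small_m100 <- function() fixture("small_m100", function()
  suppressWarnings(iterative_correction(
    simulate_hic(small_world(), "sp1", 1e5, 1e6, seed = 4))))

small_tracks <- function() fixture("small_tracks", function()
  simulate_tracks(small_world(), "sp1", seed = 8))

small_tads <- function() fixture("small_tads", function()
  call_tads(directionality_index(small_m20()), seed = 1))

# dense symmetric matrix -> ContactMatrix on a single toy chromosome
toy_matrix <- function(M, resolution = 2e4, chrom = "chr1") {
  bins <- make_bins(stats::setNames(nrow(M) * resolution, chrom), resolution)
  contact_matrix(M, bins, resolution)
}

# fraction of internal planted boundaries matched by a called boundary
# within `tol`
boundary_recovery <- function(tadset, planted, tol = 2e4) {
  hits <- vapply(seq_len(nrow(planted)), function(k) {
    b <- planted$end[k]; ch <- planted$chrom[k]
    if (b >= max(planted$end[planted$chrom == ch])) return(NA)
    cand <- tadset$boundaries$mid[tadset$boundaries$chrom == ch]
    if (!length(cand)) return(FALSE)
    min(abs(cand - b)) <= tol
  }, logical(1))
  mean(hits, na.rm = TRUE)
}

# planted conserved-compartment classes on the ancestral frame
planted_classes <- function(world) {
  sg <- do.call(rbind, world$planted$comp_leaf)
  ns <- ncol(sg)
  ifelse(rowSums(sg > 0) == ns, "CA",
         ifelse(rowSums(sg < 0) == ns, "CB", "NC"))
}
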