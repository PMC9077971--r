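#' Default pipeline configuration
#'
#' Thresholds default to the field-standard values used throughout the
#' package: trans q-cutoff 1e-6, cosine grouping 0.85, co-expression r
#' 0.9, boundary conservation 40/100 kb, unorganized-gap rule 400 kb,
#' motif score quantile 0.7. World parameters are kept small enough for a
#' complete run on one CPU in minutes.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return nested list of class `RunConfig`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    world = list(n_species = 3, chrom_count_range = c(2L, 3L),
                 chrom_len_range = c(1e7, 2e7), conserved_fraction = 0.8),
    hic = list(resolution = 2e4, comp_resolution = 1e5,
               trans_resolution = 5e5, depth = 1e6),
    thresholds = list(q_cutoff = 1e-6, cos_threshold = 0.85,
                      coexpr_r_cutoff = 0.9, conserved_dist = 4e4,
                      nonconserved_dist = 1e5, gap_threshold = 4e5,
                      motif_quantile = 0.7, k_states = 8),
    output_dir = NULL
  ), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#' @param path YAML file.
#' @return `RunConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(usr)) {
    if (is.list(usr[[nm]]) && nm %in% names(cfg))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], usr[[nm]])
    else cfg[[nm]] <- usr[[nm]]
  }
  cfg
}

#' Run the full comparative pipeline on a synthetic world
#'
#' Generates the world, simulates Hi-C and annotation tracks per species,
#' and runs every analysis stage: P(s) slopes, replicate SCC,
#' inter-chromosomal network statistics with a randomized control,
#' chromosome-territory metrics, compartment/AB-index/insulation calling
#' with conserved-state grouping, TAD calling with boundary conservation,
#' 3DR, CNE profile, co-expression stratification and TE correlations.
#' When `config$output_dir` is set, per-stage TSVs plus the serialized
#' configuration are written there.
#'
#' @param config a `RunConfig` (see [default_config()] / [read_config()]).
#' @return nested report list, invisibly written to `output_dir` if set.
#' @export
run_all <- function(config = default_config()) {
  cfg <- config
  seed <- cfg$seed
  th <- cfg$thresholds
  world <- make_world(n_species = cfg$world$n_species,
                      chrom_count_range = cfg$world$chrom_count_range,
                      chrom_len_range = cfg$world$chrom_len_range,
                      conserved_fraction = cfg$world$conserved_fraction,
                      seed = seed)
  report <- list(config = cfg, species = world$species)
  sp1 <- world$species[1]

  # --- genome summaries
  report$genome <- lapply(world$genomes, genome_summary)

  # --- per-species Hi-C at the three working resolutions
  mats <- list(); comp_mats <- list(); trans_mats <- list()
  for (i in seq_along(world$species)) {
    s <- world$species[i]
    mats[[s]] <- iterative_correction(
      simulate_hic(world, s, cfg$hic$resolution, cfg$hic$depth,
                   seed = seed + i))
    comp_mats[[s]] <- iterative_correction(
      simulate_hic(world, s, cfg$hic$comp_resolution, cfg$hic$depth,
                   seed = seed + i))
    trans_mats[[s]] <- simulate_hic(world, s, cfg$hic$trans_resolution,
                                    cfg$hic$depth, seed = seed + i)
  }

  # --- P(s) slopes vs planted exponents
  report$ps <- data.frame(
    species = world$species,
    planted = as.numeric(world$planted$ps_exponent[world$species]),
    fitted = vapply(world$species, function(s)
      ps_curve(comp_mats[[s]])$slope, numeric(1)))

  # --- replicate reproducibility (same truth, new noise seed)
  rep2 <- simulate_hic(world, sp1, cfg$hic$comp_resolution, cfg$hic$depth,
                       seed = seed + 101)
  report$scc <- scc(comp_mats[[sp1]], rep2)$aggregate

  # --- trans networks
  tests <- trans_significance(trans_mats[[sp1]])
  net <- build_bin_network(tests, q_cutoff = th$q_cutoff)
  report$network <- network_stats(net)
  rand <- randomize_network(net, seed = seed)
  report$network_random <- network_stats(rand)
  report$network_variance_fold <-
    report$network$network_variance / report$network_random$network_variance

  # --- chromosome territories of the first species
  models <- lapply(names(world$genomes[[sp1]]), function(ch)
    embed_chromosome(comp_mats[[sp1]], ch))
  report$ct <- length_scaling(models)$table

  # --- compartments, AB index, insulation, conserved states
  bins100 <- comp_mats[[sp1]]$bins
  gd <- lapply(world$species, function(s)
    gene_density(world, s, comp_mats[[s]]$bins))
  names(gd) <- world$species
  tracks <- lapply(world$species, function(s)
    call_compartments(comp_mats[[s]], gd[[s]]))
  names(tracks) <- world$species
  report$compartment_agreement <- vapply(world$species, function(s) {
    planted <- planted_comp_sign(world, s, cfg$hic$comp_resolution)
    called <- sign(tracks[[s]]$pc1)
    mean(called == planted, na.rm = TRUE)
  }, numeric(1))
  ab20 <- lapply(world$species, function(s)
    ab_index(mats[[s]], tracks[[s]]))
  names(ab20) <- world$species
  is20 <- lapply(world$species, function(s)
    insulation_score(mats[[s]])$is_value)
  names(is20) <- world$species

  # aligned frame: ancestral 100-kb grid sampled through the species scalings
  aligned <- align_tracks(world, tracks, cfg$hic$comp_resolution)
  st <- cluster_states(aligned, K = th$k_states, seed = seed,
                       cos_threshold = th$cos_threshold, mode = "ab",
                       bin_mb = cfg$hic$comp_resolution / 1e6)
  report$states <- group_summary(st)
  report$similarity <- similarity_vs_divergence(aligned, world$phylogeny)

  # --- TADs and conservation
  tadsets <- lapply(world$species, function(s)
    call_tads(directionality_index(mats[[s]]), seed = seed))
  names(tadsets) <- world$species
  report$tads <- data.frame(
    species = world$species,
    n = vapply(tadsets, function(t) nrow(t$domains), numeric(1)),
    mean_kb = vapply(tadsets, function(t)
      if (nrow(t$domains)) mean(t$domains$end - t$domains$start) / 1e3
      else NA_real_, numeric(1)))
  amaps <- lapply(setdiff(world$species, sp1), function(t)
    build_anchor_map(world, sp1, t))
  names(amaps) <- setdiff(world$species, sp1)
  bc <- classify_boundaries(sp1, tadsets, amaps,
                            conserved_dist = th$conserved_dist,
                            nonconserved_dist = th$nonconserved_dist)
  report$boundary_labels <- if (nrow(bc$labels)) table(bc$labels$label) else
    table(character())

  # --- tracks: 3DR, CNEs, co-expression, TEs
  trk <- simulate_tracks(world, sp1, seed = seed)
  borders <- border_regions(tadsets[[sp1]], flank = 2e4)
  report$threedr <- list(
    genome = compute_3dr(trk$motifs, score_quantile = th$motif_quantile)$ratio_3dr,
    borders = if (nrow(borders))
      compute_3dr(trk$motifs, regions = borders,
                  score_quantile = th$motif_quantile)$ratio_3dr else NA_real_)
  report$cne <- cne_profile(tadsets[[sp1]], trk$cnes)[c("interior_mean",
                                                        "flank_mean")]
  genes1 <- world$orthologs[world$orthologs$species == sp1, ]
  report$coexpression <- coexpression_by_distance(
    trk$expression, data.frame(gene = genes1$gene, chrom = genes1$chrom,
                               start = genes1$start, end = genes1$end),
    tadsets[[sp1]], r_cutoff = th$coexpr_r_cutoff, max_d = 3)
  cov20 <- te_coverage(trk$tes, mats[[sp1]]$bins)
  report$te_ab <- te_ab_correlation(cov20, ab20[[sp1]])
  flt <- filter_bin_pairs(mats[[sp1]], tadsets[[sp1]])
  report$te_contact <- te_contact_correlation(cov20, flt)
  report$te_filter_removed <- flt$removed_fraction
  report$enhancer <- enhancer_enrichment(trk$tes, trk$enhancers,
                                         world$genomes[[sp1]], n_boot = 200,
                                         seed = seed)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.yaml"))
    write.table(report$ps, file.path(cfg$output_dir, "ps_slopes.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(report$states, file.path(cfg$output_dir, "states.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(report$tads, file.path(cfg$output_dir, "tads.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(report$te_ab, file.path(cfg$output_dir, "te_ab.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

#' Align per-species compartment tracks on the ancestral frame
#'
#' Samples each species' PC1 at the species position of every ancestral
#' 100-kb bin (through the planted linear scalings via ortholog-anchored
#' coordinates), yielding the aligned bins-by-species matrix used for
#' conserved-state grouping.
#'
#' @param world a `SpeciesWorld`.
#' @param tracks named list of `CompartmentTrack` per species.
#' @param resolution track resolution in bp.
#' @return numeric matrix, ancestral bins x species.
#' @export
align_tracks <- function(world, tracks, resolution = 1e5) {
  anc_len <- world$planted$anc_len
  rows <- sum(anc_len / COMP_RES)
  out <- matrix(NA_real_, rows, length(world$species),
                dimnames = list(NULL, world$species))
  r <- 0
  for (ch in names(anc_len)) {
    nb <- anc_len[[ch]] / COMP_RES
    mid_anc <- (seq_len(nb) - 0.5) * COMP_RES
    for (s in world$species) {
      sc <- world$planted$scales[[s]][[ch]]
      b <- pos_to_bin(tracks[[s]]$bins, rep(ch, nb), mid_anc * sc)
      v <- ifelse(is.na(b), NA_real_, tracks[[s]]$pc1[b])
      out[r + seq_len(nb), s] <- v
    }
    r <- r + nb
  }
  out
}

#' TAD border regions (for border-restricted 3DR)
#'
#' Intervals of +/- `flank` around the midpoint of each boundary.
#' @param tadset a `TadSet`.
#' @param flank one-sided extension in bp (default 20 kb).
#' @return data.frame (chrom, start, end).
#' @export
border_regions <- function(tadset, flank = 2e4) {
  bd <- tadset$boundaries
  if (!nrow(bd)) return(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()))
  data.frame(chrom = bd$chrom, start = pmax(0, bd$mid - flank),
             end = bd$mid + flank, stringsAsFactors = FALSE)
}
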