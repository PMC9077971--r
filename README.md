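# archcompare

Comparative analysis of 3D genome architecture across species, in R.

Hi-C contact maps from different vertebrates differ in ways that track
genome and chromosome size: the contact-decay curve P(s) ~ s^α is steeper
in large mammalian genomes than in birds and fish, long chromosomes form
more condensed and less stretched territories, inter-chromosomal contacts
favor chromosomes of similar length, and the finer layers of organization
— A/B compartments, insulation, TADs, CTCF orientation at boundaries —
are conserved in proportion to phylogenetic distance. `archcompare` is a
toolkit for making those comparisons quantitatively, aimed at
computational biologists working with binned multi-species Hi-C plus the
usual annotation sidecars (orthologs, CTCF motifs, TEs, CNEs, enhancers,
expression matrices, a dated phylogeny).

The package implements, per species and then comparatively:

* **Contact-matrix core** — iterative (Sinkhorn) balancing of `M_ij`,
  distance-stratified quantile normalization across samples, the
  stratum-adjusted correlation coefficient (SCC) for reproducibility, and
  P(s) curves with least-squares log–log slopes over the long-range
  (1–10 Mb) window.
* **Chromosome territories** — classical metric MDS embeddings with
  `d_ij = c_ij^(−α)` (α = 0.25), convex-hull volume V and surface S, and
  the territory metrics VSR = V/S and VpM = V/Mb, whose reciprocals
  quantify stretchiness and condensation.
* **Inter-chromosomal networks** — per bin pair an upper-tail binomial
  test `P = Σ_{i=k}^n C(n,i) m^i (1−m)^{n−i}` with fragment-based
  background `m`, BH correction per chromosome pair, chromosome-length
  normalized q-values, bin interaction networks at a q cutoff, the
  network variance S²_d/x̄_d, clustering coefficient
  `C_n = 2e_n/(k_n(k_n−1))`, and geometric randomized controls with
  transitivity-increasing edge switches.
* **Compartments** — PC1 of the O/E correlation matrix oriented by gene
  density, the AB index `(meanA − meanB)/(meanA + meanB)` at 20 kb,
  sliding-square insulation scores, K-means + cosine-similarity grouping
  of aligned multi-species tracks into conserved states (CA/CB/NC,
  CHI/CLI/AI), and cross-tissue consistency tests.
* **TADs** — the directionality index
  `DI = sign(B−A)·((A−E)²/E + (B−E)²/E)` over ±2 Mb windows, a 3-state
  Gaussian-HMM caller, boundary classification across species by the
  40 kb / 100 kb rules (conserved / gained / lost), insulation and TSS
  profiles around boundaries.
* **Conservation analytics** — CTCF 3DR = median(d→←)/median(d←→) over
  contiguous motif pairs, CNE profiles across 50%-enlarged TADs,
  intra/inter-TAD ortholog conservation scores, and co-expression of gene
  pairs stratified by TAD co-residence.
* **TEs and chromatin** — per-family (SINE/LINE/LTR/DNA) coverage versus
  AB index, TE proportion versus contact frequency over filtered bin
  pairs, enhancer enrichment folds, and TE-coverage similarity versus
  divergence time.
* **Synthetic world** — `make_world()` generates a seeded multi-species
  universe (genomes, dated phylogeny, orthologs, planted compartments,
  TADs, decay exponents, motifs, TEs, CNEs, enhancers, expression) so the
  entire pipeline can be exercised and validated end to end without
  external data.

## Worked example

A three-species toy world, one species analyzed end to end:

```r
library(archcompare)

world <- make_world(n_species = 3, chrom_count_range = c(2, 2),
                    chrom_len_range = c(1e7, 1.5e7), seed = 3)
hic <- iterative_correction(simulate_hic(world, "sp1", resolution = 1e5,
                                         depth = 1e6, seed = 4))
ps_curve(hic)
#> PsCurve: 119 strata, fit 1e+06-1e+07 bp, slope -0.2551
world$planted$ps_exponent[["sp1"]]
#> [1] -0.280

track <- call_compartments(hic, gene_density(world, "sp1", hic$bins))
mean(sign(track$pc1) == planted_comp_sign(world, "sp1", 1e5), na.rm = TRUE)
#> [1] 1

m20 <- iterative_correction(simulate_hic(world, "sp1", resolution = 2e4,
                                         depth = 2e6, seed = 4))
tads <- call_tads(directionality_index(m20), seed = 1)
tads
#> TadSet: 27 domains (mean 703 kb), 29 boundaries, 4 unorganized gaps

trans <- simulate_hic(world, "sp1", resolution = 5e5, depth = 1e6, seed = 4)
net <- build_bin_network(trans_significance(trans), q_cutoff = 1e-6)
network_stats(net)$network_variance
#> [1] 10.22        # vs ~1.8 for randomize_network(net, seed = 1)

trk <- simulate_tracks(world, "sp1", seed = 8)
compute_3dr(trk$motifs)
#> MotifSpacing: 163 motifs, 47 convergent / 46 divergent pairs, 3DR = 2.928
compute_3dr(trk$motifs, regions = border_regions(tads))$ratio_3dr
#> [1] 29.99
```

Reading the numbers: the fitted decay slope sits within a few hundredths
of the planted exponent at this toy depth (two 10–15 Mb chromosomes);
every 100-kb bin lands in its planted compartment; the caller finds
domains of ~700 kb matching the planted 400 kb–1.2 Mb range; the observed
trans-contact network is far over-dispersed relative to its randomized
control (variance 10.2 vs 1.8); and CTCF motifs are mildly convergent
genome-wide (3DR ≈ 2.9) but strikingly convergent when restricted to TAD
borders (3DR ≈ 30), the loop-anchor signature.

`run_all(default_config(seed = 1))` executes every stage — decay slopes,
replicate SCC, networks with controls, territory metrics, compartments,
conserved states, TADs with boundary conservation, 3DR, CNE profiles,
co-expression, TE correlations — in about half a minute and returns a
nested report (optionally written as TSVs).

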