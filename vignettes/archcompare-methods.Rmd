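---
title: "Methods: comparative 3D genome architecture with archcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative 3D genome architecture with archcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`archcompare` implements a comparative analysis of chromosome conformation
(Hi-C) data across species: from binned contact matrices it derives
contact-decay curves, chromosome-territory shape metrics, inter-chromosomal
interaction networks, A/B compartments and insulation, TADs, CTCF motif
orientation statistics, and correlations of all of these with sequence
conservation, expression and transposable-element content. Because real
multi-species Hi-C collections are large and heterogeneous, the package
ships a seeded synthetic world with planted ground truth: every stage of
the pipeline is validated by recovering a parameter that the generator
planted, and every cross-species claim is validated as a direction (a sign)
on worlds whose divergence structure is known.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## The synthetic multi-species world

`make_world()` builds a shared ancestral karyotype (chromosome count drawn
once from `chrom_count_range`, lengths from `chrom_len_range`) and rescales
each chromosome per species by a smooth factor (species-level 0.85–1.15,
per-chromosome 0.95–1.05). Synteny is perfectly preserved: orthologs keep
their order, and coordinate maps between species are piecewise-linear
interpolations anchored on single-copy ortholog midpoints
(`build_anchor_map()` / `map_position()`), standing in for a whole-genome
liftOver. Chromosomal rearrangements are deliberately out of scope.

The phylogeny is a random coalescent tree (or a user tree) rescaled so the
root sits at `root_age` (default 100 million years). Two kinds of structure
evolve along it:

* **Compartment signs.** The ancestral genome carries a ±1 A/B checkerboard
  on a 100-kb grid with geometric block lengths (mean ~1 Mb). On each branch
  every bin flips sign with probability `min(0.5, rate × branch length)`,
  where `rate = (1 − conserved_fraction)/root_age`; `conserved_fraction = 1`
  therefore means no divergence anywhere on the tree.
* **TAD boundaries.** Ancestral boundaries tile each chromosome with
  domain lengths uniform in `tad_len_range` (default 400 kb–1.2 Mb). On each
  branch a boundary mutates with the same rate: it is deleted (30%) or
  shifted by N(0, 100 kb); new boundaries arise at a matching rate. After
  evolution a minimum boundary separation of `tad_len_range[1]` is enforced
  on the ancestral frame, so every species sees well-formed domains and a
  fully conserved world maps boundary-for-boundary.

Per-species contact-decay exponents are drawn from `ps_exponent_range`
(default −0.45…−0.23, the range observed across vertebrates). With
`length_coupling = TRUE` (default) species with longer genomes receive
exponents from the steep end — longer chromosomes make fewer long-range
contacts — and within a species each chromosome's exponent is shifted by
`−chrom_coupling × (len − mean len)/50 Mb` (default 0.15), which plants the
within-genome association between chromosome length, long-range contact
frequency and territory shape that the comparative analyses measure.

### Contact simulation

`simulate_hic()` draws independent Poisson counts around a multiplicative
expectation. Intra-chromosomally the expectation at bin distance *d* is

    E(i,j) ∝ d^alpha × (1 + 0.4·s_i·s_j·ramp(d)) × (1 + 1.0·[same TAD])

where `s_i` is the planted compartment sign. Two normalizations matter:

* The compartment plaid **ramps in quadratically up to 2 Mb**. In real
  Hi-C the checkerboard is a long-range phenomenon; if it acted at short
  range its block edges would masquerade as TAD boundaries in the
  directionality index. Short-range structure belongs to the decay and the
  TADs.
* The combined modulation is **renormalized per diagonal** to mean one, so
  the marginal decay is exactly `s^alpha` and the planted exponent is the
  identifiable slope of P(s). Without this the checkerboard autocorrelation
  would bias the fitted exponent by more than its recovery tolerance.

Inter-chromosomal counts are uniform within a chromosome pair with pair
weights proportional to `exp(−|len_A − len_B|/trans_tau)` (default
30 Mb), planting the decline of trans contact probability with
chromosome-length difference; `trans_frac` (default 0.35) sets the expected
trans share of the `depth` total contacts, mirroring the roughly one-third
trans fraction of fibroblast Hi-C.

`simulate_tracks()` emits the annotation side of the world: CTCF-like
motifs with background density 2/100 kb plus one motif per planted TAD
border oriented convergently inward with probability
`(1 + convergence_bias)/2` (so `convergence_bias = 0` is the unoriented
null and the 3DR is ~1); TE coverage per 20-kb bin with SINE density
elevated and LINE density depressed in planted A bins (`sine_effect`,
`line_effect`, default ±0.08 on baselines 0.12/0.20); CNEs at
`cne_rate`/100 kb inside TAD interiors but at 30% of that rate within
±20 kb of a boundary; enhancers on SINE-rich bins (sampling probability ∝
SINE coverage², ~15 enhancers per Mb, a conservative vertebrate-like
density); and a gene-by-replicate TPM matrix in which genes sharing a
planted TAD load on a common factor so that same-TAD pairs have Pearson
correlation `coexpr_r` across replicates. Gene annotations combine the
uniformly spaced orthologs with extra genes whose density is fourfold
higher in ancestral A compartment — the gene-density signal that orients
compartment calling, as in real genomes.

What the generator does **not** emulate: sequence content, restriction
fragments, mappability and copy-number biases, rearrangements, sex
chromosomes, tissue heterogeneity, and any coupling between expression
level and compartment. Passing the planted-recovery tests therefore shows
the estimators are correct and well-calibrated on clean data of realistic
size and depth; it does not certify robustness to artifacts that only real
libraries contain.

## Contact-matrix methods

**Balancing.** `iterative_correction()` is a damped Sinkhorn iteration:
weights are updated by the square root of the marginal ratio until every
retained row's balanced marginal equals the mean within `tol` (default
1e-4). Bins whose raw marginal falls below the `low_coverage_quantile`
(default bottom 2% of nonzero marginals, standard practice) are masked
(weight NA) and excluded from every downstream statistic.

**Distance-stratified quantile normalization.** Within each genomic
distance stratum (one per resolution step; all trans counts form one
stratum), nonzero values are replaced by the mean quantile across samples
at matched plotting positions `(rank − 0.5)/n`; with equal counts this is
exactly the mean of order statistics. Distance decay is untouched because
strata never mix.

**Reproducibility (SCC).** Matrices are smoothed per chromosome with a
(2h+1)² box filter (integral-image implementation, windows truncated and
renormalized at edges; `h = 1` by default), stratified by distance up to
`max_dist` (default 5 Mb), and the stratum Pearson correlations are
averaged with weights `N_k·sd(x_k)·sd(y_k)` — the stratum-adjusted
correlation. The aggregate is the median across chromosomes.

**P(s).** Mean contact per distance stratum, normalized per chromosome so
the strata sum to one, then averaged unweighted across chromosomes (the
per-chromosome choice keeps chromosomes of different lengths comparable;
the alternative global normalization would overweight long chromosomes).
The slope is ordinary least squares of log10 P on log10 s inside
`fit_range`, default 1–10 Mb — the long-range window; at least 5 strata are
required. Planted exponents are recovered within ±0.02 at depths of a few
hundred thousand contacts on 30–50 Mb chromosomes at 100 kb resolution.

## Inter-chromosomal networks

For every bin pair on different chromosomes the observed count *k* is
tested against Binomial(n, m_norm), where *n* is the total count between
the two chromosomes and `m_norm` is the product of the bins' fragment
counts over the product of the chromosomes' fragment counts; fragment
counts are proxied by fixed-width sub-bins (default 5 kb) since only their
ratio enters. p-values are upper tails, BH-adjusted separately per
chromosome pair, and q-values are length-normalized by
`len_A·len_B / (L1·L2)` with L1, L2 the two longest chromosomes. Edges of
the bin interaction network are pairs with `q_norm` below `q_cutoff`
(default 1e-6, the high-confidence threshold; the threshold is exposed
because the networks at toy depth are sparser than at real depth).

Network statistics follow the printed formulas: network variance is the
sample variance of node degrees over the mean degree; the clustering
coefficient is the mean of `2e_n/(k_n(k_n−1))` with nodes of degree < 2 set
to zero; the characteristic path length is computed on the largest
connected component; the degree power-law slope is a log-log histogram
regression.

**Randomized controls** follow the quoted construction exactly: nodes are
placed uniformly in the unit cube, the |E| closest pairs become edges, and
10·|E| degree-preserving double-edge switches are attempted, each accepted
only if transitivity increases (with degrees fixed, connected triples are
constant, so the rule reduces to increasing the triangle count). A caveat
worth knowing: at small sizes the unit cube's boundary inflates degree
heterogeneity, so the mean network variance of these controls is ~1.3 at
200 nodes/600 edges and approaches 1 only as the network grows
(~1.18 at 2000/6000). The often-quoted "close to 1" behavior is a
large-network property; observed bin networks still exceed their controls
by an order of magnitude or more.

Gene interaction networks score each ortholog by the summed significant
trans contact frequency of its overlapping bins; species are compared by
Spearman correlation over shared orthologs and clustered by average
linkage on 1 − similarity.

## Chromosome territories

`embed_chromosome()` converts balanced contacts to distances
`d = (c/scale)^(−alpha)` (`alpha = 0.25`, the conventional
contact-to-distance exponent), completes unobserved pairs by shortest
paths, and embeds with classical metric MDS. The contact `scale` is a
single genome-wide mean, not a per-chromosome mean: a shared calibration is
what makes territory metrics comparable across chromosomes of one nucleus.
`ct_metrics()` takes the convex hull (an in-package incremental hull;
volume by tetrahedral decomposition, surface by triangle areas) and reports
VSR = V/S and VpM = V/Mb with stretchiness = 1/VSR and condensation =
1/VpM: for fixed volume the sphere minimizes surface, so larger 1/VSR means
a more stretched territory. Model units are arbitrary (they depend on the
MDS scale), so only orderings and correlations across chromosomes are
meaningful, never absolute magnitudes.

## Compartments, AB index, insulation, conserved states

Compartments are called per chromosome from the Pearson correlation matrix
of the observed/expected map (diagonals divided by their means; the self
diagonal set to the neutral value 1; chromosomes whose O/E map has no
variance are reported flat and flagged low-confidence). PC1 of that
correlation matrix is oriented so its Spearman correlation with gene
density is positive, and positive PC1 is compartment A; the first three
PCs are retained for diagnostics. The AB index at 20 kb is the normalized
contrast `(meanA − meanB)/(meanA + meanB)` of a bin's mean balanced
contact with A- versus B-labeled coarse regions — bounded in [−1, 1],
antisymmetric under label swap, positive = A. The insulation score is the
sliding-square statistic: mean contact in the `window`×`window` square
(default 500 kb) crossing each bin, log2-scaled to the chromosome mean of
those values; minima mark boundaries. The AB-index formula is not printed
in full anywhere authoritative; the normalized-difference form above is
this package's contract.

Cross-species conserved states use K-means (k-means++ seeding, fixed
seed, K default 30) on aligned per-bin species vectors, then merge states
whose mean vectors are mutually similar in cosine (threshold 0.85,
strict; a state joins the first qualifying group in state-index order).
Groups whose member means are positive in every species are CA (or CHI
for insulation after per-species median centering), all-negative groups
are CB/CLI, the rest NC/AI. This K-means + cosine grouping is a
documented stand-in for full phylogenetic hidden Markov Gaussian process
inference, which is a published method in its own right and outside this
package's scope; the state count K is exposed because the choice between
model-selected and fixed state counts is ambiguous in the source
literature. Percentages are recovered within a few tenths of a point on
planted worlds.

Cross-tissue consistency compares the fraction of conserved-positive and
conserved-negative bins whose sign is retained in an independent track
against permutation controls (random reassignment of the track), with a
two-sided Wilcoxon rank-sum test. Similarity-versus-divergence analyses
use cosine similarity, average-linkage trees, and Pearson correlation of
similarity against divergence time (half the cophenetic distance on the
dated tree).

## TADs

The directionality index at 20 kb contrasts upstream (A) and downstream
(B) contact sums within 2 Mb windows: `DI = sign(B−A)·((A−E)²/E +
(B−E)²/E)` with `E = (A+B)/2`, zero when A = B. Windows are truncated
symmetrically at chromosome ends — asymmetric truncation would bias every
start-of-chromosome bin toward positive DI.

Calling proceeds through a 3-state Gaussian-emission HMM (in-package
Baum–Welch with five restarts, fixed seed, Viterbi decoding). The HMM is
fitted not to the raw DI — whose chi-square-style tails make Gaussian
states split by scale instead of sign — but to
`sign(DI)·log1p(|DI|/MAD)`, which compresses the tails and, because of the
MAD standardization, makes the call exactly invariant to global rescaling
of the DI. Decoded biased runs shorter than `min_run` (default 2 bins) are
treated as noise. A domain opens at a downstream-bias run and closes at
the **last** upstream-bias run before the next downstream onset (upstream
bias near a domain end is routinely split into several runs). Gaps between
adjacent domains shorter than 400 kb are topological boundaries, longer
gaps are unorganized chromatin; domain edges facing unorganized chromatin,
orphan upstream runs and unclosed domain starts also contribute
boundaries. Within a nonzero gap the boundary position is refined to the
DI sign changepoint (the split maximizing negatives on the left and
positives on the right). With these choices ≥90% of planted boundaries are
recovered within ±1 bin at depths around 2 million contacts per 20–30 Mb
genome — comparable per-bp coverage to published fibroblast libraries.

Boundary conservation maps each query boundary through the ortholog
anchor maps and measures the distance to the nearest boundary in every
other species: conserved below 40 kb (2 bins), non-conserved above 100 kb
(5 bins), otherwise unknown — both thresholds strict. A boundary
conserved in all mappable species is conserved; non-conserved in all
others is gained; boundaries conserved in more than half of the species
but non-conserved in one are reported lost in that species (the majority
fraction is configurable).

## Sequence- and expression-level conservation

The 3DR is the ratio of median distances between contiguous convergent
(+,−) and divergent (−,+) motif pairs after dropping motifs below the
score quantile (default 0.7); like-strand pairs contribute to neither
median, and every adjacent surviving pair is classified — no pair
skipping. It is invariant to translation, chromosome relabeling and
coordinate scaling. CNE profiles enlarge each TAD by 50% per side,
partition the enlarged region into 10+20+10 equal bins and count CNEs
(score ≥ 0.95, length > 200 bp) by midpoint — midpoint assignment keeps
each CNE in exactly one bin so the profile conserves counts.

TAD conservation scores use consecutive single-copy ortholog pairs in
reference gene order (the "all pairs within a TAD" alternative is
implemented behind `mode = "all"`; consecutive is the default because
adjacent-pair co-residence is the stricter, less size-confounded notion of
a conserved pair). A pair intra-conserves a reference TAD when both genes
share one TAD in both species; inter-conservation asks only that the genes
stay on one chromosome in both species. In a rearrangement-free synthetic
world the inter score is trivially high — a deliberate limitation, since
rearrangements are out of scope. Co-expression stratification computes
replicate-wise Pearson correlations for gene pairs at each gene-count
distance d and compares the fraction above `r_cutoff` (default 0.9) between
same-TAD pairs and all pairs; at least three replicates are required.

## TEs and chromatin

TE records are merged within family before any coverage computation
(overlapping annotations must not double count), and families outside
SINE/LINE/LTR/DNA are discarded. The TE proportion of a bin pair is the
bp-fraction mean of its two bins. Contact-frequency filtering takes the
mean inter-domain contact frequency as the lower threshold, then walks
integer frequency levels from the top down and removes levels carried by
fewer than 100 bin pairs. Enhancer enrichment is the coverage density in
enhancer bp over the density in the complement, with a seeded bootstrap
over enhancer intervals; a whole-genome enhancer set has fold 1 by
convention. Per-ortholog enhancer TE coverage (±100 kb windows) feeds the
cross-species similarity-versus-divergence comparison.

## Expression

Gene TPM matrices are filtered at mean TPM > 0.5 across replicates (genes
failing the filter are flagged, never silently dropped) and log2(TPM+1)
transformed. Per-bin expression uses the two printed rules: a single TSS
in a 20-kb bin contributes log2(TPM+1); several TSSs contribute
log2(mean TPM + 1) — average first, then log. Cross-species normalization
is a median-of-ratios scaling on shared orthologs followed by per-gene
z-scores; the published recipe it stands in for is not reproduced in any
source available to this package, and the output labels the method
accordingly.

## Orchestration and problem sizes

`run_all()` executes the whole pipeline on one configuration
(`default_config()` / `read_config()` for YAML): 3 species, 2–3
chromosomes of 10–20 Mb, 1M contacts per species, 20 kb/100 kb/500 kb
working resolutions — about half a minute end to end, deterministic for a
fixed seed, with per-stage TSV outputs and the serialized configuration
when an output directory is set. The test suite validates each stage at
the smallest size where its signal is identifiable: 100-kb matrices on
10–50 Mb chromosomes for decay and compartments, 2M-contact 20-kb
matrices for TAD recovery, and 20-seed sign tests for every directional
cross-species claim. All thresholds keep their field defaults: q-cutoff
1e-6, cosine 0.85, co-expression r 0.9, boundary rules 40/100 kb,
unorganized gap 400 kb, motif quantile 0.7.

## Known limitations

* No rearrangements, so inter-TAD conservation and gene-network
  comparisons exercise only the distance-preserving part of the method.
* Model units of 3D embeddings are arbitrary; only orderings across
  chromosomes are interpretable.
* The unit-cube randomization's network variance exceeds 1 at small
  network sizes (boundary effect); compare observed networks against
  controls of the same size only.
* The Gaussian-HMM TAD caller is a reimplementation faithful to the
  published pipeline's outline, not call-for-call identical to any
  specific tool; its contract is planted-boundary recovery.
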