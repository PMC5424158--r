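---
title: "Marker-free tumour cell profiling from single-cell RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-free tumour cell profiling from single-cell RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumourtrace)
```

# The problem

Single-cell RNA-seq of dissociated tumour tissue captures a mixture of
carcinoma cells, infiltrating immune cells and stromal cells. Surface-marker
sorting is often unavailable or biased, so `tumourtrace` separates the
populations from the transcriptome alone, exploiting the one signal that
carcinoma cells cannot hide: aneuploidy. Genes are expressed roughly in
proportion to their DNA copy number, so averaging expression along the
chromosome turns per-gene noise into a regional dosage signal. Cells whose
smoothed chromosomal profile deviates coherently from a normal-tissue
reference are aneuploid (carcinoma); cells with flat profiles are diploid
(immune/stromal) and are then told apart by signature scores.

Downstream, carcinoma cells are classified into ER+/HER2+/TNBC compartments
by pathway module scores, TNBC cells into six subgroups by correlation with
reference centroids, and immune cells into lineages and functional states.

# Expression preprocessing

Input is a gene x cell TPM matrix. TPM values below 1 are treated as
unreliable and set to zero, then the matrix is transformed to
`log2(TPM + 1)`. Cells are filtered on four sequencing-QC criteria (total
reads, mapping rate, detected genes, intergenic fraction); the cutoffs are
configuration, not constants, defaulting to 1e6 reads, mapping >= 0.5,
>= 1000 genes and intergenic <= 0.3. Genes are removed unless expressed
(TPM >= 1) in at least 10% of the cells of at least one tumour group. The
"10% of all tumour groups" rule admits a second reading — expressed in at
least 10% of the *groups* — and both are implemented
(`filter_genes(rule = "max")`, the default, vs `rule = "groups"`); the
max-over-groups reading is the default because it retains genes restricted
to a single tumour subtype, which the subtype-marker analyses depend on.

Gene-level mean centring produces a third layer. Several analyses
deliberately read the *un-centred* log layer: spike-in ratio checks,
intratumoral correlations, rank-based (self-normalizing) set scores, and
centroid classification, where centring would fabricate signal for genes
that are simply zero in every cell.

ERCC-style RNA spike-ins (defaults 12,200, 912 and 62 copies) are carried in
a flagged side set: exempt from gene filtering, excluded from CNV inference,
used only by `check_spikeins()`, which reports per-cell pairwise
log2(TPM+1) ratios, flags cells deviating more than k standard deviations
from the cohort mean ratio, and reports spikes never detected (the 62-copy
spike is expected to be below the detection limit).

# Inferred copy number

1. **Reference.** Per-gene mean and sd of log2(TPM+1) over bulk
   normal-tissue samples (>= 2 required). Standard deviations are floored at
   0.1 log2 units so near-constant reference genes cannot generate huge
   Z-scores.
2. **Z-scores.** `Z = (log_expr - mean_ref) / sd_ref`, clamped to [-3, 3].
   The clamp stops single-gene dropout spikes from dominating a 150-gene
   window; it is a numerical choice the source analysis leaves open.
3. **Smoothing.** Genes are sorted by (chromosome, start) and each gene's
   value becomes the mean Z over a window of 150 position-sorted genes
   centred on it. Windows never cross chromosome boundaries and *shrink*
   at chromosome ends rather than dropping edge genes, keeping the profile
   the same length as the gene list (necessary for clustering cells on
   profiles). For an even window the extra gene is taken downstream
   (window `[i - 74, i + 75]` for 150).
4. **Centring.** "Centred across genes" is read as per-cell centring: each
   cell's genome-wide mean smoothed value is subtracted, so a profile is a
   deviation track around the cell's own baseline. Per-gene centring is
   available via `centre = "gene"` for users who prefer the alternative
   reading.

For concordance with DNA evidence, both the inferred track (averaged over
cells) and WES-derived segments (> 10 kb only) are binned onto 10 Mb
half-open windows — gene bins average the genes whose start falls inside;
segment bins take overlap-length-weighted means with uncovered bases
counting as diploid (ratio 0) — and compared by Pearson correlation over
bins non-missing in both tracks.

A known limitation: the RNA dosage response saturates for homozygous
deletions — the affected genes are mostly dropout-zero whatever the true
copy number, and the Z-clamp bounds the remaining signal — so concordance
improves with the strength of the dosage response only up to roughly half
of the full `log2(CN/2)` effect and plateaus beyond.

# Cell typing

Cells are Ward-clustered (on Euclidean distance, `hclust` method
`ward.D2`) over their smoothed profiles; neither metric nor linkage is
prescribed by the source analysis, and these are the standard defaults for
expression profiles. The number of clusters is an analyst parameter
(typically patients + 1); `choose_n_clusters()` offers a mean-silhouette
selection when no prior is available.

Each cell gets a **CNV signal** score: the mean squared value of its
centred profile (profile energy). A cluster is *carcinoma-like* iff

* its median CNV signal exceeds `t_cnv` (default 0.022), **and**
* it is dominated by one tumour group (>= `f_dom`, default 0.5, of members
  from a single patient).

The dominance condition encodes the observation that carcinoma clusters are
patient-specific while the non-carcinoma cluster mixes patients. The
`t_cnv` default was calibrated once on the bundled generator's default
conditions as the midpoint (on the log scale) between the energy of diploid
profiles (smoothing noise, ~0.015) and the weakest aneuploid configuration
the generator produces (three minimal CN=3 segments, ~0.027); it is a
configuration value, not a constant.

Cells outside carcinoma-like clusters are called **immune** when their
immune signature score is high, else **stromal** when the stromal score is
high, else flagged unclassified (counted as stromal only when the
epithelial score is also low, configurable). Signature scores use a
rank-based single-sample enrichment statistic (below) on immune/stromal/
epithelial gene sets supplied as GMT (e.g. published tumour-purity
signatures). Because the absolute level of a rank-based score depends on
the gene set's baseline expression, the default cutoffs are data-driven:
an Otsu-style cut maximizing between-class variance of the cohort's score
distribution, which is strongly bimodal in a mixed tumour. Fixed numeric
cutoffs can be supplied instead; the data-driven default assumes both
modes are present and should not be used on cohorts known to be pure.

**Single-sample set score.** For each cell, genes are ranked by expression
(descending, ties averaged). Walking down the ranking, the in-set
cumulative distribution — weighted by rank magnitude to the power
`alpha = 0.25` — is compared with the unweighted out-of-set cumulative
distribution; the score is the mean difference over all positions. It lies
in (-1, 1), is positive when set genes concentrate at the top, and depends
on expression only through ranks, hence is invariant to any monotone
per-cell transform (and to whether TPM or log-TPM is supplied).

**Correlation structure.** Pairwise Pearson correlations between cells of
the same tumour group on the un-centred log layer, before and after
restricting to carcinoma calls, quantify how much microenvironment
admixture deflates within-tumour similarity.

# Carcinoma subtyping

**ER/HER2 module scores** are signed weighted means of centred log
expression over curated ER- and HER2-signalling modules:
`score = sum(w_i x_i) / sum(|w_i|)`. The classification rule is two
axis-aligned thresholds with HER2 precedence — HER2+ if
`her2 > t_HER2`, else ER+ if `er > t_ER`, else TNBC. Precedence follows
clinic-style calling where HER2 amplification dominates; ER positivity of
HER2+ cells is retained as evidence, so a threshold configuration can
still express ER-dominant calling. Thresholds are fitted on a labelled
reference by exhaustive grid search over observed score values maximizing
accuracy, ties resolved toward the smallest thresholds (lexicographically
HER2 then ER) for determinism.

**TNBC subgroups.** Cells are correlated (Spearman) with six subtype
centroids over the intersecting signature genes, after removing genes
never expressed in any cell and *without* centring. A cell is assigned to
every subtype with rho > 0 and p < 0.05 — possibly several, possibly none.
Spearman p-values use the t approximation at n >= 12 genes and the exact
permutation distribution below that. Proprietary centroid tables are user
input; the bundled `make_centroids()` builds synthetic stand-ins for tests.

**Aggressiveness signatures** (EMT, stemness, angiogenesis, proliferation,
recurrence) are scored per cell with the rank-based statistic; pairwise
Pearson correlations across cells quantify co-activation, and cells at or
above the top-5% cutoff on both members of a pair are flagged as rare
co-activated candidates (the cutoff is the `ceil(0.05 n)`-th largest score,
so exactly that many cells reach it when scores are tie-free).

# Immune profiling

**Lineages.** Non-carcinoma cells are factorized by NMF (`V ~ W H`,
Frobenius loss, Lee–Seung multiplicative updates, written here because no
NMF package is a dependency) on the non-negative log layer restricted to an
immune cell-type signature list; the best of 10 seeded random restarts is
kept and cells are assigned to the factor with the largest `H` coefficient.
The multiplicative updates guarantee a non-increasing reconstruction error,
which the tests assert.

**Markers.** One cluster vs rest, a gene is a marker iff log2 fold change
(difference of group means on the log layer) > 1, ROC AUC > 0.7 and the
zero-inflated LRT p < 0.05. AUC is the Mann–Whitney statistic
`U / (n_pos n_neg)` with ties counting one half.

**Zero-inflated LRT.** Each group's expression is a point mass at zero
(probability `1 - pi`) plus a Normal on the positive log values. The
alternative fits group-specific `(pi, mu)` with sigma pooled over all
positive values; the null shares `(pi, mu, sigma)`. The statistic
`2 (l_alt - l_null)` is referred to chi-square with 2 df (detection rate +
location). The original "bimod"-style test leaves the sigma
parameterization open; pooling sigma keeps the test focused on detection
and location shifts and gives 2 df — `pooled_sigma = FALSE` frees sigma
(3 df) for users preferring the other reading. Groups with no positive
values sit at the `pi` boundary and contribute nothing from the normal
part; sigma estimates are floored at 1e-6 so degenerate groups cannot
produce infinite likelihoods. Under a null simulation (50 vs 50 cells) the
chi-square reference holds its nominal 5% size to within about a point.

**Enrichment.** Over-representation of marker lists in user-supplied term
maps uses the upper-tail hypergeometric test within a finite universe;
zero-overlap terms report p = 1.

**Functional states.** T cells (or any subset) are scored on five state
sets (naive, costimulatory, regulatory, exhaustion, cytotoxicity) with the
rank-based statistic and Ward-clustered on the 5-score vectors; B-cell
subclass analyses are the same operation with B-cell sets.

# The synthetic generator

`simulate_experiment()` builds the full study: an evenly spaced gene
annotation over `n_chromosomes` chromosomes; carcinoma clones with
non-overlapping aneuploid segments (CN drawn from {0, 1, 3, 4}, each
segment covering 20–50% of a chromosome); and cells whose latent log2
mean is

```
baseline(gene) + attenuation * log2(CN / 2) + marker_effect * 1[marker]
```

with CN 0 mapped to 0.1 copies so homozygous deletions keep a finite
(strongly negative) signal. Baselines are Normal(2.5, 2) log2 units and are
shared with the simulated bulk normal reference. Gaussian log2 noise
(sd 1) is added, values are exponentiated, zeroed with a mean-dependent
logistic dropout (50% at log2 mean 1.5, slope 1 — a standard scRNA-seq
assumption; the source analysis states no dropout model), joined by
fixed-copy spike-ins, and renormalized to a 10^6 TPM column sum.

Defaults are the study conditions used throughout the tests: 3000 genes on
5 chromosomes of 100 Mb, 300 carcinoma cells in 3 clones of 3 segments
(one clone per synthetic patient), 75 T / 45 B / 30 macrophage / 30
stromal cells spread across patients, 25-gene marker modules at +4 log2,
attenuation 0.5, 20 bulk normals. The CNV-recovery condition uses 100
carcinoma cells with a single 3-segment clone; the marker-recovery
condition uses two immune populations of 50 and 100 cells with 50-gene
modules at +3 log2. These sizes make the full suite run in about a minute
and a half on one core while leaving comfortable statistical margins.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: UMI/read-level noise, batch and
cell-cycle effects, doublets, continuous differentiation gradients,
subclonal CNV heterogeneity within a clone, correlated gene modules beyond
the planted markers, and realistic gene-density/chromosome-length
variation. Thresholds calibrated on the generator (`t_cnv`, and the
generator's own marker effect sizes) transfer to real cohorts only as
starting points.

# Numerical choices and degenerate inputs

* Z clamp ±3; reference sd floor 0.1; LRT sigma floor 1e-6.
* Windows shrink at chromosome ends; chromosomes with no genes are
  skipped with a message.
* Bins are half-open, 0-based internally; BED files are converted to
  1-based inclusive on load. Empty bins are missing and excluded from
  correlations; concordance requires >= 3 shared bins and errors on
  constant tracks rather than returning NaN.
* Rank ties: average ranks in set scores and AUC; threshold grid ties:
  smallest thresholds; `which.max` ties in NMF assignment: lowest factor
  index.
* The TPM threshold-then-log transform is order-preserving on TPM >= 1;
  filters are idempotent and commute when gene margins are robust (a
  borderline 10% gene can legitimately flip when cells are removed).

# Reported figures of merit

`scripts/acceptance.R` regenerates, from a fresh seed: CNV-recovery
Pearson r (single clone, 100 cells), per-class recall and carcinoma
accuracy of the marker-free classifier over five seeds of the default
mixture, the LRT null rejection rate (2000 genes, 50 vs 50), marker
recall/false-positive rate under the fold/AUC/LRT rule, within-group
correlation medians before and after carcinoma restriction, and centroid
self-consistency. The vignette states no number the tests or that script
do not themselves compute.
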