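---
title: "Methods: methylation evolution and ITH in staged tumor precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation evolution and ITH in staged tumor precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methevo)
```

# Scope and data model

`methevo` analyses paired tumor/normal bisulfite sequencing data at three
resolutions: single CpGs (coverage-level methylation calls), 4-CpG
read-level epiallele windows, and genomic intervals (DMRs, region sets,
5-kb tiles). All in-memory positions are 1-based cytosine coordinates on
the forward strand; CpG calls from the reverse strand are assumed to have
been collapsed onto the forward C before entry, since all analyses here
treat a CpG as a single strand-symmetric unit. BED input/output is 0-based
half-open, with conversion confined to the readers and writers. Coverage
files carry a percent-methylation column, but beta is always recomputed
from the integer read counts to avoid rounding drift. Sites with zero
coverage are never stored, so beta is always defined.

# Epiallele entropy and eloci

At a 4-CpG locus covered by one read, the methylation pattern is one of
$2^4 = 16$ epialleles. For pattern frequencies $F_1,\dots,F_{16}$ the
combinatorial entropy is

$$S = \frac{100}{4}\sum_{i=1}^{16} F_i \log_2 F_i, \qquad 0\log_2 0 := 0,$$

a scaled Shannon entropy on $[-100, 0]$: $S = 0$ iff the locus is
monoclonal and $S = -100$ iff all 16 epialleles are equally frequent. The
$100/4$ scaling is the convention under which the customary eloci cutoff
($\Delta S < -60$) and the percentile summaries used in this field are
expressed; we adopt it as the package's fixed scale.

The epiallele shift of a lesion locus against its matched normal is
$\Delta S = S_{\text{lesion}} - S_{\text{normal}}$, computed only for
windows with at least `min_window_reads` (default 60) reads in *both*
samples — a one-sided deep window has no defined shift. Windows are keyed
by the exact tuple of their four CpG positions, so staggered windows from
overlapping reads are distinct loci; reads covering fewer than four CpGs of
a window are not part of the pattern counts. Loci with $\Delta S$ strictly
below the threshold (default $-60$; $\Delta S = -60$ exactly is not an
elocus) are eloci. Per-sample eloci counts are normalized as
$\text{eloci}/\text{assessed} \times \overline{\text{assessed}}$ over the
cohort, which removes the mechanical dependence of raw counts on per-sample
coverage.

Epipolymorphism is built from $\sum_i F_i^2$. The package's default
`"diversity"` convention reports $1 - \sum_i F_i^2$ (0 monoclonal, 15/16
uniform), which increases with epiallele diversity and is the scale on
which staged comparisons are most interpretable; the `"as_printed"`
convention reports $\sum_i F_i^2$ itself. The two always sum to one, and a
switch is provided because both appear in the literature.

Group comparisons of $\Delta S$ and epipolymorphism use quantile estimates
defined as pinball-loss minimizers,
$\hat q_\tau = \arg\min_q \sum_i \rho_\tau(x_i - q)$ — the quantile
regression estimator with a group-indicator design, evaluated per group.
$\Delta S$ is compared at $\tau = 0.01$ (the informative lower tail) and
epipolymorphism at $\tau = 0.5$. When the minimizer is an interval, the
lower endpoint is returned, which makes estimates deterministic; we
implement the minimization directly on the observed support rather than
calling a quantile routine, and cross-check the indicator-design identity
with `stats::quantile(type = 1)` in the tests. Only the indicator design is
supported — no covariates — since the staged comparison needs nothing more.

Windows are stratified into region classes (promoter, enhancer,
transcribed, heterochromatin, repeat, PMD) by $\ge 1$ bp overlap of the
4-CpG span; a window may belong to several chromatin classes, while
inside/outside PMD (and repeat/non-repeat for DMRs) form binary
partitions.

# Paired DMR calling

DMRs are called per lesion specimen against its patient's normal:

1. restrict to CpGs with $\ge$ `min_reads` (default 10) in both samples;
2. smooth methylated and total counts with a triangular kernel,
   $\tilde M(x) = \sum_j \max(0, 1 - |x_j - x|/h)\, M_j$ with half-width
   $h$ = 100 bp (the site itself gets weight 1, so isolated CpGs are
   untouched and $h \to 0^+$ recovers raw counts);
3. test each CpG with a two-sided Fisher exact test on the *rounded*
   smoothed counts (the exact test is defined on integers), tumor vs
   normal, methylated vs unmethylated;
4. flag CpGs with $p <$ `max_p` (0.01) and smoothed
   $|\Delta\beta| \ge$ `min_abs_delta_beta` (0.2), with direction from the
   sign of $\Delta\beta$;
5. merge consecutive same-direction flagged CpGs within `merge_gap`
   (200 bp); drop regions with fewer than `min_cpgs` (4) flagged CpGs or
   narrower than `min_width` (50 bp). The region p-value is the minimum
   member p-value.

These defaults mirror the documented defaults of kernel-smoothing
noise-filter DMR callers for bisulfite data; every one of them is exposed
in `dmr_params()` and recorded in the pipeline manifest. The per-CpG
two-sided Fisher p is computed by a vectorised hypergeometric enumeration
(the classical two-sided definition, summing point probabilities no larger
than the observed one); `stats::fisher.test` computes the identical
quantity but is orders of magnitude too slow for per-CpG use, so it serves
as the oracle in the tests instead.

CpG-level hyper/hypo classification follows the 20% rule: *hyper* = inside
a gain DMR with normal methylation $\le 20\%$; *hypo* = inside a loss DMR
with normal methylation $\ge 20\%$. Counts of such CpGs are normalized
across samples with the same cohort-mean formula as eloci; the analogous
normalization for DMR counts is a documented reconstruction, as no
canonical formula exists for it.

Tile-level summaries average beta over non-overlapping 5-kb tiles anchored
at position 1 of each chromosome (tile phase is otherwise arbitrary;
anchoring at 1 makes it deterministic), using unweighted means over member
CpGs with $\ge 10$ reads.

# Phylogenetics

Methylation distances are Euclidean over shared beta vectors after two
filters: per-CpG coverage in *all* samples of the group, and variability
measured by the mean absolute deviation of beta on the percent scale,
$\mathrm{MAD} = \tfrac1n\sum_s |100\beta_s - \overline{100\beta}|$. Two
presets follow common practice: tree building on promoter CpGs (TSS
−1 kb/+500 bp) with $\ge 50$ reads and MAD $> 10$ percentage points;
distance-correlation analyses on all CpGs with $\ge 20$ reads and MAD
$\ge 20$. The MAD thresholds are interpreted in percentage points (the
natural reading of "10%" for a quantity that is itself a percentage), and
both are exposed.

Genetic distances are Hamming distances between variant sets (symmetric
difference size) over the per-lesion variant universe. Trees are built by
Saitou–Nei neighbor joining via `ape::nj` — the standard implementation in
this field — and re-rooted at the matched normal. Negative NJ branch
estimates (possible for non-additive inputs) are clamped to zero with the
deficit moved to the sibling edge, preserving path lengths as far as
possible; tie-breaking inside the NJ Q-matrix follows `ape`'s
deterministic implementation. For the pooled parallel-evolution analysis,
each lesion's pairwise distances are divided by the within-lesion maximum
before pooling, putting lesions of different absolute scales on a common
$[0,1]$ axis; this normalization is a documented reconstruction. Spearman
correlation between the aligned genetic and methylation pair lists uses
the exact permutation distribution for $n \le 9$ pairs and the
large-sample approximation otherwise.

# Genomic context

The LINE-1 surrogate is the unweighted mean beta over CpGs with $\ge 10$
reads inside user-supplied L1HS/L1PA intervals, averaged per CpG (not per
element — the per-element average is an equally defensible unstated
alternative; per-CpG is simpler and uses all reads). Burden correlations
(against copy-number burden, allelic-imbalance counts, log2 mutation
burden, clonal-mutation fraction, or externally supplied immune ratios)
are two-tailed Spearman. Elocus-to-TSS distances are measured from the
window midpoint (the anchor is unstated in common practice; the midpoint
is symmetric) to the strand-aware TSS point, negative upstream.

Region-set enrichment is a generic locus-overlap analysis: query loci
(e.g. eloci of one stage) versus a background universe (all loci assessed
at $\ge 60$ reads), hit = $\ge 1$ bp overlap with the target set, one-sided
Fisher exact test (upper hypergeometric tail) for over-representation,
Benjamini–Yekutieli adjustment across target sets — valid under arbitrary
dependence between targets, which overlapping chromatin-mark sets
certainly exhibit. Query regions must be a subset of the background;
violators are dropped with a warning rather than silently extending the
universe.

# The synthetic cohort generator

The generator exists because staged multi-region RRBS cohorts are
controlled-access. It emulates the *structure* of such a cohort — not any
particular dataset — with known ground truth:

- **Genome.** One synthetic chromosome laid out as cassettes of promoter
  CpG island (low beta, Beta(1.5, 15)), enhancer, transcribed and
  heterochromatin segments (high beta, Beta(12, 2.2)), and repeats, with
  LINE-1 elements (beta ≈ 0.85, Beta(30, 5.3)) in alternating repeat
  segments, TSS points in promoters, and a PMD spanning the second half of
  the genome. 4-CpG epiallele windows (span < 100 bp, so the four CpGs fit
  on one read) and single CpGs fill the segments.
- **Coverage.** Negative-binomial, mean 60 and dispersion 0.3
  (variance $= \mu + 0.3\mu^2$), floored at 10 reads — the coverage regime
  of deep RRBS.
- **Trunk events.** Gain DMRs shift beta up by $0.4 + U(0, 0.25)$ in
  randomly chosen promoter islands; loss DMRs shift beta down by the same
  magnitude in heterochromatin. The $|\Delta\beta| \ge 0.4$ floor makes
  recovery coverage-limited rather than effect-limited. Hosts are drawn
  only from segments with $\ge 4$ CpGs spanning $\ge 50$ bp, so that
  recovery is not annotation-limited either: a planted event in a
  two-CpG segment would be undetectable by any caller with a sane
  minimum-CpG gate.
- **Stage presets** (`stage_params()`): gain DMRs 6/14/20/26 and loss DMRs
  0/8/16/24 for AAH/AIS/MIA/ADC (hypermethylation from AAH onward,
  hypomethylation only from AIS onward, totals strictly increasing);
  Dirichlet concentration 80/30/18/8 (diversity increasing); LINE-1
  decrement 0.02/0.06/0.10/0.15; trunk mutations 20/40/70/120 and private
  mutation scale 8/15/25/40. These values are the generator's fixed study
  conditions, chosen once to separate the stages by roughly the planted
  trends' noise scale at the default genome size.
- **Epialleles.** Tumor pattern probabilities are Dirichlet with parameter
  $\alpha\, e_{\text{dominant}} + \mathbf{1}$: a concentration $\alpha$
  pulls mass onto the ancestral epiallele over a flat base, so lower
  $\alpha$ yields more diverse draws. This direction matters: a symmetric
  or fixed-base Dirichlet$(\alpha m)$ has the opposite monotonicity
  (draws become *sparser*, hence less diverse, as $\alpha \to 0$), and
  would invert the intended stage trend. Normals use a strong pull
  ($\alpha = 300$ over a 0.3 base). Counts are multinomial with
  $60 + \mathrm{NB}(20, 4)$ reads per window.
- **Clone tree and coupling.** Each lesion is a two-level clone tree:
  a trunk shared by all regions (trunk DMRs, trunk mutations, LINE-1
  loss) plus one private branch per region. Region $k$ has private
  mutation load $\propto r_k \sim U(0.4, 1.6)$ and private methylation
  event count $\propto \lambda r_k + (1-\lambda) s_k$ with independent
  $s_k$: $\lambda$ (the preset `coupling`) is the fraction of private
  methylation load riding on the mutation-bearing branches, so
  $\lambda = 1$ makes genetic and epigenetic distances share their
  region-level ordering and $\lambda = 0$ decouples them. Private events
  shift beta by 0.65 in one region only — deliberately above the 0.4
  trunk floor, because an event private to one of four regions has
  MAD $= 2\Delta(n-1)/n^2$ across regions, and $\Delta = 0.65$ is the
  smallest round value that clears the 20-percentage-point MAD feature
  filter at $n = 4$; a 0.4 private event would be silently removed from
  the distance feature space. At AAH (no planted losses anywhere) private
  events are hypermethylation in unused promoters; at later stages they
  are hypomethylation in enhancer/transcribed segments.
- **Mutations.** Trunk and private variant sets at uniformly drawn
  positions with random ref/alt; Hamming distances between regions are
  then exactly the sums of private loads.

Everything is deterministic given the seed, including the on-disk bundle
(coverage files, pattern TSVs, BEDs, mutation table, sample sheet, JSON
manifest with MD5 checksums).

What the generator does *not* emulate: bisulfite conversion errors,
read-level sequence context, CpG-island shores and gradual boundary
effects, copy-number-driven coverage waves, subclonal fractions within a
region (each region is a pure clone), inter-patient baseline variation,
and any genome-scale correlation structure beyond the cassette layout.
Tests passing on this generator therefore validate the *estimators and
their contracts* — recovery of planted effects at realistic coverage, the
direction and ordering of stage trends, determinism — not performance on
real tissue, where effect sizes, purity and confounding are less
favorable.

# Default problem sizes

The default genome has 2,400 CpGs with 240 epiallele windows (about 66
cassettes, ~680 kb), and the default cohort is 3 patients × 4 staged
lesions, with one patient profiled in 4 regions per lesion. These sizes
were chosen so that every stage trend the generator plants is resolvable
above sampling noise while the complete pipeline and its replicate-based
validation remain interactive (seconds to a few minutes); all of them
scale up through `default_cohort_config()` without code changes.

# Numerical and degenerate-input choices

- Entropy uses $0 \log 0 = 0$; zero-total windows are an error, never a
  silent NaN.
- Smoothed counts are rounded to the nearest integer before the Fisher
  test; the test is undefined otherwise.
- Quantile ties take the lower endpoint of the minimizing interval.
- NJ negative branches are clamped with sibling compensation; zero
  matrices give zero-length trees.
- `normalize_pairwise` maps an all-zero matrix to zeros rather than
  dividing by zero.
- Readers fail loudly with line numbers on malformed input; zero-read
  coverage rows are skipped with a warning, since they carry no
  information but are common in real exports.
- Empty intersections (no shared windows, no shared CpGs, no qualifying
  LINE-1 CpG) warn or error by whether an empty result is analytically
  meaningful (shift records: yes; a distance matrix: no).

# Known limitations

- The DMR caller is strictly paired (one lesion vs its normal); no
  population-level or multi-sample DMR model is provided.
- No per-locus significance testing of $\Delta S$ beyond the fixed
  threshold; the threshold convention is the field's, not a calibrated
  error rate.
- Quantile comparisons support group indicators only, no covariates.
- No bootstrap support, likelihood or Bayesian trees; NJ only, as is
  standard for small multi-region panels.
- Immune deconvolution, motif discovery, purity estimation, and CNV/AI
  calling are out of scope; their outputs enter only as optional columns
  or user-supplied BEDs.
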