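---
title: "Protease activity analysis with proteasekit: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protease activity analysis with proteasekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteasekit)
```

`proteasekit` analyses three kinds of protease activity measurements:
substrate-screen summary matrices, raw fluorogenic progress curves, and
sample × reporter matrices from in vivo activity-based nanosensors. This
vignette documents the models behind each analysis, the tunable parameters
and their defaults, the synthetic-data generators used for validation, and
the design decisions taken where more than one reasonable convention
exists.

## The data model

A fluorogenic (FRET-paired) peptide substrate fluoresces when cleaved, so
proteolysis appears as a rising intensity curve over time. A screen
summarizes many such assays as an *n* substrates × *k* conditions matrix
(`screen_matrix`), where a condition is typically a recombinant protease
but may be a lysate or biospecimen. Raw instrument exports are handled as
wide CSV (`kinetic_raw`): one row per (substrate, condition, replicate)
series, one column per time point, time always in minutes at the I/O
boundary. In vivo data are *n* samples × *k* reporters concentration
matrices with a class label per sample (`reporter_dataset`).

Labels are matched case-insensitively after whitespace trimming but keep
their original spelling. Duplicate labels are an error by default; a
mean-collapse policy is available for plate exports that repeat rows.
Missing cells stay missing (`NA`) and are excluded from statistics — they
are never zero-filled, because a missing well and an uncleaved substrate
are different observations.

## Efficiency and specificity scores

For an activity value $x_{ij}$ (substrate $i$, protease $j$), the
**efficiency** score is the standard score of $x_{ij}$ within protease
$j$'s column — how strongly $j$ cleaves $i$ relative to the other
substrates offered to it — and the **specificity** score is the standard
score within substrate $i$'s row — how preferentially $i$ is cleaved by
$j$ relative to the other proteases assayed. An SvE (specificity versus
efficiency) table pairs the two for every cell; the best
protease–substrate pairs score high on both. Because a standard score is
undefined for a constant vector, constant rows or columns score exactly 0
(not `NaN`): this guard keeps rankings total and is applied everywhere
z-scores appear, including database queries.

Database queries (`query_protease()`, `query_substrate()`) combine the two
scores as their arithmetic mean, per screen, then average over the screens
containing the query; ties are broken lexicographically by label so output
is deterministic. The combined-mean ranking is a package convention — it
weighs "cleaved strongly" and "cleaved selectively" equally, which matches
how screens are read in practice, but any monotone combination would
produce similar top ranks. Per-screen scores are retained on the result
(attribute `per_screen`) so users can reweight.

## Sequence similarity

The similarity ratio between two peptides is $1 - d/\max(|a|,|b|)$ for
Levenshtein distance $d$ — the simplest monotone normalization onto
$[0,1]$, with 1 if and only if the sequences are identical and two empty
sequences defined as identical. An alternative indel-style normalization,
$(|a|+|b|-d)/(|a|+|b|)$, is available via `normalization = "indel"` for
parity with common fuzzy-matching libraries. Scores are reported on
$[0,1]$, not 0–100.

The **partial ratio** slides the shorter sequence across every
equal-length window of the longer one and keeps the best ratio. It scores
1 whenever the shorter sequence appears verbatim inside the longer — the
motif-with-different-spacers case it exists for (e.g. `PLGL` flanked by
`GG` versus `GS`). Note that when neither sequence contains the other, the
partial ratio can fall *below* the full-sequence ratio: a single interior
insertion costs 1 edit against the full sequence but forces larger window
mismatches. Both metrics are computed on every hit that `query_sequence()`
returns.

k-mer motif search is case-insensitive exact substring matching; match
positions are reported 0-based and overlapping occurrences are all counted
(`AA` occurs at 0, 1, 2 in `AAAA`). Library-diversity clustering builds
the full pairwise similarity matrix and clusters the distance
$1 - \mathrm{sim}$ with average linkage by default.

The packaged ortholog table (`inst/extdata/orthologs_synthetic.csv`) is a
small synthetic stand-in covering common protease families with standard
symbol-casing conventions; it distinguishes "gene present, no ortholog in
the target species" (`NA` plus a warning) from "gene unknown" (an error),
and users with broader needs supply their own four-column table.

## Kinetics: initial rates and fold changes

The initial rate is the ordinary least-squares slope of intensity versus
time over the **rate window**: all points within the first `minutes`
minutes (default 30) or the first `min_points` points (default 5),
whichever set is larger. Replicates are averaged pointwise before fitting
(per-replicate fitting then averaging the slopes is available via
`replicate_policy`). On a saturating progress curve
$F(t) = F_0 + A(1 - e^{-kt})$ the OLS slope underestimates the true
initial rate $A k$ by roughly $k w/2$ for window length $w$, so the window
should be short relative to $1/k$; the default suits typical plate runs
where saturation takes hours, and the window is the first parameter to
tighten for fast kinetics.

Fold change is $I(t_{\mathrm{eval}})/I(t_0)$, evaluated at the last common
time point by default and linearly interpolated for interior times.
Background policies: none (default), blank-well subtraction (subtracts the
blank from numerator and baseline), and first-point subtraction with a
floor of $10^{-6}$ to keep the ratio defined. Fold change is invariant to
rescaling a series, as it must be for an arbitrary-units measurement.

Clustering of activity tables is agglomerative with average linkage and
Euclidean distance by default, run independently on rows and columns
(`cluster_bidirectional()`); rows can be z-scored first, as cleavage
heatmaps usually are. Condition–condition similarity uses the Spearman
rank correlation across substrates (average ranks for ties); constant
conditions have undefined correlation and return `NA` with a warning
rather than a silently imputed value. Catalytic-class susceptibility
summaries count, per substrate, the proteases of each class (metallo,
serine, cysteine, aspartic, other) whose fold change reaches a threshold;
the default threshold of 1.5 is a conservative "clearly above baseline"
convention — screens with low dynamic range may need 1.2, strongly
activated ones 2.

## In vivo reporter analysis

Urinary reporter concentrations vary with overall urine output, so the
default normalization (`sample_relative`) divides each sample by its
reporter total: rows sum to 1 and per-sample scale cancels exactly. The
`reporter_mean` option additionally divides each reporter by its
across-sample mean to put reporters on a common scale. Sample-relative
normalization couples reporters: a genuine enrichment in one reporter
slightly depresses the relative values of the rest, which attenuates
measured fold changes (a planted 4× effect on one of 14 reporters reads
as ≈3.3×). This is inherent to compositional data, not an artefact, and
is why fold changes are reported on the normalized scale used for
testing.

Differential enrichment runs a two-sided Mann–Whitney U test per reporter
(exact null when both groups have ≤ 8 samples; tie-corrected normal
approximation otherwise — at 10 vs 10 the approximation's attained level
at nominal 0.05 is ≈ 0.043, slightly conservative as rank tests are), with
Benjamini–Hochberg adjustment by default (Bonferroni available) and a
Welch t-test alternative. PCA is the eigendecomposition of the covariance
of the (optionally standardized) matrix; each component's sign is fixed so
its largest-magnitude loading is positive, making scores reproducible
across runs; explained-variance ratios are eigenvalues over total
variance and sum to 1 over all components of centred data.

Classification uses stratified 5-fold cross-validation (folds never exceed
the smaller class count). Three algorithms are supported: a linear-kernel
SVM (cost 1), a random forest (500 trees), and a ridge-regularized
logistic regression (`glmnet`, fixed $\lambda = 0.01$) — the latter is the
package's "linear model" classifier, preferred over least-squares on 0/1
labels because logistic loss is the proper classification objective while
keeping interpretable linear weights. Features are z-scored using
training-fold statistics only for the SVM and linear model; the random
forest is scale-equivariant and sees raw values. AUC is computed per fold
on held-out samples with the ROC direction fixed a priori (so a chance
classifier averages 0.5 rather than being folded upward), and the pooled
out-of-fold scores give the ROC curve. All randomness — fold assignment,
forest bootstraps — derives from the `seed` argument via per-component
substreams, and seeded functions restore the caller's RNG state on exit,
so package calls can be interleaved with user-level simulation loops
without perturbing either stream.

Recursive feature elimination repeatedly drops the reporter with the
smallest importance (absolute linear weight, or Gini importance for the
forest), recording the cross-validated AUC at every panel size; the
ranking is the reverse elimination order with importance ties broken by
dropping the lexicographically later reporter. Multiclass problems
(3+ classes) are evaluated by out-of-fold prediction into a confusion
matrix whose row sums equal the per-class sample counts.

## Synthetic data: what it emulates, and what it does not

`gen_kinetic_screen()` draws, per substrate–protease pair, an amplitude
$A \sim U(100, 500)$ intensity units, rate constant
$k \sim U(0.002, 0.008)\,\mathrm{min}^{-1}$ and baseline
$F_0 \sim U(40, 60)$, then samples
$F(t) = F_0 + A(1 - e^{-kt}) + \varepsilon$, $\varepsilon$ Gaussian
(optionally scaled to the amplitude), truncated at zero, in triplicate —
values typical of fluorogenic screens read on the tens-of-minutes scale.
A linear early-phase mode generates $F_0 + Akt + \varepsilon$ for
analyses confined to the pre-saturation regime. `gen_reporter_dataset()`
is lognormal: reporter base levels $e^{N(\log 100,\, 0.25)}$, per-class
multiplicative effects, and log-scale noise of 0.25 by default (a ~25%
CV, realistic for urinary reporter quantification).
`gen_substrate_library()` plants each requested motif in exactly the
requested number of sequences and rejection-samples the rest motif-free.
All generators are pure functions of (specification, seed).

What passing the validation suite on these generators demonstrates:
correct propagation from raw series to derived tables, correct statistics
under the stated models, and recoverability of planted structure at the
stated effect sizes. What it does not demonstrate: robustness to
instrument drift, inner-filter effects, substrate depletion coupling
across wells, heavy-tailed or correlated reporter noise, batch structure,
or distribution shift between cohorts — real data can violate all of
these, and the generators deliberately model none of them.

## Validation scales and numerical choices

The end-to-end suite (and `scripts/acceptance.R`) uses problem sizes
chosen to exercise each property well inside a desk-scale run:

* Sequence metrics: 1,000 random peptide pairs (lengths ≤ 6 for the edit
  distance against a memoized textbook recursion; ≤ 8 for the partial
  ratio against explicit window enumeration).
* Initial-rate recovery, noiseless: a 10×10 screen sampled every 0.25 min
  with the window set to the first 2 of 20 minutes (≈10% of the run), so
  the saturation bias bound $kw/2 \le 0.8\%$ keeps every cell within 1%
  of $Ak$.
* Initial-rate recovery, noisy: 5%-of-amplitude Gaussian noise, 10 early
  time points, triplicate wells, linear-phase curves with
  $k \sim U(0.01, 0.03)$; recovery is summarized as the calibration slope
  of estimated on true rates, which isolates systematic error from
  per-cell sampling noise (individual low-rate cells are noise-dominated
  at this noise level, as a power analysis of the OLS slope shows).
* Differential enrichment null: 10 vs 10 samples × 1,000 reporters × 20
  seeds; the pooled raw-p rejection rate is checked against 3 binomial
  SDs of 0.05 and the BH step against zero discoveries per seed.
* Classifiers: planted 4× effect at log-noise 0.1 and n = 40 for the
  perfect-AUC check; 100 pre-drawn label permutations for the chance
  check. Permutations are drawn before training because seeded trainers
  manage the RNG internally; note that permuting labels of strongly
  clustered data yields a right-skewed AUC null (a partially aligned
  permutation is learnable in either direction), which is why the
  permutation band is wide.
* RFE: 1 informative reporter among 9 at the same effect size, 50 seeded
  reruns.

Degenerate inputs are handled explicitly rather than by propagating
`NaN`: constant vectors score 0 in z-scores, constant conditions give
`NA` correlations with a warning, all-zero samples are a named error in
normalization, nonpositive baselines are a named error in fold change,
and glmnet's two-column minimum is met by padding single-feature fits
with a zero column that receives no weight.

## Known limitations

Michaelis–Menten constants ($k_{cat}/K_M$), saturation-time modeling,
substrate competition and protease-mixture deconvolution are out of
scope: the toolkit quantifies empirical screen behaviour, not mechanism.
Binary classification treats "positive class versus all others"; ordinal
structure among classes (e.g. time points) is ignored. The ranked query
score is a convention validated on synthetic structure, not a fitted
model of cleavage propensity. And all validation rests on the generators
above — conclusions about any real dataset require the usual external
controls.
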