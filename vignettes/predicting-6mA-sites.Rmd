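---
title: "Predicting DNA 6mA sites from sequence windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA 6mA sites from sequence windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dna6ma)
```

## The problem

N6-methyladenine (6mA) is a DNA modification long known from bacteria and
more recently mapped in rice, mouse and other eukaryotes. Experimental
detection (SMRT sequencing, methylated-DNA immunoprecipitation) is accurate
but expensive, so sequence-based classification is the standard first
screen: take a fixed-length window centred on a candidate adenine — 41 nt
throughout this package — and decide from sequence alone whether the centre
is methylated. Because the flanking sequence preferences of 6mA are partly
shared between species, a single cross-species model trained on pooled
windows is a sensible default, and that is the workflow `dna6ma`
implements: labeled windows in, feature matrix, classifier, evaluation
report out.

## Feature encodings

Each window of length $L$ is encoded by up to five blocks, concatenated in
the order the `encoder_config()` lists them. Feature names carry a block
prefix (`kmer:`, `ksnpf:`, `nsd:`, `bin:`, `motif:`) so block-level
ablation — dropping or reordering subsets — is a configuration change, not
a code change.

**K-mer composition.** For each word length $k$ there are $4^k$ possible
words; we count all $L-k+1$ sliding windows and report relative
frequencies, so each block sums to exactly 1 and entries live in $[0,1]$.
The defaults $k \in \{2,3,4\}$ give $16+64+256 = 336$ features. We use the
full $L-k+1$ window count as the denominator: it is the number of k-mer
windows a length-$L$ string actually has, and it is the only choice under
which the block is a probability distribution (a property the test suite
asserts for random sequences).

**K-spaced nucleotide pair frequencies (KSNPF).** For a gap size $k$, an
ordered pair $(n_1, n_2)$ occurs at position $i$ when $s_i = n_1$ and
$s_{i+k+1} = n_2$, i.e. with exactly $k$ arbitrary bases between the two.
There are $L-k-1$ such positions, which is also the normalising
denominator, so again each 16-entry block sums to 1. Defaults
$k \in \{1,\dots,4\}$ give 64 features. Gapped pairs capture spaced
dinucleotide preferences that contiguous k-mers dilute.

**Nucleic shift density.** At position $i$ the feature is the density of
the resident base within its own prefix:
$d_i = \frac{1}{i}\sum_{j=1}^{i} \mathbf{1}[n_j = n_i]$. Position 1 is
always 1; the final position equals the window-wide composition fraction
of the last base. The canonical worked example: for `CAGCTG`, the
densities of C at positions 1–6 are $1, 1/2, 1/3, 2/4, 2/5, 2/6$ — the
package reproduces this trace exactly, and `nsd_at()` exposes the
single-position primitive.

**Binary code.** Each base maps to a 3-bit triple on chemically meaningful
axes — purine $(x)$, weak pairing $(y)$, amino group $(z)$: A = (1,1,1),
C = (0,0,1), G = (1,0,0), T = (0,1,0). The four triples are pairwise
distinct, so the 3L-bit encoding is invertible (`decode_binary()`);
positional identity is preserved, which is what lets tree ensembles pick
up the strongly position-specific signal around the methylated adenine.

**Motif scores.** Motifs arrive as letter-probability matrices in MEME
minimal motif format; we keep those with E-value strictly below 0.05 (the
conventional significance cutoff for discovered motifs) and score each
window with each motif. The scoring rule is the standard PWM log-odds with
max pooling: over every placement of the motif,
$\max \sum_{\text{cols}} \log_2\frac{p + \varepsilon}{b + \varepsilon}$,
with uniform background $b = 1/4$ and pseudocount
$\varepsilon = 10^{-6}$ guarding zero probabilities. Max pooling yields
one scalar per motif per window, which is the natural "motif score of a
sample". Forward strand only by default: 6mA windows are
strand-anchored on the methylated adenine, so minus-strand hits are a
different event; `scan_reverse_complement = TRUE` enables two-strand
scanning for users who want it.

With the default subset choice (motif + k-mer + binary) and two motifs, a
41-nt window becomes a 461-dimensional vector. The density and KSNPF
blocks remain available for ablation studies and for the baseline preset
below.

## Classifiers and protocol

Five families are wired in behind one `classifier_spec()` interface:
extremely randomised trees and random forest (via `ranger`; the
extra-trees variant uses one random split per candidate feature and no
bootstrap), gradient boosting (via `xgboost`, depth-3 trees, learning rate
0.1), discrete AdaBoost (implemented in-package over `rpart` decision
stumps, with weight renormalisation each round and early exit on a
degenerate weak learner), and an RBF-kernel SVM (via `e1071`). Tree
ensembles default to 1,000 trees. The SVM defaults to $C = 0.98$,
$\gamma = 0.01$; the baseline preset `baseline_idna6ma_pseknc()` pairs a
density+binary feature matrix (164 columns) with $C = 0.336$,
$\gamma = 0.02$, reproducing the published SVM predictor this pipeline is
usually compared against.

Three protocol decisions deserve explanation:

- **Leakage-free scaling.** Tree families consume raw features. The SVM
  sees features min-max scaled to $[0,1]$, with the scaler fitted on the
  training portion only and reapplied at prediction time — fitting it on
  pooled data would leak test information into the kernel geometry.
- **Scores.** `predict_scores()` returns values in $[0,1]$ with hard
  labels at 0.5. For the SVM we pass the decision value through the
  logistic function: the transform is strictly monotone, so rank-based
  measures (AUC, AP) are unchanged relative to the raw decision value,
  while the 0.5 cutoff coincides with the decision boundary. We prefer
  this to Platt-style probability calibration, whose internal
  cross-validation adds nondeterminism.
- **Shared folds.** `make_folds()` produces a stratified assignment
  (per-class fold sizes differ by at most one) that is deterministic in
  its seed and is passed *into* `cross_validate()`, never created there.
  Comparing classifier families on identical partitions removes fold
  noise from the comparison; the CLI persists the assignment
  (`folds.tsv`) and reloads it via `--reuse-folds`.

Cross-validation reports a full evaluation per fold — Sn, Sp, ACC, MCC,
AUC, AP, F1 plus curve points — and the arithmetic mean of the scalar
fields. MCC is computed in its class-wise form
$\mathrm{MCC} = \frac{1-(FN/N^+ + FP/N^-)}{\sqrt{(1+\frac{FP-FN}{N^+})(1+\frac{FN-FP}{N^-})}}$,
which is algebraically identical to the familiar confusion-matrix formula;
the suite exercises the identity numerically to $10^{-12}$ over random
count tuples. A zero MCC denominator (a degenerate all-one-class
prediction) reports 0 with a note, a common convention. ROC integration is
trapezoidal with tied scores grouped into one threshold step, making it
exactly the Mann–Whitney statistic with half-credit for ties; AP is the
usual step sum $\sum_i (R_i - R_{i-1}) P_i$. The default decision cutoff
for Sn/Sp/ACC/MCC/F1 is 0.5 on the probability-like score.

`jackknife()` implements leave-one-out with pooled predictions — expensive
but deterministic given seeds, and the protocol used when comparing
against predictors that report jackknife accuracy. `stratified_split()`
provides the 80/20 train/test split used to hold out an independent test
set before any model selection.

## The synthetic benchmark

`generate_dataset()` emulates the structure of real 6mA benchmark sets:
balanced classes of 41-nt windows, positives centred on an adenine, with a
localised flanking motif as the discriminative signal. Negatives are i.i.d.
draws from a background composition (uniform by default); positives start
as background, then the motif span is overwritten by sampling each motif
column from the mixture
$p_{\text{mix}} = s\,p_{\text{motif}} + (1-s)\,b$, where
$s \in [0,1]$ is `motif_strength`. The mixture makes difficulty a
continuous dial: $s=0$ is an exchangeable null, $s=1$ the full motif. The
default planted motif is a sharpened 9-column ACCGATCSA consensus
(probability 0.97 on the consensus letter; the degenerate S column split
0.49/0.49 between C and G), centred on the window midpoint so its
central A column coincides with the candidate adenine; the default
strength is 1. Any MEME-format motif can be substituted.

Two generator subtleties matter for interpreting results. First,
`center_A` forces an A at the midpoint of positives (real positive windows
are centred on adenine by construction); under a *null* comparison
($s = 0$) this must be disabled, otherwise the forced centre base is
itself a legitimate class signal and the two classes are not exchangeable.
The package's null-control checks therefore generate with
`center_A = FALSE`. Second, the generator emulates composition and a
planted motif only — it does not reproduce genomic autocorrelation,
species-specific composition beyond a single 4-vector, or the sequence
redundancy that real corpora carry (real datasets should be deduplicated,
and similarity-based redundancy reduction such as CD-HIT-EST belongs in
external preprocessing). Passing synthetic-recovery tests demonstrates
that the pipeline is wired correctly and can recover a planted signal; it
does not certify accuracy on any particular genome.

## Numerical and interface choices

- Sequences are normalised at the FASTA boundary: uppercase, RNA U mapped
  to T. Other letters are never silently altered; the strict policy (the
  default) raises, the drop policy removes the record with a counted
  warning. Ambiguity codes like N would otherwise corrupt every encoder
  downstream.
- Exact duplicate windows within a class are collapsed to the first
  occurrence; a sequence labeled both positive and negative is
  contradictory evidence and every copy is removed, with a message.
- Positive windows whose centre is not A produce a warning by default
  (strict and silent modes available): real corpora occasionally contain
  off-centre artefacts, and a hard default error would block exploratory
  loading.
- MEME parsing covers the minimal motif text format (the interchange
  format for letter-probability matrices): header fields `w=`, `nsites=`,
  `E=`, followed by exactly `w` rows of four probabilities. Row sums are
  checked to $10^{-3}$ (MEME prints rounded values); row-count mismatches
  are errors naming the motif.
- Grid search over $(C, \gamma)$ evaluates every cell with
  `cross_validate()` on the shared folds and breaks AUC ties toward the
  smaller $C$, then the smaller $\gamma$ — preferring the less complex
  model deterministically. The default grids are powers of two,
  $C \in 2^{-5..5}$, $\gamma \in 2^{-9..1}$, augmented with the tuned
  values $C = 0.98$ and $\gamma = 0.01$ so a $1\times1$ grid of those
  reproduces the shipped configuration.
- Everything stochastic — fold shuffling, tree ensembles, the generator,
  the splitter — takes an explicit integer seed (default 1) and runs
  single-threaded, so identical calls are bitwise reproducible, including
  written FASTA and JSON artefacts.

## Problem sizes used in the shipped checks

The test suite and the signal-recovery checks run on synthetic data at
moderate sizes chosen to make the statistical assertions stable: signal
recovery and its null control use 200+200 windows with 5-fold
cross-validation and 1,000-tree extra-trees ensembles (observed mean AUC
is essentially 1 at full strength and near 0.5 for the null); the
permutation null uses 200+200 windows with 200 trees; oracle comparisons
(MCC identity, pairwise AUC, brute-force motif scoring) use 200–1,000
random instances each. Composition calibration uses 1,000 windows per
class, where uniform backgrounds land within ±0.02 of 0.25 per letter.

## Known limitations

- The AdaBoost implementation is the classic discrete variant over
  stumps; it is the weakest of the five families on the synthetic
  benchmarks, consistent with its published ranking, but is not a
  performance-parity reimplementation of any specific library.
- Leave-one-out with very small $n$ is biased for margin-based
  classifiers (removing one sample flips the class balance), so jackknife
  comparisons are only meaningful at realistic dataset sizes.
- The package does not discover motifs; it consumes MEME output. Nor does
  it extract windows from genome coordinates — inputs are pre-cut FASTA
  windows.
- Reported synthetic performance should never be quoted as expected
  performance on genomic data; see the generator caveats above.
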