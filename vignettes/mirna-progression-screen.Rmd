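---
title: "An integrative miRNA–mRNA screen for premalignant progression"
author: "mirprog authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative miRNA–mRNA screen for premalignant progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprog)
```

## The problem

Chronic inflammatory lesions of the oral mucosa (oral lichen planus, OLP)
can progress to oral squamous cell carcinoma (OSCC). A natural screening
design profiles miRNA and mRNA expression in matched tissue from the same
patients at three stages — adjacent normal mucosa, the premalignant
lesion, and the tumor — and asks which miRNAs fall (or rise)
*consistently and progressively* along that axis, and which up-regulated
genes they plausibly de-repress through loss of direct 3′-UTR targeting.
The canonical positive example in this setting is a highly abundant
suppressive miRNA whose loss releases a proliferation-promoting
transcription factor, which in turn drives an anti-apoptotic effector.

`mirprog` implements that screen as a reusable, tested pipeline:
normalization, replicate-free differential expression, a
monotone-progression filter with cross-patient consensus, consensus
target prediction over tool exports, de-novo seed-site scanning,
candidate ranking, a regulator–target intersection, and the
validation-side statistics (relative qPCR quantification, weighted
immunohistochemistry scores, Spearman and Mann–Whitney tests). A
synthetic-data generator with planted ground truth makes the whole chain
testable end to end without any external downloads.

## Expression quantification

mRNA abundance is expressed as RPKM,
$\mathrm{RPKM} = 10^9 \, C / (N L)$, for $C$ unique-mapping tags on a
transcript of length $L$ bp in a library of $N$ mapped tags; miRNA
abundance, which has no meaningful per-feature length, as tags per
million, $10^6\,C/N$. Fold changes are pseudocounted log2 ratios,
$\log_2\!\frac{a + c}{b + c}$ with $c = 0.5$ by default, so that a 0/0
contrast is a fold change of exactly 0 and single-digit counts do not
produce unbounded ratios. Both units are invariant under joint scaling of
counts and depth.

## Replicate-free differential expression

With one library per (patient, stage) there are no biological replicates,
so dispersion-estimating models are out of reach. The pipeline uses the
Audic–Claverie exact count test: conditional on seeing $x$ tags in a
library of size $N_1$, the count $y$ in a library of size $N_2$ has point
probability

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\bigl(1 + N_2/N_1\bigr)^{x+y+1}},$$

which is a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$; the implementation evaluates tails through `pnbinom()`
and is stable for counts up to $10^7$. The two-sided p-value is the
doubled smaller tail, capped at 1. Two numerical facts are worth noting
(both are asserted in the test suite): at equal depths the point
probability reduces to $\binom{x+y}{y} 2^{-(x+y+1)}$ and is symmetric in
$(x, y)$, but the doubled-tail p-value is *not* exchangeable under
swapping the two conditions, because the tails are summed over $y$ at
fixed $x$; and for unequal depths even the point probabilities differ
under the swap by the constant factor $N_1/N_2$. The test is slightly
conservative on Poisson nulls and — deliberately exposed by the
overdispersed generator, see below — anticonservative when counts are
negative-binomial.

Multiple testing is controlled by Benjamini–Hochberg adjustment
(`stats::p.adjust`), applied over all features within one
patient-contrast before any thresholding.

## The progression screen

Within one patient, a feature is called `down` when

1. both stage transitions (OLP vs normal, OSCC vs OLP) have negative
   log2 ratios (monotonicity; a transition of exactly 0 breaks it unless
   `allow_flat_transition` is set),
2. the overall normal→OSCC change passes the fold cutoff
   (`min_abs_log2fc`, default 1.0 — the two-fold rule), and
3. the exact test on the extreme contrast (normal vs OSCC raw counts)
   passes `max_q` (default 0.05).

`up` is symmetric. The statistical test is applied to the extreme
contrast only; the intermediate stage contributes monotonicity, not an
invented trend test. A `strict_transitions` mode additionally requires
each single transition to pass the fold cutoff. A feature reaches the
final list only when *every* patient agrees on the direction
(`cross_patient_consensus`). Fold thresholds are applied to normalized
expression by default (a configuration flag switches to raw counts; with
equal depths the two agree).

## The target-prediction cascade

For a screened-down miRNA the candidate cascade narrows monotonically:

1. **Consensus prediction** — genes reported by ≥ `consensus_k`
   (default 3) of the supplied tool exports. Prediction tools are never
   called; their exports are plain gene lists, because database versions
   drift and the contribution here is the integration logic.
2. **Intersection with up-regulated genes** — a suppressed miRNA's
   direct targets are expected among genes rising with progression.
3. **Seed-site filter** — the gene's 3′-UTR must contain a canonical
   seed site of at least the minimum class (default ≥ 7mer).
4. **Ranking** — descending peak expression (the most abundant candidate
   first), then ascending anti-correlation, then the gene symbol for a
   deterministic order.

### Seed-site scanning

Site classes follow the canonical taxonomy. Writing
$\mathrm{rc}(\cdot)$ for reverse complement and numbering miRNA
nucleotides 5′→3′:

| class   | UTR match string                 |
|---------|----------------------------------|
| 6mer    | rc(nt 2–7)                       |
| 7mer-A1 | rc(nt 2–7) + `A`                 |
| 7mer-m8 | rc(nt 2–8)                       |
| 8mer    | rc(nt 2–8) + `A`                 |

The `A` of 7mer-A1/8mer is a literal adenosine in the UTR opposite miRNA
nt 1, per the standard convention. Coordinates are 1-based inclusive on
the sense strand of the supplied UTR (so a 7-nt site at nt 482–488
satisfies $488-482+1=7$); the antisense strand is never searched. All
occurrences of all classes are reported, except that a match whose
interval lies inside a more specific reported site is collapsed into it
(specificity 8mer > 7mer-m8 ≥ 7mer-A1 > 6mer): a lone `CGAACAAA` is one
8mer, not four nested sites. RNA input (`U`) is normalized to the DNA
alphabet at ingest so miRNA and UTR sequences are comparable. The
scanner is verified against an exhaustive position-by-position oracle.
Thermodynamic context scores, conservation and non-canonical sites are
out of scope.

### Anti-correlation

`anticorr` is the Pearson correlation between the gene's and the miRNA's
per-patient stage-transition log2 ratios (two transitions per patient).
A perfectly de-repressed target has the *negated* transition vector of
its miRNA and scores exactly −1. Note a subtlety: a mirrored geometric
series (e.g. miRNA 4,2,1 against gene 1,2,4) has equal-magnitude
transitions, hence zero variance, and its correlation is undefined — the
informative signal is the shape of the trajectory, not its endpoints.
Zero-variance or short series yield `NA` and rank after defined values
within a peak-expression tie.

## Validation statistics

* **qPCR**: $2^{-\Delta\Delta C_t}$ with
  $\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$ and the
  calibrator taken as the *mean* control $\Delta C_t$ when several
  control records exist (standard practice; the upstream convention is
  silent on this).
* **IHC**: weighted score $c = a \times b$, with $a$ binning percent
  positive cells (<5%→0, 5–25→1, 25–50→2, 50–75→3, >75→4) and $b$ the
  staining intensity 0–3. The printed bin boundaries overlap; they are
  resolved as half-open lower-inclusive intervals (25% → grade 2) so the
  binning is deterministic.
* **Spearman**: Pearson correlation of mid-ranks, with the large-sample
  $t$ approximation for the p-value,
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df.
* **Mann–Whitney U**: mid-rank $U = R_1 - n_1(n_1+1)/2$; the two-sided
  p-value is exact by enumeration of all $\binom{n_1+n_2}{n_1}$
  labelings when $n_1+n_2 \le 12$ (enumeration handles ties, which the
  standard exact algorithms refuse), otherwise the normal approximation
  with tie-corrected variance and no continuity correction.
* Three-group qPCR comparisons (ANOVA with post-hoc pairs in the
  original design) are deliberately out of scope; the pipeline reports
  two-group nonparametric tests and descriptive summaries only.

## The synthetic-data generator

The generator emulates the paired study design: `n_patients = 2`
patients × 3 stages × 2 assays, 500 miRNAs of which 10 are planted as
progressively suppressed with a per-stage effect of $-1.5$ log2 units
(an 8-fold drop normal→OSCC), 5000 genes of which each planted miRNA
up-regulates 2 direct targets at $+1.5$ per stage, and a depth of $10^6$
tags. Counts are negative binomial with mean
$\text{baseline}_i \cdot 2^{\delta_i \cdot s} \cdot
\text{patient effect} \cdot \text{depth scale}$ and dispersion
$\varphi = 0.1$ (biological CV ≈ 32%). The choice of negative-binomial
rather than Poisson noise is deliberate: the exact test *assumes*
Poisson sampling, and the generator intentionally violates that
assumption so the tests measure how the full screen behaves under
realistic overdispersion rather than under the test's own model.
Baselines are log-normal (meanlog 0, sdlog 1.5 — a heavy-tailed
abundance distribution typical of expression data); planted features
draw from the upper half of that distribution, because the screen is
aimed at well-expressed regulators (the motivating miRNA is highly
abundant in all tissues and its motivating target has the highest RPKM
among candidates), and effects planted on barely-expressed features
would emulate a different, underpowered study.

UTRs are i.i.d. uniform ACGT of length 500–2000 nt; each planted pair
gets the miRNA's 7mer-A1 or 8mer string written in at a recorded
position, and decoy UTRs that contain a ≥7mer site for any planted miRNA
by chance are regenerated, so planted sites are the only ≥7mer signal.
Tool exports include each true target with probability 0.9 and each
decoy with probability 0.02, per tool, independently. Ct tables carry a
planted 4-fold case/control change with Gaussian noise (sd 0.25 cycles;
zero noise reproduces the fold exactly); IHC tables draw cases to
stochastically dominate controls, with two markers sharing a latent
per-sample severity so their scores correlate. Everything is a pure
function of `rng_seed` (sub-generators use fixed small offsets of it, so
they are individually reproducible too).

What the generator does **not** emulate: realistic sequence composition
of UTRs, miRNA families sharing seeds, correlated tool errors,
compositional (closed-sum) distortion of libraries, or batch effects. A
pipeline that recovers planted truth here is demonstrated to implement
its own contracts, not to be robust to those phenomena.

## Numerical and design choices

* Pseudocount 0.5 on expression values; 0/0 defined as fold change 0.
* Two-sided exact p = doubled smaller tail capped at 1 (conventional;
  the conditioning makes it non-exchangeable, documented above).
* Monotonicity: default requires strictly-signed transitions; the fold
  and q thresholds apply to the overall normal→OSCC contrast.
* Gene symbols are compared case-insensitively after uppercasing, with
  no alias resolution — the integration steps are plain set operations
  on symbols, as in the original screen.
* Candidate order ties break on the gene symbol, making every output
  deterministic.
* The default end-to-end problem size (500 miRNAs, 5000 genes, 2
  patients, depth $10^6$) runs in well under a minute and is the size at
  which the acceptance checks are computed.

## Known limitations

* The exact test is anticonservative under overdispersion; with only
  two patients the consensus filter mitigates but does not eliminate
  false calls. Under the default generator (dispersion 0.1) the null
  per-feature call rate is well under 1%, but because only 10 true
  miRNAs are planted, a handful of surviving false calls can still be a
  noticeable *fraction* of the called set — the acceptance checks
  measure exactly this.
* No replicate-aware modeling, no TMM/quantile normalization, no
  conservation or context scoring for sites, no alias-aware gene-symbol
  matching.
* The IHC/qPCR components compute the published scoring arithmetic; they
  do not model plate effects or amplification-efficiency curves.
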