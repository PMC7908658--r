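---
title: "Predicting mRNA targets of tRNA-derived fragments: models and methods"
author: "trftargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mRNA targets of tRNA-derived fragments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trftargets)
```

## The problem

tRNA-derived fragments (tRFs) are 14–40 nt small RNAs cleaved from mature
or precursor tRNAs. Several classes — notably tRF-3 (carrying the 3'-CCA
terminus) and tRF-5 — load into Argonaute and repress mRNAs in a
microRNA-like fashion: nucleotides 2–7 of the tRF (the *seed*) pair with a
perfectly complementary 6-mer (*seed match*) in a transcript's 3'-UTR.
Experimentally, tRF–mRNA contacts can be captured by CLASH and CLEAR-CLIP,
which ligate the Argonaute-bound small RNA to its target and sequence the
resulting *chimeric read*. Such data are sparse and cell-line specific, so
a trained predictor is needed to generalize beyond the captured pairs.

`trftargets` implements that predictor end to end, plus two independent
prediction criteria (a binomial overrepresentation model and a
conservation-score rule), and a synthetic-data generator with known ground
truth so that every stage can be exercised without any external download.

## Chimeric-read decomposition

A chimeric read is modelled as an exact concatenation of a catalog tRF and
a target fragment. `decompose_read()` finds the longest full catalog tRF
sequence that is an exact prefix or suffix of the read; no mismatches or
bulges are tolerated, which replaces heuristic local alignment with a
deterministic rule and mirrors the stringent inclusion criteria used when
only catalog (tRFdb-style) tRFs are trusted. The remaining fragment (at
least 6 nt) is exactly mapped to the 3'-UTR set; a pair becomes a
*positive* only when the mapped fragment contains a perfect Watson–Crick
seed match of that tRF. Equal-length matches by two distinct tRFs at both
read ends are rejected as ambiguous; fragments hitting several UTRs are
kept and flagged (a switch drops them).

The *background* consists of every seed match of every catalog tRF in the
3'-UTRs of transcripts that host **no** positive pair (transcript-level
exclusion). Negatives for training are sampled from the background ranked
by the host transcript's 3P-seq tag support: the pool is the top-tagged
half (twice the requested number, extended through ties) and the requested
number — five negatives per positive — is drawn uniformly from it. This
honors both halves of the design: negatives come from well-expressed
UTR isoforms, yet the draw is random and seeded.

## The feature roster

Each site is described by four feature families (the active roster is
returned by `feature_registry()`; `r nrow(feature_registry())` features by
default):

* **Site sequence context** — seed-match type indicators (position 8
  match, position 1 match, position 1 A); identity indicators for the two
  bases flanking each side; GC percentage and the distance-weighted AU
  score of the 35-nt upstream window, of that window excluding the 10 nt
  immediately upstream, and of the 15-nt downstream window; base and
  dinucleotide composition of the 35-up/15-down windows; distances to the
  UTR ends. The AU score is
  $S_{AU} = \sum_d 1/d$ over window positions $d$ (distance 1 = adjacent
  to the site) holding A or U: AU-rich, weakly structured context weighted
  toward the site. The variant excluding the nearest 10 nt exists because
  the tRF 3' portion itself tends to pair immediately upstream of the seed
  match, so that region reflects complementarity rather than openness.
* **Transcript** — lengths, GC and per-kilobase seed-match frequency of
  the 5'-UTR, CDS and 3'-UTR, plus 3'-UTR base/dinucleotide composition.
  Frequency is normalized per 1000 nt because region length is already a
  separate feature; raw counts would be redundant with it.
* **tRF** — catalog length, GC of the tRF and of its seed, and target-site
  abundance (TA): the count of the seed's complementary 6-mer over all
  3'-UTRs and, when a genome sequence set is supplied, genome-wide.
* **Duplex/accessibility thermodynamics** — duplex MFE between the full
  tRF and the site's target region (25 nt upstream + site + 5 nt
  downstream, since the tRF 3' portion pairs upstream on an antiparallel
  duplex), the number of paired tRF positions (total and outside the
  seed — both variants are exposed because either reading of "bases paired
  in duplex" is defensible), and local accessibility: unpaired site/flank
  bases in the MFE fold of a 40+site+40 window and the opening energy
  (constrained-minus-free fold energy, ≥ 0).

Windows truncated at UTR boundaries are used as-is; empty windows and
regions yield missing values that are imputed later with
training-partition medians only. Flank-identity indicators at a missing
edge base are all zero. N bases are excluded from composition denominators
and may not overlap seed matches.

## The bundled energy model

External folding engines are excellent but not exactly testable. The
bundled model keeps the monotonicities the features rely on while making
every number reproducible by exhaustive enumeration: stacking energies per
adjacent base-pair step (−3.0 kcal/mol for a G:C/G:C step, −2.0 with one
A:U, −1.0 with two, −0.5 for any step touching G:U), a flat +4.0 penalty
per internal loop/bulge/multiloop event, free hairpins and exterior bases,
minimum hairpin size 3. Both dynamic programs minimize energy with a
deterministic tie-break (duplex: more pairs; fold: fewer pairs, so
energy-neutral isolated pairs never appear). The test suite proves both
DPs equal to brute-force enumeration over all pairings (duplex, ≤ 8 nt)
and all secondary structures (fold, ≤ 13 nt) on 500 random cases each. An
adapter to the ViennaRNA command-line programs (`RNAduplex`, `RNAfold`)
is provided for production parity; swapping backends changes numbers but
not the contracts consumed downstream (MFE ≤ 0, opening energy ≥ 0,
exposure counts bounded).

## GA + SVM classifier

Sites are classified by an RBF-kernel SVM under fivefold cross-validation:
folds are stratified by label and balanced to within one row; per fold,
missing values are imputed with the training-fold medians, features are
centered/scaled on the training fold, and a probability-calibrated SVM is
fitted. Every row receives exactly one held-out probability; prediction on
new sites averages the five fold models.

Feature selection uses a canonical genetic algorithm over feature
bitmasks: population 50, tournament selection (size 3), one elite, uniform
crossover with probability 0.10, per-bit mutation at 0.30, all-zero masks
repaired by switching one random bit on. The fitness of a mask is the mean
held-out AUC of the SVM over the same five folds; fitness values are
cached per mask and the best mask ever evaluated is returned, so the best
fitness is non-decreasing. The defaults mirror the published setup
(10,000 iterations, 10%/30% crossover/mutation); the tests and the
acceptance script run 25 generations, which this package documents as the
study size at which the synthetic signal is fully recovered (held-out
AUC ≥ 0.99, two to three of the three implanted feature families
selected).

Transcript-level aggregation assumes sites act independently:
$P = 1 - \prod_i (1 - p_i)$ (noisy-OR), and a transcript is called a
target when $P > 0.5$ strictly. The noisy-OR form is used deliberately:
the verbally described quantity — the chance that at least one site is
functional — requires the complement product, and it is the only reading
under which one strong site yields a large $P$ and the $>0.5$ rule makes
sense. $P$ is monotone in added sites, bounded by 1, and never below the
best single site.

Evaluation reports sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$ and
the Matthews correlation coefficient
$(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$;
any metric with a vanishing denominator is flagged undefined (NA), never
an error. Feature distributions between positives and background are
compared by two-sided pooled-variance Student's t-tests, emitted as a
category-ordered table.

## The probabilistic model

Independently of the classifier, a tRF–UTR pair can be scored by seed-match
overrepresentation. An order-1 Markov chain is fitted to the tested
3'-UTR itself (empirical initial and transition frequencies; a pooled
transcriptome-wide background is a config option), giving the per-position
probability $P$ of the seed's complementary 6-mer. With $l$ the UTR
length, $k = 6$ and $f$ the observed match count (all occurrences,
overlaps included), the upper-tail binomial

$$Ps = \sum_{i=f}^{l-k+1} \binom{l-k+1}{i} P^i (1-P)^{l-k+1-i}$$

is computed via the regularized incomplete beta (stable for large $l$),
and Benjamini–Hochberg adjustment is applied across all pairs tested in
the run. Pairs are ranked by adjusted $Ps$; the flag threshold defaults to
0.05 and is configurable, since ranking, not a hard cutoff, is the
primary output.

## The conservation model

Per-base conservation scores in [0, 1] (phastCons-style) are consumed from
a fixedStep wiggle or bedGraph track expressed in transcript coordinates;
computing conservation or projecting genome coordinates is out of scope.
Sites are summarized by mean score over the seed region, the 35-nt
upstream and 15-nt downstream windows and the whole UTR; a site is
predicted when the *seed-region* mean reaches 0.5 (boundary inclusive —
the threshold is a probability-like score and the published cutoff does
not state the boundary; window and cutoff are configurable).

## The synthetic study

The generator emulates the statistical contrasts the features are built
for, with every site implanted deliberately: accidental catalog seed
matches are mutated away, so the provenance of each site is known exactly.
Defaults (chosen once as a realistic desk-scale study, and the conditions
under which all acceptance properties are evaluated):

| parameter | default | meaning |
|---|---|---|
| transcripts | 100 | 3'-UTRs 400–800 nt, GC 50%, i.i.d. bases |
| tRF catalog | 4 tRF-3 + 2 tRF-5 | subclass lengths 18/22 and 15/22/31 nt |
| functional sites | 50 (one per transcript) | chimeric reads generated for each |
| background sites | 400 | implanted without context effects |
| flank AU (positives) | 0.70 | background 0.50 |
| extended complementarity | 0.70 | rc of tRF 9–14 implanted upstream |
| position-8 match rate | 0.60 | background ≈ 0.25 (base composition) |
| 3P-seq tags | Poisson(50) per transcript | drives negative sampling |
| conservation | Beta(8,2) in sites, Beta(2,8) elsewhere | wiggle emitted |

Chimeric reads concatenate the full tRF with a 30-nt fragment around its
implanted site (orientation randomized) plus tRF-free decoys; recovery is
exact by construction and verified to be exactly 100%.

One instructive emergent property: the plain 35-nt upstream AU score
barely separates the classes here, because the implanted upstream
complementarity (tRF positions 8–14) sits in the highest-weight positions
and cancels the far-field AU enrichment — whereas the variant excluding
the 10 nt immediately upstream separates cleanly. This is precisely the
motivation for computing the excluded-window score.

What the generator does **not** emulate — real tRNA structures, RNase
biology, sequencing errors, adapter chemistry, isoform complexity,
correlated base composition — bounds what passing tests show: they verify
the algorithms and their contracts, not performance on real CLASH
libraries.

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based inclusive in every
  written report.
* The internal alphabet is RNA; T is mapped to U on input.
* Fold/duplex ties are broken deterministically (documented above), so
  all outputs are byte-reproducible given seeds.
* The GA fitness SVM uses fixed hyperparameters (C = 1, γ = 1/p);
  `train_cv_svm(tune = TRUE)` grid-searches a coarse C/γ grid for the
  final model when desired.
* All randomness (sampling, folds, GA, generator) flows from explicit
  integer seeds; the caller's RNG state is always restored.
* Degenerate inputs are contracts, not crashes: empty windows impute,
  undefined metrics flag NA, single-class folds raise a clear error.

## Known limitations

* Non-canonical seeds (G:U wobble, offset or bulged seeds) are not
  scanned; contiguous 3'-end pairing without a seed is out of scope.
* The bundled energy model is intentionally minimal: use the ViennaRNA
  backend when absolute energies matter.
* The per-UTR Markov background makes $Ps$ conservative for UTRs whose
  composition is itself shaped by many real sites.
* Published performance on the original CLASH/CLEAR-CLIP data (training
  AUC 0.980, validation 0.847) depends on those datasets and hg19
  annotation and is not reproducible offline; the acceptance suite
  verifies property-level correctness instead.
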