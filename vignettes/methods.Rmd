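---
title: "Three-class linear-discriminant recognition of poly(A) sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-class linear-discriminant recognition of poly(A) sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model, its
assumptions, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## The model

A poly(A) region is modeled as a cleavage site (CS, coordinate +1; there is
no coordinate 0) flanked by cooperating sequence elements: a PAS hexamer
upstream (bound by CPSF), a U/GU-rich element downstream (bound by CstF), a
characteristic cleavage-site context, and broader compositional biases in
the flanking regions. Because no single element is necessary or sufficient,
recognition is a weighted combination: a two-class linear discriminant

$$Z = \sum_{i=1}^{p} a_i x_i, \qquad \text{true site} \iff Z > c,$$

with coefficients $\vec a = s^{-1}(\vec m_1 - \vec m_2)$, threshold
$c = \vec a \cdot (\vec m_1 + \vec m_2)/2$, where $\vec m_1, \vec m_2$ are
the feature means of true and false training sites and $s$ the pooled
covariance matrix (unbiased $(n-1)$ weighting; the boundary $Z = c$ is
assigned to the false class). The Mahalanobis distance
$D^2 = (\vec m_1 - \vec m_2)^\top s^{-1} (\vec m_1 - \vec m_2)$ ranks
feature subsets; `stepwise_select()` implements greedy forward selection
with a relative-gain stopping rule (default 5%), a documented stand-in for
a significance-based inclusion criterion.

Sites are split into three classes by the hexamer present in `[-40:-1]`:
PAS-strong (AATAAA/ATTAAA), PAS-weak (ten minor variants), PAS-less
(none of the twelve, classified with strong taking precedence over weak).
Each class has its own discriminant, feature schema and window geometry:
`[-100:+50]` (strong), `[-60:+60]` (weak), `[-60:+100]` (less).

### Characteristics

* **PAS motif** (strong/weak): a 6-column position weight matrix built from
  the authentic hexamer occurrence closest to the CS in each training
  window; scored as the mean matched-column frequency of the best placement
  in `[-40:-1]`. Ties go to the placement closest to the CS. At scan time a
  position is a candidate only if this best score reaches the **gate**, the
  minimum score of the authentic training occurrences — for the strong
  class this effectively requires a literal AATAAA/ATTAAA.
* **CS motif**: a PWM over the fixed window `[-15:+3]` (18 columns,
  strong/weak) or `[-9:+3]` (12 columns, less); no search, because the
  cleavage context is anchored at the candidate position itself.
* **GU/U motif**: a 10-column PWM discovered de novo by
  one-occurrence-per-sequence (OOPS) expectation maximization on the
  `[+1:+50]` regions of all positive training windows, against a 0-order
  background equal to the base composition of those regions (the simplest
  defensible background; nothing in the data motivated a higher order).
  The downstream search bound is exposed as configuration
  (`guu_region`, default `c(1, 50)`).
* **Pentamer composition**: per-pentamer Bayes probability
  $P(S) = F_p(S)/(F_p(S)+F_n(S))$, with $F$ the occurrence frequency of the
  pentamer among all pentamer windows of the region set (an alternative
  per-region presence definition is available as `penta_mode`). A region is
  scored by the mean of $P$ over its overlapping pentamer windows — exactly
  56 of them for a 60-nt region. Pentamers unseen in both sets score the
  uninformative 0.5. Upstream regions: the 60 nt left of the PAS hexamer
  (strong; with the PAS search bounded at −40 this region always fits
  inside the `[-100:+50]` window) or `[-60:-1]` (weak/less). Downstream:
  `[+2:+60]` (weak), `[+2:+100]` (less).
* **Distances**: empirical frequency of the PAS-to-CS distance
  (convention: $1 -$ CS-relative offset of the hexamer's rightmost base, so all
  training values are positive) and of the CS-to-GU/U distance (the
  offset of the motif's leftmost base $- 1$). Unobserved distances score 0.

### Scanning and resolution

Every position of an input sequence is treated as a candidate +1 and
evaluated by the cascade strong → weak → less; the first classifier that
fires claims the position. Calls within 100 bp of each other are thinned by
a global greedy sweep ordered by (class precedence, $Z$ descending,
coordinate ascending), which reproduces the pairwise rules — strong beats
weak/less, weak beats less, same class keeps the higher score — while being
deterministic and order-independent. For throughput the scanner precomputes
per-sequence PWM placement-score tracks and cumulative pentamer sums; the
tests verify it is numerically identical to the per-window reference path
(`assemble_features()` + `ldf_score()`).

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pseudocount` | 0 | counts | scores are sums of frequencies, so zero columns are harmless; smoothing is available for users who want it |
| PAS search region | `[-40:-1]` | CS-relative coords | class definition region |
| CS window | `[-15:+3]` / `[-9:+3]` | CS-relative coords | fixed cleavage-context windows per class |
| `guu_region` | `[+1:+50]` | CS-relative coords | downstream element search region |
| EM restarts / tol / max iter | 10 / 1e-6 / 500 | — | OOPS EM is multimodal; restarts are seeded and the best final log-likelihood wins |
| `min_separation` | 100 | bp | resolution distance |
| matching `tolerance` | 12 | nt | ±12 nt true-positive criterion |
| `max_identity` | 0.90 | fraction | redundancy filter on `[-50:+50]` regions |
| `min_per_class` | 50 | records | guards against meaningless covariance estimates |
| `target_fpr` | unset | fraction | optional: tune the operating threshold to a false-positive quantile of training negatives instead of `c` |

The redundancy filter uses anchored ungapped identity (matches/100 on the
CS-anchored `[-50:+50]` regions) rather than an external alignment tool:
the regions share the CS anchor, so positional comparison is the natural
alignment, and the greedy keep-first rule is deterministic and idempotent.

Training-set gating: the PAS gate is applied at scan time only. Training
feature vectors, including negatives, use the ungated best PAS placement —
a discriminant needs false-class feature vectors, and almost no negative
fragment would pass the gate.

## Numerical choices

* Singular pooled covariance: retried once with a ridge
  ($\varepsilon = 10^{-8}\,\mathrm{tr}(s)/p$ on the diagonal) and a warning;
  still-singular matrices are a training error. This also handles collinear
  features during stepwise selection.
* PWM score ties: resolved toward the CS, then by position — fully
  deterministic.
* N bases: contribute frequency 0 in every PWM column and exclude their
  pentamer windows from region means; a region with no valid window scores
  the uninformative 0.5.
* Serialization: matrices and tables as `%.17g` text, model JSON at 17
  significant digits, so bundles and corpora reload bit-exactly and a fixed
  seed reproduces every artifact byte for byte.
* All randomness (EM initialization, synthetic generation) flows from
  explicit integer seeds; nothing reads the global RNG state implicitly.

## The synthetic corpus

The generator emulates the positive-window architecture the recognizer
assumes: i.i.d. AT-rich background (A/T 0.3, C/G 0.2, typical of 3' flanks),
the class hexamer planted upstream of the CS at a discrete-triangular gap
(12–35 nt, mode 21 — a stand-in for the observed unimodal spacing; no
published spacing distribution was available, so acceptance never depends
on its exact shape), a CA cleavage dinucleotide with probability 0.7, and a
GT/T-rich 10-mer (TGTGTTTTGT) planted with probability 0.85 at offsets
+5..+40. The strong hexamer mix is 70/30 AATAAA/ATTAAA, mirroring the ~70%
share of the two canonical forms among mapped human sites. Negatives are
codon-structured fragments (in-frame stops excluded, mimicking mid-CDS
sequence) of 150/120/160 bp with the pseudo-CS placed so the class window
exactly covers the fragment, rejection-sampled to exclude strong hexamers
upstream of the pseudo-CS.

Default sizes are desk scale — 500/200/100 positives per class with
equal-size negative sets and a 70/30 train/test split — chosen so the full
simulate–train–evaluate cycle completes in about two minutes while leaving
enough test windows for stable rates. At that scale the held-out strong
class reaches Sn ≈ 94–95% within ±12 nt with Sn^n = 100%, and the weak
class is well above chance.

**What passing these tests shows**: that the estimator recovers the
parameters of data generated under its own assumptions — matrices, tables,
distances, discriminants and the scanning/resolution logic are internally
consistent. **What it does not show**: performance on real genomic
sequence. Real 3' flanks are not i.i.d., real spacing and element-presence
distributions are broader, alternative and closely spaced sites exist, and
negative sequence is not stop-free random codons. Accuracy on real data is
characterized by the published confusion counts that
`scripts/acceptance.R` recomputes metrics from; the synthetic numbers are
upper bounds, not forecasts.

## Known limitations

* PAS-less recognition is intrinsically weak — with no gating hexamer the
  discriminant leans on diffuse compositional features, and both the
  published results and the synthetic experiments show low sensitivity.
  The class is retained for completeness of the cascade.
* Forward strand only by default; the reverse complement can be scanned as
  an independent sequence (`reverse_complement = TRUE` in
  `predict_file()`), since strand conventions of typical input are not
  standardized.
* The stepwise inclusion rule (relative $D^2$ gain) is a pragmatic
  surrogate for a formal significance test; selection traces are returned
  so users can apply their own cutoff.
* No modeling of tissue-specific site usage, alternative-polyadenylation
  isoforms, or cross-species conservation.
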