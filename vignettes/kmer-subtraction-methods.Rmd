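---
title: "Methods: k-mer subtraction screening and antisense dose-response analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer subtraction screening and antisense dose-response analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerscreen)
```

## The problem

Most genes are expressed in both tumors and normal tissue, so knocking them
down risks on-target toxicity. A small set of transcripts, however, is
effectively tumor-exclusive, and those are attractive antisense targets.
`kmerscreen` implements a reference-free way of finding them: instead of
aligning reads or estimating transcript expression, it counts every 25-mer
in tumor and normal RNA-seq libraries and asks, k-mer by k-mer, how much
more abundant the word is in every tumor sample than in *any* normal sample
of each tissue. K-mers that survive a conservative ratio filter are then
mapped back onto a reference transcriptome to nominate transcripts, and the
package's companion analytics evaluate antisense oligomers against those
transcripts in viability assays, including Chou–Talalay synergy analysis of
oligomer combinations.

## The subtraction statistic

Counting is per sample: every k-length window of every read is tallied
(windows containing a non-ACGT symbol are skipped; U is read as T), and
k-mers seen fewer than `min_count = 10` times in a sample are dropped —
this is both a memory device and a noise floor, since sequencing-error
k-mers are overwhelmingly singletons. Counts are stranded: collapsing a
k-mer with its reverse complement would create false joins when candidate
k-mers are later matched to stranded transcript sequences (a `canonical`
flag exists for interoperating with strand-collapsed external catalogs).

Raw counts are normalized to sequencing effort as counts per 10^9 bp,

> a(c, B) = c × 10⁹ / B,

with B the sample's total sequenced base pairs (the sum of read lengths
unless the sample sheet overrides it). Missing entries are imputed
asymmetrically *at the raw-count level* and then normalized: 0 for tumor
samples, `min_count` for normal samples. The asymmetry is deliberately
conservative for targeting: a k-mer missing from a tumor library counts
fully against the target, while a k-mer missing from a normal library is
treated as if it sat just under the counting threshold, which bounds every
denominator away from zero and caps how extreme a ratio can look at a given
depth.

For a k-mer and tissue t, the tumor:normal ratio is

> R_t = min over tumor samples of a / max over tissue-t normal samples of a.

Both extremes are intentional: every tumor sample must carry the k-mer
highly, and no normal sample of the tissue may. A k-mer is *over-abundant*
in tissue t when R_t strictly exceeds 500; candidates are k-mers
over-abundant in at least one tissue (breadth across tissues is rewarded at
ranking rather than required at filtering — the retention rule is a design
choice, and ≥ 1 tissue is the permissive option). Ratios are kept at full
precision in every file; `truncate_ratio()` reproduces the two-decimal
truncated display convention (0.16896 → 0.16).

## Annotation, ranking and target selection

Candidate k-mers are matched to a reference transcriptome index that
records every k-mer of every transcript with its 0-based offset. A k-mer
occurring in several transcripts credits all of them; splice variants are
not discriminated. Each transcript is scored by the contained candidate
k-mer that is over-abundant in the maximum number of tissues (its *maximum
over-abundance tissue count*); ties are broken by the larger minimum
per-tissue ratio — favoring uniformly extreme k-mers — then by the smaller
k-mer code, making selection deterministic. Transcripts are ranked by
tissue count, then minimum ratio, then id, truncated to the top 400, and
the per-tissue ratio matrix of the selected k-mers (the heat-map artifact)
is exported in rank order. Target selection counts, per ranked transcript,
the tissues whose ratio strictly exceeds 10,000; the caller applies a floor
(e.g. "all tissues") to shortlist. The antisense helper returns the reverse
complement of any transcript window, 5'→3' in DNA alphabet; it warns
outside the usual 15–30 nt oligomer range and is an involution
(designing against the oligomer recovers the window).

Both thresholds are strict inequalities (a ratio of exactly 500 or exactly
10,000 does not pass), and both are configuration parameters
(`run_config()`), defaulting to the published funnel values.

## Viability analytics

Fraction affected (dead) is FA = (control − treated)/control from
resorufin fluorescence, computed per well against the plate's mean
untreated-control signal; values are allowed to go negative (treated signal
above control). Plate summaries optionally subtract the same plate's mean
scramble-control FA from every treatment, removing sequence-independent
toxicity; the adjustment is subtractive, consistent with published negative
adjusted values.

Two dose-response models are fitted:

* **Linear sensitivity** — OLS of FA×100 (%) on dose in nM. The slope is
  the "sensitivity" in % dead cells per nM; EC50 is derived from the slope
  alone as 50/|slope| nM (reported in µM). The linear-dose (not log-dose)
  regressor follows the printed unit of the sensitivity, and the
  slope-only EC50 reproduces the published slope↔EC50 pairs exactly; the
  magnitude is used because weakly negative slopes (non-cytotoxic
  responses) still publish positive EC50s — such fits carry a warning and
  a `non_cytotoxic` flag. A `log_dose` variant is available but derives no
  EC50.
* **Median effect** — the mass-action model fa/(1−fa) = (D/Dm)^m,
  linearized as log10(fa/(1−fa)) = m·log10 D − m·log10 Dm and fitted by
  OLS. Points with FA outside (0,1) have undefined logits and are excluded
  (their count is recorded). By construction the fit is exact on noise-free
  data, and `dose_for_effect(fit, 0.5) = Dm`.

The combination index for a fixed-ratio mixture evaluated at effect level
fa is

> CI = Σᵢ fᵢ · D_combo(fa) / Dxᵢ(fa),

where D_combo(fa) comes from the mixture's own median-effect fit (dosed by
total concentration), fᵢ are the mixing fractions (must sum to 1 within
10⁻⁶; an equimolar 12-agent cocktail uses 1/12 each), and Dxᵢ is each
single agent's dose for the same effect. A sham combination of an agent
with itself gives CI = 1 identically. CI < 1 is synergy, CI > 1 antagonism;
because an exact-1 "additive" class would be vacuous in floating point
(and published CI values of 1.10 are called additive), values in
[0.9, 1.1] are labeled additive by default. Pairwise results per cell line
are assembled into labeled matrices with a consensus matrix marking pairs
"discordant" where cell lines disagree. Combination indices are positive by
definition; reports of CI "below zero" in this literature read as "below
one".

## What the synthetic cohort emulates — and what it cannot

`cohort_config()` mirrors the structure of the study cohort: 26 normal
tissues with 6–26 samples each (drawn uniformly per tissue), 3 tumor
samples, 100 bp reads. Shared transcripts (default 30, 200–400 bp) are
expressed in every sample with lognormal(0, 1) weights — a standard
heavy-tailed stand-in, as no expression model is prescribed; planted
tumor-specific transcripts have weight 0 in every normal sample and weight
`fold_excess` (default 1000) in tumor samples. Reads are drawn from
transcripts proportionally to weight with substitution errors only (rate
0.001) — enough to exercise the count threshold's noise suppression;
indels, quality models, GC bias and paired ends are out of scope. Every
output is deterministic given the config: per-sample RNG streams are
pre-assigned, so the file-emitting simulator and the streaming
simulate-and-count path produce identical catalogs.

Desk-scale depth dictates the remaining defaults. With equal per-sample
effort B, a planted k-mer (absent from all normals, hence imputed to the
floor 10×10⁹/B) has ratio

> R = (tumor count)/10,

so clearing R > 500 needs a minimum tumor count above 5,000. A planted
transcript of length L receives a fraction f of the tumor library, and each
of its k-mers is covered by a fraction (read_len − k + 1)/(L − k + 1) of
its reads. Short planted transcripts (100–130 bp, on the scale of the
fusion-breakpoint fragments that motivate tumor-specific k-mers), two of
them, and 30,000 reads per sample put the planted ratios near 10³ — about
twice the filter threshold — while a whole 26-tissue cohort (~400 samples)
simulates and counts in a few seconds. Two consequences are worth stating
plainly: at this depth planted transcripts must dominate the tumor library
(real tumor libraries are nowhere near so skewed), and the 10,000:1
production threshold for target selection is out of reach (it would need
normal libraries roughly 10⁵× deeper, i.e. the real several-Gbp scale).
End-to-end tests on the desk-scale preset therefore configure target
selection at the 500 threshold, while the strict 10,000 boundary is
exercised directly on constructed profiles. Passing recovery tests show
the funnel's machinery is correct under the generative model; they do not
certify behavior on real libraries with expression correlation, batch
effects, or annotation incompleteness.

The viability simulator draws fluorescence as
control × (1 − FA_true(D)) × (1 + ε), ε ~ N(0, noise_sd), with FA_true from
the median-effect model, plus vehicle wells and scramble wells at 3%
sequence-independent toxicity (near the reported scramble activity).
Noise-free plates round-trip (m, Dm) to machine precision. Under plate
noise the median-effect estimator is unbiased — across 200 simulated
plates at noise 0.05 with 6 replicates, the median recovered Dm sits
within a fraction of a percent of truth — but individual fits spread more
widely than the noise magnitude might suggest, because doses far from Dm
produce FA near 0 or 1 where the logit amplifies noise strongly. That
leverage is inherent to unweighted median-effect fitting, which is exactly
what the standard software does.

## Numerical choices and degenerate inputs

* K-mer codes are 2-bit (A=0, C=1, G=2, T=3); code order equals
  lexicographic order, and all serialized catalogs are written in that
  order, so artifacts are diffable and re-serialization is byte-identical.
  Codes are exact in doubles up to k = 26 on the R side (k ≤ 31 in the
  C++ kernels).
* Catalog I/O, dump parsing and the sample sheet validate eagerly with
  line-numbered or field-named errors; mixed dump dialects are rejected.
* Sequences shorter than k yield empty window sets; a sample whose reads
  are all shorter than k produces an empty catalog with a warning.
* Zero dose variance, fewer than 3 dose points (linear), fewer than 2
  usable points (median effect), non-positive CI values and mixing
  fractions not summing to 1 are hard errors; a slope of exactly 0 flags
  EC50 as infinite rather than erroring.
* Ranking and scoring are total orders (documented tie-breaks), so every
  pipeline artifact is invariant to input ordering and repeated runs are
  byte-identical.

## Problem sizes used by the test suite

The default simulated cohort (26 tissues, ~400 samples, 30,000 × 100 bp
reads per sample) runs the full subtraction in a few seconds per seed; the
recovery study repeats it over 20 seeds. Dose-response simulation studies
use 200 plates. The desk-scale preset (10 tissues × 2 samples, 24
transcripts) backs the end-to-end and determinism tests.

## Known limitations

The counter is in-memory and desk-scale by design: it will not hold the
multi-billion-k-mer catalogs of production runs (the published pipeline
used a dedicated external counter at that scale, and `parse_kmer_dump()`
exists precisely to ingest such output). Gene-level grouping of transcripts
is a user-supplied id→gene mapping, not GTF parsing. The dose-response
module fits the two models the published analysis used — no four-parameter
logistic, no Bliss independence — and the fixed-ratio CI formulation is
the implemented reading of the standard software's behavior for
constant-ratio combinations.
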