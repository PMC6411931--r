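---
title: "rbpforest: model, features, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rbpforest: model, features, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpforest)
```

## The problem and the model

An RNA-binding protein (RBP) recognizes short, degenerate sequence elements
(typically 4–7 nt), summarized as a position weight matrix (PWM) of
per-position base frequencies. Whether a given transcript region is actually
bound depends on more than the best motif match: nearby clustering of
weaker matches, the structural accessibility of the site, and its
evolutionary conservation all carry signal. `rbpforest` encodes a candidate
sequence as a fixed 40-feature vector built from its ten best PWM
placements and classifies it with a random forest.

Two model flavors address two data regimes. A *specific* model is one
forest per RBP:PWM combination, trained on that RBP's own labeled
sequences using raw features. The *general* model pools many RBPs: because
raw feature scales depend strongly on the PWM (a long, information-rich
motif yields systematically higher matching scores than a short degenerate
one), each RBP's features are first z-standardized against that PWM's
empirical background distribution, after which matrices from different
RBPs live on a common scale and can be concatenated. The pooled forest
then applies to any RBP with a PWM, including RBPs with no known targets —
the case the specific strategy cannot serve.

## Features, parameters, units

**Matching score (MS1–MS10).** The score of a placement is the plain sum of
PWM frequencies of the observed bases, one per motif position — no
log-odds, no pseudocounts, range `[0, k]` for motif length `k`
(unitless frequencies). The ten best placements, ties broken toward the
smaller start coordinate, become the putative sites; `MS_i` is
non-increasing in `i`. If a sequence has fewer than ten placements the
list is padded with zero-score sites so the vector arity never varies
(padded sites contribute 0 to every other feature type). An `N` base
contributes 0.25 anywhere, the expected frequency of a renormalized
column, so masked bases never crash a scan. Sites may overlap: nothing in
the scoring scheme forbids it, and de-overlapping would need an arbitrary
extra rule.

**Clustering score (CS1–CS10).** Inside a 50-nt window centered on the
site's midpoint (`start + k/2`, clamped at sequence bounds), the local
maxima of the matching-score profile are found, the five largest are
ranked, and `CS = sum_{r=1..5} 2^-r S_r`; missing ranks contribute 0. Local
maxima are computed on the *windowed* profile, with window edges acting as
one-sided boundaries and a plateau counting once at its leftmost index.
The windowed reading (rather than "global maxima filtered to the window")
is the design choice here: under it a constant profile — e.g. a uniform
PWM, where every placement scores exactly `k/4` — has exactly one peak per
window regardless of sequence length, giving the clean degenerate value
`CS = 0.5 * k/4` everywhere. The site's own score is eligible as a peak;
excluding it would be a second arbitrary rule with no effect on ranking.
Bounds that follow from the geometric weights, `0.5 * max <= CS <=
(31/32) * max`, are enforced as property tests.

**Accessibility (Gacc1–Gacc10).** The cost of keeping the site
single-stranded: `Gacc = G(constrained) - G(unconstrained)` for a 180-nt
segment (site taken as 10 nt from the match start, plus 2×15-nt immediate
and 2×70-nt outer flanks: 180 = 10 + 2×15 + 2×70),
with the 40-nt core (site + immediate flanks) forced unpaired in the
constrained fold. The site extent is fixed at 10 nt regardless of `k` so
the 180/40 arithmetic is exact; `k` influences only MS and CS. Near
sequence ends both intervals are clamped rather than padded — inventing
flanking sequence would fabricate structure. `Gacc >= 0` always, because
the constrained structure space is a subset of the unconstrained one.

Two folding backends satisfy one contract (deterministic; constrained
energy never below unconstrained; monotone in the mask):

* the *internal* backend is a Nussinov-style dynamic program maximizing
  nested canonical pairs (AU/GC/GU wobble, minimum hairpin loop 3; masked
  positions and `N` never pair), energy = −(pair count), a unitless
  MFE-like toy model. It is self-contained and fast, and it preserves
  exactly the two properties the feature depends on; it does *not*
  implement nearest-neighbor thermodynamics, and its energies are not
  kcal/mol.
* the *external* backend shells out to a configured RNAfold-compatible
  executable, passing the segment and a constraint string (`.` free, `x`
  forced unpaired) on stdin, and parses either the ensemble free energy
  (default) or the MFE from stdout, in the program's units (kcal/mol).
  Failures raise immediately; there is no silent fallback to the internal
  model, because silently mixing energy scales would corrupt a model.

The field is genuinely ambiguous about MFE versus ensemble free energy for
this feature; both are supported, the mode is recorded in model metadata,
and models trained under one mode refuse nothing at predict time except a
mismatch in standardization — users are expected to keep the backend fixed
per model, which the recorded metadata makes auditable.

**Conservation (Csrv1–Csrv10).** The mean of a per-position conservation
track (phyloP-like, unitless) over ten consecutive positions from the site
start, clamped at the sequence end (mean over available positions). The
printed definition of this quantity is a sum in one place and an average
in the surrounding text; the average is implemented — the two differ by a
constant factor of 10, which is rank-preserving and therefore irrelevant
to the forest, but the average keeps the feature on the track's own scale.
Tracks are supplied per sequence (TSV keyed by id and 1-based position);
unlisted positions default to 0, and a sequence with no track gets an
all-zero track with a warning rather than NA, because the forest requires
complete vectors. Genome alignment to fetch conservation for arbitrary
sequences is deliberately out of scope.

## Standardization

For each PWM, every feature column's sample mean `M_j` and sample standard
deviation `S_j` (n−1 denominator; the estimator is a convention choice)
are computed over a background sequence set, and `z = (f − M_j)/S_j`.
Degenerate columns (`S_j = 0`, reachable e.g. with a uniform PWM) map to 0
rather than NA or ±Inf. The self-standardization identity — the background
matrix standardized by its own statistics has column means ~0 and sds ~1 —
is tested to 1e−10. The background set is an input (file or generator
call), not a bundled corpus; its size, seed and backend mode are recorded
in the statistics object for provenance.

## The forest

The classifier is a from-scratch deterministic random forest (compiled):
bootstrap sampling, CART gini splits, `mtry` features sampled without
replacement per node, trees grown to purity (`nodesize = 1`). Defaults
`n_trees = 500` and `mtry = 6 ≈ floor(sqrt(40))` are the standard
classification defaults of the reference R implementation of random
forests; none of the hyperparameters were stated by the method's source,
so the implementation defaults are adopted and recorded in the model.
Randomness comes from a self-contained xorshift generator seeded per tree
from the user's integer seed, so a `(data, params, seed)` triple yields a
bit-identical model in any session — a stronger guarantee than relying on
R's global RNG state.

Out-of-bag (OOB) votes are kept per training row: each row is scored only
by trees whose bootstrap excluded it, and OOB AUC is the model's headline
evaluation. Rows that were in-bag in every tree (possible at very small
`n_trees`) are excluded from the AUC rather than imputed. Feature
importance is OOB permutation importance — the mean decrease in per-tree
OOB accuracy when a feature column is permuted among the OOB rows, seeded
and deterministic, with ties ranked by feature order.

Specific models train on raw features, the general model on standardized
ones; the state is stored on the model and enforced at predict time with a
hard error (no silent coercion), because predicting raw features through a
z-space forest yields confidently wrong votes rather than a crash. The
binding call threshold on the vote fraction defaults to 0.5 and is
configurable; no canonical threshold exists for this method. The general
model keeps all pooled positives and down-samples negatives (seeded,
without replacement when possible) to a 1:2 positive:negative ratio,
reflecting that non-binding events outnumber binding events
transcriptome-wide; the ratio is a parameter.

How predictions from multiple PWMs of one RBP should be aggregated is left
to the user: one prediction record is emitted per (sequence, PWM, model).

## Evaluation

`roc_auc` is the Mann–Whitney statistic (ties get half credit), computed
from midranks. `pr_auc` uses the non-interpolated step rule with tied
scores processed as one group — stated explicitly because AUPRC
implementations disagree; with constant scores it equals the prevalence.
Both are verified against brute-force pair/threshold enumeration. The
benchmark harness pairs one positive set with several independently drawn
random negative sets (default 5) and reports per-replicate AUC/AUPRC plus
a mean/sd summary, mirroring the random-negative evaluation protocol.
Sequences shorter than 150 nt are removed by the length filter
(`L >= 150` kept — the literal boundary reading).

## The synthetic world

The generator emulates the training data the method was designed for:
3′-UTR-like background sequences (i.i.d. bases; uniform composition by
default, with an AU-rich preset `A .3, U .3, C .2, G .2` for realism
tests), positives carrying 1–2 motif instances sampled column-wise from
the PWM at non-overlapping uniform positions, pseudo-negatives that are
plain background (random sequences approximate experimental negatives
well; an optional consensus screen exists for razor-clean unit tests, off
by default), and Gaussian conservation tracks (baseline mean 0, sd 1;
planted intervals mean 2, sd 0.5) emulating phyloP elevation at bound
sites. Default sizes: 7-nt motif from a symmetric Dirichlet with
concentration 0.1 (an informative, RNAcompete-like motif), 100 positives /
100 negatives, 300-nt sequences — long enough that interior sites have
full 180-nt folding context and everything clears the 150-nt filter.
Every generator is a pure function of (spec, seed).

What the generator does *not* emulate: real 3′-UTR composition beyond
mononucleotide frequencies, dinucleotide structure, shared homology
between sequences, realistic secondary structure at planted sites, or
positional biases of real binding. A green parameter-recovery test
therefore establishes that the pipeline recovers a planted signal under
its own stated assumptions — not that it reproduces published performance
on curated CLIP/UTR benchmarks, which require external data and are out of
scope by design.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; all emitted files are
  1-based inclusive.
* Site-selection ties break toward the smaller start; split-search ties in
  the forest keep the first candidate in sampled order (both
  deterministic).
* `T` is accepted anywhere and treated as `U`; lowercase is uppercased.
* Model and statistics files are JSON text with 17 significant digits, so
  doubles survive the round trip exactly and reloaded models predict
  bit-identically.
* Model files carry a format version; a mismatch is a hard error.
* `Gacc` is clamped at 0 if a backend reports a violation beyond 1e−6
  (and errors on larger violations).

## Known limitations

The internal energy model counts pairs rather than free energy, so Gacc
magnitudes are not comparable between backends (only within one mode,
which is why the mode is pinned in model metadata). Features for one
sequence are independent of all other sequences, so batch effects in real
data are invisible to the model. The 40-feature design caps what the
forest can learn about long-range context; that is a property of the
method being implemented, not of this implementation.
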