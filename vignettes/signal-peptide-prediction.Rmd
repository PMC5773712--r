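---
title: "Signal peptide classification and cleavage-site scanning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal peptide classification and cleavage-site scanning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscan)
```

`sigscan` implements a two-stage analysis of protein primary sequences:
a secretory / non-secretory classifier built on a 220-element
physicochemical sequence encoding, and a cleavage-site scanner that combines
a log-ratio position weight matrix with the (−3,−1) residue rule. This
vignette is the package's account of the model, its tunable parameters, the
design decisions that were genuinely open, and what the synthetic benchmark
does and does not establish.

## The sequence encoding

A sequence is a string over the 20 canonical residues, indexed alphabetically
(`AA_ALPHABET`). The encoder's premise is that composition alone discards the
order information that distinguishes a signal peptide (a basic n-region, a
hydrophobic h-region, a polar c-region, *in that order*) from an ordinary
N-terminus of the same composition. Order enters through two devices:

1. **Adjacency-pair statistics.** For each residue type â, the directed
   counts `f` of residues immediately before and after â's occurrences are
   combined with a pair function ϑ into the neighbour sum
   `XY_â = (1/38) [Σ_{k≠â} f_{k→â} ϑ(k, â) + Σ_{k≠â} f_{â→k} ϑ(â, k)]`.
   The constant 38 counts the 2 × 19 directed pair classes and is kept as a
   fixed normalizer; no further normalization by sequence length is applied.
2. **Position gaps.** The distances from the N-terminus to â's first
   occurrence (dropped if that occurrence is position 1), between successive
   occurrences, and from the last occurrence to the C-terminus (dropped if
   terminal) each multiply `XY_â`, so the same neighbourhood statistic is
   weighted by where in the chain it is realized.

The full component per residue and pair scheme is
`Π_â = Λ_â + (Λ_â − 1)!·ϑ(â,â) + Σ_g g·XY_â`, with Λ_â the occurrence count.
A residue that never occurs contributes 0 (the factorial of −1 is undefined,
so the whole component short-circuits); a singleton uses 0! = 1.

**Pair function.** ϑ(l, m) adds a contrast term
`|Δ*_s(l)|·|Δ*_s(l) − Δ*_s(m)|` on one property s to a cross-correlation term
`|(Δ*_a(l) − mean_a)(Δ*_b(m) − mean_b)| / sqrt(SS_a·SS_b)` on a property pair
(a, b). Scheme 1 uses s = hydrophobicity with (a, b) = (hydrophobicity,
hydrophilicity); scheme 2 uses s = hydrophilicity with (hydrophobicity,
side-chain mass); scheme 3 uses s = side-chain mass with (hydrophilicity,
side-chain mass). Tying the contrast property to the scheme index is a
package decision — the three pair functions are printed with an unresolved
subscript s in their source — and `pair_scheme()` exposes an override for
sensitivity analysis. ϑ is non-negative and not symmetric in general.

**Layout.** Each property block stores its 20 Π values split into three
additive parts — core (count + self term + internal gaps), leading gap, and
trailing gap — giving 60 components per property and 180 in total. The split
is information-preserving (the parts sum to Π); it is one consistent reading
of a 60-per-property layout whose exact construction the method's
description leaves open, and the test suite pins the decomposition by
checking part sums against a literal brute-force expansion, exhaustively on
all sequences of length ≤ 6 over a 4-letter sub-alphabet. The final 40
elements are per-residue composition Λ_â/N and mean position mean(p)/N (0
when absent) — the simplest order/composition summaries.

**Numerical choices.** Sequences are truncated to their first 100 residues
before encoding, mirroring the curation rule for secretory extractions and
bounding Λ at 100 so the factorial self term stays finite; `(Λ − 1)!` is
evaluated in log space and capped at 1e300 when truncation is disabled.
Encoding a single residue is refused (no pairs exist). Non-standard residues
(B, Z, X, U, O) are rejected by default, with an explicit opt-in mapping to
a stand-in residue, because silent coercion corrupts the adjacency counts.

## Property scales and standardization

The three scales — Tanford hydrophobicity, Hopp–Woods hydrophilicity,
textbook side-chain masses (Da) — ship as a plain-text table
(`inst/extdata/aa_properties.tsv`). Each is standardized to [−R, R] by the
affine map `Δ* = [2R/(Δ_max − Δ_min)](Δ − Δ_max) + R`, which is
order-preserving and attains both endpoints exactly. R defaults to 1 and is
exposed as a parameter: the unit range keeps the three properties'
contributions to ϑ on a comparable scale. The method's source cites the
scale authors but prints no numbers and no R, so encoded feature values are
reproducible only relative to the shipped table; alternative scales can be
supplied through the same table interface.

## The classifier

`sp_classifier()` fits a fully connected 220–50–2 network, sigmoidal in both
layers, by full-batch gradient descent on the mean squared error against
one-hot targets — the classical backprop-era configuration. The learning
rate adapts: an epoch that lowers the loss is accepted and the rate
multiplied by `lr_up` (default 1.05, capped at `lr_max`); an epoch that
raises it is rejected — weights restored — and the rate multiplied by
`lr_down` (default 0.7, floored at `lr_min`, which also stops training).
Accepted-step losses are therefore non-increasing by construction. Weights
initialize uniformly in ±1/√(fan-in) from a user seed; identical data,
configuration and seed reproduce identical weights bit for bit.

Feature columns are standardized inside the fit (stored center and scale,
re-applied by `predict`): raw components mix occurrence counts with
gap-weighted sums whose magnitudes differ by orders of magnitude, and
sigmoid units saturate without it. This is a package design choice; the loss
(MSE), the adaptive constants and the epoch budget are likewise package
defaults, since the method's description names the mechanisms but no
constants. Defaults: `max_epochs = 300`, `lr0 = 0.5`, `tol = 1e-10`.

The secretory output unit's activation serves as the classification score in
[0, 1]; an exact tie between the two output units is resolved to
`non_secretory`, so a degenerate symmetric network never asserts a signal.
Models serialize to a versioned JSON document (shapes, weights,
standardization, configuration) readable outside R.

## Cleavage-site model

**Weight matrix.** Training windows are residue strings aligned on the
cleavage bond, by default spanning −13..+2 — wide enough to cover the
h-region signal while keeping three residues of padding inside the shortest
admissible signal; the window is configurable. Entries are
`Q(â, i) = ln((P(â, i) + c) / (⟨P(â)⟩ (n + 20c)))` with column counts P,
background abundance ⟨P⟩ and pseudocount c. The default c = 1 (add-one)
exists because the logarithm is undefined on zero counts; c = 0 is allowed
explicitly and yields −Inf sentinels. With counts exactly proportional to
the background, Q is identically 0.

**The (−3,−1) rule.** `rule_set("eukaryote")` implements the printed
eukaryotic constraints verbatim: −1 ∈ {Ala, Ser, Gly, Cys, Thr}, −3 ∈ {Asp,
Glu, Lys, Arg, Asn, Gln} and not {Phe, His, Tyr, Trp}, no proline in −3..+1.
This −3 set (charged/polar) contradicts the classical von Heijne
small-residue rule; the package does not silently correct it and instead
provides `rule_set("classic_von_heijne")` as the documented alternative.
The prokaryotic set is −1 ∈ {Ala, Gly, Ser, Thr}, −3 ∈ {Ala, Gly, Leu, Ser,
Thr, Val}; its −7/−8 hydrophobic preference ("Leu or another hydrophobic
residue other than Val, Phe") is recorded on the rule set but not enforced
by `rule_check()` — it is described as a tendency, not a constraint.

**Scanning.** Candidate +1 positions run 4..min(61, N−1) (a 3–60-residue
signal puts +1 at 4..61). Non-compliant positions score 0 and are never
returned; compliant ones score the sum of Q over the aligned window, clipped
at the sequence start for short signals. The maximum wins; exact ties break
to the most N-terminal candidate, reflecting the bias toward shorter
signals. How rule filtering and matrix scores combine is only sketched in
the method's source; zeroing non-compliant positions and summing Q over the
rest is the reading implemented here, and with a flat matrix the scanner
degenerates to pure rule filtering plus the tie-break, which the tests
verify directly.

## Data curation and the annotation table

Curation operates on a documented TSV stand-in for the database fields used
to assemble benchmark sets (`id`, `oc`, `location`, `signal_start`,
`signal_end`, `keywords`, `sequence`); live database querying is out of
scope. Secretory records must carry a signal annotation and none of the
ambiguous keywords *potential*, *probable*, *fragment*, *by similarity*
(case-insensitive substring match on the keyword field — the sources list
phrases, not a grammar), and are truncated to their first 100 residues.
Non-secretory records are nucleus/cytoplasm (eukaryotes) or cytoplasm only
(prokaryotes) and are not truncated — truncation is stated only for the
secretory extraction. Exact duplicate sequences are removed, first
occurrence kept; no homology-based redundancy reduction is attempted.
`curate()` returns the filtered table itself, which makes its idempotence
(`curate(curate(x)) == curate(x)`) directly testable.

## The synthetic generator

`generate_synthetic()` emulates the canonical three-region anatomy:

* **n-region**, 1–5 residues from a basic-biased pool with at least one
  Lys/Arg forced;
* **h-region**, 7–15 residues from a hydrophobic pool (Leu-dominated, with
  Ala, Val, Ile, Phe, Trp, Met);
* **c-region**, 3–7 residues from a polar *uncharged* small-residue pool
  (Ser, Thr, Ala, Gly, Asn, Gln), with the −3 and −1 positions drawn from
  the organism's allowed rule sets, so every positive passes `rule_check()`
  at its planted site by construction;
* **mature region**, 30–80 residues from a database-like background
  composition (`aa_background()`), with no proline at +1.

Negatives are background-composition sequences with an initiator Met and no
planted structure. Region-length ranges follow the stated signal anatomy;
the residue pools are the package's own realism choices, fixed once. The
generated classes differ in n-terminal hydrophobicity — the property the
encoder must exploit — and the tests assert this one-sidedly on generator
output.

What the generator does **not** emulate: database noise (annotation errors,
fragments, non-standard residues), homologous redundancy, length and
composition heterogeneity across taxa, signal-anchor sequences,
transmembrane segments that mimic h-regions, and cleavage sites that violate
the printed rules (which real data contain). Passing the synthetic
benchmarks therefore demonstrates that the implementation is faithful and
that the pipeline can recover planted structure — not that the stated
accuracies transfer to any particular database snapshot. Reproducing the
published benchmark accuracies is explicitly not claimed: they depend on an
unversioned database extraction and unstated training constants.

A note on the cleavage benchmark: the planted-site recovery check builds the
weight matrix from the generated dataset's own aligned windows — the same
protocol the method uses on its benchmark set. Recovery is limited by decoy
candidates, because Asn/Gln sit both in the eukaryotic −3 allowed set and in
any realistic polar c-region pool, so neighbouring compliant positions can
score close to the true site; typical recovery on 200 positives is in the
0.93–0.98 range across seeds. The weight-matrix parameter-recovery check
compares rebuilt log-ratios to the generating profile by mean absolute
deviation over the profile's support: at 500 windows the entrywise maximum
is dominated by sampling noise for any profile over 20 residues, so a
max-error criterion would test the sample size, not the estimator.

## Validation protocols

`run_protocol()` implements self-consistency (train and test on the full
set), stratified k-fold cross-validation (default k = 10; folds are
stratified by class because unstratified folds can degenerate to a single
class, leaving sensitivity or specificity undefined), and the jackknife
(leave-one-out with a full retrain per held-out sample; at k = n the k-fold
path coincides with it exactly). Pooled confusion counts, per-fold counts,
the averaged per-fold accuracy, and scores for ROC analysis are returned.
`sp_metrics()` reports Sn, Sp, Acc, MCC and the class-wise true-prediction
rates; accuracy and the overall true-prediction rate are the same statistic
under two parameterizations, and the tests assert the identity (and the two
MCC forms) on 10,000 random confusion tables. MCC is reported as `NA` when a
marginal is zero. Display rounding is 2 decimals; computations are never
rounded internally. Of note, two cells of the published worked-example table
(eukaryotic accuracy and Gram-negative MCC) differ by 0.01 from the values
implied by their own printed confusion counts; the package reports the
computed values.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at 200 +
200 sequences (encoding, one self-consistency fit, one 10-fold
cross-validation), 200 positives for cleavage recovery, 500 windows for
weight-matrix recovery, and exhaustive encoder verification on all 5,440
sequences of length 2–6 over {A, C, D, E}. These sizes give stable
statistics while keeping a complete run in well under a minute for the
script and a few tens of seconds for the suite; jackknife validation, which
retrains per sample, is exercised on small datasets in the unit tests.

## Known limitations

* Feature values are only reproducible relative to the shipped property
  table; sources for the scales print no numbers.
* The 60-per-property layout is one consistent construction of an
  underdetermined description; alternatives would change feature values but
  not the information content.
* Adjacency counts are raw counts, not relative frequencies (configurable
  readings exist; raw counts follow the "frequency of pair" description).
* The eukaryotic −3 rule set is implemented verbatim despite conflicting
  with the classical small-residue rule; use `classic_von_heijne` for the
  latter.
* The classifier is a small dense network with full-batch updates: adequate
  for hundreds to a few thousand sequences, not engineered for
  database-scale training.
* Cleavage scanning assumes exactly one site per secretory sequence and
  reports none when no candidate is rule-compliant.
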