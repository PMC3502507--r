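---
title: "The H-factor: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The H-factor: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfactor)
```

## The problem and the model

Homology modeling builds a target protein's structure on the framework of a
homologous template, and the result depends on everything upstream: the
choice of template, the target–template alignment, and the modeling run
itself. The H-factor condenses a retrospective audit of those inputs into
one percentage on a 0–100 scale (0 = good), by analogy with the
crystallographic R-factor. It deliberately scores a *set* of models
generated from the same input rather than a single model — heterogeneity
across the set is itself evidence about input quality — and therefore
refuses to run on a single model. Its counterpart limitation is that it
cannot rank the members of one ensemble against each other.

Four sub-scores on a common 0–10 scale are averaged and multiplied by 10:

* **score₁ — secondary-structure agreement.** Per alignment column the
  penalty is 0 when the target's predicted state equals the template's
  assigned state, `c + 1` when they differ (`c` is the 0–9 prediction
  confidence), and 1 when either row is gapped. The mean penalty maps
  through `1.3 · x + 0.9`, clipped to [0, 10].
* **score₂ — sequence non-identity.** `10 · (1 − identities / N)` with `N`
  the full alignment length, gap columns included in `N` and never counted
  as identities (the only reading consistent with the sum-over-columns
  form of the score).
* **score₃ — ensemble heterogeneity.** Mean Cα cRMS of the members to the
  ensemble's average model, mapped through `1.3 · x + 0.87`.
* **score₄ — domain integrity.** Mean Cα cRMS between average-model
  fragments at Pfam domain envelopes and reference structures of the same
  domains, mapped through the same constants as score₃.

## Parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| score₁ offsets `a1`, `b1` | 1.3, 0.9 | — | published calibration; perfect agreement scores 0.9 |
| score₃/₄ offsets `a3`, `b3`, `a4`, `b4` | 1.3, 0.87 | per Å, — | places mean cRMS 0.1 Å at score 1 and 7 Å at score 10 |
| clip bounds | [0, 10] | score | the constants can push raw values past 10 (e.g. 1.3·10 + 0.9 = 13.9); clipping enforces the stated range |
| E-value cutoff | 1.0e-10, inclusive | — | published cutoff for domain hits; stated without strictness, so a hit at exactly 1.0e-10 is kept |
| hit cap | 5 | hits | published maximum number of domain fragments |
| average-model tolerance | 1e-6 | Å | plain RMSD between successive consensus coordinate sets |
| average-model iteration cap | 50 | — | safety bound; non-convergence is flagged, not an error |
| correspondence alignment | BLOSUM62, gap open 10, extend 0.5 | — | standard global-alignment parameters for matching fragment to reference residues |

Overriding the affine constants is possible through `scoreConstants()` but
warned against: the 0–10 sub-score scale, and hence the percentage scale of
the composite, is defined by these values.

### Two readings of the mismatch penalty

The mismatch penalty is implemented as `f = c + 1`, giving mismatches a
range of 1–10 that dominates the gap penalty of 1 and uses the full 0–10
score range; a confidently wrong prediction at `c = 9` costs ten times a
gap. The alternative reading `f = (c + 1) / 10` would cap score₁ at 2.2,
which contradicts both the intended 0–10 range and observed sub-score
values around 7 on hard targets. The alternative remains selectable
(`ssAgreementScore(..., mismatchPenalty = "scaled")`) for sensitivity
checks only. Gap columns are penalised identically whether the gap is on
the target or the template row, and a mismatch at confidence 0 costs the
same as a gap (`f = 1`); nothing in the score's definition distinguishes
these cases further.

## Geometry

`crms()` is the RMSD after least-squares rigid-body superposition (Kabsch,
via singular value decomposition), computed over all Cα positions with no
trimming of flexible termini. The reflection branch is excluded by a sign
flip on the smallest singular direction, so rotations are always proper
(det = +1), including for mirror-image inputs; collinear inputs are flagged
degenerate but still yield the minimum RMSD.

A per-residue coordinate average is frame-dependent, so the average model
is defined iteratively: seed the consensus with model 1, superpose every
member onto it, re-average, and repeat until the consensus moves by less
than the tolerance. Tests assert the result is independent of the seed
frame up to a rigid motion. With an ensemble of identical members the
procedure converges in one iteration to the member itself.

### score₄ normalisation and residue correspondence

When domains have unequal reference counts, averaging "per domain, then
across domains" and pooling all (domain, reference) pairs differ; the
pooled grand mean is used, which coincides with the `1/(m·n)`
normalisation whenever every domain has the same number of references.
Fragment and reference are put in residue correspondence by a global
Needleman–Wunsch alignment of their sequences (BLOSUM62, gap open 10,
extend 0.5); the cRMS runs over the aligned non-gap pairs, at least 3 of
which are required. Fragments are sliced from the average model at the hit
envelope's target positions; unmodeled positions are dropped and counted.
A fragment with no usable reference is skipped with a recorded reason, and
when every fragment is skipped score₄ is absent and the H-factor averages
the three remaining scores — the composite is defined for 3 or 4 present
sub-scores, never fewer.

## File dialects

Parsers accept the dialects the upstream programs write: PDB ATOM records
(first MODEL only — each file contributes one model; alternate locations
resolved by highest occupancy, ties by first appearance; HETATM ignored),
aligned FASTA and Clustal, PSIPRED `.ss2` and `.horiz`, STRIDE ASG records,
and `hmmsearch --domtblout`. Three choices deserve a note:

* **STRIDE collapse.** The 7-state STRIDE alphabet is reduced to 3 states
  by the conventional table H,G,I → H; E,B,b → E; T,C,S → C, kept in one
  internal table so it can be swapped.
* **ss2 confidence.** `.ss2` files carry three per-state probabilities
  rather than a 0–9 digit; the confidence is `floor(10 · max probability)`
  capped at 9, which reproduces the `.horiz` digit scale.
* **domtblout E-value.** Hits are per-domain envelopes, so the per-domain
  independent E-value (column 13) is filtered, not the full-sequence
  E-value.

## The synthetic-data generator

Every knob of `fixtureSpec()` targets exactly one sub-score, and altered
positions are chosen as an exact count (`round(fraction · n)` seeded
positions) rather than by i.i.d. coin flips, so fixture sub-scores are
exact rather than approximate: identity 0.5 gives score₂ = 5.0 exactly.
The base trace is an ideal α-helix (radius 2.3 Å, rise 1.5 Å/residue,
100°/residue twist — fixed for reproducibility, not realism); ensemble
members add i.i.d. Gaussian coordinate noise; the domain fixture is one
full-length hit whose reference is the unperturbed base. A seed is
mandatory everywhere and the generated bundle is byte-deterministic.

Defaults (100 residues, 20 models, σ = 0.5 Å, identity 0.5, mismatch 0.2
at confidence 7) describe a mid-quality modeling scenario: 20 models
matches common ensemble practice for this kind of assessment, and 0.5 Å of
coordinate noise yields a mean ensemble cRMS near 0.8 Å, within the range
observed for usable homology models.

What the generator does **not** emulate: correlated, structured deviations
(loop excursions, domain hinge motions) — its noise is isotropic and
independent per atom; alignment gaps (identity fixtures are gapless);
realistic secondary-structure segment statistics; and multi-chain or
multi-template situations. Passing tests on these fixtures therefore
demonstrates the arithmetic and plumbing of the scores under controlled
conditions, not performance on real modeling pipelines.

## Numerical choices and degenerate inputs

* Score clipping happens after the affine map; bounds are asserted on
  randomized sweeps.
* Display rounding of the percentage is half-up to an integer
  (`floor(x + 0.5)`); the raw value is retained in reports. Published
  benchmark tables round the same way, and the worked-example suite
  reproduces their integer percentages from their sub-score quadruples.
  Two rows of that table are known not to round-trip from their own
  printed sub-scores (off by ≤ 1 point), consistent with sub-scores having
  been rounded before printing; they are documented and excluded from
  checks.
* `hFactor()` refuses fewer than 3 present sub-scores and any sub-score
  outside [0, 10].
* Ensembles must have ≥ 2 members of identical length and sequence; the
  mismatch error names the offending pair of files.
* The average-model iteration converges in a handful of iterations on all
  tested inputs (tolerance 1e-6 Å, cap 50); non-convergence is reported in
  the flag and diagnostics.

## Problem sizes used in the tests

The shipped suites run on 25–100-residue traces and 2–20-member ensembles,
with the brute-force rotation-grid oracle (15° grid plus Nelder–Mead
polish) applied to toys of at most 6 points; these sizes exercise every
code path while keeping the full suite around ten seconds. The calibration
check tunes σ so the generated ensemble's mean cRMS is 0.1 Å (with a fixed
seed Gaussian noise scales exactly with σ, so a proportional search
converges in a few steps) and verifies the heterogeneity score equals 1.0.

## Known limitations

Single template and single chain only; Cα backbone only (side-chain errors
are invisible); no per-residue quality profile; no ranking within an
ensemble; domain references must be supplied as coordinate files (the
package consumes HMMER/PSIPRED/STRIDE *output*, it does not run the
programs). The identity score is strict identity — a similarity-based
variant would score conservative substitutions differently, and published
percent-identity columns computed over different alignments need not agree
with score₂.
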