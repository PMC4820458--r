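---
title: "Methods: in-silico RFLP typing and biocontrol arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico RFLP typing and biocontrol arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagerflp)
```

This vignette is the package's account of what it computes, the modelling
choices behind each stage, and what the simulation-backed tests do and do
not establish about real data.

## Virtual digestion

A restriction enzyme is a triple (name, recognition sequence, cut offset);
the built-in default is HindIII, `A^AGCTT` (cut offset 1). Site search is
exact, single-strand matching of the unambiguous recognition sequence
against the genome:

* **Ambiguity codes.** A genome position carrying an IUPAC ambiguity code
  (including `N`) never matches a recognition base. The alternative —
  expanding ambiguity codes into all compatible sites — invents cuts the
  molecule may not have; dropping such sites is conservative and
  reproducible, and the choice only matters for draft-quality sequence.
* **Topology.** Packaged phage DNA extracted from virions is linear, so
  `linear` is the default; genome records deposited as replicative forms
  can be digested as `circular` (a per-genome flag, echoed in pipeline
  reports). For a circular genome the scanner extends the sequence by the
  first `k − 1` bases so sites spanning the origin are found, and cut
  coordinates are reduced modulo genome length. A linear genome with *k*
  sites yields *k* + 1 fragments (terminal fragments included); a circular
  genome with *k* ≥ 1 sites yields *k* fragments; zero sites yield the
  full-length fragment flagged `uncut`. In every case fragment lengths sum
  exactly to genome length — the invariant the property tests enforce.
* **Coordinates** are 0-based half-open internally; human-readable output
  reports fragment ranks, not coordinates, which sidesteps off-by-one
  drift entirely.

Overlapping sites are all reported and cut positions are deduplicated;
this cannot arise for `AAGCTT` but can for other enzymes loaded from an
enzyme TSV.

## The virtual gel

Band migration follows the single log-linear law `d(s) = a − b·log10(s)`
(`b` > 0, distance in mm), the standard empirical description of
conventional agarose electrophoresis away from its extremes. No reptation
or limiting-mobility correction is applied: over the ~0.5–25 kb range a
0.8% gel resolves, the log-linear law is adequate, and it has the virtue
of being exactly invertible — which is what makes round-trip testing
possible. Outside that range (very small or >50 kb fragments) real gels
compress and the model is knowingly optimistic; this is a documented
limitation, not a bug.

Defaults: detection window 100 bp – 50 kb (fragments outside it leave no
band), resolution limit 0.5 mm (bands closer than this merge into one
band at their mean position with summed multiplicity), Gaussian noise on
*distance* (not size), and a default model of `a = 220`, `b = 40` so that
distances stay positive across the whole 100 bp – 150 kb range the
package simulates. Calibration is an ordinary least-squares fit of
distance against log10(size) from a ladder of at least three rungs; the
RMS residual is kept on the model object.

Numerical conventions: inferred sizes are rounded to integer bp and
exported distances to 0.01 mm, but the in-memory lane keeps full
precision. Rounding distances before inversion would inject a ~3 × 10⁻⁴
relative size error (more than 1 bp above ~3.5 kb) and would break the
noiseless round-trip identity that anchors the gel module's tests.

Genome-size estimation sums inferred band sizes times multiplicities. It
is biased low whenever fragments fall below the detection window — the
same bias a bench estimate from a gel photograph has — and the tests
assert the direction of that bias rather than pretending it away.

## Band matching and similarity

Two bands of sizes `s_p`, `s_q` are *compatible* when
`|s_p − s_q| ≤ tol · (s_p + s_q)/2`, with `tol = 0.01` by default: a 1%
position tolerance applied to band molecular weight. Applying the
tolerance to MW rather than to run position keeps the comparison
independent of any particular gel calibration; a gel-position reading can
be had by passing profiles through the virtual gel first (the pipeline's
`gel` mode). The score is the maximum-cardinality one-to-one matching
among compatible pairs, computed by a two-pointer sweep over the
size-sorted profiles. For this interval-compatibility structure the sweep
attains the true maximum; rather than relying on that argument, the test
suite checks the sweep exhaustively against a brute-force matching oracle
on hundreds of randomized profiles of up to 8 bands, including
near-coincident sizes that sit right at the tolerance boundary.

Similarity is Dice (Nei–Li), `S = 2m/(n_p + n_q)` — the de-facto standard
of band-based fingerprint analysis — with Jaccard behind a flag; the
distance is `1 − S`. Duplicated sizes are legitimate (distinct
co-migrating fragments) and participate in the matching individually.
An uncut genome still carries its single full-length band, so empty
profiles are a usage error, not a valid state.

## UPGMA

The dendrogram is classic size-weighted UPGMA: merge the closest pair,
set the merge node at half the merge distance, and update distances as
the size-weighted arithmetic mean `(|A|·d(A,C) + |B|·d(B,C))/(|A|+|B|)`.
Two deterministic conventions make output byte-stable across platforms:
ties between equally close pairs break on the lexicographically smallest
pair of cluster labels (each cluster represented by its smallest leaf
label), and children order with the smaller subtree-minimum label first.
The result is ultrametric by construction; the tests verify all
root-to-leaf path lengths agree to 1e-9, that ultrametric input matrices
are reproduced *exactly* by the cophenetic distances of the output tree,
and that the cophenetic structure agrees with an independent UPGMA
implementation on generic (tie-free) random matrices. Newick output
carries 6-decimal branch lengths and quotes labels containing
metacharacters.

## Biocontrol arithmetic

These are deliberately small, exact functions — the value of housing them
in a package is unit discipline and input validation, not mathematics:

* `moi_dose(moi, cfu_per_ml)` = `moi × cfu`: the phage titre needed for a
  target multiplicity of infection.
* `percent_reduction(control, treated)` = `100(1 − treated/control)`;
  bounded above by 100, attained only at complete elimination.
  `reduction_consistency()` recomputes a published reduction from its raw
  values and warns when the claim is more than one percentage point from
  the arithmetic — published figures are sometimes rounded generously,
  and the package reports the computed value rather than matching the
  quote.
* `tyramine_mm_to_mgkg(conc)` multiplies by the tyramine molar mass
  (137.179 g/mol) and assumes 1 kg of product ≈ 1 L of aqueous phase.
  That unit-density assumption is implicit in any food-matrix conversion
  of mM to mg/kg and is stated rather than hidden.
* `qpcr_cells(ct, curve)` inverts the linear standard curve
  `Ct = intercept + slope·log10(N)`. Curve coefficients are runtime
  configuration; the defaults (slope −3.32 = 100% efficiency, intercept
  40) are labelled placeholders to be replaced by a laboratory
  calibration, never used for scientific claims.
* `two_sample_t()` is the textbook pooled-variance Student's test
  (two-sided), since that is the test classical biocontrol designs name;
  Welch's form is a flag. Degenerate (zero-variance) input errors rather
  than returning NaN.

## The synthetic-data generator

The generator defines the study conditions the pipeline is validated
under:

* **Genomes** are i.i.d. base sequences at GC 0.37 (enterococcal-like) in
  the 17–148 kb range of published *E. faecalis* phage records (the
  packaged `phage_panel()` table). At that GC, `AAGCTT` occurs about
  every 3 kb, giving the 10–20-band profiles the method needs.
* **Evolution** is Jukes–Cantor-style: along a branch of length ℓ
  (expected substitutions/site), each site mutates with probability
  `1 − e^(−ℓ)` to a uniformly chosen different base. No indels — keeping
  lengths fixed keeps digest profiles directly comparable, and
  substitutions alone create the site gain/loss signal RFLP measures.
  This deliberately omits real phage genome features: mosaicism,
  recombination, terminal repeats, and length variation. Passing the
  recovery tests therefore shows the *pipeline* is correct, not that RFLP
  typing is robust to those biological complications.
* **Topology recovery** is scored on a 6-taxon, two-clade truth
  (within-clade branches 0.002, clade stems 0.05, 40 kb genomes): digest,
  Dice at 1%, UPGMA, then compare the root bipartition to the truth. The
  acceptance standard is recovery in at least 90% of 20 seeded
  replicates; in practice recovery is essentially always achieved at
  these divergences.
* **Challenge counts** are lognormal — the standard noise model for plate
  counts — parameterised by mean and CV so that the sample mean is
  calibrated (meanlog = log(mean) − sdlog²/2); `cv = 0` yields exact
  means for arithmetic identities. Replicate counts default to 3,
  matching the at-least-three-independent-results convention of the
  assays the module emulates.

Every stochastic operation takes an explicit seed and uses no global RNG
state; identical (input, seed) pairs reproduce output bit-for-bit.

## Problem sizes

The shipped test suite and acceptance script run: exhaustive matching
oracles on profiles up to 8 bands (hundreds of instances), round trips on
genomes up to ~148 kb, 20-replicate topology-recovery simulations on
40 kb genomes, and 1000 null simulations for the t-test's type-I rate —
sizes chosen to make the statistical checks decisive (binomial error
small relative to the tested bands) while keeping a full run in well
under a minute on one core.

## Known limitations

* Single log-linear gel regime; no band-intensity modelling, no
  densitometric (curve-based) similarity.
* Exact-match site finding only: no methylation sensitivity, star
  activity or partial digestion.
* Substitution-only evolution; no bootstrap support on dendrograms.
* The 1% tolerance is applied to molecular weight; gel-position tolerance
  is available only via the explicit gel mode.
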