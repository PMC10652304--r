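---
title: "Ranking oxidation-sensitive proteins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking oxidation-sensitive proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oxsens` estimates, protein by protein, how much a single oxidative
post-translational modification (PTM) would perturb a joint proteome, and
ranks proteins accordingly. This vignette explains the models behind each
stage, the parameters that matter, what the synthetic data emulate, and the
choices made where the design was genuinely open.

## The %Δ PTM/site metric

Site-level PTM quantities (spectral-count-like, non-negative) are compared
between a treated and a vehicle condition. Replicates are averaged within
condition first, then each site contributes

\[
\%\Delta = 100\,\frac{\bar q_{\mathrm{treated}} - \bar q_{\mathrm{vehicle}}}{\bar q_{\mathrm{vehicle}}},
\]

and a protein's (or a modification's) change is the **unweighted mean** of
its sites' values. The per-site normalization is what makes proteins of
different site counts comparable; a summed variant
(`aggregate = "sum"`) is provided because heat-map style totals are
sometimes wanted, and at the summed level the per-protein and
per-modification groupings total identically. An intensity-weighted mean was
considered and rejected as default: it would re-couple the metric to
absolute abundance, which the per-site form exists to remove.

Two degenerate cases need policy, not formulas:

* a site detected **only under treatment** has no defined percent change
  from zero. Default: excluded from averages and recorded as a `new_site`
  sentinel; a pseudo-count option (`+0.5` on both condition means) is
  available when retaining such sites matters more than scale purity.
* a protein **all of whose sites** are sentinels is reported as
  insufficient data (`NA` change), deliberately distinct from "no change":
  downstream displays treat the two the same color but the tables never
  conflate them.

The zero band for sign classification defaults to `1e-9` percent — an
exact-zero test in float terms, appropriate because exact zeros arise only
in noiseless data; analyses of noisy data should widen it consciously.

Correlations between per-protein change vectors (young vs old, centrality
vs change) use Pearson's r with a least-squares line and a 95% percentile
bootstrap band for the slope from case resampling, `n_boot = 1000` by
default, seeded. The bootstrap is the plainest defensible choice for a band
around a regression on per-protein quantities with unknown error structure.

## Calibrated eigenvector centrality

Influence in the interaction network is scored by the dominant eigenvector
of the unweighted adjacency matrix. Edges enter unweighted after confidence
thresholding (`min_score = 400`, the conventional medium-confidence STRING
cut) because the available topology carries no principled weighting scheme.

Numerics: power iteration on the shifted matrix \(A + I\). The shift leaves
eigenvectors unchanged but guarantees convergence on bipartite-like graphs,
where the extreme adjacency eigenvalues tie in magnitude and plain
iteration oscillates (a star graph — the analytic test case — is exactly
such a graph). The start vector is uniform, which fixes the sign of the
returned vector to non-negative; convergence is declared when the maximum
componentwise change drops below `tol = 1e-10`, with `max_iter = 1000`. The
result is normalized to unit Euclidean norm. The whole graph is processed
in one pass: the dominant component carries the eigenvector and other
components decay toward zero, which is the intended "one scale for the
whole proteome" semantics.

**Calibration** is an identity contract, not a computation: the detected
subnetwork is the induced subgraph on the detected ids, and its centrality
values are the full-network values, byte-identical. Recomputing centrality
within the subnetwork would silently change the scale and inflate the
influence of locally dense clusters; the tests assert exact equality.

Louvain community detection runs on the **largest connected component**
only, at `resolution = 1` (classic modularity) and fixed seed. The number
of communities is data-dependent and deliberately not forced: small
synthetic networks typically fragment into more communities than the four
seen in real joint-proteome subnetworks, and no merging is applied.
Proteins absent from the network are dropped from network analyses and
excluded from scoring, rather than imputed a centrality of zero, which
would let missingness masquerade as unimportance.

## The electrostatic destabilization model

The stability stage is a composition-only, net-charge model. Counting
positively charged (Arg, Lys), negatively charged (Asp, Glu) and variably
charged (His) residues gives the native and denatured net charges

\[
Q_n = C^{+} + 0.4\,C_{\mathrm{His}} - C^{-}, \qquad
Q_d = C^{+} + 0.1\,C_{\mathrm{His}} - C^{-},
\]

with histidine entering as an expected (fractional) protonation rather than
a per-residue integer charge — the reading consistent with writing the sums
as expectations. Chain dimensions come from Flory scaling in residue count
\(N\): \(R_n = 2.24\,N^{0.392}\) Å (compact native state),
\(R_d = 1.927\,N^{0.598}\) Å (expanded denatured state); the denatured
radius exceeds the native one for every \(N \ge 3\). With Bjerrum length
\(I_b = 7.13\) Å and inverse Debye length \(\kappa = 0.03\) Å⁻¹ (aqueous,
body-temperature, cytoplasmic salt; all energies in kT so temperature never
appears explicitly), the folding free-energy change from one added
(\(+\)) or removed (\(-\)) charge is

\[
\frac{\Delta\Delta G}{kT}
= \frac{I_b(\pm 2Q_d + 1)}{2R_d(1+\kappa R_d)}
- \frac{I_b(\pm 2Q_n + 1)}{2R_n(1+\kappa R_n)}.
\]

Two ambiguities required decisions:

* **Sign and aggregation.** The formula is implemented verbatim (denatured
  term minus native term), but the *averaged signed* value over the two
  charge directions collapses to a charge-independent constant — which
  cannot produce a charge-dependent susceptibility map. The per-protein
  susceptibility therefore aggregates **magnitudes**, by default the mean
  of \(|\Delta\Delta G_{+}|\) and \(|\Delta\Delta G_{-}|\) (options: max,
  plus-only, minus-only). Rankings consume this non-negative quantity, so
  the sign ambiguity cannot corrupt them.
* **Ambiguity codes.** B, Z, X, U, O count as non-charged — the
  conservative choice in a model that consumes nothing but composition.

The susceptibility map places proteins in the (net charge, length) plane —
native charge \(Q_n\) on the charge axis by default, switchable — with a
2-D kernel density estimate (`MASS::kde2d`, 100×100 grid) summarized by
level sets enclosing 25/50/75% of the proteome mass. The top-quartile flag
is defined on susceptibility itself (above the 75th percentile of the
reference proteome), so it is reproducible without reference to bandwidth
choices; an all-identical proteome degenerates the density and flags
nothing, with a warning.

## The composite sensitivity score

Over the scored set \(P\):

\[
\mathrm{RSS} = \mathrm{minmax}_P(\Delta\Delta G)\cdot \mathrm{minmax}_P(E),
\qquad
\mathrm{CSS} = \mathrm{minmax}_P(\mathrm{RSS}).
\]

Min–max normalization makes the score invariant under independent positive
affine transformations of its two raw inputs (a property the tests check
over random transforms), and the final renormalization pins the top rank to
exactly 1.00 and the bottom to 0.00. Percentile subsets are
inclusive at the cutoff so float-equal proteins are never split, and
ordering is always (CSS descending, protein id ascending) for
reproducibility.

The definition of \(P\) is genuinely open in studies of this shape: "all
proteins represented" can mean every subnetwork protein or only the
PTM-mapped ones, and published top-20-equals-top-half tables imply a scored
set of a few dozen. Both modes are implemented
(`scored_set = "ptm_mapped"`, the default, or `"network"`), and neither is
asserted to be *the* published definition. An all-equal input to `minmax()`
is an error rather than a silent zero: a degenerate normalization means the
scored set cannot support a ranking, and that should be loud.

## What the synthetic data emulate — and what they do not

The generator reproduces the *structure* of a two-age senolytic study:
four conditions (vehicle/treated × young/old), 2–3 technical replicates,
spectral-count-like site quantities under Poisson noise (the default for
count data; a mean-preserving lognormal is available), per-protein planted
effects skewed toward PTM loss in the treated old arm (70% losses) and
gain in the treated young arm (20% losses), a scale-free interaction
network, and sequences whose charge-class fractions bracket typical
proteome composition (Arg+Lys and Asp+Glu each 8–16%, His 1–4%, lengths
50–1500 residues). The default scale — 2000 proteins in the
proteome/network, 500 detected — keeps every stage's statistical behaviour
visible while the full pipeline runs in seconds; the bundled analysis
scripts and the acceptance run use exactly this scale.

Planted hubs can additionally be made sequence-extreme
(`extreme_hubs = TRUE`: maximum length, maximally imbalanced charge), which
constructs proteins that *should* top the composite ranking — the
end-to-end truth check.

Deliberately not emulated: peptide digestion and spectra, site-localization
uncertainty, identification FDR, protein-correlated effect structure,
batch effects, and missingness mechanisms other than the new-site case.
Passing tests on synthetic data therefore demonstrate that the chain
recovers known planted structure under idealized sampling — not that any
particular biological dataset satisfies the models' assumptions.

## Numerical and degenerate-input policy, in one place

* Percent change needs a positive vehicle mean; zero/zero is null,
  zero-to-positive is a sentinel.
* Power iteration: shift by \(I\), uniform start, `tol 1e-10`,
  `max_iter 1000`, explicit error on non-convergence.
* Louvain: seeded; modularity reported; edgeless input is an error.
* `minmax` on a constant vector: error.
* Quartile flags on a degenerate proteome: all false, with a warning.
* Ties: percentile cutoffs inclusive; duplicate undirected edges merged
  keeping the maximum confidence.

## Known limitations

The stability model is composition-only: no structure, no pKa shifts, no
site-specific chemistry — a protein's ΔΔG changes identically whichever
residue is modified. Centrality inherits whatever ascertainment bias the
interaction database carries. The CSS is a ranking device, not a
probability: its absolute values have no units and no significance measure,
and community CSS sums depend on community sizes. Finally, the bundled
top-20 reference table carries display-precision (2 dp) scores only, so it
anchors censuses and membership counts, not score arithmetic.
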