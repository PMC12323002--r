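---
title: "Biomass-constrained EM for function abundances across taxonomic lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomass-constrained EM for function abundances across taxonomic lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageEM)
```

## The model

Mass-spectrometry metaproteomics yields a set of confidently identified
peptides; many of them are compatible with proteins of several related taxa
(the shared-peptide problem). `lineageEM` treats each peptide's quantitative
evidence — its MS1 extracted-ion-chromatogram area $x_i$ times its spectral
count $c_i$ — as arising from a mixture over its compatible-taxon set
$T_i$, and estimates in two stages:

**Stage 1 — biomass.** The relative biomass vector $p(t)$ over the
identified taxa maximizes
$$\mathcal{L}(w) = \sum_i x_i c_i \log \sum_{t \in T_i} w_t,
\qquad \sum_t w_t = 1,$$
by EM with E-step $r_{it} = w_t / \sum_{t' \in T_i} w_{t'}$ and M-step
$w_t \leftarrow \sum_i x_i c_i\, r_{it} / \sum_i x_i c_i$. The objective is
concave in $w$ on the simplex, so the EM fixed point is the global maximum;
the unit tests verify agreement with grid-search maximization to $10^{-4}$
on small instances, and that the log-likelihood trace is non-decreasing.

**Stage 2 — function abundance.** With $p(t)$ *fixed*, each peptide also
carries per-aspect compatible pairs $A_i \subseteq \{(t, k)\}$ of taxa and
GO terms (terms annotated to a retained protein of taxon $t$ containing the
peptide). The conditional weights $\varphi(k\,|\,t)$, constrained to sum to
1 per taxon, are estimated by a second EM with responsibilities
$z_{i,(t,k)} \propto p(t)\varphi(k|t)$ over $A_i$ and a per-taxon
normalized M-step. The reported quantity is the joint abundance
$p(k|t)\,p(t)$, which by construction satisfies the biomass constraint
$\sum_k p(k|t)p(t) = p(t)$ (asserted to $10^{-9}$ in the tests). Stage 2 is
run independently per GO aspect (biological process, molecular function,
cellular component), so each aspect's table satisfies the constraint
separately.

**Lineage aggregation.** Species-level joints are summed into each
ancestor at the seven canonical ranks (root, phylum, class, order, family,
genus, species); species lacking a node at some rank aggregate to the root.
Because aggregation is a pure group-by sum, total mass is conserved at
every level and the set of unique GO ids is identical across levels — an
alternative would be to re-run the EM per level, but only aggregation
guarantees this cross-level consistency, so it is the implemented choice.

**Unannotated evidence.** Roughly half of reference protein records carry
no GO term, so a peptide-taxon pair with no annotated term maps to a
reserved `UNANNOTATED` sink term for that taxon. This keeps the biomass
constraint exact instead of silently renormalizing; consumers can drop the
sink rows when reporting annotated functions only.

## Assumptions

* E-values behave as expected false-positive counts, so the proportion of
  false discoveries among the $r$ best items can be estimated as $E_r/r$.
  The exact estimator used upstream of this package is described in prior
  work not restated here; $E_r/r$ is a documented stand-in with the same
  interpretation.
* Ion areas are comparable across peptides after mixing: no peptide
  detectability model, protein-length normalization, or missing-data
  imputation is applied. Fold-change comparisons simply exclude identifiers
  absent or zero in either table, since such outliers reflect missing data
  rather than estimation error.
* Identified taxa are decided *before* function assignment: a taxon counts
  as identified when its best protein E-value is at or below
  `taxon_evalue_cutoff`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `peptide_evalue_cutoff` | 1 | keep peptides with E-value $\le$ 1 (dimensionless expected-FP count) |
| `taxon_evalue_cutoff` | 0.01 | taxa identified at E-value $\le$ 0.01 |
| `protein_pfd` | 0.01 | protein list controlled at 1% PFD via $E_r/r$ |
| `protein_evalue_cutoff` | 1 | absolute protein E-value ceiling |
| `cluster_overlap` | 0.8 | peptide-set overlap coefficient linking two proteins |
| `em_tol` | 1e-10 | EM stop: max parameter change per iteration |
| `em_max_iter` | 2000 | EM iteration cap (non-convergence warns, result still returned) |
| `ev_threshold` | 2 | \|log2 fold-change error\| bound counted as acceptable (%EV) |
| `unipept_filter_fraction` | 0.005 | species below 0.5% of taxon-specific peptides dropped |

The clustering predicate ("a significant number of shared identified
peptides") is realized as the overlap coefficient
$|P_a \cap P_b| / \min(|P_a|,|P_b|) \ge 0.8$: the overlap coefficient is
robust to unequal protein lengths, and 0.8 demands near-containment of the
smaller peptide set. E-value ties (cluster heads, per-taxon unclustering)
break by lexicographic accession so outputs are deterministic.

## The synthetic generator

`community_spec()` defaults describe the benchmark world the pipeline is
tested in: 4 species at biomass ratios 1:2:2:4 (two genera of two species
under one order), 10 proteins per species with exactly 5 unique peptides
each (200 species-unique peptides), a genus-shared fraction of 0.2 of the
final peptide list (50 shared peptides), 1–3 GO terms per protein per
aspect from a 120-term pool, and lognormal ion-area noise with
$\sigma = 0.5$ — a typical label-free intensity dispersion. A shared
peptide's area is the sum of independent lognormal contributions of the
sharing species. E-values of simulated peptides are drawn at or below
1e-4 (every peptide is a true identification); spectral counts are
$1 + \mathrm{Poisson}(1)$.

The generator emulates the *identifier structure* of a community — which
peptide belongs to which proteins/taxa, and intensity roughly proportional
to biomass — not real spectra: peptide strings are random tryptic-like
tokens, there is no in-silico digestion of real proteomes, no missing data,
no chimeric or decoy identifications, and E-values carry no actual search
statistics. A green recovery test therefore establishes that the estimator
inverts the generative model it states, not that it survives every artifact
of real data.

The "zero-noise" world used by the exact-recovery tests sets both
$\sigma = 0$ *and* spectral counts to exactly 1 (`mean_extra_counts = 0`):
evidence weight is area × count, so random counts are themselves evidence
noise, and exact ratio recovery is only a theorem when both are switched
off. Recovery there is asserted to $10^{-12}$ rather than bitwise, because
ratio normalization and EM accumulation are different floating-point
expressions.

## Numerical choices and degenerate inputs

* EM initialization is deterministic (uniform weights); seeds affect only
  the synthetic generator. An `"area-weighted"` stage-1 initialization is
  available but not the default.
* Peptide rows are re-ordered canonically before accumulation, so shuffled
  inputs give bit-identical outputs.
* All-zero MS1 areas are a hard error suggesting `weights = "count"`
  (spectral-count-only evidence), which the CLI exposes via `--weights`.
* Peptides matching no retained protein of an identified taxon are dropped
  with a warning; a taxon with biomass but no compatible peptide for an
  aspect sends its whole mass to its `UNANNOTATED` term.
* The species filter for the LCA baseline retains a species sitting exactly
  on the 0.5% boundary (strictly-below is dropped). Its denominator is the
  species-level taxon-specific total — an interpretation, since the source
  convention could also be read as all assigned peptides.
* Printed percentages round half-up to one decimal by default;
  `format_percent(..., mode = "truncate")` is available because published
  tables are not always consistent about the rounding mode.

## Limitations

* No differential-expression layer, no missing-data handling, no
  peptide-detectability or protein-length normalization.
* Taxonomic synonym resolution (merged ids, name variants) is out of scope;
  inputs must use one consistent taxonomy.
* Stage 2 shares no information across GO aspects; whether the original
  workflow does is not documented and is deliberately not guessed.
* The protein-clustering predicate threshold (0.8) is a design choice where
  the upstream definition is unavailable; it is configurable, and the
  clustering tests exercise the predicate, not the specific value.
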