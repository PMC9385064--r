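---
title: "Methods: haploid SNP phylogenies and rho dating in ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid SNP phylogenies and rho dating in ylineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

## The setting

The non-recombining region of the Y chromosome (NRY) is transmitted
father to son as a single locus, so the derived alleles carried by a panel
of haploid sequences form, to good approximation, a perfect phylogeny:
each variant arose once, on one branch, and is carried by exactly the
samples below that branch. `ylineage` implements the analysis cycle built
on that property — filter the calls, orient them against an outgroup,
recover the tree, count mutations per branch, convert counts to time, and
classify each variant by the clade structure it supports.

## Filter cascade

Four stages run in a fixed order, each a plain function that can also be
composed by hand:

1. **Mask / indel removal.** Sites outside the callable mask, and indels,
   are removed. The mask is a merged, sorted interval set whose total
   length `L` (default 10.45 Mb) is also the denominator of the dating
   formula — filters and dating must agree on the territory where a
   mutation *could* have been observed.
2. **Depth.** Genotypes with per-sample read depth below 2 are set
   *missing*, not removed: depth is evidence about a single call, so it is
   a genotype-level operation. Site-level removal is then governed
   uniformly by the next stage. When a VCF carries no `DP` field the stage
   is a logged no-op.
3. **Missingness.** Sites whose missing fraction exceeds 0.1 are removed.
   The inequality is strict — a site at exactly 0.1 is kept — which
   matters at round sample counts (1 missing call in 10 samples passes).
4. **Monomorphic.** Sites invariant over their *non-missing* calls carry
   no signal and are removed. This stage runs last because the depth
   stage can create monomorphic sites (a site whose only derived carrier
   was a depth-1 call).

The cascade is idempotent, and the per-stage report satisfies
`sites_out = sites_in − Σ removed` by construction. Heterozygous
diploid-coded genotypes, impossible on a haploid chromosome, are treated
as missing and counted in the reader's QC attribute; multi-allelic records
are split and, where splitting would duplicate a position, only the
most-carried alternate is kept (the discarded alternatives are counted —
on Y panels these are almost always genotyping artefacts).

## Polarization

A designated outgroup sample defines the ancestral state at every site and
is then excluded from the ingroup. Sites where the outgroup is missing
cannot be oriented and are dropped (counted), as are sites with no derived
ingroup call after orientation. Polarity flips where the outgroup carries
the alternate allele; nothing downstream distinguishes REF/ALT any more,
only ancestral/derived.

## Tree construction and branch assignment

For mutually compatible sites (rooted three-gamete test: derived sets must
be nested or disjoint) the rooted perfect phylogeny is unique up to
polytomy ordering: its clades are exactly the distinct derived-carrier
sets. `build_tree()` retains a maximal laminar family greedily — largest
carrier sets first, ties broken lexicographically for determinism — and
sets conflicting sites aside. Samples with identical state vectors attach
to a common node; branches supported by no mutation simply never arise, so
unresolved structure appears as polytomies rather than arbitrary
bifurcations.

Every site (including the set-aside ones, and all sites when an external
topology is supplied) is then placed by minimum-mutation assignment with
the root state fixed ancestral and missing tips free (Sankoff dynamic
programme over the two states). Two conventions matter:

* **Root stem.** The tree always carries an ancestor node with a single
  child, the ingroup MRCA, so a site derived in every sample costs one
  event, on the MRCA stem — mirroring how an outgroup-rooted tree has a
  branch between root and ingroup ancestor. External topologies without
  such a stem get one added.
* **Tie-break.** When several minimum placements exist (typically because
  of missing tips), the traceback prefers the derived state, which pushes
  events root-ward deterministically. Branch totals are therefore
  invariant to tip-order permutations of the input.

Sites whose minimum score is two or more are flagged *recurrent*:
either genuine repeat mutation or genotyping error, and in either case a
violation of infinite sites worth inspecting rather than hiding.

## Dating

For a node with eligible descendant tips, `rho` is the mean number of
events on the tip-to-node paths, and

\[ T = \rho / (L \mu), \qquad
   T_{low} = \rho / (L \mu_{high}), \qquad
   T_{high} = \rho / (L \mu_{low}) \]

with defaults \(\mu = 0.76\times10^{-9}\) per site per year (95% CI
\(0.67\times10^{-9}\)–\(0.86\times10^{-9}\)) and \(L = 10.45\) Mb. Key
choices:

* **Eligibility.** By default only samples flagged high-coverage
  (complete sequences) enter rho: an incomplete sequence under-counts
  mutations and biases dates young — the same reason the analysis
  workflow feeds only complete sequences into dating. Nodes with fewer
  than two eligible descendants are reported *undated*, never silently
  dropped.
* **Interval.** The primary interval propagates only the rate
  uncertainty; it is exactly the rescaling
  \(T \mu/\mu_{high}\), \(T \mu/\mu_{low}\) of the point date, so
  published point estimates can be checked against their printed bounds
  (`rescale_by_rate_bounds()`). The Poisson sampling spread of rho,
  \(\sigma_\rho = \sqrt{\rho/n}\) under a star genealogy, is reported in a
  separate column and never mixed into the interval. A small number of
  published intervals are *not* reproduced by rate-only rescaling of the
  rounded point value (consistent with unrounded internals or an extra
  variance term upstream); reporting both quantities keeps such cases
  inspectable. Simulation shows the consequence of rate-only intervals:
  their coverage of the true age is well below the nominal 95% for young
  nodes (the acceptance run reports the observed fraction).
* **Rounding.** Displayed kya values round half away from zero — one
  decimal at ≥ 1 kya, two decimals below 1 kya — matching how such dates
  are conventionally printed; all computation keeps full precision.

## Clade variant partition

Relative to a sample set, every polarized site with a derived carrier is
classified: *defining* (all non-missing clade members derived, all
non-missing outsiders ancestral), *internal* (derived in a proper
non-empty subset of the clade only), *private* (internal with exactly one
carrier), *excluded* (a derived carrier outside the clade). A missing call
neither confirms nor denies carrier status; "defining" additionally
requires at least one non-missing call on each side of the clade boundary,
and sites failing that quorum are reported *unresolved* rather than
guessed. "Private" is defined relative to the loaded sample set — with
panel data there is no way to know a variant is absent from all unsampled
chromosomes. Sites assigned to the same branch form an equivalence class
(they cannot be ordered in time); for a true tree clade the defining set
equals the stem-branch SNP set, a cross-check the tests enforce. Novelty
against a catalog is keyed by position, and novel sites are named
`prefix + index` in genomic-position order from a configurable start —
position order because any other ordering would depend on unstated
history.

## Simulator

The generator inverts the dating model: a random coalescent-shaped
topology rescaled to a fixed root age (ultrametric, tips at age 0;
default 20 tips, root 20 kya — deep enough that internal branches carry
tens of mutations), Poisson mutation counts
\(\text{Pois}(\mu L t)\) per branch, positions uniform without replacement
over the mask (infinite sites). Options inject controlled violations:
`recurrent_fraction` makes a mutation reuse a position from an unrelated
branch (so the pair is genuinely recurrent, not nested), and
`missingness_rate` / `low_depth_rate` corrupt calls for the filter stages.
A user-supplied tree with branch lengths in years substitutes for the
random topology, covering arbitrary demographies. One seed drives
everything, with fixed per-stage substreams, so datasets are reproducible.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: reference-bias and alignment artefacts,
locus-specific error processes, heterogeneous per-sample coverage (all
corruption is i.i.d. across calls), ancient-DNA damage, and any
demographic realism in the topology beyond its clock. Conclusions about
estimator *bias* transfer (they depend only on the Poisson-count model);
conclusions about robustness to structured error do not.

## Validation sizes and numerical choices

The shipped checks use 20-tip trees with 200 replicates for dating bias
(mean relative error per dated node, compared against three Monte-Carlo
standard errors), 50 simulations for exact topology recovery after
collapsing unsupported branches, roughly 500 random site patterns on all
rooted binary shapes up to 4 tips plus sampled 5–6-tip trees against an
exhaustive-labeling parsimony oracle, and small hand-enumerated fixtures
for the filter cascade and clade partition. These sizes give Monte-Carlo
standard errors well under 1% for the bias check while keeping the whole
suite in a few minutes.

Degenerate inputs are defined rather than accidental: a tip has rho 0 and
dates to 0; a degenerate rate interval gives a zero-width CI; an empty
mask contains nothing; an empty novel set names nothing; and the filter
cascade with all stages disabled is the identity.

## Known limitations

* The tree builder is a perfect-phylogeny/parsimony constructor, suitable
  for haploid SNP matrices that are largely tree-compatible; it is not a
  likelihood tree search, and externally estimated topologies (e.g. ML
  trees) are accepted for the branch-assignment and dating stages instead.
* Recurrence is reported, but placement uncertainty of recurrent variants
  is not modelled.
* Dating inherits every upstream count distortion: filters that remove
  true variant sites shrink rho proportionally. The workflow therefore
  dates only complete sequences; no per-sample coverage correction is
  attempted.
* Depth filtering is per-genotype (`DP` of each call). A site-level mean
  depth rule would conflate good and bad samples at a site and is not
  offered.
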