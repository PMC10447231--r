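---
title: "clonetrace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonetrace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

clonetrace reconstructs the clonal history of a serially sampled cancer
from force-called variant read counts, and asks, with aggregated
statistical power, whether a defined lineage was already present — far
below single-site detection limits — in earlier samples. The pipeline is:
quality/germline filtering, per-sample presence calling under a
site-specific error model, Dirichlet-process clustering of mutations in
cancer-cell-fraction (CCF) space, pigeonhole clone-tree construction,
per-branch mutational-signature analysis, recombination-signal-sequence
(RSS) scanning near deletion breakpoints, and aggregated-site lineage
tracking. A fully specified simulator with machine-readable ground truth
makes every stage testable without controlled-access patient data.

# Filtering and the error model

Caller-level artifacts are removed with two annotations standard for
BWA-MEM/CaVEMan output: the median alignment score of supporting reads
(ASMD, threshold 140, boundary inclusive) and the clipping metric (CLPM,
threshold 0). Sites missing the annotations are retained with a warning by
default — force-called matrices often lack caller metrics — and can be
rejected by policy.

Germline variants are removed by a one-sided exact binomial test on counts
aggregated across the designated largely diploid samples (default: tumor
samples with ploidy in [1.8, 2.2]): under a heterozygous germline variant
the aggregate variant-read fraction is 1/2, so the lower tail
`P(X <= v)` under `Binomial(d, 1/2)` is small only for somatic variants.
Benjamini–Hochberg control is applied over sites with somatic called at
`q < 1e-5`. Note the logic: *failing* to reject leaves a site labelled
germline, so truncal somatic variants in very pure samples sit close to
the decision boundary; impure samples (which drag the aggregate fraction
below 1/2) are what make the test powerful in practice.

Presence of a variant in a sample is called against a site-specific
beta-binomial error model fitted on designated negative samples. The
paper-trail for the fit: profile likelihood over a log-spaced grid of the
overdispersion rho (0 plus 25 points in [1e-4, 0.5]), a one-dimensional
optimum of the error rate eps at each grid point, golden-section
refinement of rho, and collapse to the binomial (rho = 0) when the
likelihood gain is below 0.5 log-units — an extra free parameter's generic
improvement under the null stays below this, and the tolerance is
deliberately permissive because rho is a nuisance parameter here. The
error-rate floor is the pseudocount rate `0.5 / (total depth + 1)`.

# CCF clustering

Mutations are clustered in per-sample CCF space with a truncated
stick-breaking Dirichlet-process mixture. The expected VAF of a mutation
with cluster CCF pi in a sample with purity rho_s and local copy number
(n_major, n_minor), mutant multiplicity m, is

    xi = rho_s * pi * m / (rho_s * (n_major + n_minor) + (1 - rho_s) * 2)

Cluster CCFs live on a grid over [0, 1.2] (step 0.01); the slack above 1
absorbs noise, and an emission floor of 1e-4 on xi absorbs background
error for CCF-0 clusters. Emissions are beta-binomial with configurable
overdispersion (default 0.01, a typical site-level value at ~100x; 0 gives
the textbook binomial). The sampler precomputes, per site, sample and grid
point, the emission log-likelihood, so assignment updates are table
lookups; cluster CCFs move by Metropolis steps on the grid, and empty
components are refreshed half from the prior and half seeded at a random
site's maximum-likelihood position so that genuinely multi-sample splits
can nucleate. The DP concentration carries a Gamma(1, 1) prior resampled
by the Escobar–West auxiliary scheme. All randomness flows through R's
RNG: one seed, bit-identical output.

Label switching is resolved through the posterior co-clustering matrix:
average-linkage hierarchical clustering of 1 minus the pairwise
co-assignment frequency, cut at the number of groups maximizing the
posterior expected adjusted Rand index (maxpear). The cut is then
consolidated by a soft-EM polish over the same likelihood tables, with
three merge rules applied to convergence:

1. clusters holding under 1% of mutations are dissolved;
2. clusters indistinguishable once CCF is clamped to [0, 1] (superclonal
   slack is noise, not evidence of separation) merge when within 0.05
   everywhere;
3. nearby pairs merge unless a soft mixture likelihood-ratio supports the
   split at `15 + 5*(S + 1)` log-units for S samples. Fragments of a
   single clone cost almost nothing to merge under the *mixture*
   likelihood (unlike the classification likelihood, which is biased
   toward splitting), while clones separated by 0.1 CCF or more at 100x
   cost hundreds of units; the threshold sits between those regimes with
   a wide margin on both sides.

Sites on sex chromosomes are excluded from sampling (emission model
unspecified there) and re-assigned post hoc by maximum likelihood, as are
all sites when the co-clustering skeleton is built on a subsample for very
large studies.

An honest caveat: clones separated by ~0.1 CCF in a *single* sample at
100x are near the Bayes limit — no algorithm assigns their mutations at
high accuracy — so recovery guarantees presume separation expressed in
more than one sample, which is what the benchmark worlds provide.

# Pigeonhole phylogeny

Clusters become clone-tree nodes under the pigeonhole principle: a child's
CCF may not exceed its parent's in any sample, and the children of a node
may not sum above it (tolerance 0.05 CCF, matching typical 100x noise).
`build_tree` enumerates feasible parent assignments depth-first, ranks
feasible trees by total negative slack, then tree depth (shallower
preferred), then lexicographic order — a deterministic choice. Crossing
clusters (each exceeding the other in different samples) are forced onto
distinct branches, which is exactly how a bifurcating precursor is
recognized from two relapses. Clusters never rising above twice the
tolerance are pruned as unplaceable noise before the search. Exclusive
clone sizes (node CCF minus the sum of its children, floored at 0) feed
the fishplot-style timecourse table; newick export uses branch SNV counts
as branch lengths.

# Mutational signatures

Assigned SNVs are converted to counts over the 96 pyrimidine-centred
trinucleotide-change channels (COSMIC order: six substitution classes,
then upstream and downstream base lexicographically). Branch spectra below
100 SNVs are computed and refit but excluded from de-novo extraction, and
flagged for display. Extraction is non-negative factorization of the
branch-by-96 count matrix under the Kullback–Leibler (multinomial)
objective with multiplicative updates and 20 restarts. The first restart
is deterministic: anchor rows found by successive projection initialize
the signatures, and exposures are warm-started by a convex per-branch
refit. Random restarts replace it only when they beat its objective by
0.1% — among likelihood ties (KL-NMF solutions form a ridge), this pins
the factorization to the data's extreme rays instead of an arbitrary point
of the solution set. Refitting against a fixed catalog is EM for
maximum-likelihood multinomial mixture weights; catalog matching is cosine
similarity with an ambiguity flag when the top two entries are within
0.02.

The simulator ships three synthetic stand-in generators — *not* COSMIC
copies — resembling SBS1 (C>T at CpG), SBS5 (broad, mildly featured) and
SBS87 (T>G/T>A enriched; thiopurine-like). The signature-recovery
benchmark uses six branches of 2,000 SNVs with one near-pure branch per
signature plus three mixtures: without such anchor structure the KL-NMF
factorization of overlapping signatures is not identifiable (the
likelihood is maximized on a set, not a point), and no optimizer could
guarantee recovery; with anchors the recovery criterion tests the
implementation rather than the geometry.

# RSS scanning

RSS motifs (heptamer + 12- or 23-bp spacer + nonamer; spacer columns
uniform) are scored as position weight matrices against a zero-order
background: score = sum of log2(p/b) over positions. The default PWM
derives from the canonical consensus heptamer CACAGTG and nonamer
ACAAAAACC with pseudocount 0.25, since no trained alignment is shipped;
results are therefore motif-file-dependent and the MEME-format reader
accepts alternatives. P-values are `P(S >= s)` for a random background
sequence: computed by exact dynamic programming (convolution with merging
of numerically equal score sums) when `4^L <= 2^20`, else by a binned DP
with bin width 0.01 bits and a conservative evaluation at
`s - L*bin/2` (documented error bound). Scans report the best placement
per breakpoint side, motif and strand within a +/-50 bp window; evidence
is raw `p < 0.05` with no cross-breakpoint correction (a Bonferroni
option exists but is off, matching how such evidence is conventionally
used). The background defaults to the scanned windows' own base
frequencies. Note that a best-of-~100-placements raw p-value is not
calibrated as a single test — the null simulation in the test suite
quantifies exactly that.

# Lineage tracking

A lineage is a branch's SNV set restricted to sites diploid (1/1) in all
queried samples — excluding, for a myeloid lineage carrying a 17p loss,
the sites sitting in the lost region. The background error rate is
estimated by interrogating the same sites in unmatched panel samples:
per-sample aggregate rate `sum(V)/sum(D)`, with the model epsilon the
*mean* of per-sample rates (the pooled rate is retained for diagnostics).
Detection in a sample is the exact one-sided binomial tail
`P(X >= V)` under `Binomial(D, eps)` on aggregated counts, computed in log
space. The VAF MLE is `V/D` with an exact Clopper–Pearson 95% interval;
clone size is `min(1, 2*VAF)` under the diploid heterozygous assumption,
with the interval transformed identically. Epsilon is treated as known
(panel uncertainty is not propagated), matching a plain binomial test; an
overdispersed beta-binomial null is available through the error-model
machinery but off by default. Any single site contributing more than 5%
of a sample's aggregate variant reads is reported as an outlier to guard
against artifact-driven hits.

# The simulator and what a green test establishes

`simulate_study` draws, from one seed: branch mutation contexts from the
configured signature mixtures (written into a generated reference so
trinucleotide lookup agrees with truth); depths `d ~ Poisson(100)`;
carrier reads `v ~ BetaBinomial(d, xi, rho)` with rho = 0.01 (a mild,
realistic site-level overdispersion at WGS depth — chosen once, not
revisited); non-carrier background reads `v ~ Binomial(d, 1.6e-4)`; an
unmatched 32-sample panel at the background rate; copy-number segments
including a 17p-style loss; and deletion breakpoints with planted
consensus RSS motifs. The shipped template mirrors the case study's
stated world: eight samples over six timepoints at ~100x; diagnostic
subclones of 0.20 and 0.75 (0.88 in the second diagnostic sample); an
early myeloid/lymphoid bifurcation below a thiopurine-mutagenized
progression branch (so thiopurine-like mutations appear both shared and
private); a myeloid root branch of 2,468 SNVs, 150 in the lost region,
leaving 2,318 diploid sites; that lineage spiked at cell fraction 0.0026
(VAF 0.0013) into the second-relapse sample; and a low-purity (0.23)
marrow sample encoding the ~23% expanded clone.

What the simulator does not emulate: mapping artifacts and strand bias,
site-correlated panel errors, subclonal copy number, indel-specific error
processes, clustered mutations (kataegis), or contamination between
samples. Green tests therefore establish the statistical machinery and
its calibration under the stated world — not robustness to every failure
mode of real sequencing data.

# Numerical choices and degenerate inputs

* Binomial tails: `pbinom` in log space; beta-binomial tails by direct
  log-space summation (chunked with early termination beyond 2e5 terms).
* Zero aggregate depth is an error in detection and drops a panel sample
  with a warning in background estimation; a zero panel rate flags the
  test as degenerate (p = 0 when V > 0, with a warning).
* Ties in cluster assignment break to the lowest cluster id; feasible-tree
  ties break to shallower, then lexicographic — all outputs are
  deterministic functions of (inputs, config, seed).
* The germline test at d = 0 returns p = 1 with a warning.
* Contexts containing N are excluded from channel mapping with a warning.

# Known limitations

* The clustering assumes mutant multiplicity 1 on the major allele;
  heavily amplified regions deserve the multiplicity estimate that the
  preprocessing exposes but the default pipeline does not refine.
* Subclonal copy number is not modelled; affected sites should be
  excluded upstream.
* The RSS PWM is a consensus stand-in; attribution strength depends on
  the motif file supplied.
* Exposure recovery guarantees hold for anchor-structured worlds (see
  above); real branch spectra may be less identifiable, and cosine
  matches should be read with the ambiguity flag.
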