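---
title: "Estimating effective population size and gene turnover from prokaryote genome collections: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nepan` implements a comparative-genomics pipeline for collections of
resequenced prokaryote strains: per-species effective population size (Ne)
proxies from dN/dS and from Watterson's theta, pan- and core-genome
definitions from best-reciprocal-hit protein families, a parsimony homoplasy
ratio as a recombination proxy, per-branch gene gain/loss inference with
turnover T = G/L, and phylogenetically corrected cross-species statistics.
Because assembling hundreds of genomes is outside desk scale, the package
ships a coalescent-based synthetic-data generator with complete ground
truth; every stage is validated against that generator or against exhaustive
enumeration oracles.

# The divergence machinery

## NG86 counting

Pairwise dN/dS uses Nei–Gojobori-style counting. Each codon position
contributes one site, split between synonymous and nonsynonymous in
proportion to its single-nucleotide neighbors, with mutations to stop codons
removed from the denominator (so a position whose only non-stop neighbor is
synonymous is a full synonymous site). Differences between codons are
averaged over all orderings of the changed positions, dropping orderings
that pass through stops; if every ordering is blocked the codon pair is
skipped. Proportions are converted to distances with the Jukes–Cantor
correction d = -(3/4) log(1 - 4p/3); p >= 3/4 raises a saturation flag and
the pair is excluded downstream.

The reference analyses used the yn00 (Yang–Nielsen) estimator. We deliberately
substitute NG86 + JC because it is fully specified and verifiable against a
brute-force pathway enumeration (the acceptance suite checks all 61 x 61
sense-codon pairs exactly). The cost of this substitution is a known bias:
with transition/transversion ratio kappa > 1, NG86 underestimates dN/dS even
for neutral data. All rank-based and ordering results are unaffected (the
bias is shared across species simulated at the same kappa); neutrality
checks in the test suite therefore run at kappa = 1, where NG86 is unbiased.

## The dS window

dN/dS decays with divergence time, so species are only comparable within a
common divergence band. The species statistic is the unweighted arithmetic
mean of pairwise dN/dS over strain pairs with 0.1 <= dS <= 0.3, bounds
inclusive; a species with no pair in the window is excluded with a flag (the
source analyses grey such species out rather than guessing). Results are
reported as dS/dN, which scales positively with Ne.

## Watterson's theta and absolute Ne

Theta is estimated on four-fold degenerate sites of the core-genome
concatenate: a column qualifies only if the codon context of *every*
sequence is four-fold degenerate and ungapped, which guarantees strict
neutrality of the site set. Then theta = S/(a_n L) with a_n the harmonic
number, and Ne = theta/(2 mu) for species with a known mutation rate.
Columns containing gaps or ambiguity are excluded from both S and L (the
alternative - counting them in L - would bias theta downward).

## The nearly-neutral inversion

Absolute Ne for all species comes from inverting f(x) = x/(1 - e^(-x)) with
x = Ne s, the classic fixation-probability ratio for uniformly deleterious
nonsynonymous mutations. The printed form of this equation in the source
material is typographically corrupted; we adopt the reading above, which is
the standard nearly-neutral form (a factor-2 variant would rescale s and Ne
jointly without changing any ordering or the round-trip logic). The
calibration species (those with theta-based Ne) each yield an s by solving
f(Ne s) = dN/dS; the mean s is then used to invert every species' dN/dS
into Ne. Numerically, f uses a series expansion below |x| = 1e-5 and an
`expm1` formulation elsewhere (the naive `1 - exp(-x)` loses six digits near
the neutral limit); inversion brackets log10(-x) in [-20, 4] and polishes
with Newton steps to ~1e-10 relative error. Note the direction of the map:
smaller dN/dS means stronger purifying selection and therefore a *larger*
Ne at fixed s; this is what is implemented and tested.

# Families and pan-genomes

Orthologs of the 44 universal proteins are accepted per gene by comparing
each best hit's log10 e-value to the median of best hits versus the mean of
confirmed paralogs (rank >= 2 hits); exact ties resolve conservatively to
paralog. Strains with < 42 accepted orthologs are dropped (40 for
Mycoplasma-like reduced genomes); near-duplicate strains (distance
< 5e-5) are removed one per closest pair at random; species are capped at
400 strains and dropped below 15.

Families are connected components of accepted best-reciprocal-hit pairs
(identity >= 70%, alignment coverage >= 80% of *both* proteins - the
stricter of the two possible readings of "length conservation"). N_pan
counts all families including singletons and is normalized as
P = N_pan / alpha, alpha = sum_{i=1}^{n-1} 1/i, the expected Heaps-type
scaling of family discovery with sample size. Core families require
presence in >= 85% of strains and no paralogs.

# Homoplasy (h/m)

For every polymorphic column of a concatenate, each non-majority state is
one counted allele. The allele is homoplasic when the binary character
"carries this state" needs more than one change on the strain tree - i.e.
parsimony forces a repeated origin or a reversal, which clonal descent with
unique mutations cannot produce. h/m over all columns is the recombination
proxy. An earlier design that counted "origins with free losses" was
rejected: free losses let any pattern collapse to a single root origin,
making h identically zero. Multiallelic columns are handled per state;
gaps are treated as missing and pruned per site. The metric deliberately
conflates recurrent mutation with recombination, as does its source; the
test suite separates the two regimes by driving theta low enough that
recurrent mutation is negligible.

# Gene flux

## The gain/loss model

Family presence evolves on the strain tree under a two-state Markov chain
(gain: absent -> present; loss: present -> absent), fitted by pruning over
all families with a correction for unobservable all-absent families, 100
random restarts by default (seed-controlled; ties break to the lower gain
rate). This is a documented stand-in for the birth-death machinery of the
Count program: it supports the same per-branch event calls without
family-size dynamics.

The root presence prior is a free third parameter. This matters: with the
prior tied to the stationary distribution, a dataset whose families are
mostly ancestral forces the gain rate upward purely to raise the stationary
presence probability, which then fabricates gain calls on loss-only data.
With sparse data the prior itself can become unidentifiable (the
conditioned likelihood is flat in it); posteriors and event calls remain
well-behaved because they depend on ratios in which the degenerate factor
cancels.

## Event calls and turnover

At threshold tau = 0.2 (0.3 also produced), a gain is called on a branch
when the parent's presence posterior is <= tau and the child's is >= 1-tau;
losses symmetrically. This "symmetric certainty" reading is one of several
possible interpretations of a bare posterior threshold; it is the one that
makes precision interpretable. Branch rates are counts divided by branch
length, and T = G/L, in which the length normalization cancels. A known
limitation: on a rooted tree without an outgroup, an event on one of the two
root-adjacent branches cannot be placed (a gain on one side and a loss on
the other explain the same data), and coalescent-shaped trees concentrate
much of their length there; recovery tests therefore use trees with uniform
branch lengths and the event-call criterion is evaluated away from that
degeneracy.

## Per-branch dS/dN

The reference used CodeML free-ratios on 150,000-bp fragments; this package
substitutes marginal ancestral reconstruction under a Jukes-Cantor model
followed by NG86 counting of parent-child changes per branch, averaged
without weights across fragments. This is the largest acknowledged
deviation in the package and is validated by simulation recovery (two-leaf
additivity against the pairwise estimator, homogeneity under a uniform
omega), not by agreement with CodeML.

# Comparative statistics

Phylogenetically independent contrasts follow Felsenstein's algorithm;
missing-trait species are pruned, multifurcations are resolved with
zero-length edges, and non-positive branch lengths are floored at the 1st
percentile of positive lengths (contrasts divide by branch length sums).
"Spearman with PIC correction" is not uniquely defined; we rank-correlate
the contrast pairs (matching the source's reporting) and also expose the
orthodox Pearson-through-the-origin statistic. Ne dissimilarity |Ne_i -
Ne_j| versus patristic distance reports both the plain Spearman p and a
Mantel permutation p (pairs are not independent). Lifestyle contrasts use
two-sided Wilcoxon rank-sum tests with the conventional star coding on raw
p-values, plus a Holm-adjusted column; plant pathogens are excluded as in
the source figures. The PCA z-scores quantitative traits on complete rows;
the correlation network keeps Spearman edges at p <= 0.01 with weight
-log10 p.

# The synthetic world

The generator's defaults describe one fixed, moderately diverse bacterial
species and are not tuned per test:

* **theta_per_site = 0.02** - typical core-genome diversity for a
  well-sampled species; end-to-end dS-window tests use theta = 0.2 so that
  typical pair divergence sits mid-window (the window itself is the fixed
  0.1-0.3 band).
* **omega = 0.15, kappa = 2** - strong purifying selection on universal
  genes with a realistic transition bias.
* **root_gene_count = 1500, gain_rate = 4e4, loss_rate = 1** (per unit
  branch length, i.e. per expected neutral substitution per site) - a
  gain-dominated accessory genome: at these rates strains separated by 1%
  core divergence differ by a few hundred families, as observed in
  enterobacteria, and the pan-genome grows harmonically, which is the
  regime the alpha normalization is built for.
* **paralog_fraction = 0.05**, with ortholog and paralog log10 e-value
  distributions centered at -80 and -20 (sd 5): cleanly separated, as real
  universal-protein HMM hits are.

The coalescent genealogies are neutral and panmictic - no demography,
structure, or selection on sites; recombination is modeled only as
within-species tract copying; gains create novel families
(infinitely-many-genes), so re-gain of a lost family never occurs. A green
end-to-end test therefore establishes that the pipeline recovers the
planted signal under these idealizations, not that real data meet them.

The per-family gain/loss recovery test simulates from the two-state model
itself (`simulate_two_state_content`): the IMG generator's gain rate is a
per-lineage family-creation intensity, a different unit from the two-state
per-family gain rate, so numeric "recovery" of it by the two-state ML is a
category error; the IMG generator instead grounds the event-call
precision/recall and turnover tests, where its event log is the truth.

# Numerical and procedural choices

* Zero e-values floor at 1e-300 before log10.
* Dedup processes closest pairs first (ties by lexical id) and removes a
  uniformly random member; the distance matrix is static across removals.
* All randomness funnels through a single seed with documented substream
  derivation; generators restore the caller's RNG state.
* Root-finding tolerances: 1e-12 on the bracket, Newton-polished; the
  calibration mean is an unweighted arithmetic mean of per-species s.
* Tabular output is UTF-8 TSV with "NA" sentinels, written at 17
  significant digits so write/read round trips are lossless.

# Known limitations

* NG86/JC underestimates dN/dS at kappa > 1 (shared bias; ranks are safe).
* The two-state flux model ignores copy number and re-gain.
* h/m cannot separate recombination from recurrent mutation at high theta.
* Root-adjacent event placement is unidentifiable without an outgroup.
* The pipeline consumes trees as inputs; the neighbor-joining fallback is
  plumbing, not a recommended inference method.
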