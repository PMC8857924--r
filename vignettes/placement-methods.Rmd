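---
title: "Placing low-coverage ancient samples on a fixed phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing low-coverage ancient samples on a fixed phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloplace)
```

## The problem

Non-recombining loci — the Y chromosome, mitochondrial DNA — evolve as a
single genealogy, so a sample's position in that genealogy (its
haplogroup) can be read off from a modest number of diagnostic SNPs.
Ancient DNA complicates this in two ways: coverage is very low (often well
below 1x, so most sites have zero or one read), and post-mortem cytosine
deamination creates apparent C→T (and, read from the other strand, G→A)
substitutions that mimic real transitions.  `phyloplace` places such
samples onto a fixed, high-quality reference phylogeny instead of
re-estimating the tree, which both scales linearly in sites and samples
and remains feasible at extreme missingness.

The workflow has four stages, each an exported module:

1. **Branch assignment** (`assign_all`): every biallelic SNP of the
   reference panel is mapped to the single branch it most likely arose on.
2. **Pileup and filtering** (`pileup_at_sites`, `filter_calls`,
   `calls_from_vcf`): the query's bases at those sites become
   ancestral/derived/missing calls with damage-aware rules.
3. **Placement** (`best_path`, `likelihood_place`): the calls place the
   query on a branch, with either a support/conflict traversal or a
   per-edge posterior.
4. **Haplogroup refinement** (`load_markers`, `label_branches`,
   `refine_below`): the placement is reconciled with a curated,
   ISOGG-style marker nomenclature.

A simulator (`sim_config`, `sim_reference`, `sim_query`, `sim_markers`)
generates the whole input set with recorded truth, and every quantitative
claim below is one the test suite recomputes.

## Branch assignment model

Under the infinite-sites assumption each biallelic SNP arose once, on one
branch, and its derived-allele carriers are exactly the clade below that
branch.  Real panels deviate by genotype error and recurrent mutation, so
we score a site on branch $b$ with derived allele $d$ by a symmetric
genotype-error model: each leaf inside the clade is expected derived, each
leaf outside ancestral, and an observed genotype matches its expectation
with probability $1-\varepsilon$:

$$\log L(b, d) = m \log(1-\varepsilon) + k \log \varepsilon,$$

where $m$ and $k$ count matching and mismatching non-missing genotypes
(missing genotypes contribute nothing).  The maximising $(b, d)$ over all
branches and both polarities is the assignment.  Because
$\varepsilon < 0.5$, the argmax is exactly the minimum-mismatch
hypothesis, which is why the test suite can check it against a brute-force
enumeration.

Three exclusion rules mirror practice: records that are not biallelic
SNVs are set aside as multiallelic; sites whose non-missing genotypes are
all identical are monomorphic; and sites whose best branch still implies
more than 3 mismatching genotypes (margin expressed in nats as
$3.5\,[\log(1-\varepsilon) - \log\varepsilon]$, so the count threshold is
$\varepsilon$-stable) are excluded as low-likelihood — the signature of
repeated mutation or repeated error.  Polarity is inferred per site unless
the VCF carries an `AA=` ancestral-allele INFO tag, which then fixes it.
The tag matters more than it may appear: for a SNP on a root-adjacent
branch, "derived inside the clade" and "derived outside it with swapped
polarity" fit any genotype configuration equally well, so without an
outgroup-anchored ancestral state those sites are inherently ambiguous.
Branch lengths are never used in assignment; the mapping is topological.

Defaults: $\varepsilon = 0.001$ for reference genotypes.

## Damage-aware filtering

Base calls are collected per informative site from an indexed BAM,
requiring base quality ≥ 20 and mapping quality ≥ 25 (both adjustable).
Filtering then proceeds in three fixed steps:

1. bases matching neither REF nor ALT are dropped;
2. mode-specific damage handling:
   * `no-filter` keeps everything;
   * `default` drops a **singleton** T at a C/T site and a singleton A at
     a G/A site — exactly one such call after step 1, regardless of total
     depth; two damage-consistent reads are kept, because coincident
     double damage is much less likely than a real allele;
   * `transversions` discards every C/T and G/A site outright;
3. the most frequent remaining base is called if it reaches at least the
   consensus fraction (default 70%, inclusive at the boundary; a 50/50
   tie can never pass a threshold above one half), else the site is
   missing.

The singleton rule is applied after mismatch removal, and only to the
damage-gain base: a C at a C/T site is never singleton-filtered.
Pre-called genotypes from a query VCF can substitute for the pileup;
records whose alleles match the site table with REF/ALT swapped are
normalised by allele matching, and anything else is dropped with a counted
warning.

## Placement

Calls at assigned SNPs are binned per branch: a derived call at a SNP on
branch $b$ **supports** $b$, an ancestral call **conflicts** with it.

**Best path.**  Every root-to-tip path is walked; a path is stopped at
the first branch carrying more than `max_conflict` (default 3)
conflicting markers, with the part above the stop kept as a candidate.
Candidates are ranked by cumulative support, and the winner's branch is
the deepest one past which no further support accrues.  Ties are broken
by fewer cumulative conflicts, then the shallower branch, then the
smaller branch id, and flagged whenever the conflict criterion does not
resolve them.  The annotation string
`[support_above-conflict_above; support_on-conflict_on]` is appended to
the query's leaf label when it is inserted into the output newick.  The
insertion point along the branch is `support_on / (support_on +
conflict_on)` from the parent end (0.5 when both are zero): on-branch
derived markers sit above the divergence point, on-branch ancestral ones
below it.

**Likelihood.**  For each candidate edge $e$ the query is expected
derived at SNPs on strict ancestors of $e$ and ancestral elsewhere, with
per-call error $\varepsilon$ (default 0.01 — query calls after filtering
are noisier than panel genotypes); SNPs on $e$ itself are ignored, a
conservative choice that avoids claiming information about position along
the attachment branch.  With a uniform prior over edges, posteriors
follow by log-sum-exp normalisation.  Reported are all edges with
posterior above 0.01, the maximum-posterior edge, and the **99% placement
clade**: the lowest branch whose clade-inclusive posterior sum exceeds
0.99.  When no branch below the root qualifies — for instance under
symmetric homoplasy across the root — the clade is reported as NA,
i.e. root-level ambiguity, rather than forced to a branch.

A consequence of ignoring the attachment edge's own SNPs is worth
stating: a query that carries *none* of the attachment branch's derived
alleles is statistically indistinguishable from one attached to the
parent or a sibling (only the excluded own-branch counts differ).  Real
data resolve this because a query diverging partway along a branch shares
the branch's parent-side mutations; the simulator reproduces that via
`attachment_fraction` (default 0.5), and the recovery results below
depend on it.

## Haplogroup refinement

A branch is labelled with a haplogroup when a curated marker's position
and derived allele coincide with a SNP assigned to that branch.  After
placement, markers for labels nested below the anchor label (long-form
name nesting: `A1b1b2a` is below `A1b1b2`) are tested directly against
the query's calls; the longest label with at least one derived-observed
marker wins.  Two safeguards: incomparable supported labels (sibling
sublineages, a typical damage artefact) trigger a conservative fallback
to their deepest common supported ancestor with both siblings reported as
alternates; markers flagged provisional (`~`/parenthesised names) can
support a label only if no unflagged marker for the same label is
observed ancestral.

## What the simulator does and does not emulate

`sim_reference` draws a random rooted tree (random splits, uniform branch
lengths), places each site on one branch — proportionally to branch
length, with an optional per-branch floor — at unique positions, and sets
carrier genotypes by clade membership; site polarity is randomly swapped
and recorded.  `sim_query` draws Poisson reads per site, applies uniform
base error, then damage flips (C→T at C/T-allele sites, G→A at G/A
sites) with probability $\delta$ per read.  The defaults used by the
recovery tests are the study conditions: coverage 3 (clean and damaged
arms), base error 0.005 and $\delta = 0.2$ for the damaged arm, coverage
1 and $\delta = 0.2$ for the filter-benefit comparison, trees of 16–64
tips with 10 sites per branch on average and a floor of 8 — the floor
implements the requirement that every branch on the query's path carries
enough informative covered SNPs to be identifiable at 3x coverage.

Not emulated: fragment-length and within-read damage gradients (damage is
uniform per read), reference bias, duplicate reads, contamination, and
recurrent mutation.  Passing recovery tests on these simulations
therefore shows the estimators are correct under the stated model, not
that real aDNA libraries will reach the same rates.

## Numerical and degenerate-input choices

* Log-space throughout; posteriors normalised by log-sum-exp, so the
  normalisation error is at machine precision.
* Empty tally: best-path reports unplaced (`[0-0; 0-0]`, tie flagged);
  the likelihood posterior is uniform with an NA placement clade.
* Multifurcations are accepted as-is; both placement methods operate on
  branches and never require bifurcation.
* Missing branch lengths are treated as unit lengths for insertion
  arithmetic only; no score ever uses lengths.
* Output newick quotes leaf labels containing reserved characters, so
  annotation suffixes survive; `ape::write.tree` would mangle them, which
  is why serialisation is done by the package.
* Heterozygous diploid reference calls are set to missing with a counted
  warning (haploid-locus context).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_leaves = 12, n_sites = 220, min_sites_per_branch = 8,
                  coverage = 4, seed = 22)
res <- cmd_all(tempfile(), cfg)
res$best_path
res$posterior
res$haplogroup
```

## Known limitations

* The per-edge likelihood uses hard calls, not per-read base counts; at
  coverage near 1 this discards some information a genotype-likelihood
  model would keep.
* The low-likelihood exclusion margin is a fixed mismatch-count rule; a
  panel with strongly heterogeneous error rates would warrant a
  site-specific threshold.
* Label hierarchy relies on long-form nomenclature nesting; SNP-based
  short names (`E-M293`) need a synonym table, for which only a hook
  exists.
* One query is placed at a time; co-placement of related queries is out
  of scope.
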