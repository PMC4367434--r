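---
title: "Estimating Ne trajectories from SNP linkage disequilibrium"
author: "NeTrend authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Ne trajectories from SNP linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeTrend)
```

## The model

In a closed, panmictic, neutrally evolving population, the linkage
disequilibrium (LD) between two loci reflects a balance between genetic
drift, which builds allelic associations, and recombination, which breaks
them down.  Under Sved's drift-recombination argument the expected squared
correlation of allelic states at two loci separated by recombination
fraction $c$ is

$$E(r^2) = \frac{1}{1 + 4 N_e c},$$

where $N_e$ is the effective population size.  Because an association over
recombination fraction $c$ has a characteristic decay time, the LD observed
at a given $c$ is informative about the effective size roughly
$t = 1/(2c)$ generations ago: long-range LD (large $c$) reflects the recent
past, short-range LD the distant past.  Scanning $c$ therefore turns a
single genome-wide SNP panel into a *trajectory* of $N_e$ against
generations ago.

Solving for $N_e$ and adding the corrections in common use gives the
estimator implemented here:

$$\hat N_e(t) = \frac{1}{4\,f(c_t)}\left(\frac{1}{E[r^2_{\mathrm{adj}} \mid c_t]} - \alpha\right),
\qquad t = \frac{1}{2 f(c_t)},$$

with three correction layers:

* **Sample size and phase.** An $r^2$ estimated from $n$ individuals is
  inflated by sampling; we subtract $1/(\beta n)$ from each pair's $r^2$
  (`adjustR2()`), with $\beta = 2$ when the gametic phase is known and
  $\beta = 1$ when it is not.  Each pair carries its own $n$ (individuals
  with complete data at both loci), so the correction stays exact under
  missing data.
* **Mutation.** $\alpha \in \{1, 2, 2.2\}$ replaces the 1 in Sved's
  denominator to account for recurrent mutation; $\alpha = 1$ (no mutation
  correction) is the default, which is also the regime our validation
  simulator generates (it has no mutation).
* **Recombination-rate mapping.** Physical distance $\delta$ (bp) is first
  converted to map distance $d = k\delta$ Morgans with $k = 10^{-8}$ M/bp by
  default (the familiar 1 Mb = 1 cM rule of thumb), then to recombination
  fraction $c = f(d)$ by a mapping function: `linear` ($c = d$, clamped
  below 0.5), `haldane` ($c = (1-e^{-2d})/2$) or `kosambi`
  ($c = \tanh(2d)/2$).  Further mapping functions (e.g. the drift-based
  Sved or Sved-Feldman forms) can be added with `registerMapFunction()`;
  a registered function must be monotone with values in $[0, 0.5)$.  All
  mappings are clamped just below 0.5, since at extreme distances the
  closed forms round to exactly 0.5 in double precision.

## LD estimators

Two $r^2$ estimators are provided, chosen by the phase of the input:

* `r2Haplotype()` — from phased data, the classical haplotype-frequency
  form $r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A)\,p_B(1-p_B))$.
* `r2Genotype()` — from unphased data, the squared Pearson correlation of
  the two allele-dosage vectors (identical to PLINK's `--r2`).  It avoids
  haplotype inference entirely and is not influenced by double
  heterozygotes.

The two are not the same quantity but converge for moderate samples; the
test suite checks that genotype-based $r^2$ of individuals formed by random
pairing of haplotypes approaches the haplotype $r^2$ of the source pool.

Missing data are handled by pairwise-complete deletion.  Pairs with fewer
than 3 complete observations, or with a locus monomorphic among the
complete observations, are skipped and counted: a correlation is degenerate
below that.  Only within-chromosome pairs are formed — the inversion needs a
physical distance on one chromosome — and a distance window
(default 50 kb – 4 Mb) bounds the range of $t$ covered.

## Distance binning

Averaging $r^2$ at a fixed distance needs bins.  `makeBins(minD, maxD,
totBins, x)` places bin edges by a power law,
$e_i = minD + (maxD - minD)(i/totBins)^x$: with $x = 1$ bins have equal
width; with $x > 1$ distant bins are wider, which compensates for the
scarcity of very distant pairs and evens out per-bin pair counts.  Bins are
half-open $[lo, hi)$ with the last bin closed at $maxD$; a pair exactly on
an interior edge belongs to the upper bin.  Defaults — 30 bins, $x = 1.5$,
window 50 kb – 4 Mb — give dense coverage of the recent generations
(roughly $t$ from 12 to 1000 at the default $k$) while keeping every bin
populated on typical SNP-chip densities; they are ordinary tuning knobs,
all exposed on `neTrajectory()` and the command line.

Each pair is adjusted with its own $n$ *before* averaging, then the bin's
mean distance is mapped once to $c_t$ (adjust-then-average; a single
mapping per bin).  Averaging the mapped values per pair instead changes
little at these window sizes, and one mapping per bin keeps $t$ a function
of the reported mean distance.  The bin's standard deviation of adjusted
$r^2$ ($n-1$ denominator, 0 for a single pair) is reported so users can
judge the stability of old-generation bins, where pair counts shrink.

A bin whose mean adjusted $r^2$ is non-positive, or whose $\hat N_e$ comes
out non-positive, carries no usable signal at the sample size at hand
(the sampling correction exceeded the LD).  Such bins are excluded from the
main table but written to a diagnostics sidecar
(`<out>.excluded.tsv`) rather than silently dropped.

## The MAF filter

Markers with minor allele frequency below a threshold (default 0.05) are
removed before pairing; rare alleles make $r^2$ estimates biased and
unstable.  The convention is: retain MAF $\ge$ threshold (a marker exactly
at the threshold is kept), and always remove monomorphic markers, for which
$r^2$ is undefined.  The per-locus reference allele is the minor allele
(ties at 0.5 broken lexicographically); $r^2$ is invariant to that choice,
so only reporting is affected.

## What the synthetic-data generator emulates

`simulateWrightFisher()` is a forward-in-time neutral Wright-Fisher
simulator: $2N$ haplotypes, discrete generations, random mating, crossovers
Poisson in number and uniform in position, no mutation, no selection, no
migration.  Markers start as segregating sites at frequency exactly 0.5.
A forward simulator was chosen over a coalescent one because demographic
change points (a `demography` schedule of $(generation, N)$ pairs) are then
transparent to implement and to reason about.

It emulates exactly the force the estimator models — drift against
recombination — and nothing else.  Real SNP data differ in ways the
simulator deliberately omits: ascertainment bias of chip SNPs, mutation,
admixture and migration, selection and hitchhiking, variable local
recombination rate, genotyping error.  Passing the recovery tests therefore
shows the estimator correctly inverts the drift-recombination signal; it
does not show robustness to those confounders, which bias LD-based $N_e$
estimates in real data and are outside this package's scope (no confidence
intervals are produced either).

`generateLDProfile()` is the complementary *analytic* fixture: it emits
pairs whose $r^2$ is exactly $1/(\alpha + 4 N_e f(c)) + 1/(\beta n)$ at
each bin midpoint, so the full pipeline must return exactly $N_e$ in every
bin.  This separates algebra bugs (caught at $10^{-9}$ relative tolerance)
from stochastic behaviour.

## Numerical and validation choices

* Estimates are reliable in a window of generations: for very recent
  generations the required $c$ is large, where the theory's assumptions
  degrade, and beyond roughly $2N$ generations drift has erased most
  signal (and no marker survives sampling beyond $4N_e$).  The recovery
  test therefore checks bins with $10 \le t \le 200$ for a true $N = 100$:
  20 replicates (sample 50 of $N = 100$; 500 markers on 50 Mb at
  $10^{-8}$ M/bp; 400 generations) must give a replicate-median $\hat N_e$
  within $\pm 30\%$ of truth, and an $N = 500$ run must exceed its paired
  $N = 100$ run in at least 19 of 20 replicates.  Outside that window bias
  grows, which is expected behaviour, not failure.
* The simulator itself is validated independently of the estimator by the
  binomial drift law: at unlinked loci (markers spaced about 2 Morgans
  apart) the variance of allele frequency after $g$ generations must match
  $p(1-p)\,[1 - (1 - 1/(2N))^g]$ within Monte-Carlo error (500
  locus-replicates).
* Determinism: the simulator takes a mandatory seed and is bit-reproducible;
  the LD stage is partitioned by leading-marker blocks and re-sorted, so
  the output is identical for any thread count; identical command-line
  invocations yield byte-identical trajectory files.
* Problem sizes in the shipped validation scripts (replicate counts,
  marker counts) are chosen to exercise the stated statistical bands at
  interactive runtimes; the acceptance script uses 10 replicates per
  condition for its recovery summaries.
* Output formatting is fixed (generations, $N_e$ and mean distance with 1
  decimal; $r^2$ statistics with 6 decimals) so that files are bit-stable
  and round-trippable; the trajectory column order follows the tool's
  output contract: `GenAgo Ne AvgDist AvgR2 SdR2 NPairs`.
* The `NPairs` column counts SNP *pairs* (the quantity that drives the
  bin means), not distinct SNPs.

## A worked example

```{r example, eval = FALSE}
library(NeTrend)

# simulate a constant-size population and estimate its trajectory
g <- simulateWrightFisher(popSize = 100, sampleN = 50, nMarkers = 500,
                          chromLengthBp = 5e7, recombRatePerBp = 1e-8,
                          generations = 400, seed = 42)
traj <- neTrajectory(g)           # MAF 0.05, 50 kb - 4 Mb, 30 bins, x = 1.5
head(traj)

# the same analysis from the shell:
#   Rscript inst/scripts/netrend.R estimate --ped sim.ped --map sim.map \
#       --out run1 --bins 30 --bin-exp 1.5
```

For data whose LD was computed elsewhere, `readLDTable()` +
`runTrajectory()` (or the `from-ld` subcommand with `--n`) skip the LD
stage and apply only binning, corrections and inversion.

## Known limitations

Beyond the confounders listed above: the method yields point estimates
only; the recent-most and oldest bins should be read with caution; $k$ is a
single genome-wide constant unless the user maps distances themselves
before `from-ld`; and phased input must arrive already phased — no phasing
is performed.
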