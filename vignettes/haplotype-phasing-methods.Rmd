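---
title: "Two-tier haplotype phasing from molecular linkage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier haplotype phasing from molecular linkage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapforge)
library(dplyr)
```

## The problem

A diploid genome carries two parental copies of every chromosome, and a
short-read variant callset only reports *genotypes*: which two alleles are
present at each heterozygous site, not which allele sits on which homolog.
hapforge reconstructs chromosome-scale haplotypes by combining two kinds of
long-range evidence with complementary strengths:

* **linked reads / long reads** give dense, accurate linkage, but only over
  the span of an input DNA molecule (tens to a few hundred kb);
* **Hi-C proximity ligation** gives sparse linkage (usually a single read
  pair between two given sites) that reaches across an entire chromosome,
  with more than 90% of links joining loci on the same homolog.

The two tiers of the method mirror this: dense local evidence is phased
first into high-confidence blocks; sparse chromosome-scale evidence is then
aggregated *between blocks*, where summing over all variant pairs turns
single-link noise into a strong signal.

## The spin model

Genotypes are encoded as spins: $+1$ for the reference allele, $-1$ for the
alternate. A haplotype over $N$ sites is $\mathbf S = (s_1,\dots,s_N)$,
$s_i = \pm 1$, defined up to a global sign — flipping every spin describes
the other parental chromosome, so all scores in the package are invariant
under $\mathbf S \to -\mathbf S$ and all accuracy metrics are computed
flip-invariantly.

Each molecule observing sites $i$ and $j$ supports either *cis* linkage
($\sigma_i\sigma_j = +1$: ref–ref or alt–alt) or *trans* linkage
($\sigma_i\sigma_j = -1$). With $n^+_{ij}$ cis links, $n^-_{ij}$ trans
links, and a per-pair error rate $\epsilon_{ij}$, the log-likelihood of a
haplotype is (up to a constant) the negative energy of a one-dimensional
spin model,

$$E(\mathbf S) = -\tfrac12 \sum_{\{i,j\}} M_{ij}\, s_i s_j,\qquad
M_{ij} = (n^+_{ij} - n^-_{ij})\,\chi_{ij},\qquad
\chi_{ij} = \ln\frac{1-\epsilon_{ij}}{\epsilon_{ij}},$$

with the sum over unordered pairs. We keep the $\tfrac12$ with
unordered-pair counting so that the two perturbation scores below are
*exact* energy differences and, through the logistic transform, exact
posterior error probabilities; dropping the factor would double every
penalty and mis-calibrate the error probabilities.

The error rate of a pair is estimated from its own minor-linkage fraction,
floored at the dataset-wide average
$\epsilon_0 = \langle \min(n^+,n^-)/(n^++n^-)\rangle$:

$$\epsilon_{ij} = \max\!\left[\epsilon_0,\;
\frac{\min(n^+_{ij},n^-_{ij})}{n^+_{ij}+n^-_{ij}}\right].$$

This floor describes random errors; pairs whose discordance far exceeds it
(false variants, mis-mapped reads) get a small $\chi_{ij}$ and therefore
little say in the solution. Two numerical clamps keep $\chi$ finite:
$\epsilon$ is capped at 0.49 (a majority-discordant pair carries near-zero
weight rather than flipping sign infinitely strongly) and floored at
$10^{-4}$ (error-free aggregated counts would otherwise produce infinite
weights).

## Minimization, confidence scores, and blocks

`minimize_energy()` lowers $E$ with two move types: single spin flips,
swept in ascending coordinate order, and suffix switches that negate every
spin after a boundary — the move class that matches the dominant error mode
of 1D phasing (a switch error inverts everything downstream). Moves are
accepted only when they strictly lower the energy, so the sweep is
deterministic given the initial spins; the default initialization chains
each site to its strongest-linked predecessor through the sign of
$n^+ - n^-$. The boundary penalty is maintained incrementally during the
sweep ($O(\text{links})$ per round); a move must beat a tolerance scaled to
the total coupling weight ($10^{-9}\sum|M_{ij}|$) so that floating-point
noise at exactly-zero boundaries (linkage gaps such as centromeres) is
never mistaken for an improvement. On dense simulated data the sweep
converges in a handful of rounds; non-convergence after `max_rounds`
(default 50) returns the current state with a warning.

At the optimum, two penalties score every position:

* the **spin-flip penalty** $\Delta E_i = s_i \sum_j M_{ij} s_j$ — the cost
  of flipping one site; near zero for sites whose phase the data do not
  determine, which is the signature of false variants with balanced
  cross-haplotype linkage;
* the **switch penalty** $\Delta E_{k|k+1} = \sum_{i\le k}\sum_{j>k} M_{ij}
  s_i s_j$ — the cost of inverting everything after a boundary.

Both convert to error probabilities via $\delta = 1/(1+e^{\Delta E})$:
$\Delta E = 0$ gives $\delta = 0.5$ (a coin flip), large penalties give
vanishing error.

`segment_blocks()` cuts the chromosome at every boundary whose switch
penalty falls below a cutoff. `suggest_cutoff()` places the cutoff at the
valley of the switch-penalty distribution, which is strongly bimodal: a
near-zero mode (gaps, chromosome ends, false variants) and a bulk mode
several orders of magnitude higher. Because of that dynamic range the
valley is located on a $\log_{10}(\Delta E + 1)$ axis — the deepest local
minimum of a kernel-smoothed density below the main mode. Any cutoff
inside the empty valley yields the same segmentation, so the exact value is
not critical; when the distribution is unimodal (sparse long-read data) the
fallback is $0.1\times$ the median number of links per pair. Blocks with
fewer than 50 variants are flagged `short`: their aggregated Hi-C signal is
weak and their gauge unreliable, so they are excluded from the scaffold and
re-phased individually at the final stage.

## Hi-C concatenation

`interblock_linkage()` aggregates Hi-C links between two blocks by the
spin-product rule: a link is cis-supporting when
$\sigma(x)\sigma(y)B_s(x)B_t(y)=+1$ with $B$ the block-local spins. The
aggregated counts become couplings of a *block-level* spin model — each
block one spin — solved by the same minimizer (`concatenate_blocks()`
literally calls `minimize_energy()` on the translated instance; a test
asserts the equivalence). Pairs supported by fewer than `min_links`
(default 2) aggregated links carry no weight, so a single stray link never
joins two blocks. Concatenation runs in two stages: within each chromosome
arm using links between variants at most 10 Mb apart, then one relative
phase between the p and q arm scaffolds using all inter-arm links (the
centromere is variant-free, so no molecule-scale evidence crosses it). A
tie leaves the arms unjoined and reported.

The sensitivity of this stage to intra-block switch errors is quantified by
`switched_block_specificity()`: if two blocks carry haplotype-A fractions
$f_1, f_2$, the apparent cis fraction of links between them is $\rho = f_1
f_2 + (1-f_1)(1-f_2)$. A single mid-block switch drives $f \to 0.5$ and
$\rho \to 0.5$, destroying the signal — the reason block cutoffs are chosen
conservatively and short blocks are kept out of the scaffold.
`cis_trans_report()` verifies a finished scaffold by recomputing cis/trans
counts per block pair under the final phases.

## Final phasing and the linkage filter

With a chromosome-scale scaffold in hand, every variant — scaffold members,
sites left out of blocks, and indels, which are kept out of the energy
model because their genotyping errors would propagate — is re-phased
against it. Each molecule covering the variant is assigned to scaffold
haplotype A or B by a strict majority of its other scaffold-site genotypes
(ties discard the molecule) and casts one vote, filling four counts:
ref–A, alt–A, ref–B, alt–B. Distinct scaffolds have independent gauges, so
a molecule votes only within the scaffold holding most of its sites, and a
variant is phased in the gauge of its molecules' modal scaffold; scaffolds
under 50 sites are never used as a reference frame.

The combined evidence is $\eta_{rA} = \#(\text{ref–A}) + \#(\text{alt–B})$
and $\eta_{rB} = \#(\text{ref–B}) + \#(\text{alt–A})$, and the **linkage
filter** keeps a variant only if (I) all four marginals — ref, alt, A, B —
are linked at least once, and (II) the evidence segregates:
$\min(\eta_{rA},\eta_{rB}) \le \max[2,\, 0.1(\eta_{rA}+\eta_{rB})]$.
True heterozygous variants put their two alleles on complementary
haplotypes, so one $\eta$ dominates; false variants show balanced linkage
and fail (II). Survivors are phased to the larger $\eta$; ties stay
unphased.

## Copy number, contacts, and monosomy references

`bin_coverage()` implements haplotype-specific coverage in fixed bins
(default 250 kb): $C^{(i)}_{A,B} = D^{(i)} \bar R^{(i)}_{A,B}$ with
$D$ the normalized mean depth and $\bar R_A$ the per-variant-then-per-bin
mean fraction of allelic reads on haplotype A (per-variant averaging keeps
single-site coverage spikes from dominating a bin). `copy_number()` divides
by the pooled median of per-bin $C_{A,B}$ — the coverage of one homolog in
a mostly diploid genome — turning coverage into copy number: 1 per intact
homolog, 0 on a lost one, and non-integer values for subclonal events
(a gain in 45% of cells reads ~1.45). Bins without phased variants are
flagged and excluded from the median. `phased_contacts()` assigns each end
of a Hi-C link to a haplotype through the phased variant it covers and bins
contacts by (position, position, AA/AB/BA/BB); a rearrangement junction
appears as enrichment confined to one combination, which phases the
junction.

Monosomic single cells expose one homolog directly and provide truth data
for benchmarking. A cell/chromosome is called monosomic when its
*normalized heterozygosity* — the fraction of het sites showing both
alleles, over the squared mean allelic-coverage fraction — falls below
$0.1\times$ the diploid median; allelic coverage at a site requires
$d^* = \max(2,\, 1 + 0.1\times\text{mean depth})$ reads, whose two terms
remove random sequencing errors and sub-10% amplification artifacts
respectively. `reference_from_monosomies()` assembles the exposed alleles
into a reference haplotype; since different cells may carry either homolog,
each cell is oriented to maximize agreement with the running consensus and
sites below 2/3 agreement are dropped. The orientation and consensus rules
are this package's choices — selection of monosomies is principled, but
multi-cell assembly admits several reasonable schemes.

## The synthetic-data generator

`simulate_genome()` and its companions generate data with the statistical
structure the method relies on, so every stage is testable without any
external download:

* heterozygous SNVs as a Poisson process at 1/kb, with a variant-free
  centromeric gap and optional LOH intervals;
* 1% *false variants* whose molecule "genotypes" are random coin flips —
  non-segregating linkage, the signature the flip penalty and criterion
  (II) are designed to catch;
* linked-read molecules with exponential lengths (observed mean molecule
  lengths in real libraries are tens of kb; the family is a modelling
  choice), uniform placement, per-observation genotype error, and *barcode
  collisions*: with `molecules_per_barcode = 2` each barcode tags two
  unrelated molecules, reproducing the ~50% cis-consistency plateau beyond
  the molecule length that real linked-read data show. The pipeline
  counters collisions the same way real extraction does — barcode groups
  are split at gaps above 50 kb (`split_molecules()`; the same rule
  `extract_links()` applies to BAM input) and pairwise linkage is capped at
  100 kb;
* Hi-C link pairs with a truncated power-law distance law (exponent 1.5,
  minimum 1 kb — shorter separations are not probed by proximity
  ligation), 5% trans-homolog links and 2% genotype error, matching the
  >90% cis-consistency regime of real data;
* single-cell allele counts with disomic/monosomic states and low-frequency
  amplification artifacts at a fraction of sites;
* aneuploid depth tracks and allele counts from a clone mixture with
  per-haplotype integer copy numbers.

Defaults are the package's reference conditions (30 Mb chromosome, 1
het/kb, 60× linked-read coverage with 50 kb molecules and 1% spin error,
50,000 Hi-C links). What the simulations do *not* model: alignment and
mapping artifacts (false variants enter as label noise, not as systematic
mis-mapping clustered in low-complexity regions), GC/mappability coverage
bias, reference bias, read-level base qualities, and realistic variant
density fluctuation (real genomes have megabase-scale low-heterozygosity
troughs that are a main driver of switch errors). Passing the simulation
suite therefore demonstrates the correctness and calibration of the
machinery, not performance on any particular real library.

## Numerical and design choices

* **Coordinates.** Site positions are 1-based (VCF convention, as in
  GRanges); bins and BED-style outputs are 0-based half-open.
* **Ties.** A pair with $n^+ = n^-$ has phase sign 0 and zero weight; a
  move with $\Delta E = 0$ is rejected; a variant with $\eta_{rA} =
  \eta_{rB}$ stays unphased. No arbitrary phase is ever invented, and the
  whole pipeline is deterministic given the input and seeds.
* **Gauge fixing.** The minimizer reports the solution with $s_1 = +1$;
  each scaffold reports its first block as phase $+1$. Purely cosmetic.
* **Degenerate inputs.** Sites observed by no molecule get all-zero counts
  and fail criterion (I); an empty histogram, zero-coverage reference
  median, or all-tied error-rate input raise errors rather than guesses.
* **Problem sizes.** The bundled tests run the full pipeline on 2–5 Mb
  chromosomes and the acceptance script on 30 Mb chromosomes across 20
  seeds; both finish on a single CPU in minutes. These sizes are chosen as
  the smallest at which block structure, arm joining, and the collision
  plateau are all exercised.
* **`suggest_cutoff` scale.** The reference implementation's published
  cutoffs are dataset-specific; the log-scale valley rule reproduces the
  intent (a conservative cutoff just above the unreliable-boundary mode)
  without a per-dataset constant.

## Limitations

Only bi-allelic sites on diploid (or locally diploid) genomes are phased;
multi-allelic sites and polyploid phasing are out of scope, as are
structural-variant phasing and re-genotyping. The final indel stage trusts
the input genotypes; it filters, but does not re-call. Monte-Carlo
(annealing) minimization is not implemented — on data where the majority of
linkage is cis-consistent the sweep reaches the global optimum in practice
(the test suite verifies this against exhaustive enumeration on small
instances), but adversarial coupling patterns can in principle trap it in a
local optimum, which the certification step at least makes explicit.
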