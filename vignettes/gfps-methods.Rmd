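---
title: "Joint estimation of recombination and LD in half-sib families, and the genome fragmentation phasing strategy"
author: "gfps package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gfps methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `gfps`, the design
decisions in its estimators and simulators, and the limits of what its
validation shows.  It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## 1. The half-sib transmission model

Consider two linked biallelic SNPs with alleles written `T/t` and `M/m`
(in data, allele 1 of each SNP plays `T` and `M`).  A sire heterozygous at
both SNPs carries its four alleles in one of two linkage phases: coupling
`TM/tm` or repulsion `Tm/tM`.  Each progeny receives one sire gamete —
a parental haplotype with probability $(1-c)/2$ each or a recombinant with
probability $c/2$ each, where $c \in [0, 0.5]$ is the recombination
fraction — and one maternal gamete drawn from the dam population with
haplotype frequencies $(f_{TM}, f_{Tm}, f_{tM}, f_{tm})$.  Maternal LD is
$\delta = f_{TM}f_{tm} - f_{Tm}f_{tM}$, with admissible range
$\max(-f_Tf_M, -f_tf_m) \le \delta \le \min(f_Tf_m, f_tf_M)$
(`delta_bounds()`).

The observable data for one SNP pair are the counts $n_j$ of the nine
unordered two-SNP genotype classes `TTMM … ttmm`
(`genotype_class_probs()`, `geno_counts()`).  The log-likelihood kernel is
$\sum_j n_j \log \phi_j$ with $0\log 0 = 0$; the multinomial coefficient is
omitted because it cancels in maximization and in the phase posterior.

## 2. The joint EM estimator

`em_single_family()` maximizes this likelihood over
$(f_{TM}, f_{Tm}, f_{tM}, f_{tm}, c)$ for a given sire phase.  The
complete data are the sixteen (sire gamete, maternal haplotype) cells; the
E-step distributes each ambiguous class over its compatible cells, and the
M-step re-estimates the haplotype frequencies and $c$ as expected-count
proportions, with $c$ clamped to $[0, 0.5]$ (both constrained M-steps are
exact maximizers, so the observed-data likelihood is nondecreasing — a
property asserted on every fit in the test suite).  Convergence is a
maximum absolute parameter change below `tol` ($10^{-8}$ by default,
`max_iter` 10,000); the hot loop is compiled (Rcpp).

**Starting point — and why it defines the estimator.**  At intermediate
allele frequencies the model is *exactly* non-identifiable along a curve in
$(c, \delta)$: for example the class probabilities at
$(c{=}0.20, \delta{=}0.20)$ and $(c{=}0.10, \delta{=}0.15)$ with
$f_T{=}f_M{=}0.5$ coincide, and expected counts at
$(c{=}0, \delta{=}0.20)$ are also produced exactly by
$(c{=}0.10, \delta{=}0.25)$.  On such a ridge the maximum-likelihood
"estimate" is a set, and the EM's limit depends on where it starts.  The
package therefore defines its default estimator by the
*zero-recombination complete-data start*: haplotype frequencies from
allocating each genotype class to the maternal gametes compatible with a
parental sire gamete (the doubly ambiguous class splits equally), and $c$
started at the observed fraction of obligate-recombinant offspring.  Two
consequences matter:

* when no offspring requires a recombinant gamete, the start has $c = 0$,
  which is a fixed point of the EM map — fully linked data give
  $\hat c$ *exactly* 0, the behavior fragmentation relies on;
* on ridge data the EM resolves the ambiguity in favor of the
  no-recombination interpretation, which is the phasing-relevant branch.

Setting `n_starts > 0` in `em_config()` switches the goal to the global
maximum: seeded random restarts are added, plus a mirrored-phase start (the
opposite phase's zero-recombination allocation at $c = 0.5$) because on
data from the opposite sire phase the likelihood peaks at the $c = 0.5$
boundary where the two phases coincide — a basin random restarts can miss.
Near-ties keep the first (zero-recombination) solution.  Global-maximum
attainment is certified against `grid_oracle()`, an independent exhaustive
lattice search over $(c, f_T, f_M, \delta)$ with closed-form class
probabilities and three tenfold refinement passes around the incumbent (one
pass at coarse steps does not reliably reach the $10^{-3}$ log-likelihood
agreement the verification demands).

**Phase posterior.**  `phase_probability()` fits each phase separately and
forms $L_c/(L_c + L_r)$ from the two maximized (profile) likelihoods on the
log scale.  The reported estimates are those of the better phase.  Note an
identifiability caveat mirrored in the tests: when maternal LD is
*anti-aligned* with the sire's phase (e.g. coupling data with
$\delta < 0$ at $c = 0$), the opposite phase has an exactly equally likely
explanation at a shifted $c$ and boundary LD, so the posterior hovers near
0.5 and the selected-phase estimates are unstable.  For this reason the
single-family table reproductions condition on the true (simulated) phase,
as the original tables do for a known double-heterozygote sire, while phase
selection is used where it is actually needed — the pairwise scan, where a
wrong selection surfaces as a fragment boundary, not as a wrong chain
(Section 5).

## 3. The LE-constrained baseline

`em_le_constrained()` is the classical single-parent estimator that forces
$\delta = 0$.  By default the maternal allele frequencies are estimated
first from the offspring in which the maternal allele is directly
observed — the homozygotes at each sire-heterozygous SNP, whose second
allele must be maternal — and the likelihood is then maximized over $c$
alone; `allele_freqs = "ml"` profiles the frequencies by a constrained EM
instead.  The plug-in form was selected because it reproduces the
small-sample upward bias of the published comparison table more closely
(the two variants agree on the large-sample attenuation, e.g. both give
$\hat c \approx 0.012$ on exact expected counts from
$c{=}0.10, \delta{=}0.20$).  This estimator exists as the biased baseline:
it demonstrates why joint estimation is required, and is not used in
phasing.

## 4. Multi-family pooled estimation

`em_multi_family()` pools several half-sib families whose sires are drawn
from the population and may be double homozygotes (maternal gametes
directly observed; no information on $c$), homo-heterozygotes (maternal
posteriors at one locus; no information on $c$), or double heterozygotes.
All sire types run through one transmission model parameterized by the
sire's two haplotypes.  Each outer iteration runs a per-family E-step at
the current pooled parameters and pools by family-size-weighted averages;
an unknown double-heterozygote phase is a latent variable whose two
components are weighted by their per-iteration posterior.  Because
non-double-heterozygous sires transmit recombinants indistinguishable from
parentals, $c$ is pooled over double-heterozygote families only — pooling
zeros from uninformative families would bias the multi-family
recombination estimate downward by the fraction of such sires.  The pooled
start is neutral (uniform frequencies, $c = 0.25$); phases being latent,
no per-family zero-recombination allocation applies.

## 5. The genome fragmentation phasing strategy

`phase_family()` runs the pipeline per chromosome:

1. **QC** (`qc_filter()`): SNPs need a called sire genotype, minor allele
   frequency ≥ 0.10 over sire plus progeny, and sufficient progeny calls —
   at least `ceiling(2/3 · n_progeny)` progeny (24 of 36) *or* a call
   fraction ≥ 0.80; the two knobs are kept separate because the source
   rule conflates a per-SNP call count with a call-rate fraction.
   **Mendelian filtering** (`mendelian_check()`) then removes any SNP at
   which some progeny shares no allele with the sire — one conflicting
   call flags a genotyping problem for the whole SNP.
2. **Pairwise scan** (`pairwise_scan()`): consecutive sire-heterozygous
   SNPs, each pair sharing one SNP with the next, estimated jointly with
   the phase posterior.  Sire-homozygous SNPs are phase-trivial and carried
   inside blocks; pairs spanning more than 50 Mb are skipped and force a
   boundary.
3. **Fragmentation** (`fragmentize()`): a pair with
   $\hat c$ > `c_threshold` ends the block at its left SNP.  The threshold
   defaults to $10^{-4}$: "greater than zero" must be applied numerically
   because finite tolerance can leave tiny positive $\hat c$.  An exact
   phase tie (posterior 0.5) also splits, with a warning; the minimum
   posterior for chaining is configurable.
4. **Sire phasing** (`phase_sire_fragment()`): pairwise phase calls are
   chained left to right — coupling keeps the allele-1-bearing chromosome
   on the same strand, repulsion crosses it.  The whole-fragment
   orientation is arbitrary until alignment.
5. **Progeny phasing** (`phase_progeny()`): at a sire-het SNP, a
   homozygous progeny votes for the strand carrying its allele; unanimous
   votes fix the fragment origin, the paternal allele is the strand allele
   everywhere in the span, and the maternal allele is the genotype
   remainder (left unknown at missing genotypes, which are also excluded
   from ROI runs).  No votes leave the origin unknown; conflicting votes
   indicate a within-fragment recombination or error.
6. **Fragment alignment and chain correction.**  Adjacent blocks are
   oriented to minimize origin switches among doubly informative progeny
   (`interfragment_linkage()`; an exact tie is flagged unresolved).  A
   second pass then walks the chromosome-wide vote sequence: an inter-SNP
   point where *more than half* of the informative progeny appear to
   switch strands cannot be recombination (each meiosis recombines
   independently with probability ≤ 1/2), so it marks a mis-called pair
   phase and the strand labeling is flipped from there on.  Without this
   pass, a single weakly informative pair (posterior barely past 0.5 at 36
   progeny) can silently flip the rest of a fragment.
7. **Events** are per-progeny changes of inherited strand along the
   sequence of origin-informative SNPs — this covers switches between
   blocks and recombination hidden inside a block alike, which matters
   because a single crossover among 36 progeny produces an
   obligate-recombinant genotype (the only signal a single pair's EM can
   see) only part of the time, so most single crossovers do not terminate
   a fragment at scan time.  Each event is bounded by the last informative
   SNP before and the first after the switch, and assigned the interval
   midpoint.  Runs of agreeing votes are extended outward for paternal
   allele assignment; the gap between two disagreeing votes stays
   unassigned.
8. **Reporting**: informativity (fraction of sire-het/progeny-het SNPs
   whose origin was resolved), `genome_wide_fragment_scan()` (super-allele
   linkage of one block against all others, flagging array mis-assembly
   when a block is unlinked to its neighbors but tightly linked to a
   distant one), and `compute_rois()` — maximal runs of ≥ 20 identical,
   known same-origin alleles between two individuals.  The ROI proportion
   uses the jointly phased SNP count as denominator (identity is defined
   on SNP alleles); a bp basis is available as an option.

## 6. Simulators and the synthetic study conditions

`simulate_family()` draws offspring classes by cumulative-probability
inversion of uniforms.  `simulate_multi_family()` draws each sire's two
haplotypes from the population gamete frequencies and simulates progeny
conditional on the sire's actual genotype; family sizes default to the
six-family design (94, 77, 106, 81, 79, 100).  Per-replicate seeds are
derived once from a master seed, so replicates are order-independent;
functions that consume randomness restore the caller's RNG state.

`simulate_phased_chromosome()` transmits a phased chromosome: crossover
counts 0–3 with probabilities (0.511494, 0.398467, 0.081418, 0.00862) —
the genome-wide per-chromosome values — positions uniform over the map,
one of the two meiotic products transmitted at random, and maternal
chromosomes generated as a first-order Markov chain over consecutive-pair
haplotype frequencies.

`synthetic_chrom_spec()` fixes the synthetic validation conditions: 751
sire-heterozygous SNPs (only heterozygous SNPs are simulated; homozygous
ones are phase-trivial) uniformly placed on a 158 Mb chromosome, 36
progeny, maternal allele frequencies uniform on [0.2, 0.8], and
consecutive-pair LD with $|D'|$ uniform on [0.5, 0.95] — the strong
short-range LD of dense arrays — with arbitrary sign.  The sire's first
chromosome is itself a draw from the maternal Markov chain (the sire comes
from the same population as the dams), and heterozygosity at every
retained SNP forces its second chromosome to be the complement.  This last
point is not cosmetic: with sire haplotypes drawn independently of the
population LD, half of all pairs would have the sire phase anti-aligned
with maternal LD — the exact-tie configuration of Section 2 — which does
not reflect a real sire and makes single-pair phase calls uninformative.

What the generator does *not* emulate: genotyping errors and missing calls
(hooks exist, default off), crossover interference, more than three
crossovers per meiosis, mutation, irregular SNP spacing, and the specific
LD profile of any real chromosome.  Passing the validation therefore shows
the pipeline recovers truth under clean, strongly-LD-structured data of
realistic size; it does not bound error rates on a real array, where the
published real-data quantities (event counts, ROI means, informativity
ranges) depend on genotypes this package cannot ship.

## 7. Numerical conventions and problem sizes

* Surface argmax ties (`expected_loglik_surface()`) break toward the
  smallest $c$, then the smallest $|\delta|$ — exact expected counts can
  carry tied maxima (Section 2), and the no-recombination solution is the
  phasing-relevant one.
* The zero-recombination start is lightly smoothed (quarter-count per
  haplotype) so no frequency starts at exactly 0; at an absorbed $c = 0$
  the EM limit is start-independent (the $c{=}0$ submodel is concave in
  the frequencies), so the smoothing does not move reported estimates.
* Impossible configurations return $-\infty$ log-likelihood rather than
  erroring; empty families return posterior 0.5 and undefined estimates;
  progeny-monomorphic SNPs are flagged `"monomorphic"` rather than
  silently estimated.
* Validation sizes: the test suite and acceptance script run 10,000
  replicates for family sizes up to 300, 2,000 replicates for the
  N = 2,000 and six-family cells (their Monte-Carlo standard errors are
  below $10^{-3}$), and 100 replicate chromosomes of 751 SNPs for the
  phasing validation.

## 8. Known limitations

Two linked biallelic loci at a time; no interference model; no standard
errors or likelihood-ratio tests for $(\hat c, \hat\delta)$; genotyping
errors and true recombination are both surfaced (fragment boundaries,
conflict flags, genome-wide fragment scan) but not auto-classified;
multi-generation phasing proceeds by composing the same operations on a
phased parent rather than by dedicated machinery.
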