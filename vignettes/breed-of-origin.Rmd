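---
title: "Assigning breed-of-origin of alleles in three-way crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning breed-of-origin of alleles in three-way crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial pigs are commonly produced as a terminal three-way cross: a
synthetic sire line (S) mated to F1 dams that combine Landrace (LR) and
Large White (LW). Each cross animal therefore carries, at every SNP, one
allele inherited from the S line and one from either LR or LW. Genomic
models that distinguish allele effects by the line an allele descends from
need that *breed-of-origin* (BOA) label per allele, but SNP arrays return
unordered genotypes. `crossboa` reconstructs the labels from phased
genotypes of the crossbreds and of reference animals from the three
purebred lines.

## The method

The assignment proceeds in three steps.

**1. Phasing.** The method consumes phased haplotypes. The package does not
re-implement population-scale long-range phasing (an external tool's job);
it accepts an externally phased VCF, offers Mendelian trio phasing
(`trio_phase()`) when parents are genotyped, and — for validation — uses
the simulator's exact phase with controlled switch-error injection. This
last route lets one study how BOA assignment degrades with phasing quality
directly, which a black-box phasing tool would confound.

**2. Haplotype library.** The genome is segmented into *core windows* of a
fixed number of SNPs. Nine core:tail combinations are used (350:50,
250:100, 300:100, 350:100, 150:200, 200:200, 250:200, 300:200, 350:200),
each in a `NotOffset` tiling starting at the first SNP and an `Offset`
tiling shifted by half a core, giving 18 window configurations
(`default_window_configs()`). Tail lengths are carried as metadata only:
tails matter to the long-range phasing algorithm the windowing scheme comes
from, not to library matching, which operates on cores. Windows never span
chromosomes; the final window of a chromosome is truncated, and in offset
mode a leading half-window is emitted so that every SNP is covered — hence
every allele can be considered exactly 18 times (`count_potential_votes()`).
For every window, each gamete of each purebred reference animal contributes
one copy of its window haplotype to its breed's count; gametes with a
missing allele in the window contribute nothing.

**3. Assignment.** A window haplotype observed in a crossbred is matched to
the library (exact match first; otherwise the unique nearest entry within a
mismatch tolerance, default 1% of the window's informative positions —
echoing the 1% genotype-error allowance conventional in phasing; ties
never match). The matched haplotype's breed is decided by the *relaxation
factor* f_r: the haplotype is assigned the breed holding the majority of
its purebred copies provided that share is at least (100 − f_r)%, with
f_r = 20 by default (f_r = 0 demands exclusivity). A `min_copies` floor
(default 1) is configurable because single-copy assignments are fragile in
tiny reference panels. Window labels then become per-allele votes under two
constraints:

* **Breed composition.** In the three-way cross the paternal gamete can
  only be S and the maternal gamete only LR or LW; votes violating this
  are discarded. For F1 animals each gamete admits only its own purebred
  parent's breed (which requires a pedigree).
* **Zygosity completion.** When the maternal allele at a locus receives a
  vote, the paternal allele at that locus is simultaneously fixed to the
  sire-line breed in that configuration — the paternal breed is unique, so
  knowing which allele is maternal determines the other. The converse does
  not hold: an assigned paternal allele cannot choose between the two
  maternal lines.

Which gamete is paternal is decided per animal: a pedigree-derived
orientation (carried gamete roles, or trio-phase agreement) takes
precedence; without a pedigree, the gamete with the larger genome-wide
count of S-labelled windows across all configurations is paternal. A tie —
including zero S windows on both gametes — leaves the animal unordered and
entirely unassigned, which is itself diagnostic (see the mislabelling
screen below).

Finally `consensus_origins()` condenses up to 18 votes per allele. The
default rule is **strict unanimity**: assigned if at least one vote exists
and all votes agree, unknown on any conflict. The consensus rule over the
18 considerations is genuinely open — the originating work defers it to an
unpublished implementation detail — so the strict rule is this package's
explicit, conservative stand-in, with a configurable majority alternative
(`vote_rule = "majority"`, threshold 0.5 by default, ties never assign).
The choice is recorded in the result's provenance.

Two tie-break conventions are worth stating. If two breeds share the
maximal copy count of a haplotype, no breed is assigned even when the ratio
test passes (possible only at f_r ≥ 50). If two library entries are
equidistant from a crossbred window at the minimal distance, the window is
left unmatched rather than guessed.

## The simulator

`simulate_three_cross()` provides ground truth that real data cannot: the
true origin of every allele. Its defaults are the package's study
conditions and are deliberately fixed:

* **Breed divergence**: per-SNP ancestral frequencies uniform on
  (0.1, 0.9); each breed's frequency is an independent Balding–Nichols
  Beta draw with mean p and variance p(1−p)·F. The default `fst = 0.25`
  emulates distantly related breeds, the regime where BOA assignment is
  expected to work well; the model is the standard minimal choice when no
  breed history is available.
* **Within-breed structure**: 50 founders per breed followed by 8
  generations of random mating at constant size, then an expansion to the
  genotyped cohort. This creates the within-breed haplotype sharing
  (effective population sizes of order 50–100 are typical of commercial
  pig lines) that makes window haplotypes breed-characteristic; without it
  every window haplotype would be unique and the library useless.
* **Genome**: 5 chromosomes × 2,000 SNPs, 100 cM each, cM derived from bp
  at 1 cM/Mb — so one recombination per chromosome per meiosis on average
  (Poisson crossover counts, no interference, uniform breakpoints on the
  genetic map). A desk-scale analogue of an 18-autosome, 52k-SNP array
  study; sizes were chosen so a full validation (three breeds × 500
  reference animals, 200 crossbreds, three seeds) runs in minutes.
* **Crosses**: F1 dams are produced in both reciprocal directions
  (LR × LW and LW × LR) from the genotyped purebred cohorts, and the
  three-way crosses from genotyped S sires on those dams — mirroring field
  data, where the purebred reference contains relatives of the crossbreds'
  parents.
* **Errors**: genotype errors flip alleles independently (default 0);
  switch errors exchange the two gametes from a heterozygous site to the
  chromosome end (default 0; switches at homozygous sites are
  unobservable and not simulated). Truth tracks are never perturbed.

What the generator does **not** emulate: realistic linkage disequilibrium
decay or calibrated effective population sizes (no public description of
the real lines exists), selection, non-random mating, genotyping-chip
cluster artefacts, or sex chromosomes. Passing tests therefore show that
the method is implemented correctly and behaves as designed under a
plausible breed structure — not that a particular assignment percentage
will be attained on any given real dataset.

## Evaluation tools

`assignment_stats()` accounts per animal (optionally per chromosome) for
the percentage of alleles assigned overall, per gamete and per breed, with
a correctness column when truth is available; percentages count alleles
(two per SNP), so a fully assigned paternal gamete reads 50%. Animals or
chromosomes under 80% assignment are flagged, a threshold used to screen
for problematic animals. `compare_scenarios()` cross-classifies two runs
(e.g. f_r 0 vs 20) into concordance / assigned-in-one-only / disagreement;
the four percentages partition the alleles exactly.

`imputation_metrics()` implements the accuracy measures used to validate
genotype imputation: concordance of observed and imputed codes, and
Pearson correlation of genotypes corrected by twice the minor allele
frequency (MAF from the evaluated animals' observed genotypes). Per SNP
across animals the correction is a constant shift and cannot change the
correlation; across SNPs within an animal it re-centres every SNP and
does. Both directions are reported, labelled, because the conventional
"per-SNP, MAF-corrected" phrasing is ambiguous. SNPs under 0.80
concordance are flagged for removal. Zero-variance vectors yield an absent
correlation, never zero.

`grm_pca_outliers()` builds the Yang-style genomic relationship matrix
(genotypes centred by 2p and scaled by 2p(1−p) off-diagonal; the dedicated
diagonal estimator 1 + (x² − (1+2p)x + 2p²)/(2p(1−p)); monomorphic SNPs
skipped and counted) and eigendecomposes it. Mislabelled animals are
flagged per labelled population by a per-component robust z-score in the
first three components: |score − median| / MAD, flag above 6. A pooled
Euclidean distance-to-centroid rule was considered and rejected: the
cross population legitimately spreads along the LR-vs-LW axis (each animal's
maternal genome mixes the two lines in varying proportion), which inflates
any pooled spread estimate, whereas mislabelling displaces an animal along
a single axis — exactly what the per-component rule (the conventional
6-SD cut of PCA-based ancestry screening) detects.

## Numerical and design choices

* Internal SNP coordinates are 0-based half-open; conversion to 1-based
  VCF positions happens only at the I/O boundary.
* Half-phased or unphased VCF calls are treated as fully missing for that
  animal and site: the matcher requires known gametes.
* Records on chromosomes named X/Y are dropped with a warning; the method
  is defined for autosomes.
* Mendelian inconsistencies in trio phasing are silenced to missing and
  counted, never "corrected".
* Purebred copy counts are counted over gametes (two per animal), not
  over animals.
* Chromosome ends receive truncated windows; short windows are matched
  like any other, which is why assignment alternates more near chromosome
  ends.
* All randomness flows from a single integer seed; identical
  configurations reproduce byte-identical outputs.

## Validation summary

The test suite validates the implementation against an independent
brute-force reference (plain nested loops over windows, library entries
and votes) on randomized small instances; checks the f_r monotonicity,
breed-composition and zygosity-completion invariants on every produced
origin matrix; and measures truth recovery at the study scale (three
breeds × 500 reference animals, 200 crossbreds, 5 × 2,000 SNPs, medians
over three seeds) with and without 1% genotype and switch errors. With
errors present, assignment percentage drops substantially — library and
query haplotypes then both carry independent errors and long windows
rarely match within tolerance — while correctness among the alleles that
are assigned remains essentially intact; the strict consensus trades
coverage for reliability. `scripts/acceptance.R` re-runs these analyses
from scratch and writes the headline numbers as JSON.

## Known limitations

* The consensus rule over the 18 votes is this package's own convention
  (strict unanimity by default), as is the explicit PCA outlier rule.
* Robustness to genotype error is limited by exact-ish window matching;
  an error-correcting phasing step upstream (as long-range phasing tools
  provide) would recover much of the lost assignment.
* F1 animals can only be assigned when a pedigree identifies their parent
  breeds. Designs beyond the terminal three-way cross (rotational crosses,
  more than three breeds) are out of scope.
* The haplotype library is built from purebreds only; crossbred haplotypes
  are never used to augment it.
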