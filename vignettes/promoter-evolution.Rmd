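---
title: "Promoter-type evolution and population promoter activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-type evolution and population promoter activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterpop)
```

This vignette documents the models behind `promoterpop`, the parameter
choices that matter, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the design was
genuinely open.

## The locus and its types

The unit of analysis is a phased haplotype over an ~18-kb
low-recombination window of the *ST8SIA2* promoter region, flanked by
recombination hotspots. The ordered alleles at rs3759916, rs3759915 and
rs3759914 define the promoter type: TGT (ancestral), TCT, CGT and CGC
are scored with relative activities 3.6, 2.9, 2.1 and 1.0
(CGC-referenced, from luciferase assays); any other triplet, or any
missing call, is `OTHER` and unscored. Haplotypes identical over the
MAF-filtered site set form a *haplotype group* named after its first
carrier in panel order (`HG00097.1` style) — the naming convention of
the field's haplotype tables. Two MAF thresholds recur: 1% for
common-haplotype structure, 0.5% for analyses that must retain variants
carried mainly by archaic-related sequences. MAF is always computed on
the pooled panel, with `N` excluded from the counts.

## Archaic reconstruction

Archaic genomes arrive as unphased diploids with missing calls. One
individual (Altai) is fully homozygous across the region, which fixes
allelic linkage everywhere else: `phase_by_reference()` copies
homozygous sites to both haplotypes and, at heterozygous sites, puts the
reference-matching allele on haplotype `-2` and the other on `-1`, so
the `-2` haplotypes share the Altai sequence by construction.
Heterozygous sites where the reference is missing (or matches neither
allele) are flagged unresolved and masked. The companion
`diploid_distance()` avoids phasing altogether: per site it scores the
minimum mismatch count over the two possible pairings, halved — 0 for
identical genotypes, 1/2 when exactly one allele can be paired, 1
otherwise — matching the convention used for archaic diploid distance
matrices.

Tract analysis treats missing calls as transparent: an identical tract
around an anchor (usually the promoter triplet) extends to the nearest
flanking mismatches among compared sites, and its length is the bp span
between them, region edges when there is none. This measures length in
base pairs, not SNP counts, because the downstream survival test is a
recombination argument. `infer_mosaic_structure()` assigns each site to
the donor type with the locally longest identical run and merges
adjacent labels, recovering structures like TGT–CGT–TGT (a central
segment swapped by double crossover).

## Introgression statistics

**Frequency bound.** Observing `n` alleles of one type and none of any
other gives the posterior `Beta(n + 1, 1)` under a uniform prior; the
one-sided bound is `f0 = (1 - level)^(1/(n+1))` — with 8 archaic CGT
alleles, 71.7% at 95%. The general two-count form uses `qbeta`.

**Tract survival.** A shared tract of `m` bp survives unrecombined over
`t` years with probability `exp(-m r t / g)` (crossovers Poisson at
`r` per bp per generation, `t/g` generations). Long tracts shared
between modern and archaic sequences therefore reject the
incomplete-lineage-sorting explanation, which requires survival since
the species split rather than since introgression. The effective time
`t` depends on the tested scenario's lineage structure, so it is always
an explicit argument; the package deliberately does not guess it.

**The five-step screen.** To find modern haplotypes of archaic ancestry
whose promoter type was never sampled in an archaic genome, the screen
needs a calibrated modern–archaic site-difference band — from a known
introgressed lineage (`amh_ah_difference_range()`, excluding known
recombinants) or from split-time expectations (`2 t mu L` at the split
bounds, 550–765 kyr, giving 10–14 differences over 18 kb). Step 2
selects groups with at least one pairwise difference inside the band;
step 3 records the NJ tree's two-cluster partition (longest internal
edge); step 4 rejects groups present in two or more African
subpopulations ("widely distributed in Africa") together with their
relatives at fewer than the band minimum; step 5 examines the ages of
variants shared only by — otherwise unique to — the remaining groups,
rejecting those whose examined ages all fall outside the introgression
window (default 30–80 kyr, bracketing published age estimates of
introgression-diagnostic variants). Candidates with no age information
are flagged `age-unknown` rather than silently dropped. The widespread
threshold (2 subpopulations) and the window are configurable because no
published value pins them.

## Dating

Homozygosity tract lengths are computed pairwise among carriers — the
span from a core boundary outward to the first pairwise mismatch — and
summarised by their mean; the pairwise convention keeps the statistic
symmetric. The age converter `t = g / (k r HTL)` exposes both the
one-sided (`k = 1`) and two-sided (`k = 2`) constants, because published
applications of HTL dating differ in which flanks enter the mean and the
exact constant cannot be recovered from the reported inputs; results
always carry the `k` used. The Poisson-ML TMRCA for a star-shaped clade
is `t = S / (n L mu)` with the symmetric CI `t (1 ± 1.96/sqrt(S))`,
matching the symmetric intervals reported for this estimator; its
frequentist behaviour (unbiasedness, ~95% coverage) is verified by
simulation in the test suite rather than assumed.

## PPA

Individual promoter activity is the mean of the two allele activities;
PPA is the population mean of individual activities, with
`OTHER`-carrying individuals excluded and counted. Under random mating
the expected PPA collapses to the allele-frequency-weighted mean
`sum(f_i a_i)` — an algebraic identity (the sum over individuals of
`(a1+a2)/2n` is the allele-pool mean under *any* pairing), which the
tests assert exactly. The archaic enumeration sweeps compositions
`(f_CGT, f_TGT, f_TCT)` with `f_CGT` above the Beta bound and
`f_TGT >= f_TCT` (the ordering implied by the archaic recombination
mosaics, which require more TGT than TCT parents) on a 0.001 grid —
fine enough that the PPA extremes move by less than `3.6 x 0.001` under
tenfold refinement.

Two conventions in the index-SNP framework deserve note. The 99%
interval on panel frequency folds is a *population* interval
(`mean ± 2.576 sd`), not a standard-error interval — that is the only
reading that reproduces a (1.02–1.38) interval from mean 1.20 at
`n = 45` — and normality is checked by a one-sample KS test before the
interval is trusted. Ancestral-frequency inference multiplies the focal
frequency by the matched median fold and caps at 1; the output labels
itself approximate because the convention is not uniquely determined.
KS comparisons between populations are run on individual activities,
the observation unit of the PPA definition.

## The synthetic generator

`simulate_panel()` evolves haplotypes on a star genealogy: a common
root (default 400 kyr), one stem per promoter type, three template
lineages per type radiating at 250 kyr, and private tip branches below
100 kyr. Mutations fall as Poisson counts `mu L t` per branch at unique
uniform positions (infinite sites), with `mu = 0.5e-9` per site per
year, `r = 3.3e-8` per bp per generation (3.3 cM/Mb), and `g = 29`
years — the study's constants. The three promoter sites are set by each
haplotype's assigned type, drawn per population from the study's
meta-population compositions (exact published count fractions). The
default panel (10 subpopulations x 25 samples) keeps the full pipeline
under a couple of minutes on one CPU; screen validations use 5
subpopulations x 20 samples so that forty seeded replicates stay cheap.

Star genealogies were chosen over a full coalescent deliberately: they
match the assumptions of the estimators being validated (Poisson-ML
TMRCA, expected pairwise differences) and keep every oracle closed-form.
Template-switch crossovers are planted at a small expected rate per
sampled haplotype (default 0.05) to emulate the *surviving* recombinants
seen in real panels; applying the raw map rate over the genealogy depth
would be a statement about the whole population's recombination history,
not about a star-shaped sample, and would swamp the planted structure.

`plant_introgression()` adds a donor lineage whose stem makes the total
modern–donor divergence `2 t_split mu L` in expectation, then copies
donor tracts of `Exponential(g / (r t_intro))` mean length (~17.6 kb at
50 kyr) — the first-order introgression tract model consistent with the
survival equation — onto recipient haplotypes at the configured
frequency, always covering the promoter triplet, plus private
post-introgression mutations. `synthetic_age_table()` emulates the
external variant-age resource: variants found exclusively on carriers
are dated near the introgression time (lognormal, sd 0.15 on the log
scale), as a frequency-based dating method would date variants that
entered the modern population at introgression; all others report their
true branch times. `simulate_archaic_diploids()` pairs donor-lineage
haplotypes into unphased diploids, forces one individual homozygous
(the phasing reference), optionally makes one a modern-template mosaic,
and N-masks sites at a configurable rate.

What the generator does **not** emulate: realistic site-frequency
spectra, linkage disequilibrium decay within the region, background
selection, or population growth. Passing tests therefore demonstrate
that the estimators and the screen behave correctly *under their own
model assumptions* and on planted truth — not that the region's real
haplotype structure satisfies those assumptions.

## Numerical conventions and edge cases

Coordinates are 1-based inclusive externally (VCF convention);
tract lengths are bp spans between flanking mismatches, exclusive of the
mismatch sites, with `N` never terminating a run. Jukes–Cantor requires
`p < 0.75` and errors on saturation. NJ branch lengths below zero are
clamped to 0 with the clamped total recorded; trees are unrooted unless
rooted on an explicit outgroup. Fisher's exact test is the proportion
comparison (exact at the small counts typical of rare haplotypes); the
underlying test for the published P = 0.258 comparison is unstated, so
that number is a convention here, not a reproduction target. The
Beta-bound, fold-difference and PPA operations are deterministic; every
stochastic function takes or derives from an explicit integer seed and
is byte-reproducible.

## Known limitations

The screen's sensitivity is inherited from its inputs: a lineage that
introgressed but recombined away its diagnostic divergence, or whose
type arose within the archaic lineage, shows no modern–archaic-band
difference and is invisible to it. HTL dating exposes its constant
precisely because the literature's constant is ambiguous; absolute ages
from `htl_to_age()` should be read with that caveat. The diploid
distance is a per-site minimum and therefore a lower bound on the
phase-aware distance. The pipeline's bootstrap is over filtered sites
only, mirroring the analysis it supports.
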