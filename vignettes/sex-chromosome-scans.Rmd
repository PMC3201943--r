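---
title: "Detecting sex-chromosome differentiation with microsatellites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-chromosome differentiation with microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microXY)
```

## The problem

In species with young sex chromosomes -- many fishes, amphibians and
reptiles -- the X and Y are cytologically similar and genome assemblies,
where they exist at all, usually represent only the X. Yet once
recombination between X and Y is suppressed, codominant markers begin to
record the divergence: a microsatellite locus inside the non-recombining
region accumulates a Y-specific allele, or loses its Y copy altogether.
`microXY` turns a panel of microsatellite genotypes, scored in phenotyped
females and males, into a locus-by-locus map of that differentiation.

Under male heterogamety the expected signatures are:

* **Fixed X/Y difference** (`XY_DIFFERENTIATED`): an allele present in
  males and absent in females; in the extreme, every male heterozygous
  X/Y and every female homozygous, giving strongly negative male
  $F_{IS}$, elevated between-sex $F_{ST}$ and a perfect sex association.
* **Y-linked null** (`Y_NULL`): the Y copy fails to amplify (deletion or
  primer-site divergence). Males are scored as homozygotes for their
  single X allele, producing zero male heterozygosity at a locus that is
  clearly polymorphic, positive male $F_{IS}$, and a male-only
  homozygote-excess (null allele) signal.
* **No differentiation** (`UNDIFFERENTIATED`): allele and genotype
  distributions indistinguishable between sexes.
* Monomorphic loci are `UNINFORMATIVE`: none of the statistics can be
  estimated.

## Statistics

Per locus and sex group the package reports the allele count $A$,
observed heterozygosity $H_O$, and the unbiased expected heterozygosity

$$ H_E = \frac{2n}{2n-1}\Big(1 - \sum_i p_i^2\Big), $$

with $n$ typed diploids and $p_i$ the sample allele frequencies.

Departures from random mating are measured with the Weir & Cockerham
(1984) variance-component estimators, the same estimators implemented by
FSTAT and GENEPOP. Within one group, the components $b$ (between
individuals within the group) and $c$ (between gametes within
individuals) are accumulated over alleles and

$$ \hat f = 1 - \frac{\sum_i c_i}{\sum_i (b_i + c_i)} $$

estimates $F_{IS}$; it is reported as undefined (never zero) for a
monomorphic group. Treating females and males as two subpopulations, the
full $a$, $b$, $c$ components give

$$ \hat\theta = \frac{\sum_i a_i}{\sum_i (a_i + b_i + c_i)} $$

as the between-sex $F_{ST}$. Both estimators are validated in the test
suite against an independent brute-force evaluation of the component
formulas on an enumerated suite of small genotype tables (agreement to
$10^{-10}$).

Significance is assessed by seeded permutation with the add-one rule
$p = (k+1)/(N+1)$, where $k$ counts permuted statistics at least as
extreme as the observed one (ties count as extreme, which is
conservative). Two schemes match the two nulls: $F_{IS}$ shuffles the
$2n$ allele copies among a group's individuals (random mating within the
group), $F_{ST}$ shuffles sex labels among individuals (no
sex-genotype association). The default is 10&nbsp;000 permutations;
$F_{IS}$ is tested two-sided because both heterozygote excess and
deficit are biologically meaningful here, $F_{ST}$ one-sided (only an
excess of differentiation indicates sex linkage). Whether classical
$F_{IS}$ permutation tests are one- or two-sided varies between
programs; both are exposed through `permute_p()`.

Sex association is additionally tested per allele with a
Cochran-Armitage trend test on the allele dosage (0/1/2 copies, scores
0, 1, 2; `stats::prop.trend.test`), and the locus-level p-value is the
smallest Holm-adjusted per-allele p-value. How multi-allelic loci should
be aggregated in a trend test is a genuine design choice -- the
per-allele-dosage rule used here is explicit and is stated in the
output, rather than hidden.

Genotypic linkage disequilibrium between locus pairs uses a
G log-likelihood-ratio statistic on the genotype-by-genotype table with
a genotype-permutation null (seeded), summed over population blocks. An
exact or Markov-chain test targets the same null; the permutation
version was chosen because it is seedable and its runtime scales
predictably.

Null alleles are diagnosed from the heterozygosity gap: Chakraborty's
$r = (H_E - H_O)/(H_E + H_O)$ and Brookfield's first estimator
$(H_E - H_O)/(1 + H_E)$, plus a randomization test for homozygote
excess that reassorts the group's allele copies into genotypes
(Hardy-Weinberg resampling). A null is "suspected" when the excess is
significant and $r > 0$. This whole-locus test replaces the size-class
breakdown some dedicated programs perform; only the binary per-sex
presence/absence call feeds the classifier, so the simplification does
not change downstream behaviour. The van Oosterhout estimator is
deliberately omitted.

All multiple-comparison families (each statistic across loci, LD across
pairs, per-allele trend tests within a locus, and the per-sex
homozygote-excess tests across loci) are corrected with the Holm
step-down procedure ("sequential Bonferroni"),
`stats::p.adjust(method = "holm")`. Correcting the null-allele family
matters in practice: with a dozen loci, an uncorrected 5% test will
flag a spurious female homozygote excess every few panels, and a
single such flag would veto a genuine Y-null call under the
male-only rule.

## Classification and region summary

`classify_locus()` applies, in order: `UNINFORMATIVE` if monomorphic;
`XY_DIFFERENTIATED` if a male-specific allele reaches carrier fraction
$\tau_m$ among typed males *and* Holm-corrected between-sex $F_{ST}$ is
significant; `Y_NULL` if no typed male is heterozygous *and* the
null-allele signal is present in males but absent in females; otherwise
`UNDIFFERENTIATED`. The default $\tau_m = 1$ demands the allele in every
typed male -- the strict pattern seen in low-diversity populations --
and can be relaxed (`tau_m = 0.5`, say) for high-diversity populations
where recurrent mutation lets an occasional male carry a different
allele; near-specific alleles (male-biased but seen in a female or two)
are surfaced as evidence flags, never auto-called. "No heterozygous
males" is evaluated on typed males only, and loci with more than 20%
missing males are flagged and excluded from the Y-null rule rather than
classified on thin evidence.

`summarize_regions()` orders classified loci by map position, merges
consecutive differentiated loci into intervals, and splits an interval
where an `UNDIFFERENTIATED` locus intervenes or where the class switches
between `XY_DIFFERENTIATED` and `Y_NULL` (the two classes reflect
different Y states, so a class switch is treated as a boundary);
monomorphic loci carry no information and never split. The headline
number is the span from the first to the last differentiated locus in
Mb (bp/10^6, 1 decimal), with the covered fraction available when the
user supplies a chromosome length -- the package does not download
assemblies. Physical positions are typically lifted from a related
reference genome; where an assembly segment is known to be inverted
relative to the genetic map, `reverse_segment_coords()` mirrors
positions within user-supplied segment bounds (the bounds are not
hard-coded because they are assembly-specific).

## The synthetic-data generator

`simulate_genotypes()` draws genotypes directly from the XY inheritance
model: females receive two independent draws from the X allele pool;
males one X draw plus either the fixed Y allele (`XY_DIFF`), a
duplicated score of their X allele (`Y_NULL` -- this is how a
non-amplifying Y manifests on a fragment gel, and it is what makes
homozygote-excess detection meaningful; emitting such males as missing
would destroy the signal), or a second X draw (`AUTOSOMAL`). The Y is a
single non-recombining haplotype shared by all males in a run, so LD
among Y-linked loci emerges without any linkage model; polymorphic Y
pools are not simulated by default. A stepwise mutation model (one
repeat unit, direction equiprobable) can perturb each transmitted
allele; mutation-rate defaults are 0 in the presets because empirical
per-locus rates for such markers are rarely known -- they are
placeholders, not estimates. Missing calls are inserted at a flat 2% in
the presets, a typical genotyping failure rate.

Two diversity regimes bracket the situations in which such scans are
attempted: `HIGH` draws an 8-allele X pool with symmetric Dirichlet(1)
frequencies (multi-allelic, per-locus $H_E$ mostly 0.5-0.9), `LOW` a
near-monomorphic pool (major allele at 0.998, $H_E \approx 0.004$). X
alleles sit on an even-size lattice and Y alleles on an odd one so that
stepwise mutation can never move a Y allele into the X pool -- a
bookkeeping convenience that does not affect any statistic. Three
presets package the two study designs: `PYOREALAMPI_LIKE` (24 females +
24 males, 14 loci, low diversity, 13 XY loci + 1 effectively
monomorphic autosomal locus), `BALTIC_LIKE` (the same layout at high
diversity), and `THREESPINE_LIKE` (25 females + 23 males, 14 loci
spanning 0.5-19.6 Mb: XY clusters at 3.2-4.0 and 9.4-11.8 Mb, Y-null
clusters at 5.1-7.4 and 14.7-19.6 Mb, two autosomal loci). Feeding the
threespine preset through the scan reproduces the four-region structure
and a 16.4 Mb differentiated span.

What the generator does **not** emulate: coalescent ancestry and drift
(allele frequencies are set, not evolved), linkage between loci beyond
the shared Y haplotype, allele-specific amplification artefacts other
than the all-or-nothing Y null, and scoring error. Passing recovery
tests on these simulations therefore demonstrates that the statistics
and decision rules behave as designed under the stated model -- not that
the classifier is robust to every failure mode of real fragment data.

## Primer design across species

For species without a sequenced genome, markers can be designed from a
related reference: find microsatellites in the reference region, align
it against an orthologous sequence from a *diverged* outgroup, and place
primers only where the two species agree -- sites conserved across that
distance are likely conserved in the unsequenced target too.
`find_ssrs()` reports maximal perfect 2-6 bp repeats (defaults: at
least 6 copies for di- and trinucleotides, slightly fewer for longer
motifs; homopolymers are never reported as higher-order repeats).
`conserved_windows()` aligns globally (match +1, mismatch -1, gap open
-2, extend -1 -- fixed, unpretentious scores; the method is not
sensitive to them at these identity levels) and keeps maximal gapless
stretches meeting identity and length thresholds.
`design_primer_pairs()` enumerates 17-25-mers in the flanking windows
with Wallace-rule Tm ($2(A{+}T) + 4(G{+}C)$; adequate at these lengths,
and trivially auditable) between 50 and 65 °C, GC 40-60%, product size
70-450 bp, pair ΔTm at most 5 °C, requires each primer to occur exactly
once in the supplied region (genome-wide specificity is out of scope),
and ranks by ΔTm then by product-size closeness to 200 bp. Reverse
primers get a 5' `GTTT` pig-tail, which promotes uniform
non-templated adenylation; Tm/GC always refer to the untailed core.

## Numerical conventions

* Undefined statistics propagate as `NA`, never as 0.
* Genotype pairs are unordered and stored sorted; Genepop round trips
  are exact.
* Permutation p-values can never be 0 (add-one rule) and are identical
  for identical seeds; every pipeline output is byte-identical across
  runs with the same inputs and seed.
* Mb values are bp/10^6 rounded to one decimal, so printed spans match
  arithmetic on printed boundaries.

## Problem sizes used in validation

The bundled checks run the permutation machinery at 999 permutations
(the 10&nbsp;000 default is for real analyses), the null-calibration at
1000 autosomal loci of 24+24 individuals, and the oracle-equivalence
suite over 300 random tables of up to 6 individuals and 3 alleles --
sizes chosen to exercise every code path at a few minutes' total
runtime while keeping Monte-Carlo error well inside the asserted
tolerances.

## Worked example

```{r example, eval = FALSE}
sim <- run_simulate(preset = "THREESPINE_LIKE", seed = 1,
                    outdir = "sim_out")
res <- run_scan("sim_out/genotypes.gen", "sim_out/sexes.tsv",
                map = "sim_out/marker_map.tsv", outdir = "scan_out",
                n_perm = 10000, seed = 1)
res$region$span_mb      # 16.4 on this design
res$region$intervals    # two XY and two Y-null intervals
```

## Known limitations

Only the two-group (female/male) partition is implemented -- no
hierarchical F-statistics, no exact HWE/LD tests, no bootstrap
confidence intervals over loci. The classifier assumes male
heterogamety; for ZW systems swap the sex labels. Null-allele inference
is necessarily indirect: a locus-wide amplification failure in males
mimics a Y null, which is why the missingness guard exists.
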