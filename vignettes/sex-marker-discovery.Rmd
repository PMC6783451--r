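---
title: "Discovering sex-linked markers from resequencing cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked markers from resequencing cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sexmarkr)
library(dplyr)
```

## The problem

Many fishes — tunas among them — show no external sexual dimorphism, and
their sex chromosomes are young and morphologically undifferentiated, so sex
cannot be read off a karyotype either. Yet a sex-determination (SD) region
leaves a precise population-genetic fingerprint. In a male-heterogametic
(XY) system the Y-linked allele at any site inside the recombination-
suppressed SD region is carried by every male and no female: every male is
heterozygous and every female homozygous at such a site. A ZW system is the
exact mirror. Given whole-genome genotypes for even a modest cohort (the
motivating study resequenced 15 males and 16 females of Pacific bluefin
tuna, *Thunnus orientalis*), this *strict sex-specific segregation* pattern
is so improbable under the null that single sites reach genome-wide
significance.

`sexmarkr` implements that discovery chain end to end:

1. **Scan** — per-site exact association between sex and genotype with an
   exact Hardy–Weinberg filter;
2. **LD structure** — confidence-interval (Gabriel) haplotype-block
   partitioning of candidate regions from unphased genotypes;
3. **Region report** — per-scaffold summaries and marker-region selection;
4. **Assay design** — in-silico PCR evaluation of presence-type,
   allele-specific and indel-size sex-identification assays;
5. **Synthetic cohorts** — a generator with planted SD regions and truth
   files, used for parameter-recovery validation throughout.

## The association model

At each biallelic site the cohort reduces to a 2-by-3 table of sex against
genotype class (hom-ref / het / hom-alt), with missing calls dropped per
site and per sex. The test is Fisher's exact test on that table: all tables
with the observed margins are enumerated and the hypergeometric
probabilities of those no more probable than the observed one are summed
(log-factorial space; a relative tolerance of `1e-7` absorbs floating error
in deciding "no more probable"). For a fully sex-specific site with $a$
homozygous females and $b$ heterozygous males the observed table is a
least-probable table for its margins and the p-value has a closed form:

$$p = \frac{1}{\binom{a+b}{a}} \quad (a \neq b), \qquad
  p = \frac{2}{\binom{2a}{a}} \quad (a = b),$$

the balanced case doubling because the column-reflected table ties the
observed probability exactly. With 16 females and 15 males,
$p = 1/\binom{31}{16} \approx 3.3\times10^{-9}$, below the conventional
genome-wide threshold of $5\times10^{-8}$; the threshold is crossed at
14 + 14 ($2/\binom{28}{14} = 4.99\times10^{-8}$) and missed at 13 + 13.
The fixed threshold stands in for explicit multiple-testing correction, as
is conventional in genome-wide scans.

```{r}
fisher_exact_2x3(c(16, 0, 0), c(0, 15, 0))
fisher_exact_2x3(c(16, 0, 0), c(0, 14, 0))  # one ungenotyped male
```

A site is reported **sex-specific** when it is significant *and* strictly
segregating (`male_het` or `female_het`); both facts are computed and
reported separately, because the threshold-first and strictness-first
readings of "sex-specific" coincide on clean data but can differ under
genotyping error. Whether the heterozygous sex is male or female at the
recovered sites is what identifies the heterogametic system
(`infer_heterogamety()`).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | `5e-8` | per-site significance threshold (strict `<`) |
| `hwe_threshold` | `1e-4` | exact-HWE filter cutoff |
| `hwe_scope` | `females_only` | stratum the HWE filter is computed on |
| `min_call_fraction` | `0.8` | per-sex genotyped fraction required |

The HWE filter (an exact test conditioning on allele counts) removes call
artefacts such as paralog-collapse heterozygote excess. Its scope defaults
to the *homogametic* stratum: a genuinely sex-linked site makes the
heterogametic sex maximally out of HWE, and the filter must not punish the
signal it is meant to protect. The scope is configurable because
case/control tools differ in which stratum they test. Note the filter is
only binding for pronounced distortions at this cohort size: an
all-heterozygous stratum of 16 has exact HWE $p = 1.3\times10^{-4}$, just
*above* a `1e-4` cutoff, whereas the same pattern across 31 samples is well
below it.

`min_call_fraction = 0.8` tolerates one to three missing calls per sex in
a 15/16 cohort — the motivating data themselves include a site genotyped
in only 14 of 15 males — while refusing sites so sparsely genotyped that
strictness becomes cheap. The homozygous class may be hom-ref *or*
hom-alt: which one appears depends only on which haplotype the reference
individual carried, and must not be baked into the definition.

Half-missing genotypes (`./1`) are mapped to missing: the upstream callers'
semantics for them are not consistent enough to count half a genotype.
Multiallelic records are dropped, not split — splitting would fabricate
sites the cohort was never tested at.

## Linkage-disequilibrium blocks

Within a candidate region, recombination suppression shows up as a block of
markers in complete mutual disequilibrium. Haplotype frequencies for each
marker pair are estimated from unphased genotypes by EM — only the double
heterozygote is phase-ambiguous; it is split between coupling and repulsion
resolutions in proportion to the current estimates, starting from linkage
equilibrium, to a `1e-10` fixed point (≤ 1000 iterations). From the fitted
frequencies: $D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$, $r^2$, and a LOD
(log10 likelihood ratio against $D = 0$ on the genotype data).

Uncertainty in $D'$ is summarised by a likelihood interval: the genotype
likelihood is evaluated on a $D'$ grid (step 0.001) with allele frequencies
held at their MLE, normalised, and the central `ci_mass` (default 0.90)
tail bounds taken. Pairs are classed as in the standard
confidence-interval block method: **strong LD** when `ci_low >= 0.70` and
`ci_high >= 0.98`, **strong recombination** when `ci_high < 0.90`. A
candidate block is a marker interval whose endpoint pair is strong LD and
in which at least 95% of *informative* pairs (strong LD or strong
recombination; "other" pairs carry no verdict) are strong LD; candidates
are accepted greedily by bp span without overlap. The motivating analysis
names the program that introduced this method but none of its parameters,
so the method's published defaults are adopted and every threshold is
exposed in `ld_config()`.

Two numerical notes. First, the EM leaves $O(\text{tol})$ residue in an
emptied haplotype cell, so $D'$ values within `1e-9` of 1 are snapped to 1
(the zero-cell identity). Second, when the MLE sits on the boundary
$D' = 1$, the upper likelihood-interval bound is the 5% upper-tail
quantile of a distribution whose mass lies strictly below the boundary —
typically 0.997–0.999 at $n = 31$ — so the interval does *not* bracket a
boundary MLE. That is authentic behaviour of the method (its strong-LD
rule only requires `ci_high >= 0.98`) and is asserted as such in the
tests.

Block finding over a whole scaffold is quadratic in markers; the pipeline
therefore partitions a window around each candidate scaffold's
sex-specific region (default margin 10 kb). All eligible markers in the
window participate, not only sex-specific ones — block bounds can and do
extend past the first significant site, as in the published region, whose
largest block starts 79 bp before the first male-specific SNP. Marker
eligibility requires minor-allele frequency ≥ 0.05 (sex-linked sites in a
balanced cohort sit near 0.25 and are unaffected).

All spans are 1-based inclusive (`last - first + 1`) — the convention is
not guessed but forced by the published tables' own arithmetic, which this
package re-verifies in its tests:

```{r}
block_span(3723703, 3726876)   # the published largest block
```

## Region report and marker selection

`summarize_scaffolds()` reduces a scan to one row per scaffold with
sex-specific sites: counts, region bounds (first to last sex-specific
position), and the maximum LD block. `select_marker_region()` then picks,
among scaffolds with strictly more than `min_sites = 10` sex-specific
variants, the one with the widest maximum block — span is the headline
criterion because the widest block marks the most extensively suppressed
recombination; the site count is the tie-break, and a `metric = "n_sites"`
switch inverts the priority for users who prefer marker density. Both the
"sites in block" and "sites in region" tallies are reported: block bounds
and region bounds need not coincide, so a single count would be ambiguous.

## In-silico PCR and sex calling

The assay model is deliberately sequence-level, not thermodynamic — the
wet-lab protocol specifies cycling conditions, which carry no information
a binding model could use. A primer binds where its 3′-terminal 3 bases
match exactly and it has at most 2 mismatches overall; every convergent
forward/reverse binding pair within 2 kb yields a product whose length is
the inclusive distance between the outermost 5′ ends. All thresholds are
arguments. Reverse-primer *sets* model allele-specific designs in which
two reverse primers are combined in one tube at equal concentrations.
Off-target artefact bands (the real assay shows a ~180 bp non-targeted
male band) are outside this model's scope.

Two decision rules cover the bench designs. The **presence** rule needs an
internal control product (mitochondrial ND4 in the original): male when
target and control amplify, female when only the control does,
undetermined when the control fails — so amplification failure is never
read as "female". The **size-dimorphism** rule reads a het indel as a
double band: two distinct target lengths = male, one = female, zero =
undetermined. Undetermined counts as *incorrect* in `assay_accuracy()`,
the conservative choice given that the real assay's weaker primer pairs
failed or mis-amplified in eight females.

Per-sample templates are built by substituting called alleles into the
reference window (`sample_haplotypes()`), het sites placing ref on one
haplotype and alt on the other — within an SD region in the heterogametic
sex this reconstructs the X-like and Y-like haplotypes exactly, since all
alternates travel on the sex-limited chromosome.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a resequencing
study of a wild cohort: 15 males + 16 females by default; background SNPs
with allele frequencies from a Beta(1, 3) truncated to [0.05, 0.5]
(rare-skewed like a site-frequency spectrum, but surviving the LD module's
MAF filter) and genotypes drawn under HWE independently of sex; one
planted SD region whose *core* sites are strictly segregating by
construction — the recombination-suppression signature itself; optional
*flank* sites that behave like core in each heterogametic sample with
probability `1 - flank_leak_prob` (default leak 0.3), emulating the
partially associated shoulder around a suppressed core; per-call
genotyping error (resampled uniformly over the two wrong classes — the
simplest model that can break strict segregation) applied before per-call
missingness; and an optional 8-bp core deletion as an assay fixture. A
single seed drives five documented substreams (positions/alleles,
genotypes, errors, missingness, reference), making every artefact
byte-reproducible.

The generator's defaults are the package's validation conditions: 10⁴
background sites on five 1-Mb scaffolds, a 30-site core at ~200 bp
spacing, error 0, missingness 0.02, and *no* flank sites — the planted
truth region is the core alone, so recovered bounds can be compared
exactly. Flanks are opt-in because a leaky flank site goes all-male-het
with probability $(1 - \ell + \ell \cdot 2p(1-p))^{15}$ (~3% per site at
$\ell = 0.3$), which would legitimately — not erroneously — extend the
detected region beyond the core.

What the generator does *not* emulate: coalescent background LD,
demographic structure, linked selection, read-level error profiles, or
reference bias. Passing parameter recovery therefore demonstrates that the
statistical chain is correct under its own assumptions, not that those
assumptions hold in any particular genome. Missingness can also
legitimately defeat recovery: with four missing calls a strict site can
land at $p = 1/\binom{27}{15} = 5.75\times10^{-8}$, just above threshold —
at 2% missingness this costs roughly half a percent of seeds, which the
validation's ≥ 95/100 pass mark absorbs.

```{r, eval = FALSE}
res <- purrr::map_dfr(1:100, function(s) recover_region(cohort_config(seed = s)))
summarise(res, recovered = sum(bounds_exact & scaffold_picked),
          clean = sum(n_background_fp == 0))
```

## Problem sizes and runtime choices

The shipped tests run the full validation at the sizes above: 100 seeded
cohorts of ~10⁴ sites for parameter recovery, 10⁴ random tables (total
≤ 40) against exhaustive-enumeration oracles for both exact tests, EM
against phased-haplotype counts at n = 500. Per-site p-values are memoised
on the 6-tuple of genotype counts (a 31-sample cohort admits only a few
thousand distinct tables per scan), and the D′ grid likelihood is
evaluated vectorised over the whole grid; grid step 0.001 keeps CI bounds
stable to one step against a 10× finer grid, which the tests verify.

## Known limitations

- Diploid, biallelic, autosome-style genotypes only; no haploid or
  polyploid systems, no multi-allelic LD.
- The block finder implements the confidence-interval method only (no
  four-gamete or solid-spine rules), and no haplotype phasing is output.
- The PCR model knows nothing of melting temperature, secondary structure
  or off-target amplification; it is a design *screen*, not a design
  *guarantee*.
- A cohort of 31 gives essentially no power below strictness: the scan
  finds sites where segregation is (near-)perfect, which is exactly the
  signature of a suppressed SD region but will miss leaky or polygenic
  sex determination.
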