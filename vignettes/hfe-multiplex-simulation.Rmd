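---
title: "Modeling a multiplex PCR-RFLP assay: signal model, calling rules and design choices"
author: "hfeRFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a multiplex PCR-RFLP assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfeRFLP)
```

# Scope and model overview

hfeRFLP is a computational twin of a multiplex PCR-RFLP genotyping assay
for the *HFE* variants C282Y and H63D. It has three layers:

1. a **sequence layer** (`findSites()`, `digestAmplicon()`,
   `buildFixtureTemplates()`): IUPAC-aware restriction-site scanning and
   complete in-silico digestion of synthetic template amplicons;
2. a **signal layer** (`simulateSample()`, `simulateBlank()`,
   `simulateMixture()`, `simulateCohort()`): converts ground-truth
   genotypes into capillary-electrophoresis peak tables with a noise
   floor, DNA-input response, saturation, STR stutter and two-person
   mixtures;
3. an **interpretation layer** (`genotypeSample()` and the QC
   functions): threshold filtering, digestion-control validation,
   codominant RFLP calls, STR allele calls, stutter statistics,
   contamination detection and identity matching.

The assay's safety property lives in the control logic: because each
diagnostic restriction site is unique, an undigested marker fragment is
ambiguous between "no site on either allele" and "the enzyme failed".
The co-amplified FZD1 fragment carries obligate sites for both enzymes
and is labeled on both primers, so its two terminal double-digest
fragments (114 and 147 bp) certify each enzyme independently. The caller
refuses to call any marker whose enzyme control did not pass
(`no_call`, reason `control_fail`) — a wrong homozygote is never
emitted.

# The assay panel

The panel is a declarative YAML document
(`inst/extdata/hfe_panel.yaml`), loaded and validated by `loadPanel()`.
The primer sequences and dye labels (ATTO 565, Yakima Yellow, FAM,
ATTO 550) are the assay's published multiplex. Three groups of constants
in the default panel are *fixture constants of this in-silico twin*, not
measured values, because the assay's documentation does not print them:

* the HFE amplicon lengths and diagnostic site positions (exon 2:
  208 bp, BspHI site starting at offset 77, labeled cut fragment 78 bp;
  exon 4: 390 bp, SexAI site at 247, cut fragment 248 bp), chosen so
  that all fragments in the shared ATTO 565 channel are at least 10 bp
  apart;
* the STR ladder offsets (`size = offset + 4·repeats + microvariant bp`,
  offset 140 for FGA, 120 for SE33), which fix where the allele ranges
  12.2–51.2 and 7–39.2 sit on the size axis;
* the synthetic allele-frequency table
  (`extdata/str_freqs_synthetic.csv`) used by `matchSamples()` — invented
  unimodal frequencies, clearly labeled synthetic. Published random-match
  probabilities depend on population data this package does not ship, so
  the Hardy–Weinberg product is exercised and tested arithmetically, not
  against a population value.

`loadPanel()` additionally enforces channel separability: no two
expected fragment sizes in one dye channel may be closer than 1.0 bp
(the caller's resolution). The check is deliberately *not* part of the
S4 validity method so that intentionally conflicting panels can be
constructed and inspected with `validateChannelSeparability()`.

## The control fragment's failure sizes

The assay's description reports 171 and 204 bp as the labeled control
fragments seen when SexAI or BspHI respectively fails, alongside
114 + 147 bp for the successful double digest of the 309 bp amplicon.
Those four numbers are not mutually consistent with one linear fragment
layout (114 + 147 leaves a 48 bp middle fragment, which would put the
single-digest products at 162 and 195 bp). The package keeps both,
deliberately decoupled:

* the **panel configuration** stores 171/204 as the sizes the caller
  matches and the simulator emits in a digestion-failure scenario —
  these are interpretation constants of the assay definition;
* the **sequence fixture** built by `buildFixtureTemplates()` uses the
  self-consistent 114 | 48 | 147 layout, so sequence-level digestion
  obeys fragment-length conservation exactly.

The two never meet in one code path, and the discrepancy is surfaced
here rather than silently resolved.

## Allele–site polarity

Whether the variant allele creates or destroys each diagnostic site is
config-driven (`variant_creates_site`). The default is `TRUE` for both
markers, by analogy with the classical RsaI/MboI RFLP designs for these
variants which the replacement enzymes emulate. Flipping the flag
inverts the genotype mapping and is covered by a unit test.

# The signal model

The simulator is intentionally simple and fully parameterized; its
defaults are calibrated to the assay's qualitative anchors rather than
to any instrument physics.

| quantity | default | unit | rationale |
|---|---|---|---|
| reference peak height `hRef` | 8000 | RFU | mid-dynamic-range signal at the reference input |
| reference DNA input | 25 | ng | midpoint of the 15–50 ng working window |
| height scaling | linear in input | — | template-limited amplification below saturation |
| multiplicative noise | lognormal, sdlog 0.15 | — | peak-height CVs of ~15% typical of CE |
| control (FZD1) efficiency | 0.2 | — | makes the control digest peaks the first casualties of low input |
| noise peaks | Poisson(8) per dye | — | sparse baseline |
| noise heights | Uniform(0, 50) | RFU | noise ceiling of the blank runs |
| size jitter | Uniform(±0.3) | bp | sub-bp mobility scatter, < half the 1 bp bin |
| saturation | 32000 | RFU | detector ceiling; heights clip exactly here |

An expected allele peak is `hRef · (input/25) · efficiency · share`,
where `share` is the allele's fraction of the marker's template (½ per
heterozygous allele). These choices jointly reproduce the anchors the
tests assert: at 2 ng the FZD1 digest peaks are visible but below the
250 RFU analytical cutoff; from 10 through 200 ng every true-allele
peak lies within [250, 32000] RFU; at 200 ng the ceiling is actually
reached.

Stutter is simulated for every STR allele peak as a single companion
exactly one repeat unit (4 bp) shorter, with ratio drawn from
`Normal(mean, SD)` truncated at zero (FGA 0.080 ± 0.024, SE33
0.106 ± 0.024) and applied to the *realized* parent height, so the
configured ratio distribution is recovered exactly by measurement.
n+1 ("plus") stutter, pull-up between dyes, the plus-A artifact,
degradation and size-standard modeling are deliberately out of scope;
passing tests therefore say nothing about real data exhibiting those
artifacts.

Mixtures: a "1:d" mixture assigns the minor contributor a template
share of `r/(1+r)` with `r = 1/d` (one part contaminant to d parts
main). Shared alleles and a minor allele landing in a major allele's
stutter bin simply add, which is what makes that placement adversarial.
A whole-enzyme digestion failure is a property of the reaction; in a
mixture the major contributor's flag governs the mix.

Peak tables bin at 1.0 bp: co-binned true peaks merge by summing
heights (size by height-weighted mean), co-binned *noise* fluctuations
merge by maximum so a blank can never exceed its own ceiling, and
clipping is applied after merging so no reported peak ever exceeds
saturation.

# Calling rules and numerical conventions

* All size matching uses ±1.0 bp; the height cutoff is inclusive
  (`height >= cutoff`), fixing the behavior of a peak at exactly
  250 RFU.
* `deriveCutoff()` rounds the blank maximum up to the nearest 10 RFU
  before multiplying, so 43.2 RFU noise and a 5× multiplier still give
  250.
* STR designations: `(size − offset) / 4`, remainder in bp as the
  microvariant decimal (remainder 2 → x.2). A peak one repeat below a
  *taller* peak is classified as stutter and excluded from allele
  status; of the survivors the two tallest are the call (ties broken by
  height, then lower designation), further survivors are
  `extraAlleles`, and out-of-range designations are recorded as
  off-ladder rather than raised as errors.
* Heterozygote peak-height balance is *not* required for a het call;
  no published ratio rule exists for this assay, so imbalance checks
  are out of scope and flagged here as an implementer convention.
* `no_call` reasons are a controlled vocabulary: `control_fail`,
  `amplification_fail`, `no_peaks`, `ambiguous`.

A consequence of the "one repeat below a taller peak" stutter rule,
inherited deliberately from the assay's analyst logic: a *balanced*
heterozygote with adjacent alleles (d, d+1) is occasionally miscalled
homozygous when noise makes the d peak slightly the smaller one. Two
mitigations are built in. The stutter *estimator* excludes candidate
ratios above 0.5 — a "stutter" half as tall as its parent is a second
allele, and without this guard those near-1 ratios would bias the
calibration mean upward by about a percentage point. The contamination
*detector* applies no such guard: there, a near-1 stutter ratio is
precisely the evidence wanted.

# Contamination detection

Three evidence kinds, any one of which flags the sample (the assay
description does not state whether a lone RFLP finding should flag, so
the inclusive default is used):

1. `extra_str_allele`: more than two surviving non-stutter designations
   at a locus;
2. `elevated_stutter`: a stutter-position peak whose ratio to its
   called parent exceeds the locus's `mean + 2·SD` calibration
   threshold (0.128 for FGA, 0.154 for SE33 at the nominal calibration
   values);
3. `extra_rflp_peak`: more allele-state peaks (sizes matching a
   marker's cut/uncut fragments within 1 bp) in a marker channel than
   one genotype can explain.

With two-state markers and 1 bp binning, rule 3 can only fire on
pathological tables (e.g. two distinct bins both matching one expected
size); in simulated mixtures, detection is carried by the two STR rules
— which is also how the adversarial 1:10 mixture presents: the hidden
minor allele raises a stutter ratio to roughly `mean + 1/d` while the
minor's other alleles appear as extra designations.

The decision geometry at the detection limit is tight by construction:
at 1:25 the adversarial stutter bin gains about 4.0 percentage points
against a 2 SD margin of 4.8, so single replicates flag with
probability near 0.4 — below, but not far below, a majority vote. The
package therefore (a) calibrates the threshold on 400 simulated pure
samples, keeping its sampling error small relative to that 0.8 pp
margin, and (b) takes the majority over 200–300 seeded replicates per
ratio. Under those conditions the majority decision is positive at 1:1
and 1:10 and negative at 1:25 and 1:100, and single-replicate detection
rates decrease monotonically with dilution. The elevated-stutter rule's
nominal one-sided tail (~2.3% per measurable allele, union over up to
four alleles per sample, plus the adjacent-allele ambiguity above)
implies a per-sample false-positive rate on pure samples of roughly
10–15%, which the test suite bounds rather than hides.

# Problem sizes used by the tests and acceptance script

All simulations are desk-scale and seeded: 100 blank runs for the noise
ceiling (20 for the cutoff derivation); 20 seeds × 5 input levels for
the dynamic range; 600–1,000 single-source samples (≈1,100–1,900
measurable alleles) for stutter calibration, plus a 22-sample series
(~40 alleles) matching the scale of a manual calibration; 200–300
replicates per mixture ratio with a 400-sample calibration cohort; and
the 60-sample cohort composition (genotype classes of sizes
18/11/9/8/6/5/2/1) for end-to-end recovery. The oracle-based
site-scanning property runs 135 random sequences of 500–2,000 bp
against a brute-force IUPAC-expansion search.

# Known limitations

* The sequence fixtures are synthetic: primers and diagnostic sites are
  embedded in random filler scrubbed of off-target sites, so they test
  the engine's contracts, not genomic context (SNPs under primers,
  paralogy, CG-rich mobility shifts).
* Fragment sizes are exact integers plus bounded jitter; real CE size
  calling drifts with the size standard and temperature.
* The stutter model is a single n−1 companion with a locus-wide ratio
  distribution; real SE33 stutter varies with its compound repeat
  structure, and n+1 stutter exists.
* Heterozygote balance, degradation, pull-up and off-scale artifacts
  are not modeled; the S65C variant is represented only as a silent,
  mutable template position (which is the assay's claim about it).
* The match-probability output is only as meaningful as the supplied
  allele-frequency table; the bundled table is synthetic.
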