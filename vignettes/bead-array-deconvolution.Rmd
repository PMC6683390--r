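---
title: "Deconvolving platelet antibody specificities from bead-array reactivity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving platelet antibody specificities from bead-array reactivity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpadeconv)
```

## The measurement and the inference problem

A glycoprotein-capture bead assay reads out, for each serum sample, one MFI
per (panel donor × capture bead) cell. Each bead captures one platelet
membrane glycoprotein — GPIIb/IIIa (home of the HPA-1, HPA-3 and HPA-4
systems), GPIbα/IX (HPA-2), GPIa/IIa (HPA-5), optionally CD109 (HPA-15) — or
HLA class I. An alloantibody against allele *x* of system *X* can only
produce signal on the bead capturing *X*'s glycoprotein, and only for donors
whose genotype at *X* contains *x*. The inference problem is the inverse:
given which donors light up on which beads, and the donors' genotypes, which
antibody specificities are in the serum?

`hpadeconv` formalises the manual plate-reading logic in three stages:
cutoff estimation, reactivity calling, and consistency-based deconvolution.

## Cutoffs and reactivity

Per bead, `cutoff = mean + 3·SD` over negative-control sera pooled across
panel donors, with MFI ≥ cutoff positive (inclusive). Two deliberate choices:

* **Sample SD (n−1), not population SD.** Validation panels are small
  (8 control sera is typical); the n−1 estimate is larger, hence the more
  conservative (higher) cutoff — the safer clinical default. `sd_mode =
  "population"` switches this.
* **Pooled per bead, not per bead×donor.** One cutoff per bead is how such
  assays are validated and reported; a per-donor mode would quadruple the
  control burden for little gain at these signal separations.

Reactive values below `grey_factor × cutoff` (default 1.25) carry a
*borderline* flag. The grey zone exists because a threshold rule is brittle
within a few percent of the threshold: the packaged fixture itself contains a
lone reading 14% above cutoff (sample S2, donor G3, GPIIb/IIIa) that the
reference interpretation ignored. Rather than silently raising the cutoff or
silently calling it, the pipeline reports it: a bead whose reactive donors
are *all* borderline is excluded from the final call and flagged
`borderline_only`; if, additionally, no candidate specificity can explain
the pattern, `unexplained_reactivity` is flagged too. Both flags are visible
in the JSON report and the summary table.

## Deconvolution: minimal consistent sets

For one glycoprotein bead, with reactive donors `R` and non-reactive donors
`N`, a set `S` of candidate specificities is **consistent** iff

1. every donor in `R` carries ≥ 1 allele implicated by `S` (the antibody has
   an antigen to bind), and
2. no donor in `N` carries any implicated allele (a non-reacting carrier
   falsifies the hypothesis).

Carriage ignores antigen dosage: `ab` and `aa` carriers are equivalent. MFI
magnitudes in real plates do not separate heterozygotes from homozygotes
reliably, and the reference interpretations never use dosage.

`infer_bead()` enumerates candidate subsets in cardinality order up to
`max_set_size` (default 2 — one specificity per glycoprotein is the common
case and two covers reported mixtures), keeps consistent sets, drops
non-minimal ones, and ranks by (cardinality ascending, prior score
descending, lexicographic). An independent brute-force oracle
(`oracle_infer()`, all 2^k subsets, pairwise-subset minimality) ships in the
package and is held equal to the incremental search on thousands of random
panels in the test suite.

**Priors, not hard-coding.** On a panel whose donors are all HPA-1aa *and*
HPA-4aa, an all-reactive GPIIb/IIIa bead is equally consistent with
anti-HPA-1a and anti-HPA-4a; no genotype can separate them. The shipped
prior table (`default_priors()`, editable CSV) encodes that HPA-4/6/21w
alloantibodies are vanishingly rare in the populations this assay serves, so
anti-HPA-1a outranks anti-HPA-4a — an explicit, auditable tie-break (logged
`by=prior` in verbose runs) rather than a buried constant. Prior weights are
unitless plausibilities in [0,1]; only their order within equal-cardinality
ties matters.

Beads are deconvolved independently and the HLA bead is never subtracted
from glycoprotein beads: the assay class shows no cross-reactivity between
the HLA and glycoprotein channels, and any leakage would surface as
`unexplained_reactivity` rather than silently biasing calls. HLA positivity
is sample-level (any reactive donor): per-donor HLA patterns depend on the
donors' unknown HLA types, so they are reported but not interpreted.

### What the panel can and cannot resolve

Informativeness is a property of the donor panel. `load_panel()` warns about
specificities lacking a carrier or a non-carrier, and every call object
carries `uninformative:` flags so a negative is never over-read — on the
packaged four-donor panel, anti-HPA-1b is structurally undetectable (no
HPA-1b carrier). `resolvable_specificities()` goes further and computes the
panel's effective repertoire by a noise-free round trip per candidate; for
the packaged panel that is anti-HPA-1a/2a/2b/3a/3b/5a/5b plus anti-HLA.
Anti-HPA-4a is *consistent* but never *called* (shadowed by the
higher-prior anti-HPA-1a), and two specificities on one bead collapse into
a single parsimonious explanation — both are limitations of any
four-donor design, not of the implementation.

The CD109/HPA-15 bead is defined in the shipped configuration but disabled:
detection on this chemistry is unreliable (CD109 is low-abundance and labile
in stored platelets). Enabling it is a one-line config change.

## Titration

`endpoint_titer()` implements the endpoint definition exactly: the largest
dilution factor with MFI ≥ cutoff; right-censored when the last measured
point is still positive; titer 0 (no defined concentration) when nothing is.
No 4PL/logistic fit is attempted — endpoint dilutions are what this assay
class reports — and non-monotone series (prozone/hook effects) keep the
endpoint rule but warn. `to_concentration()` divides the reference-standard
potency by the titer; the default 100 IU/mL corresponds to the NIBSC
anti-HPA-1a standard (03/152) and reproduces both conventional conversions
(1:512 → 0.195 IU/mL, 1:64 → 1.56 IU/mL at 3 significant figures).

## The synthetic generator: a stated world

`simulate_assay()` draws reactive cells from a log-normal signal
(`10^N(3, 0.3)` by default — positives one to two decades above background,
as on real plates) and everything else from a normal truncated at zero
(mean 60, sd 25 — typical negative wells), with anti-HLA samples hitting
each donor's HLA bead independently with probability 0.75 (partial patterns
are the norm since donor HLA types differ). Dilution series decay
geometrically with per-doubling retention ρ (default 0.65) on top of the
background. Everything is reproducible from one integer seed.

What a green synthetic test establishes: the cutoff geometry, the
deconvolution algebra and the flag plumbing work end to end at realistic
signal separation (≈97–99% exact-truth recovery per seed at defaults, the
residual failures being borderline draws, background false positives and
all-donors-miss HLA Bernoulli draws — and those carry flags). What it does
not establish: robustness to plate effects, bead-count variation, prozone,
cross-reactive clones or operator drift, none of which the generator models.

Two numerical notes on the decay model. First, the default ρ = 0.65 is a
round value near the head of real standard-serum series; the geometric-mean
step ratio of the canonical anti-HPA-1a series is ≈0.59 and its tail implies
≈0.55, so a noise-free ρ = 0.65 series with neat amplitude 16,800 is still
above a 75.1 cutoff at 1:1024 (censored) — tests that need a 1:512 endpoint
set ρ = 0.55 explicitly. Second, `analytic_titer()` provides the closed-form
crossing point of the noise-free model and is held equal to
`endpoint_titer()` across a parameter grid in the acceptance suite.

## Degenerate inputs and numeric edges

* MFI exactly at cutoff: reactive (≥ is inclusive, by definition).
* Missing (sample, donor, bead) cells: flagged, excluded from both `R` and
  `N`; inference proceeds on measured donors.
* `R = ∅`: no explanation sets (and no flags) — an unreactive bead is not
  evidence of absence for uninformative specificities, hence the separate
  `uninformative:` channel.
* Negative MFI, duplicate triples, thousands separators, unknown ids:
  schema errors (CLI exit 2), never coerced.
* sd = 0 noise degenerates the generator to its two means exactly; cutoff
  then equals the background constant and every truth round-trips.

## Known limitations

Single-antigen HLA resolution, auto- vs allo-antibody discrimination, and
quantitative strength modelling from MFI magnitudes are out of scope. The
deconvolution is exact but combinatorial; it is intended for the 4–12
candidate specificities of real bead panels, not for hundreds. Calls are
only as good as the genotype table: a genotyping error silently re-labels
explanations, which is why every run logs the cutoffs used, the tie-breaks
taken and the flags raised.
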