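---
title: "Virtual crossmatch assessment and multi-laboratory survey analysis with vxmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual crossmatch assessment and multi-laboratory survey analysis with vxmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vxmkit)
```

## The problem

Before an organ transplant, the recipient's anti-HLA antibody profile must be
checked against the donor's HLA type. The traditional instrument is the
*physical crossmatch* (PXM): donor lymphocytes incubated with recipient serum,
read by flow cytometry (FCXM) or complement-dependent cytotoxicity (CDCXM).
Modern practice increasingly replaces the prospective PXM with a *virtual
crossmatch* (VXM): an interpretation of single-antigen-bead (SAB) antibody
data against the donor typing, without any wet-lab step. The VXM is fast and
cheap, but it inherits every limitation of the SAB assay: donor alleles that
are simply not on the bead panel, antibodies against eplets shared across many
antigens, several weak donor-specific antibodies (DSA) that may act additively
on a cell even though each bead looks unimpressive, and complement behaviour
that MFI does not reveal.

vxmkit implements both halves of the workflow that proficiency-testing
programs exercise across laboratories:

1. a **VXM engine** — DSA calling against a donor typing, FCXM/CDCXM
   prediction, organ-specific risk stratification, and an explicit
   recommendation of whether a physical crossmatch is still needed; and
2. a **survey layer** — consensus grading of multi-laboratory submissions,
   inter-laboratory MFI dispersion statistics, VXM-versus-PXM concordance,
   and a synthetic survey generator that reproduces the archetypal
   discordance scenarios so the whole pipeline is testable end to end.

## HLA nomenclature and the lookup tables

Donor typings arrive at mixed resolution: two-field alleles (`A*02:05`),
one-field groups (`A*02`), serologic antigens (`B65`), and alpha/beta
heterodimers for DQ/DP (`DQA1*01:04/DQB1*05:01`). `parse_hla()` canonicalizes
all of these; null/expression-variant suffixes and three/four-field names are
rejected because silently accepting them would corrupt DSA matching, and the
package deliberately does not attempt full nomenclature coverage (G/P groups,
NMDP ambiguity codes).

Matching logic consults two plain-CSV tables that users can replace or
extend:

* `equivalence.csv` maps alleles to split and broad serologic antigens and
  records the Bw4/Bw6 motif of every B-locus antigen (plus the A-locus
  antigens with a Bw4 association). The shipped table covers the antigens
  needed by the worked examples plus the common catalogue around them. DR
  antigens are encoded split-only (DR12 is not broadened to DR5) because
  antibody-survey consensus is reported at split level; B-locus broads
  (B65 under B14, B38 under B16, ...) are kept because shared-motif
  reasoning needs them.
* `eplets.csv` maps eplet names to carrier antigens. Carriage can be
  `confirmed` or `unverified`; the latter records antigens where only
  specific, unnamed alleles carry the eplet (16Y on DR12/DR14), which
  `eplets_of()` excludes but `eplet_carrier_status()` surfaces as
  `"unknown"` rather than a hard yes/no.

Bw4/Bw6 are modelled as attributes of B-locus antigens, not as a locus:
they are public motifs, and for reactivity analysis they behave exactly like
shared eplets.

## DSA identification

`identify_dsa()` walks the donor typing in decreasing stringency:

1. **allele** — a bead carrying exactly the donor allele. Heterodimer
   matching requires both chains when both are typed; when only one side can
   be compared (a beta-only bead against a heterodimer typing, or vice
   versa) the beta-chain match is accepted and tagged `beta_chain_only`,
   since laboratories commonly report beta-led specificities.
2. **antigen** — for donor entries given at group or serologic resolution,
   beads whose serologic equivalents cover the entry.
3. **surrogate** — when the donor allele is absent from every panel,
   positive beads in the same antigen group (or sharing a serologic
   equivalent) stand in for the untested allele. A donor allele that *is*
   represented but below cutoff yields nothing and suppresses surrogates:
   the assay answered the question.
4. **eplet-inferred** — `flag_shared_eplet()` reports each eplet carried by
   a donor specificity for which the panel holds at least two carrier beads
   and *all* of them are positive (the characteristic low-MFI "stacking"
   pattern). The two-bead minimum exists because a single positive carrier
   is indistinguishable from an ordinary single-antigen reactivity.

Positive beads matched at allele/antigen level support exactly one call;
surrogate calls may reuse beads, because the same same-group beads
legitimately stand in for several untested alleles. A call's representative
MFI is the **maximum** over its supporting beads — conservative, and
consistent with reports quoting a single representative MFI per DSA.

## Crossmatch prediction

Numeric MFI-to-crossmatch thresholds are center-specific by design; the
package ships declared conventions (`prediction_thresholds()`), all
calibratable:

| parameter | default | rationale |
|---|---|---|
| `t_fcxm` | 3000 MFI | a ~2100 MFI C-locus DSA should predict negative; a ~12000 MFI class I DSA clearly positive |
| `b_fcxm` | 2000 MFI | B cells express class I and II; lower than the T threshold |
| `cdc` | 10000 MFI | CDC requires strong antibody |
| `locus_weights` | C = 0.5, DP = 0.5 | lower cell-surface expression of HLA-C; laboratories' higher C/DP cutoffs |
| `additive` | TRUE | multiple low-level DSA may have an additive effect; toggleable |
| `indeterminate_band` | ±25% | borderline-strength calls need a third outcome; the width is a convention |

The T-cell signal aggregates class I calls only; the B-cell signal all calls.
Eplet-inferred candidates are **excluded from the aggregate signal**: they
carry the MFI of beads that are not donor antigens, and letting them add
signal would flip the modal prediction positive in exactly the scenarios
where real laboratories predict negative. Instead they act through the
indeterminate band and the PXM recommendation. A surrogate or eplet-inferred
call whose weighted MFI lands within the band around a threshold makes that
prediction `indeterminate`.

CDC prediction never turns positive on MFI alone: without
complement-binding information (e.g. a C1q result), any FCXM-positive signal
yields `indeterminate`. This encodes the observed failure mode in which most
laboratories predicted a positive CDCXM from a very high MFI while the
physical CDCXM was consensus negative. A separate AHG-augmentation pathway is
not modelled: its semantics are not defined well enough to encode, and the
complement-binding flag covers the decision-relevant distinction.

Risk stratification bands the peak weighted MFI (< 1000 low, 1000–4999
moderate, ≥ 5000 high) and applies a configurable one-band downgrade for
combined kidney/liver transplants: reported risk assessments for
kidney/liver recipients spread one band below the same laboratories'
kidney-alone assessments, and a deterministic single-band shift reproduces
that modal spread.

`recommend_pxm()` is deliberately conservative: any surrogate or
eplet-inferred call, any indeterminate prediction, any DSA within the
borderline band of an applicable threshold (the CDC threshold only when CDC
prediction is enabled), or a donor entry with zero representation on a
supplied panel of its class triggers a recommendation, each with a
machine-readable reason code.

## Survey grading and statistics

Crossmatch analytes reach consensus at ≥ 80% agreement, antibody
specificities at ≥ 90%, both inclusive and both requiring at least 10
informative laboratories for grading. Laboratories answering outside
positive/negative ("other", indeterminate) leave the denominator but are
tallied separately. All percentages and %CV values round half away from zero
(`round_half_up()`): this convention reproduces every printed
(mean, SD, %CV) triple in the shipped challenge statistics (e.g.
6603/15164 → 43.54 → 44) and every printed count percentage (42/52 → 80.77 →
81), where banker's rounding would not. The SD is the sample standard
deviation (n − 1), the standard choice for inter-laboratory surveys; the
source tables do not state the convention, so it is recorded here as a
package decision. With a single reporting laboratory the SD is undefined by
default (`single_sd = "na"`), with an opt-in zero.

Percentage denominators for "%labs reporting a DSA" default to the
laboratories submitting that cell/serum pair (not the whole survey
membership); `dsa_summary(..., denominator = "all")` switches.

## The synthetic survey generator

`generate_survey()` emulates the statistical structure the analysis assumes,
one cell/serum combination at a time:

* **MFI dispersion** — each laboratory draws every bead log-normally around
  the bead's true value, parameterized so the *linear-scale* CV equals
  `interlab_cv`. MFIs are positive and right-skewed, and observed inter-lab
  CVs of 19–61% are the only dispersion facts available, so the log-normal
  with a CV dial is the natural minimal model.
* **Cutoff heterogeneity** — 66% of laboratories draw a cutoff uniformly in
  500–1000 MFI, 34% in 1001–2000 MFI, matching the reported distribution of
  laboratory practice. Reporting censoring is mechanistic: a laboratory
  whose own draw falls below its own cutoff reports no DSA, which is what
  produces "%labs reporting" strictly between 0 and 100 for low-level DSA.
* **Assessment** — each laboratory's DSA report and virtual predictions come
  from running the package's own engine on its noisy panel, with a small
  log-normal jitter (`threshold_jitter = 0.1`) on its prediction thresholds.
  A fraction `eplet_analysis_rate` (default 0.3) of laboratories performs
  eplet-pattern analysis; the rest call DSA by cutoff alone. Real surveys
  show exactly this split: most laboratories reason from bead MFIs, a
  minority reports shared-eplet patterns in comments.
* **Physical crossmatch** — per-laboratory Bernoulli draws from a logistic
  model on the weighted true DSA signal (laboratories disagree on the PXM
  too). No quantitative MFI-to-PXM link is established in the literature
  used here; the logistic is a declared stand-in and each preset's
  intercept/slope encodes its scenario's documented physical outcome.

All draws flow from one seeded stream in fixed order, so identical
configurations are byte-identical and datasets differing only in a true MFI
share all other randomness — which is what makes the censoring-monotonicity
property exactly testable.

Five presets encode the archetypal discordance scenarios, with true MFIs
taken from their worked examples: `low_level_dsa` (a 1377 MFI class I DSA
near the cutoff range, CV 0.44), `off_panel_allele` (donor A\*02:05 absent
from the panel, A\*02:01 as surrogate), `c_locus_only` (Cw5/Cw6 DSA at
10024/8924), `shared_eplet` (off-panel DRB1\*13:02 with all 96HK/11STS
carrier beads stacking at 1201–1336, physical B-cell FCXM forced positive,
CV 0.19 at the low end of the observed range so the stacking pattern stays
coherent), and `high_mfi_cdc_negative` (a 12235 MFI B8 DSA, physical CDC
modelled consensus-negative).

What the generator does **not** emulate: bead chemistry and lot effects,
prozone/inhibition, serum-treatment effects, denatured-antigen false
positives, correlated errors between laboratories sharing a vendor, and any
real link between antibody titer and CDC positivity. Passing pipeline tests
on synthetic surveys therefore demonstrates internal consistency of the
statistical machinery under the declared model, not clinical validity on
real laboratory data.

## Numerical and testing choices

* Positivity and consensus comparisons are inclusive (`>=`): cutoff
  attainment is positive — the conservative patient-safety reading of
  reported cutoff ranges — and "≥ 90%" consensus wording is taken literally.
* Degenerate inputs: an empty donor typing, an empty panel file, duplicate
  bead specificities, mixed-class panels, negative MFIs and malformed HLA
  names are hard errors with row/token context; a specificity missing from
  the equivalence table is *not* an error (empty equivalents, caller
  decides).
* Tie-breaks: calls are sorted by descending MFI, then donor target and
  match mode, so outputs are deterministic under equal MFIs.
* The matching engine is cross-checked against an independent brute-force
  enumerator over random small instances (panels up to 10 beads, up to 6
  donor entries), and the suite runs 500 such instances; scenario tests use
  50 laboratories and parameter recovery 200, sizes at which the checked
  properties are stable while the full suite stays fast.

## Known limitations

* The equivalence and eplet tables are deliberately small; production use
  against arbitrary typings requires extending them (both are plain CSV).
* Thresholds, weights and bands are conventions to be calibrated per
  center; the defaults reproduce the documented example patterns but are
  not clinical guidance.
* Normalized-MFI computation is out of scope; normalized values are
  accepted as input only.
* The C1q/complement pathway is a boolean flag, not a titer model.
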