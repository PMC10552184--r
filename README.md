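# vxmkit

Virtual crossmatch assessment and proficiency-survey analysis for HLA
(histocompatibility) laboratories.

Before a transplant, a recipient's anti-HLA antibody profile — measured as
mean fluorescence intensity (MFI) on single-antigen beads (SAB) — is checked
against the donor's HLA typing. Increasingly this *virtual crossmatch* (VXM)
replaces the prospective physical crossmatch (PXM: flow-cytometry FCXM or
complement-dependent-cytotoxicity CDCXM). The VXM fails in characteristic
ways: donor alleles missing from the bead panel, antibodies against eplets
shared across many antigens (Bw4/Bw6, 96HK, 11STS, ...), several weak
donor-specific antibodies (DSA) acting additively, and complement behaviour
invisible to MFI. vxmkit is for laboratory scientists and
proficiency-testing (PT) programs who need these mechanics as tested,
reproducible code.

## What it implements

**VXM engine.** `parse_hla()` handles mixed-resolution nomenclature
(two-field alleles, one-field groups, serologic antigens, DQ/DP
heterodimers). `identify_dsa()` matches SAB panels against a donor typing
with four match modes — `allele`, `antigen`, `surrogate` (same-group beads
standing in for off-panel donor alleles) and `eplet_inferred`
(`flag_shared_eplet()`: every carrier bead of a donor eplet positive,
"stacking"). `predict_fcxm()`/`predict_cdcxm()` aggregate locus-weighted
MFIs (T cells: class I; B cells: class I + II; sum or max):

```
signal_cell = aggregate over DSA d ( w(locus_d) * MFI_d ),   positive iff signal >= threshold
```

with an indeterminate band (default ±25%) for borderline surrogate or
eplet-inferred calls, and CDC prediction that stays indeterminate without
complement-binding information. `risk_stratify()` bands peak weighted MFI
per organ, and `recommend_pxm()` returns reason codes for when a physical
crossmatch is still warranted.

**Survey layer.** Consensus grading with the PT rules — crossmatch analytes
at ≥ 80% agreement, antibody specificities at ≥ 90%, minimum 10
laboratories (`grade_crossmatch()`, `grade_specificity()`) —
inter-laboratory statistics (`summarize_dsa()`: mean, sample SD, %CV =
round-half-up(100·SD/mean)), concordance tables (`concordance()`), and a
synthetic multi-lab survey generator (`generate_survey()`) with presets for
the archetypal VXM/PXM discordance scenarios.

## Worked example: an off-panel donor allele with shared-eplet stacking

A donor types as `DRB1*13:02`, an allele absent from the class II panel.
The other DR beads carrying the 96HK/11STS eplets all react weakly:

```r
library(vxmkit)

donor <- donor_typing("case-donor", "DRB1*13:02")
panel <- sab_panel(data.frame(
  bead_id     = paste0("b", 1:10),
  specificity = c("DRB1*13:01", "DRB1*13:03", "DRB1*11:01", "DRB1*12:01",
                  "DRB1*08:01", "DRB1*14:01", "DRB1*03:01", "DRB1*03:02",
                  "DRB1*01:01", "DRB3*01:01"),
  raw_mfi     = c(1201, 1336, 1280, 1220, 1250, 1260, 1300, 1310, 90, 120)),
  serum_id = "case-serum")

vxm_assess(donor, panel)
#> <vxm_result> donor case-donor
#>   DSA:
#>     DRB1*13:02               eplet_inferred MFI   1336 (6 beads) via 11STS
#>     DRB1*13:02               eplet_inferred MFI   1336 (8 beads) via 96HK
#>     DRB1*13:02               surrogate      MFI   1336 (2 beads)
#>   FCXM prediction: T negative, B negative
#>   CDCXM prediction: T negative, B negative
#>   Risk: kidney=moderate, heart=moderate, lung=moderate, pancreas=moderate, kidney_pancreas=moderate, kidney_liver=low
#>   Physical crossmatch recommended: yes [off_panel_allele, shared_eplet]
```

Reading the output: the donor allele is off-panel, so the two DR13 beads act
as *surrogates* (representative MFI 1336, the maximum over supporting
beads); all eight 96HK-carrier and all six 11STS-carrier beads are positive,
so both eplets are flagged as *eplet-inferred* candidates. The weak
surrogate signal keeps the B-cell FCXM prediction negative — yet the
assessment still recommends a physical crossmatch, because inferred
reactivity to a shared eplet can produce a positive B-cell FCXM that the
bead MFIs understate. That is precisely the discordance this scenario is
known for.

The survey side works on plain vectors and tibbles:

```r
summarize_dsa(c(1000, 2000, 3000), n_submitters = 3)
#> <summary_stats> 3 labs (100%), mean MFI 2000, SD 1000, CV 50%

grade_crossmatch(rep(c("positive", "negative"), c(81, 19)), analyte = "T-cell FCXM")
#> <consensus_result> T-cell FCXM
#>   n = 100
#>   agreement: 81 % -> positive (graded)
```

A thin command-line front end is included:

```sh
Rscript inst/cli/vxm.R assess --donor donor.csv --panel class2.csv --out result.json
Rscript inst/cli/vxm.R simulate --scenario shared_eplet --n-labs 50 --seed 7 --out survey/
```

## Package layout

- `R/hla_core.R` — nomenclature parsing, equivalence/eplet tables
- `R/antibody_panel.R` — SAB panel model, CSV I/O, cutoff positivity, YAML config
- `R/vxm_engine.R` — DSA identification, predictions, risk, PXM recommendation
- `R/survey_grading.R` — consensus grading, %CV statistics, concordance
- `R/synthetic_survey.R` — scenario presets and the survey generator
- `inst/extdata/` — equivalence, eplet and published challenge-statistics CSVs
- `vignettes/virtual-crossmatch-methods.Rmd` — the model, its assumptions and design choices
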