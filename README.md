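# mlpadose

Copy-number analysis of the **HEXB** gene (Sandhoff disease) from MLPA
fragment data, for molecular-diagnostics and research users who need
exon-level deletion calls from peak tables rather than raw traces.

Multiplex ligation-dependent probe amplification (MLPA) ligates a probe
pair on each target locus and co-amplifies all ligation products with one
universal primer pair, so each probe's capillary-electrophoresis peak
height tracks its target's copy number. The package implements the full
dosage analysis around a 17-probe HEXB panel — 14 exon-specific probes
plus reference probes in *ACTR1a*, *AFAP* and *ALB*:

1. **Binning** — observed peaks are assigned to panel probes by expected
   amplicon size (tolerance 1.5 nt).
2. **Dosage quotient** — for sample *i* and probe *p*,

   ```
   raw[i,p]  = height[i,p] / Σ_ref height[i,ref]          (cancels sample scale)
   r[i,p]    = raw[i,p] / mean_controls(raw[·,p])         (cancels probe efficiency)
   ```

   so `r ≈ copy_number / 2` for a cohort of diploid controls (n = 8 by
   default).
3. **Calling** — threshold bands: `0.75 ≤ r ≤ 1.25` → 2 copies,
   `0.25 ≤ r < 0.75` → 1 copy, `r < 0.25` → 0 copies, `r > 1.25` → gain.
4. **Segmentation** — maximal runs of reduced exons become deletion calls
   with zygosity.

It also ships a seeded synthetic peak-table generator with the noise
structure the method assumes (per-probe efficiency, per-sample scale,
multiplicative lognormal noise), a parser and catalog for the HGVS-style
Sandhoff-disease genotypes (14 patients, 16 distinct alleles, 9 novel),
and frame arithmetic for splice-event transcript consequences
(exon skips, partial skips, cryptic acceptors).

## Worked example

Simulate a heterozygous carrier of the 16-kb promoter–exon-5 deletion
against 8 diploid controls and call it:

```r
library(mlpadose)
panel <- default_hexb_panel()
set <- simulate_set(panel, n_controls = 8,
                    cases = list(preset_genotype("del2_het", panel)),
                    noise = noise_model(cv = 0.05, sample_scale_cv = 0.15),
                    seed = 1)
res <- mlpa_call_sample(panel, set$controls, set$cases[[1]]$peaks)
res$segments
#>   gene exon_start exon_end     zygosity
#> 1 HEXB          1        5 heterozygous
round(res$ratios$normalized, 2)
#>  HEXB_ex01  HEXB_ex02  HEXB_ex03  HEXB_ex04  HEXB_ex05  HEXB_ex06  HEXB_ex07
#>       0.46       0.49       0.46       0.52       0.50       0.94       1.00
#>  HEXB_ex08  HEXB_ex09  HEXB_ex10  HEXB_ex11  HEXB_ex12  HEXB_ex13  HEXB_ex14
#>       1.06       1.02       0.93       0.93       0.89       0.91       0.98
#> REF_ACTR1a   REF_AFAP    REF_ALB
#>       0.95       0.98       1.05
```

Exons 1–5 sit near 0.5 (one copy) and everything else near 1 (two
copies), so the segmenter reports a single heterozygous exons-1–5
deletion. The genotype catalog and the splice presets:

```r
str(sd_catalog_summary()[1:4])
#> List of 4
#>  $ n_patients          : int 14
#>  $ n_distinct_genotypes: int 13
#>  $ n_distinct_alleles  : int 16
#>  $ n_novel_alleles     : int 9
minigene_consequences("c.1242+1G>A")
#> $exon10_skip
#> splice consequence: 73 nt removed, frameshift
#> $exon10_skip_plus_cryptic
#> splice consequence: 185 nt removed, frameshift
```

A thin command-line wrapper over the same functions is in
`inst/scripts/mlpa-dose` (subcommands `simulate`, `call`, `catalog`,
`splice`). The methods vignette
(`vignettes/mlpa-dosage-analysis.Rmd`) documents the model, the band
conventions, the simulator's assumptions and the package's design
decisions.

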