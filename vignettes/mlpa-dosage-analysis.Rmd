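---
title: "MLPA dosage analysis for HEXB: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLPA dosage analysis for HEXB: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpadose)
```

## The measurement model

Multiplex ligation-dependent probe amplification (MLPA) quantifies locus
copy number by ligating probe pairs on genomic DNA and co-amplifying all
ligation products with one universal primer pair. Because every product
competes in the same PCR, a probe's peak height on capillary
electrophoresis is proportional to how many target copies were present —
up to two nuisance factors this package's dosage quotient is built to
cancel:

* a **per-probe amplification efficiency** \(e_p\) (probes ligate and
  amplify unequally, but reproducibly), and
* a **per-sample scale** \(s_i\) (DNA input, PCR yield, injection).

The height model is
\[
  h_{ip} \;=\; B \, e_p \, \frac{c_{ip}}{2} \, s_i \, \varepsilon_{ip},
\]
with \(B\) a baseline height, \(c_{ip}\) the integer copy number and
\(\varepsilon_{ip}\) multiplicative noise. The **raw dosage ratio** divides
each probe's height by the summed heights of the three reference probes
(ACTR1a, AFAP, ALB — loci assumed diploid in every sample), which cancels
\(s_i\) exactly. Dividing by the average raw ratio of a diploid control
cohort then cancels \(B e_p\), leaving
\[
  r_{ip} \;\approx\; \frac{c_{ip}}{2}.
\]
So 1 means two copies, 0.5 a heterozygous deletion, 0 a homozygous
deletion. Copy states are called from threshold bands: 0.75–1.25 → 2
copies, 0.25–0.75 → 1 copy.

## The HEXB panel

`default_hexb_panel()` defines 17 probes: targets for HEXB exons 1–14 and
the three reference probes. The amplicon sizes are synthetic constants on
an 8-nt grid (94 + 8(k−1) nt for exon k; references at 210/218/226 nt): a
real assay's product sizes are a property of its oligo design, which this
package does not model. What matters analytically is only that sizes are
unique and separated by more than twice the binning tolerance, which
`validate_panel()` enforces.

The **size tolerance** defaults to 1.5 nt. Capillary sizing is
sub-nucleotide accurate in the 90–230 nt range, and with 8-nt spacing any
tolerance below 4 nt makes peak-to-probe assignment unambiguous: each
observed peak can then be within tolerance of at most one probe, and the
greedy nearest-match assignment in `bin_peaks()` is provably the optimal
one (the test suite cross-checks it against a brute-force optimal matcher
on jittered inputs anyway).

## Band boundaries and extrapolated states

The published bands ("between 0.75 and 1.25", "between 0.25 and 0.75")
leave boundary inclusivity and the behaviour outside [0.25, 1.25]
unstated. The package's convention, chosen so every ratio gets exactly one
state:

| normalized ratio r | copy state |
|---|---|
| r < 0.25 | 0 |
| 0.25 ≤ r < 0.75 | 1 |
| 0.75 ≤ r ≤ 1.25 | 2 |
| r > 1.25 | gain |

States 0 and gain are extrapolations beyond the two defined bands: a
missing target peak yields raw ratio 0 by convention (the homozygous
deletion signature), and gains, while not part of the deletion assay's
design, are needed for a total calling function. Both are flagged as such
here rather than hidden. A probe whose normalized ratio is undefined
(e.g. absent from the control reference) is called `indeterminate` and
never enters a deletion segment. All three band edges are configurable via
`calling_bands()`.

Control aggregation uses the arithmetic **mean** of the raw ratios, the
aggregation the dosage method defines; `build_control_reference()` offers
a median mode for robustness, off by default. A per-probe control CV above
0.10 attaches a dispersion warning, since a noisy cohort erodes the margin
between the 1-copy and 2-copy bands.

## What the simulator emulates — and what it does not

`simulate_sample()` draws from exactly the height model above: per-probe
efficiencies lognormal with mean 1 and sdlog 0.3 (drawn once per panel
under a fixed internal seed, so they behave as a panel property the
control normalization must remove); per-sample scale lognormal with CV
`sample_scale_cv` (default 0.15); per-peak lognormal noise with CV `cv`
(default 0.05, a typical per-probe reproducibility for a well-optimized
MLPA run and one that keeps an 8-control cohort comfortably inside the
diploid band); observed sizes jittered uniformly within ±0.5 nt. Probes at
copy 0 emit no peak. Reference probes are pinned at copy 2 — the ratio
formula makes a reference CNV unidentifiable, so the simulator refuses to
encode one rather than silently misrepresent it.

Deliberately **not** simulated: electropherogram traces (dye channels,
stutter, pull-up, baseline), partial-digestion or ligation artifacts,
inter-run drift, mosaicism, and reference-locus CNVs. Passing tests
therefore demonstrate that the normalization and calling arithmetic are
correct under the method's own assumptions, not that the assay is robust
to artifacts the model excludes; real-data QC still matters, which is why
`qc_sample()` fails any sample with a missing or weak reference signal.

The default study design mirrors the assay's validation setup: 8 diploid
controls plus the two deletion controls — a heterozygous exon-2 deletion
(`del1_het`, the 2.4-kb deletion) and a heterozygous promoter–exon-5
deletion (`del2_het`, the 16-kb deletion). At the default noise levels the
test suite measures exact segment recovery (correct exon range and
zygosity) across 100 seeded runs and requires ≥ 99%; the observed rate is
printed by the test.

## Genotype catalog

The packaged catalog ships the 14 Sandhoff-disease genotype strings and
the 9 alleles annotated as previously unpublished. The parser accepts only
the dialect these strings use — cDNA substitutions with optional intronic
offsets, small deletions with spelled-out sequence, and two named large
deletions — full HGVS is out of scope. Allele identity is the
whitespace-stripped cDNA description: protein and RNA annotations are
carried but ignored for identity, so `c.445+1G>A (r.0)` and `c.445+1G>A`
unify, matching allele counting at the DNA level. The unknown allele `?`
is excluded from allele counts (this reproduces the published count of 16)
but kept in genotype keys, so a genotype with one uncharacterized allele
still counts as one genotype. The named large deletions (`16Kbdel`,
`c.299+1471_408del2406`) are opaque keys, not coordinate-resolved — their
breakpoints live in prior literature, and nothing downstream needs them.

## Splice-event arithmetic

`apply_events()` computes what a set of splice events removes from the
mature transcript and whether the loss preserves the reading frame; it is
arithmetic only. Premature-stop positions (the `fsX` annotations) require
the actual cDNA sequence and are carried as annotations, never recomputed.
The minigene presets encode the characterized outcomes: exon-8 skip
(181 nt, frameshift), 87-nt partial skip of exon 9 (in frame — 29 codons;
note 87/3 = 29, and the deletion annotation p.E362_K390del spans 29
residues, although the loss is sometimes quoted as 28 amino acids), and
for c.1242+1G>A two isoforms, the 73-nt exon-10 skip and the 73 + 112 =
185-nt skip-plus-cryptic-acceptor product, both frameshifts. The cryptic
acceptor 112 nt inside exon 11 is also used by the normal construct, so it
appears as its own preset. Two recorded inconsistencies: the exon-8 skip
is quoted both as 181 nt (transcript-size result, used here) and 178 nt
(figure legend, recorded in the preset's notes and used nowhere).

Exon lengths in the preset model are real where a full skip fixes them
(exon 8: 181 nt, exon 10: 73 nt) and synthetic placeholders elsewhere
(exons 7, 9, 11) — partial events only need the exon to be long enough,
and the placeholders never enter a computed consequence.

## Numerical and degenerate-input choices

* Peak binning is deterministic: candidates ordered by absolute size
  difference, ties broken by smaller expected size, then input position;
  peak order never matters.
* An empty peak table parses fine and fails QC downstream, rather than
  erroring at read time.
* A control sample with a zero raw ratio aborts reference building — a
  cohort member with a deletion would silently bias every call.
* `simulate_set()` derives per-sample seeds from the master seed via one
  `sample.int()` draw, so the whole simulate → call pipeline is
  reproducible from a single integer, and results are identical across
  sessions.
* Problem sizes throughout the tests (8-control cohorts, 100-seed recovery
  loops, 20 random genotypes for the noiseless oracle) are chosen to match
  the study design the method was built around while keeping the suite
  fast to run routinely.

## Worked example

```{r example}
panel <- default_hexb_panel()
noise <- noise_model(cv = 0.05, sample_scale_cv = 0.15)
set <- simulate_set(panel, n_controls = 8,
                    cases = list(preset_genotype("del2_het", panel)),
                    noise = noise, seed = 1)
res <- mlpa_call_sample(panel, set$controls, set$cases[[1]]$peaks)
res$segments
round(res$ratios$normalized, 2)
```

## Limitations

Single target gene plus references only; no confidence intervals on
ratios (the band margins stand in for them); no mosaicism (non-integer
copy states land in whichever band they fall); heights, not areas, carry
the signal, and `.fsa` trace parsing is out of scope — the CSV peak table
is the package's interchange format.
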