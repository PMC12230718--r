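# irescan

Prediction and scoring of iron-responsive elements (IREs) in RNA and DNA
sequences.

IREs are cis-acting stem-loop motifs, mostly in the untranslated regions of
iron-metabolism mRNAs (ferritins, transferrin receptor, ferroportin, DMT1,
ALAS2, HIF-2α, ...), that bind the iron regulatory proteins IRP1/IRP2.
Binding to a 5′UTR IRE represses translation; binding to a 3′UTR IRE
stabilizes the transcript. Mutations that disturb the element — notably at
its N7·N25 closing pair — underlie human disease, so finding and grading
candidate IREs is a recurring task for the iron-biology community. This
package is for researchers who want that search as a scriptable, offline,
reproducible library rather than a web form.

## The model

The canonical element is a hairpin: a 6-nt apical loop N14–N19
(5′-CAGWGH-3′ in the classical motif, with an N14·N18 cross-loop
interaction), a 5-bp upper stem (N9–N13 · N24–N20), an unpaired bulge
nucleotide N8 on the 5′ strand (canonically C; U or G in validated
variants), the N7·N25 first lower-stem pair, and optionally one extra
unpaired 3′-strand nucleotide before N25. Scanning proceeds in three
stages:

1. **loop matching** against a curated registry of 23 degenerate patterns
   covering 22 motifs (18 legacy + noncanonical and U8-bulge additions,
   including an 8-nt extended loop);
2. **candidate assembly** of every stem interpretation within defect
   limits (≤1 mismatched pair, ≤1 single-nt stem bulge by default; G·U
   wobbles count as paired), recording every defect;
3. **scoring**: `score = 8 − Σ penalties` over stem defects, motif class,
   the (heavily penalized) N7·N25 defects, discordance with the
   minimum-free-energy structure of the candidate in context
   (ViennaRNA's `RNAfold`, or a built-in approximate fallback), and
   non-negative ΔG. Scores map to six confidence categories
   (High … Very-low) pooled into high/medium/low tiers for benchmarking.

With CDS coordinates, each prediction is placed in one of five transcript
locations (5′UTR, 5′UTR-CDS, CDS, CDS-3′UTR, 3′UTR, with a strict <15-nt
junction window around start and stop) and annotated with the distances
d5′IRE-AUG, dCAP-5′IRE and dTER-3′IRE.

## Worked example

Build a perfect classical-motif element with a 6-bp lower stem, plant it in
a random 120-nt background, and scan the padded record with CDS annotation:

```r
library(irescan)
fx  <- build_core("1", lower_stem = 6, seed = 11)
pl  <- plant_core(fx, 120, 41, seed = 12, seq_id = "demo_tx")
ctx <- list(demo_tx = transcript_context("demo_tx", 91, 240, 400))
res <- find_ires(setNames(paste0(pl$seq, strrep("A", 280)), "demo_tx"),
                 cds = ctx)
res
#> IRE scan (batch mode, vienna engine): 1 prediction(s) in 1 record(s)
#> scoring config: 2849ba405432c5371f1d1bb84cde0fba
#>   seq_id motif_id start end score category delta_g location
#>  demo_tx        1    47  65     8     High   -23.4     5UTR
res$predictions[, c("concordance", "d5_ire_aug", "d_cap_5ire")]
#>   concordance d5_ire_aug d_cap_5ire
#> 1           1         35         55
```

The planted element is recovered at its true coordinates (core 47–65): a
perfect classical candidate, all six model base pairs present in the MFE
structure (concordance 1), free energy −23.4 kcal/mol, the maximum score of
8 (category High), located in the 5′UTR with its midpoint 35 nt upstream of
the start codon and 55 nt from the cap. Every penalty is itemized per
prediction in interactive mode (`mode = "interactive"`), and
`evaluate_predictions()` / `benchmark_report()` grade a labelled control
set by sensitivity, specificity, precision and balanced accuracy per
pooled tier.

A thin command-line wrapper lives at `inst/cli/irescan.R`
(`scan`, `fixtures`, `bench` subcommands).

See `vignettes/ire-prediction.Rmd` for the full model, the penalty
calibration and its rationale, and known limitations.

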