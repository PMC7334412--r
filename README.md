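# nkgate

Automated, reproducible gating for **CD56-negative (CD56^neg^) NK cells**
in multi-parameter flow cytometry, built around an **NKp80-based
identification strategy** and the machinery needed to evaluate it against
the classical CD16-based gate.

## The problem

Human NK cells are usually CD56+, but a rare CD56^neg^ subset — expanded
in chronic HIV infection and multiple myeloma — has classically been
gated as CD56^neg^CD16+. That definition is fragile twice over:

* **CD16 is unstable.** It is shed from the cell surface (ADAM17/MMP25)
  after target-cell or cytokine stimulation and is down-modulated by
  cryopreservation, so the CD16 gate loses exactly the activated cells a
  functional assay is trying to measure.
* **CD16 is not NK-specific.** After a standard dump gate
  (viability/CD3/CD14/CD19), CD16+CD56^neg^ events still include CD123+
  pDC- and basophil-like cells and other CD16+ non-NK cells. These lack
  the NK lineage transcription factor **Eomes**, which serves as the
  ground-truth identity marker.

NKp80 (*KLRF1*), an activating receptor on essentially all mature NK
cells, is stable under freezing and stimulation; a
CD56^neg^NKp80+ gate is therefore purer (higher %Eomes+) and retains
functional (CD107a/IFNγ/TNF-positive) cells that the CD16 gate drops.

`nkgate` implements this comparison as a fully synthetic, label-aware
pipeline — no patient data are required or included:

1. **Synthetic cohorts** (`build_cohort`): 17-population PBMC model with
   per-marker two-state Gaussian intensities on the arcsinh scale,
   donor-level compartment jitter, ground-truth labels per event, disease
   presets (HD, untreated HIV, HIV+cART, multiple myeloma) and
   perturbation models (cryopreservation, K562 and IL-12+IL-18
   stimulation with preferential CD16 shedding on degranulating cells).
2. **Gating** (`estimate_panel_thresholds`, `apply_strategy`,
   `builtin_strategies`): per-channel cutoffs from a two-component
   Gaussian mixture on arcsinh(x/150) (equal-posterior boundary,
   quantile fallback for unimodal channels), and hierarchical strategies
   — `nkp80`, `cd16`, `cd7_cd16`, `cd7_only`, `cd300a`, `tb4`,
   CD16×NKp80 `quadrants`, `cd56dim`, each with and without CD123 in the
   dump channel.
3. **Metrics** (`subset_stats`, `donor_table`): per-donor frequencies,
   Eomes purity, CD123 contamination, MFIs, FSC medians, functional
   positivity.
4. **Statistics** (`paired_compare`, `group_compare`): two-sided
   Wilcoxon signed-rank (exact for ≤ 25 non-zero pairs) and
   Mann–Whitney U tests.
5. **Figure-analog reports** (`reproduce`, `run_report`) and **FCS 3.1
   I/O** (`read_fcs`, `write_fcs`) plus a CLI (`nkgate_cli`).

## Worked example

```r
library(nkgate)

# a 5-donor healthy cohort, 20,000 events per donor
cohort  <- build_cohort(cohort_config("HD", n_donors = 5,
                                      n_events = 20000, seed = 42))
an      <- analyze_cohort(cohort, treatments = "stim_K562")
tab     <- donor_table(an)

purity <- function(strategy) {
  rows <- tab$strategy == strategy & tab$subset == "target" &
          tab$treatment == "none"
  mean(tab$pct_eomes_pos[rows])
}
round(c(cd16 = purity("cd16"), nkp80 = purity("nkp80")), 1)
#>  cd16 nkp80
#>  42.3  74.0

cc <- paired_compare(
  tab$pct_eomes_pos[tab$strategy == "cd16"  & tab$subset == "target" &
                    tab$treatment == "none"],
  tab$pct_eomes_pos[tab$strategy == "nkp80" & tab$subset == "target" &
                    tab$treatment == "none"],
  label = "Eomes+ purity: cd16 vs nkp80", labels = c("cd16", "nkp80"))
cc
#> <nk_comparison>  Eomes+ purity: cd16 vs nkp80
#>   wilcoxon_signed_rank: statistic = 15, p = 0.0625
#>   direction: nkp80 larger, effect = 33.69
```

Roughly 42% of events in the CD16 gate are Eomes+ (true NK) versus ~74%
in the NKp80 gate; the paired signed-rank test (here at its exact
minimum for n = 5) favours NKp80 in every donor. At the default cohort
size (20 donors × 50,000 events) the difference is significant at
p < 0.0001, about 20% of CD56^neg^NKp80+ events are Eomes−, and the
CD56^neg^CD16+NKp80− quadrant is ~50% CD123+.

Figure-analog tables, summaries and plots:

```r
study <- run_study(seed = 42, n_donors = 5, n_events = 20000)
fig   <- reproduce("2B", study)   # Eomes+ % per CD16xNKp80 quadrant
run_report(study, out_dir = "report")   # all figures + index.csv
```

## Command line

```sh
Rscript inst/cli/nkgate.R simulate --condition HD --donors 2 \
    --events 1000 --seed 7 --out sim/
Rscript inst/cli/nkgate.R gate --fcs sim/HD_donor01.fcs \
    --strategy nkp80 --out membership.csv
Rscript inst/cli/nkgate.R metrics --dir sim/ --out stats.csv
Rscript inst/cli/nkgate.R reproduce --figures 1A,2B --seed 42 --out report/
```

`simulate` writes one FCS 3.1 file per donor (float data, linear `$PnE`,
`$PnN` = channel id, `$PnS` = marker), a `*_truth.csv` sidecar with
per-event ground-truth labels, and a `manifest.yaml` recording every
resolved parameter including per-donor seeds.

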