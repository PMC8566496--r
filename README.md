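# pol2wave

Time-resolved RNA polymerase II occupancy, pausing and recycling
dynamics from timed ChIP-seq.

## The problem

CDK9 inhibitors (e.g. flavopiridol) block the release of promoter-paused
RNA Pol II into productive elongation without stopping polymerases that
are already elongating.  Sampling Ser2-phosphorylated Pol II ChIP-seq at
timed points *during* inhibition and *after* washout turns a static
occupancy snapshot into a movie: during the block the elongating cohort
drains 3'-wards (a "retreating wave") while terminated polymerase that
is handed back to the promoter — *recycled* — accumulates there; after
washout the queued cohort is released as an "emerging wave" whose
leading edge moves at the elongation velocity.  Comparing a control
against a recycling-factor-depleted condition on these readouts asks
whether the factor is required for Pol II transcriptional recycling.

pol2wave is for analysts working with such block/washout time courses
(aligned reads in, statistics and reports out).  It provides:

* **Coverage tracks** — BED6 reads, 5'-anchored fragment extension
  (default 300 bp), normalisation to a common sequencing depth
  (default 5×10⁷ reads), bedGraph/bigWig I/O.
* **Pausing statistics** — each gene is split into a 5'-end bin
  [TSS−50, TSS+200), a gene-body bin [TSS+200, TTS−500) and a 3'-end
  bin [TTS−500, TTS+500); the **5' pausing ratio** is
  `pr5 = d5/dbody` and the **3' release ratio** `rr3 = d3/dbody`,
  where `d*` are mean per-nucleotide densities.
* **Metagenes and promoter decay** — scaled gene-body metagene
  profiles, TSS/TTS-anchored profiles, per-gene promoter-density time
  series, percent decrease `100·(1 − median(t1)/median(t0))`, and
  Kruskal–Wallis comparisons between conditions.
* **Wave dynamics** — the wave front as the position where 5'→3'
  cumulative gene-body mass first reaches a quantile (0.9 leading /
  0.1 trailing edge); the elongation rate as the OLS slope of the
  median front against time; a recycling index (slope of median
  promoter density during the block over a gene-body baseline); and a
  two-condition report with a recycling-defect flag.
* **A kinetic simulator** — initiation → pause → release → elongation
  → termination → recycling with a drug block/washout schedule,
  emitting BED read sets plus ground truth, so the whole pipeline is
  testable offline.

## Worked example

Simulate a control (recycling probability ρ = 0.9, velocity
2000 bp/min) against a depleted condition (ρ = 0.2, 1200 bp/min) over
the 0/10/20/40-min block and washout design, then analyse the dataset
directory end to end:

```r
library(pol2wave)

sched <- drug_schedule()                       # 60-min block, 4+4 samples
make_timecourse(list(control  = sim_config(rho = 0.9, v = 2000, seed = 1),
                     depleted = sim_config(rho = 0.2, v = 1200, seed = 2)),
                sched, "demo_ds")
res <- run_analyze("demo_ds", "demo_report")
res$report
```

```
Condition report
   condition   phase time median_pr5 median_rr3 median_d5 n_valid
1    control   block    0   4.71e-02     0.0743     151.0      50
2    control   block   10   2.72e+01     0.1130   67160.4      50
3    control   block   20   7.57e+01     0.1277  176565.5      50
4    control   block   40   2.11e+02     0.1193  383696.0      50
5    control washout    0   3.93e+02     0.1311  542850.5      50
6    control washout   10   3.03e-02     0.0428      96.5      50
...
9   depleted   block    0   4.89e-03     0.0707      18.5      50
12  depleted   block   40   1.23e-01     0.0718     314.0      50
13  depleted washout    0   3.51e+01     0.0963   55812.0      50
...

Control vs depleted:
            metric control depleted  delta
1  recycling_index    4.03  0.00264 -4.024
2 percent_decrease   99.97 99.74378 -0.225

Recycling defect flagged: TRUE
```

Reading the numbers: in the control, the median 5' pausing ratio climbs
from 0.05 to 211 across the 40-min block — terminated polymerase is
recycled to promoters where the block traps it — and the recycling
index (slope of median promoter density per minute over the gene-body
baseline) is 4.0/min.  The depleted condition barely accumulates
(index 0.003), and after washout its promoter signal empties less
completely (smaller percent decrease), so the report flags a recycling
defect.  `demo_report/` also contains the per-gene ratio table,
metagene profiles, summary tables, `report.json` and plots.

A command-line wrapper with the same functionality ships in
`inst/scripts/pol2wave` (`pol2wave simulate --config config.yaml --out
ds/`, `pol2wave analyze --dataset ds/ --out report/`); an example YAML
configuration is in `inst/extdata/example_config.yaml`.

## Further reading

The methods vignette (`vignettes/pol2wave-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, numerical choices and degenerate-input policies, the design
of the validation studies, and the known limitations of the simulator
as a stand-in for real ChIP-seq data.
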