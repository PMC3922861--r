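# cazyscreen

Multi-evidence screening for candidate regulators of cellulase and
hemicellulase (CAZyme) genes in lignocellulolytic fungi.

## The scientific problem

Fungi like *Trichoderma reesei* are industrial workhorses for
lignocellulose-degrading enzymes, yet the transcription-factor network
that induces those enzymes is incompletely mapped. A productive way to
nominate new regulators is to screen every regulatory-class gene (e.g.
fungal Zn2-C6 / C6 zinc-cluster domains) against evidence that it
behaves like the enzyme genes it might control:

1. **Broad induction** — differentially induced on ≥ 3 lignocellulosic
   substrates (Avicel cellulose, wheat straw, spruce, sophorose) versus
   a time-matched uninduced control;
2. **Co-expression** — member of the fuzzy c-means clusters holding the
   known cellulase/hemicellulase reference genes;
3. **Production correlation** — chemostat expression correlated with
   the specific protein production rate (|r| ≥ 0.5);
4. **Proteome support** — concordant protein-level change;
5. **Co-localization** — inside a co-regulated genomic region or
   adjacent to a CAZyme/transporter gene.

`cazyscreen` implements the full pipeline plus a synthetic-data
generator with planted ground truth, so the whole screen is verifiable
without any external data.

## The core method, briefly

Per (substrate, time) contrast the package uses an empirical-Bayes
moderated *t*: gene variances get a scaled-inverse-χ² prior
(*d*₀, *s*₀²) fitted by moment matching on log *s*²; the statistic

> *t̃* = (x̄ᵢ − x̄꜀) / (*s̃* √(1/nᵢ + 1/n꜀)),  *s̃*² = (*d*₀*s*₀² + *d s*²)/(*d*₀ + *d*)

is referred to a *t* distribution on *d*₀ + *d* df; calls use
P < 0.01 and |log₂FC| > 0.4. Fold-change profiles are clustered by
fuzzy c-means (minimizing Σᵢⱼ uᵢⱼᵐ‖xᵢ − vⱼ‖²); class
over-representation is the hypergeometric upper tail; co-regulated
regions are ≥ 3 same-cluster genes within a 9-gene window with gaps
≤ 5 (plus strict-adjacency patches ≥ 3); and candidates are
regulatory-class genes meeting ≥ 3 of the five criteria, ranked by a
weighted score. Details and rationale are in the vignette
(`vignettes/candidate-regulator-screening.Rmd`).

## Worked example

```r
library(cazyscreen)

cfg <- pipeline_config(sim = sim_config(), out_dir = "results/run1",
                       seed = 1)
res <- run_pipeline(cfg)

head(res$report[res$report$selected,
                c("gene_id", "criteria_met", "score", "rank")])
#>   gene_id criteria_met score rank
#> 1   g0002            5     5    1
#> 2   g0017            5     5    2
#> 3   g0019            5     5    3
#> 4   g0021            5     5    4
#> 5   g0026            5     5    5
#> 6   g0029            5     5    6

head(as.data.frame(res$enrichment), 3)
#>               class    N  K   n  k     fold            p        p_adj
#> 2       CAZy_enzyme 2000 12 584 12 3.424658 3.544434e-07 1.063330e-06
#> 1      fungal_C6_TF 2000 50 584 27 1.849315 1.739670e-04 2.609505e-04
#> 3 sugar_transporter 2000 30 584  8 0.913242 6.871533e-01 6.871533e-01

sel  <- res$report$gene_id[res$report$selected]
regs <- res$dataset$truth$regulators
c(recall = length(intersect(sel, regs)) / length(regs),
  precision = length(intersect(sel, regs)) / length(sel))
#>    recall precision
#> 1.0000000 0.9090909
```

On this default 2,000-gene genome the screen selects 22 candidates,
recovering all 20 planted regulators; the transcription-factor class is
enriched among the 584 co-clustered genes (fold 1.85, P = 1.7 × 10⁻⁴),
and the scan reports 341 windowed regions and 37 adjacent patches.
Every output file (contrasts, clusters, enrichment, regions TSV/BED,
correlations, evidence, candidates, run log) lands under
`cfg$out_dir`, each re-readable by the package's own readers and
byte-identical across repeated runs with the same seed.

The same analysis can be run stepwise from files with the numbered
scripts in `analysis/` (simulate → differential expression →
clustering → enrichment → genome scan → correlation → candidate
selection), which write their tables under `results/`.

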