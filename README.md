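# hypoTF

Prioritization of candidate master-regulator transcription factors (TFs)
from tumor-specific DNA hypomethylation, for epigenomics and regulatory
genomics analysts working with region-level methylation, chromatin
accessibility and expression data.

Cancer genomes lose DNA methylation at distal regulatory elements, and the
elements that become hypomethylated are enriched for binding sites of the
TFs driving the tumor program. `hypoTF` turns that observation into a
tested, reusable pipeline:

1. **hypoDMR calling** — per region, a Welch *t*-test on beta values
   (tumor vs normal) with BH correction; a region is a hypoDMR when
   Δβ = β̄_tumor − β̄_normal ≤ −δ (default δ = 0.2) at q ≤ 0.05.
2. **Motif enrichment** — log-odds PWM scanning of region sequences on
   both strands (hit when score ≥ 0.8 × maximum attainable); per TF, a
   one-sided Fisher exact test on the 2×2 table of hypoDMRs vs background
   regions by motif presence. Candidates are kept at q ≤ 0.05 with mean
   tumor expression > 5 (top 30).
3. **Target inference** — a hypoDMR qualifies for a TF when it carries a
   motif hit *and* overlaps an open-chromatin (ATAC) peak; each
   qualifying hypoDMR contributes its nearest gene (region midpoint →
   TSS).
4. **Preranked GSEA** — genes are ranked by tumor/normal log₂ fold
   change; each TF's target set is scored by the weighted
   Kolmogorov–Smirnov-style enrichment statistic
   ES = max deviation of Σ_hits |s|ᵖ/Σ|s|ᵖ − Σ_miss 1/(N−k), with a
   random-gene-set permutation null giving NES, nominal *p* and a
   sign-stratified ratio-of-tails FDR.
5. **TF ranking** — TFs with target-set FDR ≤ 0.25 and positive own fold
   change, ordered by NES (the machine-readable version of the
   NES-vs-fold-change scatter).
6. **Activity signatures** — consensus ChIP peaks (regions covered by
   every replicate set) → occupied genes (nearest TSS within 25 kb) ∩
   knockdown-downregulated genes → a signature scored per sample as the
   mean gene-wise *z* of log₂ expression.
7. **Stratified pathway screen** — samples split at the top/bottom 30% of
   a stratifier gene's expression; high-vs-low differential expression
   feeds preranked GSEA over a pathway collection, flagging programs that
   track or oppose the TF.

A synthetic-data generator (`simulate_dataset()`) emits every input the
pipeline consumes — BED regions and peaks, beta and expression matrices,
MEME-minimal motifs, GMT pathway sets — with planted ground truth
(hypoDMRs, motif placements, a TF regulon, an anticorrelated immune-like
program), so the whole chain is testable without downloads.

## Worked example

```r
library(hypoTF)
bundle <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(bundle)
res$tf_report
#>   tf_id odds_ratio enrich_q n_targets    es  nes gsea_q tf_log2fc tf_fc combined_rank
#> 1  TF01       2151 1.64e-27        18 0.989 2.84      0      1.67  3.19             1
```

The planted TF (TF01) is the only motif significantly enriched in the 20
called hypoDMRs (odds ratio 2151, q = 1.6e-27), its 18 inferred targets
sit at the top of the tumor/normal ranking (ES 0.99, NES 2.84, FDR 0),
and it is itself 3.2-fold up in tumors — so it takes combined rank 1.
Downstream:

```r
res$signature
#> signature_spec: 18 occupied, 19 downregulated, 18 in signature
res$scores$comparison
#>   group1 group2 mean_diff  p_value
#>   normal  tumor     -1.32 2.83e-12
head(res$screen$gsea[order(res$screen$gsea$nes), c("set_id", "nes", "q_fdr")], 1)
#>           set_id    nes q_fdr
#> 1 IMMUNE_PROGRAM -3.215     0
```

The 18-gene activity signature separates tumor from normal samples by
1.32 mean z-units (p = 2.8e-12), and the planted immune-like program is
the most negatively enriched pathway between TF-high and TF-low tumors
(NES −3.2, q = 0) — the anticorrelation direction the screen is designed
to detect.

A thin command-line wrapper is provided at `inst/scripts/hypotf.R`
(`simulate`, `call-dmrs`, `run-all` subcommands over the same functions).

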