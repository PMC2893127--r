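# peaktriad

Control-free ChIP-Seq peak calling from three lines of evidence.

ChIP-Seq locates transcription-factor (TF) binding sites by sequencing
immunoprecipitated DNA fragments, but the tag counts along the genome
mix four signals: true TF binding, focal amplification, nonspecific
protein–DNA binding, and procedural noise. Matched input controls do
not remove nonspecific binding — it is a genuine property of the TF —
so `peaktriad` calls peaks from the ChIP sample alone and separates
true sites from confounders by combining three independent kinds of
evidence per candidate region:

1. **Count evidence** (`p_c`). The genome is divided into
   non-overlapping windows of `d` bp, the known maximum fragment size.
   Window counts of unique 5'-end tags are fitted to a zero-truncated
   Gamma-Poisson (negative binomial) background
   `P(X = x) = C(x+r-1, x) p^r (1-p)^x / (1 - p^r)`, with mean
   `r(1-p)/p`; zeros are excluded because they can reflect
   non-mappability. An empirical FDR per count threshold `k`,
   `eFDR(k) = min(1, N_total · Pr(X > k) / N_observed(X > k))`,
   selects the smallest `k` with `eFDR ≤ α`; above-threshold windows
   merge into potential binding regions (PBRs), and each PBR gets a
   tail p-value for its peak window count.
2. **Pattern evidence** (`d_p`). A true site yields forward-strand tags
   upstream and reverse-strand tags downstream, so the sliding-window
   difference `S = F − R` crosses zero at the site with one positive
   lobe before one negative lobe. Observed patterns are denoised by a
   maximal overlap discrete wavelet transform (la8 filter, universal
   hard threshold), aligned to a simulated reference pattern by
   mapping peak and trough, and scored by the summed absolute
   difference. Amplification-driven enrichment lacks the strand shift
   and is penalized.
3. **Motif evidence** (`p_m`). Sequences (±20 bp) around the peak
   estimates of the best regions feed a zero-or-one-occurrence-per-
   sequence (ZOOPS) EM motif finder; an accepted motif (present in
   ≥25% of inputs) is turned into a position weight matrix, every PBR
   is scanned on both strands, and the best hit gets an exact p-value
   from the dynamic-programming null score distribution.

The log scores are rescaled to a common level by quantile-matching
regression, averaged, and the top `1 − α` of re-ranked PBRs are the
significant regions — re-ranking does not change the count-stage FDR,
so `α` still controls it.

The package also ships a fully labelled synthetic-data generator
(genome FASTA, BED tags, truth table, with amplification and
nonspecific-hotspot confounders and a decoy chromosome) so the entire
pipeline is testable without any download.

## Worked example

```r
library(peaktriad)

ds <- generate_dataset(dataset_config(seed = 1))   # labelled synthetic data
paths <- write_dataset(ds, "demo_data")
run <- run_pipeline(pipeline_config(
  tags = paths[["tags"]], genome = paths[["genome"]],
  fasta = paths[["fasta"]], out_dir = "demo_out",
  d = 250, alpha = 0.5, n_high_quality = 10, seed = 1))
```

The log reports each stage; with seed 1 it prints

```
[input] 26016 unique tags (137 duplicates removed)
[fit] G-P r = 3.807, p = 0.5483 (logLik -15185.0 vs Poisson -16011.5)
[efdr] count threshold k* = 13 at alpha = 0.5
[pbrs] 18 potential binding regions
[rank] 9 of 18 regions significant at alpha = 0.5
```

meaning: window counts are clearly overdispersed (the Gamma-Poisson
beats the Poisson by ~830 log-likelihood units), windows with more
than 13 tags are enriched beyond chance at eFDR 0.5, and the 18
merged candidate regions are re-ranked by the three evidence scores.
All ten planted sites are recovered among the candidates, and the
decoy-chromosome regions — enriched in counts but lacking the strand
shift and motif — drop toward the bottom of the ranking. `demo_out/`
contains the ranked BED (`regions_ranked.bed`), a per-region audit
table with `p_c`, `d_p`, `p_m` and the combined score, the eFDR
table, the discovered motif in MEME minimal format, and a JSON run
manifest. Re-running with the same seed reproduces every output file
byte for byte.

Diagnostics mirror the control-free quality checks used on real data:

```r
overlap_report(24.3e6, 20.9e6, 0.34e6)$pct_in_both        # 0.75 (%)
background_noise_report(89835, 409136, 22585024)
# ratio 0.2196, expected ChIP background 4959671 reads
```

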