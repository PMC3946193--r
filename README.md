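# conpromo

Identification of bacterial **constitutive promoters** — promoters that the
RNA polymerase sigma-70 (RpoD) holoenzyme recognizes on its own, with no
supporting transcription factor — from genome-wide holoenzyme-binding data.

The package implements the full computational arm of that analysis for
*E. coli*-like genomes:

1. **Peak calling** on tiling-array binding signal (60-mer probes every
   105 bp, Cy5/Cy3 ratios). A binding peak requires a probe ratio of at
   least 2% of the genome-wide maximum on **two or more consecutive
   probes**, since a bound ~300-bp fragment must cover at least two probes.
2. **Spacer classification.** Intergenic spacers are typed by the strands
   of their flanking genes: **A** between divergent genes (holds promoters
   for both directions), **B** between codirectional genes (one promoter),
   **C** between convergent genes (none). With `nA` and `nB` peak-bearing
   A/B spacers, the constitutive-promoter count is bounded by
   `min = nA + nB` and `max = 2·nA + nB`.
3. **Consensus promoter scan.** A candidate is a pair of hexamers scored
   against the −35 consensus `TTGACA` and −10 consensus `TATAAT` (one
   point per matching base, no gaps) plus a spacer-length bonus
   (+3 for 17 bp, +2 for 16/18, +1 for 15/19). The perfect promoter
   `TTGACA-17-TATAAT` scores **15**. Candidates are retained when both
   boxes reach 4/6 matches and the box scores sum to ≥ 8.
4. **Consensus statistics**: conservation cross-tabs, sequence-logo
   information content `R(i) = 2 − H(i)` bits, H-NS silencer overlap
   (a silenced type-A spacer counts twice — both of its promoters), and
   essential-gene coverage.
5. **Kinetics.** Single-round mixed-transcription time courses are fitted
   with `y(t) = A(1 − e^{−kt})`; the plateau `A` is parameter I (binding
   level), and parameter II (opening rate) is the reciprocal time to reach
   95% of the plateau, `k / ln 20`.
6. **Synthetic data** with known ground truth — genomes, gene layouts,
   planted promoter motifs with controlled mismatch counts, probe-level
   signal with triangular peak kernels, AT-rich silencer sites, and noisy
   time courses — so every stage is testable end to end.

## Worked example

```r
library(conpromo)
g   <- generate_genome(50000, 0.5, seed = 101)
lay <- plant_gene_layout(g, data.frame(type = c("A","B","C","A","B"),
                                       spacer_len = c(400, 300, 250, 350, 300)))
tr  <- simulate_array_signal(50000,
         data.frame(center = (lay$truth$start + lay$truth$end) %/% 2,
                    amplitude = c(80, 60, 40, 70, 50)),
         noise_sd = 0.05, seed = 102)
pk  <- rank_peaks(call_peaks(normalize_ratio(tr)))
head(pk)
#>   start  end summit   height rel_height n_probes rank
#> 1  6405 6675   6510 67.39269  1.0000000        3    1
#> 2   735 1005    840 56.67420  0.8409548        3    2
#> 3  2625 2895   2730 53.40132  0.7923903        3    3
#> ...
```

Five peaks are recovered at the five planted centers; each spans ≥ 2
probes and its height is reported relative to the genome-wide maximum.
Assigning peaks to spacers and bounding the promoter count:

```r
sp  <- extract_spacers(lay$genes)
sp  <- tally_spacer_peaks(sp, assign_peaks(pk, sp, lay$genes))
count_constitutive_bounds(sp)
#> min max
#>   4   6
```

Two peak-bearing divergent (A) spacers and two codirectional (B) spacers
give between 4 and 6 promoters (the type-C peak is excluded). With the
genome carrying promoters planted at 6/6 −35 and 5/6 −10 agreement,
scanning the peak-bearing spacers finds them:

```r
hits <- scan_regions(genome_with_promoters, sp[sp$n_peaks > 0 & sp$type != "C", ])
do.call(rbind, lapply(split(hits, hits$region), best_hit))
#>   strand pos35  seq35 spacer_len  seq10 m35 m10 spacer_score total region
#> 1      +   700 TTGACA         17 TACAAT   6   5            3    14      1
#> 2      +  2700 TTGACA         17 TATAAC   6   5            3    14      2
#> ...
```

Each best hit scores 14 = 6 + 5 + 3, exactly the planted agreement plus
the 17-bp spacer bonus. On the published genome-scale counts the same
arithmetic gives `count_constitutive_bounds(n_a = 177, n_b = 315)` →
(492, 669) and `hns_silencing_count(n_a_hns = 63, n_b_hns = 77,
max_count = 669)` → 203 silencer-exposed promoters.

Kinetics:

```r
fit <- fit_single_round(simulate_time_course(100, 0.5))
fit
#> <kinetic_fit>
#>   status: ok
#>   amplitude (parameter I): 100
#>   rate k: 0.5 /min
#>   parameter II (1/t at 95% plateau): 0.1669 /min
```

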