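# slafbsa

Bulked-segregant analysis (BSA) of quantitative traits from
reduced-representation sequencing, built around the SNP-index statistic.
The package targets the workflow used to map fiber content in hemp:
an F1 population from two heterozygous outcrossing parents, extreme
phenotype bulks sequenced as pools over SLAF tags (restriction fragments
selected in a narrow size window), and a genome scan for allele-frequency
divergence between the bulks.

It is written for quantitative geneticists and breeders who have (or plan)
a pooled extreme-bulk experiment and want a reproducible, testable
implementation of every step between raw calls and candidate genes.

## What it computes

For each biallelic site, per bulk, the **SNP-index** is the fraction of
reads carrying the oriented allele, and

Δ(SNP-index) = index(high bulk) − index(low bulk)

is near 0 at trait-unlinked loci and extreme near a causal locus. The
scanned statistic is the sliding-window value **m**, the mean Δ(SNP-index)
of 10 consecutive SNPs (step 1, never spanning chromosomes). Significance
thresholds for |m| come from 10,000 simulated replications of the
no-association null for the mating design (F1 pseudo-testcross by default,
F2 optional), at confidence 0.90 / 0.95 / 0.99, with an empirical
99th-percentile fallback. Runs of above-threshold windows become candidate
regions, annotated with overlapping genes from a GFF3.

Around that core: in-silico double digestion (RsaI + HaeIII, 314–364 bp
size selection) for SLAF tag prediction and enzyme-combination scoring;
fiber-content phenotypes (bast weight / stem weight × 100) and extreme-bulk
selection; the five-stage SNP hard-filter cascade with a conservation
ledger (`total == retained + Σ removed`, enforced by construction); and a
forward simulator of the entire experiment (genotypes, recombination,
trait, bulks, pooled reads, caller annotations) that emits standard
FASTA/GFF3/VCF/TSV/JSON fixtures.

## Worked example

Simulate a full experiment under the default study design (305 F1 plants,
bulks of 30, 2,000 markers on a 100 Mb chromosome, one causal locus with
effect twice the environmental SD, ~45X pooled depth), then filter, scan
and call regions:

```r
library(slafbsa)

sim  <- simulate_bsa_experiment(sim_config(seed = 1))
res  <- filter_snps(sim$records)
scan <- bsa_scan(res$retained, seed = 1)
print(scan)
#> Bulked-segregant SNP-index scan
#>   sites: 1669 (0 masked), windows of 10 SNPs: 1660
#>   null: F1_pseudo_testcross, 10000 replicates
#>   |m| threshold @ 0.90: 0.0859
#>   |m| threshold @ 0.95: 0.1031
#>   |m| threshold @ 0.99: 0.1347
#>   empirical 99th pct of |m|: 0.3171

regions <- call_regions(scan, scan$thresholds, max_gap_snps = 10)
regions[which.max(abs(regions$peak_m)), ]
#>   chrom    start      end length_mb n_windows n_snps    peak_m
#> 9  chr1 37113177 56796883  19.68371       351    360 0.3616315

sim$truth$causal_pos
#> [1] 49449452
```

The filter ledger shows where sites went (here 299 uniform-pool sites —
markers monomorphic across bulks — and 32 planted quality violations were
removed, leaving 1,669 of 2,000), the 99%-confidence |m| threshold is
0.135, and the top candidate region contains the true causal position.
`plot(scan)` draws the three standard panels (per-bulk SNP-index and
windowed Δ with threshold lines).

File-based workflows use `run_pipeline(run_config(...))` (writes every
stage's TSV/BED outputs plus a hash manifest under `out_dir`) or the CLI
wrapper `inst/scripts/slafbsa.R` with subcommands `digest`, `bulks`,
`filter`, `scan`, `regions`, `simulate`, `run`.

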