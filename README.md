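# hmcscan

Downstream analysis of 5-hydroxymethylcytosine (5hmC) capture
sequencing across tissues. 5hmC, the first TET oxidation product of
5-methylcytosine, accumulates in the bodies of transcribed genes;
capture-seq experiments recover 5hmC-enriched DNA fragments per sample
(e.g. five brain regions and liver, in both sexes) together with an
input control and matched RNA-seq. `hmcscan` turns those raw materials
— fragment/peak BED files, a GENCODE-style GTF, a chromosome-sizes
table, and a gene-by-sample count matrix — into the analyses this study
design calls for, and ships a fully parameterised synthetic study
generator so the entire pipeline is testable with known truth and no
downloads.

The package is written for epigenomics analysts: every step is an
exported R function over Bioconductor containers (`GRanges`, plain
matrices), and the `analysis/` scripts run the whole study end to end.

## What it computes

* **Island calling** — a SICER-style window-clustering caller:
  fragments are deduplicated (redundancy 1), shifted by half the
  fragment size, counted in 100 bp windows; windows beyond a Poisson
  background tail are joined across ≤ gap-size holes into islands,
  scored against the scaled input control, and retained at
  Benjamini–Hochberg q < 0.01.
* **Intragenic coverage** — the genes × samples matrix of gene-body
  fractions covered by merged peaks, the study's central statistic,
  with five-level coverage classes (0%, <20%, 20–50%, 50–80%, >80%).
* **Metagene profiles** — mean covered fraction in 2.5 kb flanks (25
  bins each) and 40 length-scaled gene-body bins, strand-aware.
* **Expression** — TMM normalisation (implemented here, oracle-checked
  against an independent implementation) and log2 CPM; "moderate-high"
  expression means log2 CPM ≥ 2.5.
* **Association** — Spearman sample-similarity matrix; Wilcoxon
  rank-sum tests of marked vs unmarked genes per biotype; Ward-linkage
  hierarchical clustering of gene-body enrichment patterns into
  clusters C1–C5 ordered by increasing coverage; per-cluster expression
  summaries; gene-set membership percentages; one-/two-way ANOVA with
  Tukey HSD; Welch t-tests.
* **Specificity** — threshold-rule organ-specific genes, the strict
  female-only/male-only sex-specific enrichment scan (the Xist
  pattern), and the two exception classes of the coverage–expression
  association: expressed-but-unmarked and marked-but-silent genes, over
  autosomal protein-coding genes.
* **Synthetic data** — `simulate_hmc_study()` plants all of the above
  (coverage targets with an organ/region correlation hierarchy, a
  1.5-slope negative-binomial coverage→expression link, decoupled
  housekeeping genes, organ-specific and exception sets, a female-only
  X-linked analog, ~800 bp 3'-biased peaks) and returns the truth for
  recovery testing.

## Worked example

```r
library(hmcscan)

study <- simulate_hmc_study(seed = 1)
res <- run_hmc_pipeline(study$genes, study$sizes, study$peaks,
                        study$counts, study$coverage_samples,
                        study$expression_samples,
                        out_dir = "results/pipeline")
res$clustering$sizes
#> lab
#>  C1  C2  C3  C4  C5
#>  37 115 103 138  99
```

Or file-based, as with real data, via the numbered drivers:

```sh
Rscript analysis/01_simulate.R        # writes results/synthetic_study/
Rscript analysis/02_island_calling.R  # caller calibration with known truth
Rscript analysis/03_run_pipeline.R    # full downstream pipeline
Rscript analysis/04_recovery_checks.R # compare output to planted truth
Rscript analysis/05_worked_examples.R # reported-count arithmetic
```

`02_island_calling.R` prints, for a 1 Mb toy genome with nine planted
2 kb islands at 10× background:

```
background-only: median 0 islands (max 0) over 25 reps
planted recovery: 100.0% of 25 x 9 islands
example call: 9 islands, lambda_bg 2.336, l0 5
```

i.e. the caller finds nothing on matched treatment/control input and
recovers every strong planted island. `04_recovery_checks.R` prints the
study-level recovery of the planted structure:

```
                              check       value
 coverage_expression_spearman_nonhk  0.66885022
              housekeeping_spearman -0.05005272
             brain_specific_jaccard  1.00000000
             liver_specific_jaccard  1.00000000
                 sex_specific_calls  1.00000000
                 xist_analog_unique  1.00000000
                     class1_jaccard  1.00000000
                     class2_jaccard  1.00000000
```

The planted coverage→expression link (slope 1.5) comes back at Spearman
≈ 0.67 over non-housekeeping genes while the housekeeping set stays
decoupled (|ρ| ≈ 0.05); all planted organ-specific and exception gene
sets are recovered exactly, and the female-only X-linked analog is the
single sex-specific call genome-wide.

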