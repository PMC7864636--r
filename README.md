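# stretchmap

Regulatory-genomics toolkit for prioritizing disease risk genes through
developmental-stage-specific **stretch enhancers**. The package implements,
as composable R functions, the analysis chain used to connect type 2
diabetes GWAS signal to pancreatic-progenitor regulatory elements:

* **Stretch-enhancer calling.** Contiguous active-enhancer (EnhA) runs are
  extracted from ChromHMM-style chromatin-state segmentations (200 bp
  bins). The consecutive-bin count *k* of each element is modeled as
  Poisson with rate λ̂ = mean(*k*) per cell type; elements with inclusive
  upper-tail probability P(K ≥ k) < 0.001 are stretch enhancers (SE),
  the rest typical enhancers (TE).
* **Progenitor-specificity filter.** PSSE are the PP2-stage SE with zero
  bp of overlap against SE at the ES/DE/GT stages and against any enhancer
  (TE or SE) in islets.
* **Permutation overlap enrichment.** Observed overlap with e.g. ATAC-seq
  peaks is compared to 10,000 length- and chromosome-preserving shuffles;
  empirical p = (r+1)/(n+1), reported as `p < 1e-4` when no null draw
  reaches the observed statistic.
* **Variant prioritization.** GWAS variants inside PSSE are tested against
  the Bonferroni threshold α/n (0.05/10,738 = 4.66 × 10⁻⁶ at the published
  variant count), grouped into loci by 500 kb single linkage, and flagged
  novel when ≥ 500 kb from every known risk locus.
* **Hi-C loop calling.** Raw contact matrices are balanced by iterative
  proportional fitting; each pixel's expected count is estimated from the
  donut annulus around it (inner radius 2, outer 5 bins, center cross
  excluded) and tested with a Poisson upper tail. Candidates (p < 0.01)
  without a neighboring candidate are dropped, survivors within 20 kb are
  collapsed to their most significant pixel, and representatives with
  p < 1e-5 are the final loops.
* **Target genes.** Nearest expressed TSS (FPKM ≥ 1 at the relevant
  stage), or all expressed genes in the same TAD.
* **Synthetic data.** Every input format can be generated with planted
  enhancers, variant signals, biases and loops, so the full pipeline is
  testable end to end; `run_pipeline()` orchestrates all stages and writes
  a JSON manifest of per-stage counts.

See `vignettes/stretch-enhancers.Rmd` for the models, parameter choices
and limitations.

## Worked example

Simulate a six-stage study and run the whole chain:

```r
library(stretchmap)

res <- run_pipeline(pipeline_config(seed = 7), outdir = "demo_run")
str(res$manifest$counts)
#> List of 9
#>  $ n_enhancers       :List of 6
#>   ..$ ES   : int 530
#>   ..$ DE   : int 530
#>   ..$ GT   : int 530
#>   ..$ PP1  : int 530
#>   ..$ PP2  : int 540
#>   ..$ islet: int 530
#>  $ n_se              :List of 6
#>   ..$ ES   : int 30
#>   ..$ DE   : int 30
#>   ..$ GT   : int 30
#>   ..$ PP1  : int 30
#>   ..$ PP2  : int 40
#>   ..$ islet: int 30
#>  $ n_psse            : int 10
#>  $ n_variants_in_psse: int 39
#>  $ threshold         : num 0.00128
#>  $ n_significant     : int 3
#>  $ n_loci            : int 2
#>  $ n_novel           : int 2
#>  $ n_loops           : int 5
```

Reading the counts: each stage carries ~530 active enhancers of which the
planted 30–40 long ones are called SE; the 10 PP2-only SE survive the
specificity filter (`n_psse`); 39 variants fall inside PSSE, so the
Bonferroni threshold is 0.05/39 ≈ 1.28 × 10⁻³; the 3 variants with planted
association clear it and group into 2 loci, both ≥ 500 kb from the
simulated known loci (`n_novel`); and all 5 planted chromatin loops are
recovered (`n_loops`). The enrichment entry of the manifest reports the
permutation test of PP2 SE against PP2 accessible chromatin — here
observed overlap 0.9, fold 8.1 over the shuffled null, empirical
p = 9.999 × 10⁻⁵, i.e. `p < 1e-4` at 10,000 iterations.

The same stages are available piecemeal:

```r
seg   <- read_segmentation("segmentation_PP2.bed", bin_size = 200, stage = "PP2")
el    <- extract_enhancers(seg, "EnhA")
model <- fit_poisson_rate(el, alpha_se = 0.001)
model
#> poisson_model: lam = 4.457407  alpha_se = 0.001
cl <- classify_stretch(el, model)
table(cl$klass)
#>  SE  TE
#>  40 500
```

A thin command-line wrapper over these functions ships in
`inst/scripts/stretchmap.R` (subcommands `run`, `simulate`, `call-se`).

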