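# nascentRates

Kinetic rates of initiation, pause release and premature termination from
nascent transcription data.

## The problem

RNA polymerase II pauses 50–100 bp downstream of the transcription start
site before committing to productive elongation, and a paused polymerase
can instead terminate prematurely. Which of these steps a transcription
factor or drug regulates — and how fast each step runs — cannot be read
directly from a PRO-seq or GRO-seq browser track. `nascentRates` is for
genomicists with strand-specific nascent run-on data in two conditions
(control vs. acute treatment, degradation or stimulus) who want per-gene
kinetic rate constants and a mechanistic call on what the perturbation
changed.

## The model

Pause-region and gene-body polymerase densities are treated as steady
states of a two-compartment linear system,

    dp/dt = k_init − (k_pre + k_rel)·p        p = k_init / (k_pre + k_rel)
    db/dt = k_rel·p − k_elong·b               b = (k_rel / k_elong)·p

with `k_init` the initiation rate (RNAP/min), `k_pre` premature
termination (min⁻¹), `k_rel` pause release (min⁻¹) and `k_elong`
elongation (bp/min). The consequences the package computes:

* fold change in pause release = fc(b)/fc(p), the inverse fold change of
  the pausing index — independent of any normalization;
* the fold change in initiation is bounded by fc(p) (when k_pre ≫ k_rel)
  and fc(b) (when k_pre ≪ k_rel), and equals
  fc(p)·(r + fc(k_rel))/(r + 1) at a known r = k_pre/k_rel;
* r itself can be solved per gene from an initiation inhibitor of known
  efficacy: r = (fc(k_rel) − X)/(X − 1), X = fc(k_init)/fc(p);
* absolute rates from occupancy-calibrated densities:
  k_rel = k_elong·b/p, k_init = p·k_pre + k_elong·b, effective release
  k_rel·p, polymerase spacing 1/b, and paused-polymerase half-life
  ln 2/(k_pre + k_rel).

The workflow: per-gene pause sums and body means from bedGraph/bigWig
tracks → median-of-ratios size factors → fold changes → saturation-based
occupancy calibration (tanh fit on UMI data, 90th-percentile fallback
otherwise) → rate report, ratio inference and factor classification. A
synthetic-data generator with known kinetic ground truth backs the test
suite.

## Worked example

Simulate 400 genes with pause release doubled on the first 80, generate
Poisson reads for two replicates per condition with unequal library
sizes, and run the whole pipeline:

```r
library(nascentRates)

genes <- sample_gene_rates(400, seed = 20)
fc_krel <- rep(1, 400); fc_krel[1:80] <- 2
sim <- generate_condition_pair(genes, fc_krel = fc_krel, depth = 5e5,
                               seed = 21, replicates = 2,
                               lib_factors = c(1, 1.2, 0.9, 1.1))
res <- run_end_to_end(
  run_config(),
  lapply(sim$samples, function(s) s[c("condition", "replicate",
                                      "plus", "minus")]),
  genes[, 1:5],
  de_lists = list(activated = genes$gene_id[1:80]))

round(res$size_factors, 3)
#>   control.1   control.2 treatment.1 treatment.2
#>       0.946       1.137       0.873       1.061

pert <- res$fold_changes$gene_id %in% genes$gene_id[1:80]
round(median(res$fold_changes$fc_krel[pert]), 2)    #> 1.98
round(median(res$fold_changes$fc_krel[!pert]), 2)   #> 1.01

res$summary[res$summary$quantity %in%
              c("krel_control", "half_life_control"), ]
#>            quantity    median      q10       q90   n
#> 1      krel_control 0.8985065 0.258605  3.393708 400
#> 9 half_life_control 6.0112836 1.591544 20.885780 400

res$classification$activated$call                   #> "pause_release"
```

The size factors recover the simulated library multipliers (1, 1.2, 0.9,
1.1 up to a common constant); perturbed genes recover the doubled pause
release (median 1.98 vs. 1.01 for unperturbed); the control median
`k_rel` of 0.90/min and half-life of 6.0 s sit at the scale of the
generating rates; and the classifier calls the perturbation a
pause-release regulator.

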