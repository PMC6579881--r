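# cytoscreen

Analytics for large barcoded mass cytometry (CyTOF) experiments, built
around the design of plate-format antibody staining screens: pooled
samples carrying two tiers of combinatorial barcodes are debarcoded back
to their source wells, cell subsets are labeled against a knowledge-based
gating hierarchy with unbiased clustering, staining quality is monitored
with the Average Overlap Frequency (AOF), and the screen itself is
summarized as blank-thresholded percent-positive tables, fixation
gain/loss classes, and differential markers between cell subsets.

It is aimed at immunologists and cytometry bioinformaticians running
immune-monitoring studies in which hundreds of samples are acquired over
weeks: the package gives them a reproducible, seedable, file-based
pipeline from FCS ion counts to screen-level statistics, plus a synthetic
data generator with ground-truth sidecars so every stage can be validated
without any real acquisition.

## The methods at the core

**Two-tier combinatorial debarcoding.** Samples are encoded as k-of-n
patterns of barcode channels (e.g. 2-of-4 CD45 channels for the donor x
treatment tier, 2-of-5 palladium channels for the well tier; a full batch
carries 6 x 10 = 60 codes). Per event, channels are rescaled to [0, 1] by
their 1st–99th percentile window; the k brightest channels form the
candidate code, accepted only if it is a valid scheme code and the gap
between the k-th and (k+1)-th channel exceeds a separation cutoff. A
cluster-then-label route (SOM clusters signed per channel and matched to
code conjunctions) is available as an alternative.

**Hierarchy labeling.** A gating hierarchy is a leveled tree of rules such
as "cells that are CD3+ CD19− are T cells". At each level, each parent
population is clustered with a self-organizing map on that level's rule
markers; per marker, a cutoff `t*` is chosen over the midpoints of sorted
cluster medians to maximize the Matthews correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

between event-level calls (`x > t*`) and cluster-propagated calls; each
cluster's sign vector then selects the unique rule it satisfies. Terminal
subsets are profiled separately: heterogeneous markers (by achievable
binarization MCC) drive the cluster count, and clusters are auto-named by
their most separating markers (`CD161hi` / `CD161lo`).

**AOF staining QC.** For a marker with negative and positive modalities,

    AOF = ½ ( |X⁻ above the 5th pct of N(μ⁺, σ⁺)| / |X⁻|
            + |X⁺ below the 95th pct of N(μ⁻, σ⁻)| / |X⁺| )

is 0 for separated modalities and ≈0.95 for identical ones. Scaled²AOF
z-scores each marker across samples (floored at 0, squared) and
Quality²AOF sums it per sample; time-quartile AOF detects acquisition
drift, which is recoverable by restricting analysis to the first quartile.

**Screen statistics.** Percent positive is the fraction of a subset's
events above the 99th percentile of the blank control well; fixation
effects are classified gain/loss/unchanged by a 2-fold change in the
fixed/fresh median intensity ratio; differential markers between two
subsets are antibodies whose absolute standardized regression residual
(percent positive in subset A regressed on subset B across antibodies)
exceeds 2 in every donor with a consistent sign.

## Worked example

Simulate one pooled, barcoded batch of the bundled synthetic screen,
debarcode it, and label one recovered sample unit:

```r
library(cytoscreen)

cfg <- defaultSimulationConfig(seed = 7, nEvents = 500)
man <- defaultManifest(cfg)
man
#> ExperimentManifest: 3 donors x 2 treatments x 14 wells
#> 2 batches (size <= 10 ), 84 sample units, 84 retained
#> inner: 2-of-4; outer: 2-of-5

sim <- simulateBatch(cfg, man, "batch_01")
ev  <- asinhTransform(sim$events)            # asinh(x / 5)
asg <- twoTierDebarcode(ev, man, "batch_01")
mean(asg$assigned)                           # 0.937 of 30,000 events
# accuracy vs the generator's sidecar among assigned events: 1.000

unit <- asg$assigned & asg$donor == "D1" & asg$well_id == "W002" &
        asg$treatment == "fresh"
unit_ev <- cytoEvents(intensities(ev)[unit, , drop = FALSE],
                      scale = "arcsinh")
lab <- labelEvents(unit_ev, defaultHierarchy(), clusterParams(seed = 7))
labelCounts(lab)
#>     B Cells CD4 T Cells CD8 T Cells    NK Cells  UNASSIGNED
#>         121         156         107          88           1
```

93.7% of the pooled events resolve to a (donor, treatment, well) unit —
the rest are rejected as ambiguous barcode signatures — and every
assigned event matches the generator's ground truth. The labeled counts
reflect donor D1's configured subset frequencies. The printed-metric
helper reproduces the debarcoding F1 worked example:
`f1Score(0.996, 0.914)` = 0.953.

The whole pipeline (simulate → debarcode → label → profile → AOF QC →
screen → fixation → differential markers) runs as composable stages over
on-disk FCS/CSV artifacts:

```r
runPipeline("all", pipelineConfig(outDir = "run1", seed = 1))
```

or from a shell via `Rscript inst/cli/cytoscreen.R all --out run1 --seed 1`.

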