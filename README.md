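# logstage

Self-supervised T-staging of grayscale MRI slices: Laplacian-of-Gaussian
(LoG) texture enhancement, convolutional features, sequential
information-bottleneck clustering, and pseudo-label training.

## The problem

Pathological T-staging grades how deeply a rectal tumor invades the
bowel wall (T1 submucosa … T4 adjacent organs).  Because ground truth
requires post-resection biopsy, most archived MRI slices are unlabeled.
`logstage` learns a four-way slice classifier from unlabeled data by
alternating two steps:

1. **Cluster.** Central-crop features of LoG-filtered slices are
   clustered into `k = 4` groups by a sequential information bottleneck
   (sIB) that maximizes

   L = I(T; Y) − λ⁻¹ I(T; X),   λ = 100,

   via draw-and-merge: each point is drawn out as a singleton and
   re-merged into the cluster with minimal merger cost
   ΔL = (p(x)+p(t)) · JS_w[p(y|x), p(y|t)] − λ⁻¹ (p(x)+p(t)) · H(w),
   where w = (p(x), p(t))/(p(x)+p(t)) and JS_w is the weighted
   Jensen–Shannon divergence.

2. **Train.** The cluster assignments become pseudo-labels for a few
   epochs of minibatch SGD on the negative log-softmax loss of a small
   CNN; the backbone persists across rounds and the linear head is
   reinitialized each round.

Staging quality is reported with one-vs-rest accuracy, sensitivity,
specificity, balanced accuracy (mean of sensitivity and specificity),
ROC/AUC, and patient-grouped 10-fold cross-validation splits.  A
synthetic staged-phantom generator (rings whose wall thickness and
boundary irregularity increase with stage, class proportions
18/27/35/20%) makes every part testable without clinical data.

## Worked example

```r
library(logstage)

# sIB on four well-separated Gaussian feature blobs
blob  <- generate_feature_blobs(200, 16, 4, separation = 10, seed = 1)
state <- sib_cluster(blob$features, sib_config(k = 4, lam = 100, seed = 1))
state
#> <cluster_state k=4 n=200 objective=0.033620 sizes=50/50/50/50>
nmi(state$assignment, blob$labels)
#> [1] 1

# end-to-end: 200 training phantoms, 5 cluster/train rounds,
# Hungarian cluster-to-stage mapping, 100 held-out phantoms
cfg <- train_config(rounds = 5, seed = 11)
ex  <- phantom_experiment(200, 100, cfg, spec_seed = 11)
sapply(ex$fit$history, function(h) round(h$nmi_truth, 3))
#> [1] 0.676 0.880 0.942 0.893 0.941
ex$report
#> Per-stage one-vs-rest metrics:
#>  stage accuracy sensitivity specificity balanced_accuracy auc
#>     T1     0.98      1.0000      0.9756            0.9878   1
#>     T2     0.98      0.9259      1.0000            0.9630   1
#>     T3     0.99      1.0000      0.9846            0.9923   1
#>     T4     0.99      0.9500      1.0000            0.9750   1
#> Macro balanced accuracy: 0.9795
```

The NMI trace shows pseudo-labels agreeing more with the (hidden)
ground truth as the loop alternates; the held-out report shows the
trained classifier staging unseen phantoms after the cluster-to-stage
permutation is fixed on the training labels.

## Command-line use

A thin wrapper lives at `inst/cli/logstage.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","logstage.R",package="logstage"))')
Rscript $CLI synth    --n 200 --out data/ --seed 11
Rscript $CLI filter   --in data/ --sigma 1.6 --out filtered/ --pyramid
Rscript $CLI train    --manifest data/manifest.csv --out run/
Rscript $CLI predict  --model run/model.rds --in data/ --mapping run/mapping.json --out pred.csv
Rscript $CLI evaluate --pred pred.csv --truth data/manifest.csv --out report.json --roc-png roc.png
```

## Scope

Slices are treated as independent grayscale 2D samples (axial plane;
registration and modality fusion are upstream concerns).  Supported
inputs: NIfTI volumes, uncompressed explicit-VR little-endian DICOM
series, grayscale PNGs, and `path,label,patient_id` manifest CSVs.
See the vignette in `vignettes/log-staging.Rmd` for the method's
assumptions, parameter defaults, and known limitations.
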