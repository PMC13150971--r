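# lungfuse

Lung-field segmentation support for posteroanterior chest radiographs:
a **training-free heuristic stage** that extracts structural prior channels
from a radiograph, and an **early-fusion training harness** that feeds those
channels, together with the raw image, into a compact encoder–decoder
segmentation network.

## Who this is for

Researchers working on chest-radiograph lung-field segmentation (LFS) who
want edge-based structural priors that need no ground truth to compute, a
controlled way to measure what each prior contributes to a trained model,
and a fully seeded synthetic phantom bench for testing the whole chain on a
laptop.

## The method

**Stage 1 — heuristic prior extraction.** The radiograph is rescaled to a
fixed working width and processed through:

1. *Body blob*: log-transform and full-range contrast stretch, a
   histogram-valley threshold on the 8-bit window \[130, 170\], and
   morphological cleanup to a single body region `Ib` with dilated boundary
   band `Mb`.
2. *LoG channel*: CLAHE, median and min filtering; Rayleigh-CLAHE
   enhancement; Laplacian-of-Gaussian zero-crossing detection at variance
   `sigma^2 = min(M, N) * eps * 0.6`, where `eps` is the mean local
   standard deviation of the image scaled by its maximum. Boundary
   subtraction, a ribcage mask (closing then adaptive erosion of `Ib`) and a
   shoulder mask prune the edge components; convex-hull reconstruction
   refines the lung region of interest.
3. *Spine model*: bone-tissue Canny edges, skeletonised inside a vertical
   band at the hull centroid, summarised per row and fitted with a stiff
   smoothing spline; the thickened spline removes whole paraspinal edge
   components.
4. *Canny channel*: two Canny variants on the \[0.4, 0.73\] stretch with
   adaptive thresholds and variances, pruned by the spine model and a
   saturation mask; the left and right lungs are separated, hulled, and
   combined with the LoG representation into a heuristic predicted lung
   mask.

The stage emits five aligned 256 x 256 planes: `Io` (grayscale), `cn1`,
`cn2` (Canny variants), `log` (pruned LoG representation) and `pm`
(predicted mask).

**Stage 2 — early fusion.** Each of the 16 channel combinations
`C_k = {Io} + H_k`, `H_k` a subset of `{cn1, cn2, log, pm}`, is applied as a
binary selection mask on the five-plane stack and projected through a
learnable 1 x 1 mixer to three planes (`Xfused = Conv1x1(X * m)`), with the
`Io` weight initialised to 1 and the rest to 0 so the untrained front end
reproduces the plain radiograph exactly. A configurable U-Net family (plain,
residual, attention-gated, nested, attention+nested) trains on logit binary
cross-entropy with Adam; dice, Jaccard (IoU), accuracy, precision and recall
are reported under hold-out, k-fold and cross-dataset protocols.

## Worked example

```r
library(lungfuse)

ph  <- generatePhantom(phantomSpec(seed = 1))        # synthetic PA film + truth
res <- runStage1(ph$image, heuristicParams(inputWidth = 512L))
pixelMetrics(res$artifacts$LFfinal, ph$mask)
#>        dice       iou  accuracy precision recall nImages
#> 1 0.8098696 0.6804881 0.9146957 0.6804881      1       1
```

The heuristic mask alone reaches dice ~0.81 on this phantom without any
training; `res$channels` holds the five-plane set ready for fusion:

```r
res$channels
#> ChannelSet 256 x 256 x 5; nonzero planes: Io, cn1, cn2, log, pm
enumerateCombinations()$label[c(1, 6, 16)]
#> [1] "Io"                "Io_cn1_cn2"        "Io_cn1_cn2_log_pm"
```

A reduced-scale training smoke (8 phantoms, 64 x 64, 200 Adam steps at
learning rate 1e-4) overfits to training dice >= 0.95, which verifies the
gradient path through selection, mixer and network.

A shell entry point wrapping the same functions lives at
`inst/scripts/lungfuse.R` (subcommands `extract`, `phantom`, `train`,
`eval`, `sweep`).

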