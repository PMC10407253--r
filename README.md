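# temsig

Quantification of endothelial signaling during neutrophil
transendothelial migration (TEM): an R package for the image- and
trace-analysis pipelines behind single-cell kinase-translocation-reporter
(KTR) experiments, apical filopodia counting, two-wave adhesion spatial
statistics and FRET/FRAP/crosstalk ratiometrics — together with
ground-truth-annotated synthetic data generators so every stage can be
tested and benchmarked without raw microscopy.

It is written for cell biologists and image analysts who run (or review)
leukocyte TEM experiments on endothelial monolayers and want the
quantification steps as reproducible, scriptable functions instead of a
chain of GUI tools.

## What it computes

**KTR activity.** A KTR leaves the nucleus when its kinase is active, so
the cytoplasm/nucleus intensity ratio C/N reads out single-cell kinase
activity. From a two-channel time-lapse the pipeline applies rolling-ball
background subtraction (50 px), nuclear segmentation (global threshold
0.1, diameter gate 30–100 px), a 10 px cytoplasmic ring at threshold
0.08, C/N measurement, and overlap tracking with a 3 px displacement
gate, yielding one C/N trace per cell.

**Responder classification.** Traces are converted to relative kinase
activity, `r(t) − mean(r(baseline frames))`, pair-binned, and clustered
jointly across conditions with Manhattan (L1) distance and Ward.D2
linkage at k = 2, using only post-stimulus frames; the higher-activity
cluster is "activated" and per-condition responder fractions are
reported.

**Filopodia density.** Apical ICAM-1 spots are detected with a
Laplacian-of-Gaussian detector tuned to 0.6 µm, filtered by detector
quality and a dilated junction (VE-cadherin) mask, and reported as
filopodia/µm², optionally split by GFP transduction in mosaic
experiments. A companion morphometry function yields per-cell area,
circularity (4πA/P²) and mean ICAM-1 intensity.

**Two-wave spatial statistics.** Signed nearest-neighbour distances of
second-wave neutrophils to first-wave surfaces (disks, negative inside),
compared against a uniform random-dot null matched in number; plus
adhesion counts, wave2/wave1 ratios, diapedesis efficacy and
crawling-track statistics.

**Ratiometrics.** FRET acceptor/donor (Venus/Cerulean3) ratio traces per
ROI, two-point FRAP normalization (100% at 0 s, 0% at 15 s) and
fluorophore crosstalk matrices from single-colour acquisitions
(brightest-cell ROI, row-normalized to the native channel).

## Worked example

Generate the two study conditions (control: 5% responders; neutrophil
co-incubation: 50%), normalize, and classify:

```r
library(temsig)

ctrl <- gen_traces(200, ktr_preset("control"),    n_frames = 30, stimulus_frame = 5, seed = 1)
neut <- gen_traces(200, ktr_preset("neutrophil"), n_frames = 30, stimulus_frame = 5, seed = 10001)

activity <- normalize_baseline(rbind(ctrl$cn, neut$cn), stimulus_frame = 5)
cl <- cluster_responders(activity, stimulus_frame = 5,
                         condition = rep(c("control", "neutrophil"), each = 200))
round(100 * cl$fractions, 1)
#>    control neutrophil 
#>          5         50
```

5% of control cells and 50% of neutrophil-exposed cells land in the
activated cluster — the generator planted exactly those rates
(`round(rate * n)` responders), and the joint Ward.D2/Manhattan
clustering recovers every label here.

The imaging arm is exact on noise-free input:

```r
spec <- scene_spec(n_cells = 8, field_size_px = c(360, 360),
                   n_frames = 10, stimulus_frame = 3, seed = 11)
mv  <- gen_ktr_movie(spec, ktr_preset("neutrophil", noise_sd = 0))
tab <- run_ktr_pipeline(mv$nuclear, mv$ktr)
length(unique(tab$track_id))
#> [1] 8
```

All 8 planted cells come back as unbroken tracks whose C/N traces match
the analytic ground truth to ~1e-16 relative error (the rendered movie
conserves each cell's total KTR signal, so compartment means are exact).

The `analysis/` directory holds the same steps as a numbered workflow
(`01_simulate.R` … `06_ratiometrics.R`); each script prints what it found
and writes its tables under `results/`.

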