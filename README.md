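# sptkit

Single-molecule tracking (SMT) analysis of membrane protein dynamics,
for experiments that image two proteins in two colours — e.g. a
G-protein-coupled receptor together with a GPCR kinase by TIRF
microscopy — and ask how their mobility, confinement, interaction
kinetics and oligomeric state change across conditions. The package
starts from linked trajectories (one CSV row per localization) and
provides every downstream stage, plus a synthetic trajectory
generator with complete ground truth so each stage can be validated
by parameter recovery without external data.

## What it computes

* **Diffusion-state segmentation.** A variational-Bayes hidden Markov
  model over per-frame displacements: in state *k* the displacement
  per axis is N(0, σ²ₖ), states switch by a row-stochastic matrix *A*,
  and conjugate Dirichlet/Gamma posteriors are updated by
  forward–backward VB iterations (compiled core). The number of
  states is selected by the highest variational lower bound; states
  are ordered by increasing variance (immobile → fast), with
  Dₖ = max(0, (σ²ₖ − 2σ²loc)/(2Δt)).
* **MSD and confinement.** State-wise mean-square displacement with
  pair-count weighting; free fits MSD(t) = 4Dt + c and confined
  (square-domain) fits MSD(t) = (L²/3)(1 − e^{−12Dt/L²}) + c;
  localization precision from photon statistics
  (σ²ₐ = σ²psf + a²/12; σ²loc = F·(σ²ₐ/N)(16/9 + 8πσ²ₐb²/(Na²))).
* **Colocalization kinetics.** Events are frames where a channel-1
  and a channel-2 particle are within 100 nm *and* in the same
  diffusion state, greedily paired and merged over consecutive
  frames. On-event rate per channel-1 particle time; dissociation
  rate by censoring-aware, left-truncated exponential MLE; shuffled
  (toroidal-shift) baseline for chance colocalization.
* **Oligomer orders.** Spot-intensity histograms decomposed into a
  constrained Gaussian mixture with component means n·μ₁ and SDs
  √n·σ₁, monomer scale anchored on the (monomeric) fast state; mean
  order Σn·wₙ with bootstrap CIs for condition differences.
* **Plate assays.** Fold-change and window quantification for
  split-luciferase kinetics (13–15 min window; vehicle-normalized
  27–30 min window for internalization), and the BRET index
  I_acceptor/(I_donor + I_acceptor).
* **Reporting.** Per-cell metrics summarized as mean ± SEM across
  cells per condition, with run manifests.

See `vignettes/sptkit-methods.Rmd` for the model details, default
parameters and known limitations.

## Worked example

Simulate the reference two-channel acquisition (four diffusion
states, 30.5 ms frames, 300-frame movies, scripted binding), segment
each channel, and quantify confinement and interaction kinetics:

```r
library(sptkit)

cfg <- default_config(n_tracks = 60, seed = 8)
sim <- simulate_tracks(cfg)
sim$tracks
#> track_set: 19612 localizations, 120 tracks, 1 cell(s), dt = 0.0305 s

fit1 <- vb_fit(sim$tracks, K = 4, channel = 1, sigma_loc = cfg$sigma_loc, seed = 1)
fit2 <- vb_fit(sim$tracks, K = 4, channel = 2, sigma_loc = cfg$sigma_loc, seed = 1)
fit1
#> vbhmm: K = 4, lower bound = 24976.87 (converged)
#>   sigma2 (um^2): 0.0009657 0.002165 0.008194 0.02762
#>   D (um^2/s):    0.002716 0.02238 0.1212 0.4396

labels <- rbind(frame_labels(fit1), frame_labels(fit2))
curves <- state_msd(sim$tracks, labels, max_lag = 10)
fit_msd(curves[curves$state == "1", ], "confined")
#> msd_fit (confined): D = 0.009631 um^2/s, L = 0.1465 um (147 nm), offset = 0.001473 um^2

ev <- detect_coloc(sim$tracks, labels)          # 100 nm + same state
coloc_kinetics(ev, sim$tracks)
#> coloc_summary: 71 events, on-rate 0.2178 /particle/s
#>   k_off 6.171 /s (95% CI 4.857-7.84), lifetime 0.1621 s

round(state_fractions(fit1)$fraction, 3)
#> [1] 0.260 0.243 0.243 0.253
```

The recovered diffusion coefficients bracket the generating values
(0.005, 0.03, 0.12, 0.45 µm²/s), the immobile-state confinement
length (147 nm) lies in the 90–250 nm range typical of membrane
domains, and the colocalization summary reflects the scripted binding
(note that proximity dwell times are shorter than bond lifetimes —
see the vignette).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/sptkit simulate --config inst/extdata/default_config.yaml \
        --seed 7 --out out/sim
Rscript inst/scripts/sptkit segment --tracks out/sim/tracks.csv --dt 0.0305 \
        --kmin 1 --kmax 6 --out out/seg
```

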