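---
title: "Models and methods behind dfmcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dfmcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfmcyto)
```

# The problem

Differential fluorescent marking (DFM) encodes bacterial strain identity
combinatorially: three fluorescent proteins — mCherry, sYFP2 and mTagBFP —
are expressed singly or in pairs, giving six distinguishable
presence/absence patterns (R, Y, B, RY, RB, YB). A conventional
three-laser flow cytometer then demultiplexes a mixed community, e.g. a
six-member synthetic community colonising plant roots, into per-strain
event counts, which are converted to absolute abundances per gram of
root. `dfmcyto` implements the full analysis chain plus a calibrated
event simulator, so every stage can be tested against known ground truth.

# The gating model

Gating is a fixed, deterministic chain:

1. **Bacteria**: the concentrated region of the (log FSC, log SSC) plane.
   Manual instrument software draws this by eye; we use a reproducible
   surrogate: bin events on a 128×128 grid over the data range, rank bins
   by occupancy, and keep events in the densest bins that jointly contain
   a fraction `density_fraction` (default 0.95) of events. A polygon
   override exists for parity with GUI gating. Events with non-positive
   scatter cannot be log-transformed; they are excluded and counted.
2. **Singlets**: bacteria with FSC > 0 and aspect-ratio of SSC > 0.4.
   Aggregates have elongated SSC pulses and fall below the cut. All
   thresholds in the chain are strict (`>`), following the convention
   "above N FI units".
3. **Colour populations**: a singlet is Red if its "561-611/31" intensity
   exceeds 550 FI, Yellow if "488-528/46" exceeds 500 FI, Blue if
   "405-456/51" exceeds 450 FI. Intensities are thresholded as stored —
   no log transform, no compensation.
4. **Combined populations**: the six exclusive classes are the single and
   pairwise colour patterns. All-negative *and* triple-positive singlets
   are labelled `Unassigned` — the scheme defines six classes only, and
   silently folding triple positives into a colour class would hide
   spillover pathologies. They are reported, never dropped.

Spillover-matrix unmixing and cluster-based auto-gating are deliberately
out of scope: the method's point is that fixed one-dimensional thresholds
suffice for presence/absence barcodes.

# The event simulator

No per-strain fluorescence distributions are published for this assay, so
the simulator is calibrated to reproduce the printed accuracy bounds
rather than raw data. This is the single most important caveat: a green
acceptance test establishes that the pipeline reproduces the published
detection/accuracy bounds *under the frozen calibration below*, not that
the simulator matches any particular instrument.

**Spectra.** Each fluorophore's excitation and emission spectra are
Gaussians parameterised by (peak, sigma) with peaks from the fpbase
reference spectra (mTagBFP 399/456 nm, sYFP2 515/527 nm, mCherry
587/610 nm) and sigma 30 nm. The response of fluorophore *f* in channel
*c* with laser $\lambda_L$ and filter $[lo, hi]$ is

$$R_{f,c} = e^{-(\lambda_L - ex_f)^2/(2\sigma_{ex}^2)}
  \left[\Phi\!\left(\tfrac{hi - em_f}{\sigma_{em}}\right) -
        \Phi\!\left(\tfrac{lo - em_f}{\sigma_{em}}\right)\right].$$

Responses below $10^{-3}$ of the fluorophore's peak response are clipped
to zero — a detector noise floor. This keeps the two physically
meaningful spillovers (sYFP2 into the red channel, ~0.9% of its primary
response; mTagBFP into yellow, ~0.1%) and removes the negligible ones,
so a noise-free mCherry-only strain is *exactly* zero in yellow and
blue. No maturation kinetics, photobleaching or detector saturation are
modelled.

**Frozen signal/noise calibration.** Brightness is normalised per
fluorophore so the primary-channel median signal is 5000 FI at
`expression_scale = 1`. Per-event expression noise is log-normal with
geometric SD 2.0 (one draw per fluorophore per event). Autofluorescence
is additive and log-normal per channel: medians 80/40/40 FI
(blue/yellow/red) with geometric SDs 2.2/2.0/2.0. Under these tails the
unlabelled strain exceeds the blue threshold with probability
$1-\Phi(\ln(450/80)/\ln 2.2) = 0.0142$ — the dominant false-positive
route, matching the published observation that misassignment is blue —
while expressed channels are detected for >99% of singlets. These
parameters are frozen; they are generator fixtures, not measurements.

**Doublets and debris.** A doublet (default 2% of events) is the
channel-wise sum of two singlets with aspect-ratio drawn below 0.4, so
the singlet gate is consequential. Debris (default 3%) has low
log-normal scatter (medians 300/150 vs 20000/10000 for cells), dim
autofluorescence and uniform aspect-ratio, and is mostly removed by the
density gate. Uninoculated-root background events have broad debris-like
scatter and elevated blue autofluorescence (median 120 FI, GSD 2.5 for
pea; 100 for barley) — lignin/suberin-type blue background — so
background events that survive gating land mainly in B-containing
classes.

**Determinism.** Every generator draws all randomness under one integer
seed (default 3841) and restores the caller's RNG state; same seed,
same inputs means bit-identical output.

# Absolute quantification

Gated counts become concentrations and then per-root-mass abundances:

$$\mathrm{emL} = \frac{count \cdot dilution}{V_{analysed}},\qquad
  \mathrm{egr} = \mathrm{emL}\cdot\frac{V_{harvest}}{m_{root}}$$

with $V_{analysed}$ either recorded directly or as flow rate × time
(default 3.66 µL·min⁻¹, the low-speed/high-sensitivity setting) and
$V_{harvest}$ defaulting to 25 mL. `dilution` defaults to 1: passive
subsampling does not change a concentration, so the factor exists only
for explicit user dilutions.

Background correction subtracts, per (plant, combined population), the
mean egr of uninoculated-plant replicates — pooled across timepoints,
since a single background table is the published convention; whether the
original background was pooled or per-timepoint is not stated, and
pooling is this package's choice. Negative corrected values clamp to
zero and raise `below_background`; a missing background key is a hard
error. Relative abundances normalise the six combined populations per
sample (Unassigned excluded from the denominator); an all-zero sample is
flagged `undefined`, not dropped.

# Growth curves and MGT

The generator produces logistic growth after a lag with specific rate
$\mu = \ln 2 / \mathrm{MGT}$, additive Gaussian OD noise (default SD
0.002, a realistic plate-reader repeatability) and a recorded blank.
Defaults: lag 2 h, od0 0.005, od_max 1.0, dt 0.25 h, 72 h — a minimal
medium run for a rhizobium with MGT ≈ 3.4 h.

`estimate_mgt()` slides a `window_size`-point window (default 5) over
$\ln(\mathrm{OD} - \mathrm{blank})$ versus time, keeps windows with
$R^2 \geq$ `r2_min` (default 0.99) and positive slope, and takes the
maximum qualifying slope: $\mathrm{MGT} = \ln 2/\mu$. Windows containing
readings at or below `od_min` (default 0.005 above blank) are excluded
as noise-dominated; a curve with no qualifying window returns an invalid
estimate rather than a number.

**Accuracy analysis (why one acceptance criterion is red).** With a
5-point window the fitted log-slope has standard error
$\sigma_{\ln}/0.79$ per window, where $\sigma_{\ln} \approx
\mathrm{noise\_sd}/\mathrm{OD}$. The $R^2$ filter admits a window only
when $\sigma_{\ln} \lesssim \sqrt{0.01\,SST/3}$, which for a slow grower
(MGT 6 h) forces windows to OD $\gtrsim 0.3\,K$, where logistic
curvature deflates the slope by 25% or more; at lower ODs, the
max-slope rule selects noise-inflated windows. Parameter scans (window
5–29 points, $R^2$ 0.8–0.99, OD floors and caps, up to 21 replicates)
never achieved 5% median recovery for all of MGT {1, 2, 3.4, 6} h at
0.005-OD noise; the corresponding acceptance test is therefore left
failing, with the analysis recorded, rather than weakened. The same
estimator recovers MGT within 1% on noise-free curves and exactly (to
machine precision) on pure exponentials, which is what its green tests
assert. Parametric (Gompertz/Baranyi) fitting is out of scope.

Blank handling: the recorded blank is used when present; curves read
from plate-reader CSV default to the minimum of the first three
readings. That self-blank also subtracts the inoculum OD, which inflates
early log-slopes when the inoculum is large; in practice inoculum OD is
below reader resolution, and the tests mirror that.

# Assembly statistics

`summarise_series()` reports mean, SD, SEM ($= SD/\sqrt{n}$) and
replicate count per strain × timepoint on corrected egr; empty cells are
absent, not zero-filled. `correlate_strains()` pairs observations at
(replicate, timepoint) level by default — the published pairing is not
fully specified, so timepoint-mean pairing is available as an option —
and returns Pearson r, r² and the two-sided p-value. t-test/Wilcoxon
wrappers are thin conveniences over `stats`, documented as standard
statistics. `simulate_colonisation()` provides logistic colonisation
trajectories with log-normal replicate noise (GSD 1.5, 4 replicates by
default) purely as a test bed with known truth; it models no ecology
(no interactions, no succession), so green assembly tests establish
statistical bookkeeping, not biology.

# Tn7 junction calling

A junction read runs from the 3' end of *glmS* (ending at its stop
codon) across `offset` bases of downstream genome into the transposon
right end (Tn7-R). `call_att()` anchors the read with the 30-bp 3'
suffix of the *glmS* reference and the 20-bp prefix of Tn7-R — exact
substring matches, each required exactly once and non-overlapping — and
reports the number of bases strictly between the stop codon's last base
and the start of the Tn7-R match, plus the 5 bases immediately upstream
of the insertion point (the target-site duplication). The prose
convention "N bp from the stop codon" is implemented; the alternative
figure convention (coordinate 0 at the centre of the duplicated 5-mer)
differs only by a fixed anchor shift. If forward anchoring fails the
reverse complement is tried, so reads in either orientation give the
same call. An optional Hamming scan tolerates up to 2 mismatches per
anchor (off by default — Sanger-quality reads do not need it). Offset
histograms plus positional 5-mer consensus tallies replace multiple
sequence alignment: for this question (is the distance conserved? is the
sequence?) they carry the same information. Random target sites yield
"no conservation", the expected conclusion for a transposon that targets
a distance, not a sequence.

# Files, configuration, reproducibility

Event tables round-trip through per-event CSV and a minimal FCS 3.1
codec (list mode, float32, `$PnN` names `FSC`, `SSC`, `AspectRatioSSC`,
`Intensity_<channel>`; `|` as TEXT delimiter because channel keys
contain `/`). The FCS reader accepts FCS 3.0/3.1 with float or integer
data and either byte order, and maps vendor `$PnN` names to canonical
channels through a user-supplied map — an unmapped required channel is a
hard error naming the channel. `run_pipeline()` validates its JSON/list
config strictly (unknown keys anywhere are rejected; enabling
background subtraction without a background block fails before any
stage runs), executes simulate → gate → demultiplex → quantify →
subtract → summarise, and writes tidy CSVs plus a JSON report carrying
the seed, config MD5 and package version. Identical configs produce
byte-identical outputs.

# Known limitations

- The simulator is calibrated to published summary bounds, not to raw
  instrument data; absolute FI scales are nominal.
- The density-grid Bacteria gate is a reproducible surrogate for a
  hand-drawn gate, not a clone of any vendor algorithm.
- MGT estimation under realistic per-read noise carries 10–20% scatter
  (see above); replicate medians and low-noise data are required for
  accurate values.
- Statistics on real plant data (CFU comparisons, published
  field-sample tables) are out of scope; all tests run on synthetic
  data with known truth.
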