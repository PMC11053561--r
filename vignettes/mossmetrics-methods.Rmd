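---
title: "Methods: water retention and 3D colony morphometry in Sphagnum"
author: "mossmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water retention and 3D colony morphometry in Sphagnum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossmetrics)
```

# The scientific problem

*Sphagnum* mosses regulate the water balance of peat bogs. They lack the
hydration controls of vascular plants, so almost everything about their
drought resilience comes down to where and how much water they can hold:
in the dead hyaline storage cells, in capillary films on and between the
two branch types (lateral *spreading* branches and stem-appressed
*pendent* branches), and in the pore spaces of the colony between
neighbouring stems. `mossmetrics` implements the three quantitative
procedures used to dissect these stores:

1. **Centrifugal water fractionation** — a saturated plant is spun at a
   schedule of increasing relative centrifugal forces (default 17, 66,
   149, 266 g for 5 min each) and the water recovered at each step is
   weighed. Loosely held (extracellular, capillary) water leaves at low
   force; hyaline and intracellular water does not leave at all under
   gentle spinning.
2. **Micro-CT morphometry** — single plants and intact colony cores are
   imaged as 3D voxel stacks; the package computes plant volume, surface
   area, the convex hull of the specimen, pore volume and porosity.
3. **Cosm drought dynamics** — microcosms holding 10–40 plants over a
   20 cm² cross-section (0.5–2.0 plants cm⁻²) are weighed through a
   three-week drought and one week of rewetting; the package converts
   weights to relative water content (RWC), fits loss rates, integrates
   time below a low-water threshold, and scores recovery.

Because the study design rests on physical specimens, the package ships
a first-class synthetic-data module — voxel phantoms with analytic
ground truth, pool-based centrifugation ledgers, and closed-form drought
trajectories — so that every estimator can be validated against known
truth.

# Definitions and units

All physical quantities are carried in fixed units named in the column
headers: µm (voxel spacing), mm³ (volumes), mm² (areas), g (masses),
% (RWC), days (time). The central quantity is relative water content,

$$\mathrm{RWC} = \frac{\text{wet weight} - \text{dry weight}}
  {\text{dry weight}} \times 100\%,$$

which for saturated *Sphagnum* can exceed 2000%. Porosity is the void
fraction within the convex hull of the specimen,

$$\phi \;=\; \frac{V_{\text{hull}} - V_{\text{plant}}}{V_{\text{hull}}},
  \qquad V_{\text{pore}} = V_{\text{hull}} - V_{\text{plant}},$$

with all three terms computed from the same voxel counts so the identity
$\phi\,V_{\text{hull}} = V_{\text{pore}}$ holds exactly.

# Fractionation analysis

`percent_weight_loss()` expresses the water released at each force as a
percentage of the *initial* (saturated) weight — never the running
weight — so per-force losses sum to the cumulative loss and the
cumulative series is non-decreasing by construction. `rwc_before_after()`
computes RWC before the first and after the final spin; the post-spin
weight is taken from the ledger (`saturated − Σ released`) unless a
measured value is supplied, and a measured value that disagrees with the
ledger by more than 1% of the saturated weight is an error rather than
something to average away. One sentence in the source protocol can be
read as normalising the post-spin RWC by the initial weight instead of
the dry weight; the package follows the unambiguous dry-weight formula
and exposes the alternative as `normalise = "initial_weight"` without
claiming either is what was done historically.

`branch_contribution()` compares total recovered water between intact
and dissected plants of one species: the two-sample gate below plus a
difference of group means with a seeded bootstrap percentile interval
(10 000 resamples by default — stable 95% intervals at n ≈ 10 per
group).

## The two-sample gate

Every two-group contrast runs through `compare_groups()`: a gross-error
screen, Shapiro–Wilk normality on each group at α = 0.05, then a Welch
two-sample t-test if both groups look normal and a two-sided Wilcoxon
rank-sum test otherwise. The rank-sum p-value is computed by full
enumeration of all $\binom{N}{n_a}$ group assignments (midranks for
ties) whenever the pooled sample has at most 20 observations, and by the
tie-corrected normal approximation beyond that.

The outlier screen uses Tukey fences at **3 × IQR** (Tukey's "far out"
fences), not the conventional 1.5 × IQR. This was a deliberate
calibration decision: at n = 10 per group, 1.5 × IQR fences flag at
least one observation in roughly 40–48% of clean normal samples, and
trimming those tails inflates the size of the downstream t-test to about
0.09–0.10. The far-out fences still catch the transcription and
recording errors the screen exists for, flag clean samples only rarely,
and keep the empirical type-I error of the whole pipeline at ≈ 0.045–0.07
(measured over 1000 replicates in the acceptance suite). The multiplier
is exposed as `outlier_k` for users who want the conventional fences.
Removed observations are always logged by id in the result.

# Morphometry pipeline

`analyze_specimen()` chains the stages:

* **Segmentation** (`segment()`): Otsu's threshold on the intensity
  histogram by default (the scan protocol's manual threshold is unknown,
  so a deterministic automatic threshold is the honest default, with
  `method = "fixed"` as an override), followed by removal of connected
  components (26-connectivity) smaller than 27 voxels — the programmatic
  counterpart of removing "unwanted components" by hand. 26-connectivity
  for component cleanup is paired with 6-connectivity for face exposure,
  the standard morphological pairing.
* **Apex crop** (`crop_top()`): the apex is the lowest z-slice holding
  any foreground after cleanup (arrays are `[z, y, x]` with z = 1 at the
  top; 1-based indices, and the crop keeps
  `floor(height/spacing_z)` slices starting at the apex). Cropping (40 mm
  by default) is also the sole mechanism for excluding standing water at
  the base of a scanned core — no intensity unmixing is attempted.
* **Volume**: foreground voxel count × voxel volume.
* **Surface area** (`surface_area()`): the default `face_count`
  estimator counts exposed voxel faces (the voxel reading of "sum of
  external pixels"). This estimator is *biased upward* for smooth oblique
  surfaces — by a factor approaching 1.5 for a sphere — which is
  documented and deliberate: it is the definition used for the headline
  outputs, and comparisons between specimens share the bias. The
  `isosurface` estimator is the cross-check: the binary mask is smoothed
  with a small separable Gaussian (σ = 1.5 voxels) and the area is
  computed by the coarea formula as $\int |\nabla u|\,dV$, which is
  accurate to well under 3% for smooth shapes (0.2% on an r = 30 voxel
  sphere). A triangulated-mesh estimator was considered and rejected:
  no marching-cubes implementation is available as a dependency, and the
  gradient-integral estimator achieves the same cross-check purpose with
  far less machinery. The isosurface estimator under-reads sharp-edged
  objects (smoothing rounds corners), so it is a cross-check for organic
  shapes, not a replacement.
* **Convex hull** (`convex_hull()`): an incremental (quickhull-style) 3D
  hull over the physical coordinates of foreground voxel *centres*,
  implemented in the package because no installed dependency provides 3D
  hulls. Using centres rather than voxel corners biases the hull small
  by up to one voxel shell; this is documented and covered by the stated
  tolerances (hull volume of a 30-voxel-radius sphere is within 2% of
  the closed form). The candidate cloud is first reduced to per-column
  extreme voxels, which provably contain every hull vertex. The hull is
  rasterized back onto the lattice by exact plane slicing: each z-plane
  cross-section of the polytope is a convex polygon, scan-converted row
  by row; rasterizing the hull of a rasterization is idempotent.
* **Porosity** (`porosity()`): voxel-count arithmetic on the rasterized
  hull, as defined above. A foreground voxel outside its own hull raster
  is an internal-consistency error, not a warning. The hull is computed
  on the *cropped* region (whether the historical workflow computed it
  per core or per cropped region is unknown; cropped is the choice here,
  stated in the output).

Scanner resolutions quoted as bare numbers ("29.6", "73.6") are
interpreted as isotropic voxel edge lengths in µm, but spacing is always
read from file metadata (NRRD/MetaImage headers, or the JSON sidecar of
a TIFF stack) and never assumed — a volume without spacing metadata is a
hard error.

# Drought dynamics

`rwc_trajectory()` converts cosm weights to RWC using the
end-of-experiment dry weight and a *required* container tare (the tare
has no default: cosm weights without tare handling are ambiguous).
Statistics that involve dry weight use the final-day measurements, since
drying the plants ends the experiment. Water content is reported both
per cosm and per plant, labelled, because figure conventions differ on
this point.

`loss_rate()` fits a least-squares line to RWC over the drought window —
the default because observed drying is quasi-steady — with an
exponential-to-floor fit behind `method = "exponential"`.
`time_below()` integrates time spent under a configurable low-water
threshold (default 100% RWC; the notion of "low water" is qualitative,
so the threshold is a config knob) with linear interpolation at
crossings. `recovery()` compares the last rewetting-window observation
to the pre-drought baseline, defined as the mean of *all* pre-drought
observations (the operational meaning of "pre-drought condition" is
otherwise unspecified).

`density_effect()` tests whether resilience improves across ordered
planting densities with a Jonckheere–Terpstra permutation trend test on
the loss-rate magnitude (and on time-below when available): the ordered
design carries more information than pairwise tests, and the permutation
null requires no distributional assumptions. All distinct group
assignments are enumerated exactly for small designs (≤ 20 000
arrangements); otherwise seeded random permutations with the add-one
rule are used.

# The synthetic-data module

The generators define the study conditions; they are fixtures *and*
tested code.

**Phantoms.** Analytic solids (sphere, cuboid, hollow cylinder) carry
closed-form volume, area, hull volume and porosity. The procedural
branched plant is a vertical stem cylinder with spreading branches at
80° from the stem axis and pendent branches appressed at 10°, azimuths
spread by the golden angle — a geometric caricature of the two branch
types, with no claim of anatomical accuracy. Colony cores place
vertical stems by seeded dart-throwing (Poisson-disc) sampling inside a
73 mm circular holder at a target areal density, with a deterministic
ring of stems at the wall (a core cut from a continuous cushion has
plants out to its boundary; the ring also keeps the hull stable as
interior stems are added, which is what makes the density–porosity
relationship strictly monotone by construction). Foreground and
background intensities are fixed constants (200 and 30) so the default
segmentation threshold is deterministic; Gaussian noise is optional.

**Centrifugation ledgers.** A plant's water is split into four labelled
pools — branch capillary, inter-stem, hyaline, intracellular — each
draining completely once the applied force reaches its threshold, with
thresholds ordered so the loosest water drains first. Defaults (0.9,
0.5, 0.35, 0.15 g over a 0.1 g dry weight; thresholds 15, 60, 600,
5000 g) give a saturated RWC of 1900% and a post-spin RWC of 500%, with
the hyaline and intracellular pools deliberately out of reach of the
gentle force schedule. Weighing noise is zero-mean Gaussian truncated so
masses stay non-negative and never exceed the water actually present;
the noise-free ledger conserves mass exactly.

**Drought trajectories.** The observed drying curves come with no
governing equation, so the generator's closed form is an explicit
modelling choice, not a claim about the mechanism: RWC decays
exponentially towards a residual floor,
$RWC(t) = f + (R_0 - f)e^{-k(n)t}$ with
$k(n) = \frac{\text{base}}{R_0 - f}\,a^{\,n-10}$.
Defaults: $R_0 = 1200\%$, floor $f = 50\%$ (plants keep a substantial
fraction of their weight as tightly held water even when air-dry),
base = 145 %/day at the 10-plant reference, attenuation $a = 0.97$ per
added plant, 7 d baseline + 21 d drought + 7 d rewetting observed every
3.5 d. The base rate was chosen so the drying curve stays quasi-linear
over the three-week drought (matching the observed steady decline); a
useful side effect is that the fitted *linear* loss-rate magnitude is
then strictly decreasing in density over the 10–40 plant range (a very
fast early decay would flatten most of the window and break that
ordering for the linear summary, though never for the rate constant
itself). Rewetting relaxes RWC back to $R_0$ with time constant
`rewet_days/5`, i.e. essentially complete recovery, which is what was
observed. Fv/Fm, when simulated, is a saturating logistic link from RWC
(≈ 0.78 when wet, collapsing below ≈ 150% RWC) — a heuristic proxy, not
a photosynthesis model.

What the generators deliberately do *not* emulate: hyaline-cell
microstructure, capillary flow, evaporation physics, microclimate
covariates, or species identification. Tests passing on this synthetic
material therefore validate the *estimators* (their arithmetic,
invariances and calibration), not any biological claim about real
colonies.

# Numerical choices and degenerate inputs

* Hull computations use a relative tolerance of $10^{-9}$ of the cloud
  diameter for visibility tests and $10^{-6}$ of the voxel spacing for
  raster inclusion, padded symmetrically so lattice symmetries (90°
  rotations) are preserved exactly. Collinear or coplanar foregrounds
  are errors (a 2D fallback is out of scope).
* The exact rank-sum test doubles the smaller tail and caps at 1, which
  matches full-enumeration two-sided p-values for tie-free data;
  identical samples give p = 1.
* Ledger consistency uses a 1 e-9 g tolerance; simulated noise-free
  records satisfy it exactly.
* Zero-residual fits (noise-free simulations) trip `nls`/`lm`
  convergence warnings; these are suppressed where the estimates are
  exact by construction.
* Empty foreground after cleanup, missing tare, missing spacing, tare
  above the recorded weight, inconsistent post-spin weights, unknown
  config keys, and single-density trend requests are all hard errors.

# Problem sizes

The test and acceptance workloads are sized for a single CPU: phantom
grids up to 128³ voxels (the sphere oracle), colony sweeps at
24 × 76 × 76, 1000-record mass-balance sweeps, 1000-replicate gate
calibration, and 200-replicate power/type-I studies of the trend test
with 199 permutations each. At these sizes the full suite runs in about
a minute and the acceptance script in under a minute.

# Known limitations

* The hull-over-centres bias (≤ one voxel shell) makes hull volume and
  porosity slightly conservative for small specimens; at the grid
  resolutions used here the effect is under 2%.
* Face-count surface area carries the voxelization factor (up to 1.5 on
  smooth surfaces); cross-specimen comparisons share it, absolute areas
  do not.
* The drought generator's exponential-to-floor form is a stand-in for
  unknown drying dynamics; conclusions about real drying curves require
  real cosm data through the same interface (`read_cosm_csv()`).
* The Fv/Fm link is heuristic; recovery ratios for Fv/Fm should be read
  as plumbing checks, not physiology.
* Scanner-native (ISQ) import is out of scope; volumes must arrive as
  NRRD, MetaImage or TIFF + sidecar.
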