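---
title: "Models and methods behind amwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Arbuscular mycorrhizal (AM) fungi colonize space as a travelling wave: a
pulse of growing hyphal tips advances at a constant speed while the
filament density left behind saturates at a low, spatially uniform value.
`amwave` implements the quantitative machinery of that picture — a minimal
reaction-advection model, ring-frame density estimation, tracking-based
event detection, reference-normalized graph metrics, and kymograph
velocimetry — together with an agent-based generator of synthetic colonies
that supplies ground truth for every estimator. This vignette records the
models, the parameter choices, the numerical decisions, and the known
limits of what the synthetic validation can show.

## The BARE wave model

Two coupled fields live on a 1D transect (Cartesian) or radius (radial):
the growing-tip density $n(r,t)$ (mm$^{-2}$) and the hyphal filament
density $\rho(r,t)$ (µm mm$^{-2}$, length of hypha per unit area):

$$\partial_t n = \alpha n \;-\; \beta n \rho \;-\; \nabla\!\cdot\!\big(v\,
n\,\hat r - D_n \nabla n\big), \qquad \partial_t \rho = v\, n .$$

Tips multiply by branching at rate $\alpha$ (default 0.04 h$^{-1}$), are
annihilated by anastomosis at rate $\beta\rho$ (with $\beta$ = 23 µm h$^{-1}$
in the convention where $\beta\rho$ carries an implicit µm²/mm² = 10$^{-6}$
factor, so $\beta\rho_{\rm sat}\approx 2\%$ h$^{-1}$ at $\rho\sim10^3$
µm mm$^{-2}$), and advect outward at the tip extension speed $v$. Every tip
deposits filament at speed $v$, which is the $\rho$ equation. The flux form
$J = D_n\nabla n - v n \hat r$ is a modelling commitment of this package:
advection-dominated transport with a small diffusivity reproduces a pulled
front whose speed is $c = v + 2\sqrt{\alpha D_n}$, and the default
$D_n = 12$ µm² h$^{-1}$ keeps the Fisher correction below 0.5% of $v$.

Two consequences are used as oracles. First, the front is *pulled*: its
speed equals the advection speed of the leading tips, up to the
$2\sqrt{\alpha D_n}$ correction. Second, integrating the $n$ equation
across a steadily travelling profile gives the wake balance
$\alpha\rho_{\rm sat} = \tfrac12\beta\rho_{\rm sat}^2$, i.e.
$\rho_{\rm sat} = 2\alpha/\beta$ (≈ 3.5×10³ µm mm$^{-2}$ at the default
parameters). The balance holds only for the *equilibrated* wave. With a
small $D_n$ the relaxation is extremely slow — in the comoving frame tips
drift backwards at just $2\sqrt{\alpha D_n}$, so crossing the ~7 mm wide
wake takes thousands of hours — and transient wakes over- or under-shoot.
The wake-balance checks therefore run with $D_n = 3000$ µm² h$^{-1}$ for
1200 h, where the numerical wake agrees with $2\alpha/\beta$ to under 2%
at 50 µm resolution.

### Numerics

First-order conservative upwind advection, explicit central diffusion and
forward-Euler reactions. The time step is tied to the grid through the
Courant number $v\,\Delta t/\Delta r$, **default 1**, at which the upwind
transport step is exact (zero numerical diffusion); this matters because at
Courant < 1 the scheme's effective diffusivity $v\Delta r/2\,(1-C)$ would
inflate the pulled-front speed by ~10% at practical grids. The radial
geometry cannot run at Courant 1 (the outflux factor $(r+\Delta r/2)/r$
exceeds 1 near the origin), so radial runs internally scale the step by
0.45; radial-vs-Cartesian comparisons therefore match the Courant number
explicitly. Positivity is enforced (a CFL-violating configuration is
refused with the stable step reported), $\rho$ is non-decreasing by
construction, and halving $\Delta r,\Delta t$ moves the measured speed and
wake density by under 1%.

### Phosphorus extension

Analyses of this system couple the wave to diffusion-limited phosphorus
absorption; the exact uptake law is not standardized, so `amwave` declares
its own minimal form,

$$\partial_t P = D_P \nabla^2 P - k_{\rm up}\,\rho\,P,$$

first-order in both filament density and concentration, with absorbed P
accumulated exactly so that medium + absorbed is conserved to round-off.
A depletion front co-propagates with the colony, and total absorbed P
increases with wave speed. One qualitative claim sometimes made for such models does **not**
follow from this form: the carbon cost per absorbed P,
$\gamma L_{\rm tot}/P_{\rm abs}$, is asymptotically independent of $v$
(both numerator and denominator scale with the swept area, and the
diffusive correction in fact slightly favours slow waves). The package
reports what its declared model does; `cost_per_phosphorus()` and the
tests assert the invariances that actually hold.

## The agent-based colony generator

`simulate_colony()` grows an off-lattice planar colony from root-anchor
points on the barrier line ($y=0$, fungal half-plane $y>0$): each tip
advances $v\,\Delta t$ along its heading per 1 h frame with small heading
noise (0.02 rad step$^{-1}$; runner hyphae are nearly straight), branches
at rate $\alpha$ with daughters placed up to 100 µm behind the apex at
30–90° offsets, and on contact with existing filament either fuses
(probability `p_fuse`) — annihilating the tip, whose tracked node becomes a
degree-3 junction — or crosses, creating a degree-4 junction. Tip speeds
are persistent draws from a truncated normal (mean 240, maximum 280
µm h$^{-1}$); the fast subpopulation that ends up at the front *is* the
puller population rather than being imposed.

Defaults encode the measured conditions: $\alpha = 0.04$ h$^{-1}$ and
`p_fuse` = 0.12, chosen once so that the realized annihilation coefficient
$\beta_{\rm eff} \approx p_{\rm fuse}\, v\, \langle|\sin\theta|\rangle$
(with $\langle|\sin\theta|\rangle \approx 0.8$ over realized encounter
angles) lands at the measured 23 µm h$^{-1}$. BAS decoration appends short
(< 400 µm), thin laterals behind the front until the BAS length fraction
tracks 30%; spores are a Poisson process at 5×10$^{-4}$ mm$^{-1}$ h$^{-1}$
of filament exposure, a rate chosen once to reproduce the reported
order of ~300 spores per colony at full (400 h) duration.

### Data model

The bundle format stores per-timepoint node positions and degrees plus a
static edge table, which cannot express edges that grow or split. The
package's representation: each hypha is **one edge** from its origin
junction to its (mobile) tip node, whose polyline is the full final path;
a snapshot truncates the polyline at the tip's tracked position. Junctions
created later (branch points, crossings, fused tips) may sit on the
*interior* of an edge's polyline; snapshots detect these pass-through
incidences geometrically (0.05 µm tolerance) and split edges on the fly,
so degrees and topology are exact at every frame while the stored tables
never rewire or delete an element. A fused tip's tracked node is the
junction itself, which is what produces the 1→3 degree signature the
anastomosis detector looks for. Two deliberate blind spots: branching is
suppressed within 600 µm of the ROI boundary and on the final frame
(daughters born there could never display the displacement that defines a
growing tip — the imaging analogue has the same limitation), and crossings
appear as degree-4 junctions from birth, without the transient 1→3→1
track that skeleton re-identification produces in real tracking (the
detector's revert rule is exercised on constructed histories instead).

## Ring-frame estimation

`make_rings()` builds $N$ = 15 equal-area half-annuli, boundaries
$r_k = r_{\max}\sqrt{k/N}$. Filament density is exact clipped polyline
length per ring area (segments are split at ring circles, so boundaries
introduce no bias and lengths are conserved); tip density counts growing
runner-hypha tips. Bootstrap bands split a ring into 10,000 equal-area
radial–angular cells and resample cell densities 100 times — annular
sector cells stand in for equal-area "rectangles", which cannot tile an
annulus. Arrival times come from sigmoid fits
$\rho(t) = K_1/(1+e^{\lambda(t_n - t)})$ (tips: the sigmoid-derivative
pulse), by Levenberg–Marquardt with documented initial guesses
($K_1 = \max\rho$, $\lambda = 4/(t_{90}-t_{10})$, $t_n$ at first half-max
crossing) and residual-bootstrap confidence intervals. Wavefront speed is
the linear-fit slope of arrival position against arrival time; the puller
proxy is the mean per-frame speed of growing tips that are convex-hull
vertices at consecutive frames. On generator defaults the three speed
estimates (arrival slope, hull-radius slope, mean puller speed) agree
within ~10%; the hull-semicircle radius $r = \sqrt{2A/\pi}$ is the noisier
of the three, exactly as its definition suggests.

## Event detection and rate scaling

Growing tips: degree-1 tracked nodes displaced ≥ 40 px (× 3.25 µm/px
default pitch) from the previous frame. Runner-hypha tips: net displacement
ever > 2.5 mm. Branchings: growing tips first appearing after the initial
frame. Anastomoses: degree histories jumping 1→3 without reversion, timed
at the last degree-1 frame; reverting histories are crossings. On
simulator output these detectors reproduce the ground-truth log exactly
(counts and node identities; times within one frame).

$\alpha$ and $\beta$ are estimated from ring-binned rates as
exposure-weighted ratio estimators — total events over total density
exposure, the Poisson MLE. An unweighted per-frame regression would be
attenuated by ~35% because per-ring tip counts are small (errors in
variables); the MLE recovers $\alpha$ to a few percent and $\beta$ within
~20% of the generator's realized $\beta_{\rm eff}$. The reported
shape-matching claim ($b \propto n$, $a \propto n\rho$) is made assertable
via `wave_frame_profiles()`: per-ring series are aligned by arrival time,
binned (5 h), averaged across rings, and correlated with support weights
(bin means have variance ∝ 1/support; extreme relative-time bins are
covered by one or two rings and are dropped below 20 ring-frames). Both
correlations exceed 0.9 on three pooled replicates; a single 65 h colony
is event-limited (~50 anastomoses) and fluctuates around 0.9.

The cumulative anastomosis count uses the Euler formula: the loop count
$e - v + c$ of the planar snapshot equals the number of bounded faces,
counting fusions *and* loop-closing crossings (degree-4 anastomoses),
matching the field's counting choice. The normalization of anastomosis
density is not defined in the available text; `anastomosis_density()`
defaults to loops per unit network length with an area alternative behind
a flag.

## Graph metrics

Betweenness centrality to the root: one length-weighted shortest path from
every node to its nearest root anchor (via a zero-weight super-root);
an edge's BC is the number of such paths through it. Ties follow igraph's
deterministic traversal order, and one path per node is counted — both
choices the available text leaves open. Efficiencies compare Euclidean to
along-network distance over all node pairs (≤ 2000 nodes, else 10⁵ seeded
pairs) or node–anchor pairs. Reference networks are built on the same node
set: Euclidean MST (computed on the Delaunay edge set, which contains it)
and Delaunay triangulation, giving the normalization
$\hat X = (X - X_{\rm MST})/(X_{\rm DT} - X_{\rm MST})$ for global and
root efficiency and carbon cost $C = \gamma \times$ total length. The node
set is all graph nodes by default. One caveat the tests carry explicitly:
network path lengths follow curved polylines while the references use
straight chords, so a young, nearly tree-like colony can sit marginally
below its MST's efficiency; the bracketing checks allow a 0.02 curvature
margin.

## Kymograph velocimetry

`synthesize_kymograph()` renders constant-velocity particles (Gaussian
point-spread, 20 µm ROI, 144 px, 20 fps defaults) over Gaussian noise.
Trajectory extraction in this field often uses learned tracers; `amwave`
substitutes a classical one with the same contract: per-frame subpixel
peak detection, nearest-neighbour linking under constant-velocity
prediction with an orientation-consistency gate (an established track may
not swap onto a crossing antiparallel line), Theil–Sen slopes, a minimum
duration of 10 consecutive frames, and a speed cap of 20 µm per 10 frames
(40 µm/s at 20 fps). Immotile objects are dropped below 0.8 µm/s — the
reported threshold; re-evaluating the stated Stokes–Einstein formula
($T$ = 298 K, $\eta$ = 0.89 mPa s, $r$ = 35 nm, $\Delta t$ = 20 s) gives
≈ 0.59 µm/s, and the filter reports this formula value alongside. Mapping
to the network snaps a position to the nearest edge within the 100 µm
alignment budget; because each edge is a whole hypha, the curvilinear
distance to its tip is a single arc length. End-to-end (synthesize →
extract → filter → stats), injected per-edge mean speeds are recovered
within 15% at SNR ≥ 3, and linear speed–distance gradients are recovered
within bootstrap CIs.

## Problem sizes

The default validation colonies are one to three barrier anchors for
60–100 h (hundreds of nodes, ~50–250 mm of filament) and three pooled
25-anchor, 65 h colonies (~150 anastomoses) for the rate-scaling checks;
PDE runs use 50 µm grids over 60–400 mm domains. These sizes were chosen
so each property is measured comfortably above its sampling noise while a
full check of the package stays a coffee-break affair on one core.

## What the synthetic validation does and does not show

The generator reproduces the statistical structure the analysis targets —
constant front speed with an emergent puller subpopulation, density
saturation by fusion, BAS decoration, Poisson sporulation, bidirectional
flows tied to network position — so passing tests demonstrate that the
estimators recover known truth under that structure. They do not
demonstrate robustness to what real imaging adds: segmentation and
tracking errors, broken node identities, retracting or collapsing hyphae,
width measurement noise, or colonies whose rate laws deviate from
$b = \alpha n$, $a = \beta n\rho$. The saturation density implied by the
measured $\alpha$ and $\beta$ (2$\alpha$/$\beta$ ≈ 3.5×10³ µm mm$^{-2}$)
also exceeds the ~10³ observed in the source system by a factor of ~3 — a
tension in the reported numbers themselves that the package surfaces
rather than tunes away.
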