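---
title: "A closed-loop digital twin of a laser-scanning photothermal therapy workstation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop digital twin of a laser-scanning photothermal therapy workstation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galvotherm)
```

## The problem

Photothermal therapy (PTT) of superficial tumors heats the lesion with
absorbed laser light. The mild-hyperthermia regime holds the tissue near
42 °C — enough to damage tumor cells and increase vascular permeability,
while staying below ablative temperatures. Doing this safely requires an
instrument that (i) confines the irradiation to an irregular lesion
outline, and (ii) regulates the lesion temperature in real time with a
hard cap (46 °C here) against thermal damage.

`galvotherm` models such an instrument end to end: a two-mirror
galvanometric scanner steering a near-infrared laser over a 5 cm × 5 cm
field at 15 cm distance, a visible camera that supplies the lesion
outline, a radiometric thermal camera that supplies the feedback signal,
and a discrete PID controller that commands the laser power. Because
every hardware element is replaced by a model — including a
heat-diffusion phantom standing in for the absorbing target — the whole
feedback loop can be exercised and tested in software.

## Scanner geometry

Two mirrors deflect the beam by optical angles $\theta_x$, $\theta_y$.
With $d$ the distance from the second mirror to the target plane and $e$
the inter-mirror offset, the beam lands at

$$y = d\tan\theta_y, \qquad
  x = \left(\sqrt{d^2+y^2}+e\right)\tan\theta_x,$$

the $x$ lever arm growing with the $y$ deflection because the $x$ mirror
sits behind the $y$ mirror. `plane_to_angles()` is the closed-form
inverse; the round trip is exact to numerical precision. The treatment
field is discretized as a 30 × 30 matrix with pitch $dp = 50/30 \approx
1.67$ mm; cell $(n_r, n_c)$ (1-based, row 1 at the top) sits at

$$x = (n_c - 15.5)\,dp, \qquad y = -(n_r - 15.5)\,dp,$$

with the 15.5 centering constant generalized to $(n+1)/2$ for other grid
sizes. Mirror commands go through a servo scale factor $s = 0.5$ V per
degree of *mechanical* angle; the optical-to-mechanical ratio defaults
to 2 (a reflected beam turns twice as fast as the mirror — the
instrument convention when the ratio is not stated). The 12-bit bipolar
DAC code is

$$D = \mathrm{round}\!\left(\frac{V - V_\min}{V_\max - V_\min}
      \left(2^N-1\right)\right)$$

with round-half-up, so $\pm 20$ V map exactly to codes 0 and 4095 and
0 V maps to 2048.

```{r geometry}
cfg <- galvo_config()
p <- grid_to_plane(1, 1)               # top-left cell center, mm
a <- plane_to_angles(p, cfg)
v <- angle_to_voltage(a, cfg)
voltage_to_dac_code(v$vx, cfg)
```

## Raster planning and the slew limit

The beam visits the selected cells line by line, left to right, top to
bottom, dwelling `dt_ms` (default 1 ms) on each; retraces are modeled as
instantaneous voltage steps under zero-order hold. Unselected cells are
skipped — equivalent to blanking the laser between dwell points — so
every selected cell receives exactly one dwell per cycle (the basis of
uniform exposure). A full 30 × 30 sweep at 1 ms per point therefore
takes 0.9 s per cycle. `check_slew()` compares the optical-angle change
of every transition (including the cyclic bottom-right → top-left
retrace) against the mirrors' maximum step rate; the horizontal retrace
is normally the fastest transition and is the first to fail when the
dwell time shrinks. The default limit (40°/ms optical) brackets the
behavior of the modeled scanner: a 0.9 s cycle is feasible while a
0.25 s cycle distorts.

## The phantom

The synthetic target emulates a slab of black modeling clay carrying an
irregular dark lesion: a connected union of overlapping disks (3 lobes,
radii drawn from 6–10 mm, center jittered up to 4 mm), absorptivity 0.9
inside and 0.1 outside. Lesion sizes of one to a few centimeters match
the lesions that motivate a 5 cm field. The slab's thermophysical
constants are generic clay values — $\rho = 1600$ kg/m³, $c = 1000$
J/(kg K), $k = 0.6$ W/(m K), thickness 5 mm, linearized surface loss
$h = 15$ W/(m² K), emissivity 0.95, ambient 23 °C — chosen once so a
42 °C plateau is reachable with a ≤ 2 W source; the real clay's
properties are not tabulated, so all are configuration fields.

Heating uses the *cycle-averaged* power map: each dwell deposits a
Gaussian spot ($\sigma$ = beam diameter / 4, the 1/e² convention for the
5 mm beam) of energy $P\,\Delta t$, discretized on the phantom grid with
exact energy conservation and weighted by the local absorptivity; the
per-cycle energy divided by the cycle time gives the average absorbed
power. This is valid because one scan cycle (0.9 s) is far shorter than
the slab's thermal response (τ = ρcL/h ≈ 533 s); `advance_heat_moving()`
implements the true moving spot and the test suite confirms the two
agree to within 2 % of the temperature rise on a reduced grid.

The surface field evolves by an explicit finite-difference step,

$$\frac{\partial T}{\partial t} = \alpha \nabla^2 T
  + \frac{Q}{\rho c\, V_{cell}} - \frac{h\,(T - T_{amb})}{\rho c\, L},$$

with zero-flux lateral boundaries and the classic stability bound
$\Delta t < \Delta x^2 / 4\alpha$ enforced (violations are rejected with
the computed bound, and `advance_heat()` subdivides long intervals at
80 % of the bound). The insulated, lossless scheme conserves total
enthalpy exactly, which the tests use as an energy-bookkeeping oracle.
The default grid is 60 × 60 cells over the 5 cm field (0.83 mm cells,
stability bound ≈ 0.46 s) — fine enough to resolve the 5 mm spot,
coarse enough that a 300 s closed-loop session simulates in seconds.

## Cameras

The visible camera sees the scene through a 3 × 3 homography. The
default view tilts the camera ~10°, producing the keystone distortion a
real bench shows: the top edge of the square field images shorter than
the bottom. The clay plate renders mid-grey (~180), the lesion dark
(~40), the background light (~235), with Gaussian pixel noise.

The thermal camera (256 × 192 px, matching the modeled sensor) shares
the same view rescaled to its sensor size and shifted by a parallax
offset (default 12 px vertically — it is mounted a few centimeters
below the visible camera). Each frame adds Gaussian noise at the
sensor's NETD (65 mK), an optional constant radiometric bias within the
±2 °C accuracy (default 0), and quantizes temperatures linearly to
8 bits; the frame's noisy extreme temperatures are stored as the
$(T_{\min}, T_{\max})$ metadata a radiometric camera reports. A uniform
field cannot be quantized (the intensity span is zero), so such frames
are flagged degenerate rather than propagating NaN, and the pipeline
reports the measured ambient for them.

## Image pipeline

The visible path: inverse binary threshold (the lesion is dark),
morphological closing (3 × 3, fills pinholes), Gaussian smoothing;
corner extraction of the largest connected component using the extreme
sum/difference rule (smallest $x+y$ → top-left, largest $x+y$ →
bottom-right, the $x-y$ extremes resolving the other two, ties broken by
$y$ then $x$); perspective rectification by the homography sending those
corners to an axis-aligned square (projective bilinear resampling,
hand-rolled since no installed package provides a general image
homography warp); exact area-weighted reduction to 30 × 30; a 3 × 3
opening; binarization at 0.5 cell occupancy. Automatic (Otsu)
thresholding is available, but the default session uses fixed thresholds
(100 for the lesion, 210 for the plate outline) because the rendered
scene is trimodal — lesion, clay, background — and a single Otsu split
separates the two large modes rather than isolating the lesion.

The thermal path: segment the hot region, compute its centroid and the
centroid of the (rescaled) visible lesion mask, shift the thermal ROI by
their difference (parallax correction; clipped to the image bounds, with
an error if the ROI would leave the frame entirely), convert intensities
to temperatures with the per-frame linear map

$$T_{pixel} = \frac{T_{\max}-T_{\min}}{I_{\max}-I_{\min}}
  \,(I_{pixel}-I_{\min}) + T_{\min},$$

rectify with the (rescaled) visible-derived corners, and block-average
onto the 30 × 30 grid before taking ROI statistics — the controller
works on the discrete temperature matrix, not on raw pixels. Early
frames with less than 2 °C of contrast reuse the last estimated parallax
shift instead of re-segmenting noise.

## The controller

Temperature feedback arrives every $T = 5$ s. The discrete PID law is

$$u[n] = K_p e[n] + K_i T \sum_{k=0}^{n} e[k]
  + K_d \frac{e[n]-e[n-1]}{T},$$

with the running sum including the current sample, the derivative acting
on the error, and the first-sample derivative defined as 0 (no start-up
kick). The error is `target − mean(ROI)`; the ROI mean is the process
variable, as it is the quantity the instrument regulates and plots. The
raw output is in percent of full power (`u_scale = 100`) and clamps to
[0, 1]; while the command is saturated and the error keeps pushing into
the bound, that sample's integral contribution is rolled back
(conditional-integration anti-windup, toggleable to observe windup).
Defaults are the tuned gains $K_p = 25$, $K_i = 0.3$, $K_d = 20$.

A safety supervisor forces the power to zero whenever the measured ROI
temperature exceeds the 46 °C cap. The cap is enforced on the process
variable deliberately: with the default clay constants the hottest ROI
cell of an irregular lesion rides several °C above the ROI mean (the
cold lesion rim drags the mean down), so a per-cell-max cut-out at 46 °C
would trip on most control steps of a correctly regulated 42 °C session
and turn regulation into a safety-driven limit cycle. The per-cell
maximum and minimum are still logged at every control step, so a
stricter supervisor can be evaluated from any trace.

## The closed loop

```{r session, eval = FALSE}
tr <- run_session(session_config(seed = 1))
tr
plot_trace(tr)   # mean ROI temperature, 42/46 degC dashed red lines
plot_power(tr)   # commanded laser power, %
```

One session: generate the phantom, render the visible frame, segment and
rectify to the scan matrix, plan the raster, then 61 control steps
(300 s / 5 s + 1) of render → align → thermogram → ROI statistics → PID
→ heat. Sessions are bit-reproducible for a fixed master seed. With the
tuned gains the trace reproduces the expected treatment profile: an
initial full-power ramp (the actuator saturates — a steeper rise would
need a stronger laser), convergence to the setpoint in about a minute,
and small steady fluctuations as the controller keeps adjusting.

`tuning_sweep()` replays the manual tuning narrative. Two of its three
classic signatures hold in this surrogate: without integral gain the
response settles below the setpoint (pure-P steady-state error), and a
larger integral gain overshoots more. The third — proportional-only
oscillation that derivative gain damps — does not: with one-sample
feedback delay and an effectively first-order thermal plant, the error
recursion $e[n+1] = (1-a-b)e[n] + b\,e[n-1]$ (loop P-gain $a$, loop
D-gain $b$) has only real roots, and derivative action pushes the
negative root *outside* the unit circle, amplifying the two-sample
alternation instead of damping it. A physical bench oscillates at a
multi-sample period because its thermal dynamics are higher-order (heat
moves through the target's depth before the surface camera sees it); a
2-D surface model has no such mode. The corresponding test asserts the
bench ordering and is expected to fail on this simulator; it is kept as
an honest record of the discrepancy.

## What the generator does and does not emulate

The synthetic scenes capture: irregular connected lesions with high NIR
absorption contrast, keystone tilt, dual-camera parallax, 8-bit thermal
quantization with per-frame min/max metadata, NETD-scale sensor noise,
and the slow surface heat dynamics of a thin absorbing slab. They do not
capture: depth-resolved heating (the slab is laterally 2-D), emissivity
or reflection artifacts, lens distortion beyond the projective model,
nanoparticle photothermal conversion, perfused tissue, or degradation of
the target across repeated sessions. Passing tests therefore validate
the processing and control chain against a self-consistent physical
surrogate — not the thermal response of any particular real material.

## Numerical choices

* DAC rounding is half-up; codes are integers in $[0, 2^N-1]$.
* Gaussian spots are normalized discretely (sum over the grid = 1), so
  commanded power is conserved exactly even near the field edge.
* Bilinear scene sampling clamps within the outer half-cell band of the
  phantom grid; beyond it the visible camera sees background and the
  thermal camera sees ambient.
* Area resizing uses exact interval-overlap weights (two small weight
  matrices), valid for down- and up-scaling; scan-cell occupancy
  binarizes at ≥ 0.5.
* Corner ordering ties break deterministically by $y$ then $x$.
* Degenerate (zero-span) thermal frames are flagged, never divided by.
* Problem sizes: 60 × 60 phantom cells, 192 × 192 visible px,
  256 × 192 thermal px, 180 × 180 rectified px, 90 × 90 rectified
  thermogram before block-averaging to 30 × 30 — sizes at which a full
  300 s session runs in a few seconds while every stage stays resolved.

## Limitations

Absolute heating rates depend on assumed clay constants, so quantitative
claims are property-based (conservation, monotonicity, round-trips,
closed-loop regulation) rather than comparisons to measured phantom
temperatures. The parallax model is a pure translation; a real two-camera
rig also differs slightly in perspective. The supervisor-versus-spread
interaction discussed above means per-pixel peak temperatures in the
lesion can exceed the cap on the *mean* by a few °C — a real treatment
protocol would set the mean setpoint with that margin in mind.
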