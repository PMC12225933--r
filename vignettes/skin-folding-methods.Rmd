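---
title: "Mechanics of self-organized skin folding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of self-organized skin folding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

scutefold studies how compressive stress from constrained skin growth
self-organizes the polygonal scale patterns on the central dorsal head
surface of tortoises. The head skin there is a bilayer — a thin, stiff,
keratinizing epidermis on a softer, thicker dermis — adhered to skull bone
that neither grows nor deforms on the relevant timescale. As both skin
layers grow while the bone does not, the skin is placed under increasing
tangential compression; past a threshold the smooth state gives way to
folds (creases) that propagate and interconnect into a disordered network
of scale domains, many of whose edges remain unjoined. This vignette
records the model, every numerical choice that matters, and what the
synthetic benchmarks do and do not establish.

## The mechanical model

**Kinematics.** Deformation is decomposed multiplicatively,
$F = F_e\,G$: the growth tensor $G$ is stress-free, and only the elastic
accommodation $F_e = F\,G^{-1}$ stores energy. Growth is transversely
isotropic about the local reference skin normal $n$:

$$G = (1+g_t)\,(I - n n^\top) + (1+g_n)\, n n^\top,
\qquad \det G = (1+g_t)^2 (1+g_n),$$

with per-layer tangential/normal fractions $(g_t, g_n)$. Growth is
relative to the rigid bone, so bone growth is identically zero. The
reference normals are evaluated once on the undeformed layer mid-surface
and held fixed (total-Lagrangian growth); re-evaluating them under
deformation is out of scope.

**Constitutive law.** Each tetrahedral element carries a compressible
neo-Hookean energy density in $F_e$ (with $J_e = \det F_e$):

$$W = \tfrac{\mu}{2}\left(\operatorname{tr}(F_e^\top F_e) - 3\right)
      - \mu \ln J_e + \tfrac{\lambda}{2} (\ln J_e)^2,$$

a standard form for soft tissue that behaves well from small to large
deformations and moderate compressibility. The element energy is $W$
integrated over the grown reference volume, $V_{\mathrm{ref}}\det G$.
Nodal forces are the exact analytic gradient of this energy; the test
suite verifies them against central finite differences to better than
$10^{-6}$ relative error, and a single-element bar at $\nu = 0$ against
the closed-form nominal stress $\mu(s - 1/s)$.

Only modulus *ratios* matter: multiplying every Young's modulus by a
constant rescales forces and time but leaves the equilibrium geometry
unchanged, which the acceptance suite checks directly.

**Species parameter sets.** `species_parameters()` returns the per-layer
Young's moduli (relative units), Poisson's ratios, and final
tangential/normal growth fractions used for the three study species
(sulcata, Greek, marginated tortoise). These values are inputs of the
study, not fitted by this package.

**Quasi-statics.** Equilibria are found by damped explicit relaxation:
semi-implicit Euler with an implicit viscous drag term
$v \leftarrow (v + \Delta t\, f / m)\,/\,(1 + c\,\Delta t)$, lumped unit-density
masses, `bone_fixed` nodes clamped, and `lateral` nodes projected onto
their constraint planes. Growth is ramped linearly over `ramp_steps`
increments (default 50); after each increment the state is relaxed until
the maximum nodal residual force falls below `tol` times a force scale
$(\mu + \lambda)_{\max} \bar V^{2/3}$ or `max_steps` is exhausted (reported
as a convergence failure). Defaults: `tol = 2e-4`, `max_steps = 8000`.
The tolerance is deliberately small: the folding instability is weak near
onset, and a lax residual test accepts the smooth (unstable or metastable)
branch before folds have grown.

* **Time step** — conservative explicit bound
  $\Delta t = 0.5\, h_{\min} \sqrt{\rho/(\lambda + 2\mu)}$ with unit
  pseudo-density, $h_{\min}$ the smallest element altitude.
* **Damping** — near-critical for the slowest elastic mode of the domain,
  $c = 2\pi\,c_w / L$ with $c_w$ the fastest wave speed and $L$ the domain
  diagonal; overridable.
* **Self-contact** — node-triangle penalty between non-adjacent pairs of
  the free surface closer than the detection radius (default half an
  epidermis thickness), force $k(r - d)$ along the separation direction,
  distributed barycentrically so the pair exchange is momentum-free and
  vanishes continuously at $d = r$. Penalty stiffness defaults to the
  largest shear modulus; no friction. Candidate pairs are refreshed every
  10 steps from a uniform spatial hash with a half-radius margin.
* **Inversion guard** — an element reaching $J_e \le 0$ aborts the run
  with the element index; no invertible-element fix is attempted.

## The synthetic dome and what it takes to make it fold

The simulation domain is a three-layer spherical cap: rigid bone shell
innermost, dermis (default 5 units thick), epidermis (1 unit — the length
unit of the package) outermost. Two geometric choices required care:

* **Dome curvature.** The dome radius defaults to 200 epidermis
  thicknesses (`cap_radius = 200`, polar angle 0.13 rad, arc about 52
  units). A strongly curved cap (radius a few tens of epidermis
  thicknesses) *cannot* fold under the study's parameter sets: at modulus
  contrast 2–3 the critical tangential compression is roughly 25–30%, and
  such a dome relieves most of its 45–70% growth by inflating radially.
  We verified this numerically — fully converged smooth solutions at fine
  resolution on small-radius domes, while identical parameters on a flat
  slab crease deeply. On the animal the head is large against the skin
  thickness, so the nearly flat dome is also the realistic regime.
* **Symmetry breaking.** Creasing here is a subcritical instability: the
  smooth compressed state remains a local equilibrium, and folding must be
  nucleated. Seeded uniform node jitter provides the "small stochastic
  spatial fluctuations"; its default amplitude is 0.05 epidermis
  thicknesses (5% of the thinnest layer). A much smaller jitter (e.g.
  $10^{-3}$) leaves the quasi-static relaxation on the smooth branch.
  Jitter is confined to the initial geometry (never the material), skipped
  on bone nodes, projected into the rim constraint planes, and applied
  only tangentially at the outer free surface — the reference surface
  stays smooth, so measured curvature reflects folds rather than seeded
  roughness (the flat bilayer keeps full jitter: there the wrinkle
  amplitude, far above the jitter, is what is measured).

The rim of the excised region is constrained only against escaping
through the cut cone (constraint normal $e_\theta$); sliding within the
cut surface — thickening and azimuthal motion — stays free, mirroring how
a slab's vertical walls block normal escape but allow vertical motion.

The default in-surface element spacing is 1.6 units with two element
layers per skin layer (about 18k deformable tetrahedra, roughly a minute
per simulation on one CPU): the folding survey and the acceptance checks
run at this resolution. The fold wavelength (~6–10 units) is then
resolved by 4–6 elements; halving the spacing deepens the creases
slightly but does not change the species ordering.

## Fold-pattern quantification

Mean curvature is the discrete cotangent-Laplacian estimate,
area-normalized and signed so that a convex sphere seen from outside is
positive, a plane zero, and creases (concave valleys) negative. Crease
extraction keeps vertices below a negative curvature threshold and thins
the band to one-vertex-wide paths on the surface graph (peeling
band-boundary vertices, least-concave first, protecting endpoints and
local connectivity). Components with an endpoint are *open* — the
operational definition of an "unjoined" scale edge — and components that
close into loops bound isolated domains. Domains are flood fills of
non-crease vertices; boundary-touching domains are flagged.

Two thresholding modes exist. For a single surface the default adapts to
the 10th percentile of its curvature distribution (empty network if that
percentile is non-negative, i.e. the surface is judged smooth). For
*cross-specimen comparison* a common criterion is essential — a
per-surface adaptive threshold would label ~10% of every surface as
crease and flatten real differences — so `species_fold_survey()` fixes
one threshold at the pooled 10th percentile over all surveyed surfaces
and applies it uniformly. Species are then ranked by the median crease
length density (crease length per unit deformed area) over seeds, with a
seed-bootstrap confidence attached; fewer than three seeds per species is
refused.

The dominant pattern wavelength is the peak of the radially averaged 2D
power spectrum of surface height over the vertex PCA plane, excluding
wavelengths beyond half the domain (which absorb the overall dome shape).
On a bilayer with modulus contrast 100 and film growth just past onset,
the measured wavelength agrees with the classic film-on-substrate
prediction $\lambda = 2\pi h\,(\bar E_f / 3 \bar E_s)^{1/3}$
(plane-strain moduli $\bar E = E/(1-\nu^2)$) to within a few percent.

## Image phantoms and segmentation

The phantom emulates a two-channel light-sheet volume of the dome:
a nuclear-stain channel with a bright epidermis band (dense nuclei) over
a dimmer dermis on a dark bone core, with one-voxel cross-faded
interfaces; and a separate proliferation-label channel containing only
the Gaussian-blob nuclei of cycling cells (radius 3 voxels, sigma half
the radius, common amplitude so every blob integrates to the same mass).
Cells are rejection-sampled inside the skin shell with pairwise
separation strictly greater than twice the cell radius; impossible
packings error out with the failing count. Noise is additive Gaussian,
seeded, applied per channel, and intensities are clipped to [0, 1]. The
phantom does not model light-sheet optics, striping, attenuation, or
clearing-induced shrinkage — so passing segmentation tests demonstrate
algorithmic correctness on idealized data, not robustness to real optics.

Segmentation follows the classical chain: 3D Canny edges (Gaussian
smoothing, central-difference gradients, non-maximum suppression along
the gradient by trilinear interpolation, 26-connected hysteresis);
oriented point clouds from the negated smoothed gradient (normals point
from high to low intensity, outward from tissue); implicit
moving-least-squares signed distance extracted by marching tetrahedra and
Taubin-smoothed into a triangle surface whose vertex count is far below
the cloud size; ray-cast epidermis thickness from the outer surface along
inward normals with a nearest-point fallback; and Hessian
principal-curvature blob detection (all three eigenvalues negative,
smallest magnitude above threshold, half-peak-weighted component
centroids) for the proliferation channel.

Hysteresis thresholds default to fractions (0.2/0.4) of the strongest
ridge response — the maximum gradient magnitude over non-maximum-
suppression survivors — rather than global intensity quantiles: on a
two-band volume most positive-gradient voxels belong to the strongest
interface, so high quantiles silently discard the weaker epidermis–dermis
boundary. Explicit thresholds remain available. The blob threshold
(0.01) and scale (1.5 voxels for radius-3 cells) were calibrated only on
phantoms, where they separate planted cells from layer-boundary artifacts
by a factor of about three in score.

## Indentation analysis

The forward model is Hertzian spherical contact,
$F = \tfrac{4}{3} E_{\mathrm{eff}} \sqrt{R}\,\delta^{3/2}$, in the
instrument convention: $E_{\mathrm{eff}}$ carries no $(1-\nu^2)$
correction (divide by it to convert to a true modulus). Fitting is least
squares, linear in the modulus after the $\delta^{3/2}$ transform; fit
quality is the coefficient of determination, and curves below 0.95 are
dropped (inclusive threshold — exactly 0.95 is retained). An optional
contact-point offset is pre-estimated by a one-dimensional search, since
real instruments rarely trigger exactly at contact. Aggregation follows
the grid protocols of the study (30 indentations in a 3x10 grid, or 9 in
3x3), reporting mean ± SD of retained moduli per biological replicate.
Synthetic curves sample the forward model on a uniform depth grid with
multiplicative Gaussian noise and enforce the small-contact regime
(`max_depth < probe_radius / 10`).

## Reproducibility plumbing

Every stochastic operation takes an explicit integer seed; pipeline
stages derive theirs from the global seed by the documented rule
`stage_seed = (seed * 1009 + 9176 * stage_index) mod 2147483647`. Runs
write a manifest (config, FNV-1a config hash, per-stage seeds and files);
re-running an identical config reproduces byte-identical artifacts, which
the acceptance suite asserts. Configuration is flat `key = value` text
whose keys use the parameter-table symbol names (`E_epid`, `nu_dermis`,
`gT_epid`, ...), so a config diffs directly against the published table.

## Problem sizes and limitations

The shipped benchmarks use: the default dome (~18k deformable
tetrahedra) for the nine-run species survey; a 120x4x11 strip (~20k
tetrahedra) for the wrinkling oracle; 64x64x48 phantoms; 30-curve
indentation batches. These sizes were chosen so a complete survey runs in
minutes on a single CPU while resolving the fold wavelength.

Known limitations: purely elastic response (no viscoplasticity or yield,
so morphogenetic processes dominated by tissue flow are out of scope);
static parameter sets (the measured developmental stiffening appears only
through the choice of parameters, not as a time-dependent modulus);
total-Lagrangian growth normals; penalty contact without friction; linear
tetrahedra, which are bending-stiff, so crease depths at the default
resolution are conservative; and the graeca/marginata contrast rests on a
small difference in epidermal growth (0.50 vs 0.45), so their ordering by
median crease density is reproducible but not large against seed-to-seed
variability.
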