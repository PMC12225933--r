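# scutefold

Mechanics of self-organized skin folding in reptile head scales.

On the central dorsal head surface of tortoises, polygonal scales do not
arise from placodes (the chemically patterned units that build most skin
appendages). Instead they emerge mechanically: the bilayer skin — a thin,
stiff, keratinizing epidermis over a softer dermis — grows while adhering
to rigid skull bone, accumulates tangential compression, and folds into a
disordered network of creases whose open ("unjoined") edges are the
visual signature of mechanical, rather than chemical, patterning. The
amount of folding differs between species (sulcata > Greek > marginated
tortoise), tracking differences in layer growth and stiffness.

scutefold is a desk-scale R toolkit for studying this process end to end:

* **Growth mechanics** — a finite-strain neo-Hookean tetrahedral
  finite-element simulator (Rcpp core) with multiplicative growth
  decomposition `F = F_e G`, per-layer transversely isotropic growth
  tensors `G = (1+g_t)(I − n nᵀ) + (1+g_n) n nᵀ`, rigid-bone boundary
  conditions, penalty self-contact, and damped explicit quasi-static
  relaxation under a linear growth ramp. Energy density:
  `W = μ/2 (tr(FᵉᵀFᵉ) − 3) − μ ln Jᵉ + λ/2 (ln Jᵉ)²`.
* **Synthetic data** — layered dome and film-on-substrate meshes, 3D
  two-channel image phantoms (nuclear stain + proliferation label), and
  Hertzian indentation curves, all with known ground truth and explicit
  seeds.
* **Segmentation** — 3D Canny edges, gradient-oriented point clouds,
  implicit (moving-least-squares + marching tetrahedra) surface
  reconstruction, epidermis thickness maps, principal-curvature cell
  detection, per-layer proliferation densities.
* **Pattern analysis** — signed discrete mean curvature, crease-network
  extraction and thinning, polygonal domain segmentation, spectral fold
  wavelength, and cross-species ranking by crease length density.
* **Indentation** — Hertz fits `F = 4/3 E_eff √R δ^{3/2}` with R² quality
  filtering (≥ 0.95 retained) and per-replicate grid aggregation.

Species parameter sets (relative moduli, Poisson ratios, final
tangential/normal growth per layer) ship with the package via
`species_parameters()`.

## Worked example

```r
library(scutefold)

## growth simulation of the sulcata head dome
pars <- species_parameters("sulcata")
mesh <- make_layered_cap(seed = 1)          # default dome, seeded jitter
sim  <- simulate(mesh, pars$material, pars$growth, sim_options(seed = 1))
print(sim)
#> <sim_result> 4902 nodes, 50 growth increments
#>   final elastic energy 1.51e+04, min J_e 0.439, all increments converged

## quantify the fold pattern
surf <- free_surface(mesh, sim$positions)
net  <- extract_creases(surf)
print(net)
#> <fold_network> 66 crease vertices, 40 components ( 40 open ), total length 51.22
pattern_statistics(surf, net)
#> <pattern_stats>
#>   domains: 1 (mean area 1.79e+03)
#>   crease length density: 0.02597 per unit area
#>   open crease fraction: 1.00
#>   dominant wavelength: 22.4

## Hertzian indentation of synthetic curves (true modulus 100 kPa)
curves <- make_indentation_curves(E_true = 1e5, probe_radius = 99,
                                  max_depth = 2, n_curves = 30,
                                  noise_sd = 0.01, seed = 1)
fits <- lapply(seq_along(curves), function(i)
  fit_hertz(curves[[i]], curve_id = i, replicate_id = 1, grid_position = i))
filter_and_aggregate(fits, min_quality = 0.95, grid = c(3, 10))
#>   replicate_id   mean_E     sd_E n_retained missing
#> 1            1 99986.83 142.6559         30   FALSE
```

The simulation output reads as follows: after ramping growth to its final
value the dome is folded (the free surface carries 40 crease components,
all open — unjoined edges), the crease length density is ~0.026 per unit
area, and every growth increment relaxed below the residual tolerance.
The indentation fit recovers the 100 kPa ground truth within 0.02% from
thirty 1%-noise curves, all of which pass the ≥ 0.95 R² filter.

`species_fold_survey()` runs the three species over several seeds and
`compare_species()` ranks them by median crease length density with a
bootstrap confidence — the package's headline cross-species comparison.

A thin command-line wrapper lives at `inst/scripts/scutefold`
(subcommands `generate-mesh`, `simulate`, `analyze-pattern`,
`generate-phantom`, `segment`, `generate-curves`, `fit-indentation`,
`compare-species`, `pipeline`), driving the same functions through flat
text configs and writing a manifest for every run.

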