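# cfeddy

Larval dispersal of invasive sun corals (*Tubastraea* spp.) in a cyclonic
eddy scenario off Cape Frio, Brazil — rebuilt as a desk-scale, fully
testable pipeline.

## The problem

Sun-coral planulae are lecithotrophic: they drift passively for weeks,
which makes their spread a question of physics. Off Cape Frio (~23°S) the
Brazil Current (BC) runs south-westward along the shelf break at >0.5 m/s
while a recurrent cyclonic eddy (the Cape Frio Eddy, CFE) grows
quasi-stationarily and then migrates southwest. The eddy's nonlinearity
parameter

> U/c — the ratio of its maximum circum-averaged geostrophic swirl speed U
> to its translation speed c

is of order 10, which means it traps the water (and the plankton) in its
interior and carries it along. For larvae released near offshore oil
platforms in the Campos Basin the eddy therefore acts as a *dispersal
constrictor*: trapped larvae travel a few hundred km with the eddy while
free larvae ride the BC up to ~800 km in a month, and none reach the
coast across the 200-m isobath.

`cfeddy` reproduces this experiment end to end with a synthetic ocean in
place of a hydrodynamic hindcast:

1. **`R/` synthetic ocean** — shelf–slope bathymetry, a geostrophically
   consistent boundary jet, and a growing, translating Gaussian SSH
   depression with prescribed swirl, vertical-velocity and temperature
   structure (CF-style NetCDF I/O via `ncdf4`);
2. **Lagrangian floats** — RK4 horizontal advection on the gridded
   fields, vertical advection plus random-walk mixing
   (`z' = z + w·dt + N(0,1)·sqrt(2K·dt)`, reflective boundaries), release
   schedule 3000 larvae/day × 16 days from 41.255°W, 23.316°S;
3. **eddy tracker** — closed-contour SSH identification (pixel, amplitude,
   single-extremum and shape-error criteria), day-to-day association,
   effective radius, swirl U, translation c, U/c, and a logistic fit to
   the radius growth;
4. **dispersal statistics** — daily point-in-polygon capture against the
   effective contour, residence–distance Pearson correlation, depth and
   cold-water exposure, vicinity analysis, coastal arrivals, density maps.

## Worked example

The analysis is organised as numbered drivers over the package functions;
each stage prints what it found and writes its tables under `results/`:

```sh
Rscript analysis/01_build_fields.R
Rscript analysis/02_track_eddy.R
Rscript analysis/03_run_floats.R --seed 1 --scale 0.1
Rscript analysis/04_dispersal_statistics.R
```

Output of a reference run (seed 1, release scale 0.1 → 4800 larvae):

```
done. SSH depression deepens from 0.21 to 0.34 m; jet core 0.60 m/s
tracked 30 days: mean radius 58.4 km (35.6..81.4), mean U 0.90 m/s,
  mean c 0.086 m/s, mean U/c 12.1, growth k 0.0515 /day (r^2 0.980),
  track length 216 km
released 4800 larvae over 16 days (seed 1, scale 0.10): 3960 still in
  the domain, 840 advected out
day-10 inside 19.0%, day-16 outside 83.8%, day-30 inside 17.4%;
  r = -0.67; deep records 0.93%; cold (day 26) 7.78%;
  coastal arrivals 0; furthest larva 805 km
```

Reading this: the tracked eddy matches the published CFE statistics (mean
effective radius ≈58 km, U/c ≈12, growth rate ≈0.05 day⁻¹ with r²≈0.98 on
the logistic fit). About a fifth of the larvae are inside the eddy late in
the run, decaying after releases stop as the accelerating translation
sheds the edge of the trapped cloud; larvae that stayed longer inside
ended up closer to the origin (Pearson r = −0.67); ~1% of larva-day
records are deeper than 60 m (eddy-edge downwelling); no larva ever
crossed the 200-m isobath. Early capture in a smooth kinematic eddy is
slower than in the turbulence-resolving hindcast being emulated — the
day-10/day-16 trapped fractions undershoot — see the methods vignette
(`vignettes/cape-frio-eddy-dispersal.Rmd`) for the analysis of why, and
for every parameter choice.

The same pipeline is available as one call:

```r
library(cfeddy)
bundle <- run_scenario(seed = 1, scale = 0.1)   # ~90 s on one CPU
print(bundle)
write_bundle(bundle, "results/bundle")
```

All scenario parameters live in one plain-text file,
`inst/extdata/reference_scenario.yaml`; pass an edited copy via
`run_scenario(load_scenario_config("my.yaml"))`.

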