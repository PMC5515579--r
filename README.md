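# bcdecode

Tools for studying how the early *Drosophila* embryo decodes the Bicoid
(Bcd) morphogen gradient **in time**. Optogenetic experiments that switch
Bcd-dependent transcription off in defined windows before gastrulation
show that cell fates exposed to higher Bcd concentrations require its
input for longer. `bcdecode` implements the computational side of such a
study for modellers and quantitative biologists:

* a **gap-gene gene-circuit simulator** (Hb, Gt, Kr, Kni on a 1-D AP
  axis, maternal inputs Bcd/Cad/Tll/Hkb, Hb acting through monomer and
  dimer forms) with instantaneous, time-windowed deactivation of all Bcd
  interactions;
* **scenario batteries and criterion scoring**: run the illumination
  scenarios, call half-maximum expression boundaries, score the five
  qualitative perturbation criteria, select parameter subsets and
  compute per-parameter ensemble z-scores;
* the **MS2 transcription-spot pipeline**: threshold + regional-contrast
  spot detection, greedy nearest-neighbour frame-to-frame linking, the
  160 s persistence filter, and per-region persistence/density
  statistics;
* **gradient quantification**: 5 µm nuclear binning, exponential
  length-scale fitting, half-maximum boundary calls, and ChIP-qPCR
  percent-input normalisation;
* **seeded synthetic-data generators** (spot movies with ground truth,
  gradient nuclei, parameter ensembles, and a shipped reference circuit)
  so the full pipeline is testable without imaging data.

## The model in brief

Each gap gene `a` evolves as

    dv_a/dt = R_a * Phi(u_a) - lambda_a * v_a + D_a * d^2 v_a / dx^2
    u_a(x)  = sum_b T[a,b] reg_b(x) + sum_m M[a,m] g_m(x) + h_a

with `Phi(u) = (u/sqrt(u^2+1)+1)/2`, no-flux boundaries, and Hb split
into monomer/dimer regulators by mass-action equilibrium. Illumination
zeroes the Bcd column of `M` for the duration of each window. Time is in
minutes with gastrulation at t = 0; positions are %EL with the anterior
pole at 100. Boundaries are called where a profile crosses half of its
domain peak. Ensemble scoring uses
`z_i = (<p_i^all> - <p_i^subset>) / (sigma_i^all / sqrt(n))`.

## Worked example

Simulate the shipped reference circuit in the dark and under scenario 5
(Bcd off from n.c. 13 onward), then score the perturbation criteria:

```r
library(bcdecode)

grid     <- axis_grid(100)                 # 1 %EL bins, 500 um embryo
maternal <- make_maternal_inputs(grid)     # exponential Bcd, 80 um scale
params   <- make_reference_circuit()

dark <- simulate_circuit(params, maternal, grid = grid)
sc5  <- simulate_circuit(params, maternal, grid = grid,
                         scenario = illumination_scenario("5", list(c(-60, 0))))

kr <- expression_profile(grid$el, end_state(dark)["kr", ])
boundary_position(kr, "anterior",  c(30, 72))   # 58.3 %EL
boundary_position(kr, "posterior", c(30, 72))   # 45.4 %EL

score_criteria(end_state(dark), end_state(sc5), grid, scenario_id = "5")
#> <criterion_report> scenario 5: 3 of 5 criteria met
#>   (i) Kr anterior boundary shift       yes
#>   (ii) Kni anterior boundary shift      yes
#>   (iii) anterior Kni reduction           no
#>   (iv) anterior Gt reduction            yes
#>   (v) Hb posterior shift + reduction   no
#> measures (%EL shifts / fractional drops):
#>  kr_anterior kr_posterior kni_anterior hb_posterior      kni_ant       gt_ant
#>        4.566        1.149        1.314       -1.125       -1.154        0.987
#>       hb_ant
#>        0.316
```

The dark control reproduces the wild-type domain geometry (Kr spanning
58–45 %EL); removing Bcd from n.c. 13 onward shifts both Kr boundaries
and the Kni anterior boundary towards the anterior (positive %EL shifts)
and collapses anterior Gt (99% reduction), while the terminal-driven
posterior Kni boundary barely moves.

The quantification pipeline runs the same way on synthetic movies:

```r
m      <- make_ms2_movie(synth_movie_config(seed = 42))
tc     <- tracking_config()                       # 160 s cutoff, N = 3
tracks <- filter_tracks(link_tracks(detect_spots(m$movie, tc), tc, 40), tc)
persistence_stats(tracks)
#> <persistence_stats> per AP region (minutes):
#>   100-75     n =   2  mean = 5.33  sd = 0.943
#>   ...
#>   60-40      n =   4  mean =    8  sd = 1.81

g <- make_gradient_nuclei(500, noise_sd = 0.05, seed = 1)
fit_exponential(extract_profile(g$nuclei), 500)
#> <exp_fit> amplitude 976.6, length scale 81.99 um, offset 48.35 (rms 8.16, n = 100)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/bcdecode.R`
(`Rscript bcdecode.R <synth|simulate|perturb|score|track|profile|chip> --config ... --seed ... --out ...`);
every run writes a manifest tying outputs to the configuration hash and
seed.

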