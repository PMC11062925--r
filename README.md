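# myoperf

Personalized coronary and myocardial blood-flow modeling at desk scale.

## The problem

Coronary flow simulations are only as good as their boundary conditions.
The conventional recipe distributes flow among coronary branches by a
diameter power law (Murray's law, exponent 2.6), but measured myocardial
perfusion shows no consistent diameter–flow relationship across patients:
a vessel's true territory demand can differ several-fold from its
diameter-law share. Dynamic CT myocardial perfusion imaging (MBF maps in
mL/min per 100 mL tissue) measures that demand directly — but only as a
*relative* distribution, and only after it has been mapped onto
vessel-specific perfusion territories and translated into outlet boundary
conditions of a flow model.

`myoperf` implements that translation end to end, for researchers in
computational cardiovascular physiology:

* **closed-loop 0D circulation** — time-varying elastance chambers,
  smooth-diode valves, Windkessel systemic/pulmonary beds and the
  coronary outlet block R_a–C_a–R_mu–C_im(P_im)–R_v, integrated by
  backward Euler (C++ core) to periodic convergence;
* **perfusion territories** — Voronoi assignment of LV mesh nodes to
  outlets, conservative control-volume integration of MBF into per-outlet
  flow fractions;
* **synthetic vascular trees** — constrained constructive optimization
  (CCO) growth of 500-terminal binary trees inside the territories,
  Murray radii (gamma = 3), volume-minimizing connections;
* **Darcy perfusion** — single-compartment porous-medium FEM on the
  tetrahedral LV mesh with the beta parameterization
  `beta_src = Q_LV/(V_LV(p_src_bar - p_cap))`,
  `beta_snk = Q_LV/(V_LV(p_cap - p_snk))`, `p_cap` = 15 mmHg;
* **two-stage tuning** — restarted Nelder–Mead for cardiac function
  (systolic/diastolic BP, stroke volume, ejection fraction), then flow
  distribution at hyperemia (distal resistances x 0.24): per-outlet
  resistance scales in [0.5, 2] without trees, or the iterative
  resistance/dilation loop (`alpha = (R_path,syn/R~_path,syn)^(1/4)`)
  with trees, to < 5% flow and pressure error;
* **FFR** — mean-pressure ratio P(s)/P_aorta along any branch, with the
  0.80 positivity threshold;
* **a synthetic-patient generator** — seeded LV shell mesh, epicardial
  tree, dispersed ground-truth flows and a consistent noisy MBF field, so
  the whole pipeline runs and is tested without any clinical data.

Initialization follows the published framework constants: total vascular
resistance from mean pressure over cardiac output, `Q_LV = 3.41 V_LV^0.75`
mL/min (plus 20% for branches not perfusing the LV), total capacitances
0.28e-3 (aortic) and 1e-6 (coronary) cm5/dyn, `R_a/R_mu = 0.38`.

## Worked example

```r
library(myoperf)

cfg <- pipeline_config(seed = 1, total_terminals = 120, stage1_restarts = 4)
report <- run_pipeline(cfg)
print(report)
```

```
pipeline_report: stage-1 error 0.20%
           run trees targets flow_fraction_error_pct mbf_fraction_error_pct
1      epi_mpi FALSE     mpi             4.668293044               30.66966
2   epi_murray FALSE  murray            45.375463917               60.89743
3    trees_mpi  TRUE     mpi             0.006619152               34.15301
4 trees_murray  TRUE  murray            46.383350729               51.41669
    min_ffr ffr_positive
1 0.9724128        FALSE
2 0.9770870        FALSE
3 0.9710732        FALSE
4 0.9748424        FALSE
```

Reading: Stage-1 tuning matched the four cardiac-function targets
(137/73 mmHg, SV 40.4 mL, EF 0.65) to 0.20% mean error. The synthetic
patient's true flow distribution deviates from the diameter law
(lognormal dispersion sigma = 0.4), so the Murray-law models misassign
flow fractions by ~45% while the perfusion-imaging-informed models
recover them to 4.7% (epicardial outlets only) and 0.007% (with synthetic
trees). MBF fraction errors are larger for all models because the Darcy
compartment smooths flow across territory borders, but keep the same
ordering. No stenoses exist in the synthetic anatomy, so minimum FFR
stays near 1 and no branch is flagged (threshold 0.80).

Individual stages are exported (`make_patient()`, `territory_analysis()`,
`grow_synthetic_trees()`, `stage1_tune()`, `stage2_no_trees()`,
`stage2_with_trees()`, `solve_darcy()`, `compute_ffr()`, ...); a small
CLI lives at `system.file("cli", "myoperf", package = "myoperf")`.

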