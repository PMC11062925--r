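# shared fixtures, built once per test run (everything is generated in
# code; no binary fixtures)

.fixtures <- new.env()

memo <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# default synthetic patient (the "stated world": seed 1, 16 LV outlets,
# sigma 0.4, patient-2 style targets)
fix_patient <- function() {
  memo("patient", function() make_patient(synthetic_patient_config(seed = 1)))
}

# small patient for expensive network/tuning tests
fix_small_patient <- function() {
  memo("small_patient", function() {
    make_patient(synthetic_patient_config(
      seed = 2, n_lv_outlets = 8, lv = list(nu = 18, nv = 9, nw = 2)))
  })
}

fix_init <- function(pat) {
  initialization_rules(pat$targets, pat$map$v_lv)
}

fix_params <- function(pat) {
  init <- fix_init(pat)
  p <- default_lpn_params(period = 60 / pat$targets$heart_rate,
                          R_sys = init$R_total)
  p$R_cor_total <- init$R_cor_total
  p$C_ao <- init$C_aortic_total
  p$C_cor_total <- init$C_cor_total
  p
}

fix_murray <- function(pat) {
  init <- fix_init(pat)
  leaves <- pat$tree$outlet_ids
  seg <- pat$tree$segments
  dia <- setNames(2 * seg$radius[match(leaves, seg$id)], leaves)
  lvf <- setNames(seg$perfuses_lv[match(leaves, seg$id)], leaves)
  murray_outlet_resistances(dia, lvf, init$R_cor_total,
                            exponent = init$murray_exponent,
                            lv_share = init$lv_flow_share)
}

# stage-1 fit on the small patient, shared by several tuning tests
fix_small_stage1 <- function() {
  memo("small_stage1", function() {
    pat <- fix_small_patient()
    net <- build_patient_network(fix_params(pat), pat$tree,
                                 fix_murray(pat)$shares, reduce = TRUE)
    stage1_tune(net, pat$targets, restarts = 3, seed = 1)
  })
}
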