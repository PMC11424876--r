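test_that("model assembly validates tissue names and flow balance", {
  m <- make_test_model()
  expect_s3_class(m, "pbpk_model")
  bad_kp <- uniform_kp()
  names(bad_kp)[1] <- "pancreas"
  expect_error(make_test_model(kp = bad_kp), "tissues")
  ph <- default_physiology()
  ph$flow_L_h[["liver"]] <- 40  # breaks the systemic flow balance
  expect_error(make_test_model(phys = ph), "imbalance")
  ph2 <- default_physiology()
  ph2$flow_L_h[["gut"]] <- ph2$flow_L_h[["liver"]]  # portal exceeds total inflow
  expect_error(make_test_model(phys = ph2), "hepatic-artery")
})

test_that("a zero dose gives an identically zero profile", {
  sim <- simulate_pbpk(make_test_model(), 0)
  expect_true(all(sim$conc_ng_ml == 0))
  expect_true(all(as.matrix(sim[, -1]) == 0))
})

test_that("with uniform Kp and no clearance the steady state is uniform", {
  m <- make_test_model(cl = 0, ka = 1, kp = uniform_kp())
  sim <- simulate_pbpk(m, 60)
  last <- sim[nrow(sim), ]
  vols <- m$physiology$volume_L
  conc_t <- sapply(names(vols), function(tn) last[[paste0(tn, "_ug")]] / vols[[tn]])
  expect_equal(unname(conc_t / last$conc_ng_ml), rep(1, 14), tolerance = 1e-4)
  expect_equal(last$conc_ng_ml, 60000 / pbpk_vss(m), tolerance = 1e-4)
})

test_that("with no clearance plasma approaches dose/Vss at distribution equilibrium", {
  m <- make_test_model(cl = 0, ka = 1)  # real Kp map, deep adipose pool
  grid <- c(seq(0, 12, 0.05), seq(13, 2000, 1))
  sim <- simulate_pbpk(m, 24, t_grid = grid)
  expect_equal(sim$conc_ng_ml[nrow(sim)], 24000 / pbpk_vss(m), tolerance = 1e-4)
})

test_that("mass balance holds to 1e-6 of dose at every output time", {
  m <- make_test_model(cl = 262, ka = 0.1)
  for (d in c(2, 24, 90)) {
    sim <- simulate_pbpk(m, d)
    expect_lt(attr(sim, "mass_balance_resid_ug"), 1e-6 * mg_to_ug(d))
  }
})

test_that("the system is linear in dose", {
  m <- make_test_model()
  s1 <- simulate_pbpk(m, 6)
  s3 <- simulate_pbpk(m, 18)
  expect_equal(3 * s1$conc_ng_ml, s3$conc_ng_ml, tolerance = 1e-7)
})

test_that("halving solver tolerances leaves Cmax and AUC essentially unchanged", {
  m <- make_test_model(cl = 262, ka = 0.1)
  pk1 <- predicted_pk(simulate_pbpk(m, 60))
  pk2 <- predicted_pk(simulate_pbpk(m, 60, rtol = 5e-9, atol = 5e-11))
  expect_equal(pk1$cmax, pk2$cmax, tolerance = 1e-4)
  expect_equal(pk1$auc_0inf, pk2$auc_0inf, tolerance = 1e-4)
})

test_that("absorption lag delays the profile without losing mass", {
  m <- make_test_model(tlag = 1)
  sim <- simulate_pbpk(m, 12)
  expect_true(all(sim$conc_ng_ml[sim$time_h <= 1] == 0))
  expect_gt(max(sim$conc_ng_ml), 0)
  expect_lt(attr(sim, "mass_balance_resid_ug"), 1e-6 * mg_to_ug(12))
})

test_that("terminal slope is independent of dose and of ka once ka is fast", {
  m <- make_test_model(cl = 262, ka = 0.1)
  lam <- sapply(c(2, 60, 90), function(d)
    predicted_pk(simulate_pbpk(m, d))$lambda_z)
  expect_equal(lam / lam[1], rep(1, 3), tolerance = 1e-9)
  m2 <- make_test_model(cl = 262, ka = 2)
  m4 <- make_test_model(cl = 262, ka = 4)
  l2 <- predicted_pk(simulate_pbpk(m2, 60))$lambda_z
  l4 <- predicted_pk(simulate_pbpk(m4, 60))$lambda_z
  expect_equal(l2 / l4, 1, tolerance = 1e-3)
})

test_that("in the one-compartment limit the simulator matches the Bateman form", {
  # uniform partitioning and fast perfusion collapse the body to a single
  # well-mixed volume; clearance then acts like first-order elimination
  ph <- default_physiology()
  ph$flow_L_h <- ph$flow_L_h * 1000
  ph$cardiac_output_L_h <- ph$cardiac_output_L_h * 1000
  m <- make_test_model(cl = 5, ka = 0.5, kp = uniform_kp(), phys = ph)
  vtot <- pbpk_vss(m)
  sim <- simulate_pbpk(m, 60)
  pk <- predicted_pk(sim)
  expect_equal(pk$cmax, bateman_cmax(60, 0.5, 5 / vtot, vtot), tolerance = 1e-3)
  expect_equal(pk$auc_0inf, bateman_auc_inf(60, 5), tolerance = 1e-3)
})

test_that("calibration recovers known clearance and absorption parameters", {
  truth <- make_test_model(cl = 200, ka = 0.3)
  pk <- predicted_pk(simulate_pbpk(truth, 60))
  start <- make_test_model(cl = 50, ka = 2)
  fit <- calibrate(start, 60, pk$cmax, pk$auc_0inf)
  expect_equal(fit$elimination$cl_hepatic, 200, tolerance = 0.01)
  expect_equal(fit$absorption$ka, 0.3, tolerance = 0.01)
  # and the closed-form identity AUC = f_abs * D / CL of the linear system
  expect_equal(pk$auc_0inf, 60000 / 200, tolerance = 0.005)
})

test_that("unreachable calibration targets fail with achievable bounds", {
  m <- make_test_model()
  expect_error(calibrate(m, 60, 12, 0), "auc_0inf > 0|positive")
  expect_error(calibrate(m, 60, 12, 1e9, cl_bracket = c(10, 100)),
               "achievable range")
})

test_that("dose scan emits a dose-proportional prediction table", {
  m <- make_test_model(cl = 262, ka = 0.1)
  tab <- dose_scan(m, c(2, 6, 12, 24, 40, 60, 90))
  expect_equal(nrow(tab), 7)
  ratio <- tab$auc_0inf / tab$dose_mg
  expect_equal(ratio / ratio[1], rep(1, 7), tolerance = 1e-3)
  i90 <- tab$dose_mg == 90; i60 <- tab$dose_mg == 60
  expect_equal(tab$auc_0inf[i90] / tab$auc_0inf[i60], 1.5, tolerance = 1e-6)
  expect_equal(nrow(dose_scan(m, 24)), 1)
})

test_that("calibrated predictions are robust to physiology perturbations", {
  targets <- ref60()
  scan_with <- function(phys) {
    m <- calibrate(make_test_model(phys = phys), 60,
                   targets["cmax"], targets["auc"])
    dose_scan(m, c(12, 90))$auc_0inf
  }
  base <- scan_with(default_physiology())
  ph <- default_physiology()
  ph$flow_L_h <- ph$flow_L_h * 1.2
  ph$cardiac_output_L_h <- ph$cardiac_output_L_h * 1.2
  pert <- scan_with(ph)
  expect_equal(pert / base, rep(1, 2), tolerance = 0.005)
})
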