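# Shared fixture builders.  Everything is generated in code; no stored
# data beyond the package's own reference tables.

default_schedule <- function() study_design()$schedule_h

make_profile <- function(time, conc, subject = "S1", dose = 10, blq = is.na(conc)) {
  concentration_profile(subject, dose, time, conc, blq = blq)
}

# Noise-free one-compartment oral profile sampled on the clinical schedule.
make_bateman_profile <- function(dose = 60, ka = 0.8, ke = 0.0442,
                                 v = 5300, schedule = default_schedule(),
                                 subject = "B1") {
  conc <- bateman_conc(schedule, dose, ka, ke, v)
  make_profile(schedule, conc, subject = subject, dose = dose)
}

# A small PBPK model with known parameters (no calibration needed).
make_test_model <- function(cl = 200, ka = 0.5, f_abs = 1, tlag = 0,
                            kp = NULL, phys = default_physiology()) {
  drug <- if (is.null(kp)) nh130_drug_parameters() else drug_parameters(kp = kp)
  build_model(drug, phys, absorption_model(ka, f_abs, tlag),
              elimination_model(cl))
}

uniform_kp <- function(value = 1) {
  setNames(rep(value, 14), names(nh130_drug_parameters()$kp))
}

# Published 60 mg reference targets (predicted Cmax ng/mL, AUC0-inf h*ng/mL)
ref60 <- function() {
  tab <- nh130_prediction_table()
  r <- tab[tab$dose_mg == 60, ]
  c(cmax = r$cmax_predicted, auc = r$auc_0inf_predicted)
}
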