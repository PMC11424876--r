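# Packaged reference data from the NH130 first-in-human
# single-ascending-dose program: group-level observed PK summaries, the
# drug-specific PBPK inputs, and the predicted/observed exposure table
# used for fold-error validation.

#' Observed group-level PK summary of the NH130 dose-escalation study
#'
#' Geometric mean and geometric CV% of Cmax, AUC0-t, AUC0-inf, T1/2 and
#' CL/F, plus Tmax median and range, for the seven dose groups
#' (2-90 mg; n = 2 at 2 mg, n = 8 otherwise) of the NH130 phase I
#' single-ascending-dose study in healthy subjects.
#'
#' @return data.frame, one row per dose group, columns as in
#'   [summarize_group()].
#' @export
nh130_group_summary <- function() {
  read.csv(system.file("extdata", "nh130_group_summary.csv",
                       package = "fihpk"))
}

#' Predicted and observed exposure of the NH130 PBPK model
#'
#' Predicted (whole-body PBPK) and observed Cmax and AUC0-inf per dose
#' group, together with the fold-error values as printed in the study
#' report (`*_fe_printed`).  Note that the printed 24 mg Cmax fold
#' error (0.80) differs from the ratio of its own printed
#' predicted/observed pair (4.85/5.84 = 0.83).
#'
#' @return data.frame with one row per dose.
#' @export
nh130_prediction_table <- function() {
  read.csv(system.file("extdata", "nh130_prediction_table.csv",
                       package = "fihpk"))
}

#' NH130 drug parameters
#'
#' [drug_parameters()] populated with the published NH130 inputs
#' (molecular weight 423.52 g/mol, LogP 4.1, pKa 1.949/5.2/6.1,
#' solubility 5.87 mg/mL, apparent permeability 0.8e-6 cm/s, and the
#' optimized Kp map).
#'
#' @return A `drug_parameters` object.
#' @export
nh130_drug_parameters <- function() drug_parameters()
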