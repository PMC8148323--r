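# Dose-chain accounting: from e-liquid assumptions through the puff budget
# fractions to per-puff, per-session and bystander doses.
#
# Internal chain arithmetic is exact; the `paper_sigfigs` reporting mode
# reproduces the conventional printed precision of such exposure tables:
# per-puff masses to two significant figures except the exhaled mass to
# one, overall secondhand percentages to two decimals (in percent), and
# bystander doses computed from the ROUNDED overall percentages (the
# rounding order that makes the whole printed chain mutually consistent).

#' Per-puff inhaled dose from e-liquid assumptions
#'
#' @param oil_mass Oil fill mass, g.
#' @param thc_mass_fraction THC mass fraction of the oil (0-1).
#' @param puffs_per_fill Number of puffs obtained from the fill.
#' @return Inhaled dose per puff, mg.
#' @export
#' @examples
#' per_puff_dose(0.5, 0.80, 100) # 4 mg
per_puff_dose <- function(oil_mass, thc_mass_fraction, puffs_per_fill) {
  check_positive(oil_mass, "oil_mass")
  check_positive(thc_mass_fraction, "thc_mass_fraction")
  check_positive(puffs_per_fill, "puffs_per_fill")
  oil_mass * thc_mass_fraction / puffs_per_fill * 1000
}

#' Session emission from the per-puff exhaled mass
#'
#' @param exhaled_per_puff Exhaled mass per puff, mg.
#' @param puffs Puffs per session.
#' @return Emitted mass over the session, mg.
#' @export
session_emission <- function(exhaled_per_puff, puffs) {
  check_nonneg(exhaled_per_puff, "exhaled_per_puff")
  check_nonneg(puffs, "puffs")
  exhaled_per_puff * puffs
}

#' Dose-chain inputs
#'
#' @param oil_mass Oil fill, g.
#' @param thc_mass_fraction THC fraction of the oil (0-1).
#' @param puffs_per_fill Puffs per fill.
#' @param puffs_per_session Puffs per vaping session.
#' @param budget An [exposure_budget()] (fractions in percent).
#' @param secondhand_inhaled_frac_of_exhaled Bystander inhaled fraction of
#'   the exhaled vapor, percent.
#' @param secondhand_dermal_frac_of_exhaled Bystander dermal fraction of
#'   the exhaled vapor, percent.
#' @return A `dose_chain_inputs`.
#' @export
dose_chain_inputs <- function(oil_mass = 0.5, thc_mass_fraction = 0.80,
                              puffs_per_fill = 100, puffs_per_session = 20,
                              budget,
                              secondhand_inhaled_frac_of_exhaled = 0,
                              secondhand_dermal_frac_of_exhaled = 0) {
  stopifnot(inherits(budget, "exposure_budget"))
  for (f in c(secondhand_inhaled_frac_of_exhaled,
              secondhand_dermal_frac_of_exhaled)) {
    if (f < 0 || f > 100) stop_invalid("secondhand fractions must lie in [0, 100]")
  }
  structure(
    list(oil_mass = oil_mass, thc_mass_fraction = thc_mass_fraction,
         puffs_per_fill = puffs_per_fill,
         puffs_per_session = puffs_per_session, budget = budget,
         secondhand_inhaled_frac_of_exhaled = secondhand_inhaled_frac_of_exhaled,
         secondhand_dermal_frac_of_exhaled = secondhand_dermal_frac_of_exhaled),
    class = "dose_chain_inputs"
  )
}

signif_or_zero <- function(x, digits) if (x == 0) 0 else signif(x, digits)

#' Run the first-to-secondhand dose chain
#'
#' Multiplies the per-puff inhaled dose through the budget fractions and
#' the secondhand fractions of exhaled vapor. `rounding = "paper_sigfigs"`
#' applies the printed-table rounding convention described above;
#' `"full_precision"` reports the exact arithmetic.
#'
#' @param inputs A [dose_chain_inputs()].
#' @param rounding `paper_sigfigs` or `full_precision`.
#' @return A `dose_report` with per-puff masses (mg), session emission
#'   (mg), bystander doses (micrograms) and overall secondhand fractions
#'   (% of the inhaled dose).
#' @export
#' @examples
#' b <- exposure_budget(64.4, 3.2, 0, 32.4)       # post-puff fractions
#' inp <- dose_chain_inputs(budget = b,
#'   secondhand_inhaled_frac_of_exhaled = 5.9,
#'   secondhand_dermal_frac_of_exhaled = 2.6)
#' dose_chain(inp)
dose_chain <- function(inputs, rounding = c("paper_sigfigs", "full_precision")) {
  stopifnot(inherits(inputs, "dose_chain_inputs"))
  rounding <- match.arg(rounding)
  b <- inputs$budget
  dose <- per_puff_dose(inputs$oil_mass, inputs$thc_mass_fraction,
                        inputs$puffs_per_fill)
  absorbed <- dose * b$absorbed_frac / 100
  exhaled <- dose * b$exhaled_frac / 100
  lung_rem <- dose * (100 - b$absorbed_frac - b$exhaled_frac) / 100
  # overall secondhand fractions of the INHALED dose, percent
  ov_in <- b$exhaled_frac / 100 * inputs$secondhand_inhaled_frac_of_exhaled
  ov_de <- b$exhaled_frac / 100 * inputs$secondhand_dermal_frac_of_exhaled
  if (rounding == "paper_sigfigs") {
    absorbed <- signif_or_zero(absorbed, 2)
    lung_rem <- signif_or_zero(lung_rem, 2)
    exhaled <- signif_or_zero(exhaled, 1)
    ov_in <- round(ov_in, 2)
    ov_de <- round(ov_de, 2)
    by_in <- dose * 1000 * ov_in / 100
    by_de <- dose * 1000 * ov_de / 100
    session <- session_emission(exhaled, inputs$puffs_per_session)
  } else {
    by_in <- dose * 1000 * ov_in / 100
    by_de <- dose * 1000 * ov_de / 100
    session <- session_emission(exhaled, inputs$puffs_per_session)
  }
  structure(
    list(per_puff_dose = dose,
         absorbed_per_puff = absorbed,
         exhaled_per_puff = exhaled,
         lung_or_remaining_per_puff = lung_rem,
         session_emission = session,
         bystander_inhaled_per_puff = by_in,
         bystander_dermal_per_puff = by_de,
         overall_inhaled_frac = ov_in,
         overall_dermal_frac = ov_de,
         rounding = rounding),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report> (", x$rounding, ")\n", sep = "")
  cat(sprintf("  per-puff inhaled dose : %g mg\n", x$per_puff_dose))
  cat(sprintf("  absorbed per puff     : %g mg\n", x$absorbed_per_puff))
  cat(sprintf("  lung/remaining        : %g mg\n", x$lung_or_remaining_per_puff))
  cat(sprintf("  exhaled per puff      : %g mg\n", x$exhaled_per_puff))
  cat(sprintf("  session emission      : %g mg\n", x$session_emission))
  cat(sprintf("  bystander inhaled     : %g ug (%.2f%% of inhaled dose)\n",
              x$bystander_inhaled_per_puff, x$overall_inhaled_frac))
  cat(sprintf("  bystander dermal      : %g ug (%.2f%% of inhaled dose)\n",
              x$bystander_dermal_per_puff, x$overall_dermal_frac))
  invisible(x)
}

#' Serialize a dose report to JSON
#' @param report A `dose_report`.
#' @param path Optional output path.
#' @export
dose_report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "dose_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
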