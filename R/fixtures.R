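# Published PIM1/PIM2 reference material shipped with the package:
# the two literature MLR equations, the screened PubChem analogue set
# (predictions and leverages as printed; the underlying descriptor
# values were never published), and the 25-compound activity listing.

#' Published PIM kinase QSAR equations
#'
#' The two literature three-descriptor MLR models for PIM1 and PIM2
#' inhibition by 5-(1H-indol-5-yl)-1,3,4-thiadiazol-2-amines, entered
#' as [qsar_equation] objects.  The PIM1 GATS8v coefficient is stored
#' as 1.072: the source prints 1072, which is inconsistent with an
#' order-one Geary autocorrelation descriptor and would push
#' predictions far off the pIC50 scale; the printed value is kept in
#' the fixture metadata.
#'
#' @param target `"pim1"` or `"pim2"`.
#' @return a [qsar_equation].
#' @examples
#' predict(pim_model("pim1"),
#'         data.frame(AATS0p = 0, maxHBint8 = 0, GATS8v = 0))  # 6.92
#' @export
pim_model <- function(target = c("pim1", "pim2")) {
  target <- match.arg(target)
  raw <- jsonlite::read_json(system.file("extdata", "pim_models.json",
                                         package = "qsarlm"),
                             simplifyVector = TRUE)[[target]]
  qsar_equation(raw$intercept, unlist(raw$coefficients), note = raw$note)
}

#' Screened PubChem analogue candidates
#'
#' The twelve 5-(1H-indol-5-yl)-1,3,4-thiadiazol analogues retrieved by
#' similarity to the most active training compound, with the published
#' predicted pIC50 and leverage under each model.  Descriptor values
#' for these candidates were never published, so the table carries
#' predictions and leverages only — exactly the pass-through case of
#' [screen_candidates()].
#'
#' @param target `"pim1"`, `"pim2"`, or `"both"` (wide table).
#' @return data.frame; for a single target, columns `candidate_id`,
#'   `pred`, `leverage`.
#' @export
pim_candidates <- function(target = c("both", "pim1", "pim2")) {
  target <- match.arg(target)
  d <- utils::read.csv(system.file("extdata", "pim_screen_candidates.csv",
                                   package = "qsarlm"),
                       stringsAsFactors = FALSE,
                       colClasses = c(candidate_id = "character"))
  if (target == "both") return(d)
  data.frame(candidate_id = d$candidate_id,
             pred = d[[paste0("pred_", target)]],
             leverage = d[[paste0("h_", target)]],
             stringsAsFactors = FALSE)
}

#' Published activity listing for the 25 training-series compounds
#'
#' Observed pIC50 values and per-model predictions for the 25
#' thiadiazole compounds, with each compound's train/test membership
#' under the PIM1 and PIM2 models.  The source prints a single observed
#' column although the two assays differ, so these numbers serve as
#' opaque worked-example data only.
#'
#' @param target `"pim1"` or `"pim2"`.
#' @return data.frame with columns `compound_id`, `pic50_obs`, `pred`,
#'   `role` (`train`/`test` under the chosen model).
#' @export
pim_activities <- function(target = c("pim1", "pim2")) {
  target <- match.arg(target)
  d <- utils::read.csv(system.file("extdata", "pim_activities.csv",
                                   package = "qsarlm"),
                       stringsAsFactors = FALSE,
                       colClasses = c(compound = "character"))
  data.frame(compound_id = d$compound,
             pic50_obs = d$pic50_obs,
             pred = d[[paste0("pred_", target)]],
             role = d[[paste0(target, "_role")]],
             stringsAsFactors = FALSE)
}
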