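#' Bundled validation measurements from the prototype-model study
#'
#' Actual-vs-measured circumference tables recorded on sixteen 3D-printed
#' 1/16-scale prototype human models, shipped with the package as plain CSV
#' and used to validate the error statistics:
#'
#' * `prototype_models`: waistline and hip size per model (actual, measured,
#'   percent error) at 30 cm camera distance and 30-degree views.
#' * `distance_waist`, `distance_hip`: five models re-measured from 25, 30
#'   and 40 cm camera distance.
#' * `angle_waist`, `angle_hip`: four models re-measured at angular steps of
#'   10-60 degrees.
#' * `thin_overweight`: the matched thin/overweight model pair (waistline).
#' * `polygon_sides`: the six law-of-cosines polygon sides of the 15 cm
#'   worked example, per 30-degree interval.
#' * `method_comparison`: actual vs cosine vs ellipse waist/hip values for
#'   model M16.
#'
#' @param name table name (see above).
#' @return A data frame.
#' @examples
#' t1 <- reference_table("prototype_models")
#' rms_average(t1$hip_error_pct) # 4.58
#' @export
reference_table <- function(name = c("prototype_models", "distance_waist",
                                     "distance_hip", "angle_waist",
                                     "angle_hip", "thin_overweight",
                                     "polygon_sides", "method_comparison")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "bodygirth",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
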