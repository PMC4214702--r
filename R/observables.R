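# Scalar summaries of trajectories: sphere-integrated totals, cross-scenario
# ratios, the drug-efficacy ratio, and peak tracking.

#' Sphere-integrated totals of every field over time
#'
#' @param traj An `il35_trajectory`.
#' @return Tibble with columns `time`, `field`, `label`, `total`.
#' @export
field_totals <- function(traj) {
  purrr::map_dfr(seq_along(traj$times), function(i) {
    tibble::tibble(
      time = traj$times[i],
      field = .fields,
      label = unname(.field_labels),
      total = as.vector(traj$states[[i]] %*% traj$grid$vol))
  })
}

#' Ratio of sphere-integrated totals between two runs
#'
#' Compares two trajectories (e.g. the J558-IL-35 and J558-Ctrl scenarios)
#' field by field at a common output time; both the numerator and the
#' denominator are reported alongside the ratio for auditability.
#'
#' @param traj_a,traj_b Two `il35_trajectory` objects sharing the time `t`.
#' @param fields Field names to compare (default: all ten).
#' @param t Comparison time, day (default 14: end of week 2).
#' @return Tibble with columns `field`, `label`, `time`, `total_a`,
#'   `total_b`, `ratio`.
#' @export
scenario_ratio <- function(traj_a, traj_b, fields = .fields, t = 14) {
  fields <- match.arg(fields, .fields, several.ok = TRUE)
  purrr::map_dfr(fields, function(f) {
    num <- total_over_sphere(field_at(traj_a, f, t), traj_a$grid)
    den <- total_over_sphere(field_at(traj_b, f, t), traj_b$grid)
    if (den == 0) rlang::abort(paste0("zero denominator total for ", f))
    tibble::tibble(field = f, label = unname(.field_labels[f]), time = t,
                   total_a = num, total_b = den, ratio = num / den)
  })
}

#' Relative drug efficacy
#'
#' Tumor burden under treatment divided by tumor burden without drug at a
#' common time; 1 means no effect, smaller means a more effective drug.
#'
#' @param traj_drug,traj_none Trajectories with and without treatment.
#' @param t Evaluation time, day.
#' @return Tibble with columns `time`, `tumor_drug`, `tumor_none`, `ratio`.
#' @export
efficacy_ratio <- function(traj_drug, traj_none, t) {
  num <- total_over_sphere(field_at(traj_drug, "c", t), traj_drug$grid)
  den <- total_over_sphere(field_at(traj_none, "c", t), traj_none$grid)
  if (den == 0) rlang::abort("zero untreated tumor total")
  tibble::tibble(time = t, tumor_drug = num, tumor_none = den,
                 ratio = num / den)
}

#' Radius of the tumor peak over time
#'
#' Tracks the radius at which a field attains its maximum at each output
#' time (ties broken outward); outward drift of the tumor peak reflects
#' migration toward the oxygen-rich boundary.
#'
#' @param traj An `il35_trajectory`.
#' @param field Field to track (default tumor cells).
#' @return Tibble with columns `time`, `peak_radius`.
#' @export
peak_radii <- function(traj, field = "c") {
  field <- match.arg(field, .fields)
  tibble::tibble(
    time = traj$times,
    peak_radius = vapply(traj$states, function(s)
      peak_location(s[field, ], traj$grid), numeric(1)))
}
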