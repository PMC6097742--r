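#' Flow specification for reduced-order hemodynamics
#'
#' Steady mean pulmonary flow with Newtonian blood.  Density and viscosity
#' default to 1060 kg/m^3 and 3.5 mPa s, the conventional values for blood
#' in large vessels.
#'
#' @param flow_rate volumetric flow (m^3/s); default 4 L/min.
#' @param density fluid density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @return a `flow_spec`.
#' @export
flow_spec <- function(flow_rate = 4 / 60000, density = 1060,
                      viscosity = 3.5e-3) {
  if (flow_rate <= 0 || density <= 0 || viscosity <= 0)
    stop("flow_spec invariant violated: all fields must be positive")
  structure(list(flow_rate = flow_rate, density = density,
                 viscosity = viscosity), class = "flow_spec")
}

#' Cross-section-averaged Reynolds number profile
#'
#' `Re(s) = rho * Q * D_eq(s) / (mu * A(s))` with the equivalent diameter
#' `D_eq = sqrt(4 A / pi)`; equals the classic `rho * v * D / mu` with the
#' section-mean velocity.  The maximum sits at the minimum-area sample
#' (the throat).
#'
#' @param profile a `centerline_profile`, or any list/data frame with
#'   fields `arclength`/`z` (or `z`) and `areas`/`area` (m^2).
#' @param flow a [flow_spec()].
#' @return data frame with columns `s` (m), `area` (m^2), `Re`, plus
#'   attribute `max_Re`.
#' @export
reynolds_profile <- function(profile, flow = flow_spec()) {
  s <- if (!is.null(profile$arclength)) profile$arclength else profile$z
  a <- if (!is.null(profile$areas)) profile$areas else profile$area
  if (any(a <= 0)) stop("zero or negative lumen area in profile")
  deq <- sqrt(4 * a / pi)
  re <- flow$density * flow$flow_rate * deq / (flow$viscosity * a)
  out <- data.frame(s = s, area = a, Re = re)
  attr(out, "max_Re") <- max(re)
  out
}

#' Reduced-order pressure-drop estimate through the lumen
#'
#' Distributed Poiseuille loss integrated along the centerline plus a
#' Young-Tsai-type turbulent stenosis loss
#' `Kt/2 * rho * v_ref^2 * (A_ref/A_min - 1)^2` (Kt = 1.52) charged at each
#' local constriction.  This is a comparative estimator standing in for
#' full 3-D CFD: use it to rank configurations, not for absolute drops.
#'
#' @param profile as in [reynolds_profile()].
#' @param flow a [flow_spec()].
#' @param Kt turbulent loss coefficient.
#' @return estimated pressure drop (Pa).
#' @export
pressure_drop_estimate <- function(profile, flow = flow_spec(), Kt = 1.52) {
  s <- if (!is.null(profile$arclength)) profile$arclength else profile$z
  a <- if (!is.null(profile$areas)) profile$areas else profile$area
  if (any(a <= 0)) stop("zero or negative lumen area in profile")
  q <- flow$flow_rate
  deq <- sqrt(4 * a / pi)
  vbar <- q / a
  # Poiseuille: dp/ds = 32 mu vbar / D^2, trapezoid along s
  g <- 32 * flow$viscosity * vbar / deq^2
  dp_pois <- sum(diff(s) * (g[-1] + g[-length(g)]) / 2)
  # stenosis loss at the global constriction, referenced to the inlet area
  a_ref <- a[1]
  a_min <- min(a)
  dp_sten <- 0
  if (a_min < a_ref) {
    v_ref <- q / a_ref
    dp_sten <- Kt / 2 * flow$density * v_ref^2 * (a_ref / a_min - 1)^2
  }
  dp_pois + dp_sten
}
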