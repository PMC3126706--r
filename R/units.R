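#' @keywords internal
"_PACKAGE"

# 1 mmHg in Pa; SI internally, mmHg at user-facing boundaries
MMHG_PA <- 133.322

#' Convert pressures between mmHg and Pa
#'
#' All internal hydraulic computations use SI units (Pa, m^3/s, Pa.s/m^3);
#' pressures cross the user-facing boundary in mmHg.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the other unit.
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' Convert mean cross-sectional velocity to volumetric flow
#'
#' `Q = v * pi * d^2 / 4` for a circular tube of inner diameter `d`.
#' Zero velocity is allowed (zero flow); negative velocity or a non-positive
#' diameter is a domain error.
#'
#' @param velocity flow velocity in m/s (vectorised).
#' @param diameter tube inner diameter in m.
#' @return volumetric flow in m^3/s.
#' @export
velocity_to_flow <- function(velocity, diameter) {
  if (!is.numeric(velocity) || any(!is.finite(velocity)) || any(velocity < 0))
    stop("`velocity` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    stop("`diameter` must be a single positive number", call. = FALSE)
  velocity * pi * diameter^2 / 4
}

#' @rdname velocity_to_flow
#' @param flow volumetric flow in m^3/s.
#' @export
flow_to_velocity <- function(flow, diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    stop("`diameter` must be a single positive number", call. = FALSE)
  flow / (pi * diameter^2 / 4)
}

#' @importFrom ggplot2 .data
#' @importFrom stats rnorm runif sd
NULL
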