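# Spring and contact mechanics: compression -> force -> contact pressure.
# Internal units are fixed: mm, N, Pa, mmHg, with 1 mmHg = 133.322 Pa.

MMHG_PA <- 133.322

#' Compression-spring model of the clip
#'
#' The clip transmits finger force through a pre-loaded compression spring.
#' Defaults describe a spring with stiffness 0.49 N/mm, 0.1 N preload, and
#' 6.7 mm of available travel, giving an applied-force range of about
#' 0.1--3.4 N.
#'
#' @param k_constant Spring stiffness in N/mm. Must be positive.
#' @param preload_force Force at zero compression in N. Must be non-negative.
#' @param max_travel Available compression travel in mm. Must be positive.
#' @return An object of class `spring_model`.
#' @examples
#' s <- spring_model()
#' force_from_compression(6.7, s)
#' @export
spring_model <- function(k_constant = 0.49, preload_force = 0.1,
                         max_travel = 6.7) {
  stop_if_not_scalar(k_constant, "k_constant")
  stop_if_not_scalar(preload_force, "preload_force")
  stop_if_not_scalar(max_travel, "max_travel")
  if (k_constant <= 0) stop("k_constant must be > 0", call. = FALSE)
  if (preload_force < 0) stop("preload_force must be >= 0", call. = FALSE)
  if (max_travel <= 0) stop("max_travel must be > 0", call. = FALSE)
  structure(list(k_constant = k_constant, preload_force = preload_force,
                 max_travel = max_travel), class = "spring_model")
}

#' Circular finger-contact geometry
#'
#' @param contact_diameter Diameter in mm of the circular protrusion pressing
#'   on the finger (default 10 mm).
#' @return An object of class `contact_geometry`.
#' @export
contact_geometry <- function(contact_diameter = 10) {
  stop_if_not_scalar(contact_diameter, "contact_diameter")
  if (contact_diameter <= 0) stop("contact_diameter must be > 0", call. = FALSE)
  structure(list(contact_diameter = contact_diameter),
            class = "contact_geometry")
}

#' Force applied at a given spring compression
#'
#' `force = preload + k * x`; strictly increasing in `x`.
#'
#' @param x Compression in mm, within `[0, max_travel]`. Vectorised.
#' @param spring A [spring_model()].
#' @return Force in N.
#' @export
force_from_compression <- function(x, spring = spring_model()) {
  stopifnot(inherits(spring, "spring_model"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > spring$max_travel)) {
    stop(sprintf("compression must lie in [0, %.3f] mm", spring$max_travel),
         call. = FALSE)
  }
  spring$preload_force + spring$k_constant * x
}

#' Spring compression producing a given force (inverse of
#' [force_from_compression()])
#'
#' @param f Force in N; must lie within the spring's reachable range.
#' @param spring A [spring_model()].
#' @return Compression in mm.
#' @export
compression_from_force <- function(f, spring = spring_model()) {
  stopifnot(inherits(spring, "spring_model"))
  fmax <- spring$preload_force + spring$k_constant * spring$max_travel
  if (any(!is.finite(f)) || any(f < spring$preload_force) || any(f > fmax)) {
    stop(sprintf("force must lie in [%.3f, %.3f] N", spring$preload_force,
                 fmax), call. = FALSE)
  }
  (f - spring$preload_force) / spring$k_constant
}

#' Contact pressure exerted by a force on the circular contact
#'
#' Force divided by the contact-disc area, converted to mmHg
#' (1 mmHg = 133.322 Pa). With the default 10 mm disc, 0.1 N gives about
#' 9.5 mmHg and 3.3 N about 315 mmHg.
#'
#' @param f Force in N, non-negative. Vectorised.
#' @param geom A [contact_geometry()].
#' @return Pressure in mmHg.
#' @export
pressure_from_force <- function(f, geom = contact_geometry()) {
  stopifnot(inherits(geom, "contact_geometry"))
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("force must be >= 0", call. = FALSE)
  }
  r_m <- geom$contact_diameter / 2 / 1000
  pa <- f / (pi * r_m^2)
  pa / MMHG_PA
}

#' Contact pressure at a given force-scale percentage
#'
#' Maps the app's proportional 0--100% force scale to applied pressure:
#' the scale is linear in disc diameter, the diameter linear in spring
#' compression, so `compression = scale/100 * max_travel`, then
#' [force_from_compression()] and [pressure_from_force()].
#'
#' @param scale Force scale in percent (0--100). Vectorised.
#' @param spring A [spring_model()].
#' @param geom A [contact_geometry()].
#' @return Pressure in mmHg.
#' @export
pressure_from_scale <- function(scale, spring = spring_model(),
                                geom = contact_geometry()) {
  x <- clip(scale, 0, 100) / 100 * spring$max_travel
  pressure_from_force(force_from_compression(x, spring), geom)
}
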