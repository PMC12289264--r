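#' Convert keratometric power to radius of curvature
#'
#' Keratometers report corneal power `K` in diopters; the spherical model
#' needs the radius of curvature `r` in millimetres. The two are related by
#' `r = kindex / K`, where `kindex = (n - 1) * 1000` for the keratometric
#' refractive index `n`. The default `kindex = 337.5` corresponds to the
#' standard index 1.3375 used by clinical keratometers.
#'
#' @param keratometry Corneal power in diopters (positive scalar).
#' @param kindex Conversion constant in D*mm; default 337.5.
#' @return Radius of curvature in mm.
#' @examples
#' diopters_to_radius(45)    # 7.5 mm
#' diopters_to_radius(67.5)  # 5.0 mm
#' @seealso [radius_to_diopters()], [cornea_model()]
#' @export
diopters_to_radius <- function(keratometry, kindex = KINDEX_DEFAULT) {
  check_positive_scalar(keratometry, "keratometry")
  check_positive_scalar(kindex, "kindex")
  kindex / keratometry
}

#' Convert radius of curvature to keratometric power
#'
#' Inverse of [diopters_to_radius()]: `K = kindex / r`.
#'
#' @param radius Radius of curvature in mm (positive scalar).
#' @inheritParams diopters_to_radius
#' @return Corneal power in diopters.
#' @export
radius_to_diopters <- function(radius, kindex = KINDEX_DEFAULT) {
  check_positive_scalar(radius, "radius")
  check_positive_scalar(kindex, "kindex")
  kindex / radius
}

#' Spherical model of the recipient cornea
#'
#' Bundles the keratometric power, the derived radius of curvature and the
#' conversion constant. The radius is the length of the two equal sides of
#' the isosceles triangle formed by joining the trephine chord's endpoints
#' to the centre of corneal curvature.
#'
#' @inheritParams diopters_to_radius
#' @return An object of class `cornea_model` with fields `keratometry` (D),
#'   `radius` (mm) and `kindex` (D*mm), satisfying
#'   `radius * keratometry == kindex`.
#' @examples
#' cornea_model(60)
#' @export
cornea_model <- function(keratometry, kindex = KINDEX_DEFAULT) {
  r <- diopters_to_radius(keratometry, kindex)
  structure(
    list(keratometry = keratometry, radius = r, kindex = kindex),
    class = "cornea_model"
  )
}

#' @export
print.cornea_model <- function(x, ...) {
  cat(sprintf("Cornea model: K = %g D, r = %.4f mm (kindex = %g D*mm)\n",
              x$keratometry, x$radius, x$kindex))
  invisible(x)
}

#' Apex angle subtended by a trephine chord
#'
#' The trephine diameter is a chord of the corneal sphere. Joining its
#' endpoints to the centre of curvature forms an isosceles triangle with
#' equal sides `r` (radius) and base `a` (chord). The cosine rule,
#' `cos(alpha) = (b^2 + c^2 - a^2) / (2 b c)` with `b = c = r`, reduces to
#' `cos(alpha) = 1 - a^2 / (2 r^2)`; the apex angle is its arccosine.
#'
#' @param radius Radius of curvature in mm (positive scalar).
#' @param chord Trephine diameter in mm; must satisfy `0 < chord <= 2 * radius`.
#' @return Apex angle alpha in radians, in `(0, pi]`.
#' @examples
#' apex_angle_from_chord(7.5, 6)   # cos(alpha) = 0.68
#' apex_angle_from_chord(1, 2)     # semicircle: pi
#' @export
apex_angle_from_chord <- function(radius, chord) {
  check_positive_scalar(radius, "radius")
  check_positive_scalar(chord, "chord")
  if (chord > 2 * radius * (1 + REL_TOL)) {
    stop(sprintf(
      "chord (%g mm) exceeds the corneal sphere's diameter (%g mm): the trephine cannot span the cornea",
      chord, 2 * radius), call. = FALSE)
  }
  cos_alpha <- 1 - chord^2 / (2 * radius^2)
  # clamp against rounding at the semicircle boundary
  acos(min(1, max(-1, cos_alpha)))
}

#' Arc length from apex angle
#'
#' Length of the circular arc subtending the apex angle at radius `r`:
#' `x = r * alpha` (equivalently `2 pi r * alpha_deg / 360`).
#'
#' @param radius Radius of curvature in mm (positive scalar).
#' @param apex_angle Central angle in radians, in `[0, 2*pi]`.
#' @return Arc length in mm.
#' @examples
#' arc_length(7.5, apex_angle_from_chord(7.5, 6))  # 6.1727 mm
#' @export
arc_length <- function(radius, apex_angle) {
  check_positive_scalar(radius, "radius")
  if (!is.numeric(apex_angle) || length(apex_angle) != 1L ||
      !is.finite(apex_angle) || apex_angle < 0 || apex_angle > 2 * pi) {
    stop("`apex_angle` must be a single number in [0, 2*pi] radians",
         call. = FALSE)
  }
  radius * apex_angle
}

#' Arc length of the Descemet's membrane on the recipient bed
#'
#' Composes the conversion, cosine-rule and arc-length steps: converts
#' keratometry to radius, finds the apex angle subtended by the trephine
#' chord, and returns the arc length of the membrane remaining on the bed.
#' This is the diameter the donor button must match to avoid folds, since
#' the flattened donor's diameter equals the punch size. The arc is always
#' at least the trephine diameter, with equality only in the flat limit.
#'
#' @inheritParams diopters_to_radius
#' @param trephine Trephine diameter in mm.
#' @param warn Warn when inputs fall outside the tabulated envelope
#'   (45--70 D, 6--8 mm)? Default `TRUE`.
#' @return Unrounded arc length in mm.
#' @examples
#' dm_arc_length(45, 6)      # 6.1727 -> table value 6.17
#' dm_arc_length(70, 8)      # rounds to 9.43
#' @seealso [dm_arc_solution()] for the angle as well, [recommend_punch()]
#' @export
dm_arc_length <- function(keratometry, trephine, kindex = KINDEX_DEFAULT,
                          warn = TRUE) {
  dm_arc_solution(keratometry, trephine, kindex, warn = warn)$arc_length
}

#' Full arc solution for a cornea/trephine pair
#'
#' Like [dm_arc_length()] but returns the intermediate geometry too.
#'
#' @inheritParams dm_arc_length
#' @return An object of class `arc_solution` with fields `apex_angle`
#'   (radians), `arc_length` (mm), `radius` (mm), `chord` (mm),
#'   `keratometry` (D) and `kindex`.
#' @examples
#' dm_arc_solution(45, 6)
#' @export
dm_arc_solution <- function(keratometry, trephine, kindex = KINDEX_DEFAULT,
                            warn = TRUE) {
  check_positive_scalar(trephine, "trephine")
  r <- diopters_to_radius(keratometry, kindex)
  if (warn) warn_if_outside_envelope(keratometry, trephine)
  alpha <- apex_angle_from_chord(r, trephine)
  structure(
    list(apex_angle = alpha,
         arc_length = arc_length(r, alpha),
         radius = r, chord = trephine,
         keratometry = keratometry, kindex = kindex),
    class = "arc_solution"
  )
}

#' @export
print.arc_solution <- function(x, ...) {
  cat(sprintf(
    "DM arc solution: K = %g D (r = %.4f mm), trephine %g mm\n  apex angle %.4f rad (%.2f deg), arc length %.4f mm\n",
    x$keratometry, x$radius, x$chord,
    x$apex_angle, x$apex_angle * 180 / pi, x$arc_length))
  invisible(x)
}
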