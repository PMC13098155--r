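#' Nodule volume from a cross-section of a spherical (bean-type) nodule
#'
#' Determinate bean nodules are approximately spherical, so a longitudinal
#' section through the centre has area `A = pi r^2` and Feret's diameter
#' `F_d = 2r`. The sphere volume can then be recovered from the measured
#' section as `V = (2/3) A F_d` (exact for a true sphere). The alternative
#' `convention = "radius"` evaluates `V = (4/3) A F_d`, i.e. treats `F_d`
#' as a radius; it is exactly twice the diameter-convention value.
#'
#' @param A section area, mm^2 (vectorized).
#' @param F_d Feret's diameter of the section, mm. May be a vector, or a
#'   two-column matrix/data.frame of (max, min) Feret diameters, in which case
#'   the mean of the two resulting volumes is returned.
#' @param convention `"diameter"` (default) or `"radius"` (literal form).
#' @return Volume in mm^3.
#' @export
#' @examples
#' sphere_volume_from_section(pi, 2)          # unit sphere: 4*pi/3
#' sphere_volume_from_section(4.0239, 2.2634) # ~6.07 mm^3, a typical bean nodule
sphere_volume_from_section <- function(A, F_d,
                                       convention = c("diameter", "radius")) {
  convention <- match.arg(convention)
  .check_positive(A, "A")
  k <- if (convention == "diameter") 2 / 3 else 4 / 3
  if (is.matrix(F_d) || is.data.frame(F_d)) {
    F_d <- as.matrix(F_d)
    .check_positive(F_d, "F_d")
    rowMeans(sweep(k * F_d, 1, A, `*`))
  } else {
    .check_positive(F_d, "F_d")
    k * A * F_d
  }
}

#' Spherical-cap volume from chord and sagitta
#'
#' The uninfected distal cap of an indeterminate (pea-type) nodule is modelled
#' as a spherical cap measured in section by its chord length `c` and sagitta
#' (cap height) `h`. With base radius `a = c/2` the cap volume is
#' `V = (pi h / 6) (3 a^2 + h^2)` (`chord_mode = "half_chord"`, default).
#' `chord_mode = "full_chord"` evaluates the same expression with the full
#' chord in place of the base radius, `V = (pi h / 6)(3 c^2 + h^2)`.
#'
#' @param c chord length of the circular segment, mm.
#' @param h sagitta (height) of the segment, mm.
#' @param chord_mode `"half_chord"` (default; textbook cap formula) or
#'   `"full_chord"` (literal form).
#' @return Cap volume in mm^3.
#' @export
#' @examples
#' cap_volume(2, 1)  # hemisphere of radius 1: 2*pi/3
cap_volume <- function(c, h, chord_mode = c("half_chord", "full_chord")) {
  chord_mode <- match.arg(chord_mode)
  .check_positive(c, "c")
  .check_positive(h, "h")
  a <- if (chord_mode == "half_chord") c / 2 else c
  (pi * h / 6) * (3 * a^2 + h^2)
}

#' Cylinder volume from a longitudinal section
#'
#' The body of a pea nodule (and its infected zone) is modelled as a cylinder
#' seen in longitudinal section: the average width is `d = A / l_c`, so the
#' volume is `V = A d pi / 4 = (pi/4) A^2 / l_c`. For a perfect rectangular
#' section of a true cylinder this equals `pi (d/2)^2 l_c`.
#'
#' @param A longitudinal section area, mm^2.
#' @param l_c midline length of the cylinder, mm.
#' @return Volume in mm^3.
#' @export
#' @examples
#' cylinder_volume(2, 2)  # l = 2, d = 1: pi/2
cylinder_volume <- function(A, l_c) {
  .check_positive(A, "A")
  .check_positive(l_c, "l_c")
  (pi / 4) * A^2 / l_c
}

#' Fractional colonization density of the infected zone
#'
#' Ratio of green-fluorescent (bacteroid-occupied) area to infected-zone area
#' in a nodule section, `f_c = A_i / A_iz`, in `[0, 1]`.
#'
#' @param A_i infected area, mm^2.
#' @param A_iz infected-zone area, mm^2.
#' @return Unitless fraction.
#' @export
colonization_fraction <- function(A_i, A_iz) {
  .check_positive(A_i, "A_i", strict = FALSE)
  .check_positive(A_iz, "A_iz")
  if (any(A_i > A_iz)) stop("A_i must not exceed A_iz", call. = FALSE)
  A_i / A_iz
}

#' Per-nodule volumes for spherical bean nodules
#'
#' Applies the sphere model to each row of a bean section table: whole-nodule
#' volume `V_n` from (`A_nod`, Feret pair), infected-zone volume `V_iz` from
#' its own area and Feret pair, colonization density `f_c = A_i/A_iz`, and
#' infected volume `V_i = V_iz * f_c`. Max/min Feret variants are averaged
#' after volume computation.
#'
#' @param m data.frame with columns `A_nod`, `F_dmax`, `F_dmin`, `A_iz`,
#'   `F_dmax_iz`, `F_dmin_iz`, `A_i` (areas mm^2, lengths mm).
#' @param convention passed to [sphere_volume_from_section()].
#' @return data.frame with columns `V_n`, `V_iz`, `f_c`, `V_i`, `host`.
#' @export
bean_nodule_volumes <- function(m, convention = c("diameter", "radius")) {
  convention <- match.arg(convention)
  needed <- c("A_nod", "F_dmax", "F_dmin", "A_iz", "F_dmax_iz", "F_dmin_iz", "A_i")
  miss <- setdiff(needed, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  V_n  <- sphere_volume_from_section(m$A_nod, cbind(m$F_dmax, m$F_dmin), convention)
  V_iz <- sphere_volume_from_section(m$A_iz, cbind(m$F_dmax_iz, m$F_dmin_iz), convention)
  f_c  <- colonization_fraction(m$A_i, m$A_iz)
  data.frame(V_n = V_n, V_iz = V_iz, f_c = f_c, V_i = V_iz * f_c,
             host = "bean", stringsAsFactors = FALSE)
}

#' Per-nodule volumes for cap-plus-cylinder pea nodules
#'
#' Whole-nodule volume is the uninfected spherical cap plus the cylindrical
#' body, `V_n = V_c(c, h) + V_b(A_body, l_c)`; the infected zone is its own
#' cylinder `V_iz(A_iz, l_iz)`; the infected volume is `V_i = V_iz * A_i/A_iz`.
#'
#' @param m data.frame with columns `c`, `h`, `A_body`, `l_c`, `A_iz`,
#'   `l_iz`, `A_i`.
#' @param chord_mode passed to [cap_volume()].
#' @return data.frame with columns `V_n`, `V_iz`, `f_c`, `V_i`, `host`.
#' @export
pea_nodule_volumes <- function(m, chord_mode = c("half_chord", "full_chord")) {
  chord_mode <- match.arg(chord_mode)
  needed <- c("c", "h", "A_body", "l_c", "A_iz", "l_iz", "A_i")
  miss <- setdiff(needed, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  V_c  <- cap_volume(m$c, m$h, chord_mode)
  V_b  <- cylinder_volume(m$A_body, m$l_c)
  V_iz <- cylinder_volume(m$A_iz, m$l_iz)
  f_c  <- colonization_fraction(m$A_i, m$A_iz)
  data.frame(V_n = V_c + V_b, V_iz = V_iz, f_c = f_c, V_i = V_iz * f_c,
             host = "pea", stringsAsFactors = FALSE)
}
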