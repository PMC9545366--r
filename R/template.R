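#' Parametric template outline of the left proximal femur
#'
#' Builds an 85-point landmark configuration from geometric primitives: a
#' femoral head circle, a femoral neck band of constant width meeting the head
#' tangentially, greater and lesser trochanter lobes, parallel shaft borders
#' with a distal cut, and a superior acetabular arc concentric with the head.
#' Coordinates are mm in a left-hip AP frame (x medial-positive, y
#' superior-positive) with the femoral head centre at the origin.
#'
#' The point ordering follows [hip_schema()]: 1--5 medial shaft (distal to
#' proximal), 6--9 lesser trochanter, 10--14 inferior neck border, 15--32
#' femoral head arc (inferomedial to superolateral junction; the circle-fit
#' subset is 15--28 and the superior-head subset 22--31), 33--40 superior neck
#' border, 41--50 greater trochanter, 51--62 lateral shaft, 63--77 distal cut,
#' 78--85 acetabular arc from its lateral edge (point 78) medially.
#'
#' By construction the head-arc points lie exactly on the head circle, the
#' neck borders contain stretches exactly `neck_width` apart and parallel to
#' the neck axis (so the narrowest neck width equals `neck_width` and the neck
#' axis passes through the head centre), the shaft borders are vertical (so
#' the neck-shaft angle equals `nsa`), and point 78 sits at `lcea` degrees
#' lateral of the vertical through the head centre.
#'
#' @param r_head Femoral head radius, mm.
#' @param neck_width Femoral neck width (narrowest), mm; must be below
#'   `2 * r_head`.
#' @param nsa Neck-shaft angle, degrees (obtuse anatomical angle between neck
#'   and shaft axes).
#' @param shaft_width Shaft width, mm.
#' @param joint_gap Radial joint-space gap between femoral head and acetabular
#'   arc, mm.
#' @param lcea Angle of the lateral acetabular edge (point 78) lateral of the
#'   vertical through the head centre, degrees.
#' @param acetab_span Angular span of the acetabular arc, degrees.
#' @param subject_id Subject identifier for the returned tibble.
#'
#' @return A landmark tibble with attributes `params` (the geometry
#'   parameters), `head_center`, `head_arc_idx` and `acetab_arc_idx`.
#' @export
#' @examples
#' tpl <- hip_template()
#' measure_hips(tpl)
hip_template <- function(r_head = 25, neck_width = 31.6, nsa = 135,
                         shaft_width = 30, joint_gap = 4, lcea = 35,
                         acetab_span = 65, subject_id = "template") {
  if (r_head <= 0) abort("`r_head` must be positive.")
  if (neck_width <= 0 || neck_width >= 2 * r_head) {
    abort("`neck_width` must lie in (0, 2 * r_head).")
  }
  if (shaft_width <= 0) abort("`shaft_width` must be positive.")
  if (joint_gap <= 0) abort("`joint_gap` must be positive.")
  if (nsa <= 90 || nsa >= 180) abort("`nsa` must be an obtuse angle in (90, 180).")

  scl <- r_head / 25           # all hand-placed coordinates scale with the head
  th <- deg2rad(180 - nsa)     # neck-axis elevation above the medial (+x) axis
  u <- c(cos(th), sin(th))     # along the neck axis, towards the head centre
  v <- c(-sin(th), cos(th))    # perpendicular, superolateral side
  hw <- neck_width / 2
  t_j <- sqrt(r_head^2 - hw^2) # axis position of the head-neck junctions

  on_axis <- function(t, off) c(-t * u[1] + off * v[1], -t * u[2] + off * v[2])

  # femoral head arc: 18 points from the inferomedial junction, counter-
  # clockwise over the medial and superior head, to the superolateral junction
  j_inf <- on_axis(t_j, -hw)
  j_sup <- on_axis(t_j, +hw)
  a_inf <- vec_angle_deg(j_inf[1], j_inf[2])
  a_sup <- vec_angle_deg(j_sup[1], j_sup[2])
  if (a_inf > a_sup) a_inf <- a_inf - 360
  phi <- deg2rad(seq(a_inf, a_sup, length.out = 18))
  head_arc <- cbind(r_head * cos(phi), r_head * sin(phi))

  # neck borders: points along lines parallel to the neck axis at +/- hw;
  # the overlapping parallel stretches make the narrowest neck width exactly
  # `neck_width`, with the minimising segment's midpoint on the axis
  t_sup <- t_j + c(0.10, 0.26, 0.42, 0.66) * r_head
  t_inf <- t_j + c(0.66, 0.42, 0.26, 0.14, 0.06) * r_head
  sup_neck <- t(vapply(t_sup, on_axis, numeric(2), off = +hw))
  inf_neck <- t(vapply(t_inf, on_axis, numeric(2), off = -hw))

  # greater trochanter: saddle, rise to the tip, descent down the lateral
  # border into the shaft (hand-placed, head-radius-scaled)
  saddle_flare <- scl * rbind(c(-40, -17), c(-44, -13), c(-47, -7), c(-49, 0))
  gtroch <- scl * rbind(
    c(-50, 5), c(-50.8, -2), c(-50.5, -9), c(-50, -16), c(-49.4, -22),
    c(-48.8, -27), c(-48.3, -31), c(-47.9, -35), c(-47.6, -38), c(-47.3, -40.5)
  )

  xs <- -32 * scl                      # shaft centreline
  lat_x <- xs - shaft_width / 2
  med_x <- xs + shaft_width / 2
  lat_shaft <- cbind(lat_x, scl * seq(-42, -75, length.out = 12))
  bottom <- cbind(seq(lat_x + 2 * scl, med_x - 2 * scl, length.out = 15), -76 * scl)
  med_shaft <- cbind(med_x, scl * seq(-75, -45, length.out = 5))
  ltroch <- scl * rbind(c(-14.5, -43), c(-11, -41.5), c(-10, -39), c(-13, -37.2))

  # superior acetabular arc, concentric with the head at r_head + joint_gap,
  # from the lateral edge (point 78) sweeping medially
  a78 <- 90 + lcea
  psi <- deg2rad(seq(a78, a78 - acetab_span, length.out = 8))
  acetab <- cbind((r_head + joint_gap) * cos(psi), (r_head + joint_gap) * sin(psi))

  pts <- rbind(med_shaft, ltroch, inf_neck, head_arc, sup_neck, saddle_flare,
               gtroch, lat_shaft, bottom, acetab)
  stopifnot(nrow(pts) == 85)

  out <- xy_to_landmarks(pts, subject_id = subject_id)
  attr(out, "params") <- list(r_head = r_head, neck_width = neck_width,
                              nsa = nsa, shaft_width = shaft_width,
                              joint_gap = joint_gap, lcea = lcea,
                              acetab_span = acetab_span)
  attr(out, "head_center") <- c(0, 0)
  attr(out, "head_arc_idx") <- 15:32
  attr(out, "acetab_arc_idx") <- 78:85
  validate_landmarks(out, hip_schema())
  out
}
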