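#' A canine case on a (simulated or measured) panoramic radiograph
#'
#' All coordinates are calibrated millimetres on the panoramic plane, with x
#' increasing mesially (left-sided cases are mirrored before construction) and
#' y increasing apically.
#'
#' @param case_id character scalar.
#' @param cusp_tip,root_apex 2D points (mm).
#' @param occlusal_ref_molar,occlusal_ref_incisor distinct 2D points defining
#'   the occlusal line (first upper molar to central upper incisor).
#' @param midline_top,midline_bottom distinct 2D points defining the vertical
#'   line between the two central incisors.
#' @param sector_boundaries strictly increasing numeric vector of 4 x
#'   positions (mm): lateral incisor distal surface, lateral incisor midline,
#'   lateral incisor mesial surface, central incisor midline.
#' @param lateral_midline_x x position (mm) of the lateral incisor midline;
#'   must equal `sector_boundaries[2]`.
#' @return An object of class `panoramic_case`.
#' @export
panoramic_case <- function(case_id, cusp_tip, root_apex,
                           occlusal_ref_molar, occlusal_ref_incisor,
                           midline_top, midline_bottom,
                           sector_boundaries,
                           lateral_midline_x = sector_boundaries[2]) {
  if (!is.character(case_id) || length(case_id) != 1L || is.na(case_id)) {
    stop("'case_id' must be a character scalar", call. = FALSE)
  }
  cusp_tip <- assert_point2(cusp_tip, "cusp_tip")
  root_apex <- assert_point2(root_apex, "root_apex")
  occlusal_ref_molar <- assert_point2(occlusal_ref_molar, "occlusal_ref_molar")
  occlusal_ref_incisor <- assert_point2(occlusal_ref_incisor, "occlusal_ref_incisor")
  midline_top <- assert_point2(midline_top, "midline_top")
  midline_bottom <- assert_point2(midline_bottom, "midline_bottom")
  if (all(occlusal_ref_molar == occlusal_ref_incisor)) {
    stop("occlusal reference points must be distinct", call. = FALSE)
  }
  if (all(midline_top == midline_bottom)) {
    stop("midline reference points must be distinct", call. = FALSE)
  }
  if (!is.numeric(sector_boundaries) || length(sector_boundaries) != 4L ||
      !all(is.finite(sector_boundaries)) || any(diff(sector_boundaries) <= 0)) {
    stop("'sector_boundaries' must be 4 strictly increasing x positions (mm)", call. = FALSE)
  }
  if (!isTRUE(all.equal(lateral_midline_x, sector_boundaries[2]))) {
    stop("'lateral_midline_x' must equal the second sector boundary", call. = FALSE)
  }
  structure(list(case_id = case_id, cusp_tip = cusp_tip, root_apex = root_apex,
                 occlusal_ref_molar = occlusal_ref_molar,
                 occlusal_ref_incisor = occlusal_ref_incisor,
                 midline_top = midline_top, midline_bottom = midline_bottom,
                 sector_boundaries = as.numeric(sector_boundaries),
                 lateral_midline_x = as.numeric(lateral_midline_x)),
            class = "panoramic_case")
}

#' Stewart's vertical distance from the cusp tip to the occlusal plane
#'
#' Perpendicular distance (mm) from the cusp tip to the infinite line through
#' the two occlusal reference points (first upper molar to central upper
#' incisor) on the panoramic image.
#'
#' @param case a [panoramic_case()].
#' @return Nonnegative distance in mm.
#' @export
stewart_distance <- function(case) {
  stopifnot(inherits(case, "panoramic_case"))
  a <- case$occlusal_ref_molar
  b <- case$occlusal_ref_incisor
  d <- b - a
  len <- vnorm(d)
  if (len < 1e-9) stop("occlusal reference points coincide", call. = FALSE)
  p <- case$cusp_tip - a
  abs(d[1] * p[2] - d[2] * p[1]) / len
}

#' Classify Stewart's distance into treatment-duration categories
#'
#' Distances under 14 mm predict shorter treatment; 14 mm or more predicts
#' longer treatment (the tie at exactly 14 mm is "longer").
#'
#' @param d nonnegative distance in mm.
#' @return `"shorter"` or `"longer"`.
#' @examples
#' stewart_classify(14.8) # "longer"
#' @export
stewart_classify <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0) {
    stop("'d' must be a nonnegative finite distance (mm)", call. = FALSE)
  }
  if (d >= 14) "longer" else "shorter"
}

#' Ericson-Kurol sector of the canine cusp tip
#'
#' The cusp tip's mesiodistal position is classified into five sectors by four
#' boundaries (lateral incisor distal surface, lateral incisor midline,
#' lateral incisor mesial surface, central incisor midline), numbered 1
#' (most distal) to 5 (most mesial). Sectors 1-2 -- cusp tip strictly distal
#' to the lateral incisor midline -- predict easier treatment; sectors 3-5
#' predict difficult treatment. A cusp tip exactly on a boundary takes the
#' mesial (higher) sector.
#'
#' @param case a [panoramic_case()].
#' @return List with integer `sector` (1-5) and `class`
#'   (`"easy"` or `"difficult"`).
#' @export
ericson_kurol_sector <- function(case) {
  stopifnot(inherits(case, "panoramic_case"))
  x <- case$cusp_tip[1]
  if (!is.finite(x)) stop("cusp tip x coordinate is not finite", call. = FALSE)
  sector <- 1L + sum(case$sector_boundaries <= x)
  list(sector = sector, class = if (sector <= 2L) "easy" else "difficult")
}

#' Canine inclination (alpha angle) to the inter-incisor midline
#'
#' Unsigned angle, in degrees within [0, 90], between the canine long axis
#' (root apex to cusp tip) and the vertical line traced between the two
#' central incisors. An inclination has no sign, so the angle is folded:
#' reversing either line's direction leaves it unchanged.
#'
#' @param case a [panoramic_case()].
#' @return Angle in degrees, in [0, 90].
#' @export
alpha_angle <- function(case) {
  stopifnot(inherits(case, "panoramic_case"))
  axis <- case$cusp_tip - case$root_apex
  mid <- case$midline_top - case$midline_bottom
  if (vnorm(axis) < 1e-9) stop("canine axis has zero length", call. = FALSE)
  if (vnorm(mid) < 1e-9) stop("midline has zero length", call. = FALSE)
  ca <- abs(sum(axis * mid)) / (vnorm(axis) * vnorm(mid))
  acos(min(1, max(0, ca))) * 180 / pi
}

#' Estimated additional traction time from the alpha angle
#'
#' Every 5 degrees of alpha-angle opening corresponds to approximately one
#' more week of active orthodontic traction; the rule is applied linearly
#' with zero intercept, so the value estimates *additional* traction time,
#' not an absolute duration.
#'
#' @param alpha angle in degrees, in [0, 180).
#' @return Estimated weeks (nonnegative real, not rounded).
#' @examples
#' crescini_traction_weeks(20) # 4
#' @export
crescini_traction_weeks <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 180) {
    stop("'alpha' must be in [0, 180) degrees", call. = FALSE)
  }
  alpha / 5
}

#' All three panoramic measures for one case
#'
#' @param case a [panoramic_case()].
#' @return An object of class `planar_result`: list with
#'   `stewart_distance_mm`, `stewart_class`, `ek_sector`, `ek_class`,
#'   `alpha_deg`, `traction_weeks`.
#' @export
planar_measures <- function(case) {
  d <- stewart_distance(case)
  ek <- ericson_kurol_sector(case)
  a <- alpha_angle(case)
  structure(list(case_id = case$case_id,
                 stewart_distance_mm = d,
                 stewart_class = stewart_classify(d),
                 ek_sector = ek$sector,
                 ek_class = ek$class,
                 alpha_deg = a,
                 traction_weeks = crescini_traction_weeks(a)),
            class = "planar_result")
}

#' @export
print.planar_result <- function(x, ...) {
  cat(sprintf("Panoramic measures [%s]\n", x$case_id))
  cat(sprintf("  Stewart: %.1f mm (%s) | EK sector %d (%s) | alpha %.1f deg (~%.1f wk)\n",
              x$stewart_distance_mm, x$stewart_class, x$ek_sector, x$ek_class,
              x$alpha_deg, x$traction_weeks))
  invisible(x)
}

#' Panoramic measures for a list of cases
#'
#' @param cases list of [panoramic_case()] objects.
#' @return data.frame, one row per case.
#' @export
measure_cases_2d <- function(cases) {
  rows <- lapply(cases, function(cs) {
    m <- planar_measures(cs)
    data.frame(case_id = m$case_id,
               stewart_distance_mm = m$stewart_distance_mm,
               stewart_class = m$stewart_class,
               ek_sector = m$ek_sector, ek_class = m$ek_class,
               alpha_deg = m$alpha_deg, traction_weeks = m$traction_weeks,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
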