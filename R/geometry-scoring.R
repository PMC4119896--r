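#' Zone thresholds for the six KPG subscores
#'
#' The KPG index assigns an integer subscore from 0 to 5 to the cusp tip and
#' to the root apex on each of the three anatomical axes (mesiodistal x,
#' vertical y, bucco-palatal z). Each subscore is the number of zone
#' boundaries strictly exceeded by the landmark's displacement, so a strictly
#' increasing list of exactly five boundary values (mm) defines the six zones
#' per axis and landmark.
#'
#' The shipped defaults are calibration surrogates: the original index defines
#' its zones graphically against adjacent anatomy and no millimetre boundaries
#' are published, so these values are configuration, not a claim about the
#' original instrument. Defaults: x and z boundaries at 2, 4, 6, 8, 10 mm
#' (roughly quarter-tooth-width steps), y boundaries at 3, 6, 9, 12, 15 mm.
#'
#' @param cusp_x,root_x,cusp_y,root_y,cusp_z,root_z strictly increasing
#'   numeric vectors of length 5, values >= 0 (mm).
#' @return An object of class `zone_thresholds`.
#' @examples
#' zt <- zone_thresholds()
#' zt$cusp_x
#' @export
zone_thresholds <- function(cusp_x = c(2, 4, 6, 8, 10),
                            root_x = c(2, 4, 6, 8, 10),
                            cusp_y = c(3, 6, 9, 12, 15),
                            root_y = c(3, 6, 9, 12, 15),
                            cusp_z = c(2, 4, 6, 8, 10),
                            root_z = c(2, 4, 6, 8, 10)) {
  th <- list(cusp_x = cusp_x, root_x = root_x,
             cusp_y = cusp_y, root_y = root_y,
             cusp_z = cusp_z, root_z = root_z)
  for (nm in names(th)) {
    b <- th[[nm]]
    if (!is.numeric(b) || length(b) != 5L || anyNA(b) || any(b < 0)) {
      stop(sprintf("threshold set '%s' must be 5 nonnegative values (mm)", nm), call. = FALSE)
    }
    if (any(diff(b) <= 0)) {
      stop(sprintf("threshold set '%s' must be strictly increasing", nm), call. = FALSE)
    }
    th[[nm]] <- as.numeric(b)
  }
  structure(th, class = "zone_thresholds")
}

#' Anatomical reference frame for 3D canine scoring
#'
#' Describes the patient-level anatomy against which a canine's displacement
#' is measured, in a right-side-normalised coordinate frame: x mesiodistal
#' (increasing mesially, dental midline at `midsagittal_x`), y vertical
#' (occlusal plane at y = 0 in the template, increasing apically), z
#' anteroposterior (increasing anteriorly). Left-sided cases are mirrored
#' about the midsagittal plane before scoring.
#'
#' @param midsagittal_x x position (mm) of the dental midline.
#' @param occlusal_points 3 x 3 numeric matrix, one non-collinear reference
#'   point per row (first upper molars and the central-incisor contact point)
#'   defining the occlusal plane.
#' @param arch_curve k x 3 matrix (k >= 4) of control points tracing the
#'   occlusal reference arch, strictly ordered along x.
#' @param ideal_cusp,ideal_apex 3D points (mm): the cusp tip and root apex of
#'   an ideally positioned canine. All displacements are measured relative to
#'   these explicit landmarks so scoring is deterministic.
#' @param lateral_distal_x,lateral_midline_x,lateral_mesial_x,central_midline_x
#'   x positions (mm) of the lateral incisor distal surface, lateral incisor
#'   long-axis midline, lateral incisor mesial surface and central incisor
#'   midline; strictly increasing. Used as sector boundaries after panoramic
#'   projection.
#' @return An object of class `anatomy_frame`.
#' @seealso [arch_template_frame()] for a ready-made template.
#' @export
anatomy_frame <- function(midsagittal_x, occlusal_points, arch_curve,
                          ideal_cusp, ideal_apex,
                          lateral_distal_x, lateral_midline_x,
                          lateral_mesial_x, central_midline_x) {
  if (!is.numeric(midsagittal_x) || length(midsagittal_x) != 1L || !is.finite(midsagittal_x)) {
    stop("'midsagittal_x' must be a finite scalar (mm)", call. = FALSE)
  }
  occlusal_points <- as.matrix(occlusal_points)
  if (!is.numeric(occlusal_points) || any(dim(occlusal_points) != c(3L, 3L)) ||
      !all(is.finite(occlusal_points))) {
    stop("'occlusal_points' must be a finite 3 x 3 matrix", call. = FALSE)
  }
  n <- cross3(occlusal_points[2, ] - occlusal_points[1, ],
              occlusal_points[3, ] - occlusal_points[1, ])
  if (vnorm(n) < 1e-9) {
    stop("occlusal plane points are collinear", call. = FALSE)
  }
  arch_curve <- as.matrix(arch_curve)
  if (!is.numeric(arch_curve) || nrow(arch_curve) < 4L || ncol(arch_curve) != 3L ||
      !all(is.finite(arch_curve))) {
    stop("'arch_curve' must be a finite k x 3 matrix with k >= 4", call. = FALSE)
  }
  if (any(diff(arch_curve[, 1]) <= 0)) {
    stop("'arch_curve' control points must be strictly ordered along x", call. = FALSE)
  }
  bounds <- c(lateral_distal_x, lateral_midline_x, lateral_mesial_x, central_midline_x)
  if (!is.numeric(bounds) || length(bounds) != 4L || !all(is.finite(bounds)) ||
      any(diff(bounds) <= 0)) {
    stop("sector boundary x positions must be finite and strictly increasing", call. = FALSE)
  }
  structure(list(
    midsagittal_x = as.numeric(midsagittal_x),
    occlusal_points = occlusal_points,
    arch_curve = arch_curve,
    ideal_cusp = assert_point3(ideal_cusp, "ideal_cusp"),
    ideal_apex = assert_point3(ideal_apex, "ideal_apex"),
    lateral_distal_x = as.numeric(lateral_distal_x),
    lateral_midline_x = as.numeric(lateral_midline_x),
    lateral_mesial_x = as.numeric(lateral_mesial_x),
    central_midline_x = as.numeric(central_midline_x)
  ), class = "anatomy_frame")
}

#' One impacted canine's 3D landmarks
#'
#' @param case_id character scalar identifying the canine.
#' @param side `"left"` or `"right"`.
#' @param cusp_tip,root_apex 3D points (mm) in the patient frame.
#' @return An object of class `canine_case`.
#' @export
canine_case <- function(case_id, side, cusp_tip, root_apex) {
  if (!is.character(case_id) || length(case_id) != 1L || is.na(case_id)) {
    stop("'case_id' must be a character scalar", call. = FALSE)
  }
  side <- match.arg(side, c("left", "right"))
  cusp_tip <- assert_point3(cusp_tip, "cusp_tip")
  root_apex <- assert_point3(root_apex, "root_apex")
  if (isTRUE(all(cusp_tip == root_apex))) {
    stop("cusp_tip and root_apex must be distinct points", call. = FALSE)
  }
  structure(list(case_id = case_id, side = side,
                 cusp_tip = cusp_tip, root_apex = root_apex),
            class = "canine_case")
}

#' Mirror a canine case about the midsagittal plane
#'
#' Reflects both landmarks' x coordinates about `midsagittal_x` and flips the
#' side label. Scoring a mirrored case against the same frame yields an
#' identical KPG score (side symmetry).
#'
#' @param case a [canine_case()].
#' @param midsagittal_x x position (mm) of the dental midline.
#' @return A [canine_case()] on the opposite side.
#' @export
mirror_case <- function(case, midsagittal_x) {
  stopifnot(inherits(case, "canine_case"))
  refl <- function(p) c(2 * midsagittal_x - p[1], p[2], p[3])
  canine_case(case$case_id,
              if (case$side == "left") "right" else "left",
              refl(case$cusp_tip), refl(case$root_apex))
}

#' Score one displacement against a set of zone boundaries
#'
#' The subscore is the number of boundaries strictly less than the
#' displacement: 0 below the first boundary, 5 above the last. A displacement
#' exactly equal to a boundary takes the lower subscore (deterministic
#' tie-break).
#'
#' @param displacement nonnegative displacement magnitude (mm).
#' @param thresholds strictly increasing numeric vector of length 5 (mm).
#' @return Integer subscore in 0..5.
#' @examples
#' score_axis(5, c(2, 4, 6, 8, 10)) # 2
#' @export
score_axis <- function(displacement, thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 5L || any(diff(thresholds) <= 0)) {
    stop("'thresholds' must be a strictly increasing numeric vector of length 5", call. = FALSE)
  }
  if (!is.numeric(displacement) || length(displacement) != 1L || !is.finite(displacement)) {
    stop("'displacement' must be a finite scalar (mm)", call. = FALSE)
  }
  if (displacement < 0) {
    stop("'displacement' must be nonnegative", call. = FALSE)
  }
  as.integer(sum(thresholds < displacement))
}

#' Difficulty category for a KPG total
#'
#' Three banding schemes over the 0-30 total are supported. Original: 0-9
#' easy, 10-14 moderate, 15-19 difficult, 20-30 extremely difficult.
#' Modified: easy shrinks to 0-6 and moderate extends over 7-14, upper bands
#' unchanged. Dichotomous (used for cross-index comparison): 0-14
#' easy-moderate, 15-30 difficult-very difficult.
#'
#' @param total integer KPG total in 0..30.
#' @param scheme `"original"`, `"modified"` or `"dichotomous"`.
#' @return Category label (character scalar).
#' @examples
#' categorize_kpg(11, "original")    # "moderate"
#' categorize_kpg(7, "modified")     # "moderate"
#' categorize_kpg(15, "dichotomous") # "difficult-very difficult"
#' @export
categorize_kpg <- function(total, scheme = c("original", "modified", "dichotomous")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(total) || length(total) != 1L || is.na(total) ||
      total != round(total) || total < 0 || total > 30) {
    stop("'total' must be an integer in 0..30", call. = FALSE)
  }
  switch(scheme,
    original = if (total <= 9) "easy" else if (total <= 14) "moderate"
               else if (total <= 19) "difficult" else "extremely difficult",
    modified = if (total <= 6) "easy" else if (total <= 14) "moderate"
               else if (total <= 19) "difficult" else "extremely difficult",
    dichotomous = if (total <= 14) "easy-moderate" else "difficult-very difficult")
}

# Per-landmark displacement components relative to the landmark's ideal
# reference point: x as mesiodistal offset, y as the change in perpendicular
# distance from the occlusal plane, z as the change in perpendicular distance
# from the occlusal reference arch in the axial (x, z) view. For the cusp tip,
# whose reference lies on the occlusal plane and on the arch, these reduce to
# plain distances from plane and arch.
landmark_displacements <- function(p, ref, frame) {
  arch_xz <- frame$arch_curve[, c(1, 3)]
  c(x = abs(p[1] - ref[1]),
    y = abs(point_plane_distance(p, frame$occlusal_points) -
              point_plane_distance(ref, frame$occlusal_points)),
    z = abs(polyline_distance(p[c(1, 3)], arch_xz) -
              polyline_distance(ref[c(1, 3)], arch_xz)))
}

#' Compute the KPG severity score for one canine
#'
#' Maps a canine's cusp-tip and root-apex landmarks to the six 0-5 subscores
#' (Cx, Rx, Cy, Ry, Cz, Rz), their 0-30 total, and the category label under
#' each banding scheme. Left-sided cases are mirrored about the midsagittal
#' plane first so mesial displacement is sign-consistent.
#'
#' Displacements per landmark: x is the mesiodistal offset from the landmark's
#' ideal position; y is the change in perpendicular distance from the occlusal
#' plane relative to the ideal position; z is the change in perpendicular
#' distance from the occlusal reference arch in the axial view. A canine
#' exactly at its ideal position scores 0 on every axis.
#'
#' @param case a [canine_case()].
#' @param frame an [anatomy_frame()].
#' @param thresholds a [zone_thresholds()] object.
#' @return An object of class `kpg_score`: list with integer subscores
#'   `Cx, Rx, Cy, Ry, Cz, Rz`, `total`, and `category_original`,
#'   `category_modified`, `category_dichotomous`.
#' @examples
#' fr <- arch_template_frame()
#' cs <- canine_case("ex", "right", fr$ideal_cusp, fr$ideal_apex + c(0, 0.5, 0))
#' compute_kpg(cs, fr)$total
#' @export
compute_kpg <- function(case, frame, thresholds = zone_thresholds()) {
  stopifnot(inherits(case, "canine_case"), inherits(frame, "anatomy_frame"),
            inherits(thresholds, "zone_thresholds"))
  if (case$side == "left") {
    case <- mirror_case(case, frame$midsagittal_x)
  }
  dc <- landmark_displacements(case$cusp_tip, frame$ideal_cusp, frame)
  dr <- landmark_displacements(case$root_apex, frame$ideal_apex, frame)
  sub <- c(
    Cx = score_axis(dc[["x"]], thresholds$cusp_x),
    Rx = score_axis(dr[["x"]], thresholds$root_x),
    Cy = score_axis(dc[["y"]], thresholds$cusp_y),
    Ry = score_axis(dr[["y"]], thresholds$root_y),
    Cz = score_axis(dc[["z"]], thresholds$cusp_z),
    Rz = score_axis(dr[["z"]], thresholds$root_z)
  )
  total <- as.integer(sum(sub))
  structure(c(as.list(sub), list(
    total = total,
    category_original = categorize_kpg(total, "original"),
    category_modified = categorize_kpg(total, "modified"),
    category_dichotomous = categorize_kpg(total, "dichotomous"),
    displacements = rbind(cusp = dc, root = dr)
  )), class = "kpg_score")
}

#' @export
print.kpg_score <- function(x, ...) {
  cat(sprintf("KPG score: %d (Cx=%d Rx=%d Cy=%d Ry=%d Cz=%d Rz=%d)\n",
              x$total, x$Cx, x$Rx, x$Cy, x$Ry, x$Cz, x$Rz))
  cat(sprintf("  original: %s | modified: %s | dichotomous: %s\n",
              x$category_original, x$category_modified, x$category_dichotomous))
  invisible(x)
}

#' Score a list of canine cases
#'
#' @param cases list of [canine_case()] objects.
#' @param frame an [anatomy_frame()].
#' @param thresholds a [zone_thresholds()] object.
#' @return data.frame, one row per case, with columns `case_id`, `side`,
#'   `Cx`..`Rz`, `total`, `cat_original`, `cat_modified`, `cat_dichotomous`.
#' @export
score_cases <- function(cases, frame, thresholds = zone_thresholds()) {
  rows <- lapply(cases, function(cs) {
    k <- compute_kpg(cs, frame, thresholds)
    data.frame(case_id = cs$case_id, side = cs$side,
               Cx = k$Cx, Rx = k$Rx, Cy = k$Cy, Ry = k$Ry, Cz = k$Cz, Rz = k$Rz,
               total = k$total,
               cat_original = k$category_original,
               cat_modified = k$category_modified,
               cat_dichotomous = k$category_dichotomous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
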