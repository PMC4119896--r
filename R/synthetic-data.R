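#' Template anatomical frame over a parabolic dental arch
#'
#' A ready-made [anatomy_frame()] emulating an adult upper arch, in mm:
#' dental midline at x = 0, right side at negative x (so mesial displacement
#' increases x on the right-normalised side), occlusal plane at y = 0 with y
#' increasing apically, z increasing anteriorly. The occlusal reference arch
#' follows z = 30 (1 - (x/45)^2) sampled at 5 mm steps over the right
#' hemi-arch; the ideally positioned canine has its cusp tip on the arch at
#' x = -20 and its root apex 25 mm apically. Sector boundaries use typical
#' incisor widths (central 8.5 mm, lateral 6.5 mm).
#'
#' @return An [anatomy_frame()].
#' @export
arch_template_frame <- function() {
  arch_x <- seq(-40, 0, by = 5)
  arch_z <- 30 * (1 - (arch_x / 45)^2)
  arch <- cbind(arch_x, 0, arch_z)
  ideal_cusp <- c(-20, 0, 30 * (1 - (20 / 45)^2))
  anatomy_frame(
    midsagittal_x = 0,
    occlusal_points = rbind(c(-40, 0, arch_z[1]),
                            c(40, 0, arch_z[1]),
                            c(0, 0, 30)),
    arch_curve = arch,
    ideal_cusp = ideal_cusp,
    ideal_apex = ideal_cusp + c(0, 25, 0),
    lateral_distal_x = -15,
    lateral_midline_x = -11.75,
    lateral_mesial_x = -8.5,
    central_midline_x = -4.25
  )
}

#' Configuration of the synthetic study
#'
#' Defaults emulate the study conditions: 105 impacted canines from 90
#' patients (15 bilateral, i.e. a bilateral fraction of 1/6), scored by three
#' raters at two timepoints. Displacement magnitudes are truncated normals
#' (nonnegative mm): mesiodistal location 8, scale 5; vertical location 8,
#' scale 4; bucco-palatal location 3, scale 2.5 -- chosen so the simulated
#' cohort spans all five sectors and both Stewart classes. The panoramic
#' projection defaults encode the known distortions of the anterior maxilla
#' on panoramic films: 1.25x magnification, a mild nonlinear horizontal
#' stretch, and a +5 degree overestimation of canine inclination.
#'
#' @param n_cases number of impacted canines to generate.
#' @param displacement per-axis list `list(x=, y=, z=)`, each
#'   `list(family, location, scale)` with family one of `"truncnorm"`,
#'   `"halfnormal"`, `"uniform"`, `"exponential"` (mm).
#' @param bilateral_fraction probability that a patient has bilateral
#'   impactions.
#' @param axis_length_range canine long-axis length range (mm).
#' @param root_fraction_range fraction of the cusp displacement inherited by
#'   the root apex (roots stay closer to their ideal position).
#' @param projection list: `magnification` (> 0), `nonlinearity` (per-mm
#'   horizontal distortion coefficient), `angular_bias_deg`,
#'   `landmark_noise_sd` (mm, image-formation noise).
#' @param raters list: `n_raters`, `timepoints`, `noise_sd_3d` and
#'   `noise_sd_2d` (mm, per-rater landmark re-measurement noise).
#' @param seed master seed; every operation derives a named substream from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 105,
                              displacement = list(
                                x = list(family = "truncnorm", location = 8, scale = 5),
                                y = list(family = "truncnorm", location = 8, scale = 4),
                                z = list(family = "truncnorm", location = 3, scale = 2.5)),
                              bilateral_fraction = 15 / 90,
                              axis_length_range = c(22, 28),
                              root_fraction_range = c(0.1, 0.5),
                              projection = list(magnification = 1.25,
                                                nonlinearity = 0.003,
                                                angular_bias_deg = 5,
                                                landmark_noise_sd = 0.5),
                              raters = list(n_raters = 3, timepoints = 2,
                                            noise_sd_3d = 0.75,
                                            noise_sd_2d = 0.75),
                              seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) stop("'n_cases' must be >= 1", call. = FALSE)
  if (bilateral_fraction < 0 || bilateral_fraction > 1) {
    stop("'bilateral_fraction' must lie in [0, 1]", call. = FALSE)
  }
  for (ax in c("x", "y", "z")) {
    sp <- displacement[[ax]]
    if (is.null(sp$family) || is.null(sp$location) || is.null(sp$scale)) {
      stop(sprintf("displacement spec for axis '%s' needs family, location, scale", ax),
           call. = FALSE)
    }
    if (!sp$family %in% c("truncnorm", "halfnormal", "uniform", "exponential")) {
      stop(sprintf("unknown displacement family '%s'", sp$family), call. = FALSE)
    }
    if (sp$scale < 0) stop("displacement scales must be >= 0", call. = FALSE)
  }
  if (projection$magnification <= 0) stop("'magnification' must be > 0", call. = FALSE)
  if (projection$landmark_noise_sd < 0 || raters$noise_sd_3d < 0 || raters$noise_sd_2d < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (raters$n_raters < 1 || raters$timepoints < 1) {
    stop("need at least one rater and one timepoint", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases), displacement = displacement,
                 bilateral_fraction = bilateral_fraction,
                 axis_length_range = axis_length_range,
                 root_fraction_range = root_fraction_range,
                 projection = projection, raters = raters,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

draw_displacement <- function(n, sp) {
  switch(sp$family,
    truncnorm = {
      if (sp$scale == 0) rep(max(sp$location, 0), n)
      else stats::qnorm(stats::runif(n, stats::pnorm(0, sp$location, sp$scale), 1),
                        sp$location, sp$scale)
    },
    halfnormal = sp$location + abs(stats::rnorm(n, 0, sp$scale)),
    uniform = stats::runif(n, sp$location, sp$location + sp$scale),
    exponential = sp$location +
      (if (sp$scale == 0) 0 else stats::rexp(n, 1 / sp$scale)),
    stop(sprintf("unknown displacement family '%s'", sp$family), call. = FALSE))
}

#' Generate a synthetic cohort of impacted canines
#'
#' Draws patients (bilateral with probability `bilateral_fraction`, two
#' canines sharing the patient id) until `n_cases` canines exist. Each
#' canine's cusp tip is displaced from the frame's ideal position by
#' independent nonnegative per-axis magnitudes (mesially, apically and
#' palatally); the root apex inherits a random fraction of that displacement
#' and is then placed at a random long-axis length from the cusp, keeping the
#' tooth anatomically coherent. Left-sided canines are mirrored about the
#' midsagittal plane. Fully deterministic given `config$seed` (named
#' substream `"cases"`).
#'
#' @param config a [simulation_config()].
#' @param frame an [anatomy_frame()]; defaults to [arch_template_frame()].
#' @return An object of class `canine_cohort`: list with `cases` (list of
#'   [canine_case()]), `frame`, `config` and a `patients` data.frame.
#' @export
generate_cases <- function(config = simulation_config(), frame = arch_template_frame()) {
  stopifnot(inherits(config, "simulation_config"), inherits(frame, "anatomy_frame"))
  with_substream(config$seed, "cases", function() {
    cases <- list()
    patients <- list()
    pid <- 0L
    while (length(cases) < config$n_cases) {
      pid <- pid + 1L
      patient_id <- sprintf("P%03d", pid)
      bilateral <- stats::runif(1) < config$bilateral_fraction
      sides <- if (bilateral) c("right", "left") else sample(c("right", "left"), 1L)
      patients[[pid]] <- data.frame(patient_id = patient_id, bilateral = bilateral,
                                    stringsAsFactors = FALSE)
      for (side in sides) {
        d <- c(draw_displacement(1L, config$displacement$x),
               draw_displacement(1L, config$displacement$y),
               -draw_displacement(1L, config$displacement$z))
        f <- stats::runif(1, config$root_fraction_range[1], config$root_fraction_range[2])
        len <- stats::runif(1, config$axis_length_range[1], config$axis_length_range[2])
        cusp <- frame$ideal_cusp + d
        apex0 <- frame$ideal_apex + f * d
        dir <- apex0 - cusp
        dir <- dir / vnorm(dir)
        apex <- cusp + len * dir
        cs <- canine_case(paste0(patient_id, "_", toupper(substr(side, 1, 1))),
                          "right", cusp, apex)
        if (side == "left") cs <- mirror_case(cs, frame$midsagittal_x)
        cases[[length(cases) + 1L]] <- cs
      }
    }
    structure(list(cases = cases[seq_len(config$n_cases)],
                   frame = frame, config = config,
                   patients = do.call(rbind, patients)),
              class = "canine_cohort")
  })
}

#' @export
print.canine_cohort <- function(x, ...) {
  cat(sprintf("Synthetic canine cohort: %d canines from %d patients (%d bilateral), seed %d\n",
              length(x$cases), nrow(x$patients), sum(x$patients$bilateral),
              x$config$seed))
  invisible(x)
}

arch_z_at <- function(frame, x) {
  stats::approx(frame$arch_curve[, 1], frame$arch_curve[, 3], xout = x, rule = 2)$y
}

#' Project a 3D canine case onto a panoramic-like 2D plane
#'
#' A deliberately simple parametric projection emulating panoramic-film
#' distortion, not focal-trough physics: after mirroring left cases to the
#' right-normalised side, `x' = m (x + c x |z|)` and `y' = m y` with
#' magnification `m` and horizontal nonlinearity `c`; the projected canine
#' axis is then opened away from the vertical midline by `angular_bias_deg`,
#' and independent Gaussian noise of sd `landmark_noise_sd` is added to the
#' canine landmarks (reference points project noise-free). With magnification
#' 1 and all distortions zero the projection is the orthogonal (x, y) drop.
#'
#' @param case a [canine_case()].
#' @param frame an [anatomy_frame()].
#' @param config a [simulation_config()] or its `projection` sub-list.
#' @return A [panoramic_case()].
#' @export
project_to_panoramic <- function(case, frame, config = simulation_config()) {
  pj <- if (inherits(config, "simulation_config")) config$projection else config
  mag <- pj$magnification
  nl <- pj$nonlinearity
  if (case$side == "left") case <- mirror_case(case, frame$midsagittal_x)
  proj <- function(p3) c(mag * (p3[1] + nl * p3[1] * abs(p3[3])), mag * p3[2])
  cusp <- proj(case$cusp_tip)
  apex <- proj(case$root_apex)
  if (pj$angular_bias_deg != 0) {
    ax <- cusp - apex
    flip <- ax[2] < 0
    if (flip) ax <- -ax
    phi <- atan2(ax[1], ax[2])  # folded inclination to the vertical midline
    s <- if (phi == 0) 1 else sign(phi)
    phi2 <- phi + s * pj$angular_bias_deg * pi / 180
    ax2 <- vnorm(ax) * c(sin(phi2), cos(phi2))
    if (flip) ax2 <- -ax2
    apex <- cusp - ax2
  }
  if (pj$landmark_noise_sd > 0) {
    cusp <- cusp + stats::rnorm(2, 0, pj$landmark_noise_sd)
    apex <- apex + stats::rnorm(2, 0, pj$landmark_noise_sd)
  }
  bx <- c(frame$lateral_distal_x, frame$lateral_midline_x,
          frame$lateral_mesial_x, frame$central_midline_x)
  bounds <- mag * (bx + nl * bx * abs(arch_z_at(frame, bx)))
  if (any(diff(bounds) <= 0)) {
    stop("projection distortion collapsed the sector boundaries; reduce 'nonlinearity'",
         call. = FALSE)
  }
  mx <- frame$midsagittal_x
  mz <- abs(arch_z_at(frame, mx))
  panoramic_case(
    case_id = case$case_id,
    cusp_tip = cusp, root_apex = apex,
    occlusal_ref_molar = proj(frame$occlusal_points[1, ]),
    occlusal_ref_incisor = proj(frame$occlusal_points[3, ]),
    midline_top = c(mag * (mx + nl * mx * mz), mag * 20),
    midline_bottom = c(mag * (mx + nl * mx * mz), 0),
    sector_boundaries = bounds
  )
}

project_cohort <- function(cohort, config = cohort$config) {
  with_substream(config$seed, "projection", function() {
    lapply(cohort$cases, project_to_panoramic, frame = cohort$frame, config = config)
  })
}

#' Simulate multi-rater, multi-timepoint ratings of a synthetic cohort
#'
#' The cohort is first projected once (the "image", fixed across raters,
#' substream `"projection"`). Then each rater at each timepoint re-measures
#' the landmarks with independent Gaussian noise -- 3D noise on the CBCT
#' landmarks before KPG scoring, 2D noise on the projected landmarks before
#' the panoramic measures -- and every index is recomputed (substream
#' `"raters/<r>/<t>"`, so adding raters or timepoints never perturbs earlier
#' draws or case generation). Zero noise yields identical panels across
#' raters and timepoints.
#'
#' @param cohort a [canine_cohort()][generate_cases()].
#' @param config a [simulation_config()]; defaults to the cohort's own.
#' @param thresholds a [zone_thresholds()] object for KPG scoring.
#' @return A [rating_panel()] with indexes `kpg_total`, `kpg_class`,
#'   `stewart_mm`, `stewart_class`, `ek_sector`, `ek_class`, `alpha_deg`.
#' @export
simulate_raters <- function(cohort, config = cohort$config,
                            thresholds = zone_thresholds()) {
  stopifnot(inherits(cohort, "canine_cohort"))
  proj <- project_cohort(cohort, config)
  sd3 <- config$raters$noise_sd_3d
  sd2 <- config$raters$noise_sd_2d
  out <- list()
  for (r in seq_len(config$raters$n_raters)) {
    for (t in seq_len(config$raters$timepoints)) {
      rows <- with_substream(config$seed, paste("raters", r, t, sep = "/"), function() {
        lapply(seq_along(cohort$cases), function(i) {
          cs <- cohort$cases[[i]]
          noisy3 <- canine_case(cs$case_id, cs$side,
                                cs$cusp_tip + stats::rnorm(3, 0, sd3),
                                cs$root_apex + stats::rnorm(3, 0, sd3))
          k <- compute_kpg(noisy3, cohort$frame, thresholds)
          p <- proj[[i]]
          p2 <- p
          p2$cusp_tip <- p$cusp_tip + stats::rnorm(2, 0, sd2)
          p2$root_apex <- p$root_apex + stats::rnorm(2, 0, sd2)
          m <- planar_measures(p2)
          data.frame(
            case_id = cs$case_id,
            rater_id = sprintf("R%d", r),
            timepoint = sprintf("t%d", t - 1L),
            index = c("kpg_total", "kpg_class", "stewart_mm", "stewart_class",
                      "ek_sector", "ek_class", "alpha_deg"),
            value = c(as.character(k$total), k$category_dichotomous,
                      as.character(m$stewart_distance_mm), m$stewart_class,
                      as.character(m$ek_sector), m$ek_class,
                      as.character(m$alpha_deg)),
            stringsAsFactors = FALSE)
        })
      })
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  rating_panel(do.call(rbind, out))
}
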