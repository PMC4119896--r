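# Shared fixtures built in code.

# Frame with a straight occlusal reference arch (z = 25) so that axial
# displacement magnitudes map exactly onto arch distances: a cusp offset of
# (dx, dy, -dz) from the ideal position yields displacements (dx, dy, dz).
straight_frame <- function() {
  anatomy_frame(
    midsagittal_x = 0,
    occlusal_points = rbind(c(-40, 0, 25), c(40, 0, 25), c(0, 0, 30)),
    arch_curve = cbind(seq(-40, 0, by = 10), 0, 25),
    ideal_cusp = c(-20, 0, 25),
    ideal_apex = c(-20, 25, 25),
    lateral_distal_x = -15, lateral_midline_x = -11.75,
    lateral_mesial_x = -8.5, central_midline_x = -4.25
  )
}

# Canine displaced from the straight frame's ideal position by exact per-axis
# magnitudes: cusp by (dxc, dyc, dzc), root apex by (dxr, dyr, dzr); z offsets
# applied palatally (negative z).
offset_case <- function(dxc, dyc, dzc, dxr, dyr, dzr,
                        id = "case", side = "right", frame = straight_frame()) {
  cs <- canine_case(id, "right",
                    frame$ideal_cusp + c(dxc, dyc, -dzc),
                    frame$ideal_apex + c(dxr, dyr, -dzr))
  if (side == "left") cs <- mirror_case(cs, frame$midsagittal_x)
  cs
}

# Panoramic case with axis-aligned reference geometry: occlusal line y = 0,
# inter-incisor midline x = 0, standard sector boundaries.
pano_case <- function(cusp, apex = cusp + c(0, 20),
                      occ_a = c(-30, 0), occ_b = c(30, 0),
                      mid_a = c(0, 20), mid_b = c(0, 0),
                      bounds = c(-15, -11.75, -8.5, -4.25), id = "p") {
  panoramic_case(id, cusp, apex, occ_a, occ_b, mid_a, mid_b, bounds)
}

zero_noise_config <- function(n_cases = 30, seed = 11) {
  simulation_config(
    n_cases = n_cases, seed = seed,
    projection = list(magnification = 1, nonlinearity = 0,
                      angular_bias_deg = 0, landmark_noise_sd = 0),
    raters = list(n_raters = 3, timepoints = 2, noise_sd_3d = 0, noise_sd_2d = 0))
}

noisy_config <- function(noise_sd, n_cases = 200, seed = 42) {
  simulation_config(
    n_cases = n_cases, seed = seed,
    projection = list(magnification = 1.25, nonlinearity = 0.003,
                      angular_bias_deg = 5, landmark_noise_sd = 0),
    raters = list(n_raters = 3, timepoints = 2,
                  noise_sd_3d = noise_sd, noise_sd_2d = noise_sd))
}

# Random 2x2 table with all cells (hence all margins) positive.
random_table <- function() {
  contingency_2x2(matrix(sample(1:30, 4, replace = TRUE), 2, 2),
                  c("pos", "neg"), c("pos", "neg"))
}

# Expand a 2x2 table into the two paired 0/1 indicator vectors it summarises.
expand_indicators <- function(table) {
  m <- table$counts
  list(row = rep(c(1, 1, 0, 0), times = c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])),
       col = rep(c(1, 0, 1, 0), times = c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])))
}

reproduce_tables_quietly <- function(...) {
  suppressWarnings(reproduce_tables(...))
}
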