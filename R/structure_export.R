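# 3D realization of a plant state: petioles as line segments on a spiral
# phyllotaxis, blades as planar ellipses. Pure visualization/ray-casting
# plumbing with no physiological claim; all angles are config-exposed.

#' Export the 3D organ layout of a plant
#'
#' Each phytomer becomes a petiole segment leaving the stem base at its
#' phyllotactic azimuth with a rank-dependent elevation, and a horizontal
#' elliptic blade of dimensions length x width attached beyond the petiole
#' tip. Coordinates are centimetres relative to the stem base at the origin.
#'
#' @param state A `plant_state`.
#' @param elevation0 Petiole elevation of rank 1 above the horizontal,
#'   degrees.
#' @param elevation_step Decrease in elevation per rank, degrees (elevation
#'   is floored at 5 degrees).
#' @return A tibble with one row per phytomer: azimuth/elevation, petiole
#'   tip coordinates, blade center, blade normal and semi-axes (cm).
#' @export
export_structure <- function(state, elevation0 = 60, elevation_step = 2) {
  stopifnot(inherits(state, "plant_state"))
  ph <- state$phytomers
  if (nrow(ph) == 0) {
    return(tibble::tibble(rank = integer(), azimuth_deg = numeric(),
                          elevation_deg = numeric(),
                          tip_x = numeric(), tip_y = numeric(),
                          tip_z = numeric(), blade_cx = numeric(),
                          blade_cy = numeric(), blade_cz = numeric(),
                          normal_x = numeric(), normal_y = numeric(),
                          normal_z = numeric(), semi_major_cm = numeric(),
                          semi_minor_cm = numeric()))
  }
  elev <- pmax(5, elevation0 - elevation_step * (ph$rank - 1))
  az_r <- ph$azimuth * pi / 180
  el_r <- elev * pi / 180
  hx <- cos(az_r)
  hy <- sin(az_r)
  tip_x <- ph$petiole_length * cos(el_r) * hx
  tip_y <- ph$petiole_length * cos(el_r) * hy
  tip_z <- ph$petiole_length * sin(el_r)
  half_len <- ph$blade_length / 2
  tibble::tibble(
    rank = ph$rank, azimuth_deg = ph$azimuth, elevation_deg = elev,
    tip_x = tip_x, tip_y = tip_y, tip_z = tip_z,
    blade_cx = tip_x + half_len * hx,
    blade_cy = tip_y + half_len * hy,
    blade_cz = tip_z,
    normal_x = 0, normal_y = 0, normal_z = 1,
    semi_major_cm = half_len, semi_minor_cm = ph$blade_width / 2)
}

#' Write a plant structure as a Wavefront OBJ mesh
#'
#' Petioles are emitted as line elements, blades as polygon fans
#' approximating each ellipse with `n_segments` vertices. An empty structure
#' yields a valid empty mesh.
#'
#' @param structure A structure table from [export_structure()].
#' @param path Output `.obj` path.
#' @param n_segments Vertices per blade ellipse outline.
#' @return `path`, invisibly.
#' @export
write_obj <- function(structure, path, n_segments = 16) {
  lines <- c("# napusgrow plant structure (cm)")
  v_count <- 0
  for (i in seq_len(nrow(structure))) {
    s <- structure[i, ]
    az <- s$azimuth_deg * pi / 180
    u <- c(cos(az), sin(az), 0)                 # blade major axis
    w <- c(-sin(az), cos(az), 0)                # blade minor axis
    lines <- c(lines, sprintf("o phytomer_%d", s$rank),
               "v 0 0 0",
               sprintf("v %.4f %.4f %.4f", s$tip_x, s$tip_y, s$tip_z))
    lines <- c(lines, sprintf("l %d %d", v_count + 1, v_count + 2))
    v_count <- v_count + 2
    if (s$semi_major_cm > 0) {
      th <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
      px <- s$blade_cx + s$semi_major_cm * cos(th) * u[1] +
        s$semi_minor_cm * sin(th) * w[1]
      py <- s$blade_cy + s$semi_major_cm * cos(th) * u[2] +
        s$semi_minor_cm * sin(th) * w[2]
      pz <- rep(s$blade_cz, n_segments)
      lines <- c(lines, sprintf("v %.4f %.4f %.4f", px, py, pz),
                 paste("f", paste(v_count + seq_len(n_segments),
                                  collapse = " ")))
      v_count <- v_count + n_segments
    }
  }
  writeLines(lines, path)
  invisible(path)
}
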