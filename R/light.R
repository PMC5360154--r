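# Monte-Carlo light transport in a reconstructed growth chamber: Lambertian
# wall-mounted area emitters, differential upward-facing sensors, and leaves
# as single-interaction absorbing ellipses.

.panel <- function(origin, e1, e2) {
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  n <- n / sqrt(sum(n^2))
  list(origin = origin, e1 = e1, e2 = e2, normal = n,
       area = sqrt(sum(e1^2)) * sqrt(sum(e2^2)))
}

#' Construct a rectangular area emitter
#'
#' A Lambertian panel spanned by two edge vectors from an origin corner. The
#' emitting normal defaults to `e1 x e2` but can be overridden to point into
#' the chamber.
#'
#' @param origin Corner position, m.
#' @param e1,e2 Edge vectors, m.
#' @param normal Optional unit emission normal.
#' @return A panel list usable in [chamber_scene()]'s `panels` argument.
#' @export
light_panel <- function(origin, e1, e2, normal = NULL) {
  p <- .panel(origin, e1, e2)
  if (!is.null(normal)) p$normal <- normal / sqrt(sum(normal^2))
  p
}

#' Reconstructed growth-chamber scene
#'
#' A box with Lambertian area emitters on the two lateral walls and the back
#' wall (the wall-mounted lamp banks), two upward-facing virtual sensors
#' above the shelf positions, and optionally plant canopies as absorbing
#' blade ellipses. The interior dimensions of the real chamber are not
#' published; the default box (1.0 x 0.6 x 1.5 m) with lamp strips spanning
#' 0.2-1.5 m height and 0.05 m lateral margins was calibrated once so that
#' the default sensors average the measured 150 umol m-2 s-1 when the
#' source output is 330 umol m-2 s-1. All geometry is exposed here.
#'
#' @param width,depth,height Interior box dimensions, m.
#' @param source_output Radiant exitance of the emitting wall surfaces,
#'   umol m-2 s-1 (total lamp output; default 330).
#' @param panel_z Height range `c(low, high)` of the lamp strips, m.
#' @param panel_margin Lateral margin of each lamp strip, m.
#' @param sensors Matrix (or data frame) of sensor positions, columns
#'   x, y, z in m; defaults to two sensors above the shelves.
#' @param absorptance Leaf absorptance in the photosynthetically active
#'   band (single-interaction absorption, no rescattering).
#' @param plant_origin Position of the plant stem base in the box, m.
#' @param panels Optional list of [light_panel()] objects replacing the
#'   default wall strips.
#' @return An object of class `chamber_scene`.
#' @export
chamber_scene <- function(width = 1.0, depth = 0.6, height = 1.5,
                          source_output = 330,
                          panel_z = c(0.2, height), panel_margin = 0.05,
                          sensors = NULL, absorptance = 0.85,
                          plant_origin = c(0.5, 0.3, 0.25),
                          panels = NULL) {
  stopifnot(width > 0, depth > 0, height > 0, source_output >= 0,
            absorptance > 0, absorptance <= 1)
  z0 <- panel_z[1]
  z1 <- panel_z[2]
  m <- panel_margin
  custom_panels <- panels
  panels <- list(
    # left wall (x = 0), emitting toward +x
    .panel(c(0, m, z0), c(0, depth - 2 * m, 0), c(0, 0, z1 - z0)),
    # right wall (x = width), emitting toward -x
    .panel(c(width, m, z0), c(0, 0, z1 - z0), c(0, depth - 2 * m, 0)),
    # back wall (y = depth), emitting toward -y
    .panel(c(m, depth, z0), c(0, 0, z1 - z0), c(width - 2 * m, 0, 0)))
  # orient normals into the box
  panels[[1]]$normal <- c(1, 0, 0)
  panels[[2]]$normal <- c(-1, 0, 0)
  panels[[3]]$normal <- c(0, -1, 0)
  if (!is.null(custom_panels)) panels <- custom_panels
  if (is.null(sensors)) {
    sensors <- rbind(c(width / 2, depth / 2, 0.25),
                     c(width / 2, depth / 2, 0.95))
  }
  sensors <- as.matrix(sensors)
  colnames(sensors) <- c("x", "y", "z")
  if (any(sensors[, 1] < 0 | sensors[, 1] > width |
            sensors[, 2] < 0 | sensors[, 2] > depth |
            sensors[, 3] < 0 | sensors[, 3] > height)) {
    stop("degenerate geometry: sensor outside the chamber box",
         call. = FALSE)
  }
  structure(list(width = width, depth = depth, height = height,
                 source_output = source_output, panels = panels,
                 sensors = sensors, absorptance = absorptance,
                 plant_origin = plant_origin, leaves = NULL),
            class = "chamber_scene")
}

# Leaves as absorbing ellipses in box coordinates (m), from a structure
# table (cm) placed at the scene's plant origin.
.scene_leaves <- function(scene, structure_tab) {
  if (is.null(structure_tab) || nrow(structure_tab) == 0) return(NULL)
  o <- scene$plant_origin
  list(center = cbind(o[1] + structure_tab$blade_cx / 100,
                      o[2] + structure_tab$blade_cy / 100,
                      o[3] + structure_tab$blade_cz / 100),
       normal = cbind(structure_tab$normal_x, structure_tab$normal_y,
                      structure_tab$normal_z),
       azimuth = structure_tab$azimuth_deg * pi / 180,
       a = structure_tab$semi_major_cm / 100,
       b = structure_tab$semi_minor_cm / 100,
       rank = structure_tab$rank)
}

# Vectorized intersection of rays (orig + t * dir) with horizontal ellipse
# j of `leaves`; returns t (Inf where missed). Blades are horizontal
# (normal +z) in the present layout, so the plane solve is direct.
.ray_ellipse_t <- function(ox, oy, oz, dx, dy, dz, leaves, j) {
  cz <- leaves$center[j, 3]
  t <- (cz - oz) / dz
  t[!is.finite(t) | t <= 1e-9] <- Inf
  px <- ox + t * dx - leaves$center[j, 1]
  py <- oy + t * dy - leaves$center[j, 2]
  ca <- cos(leaves$azimuth[j])
  sa <- sin(leaves$azimuth[j])
  u <- px * ca + py * sa
  v <- -px * sa + py * ca
  inside <- (u / leaves$a[j])^2 + (v / leaves$b[j])^2 <= 1
  t[!inside] <- Inf
  t
}

#' Monte-Carlo sensor PPFD estimate
#'
#' Each sensor is a differential upward-facing element; its irradiance from
#' the Lambertian wall emitters equals the source exitance times the
#' cosine-weighted fraction of its hemisphere covered by emitting surface.
#' That fraction is estimated by cosine-weighted hemisphere sampling; rays
#' blocked by plant leaves (if the scene carries any) do not count. The
#' estimate converges as `1/sqrt(n_rays)` and its standard error is
#' reported.
#'
#' @param scene A [chamber_scene()].
#' @param n_rays Rays per sensor (>= 1000; use >= 1e5 for reported values).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A tibble with one row per sensor: position, `ppfd`
#'   (umol m-2 s-1) and `se` (Monte-Carlo standard error).
#' @export
#' @examples
#' \donttest{
#' estimate_sensor_ppfd(chamber_scene(), n_rays = 1e5, seed = 1)
#' }
estimate_sensor_ppfd <- function(scene, n_rays = 1e5, seed = 1L) {
  stopifnot(inherits(scene, "chamber_scene"))
  if (n_rays < 1000) stop("n_rays must be at least 1000", call. = FALSE)
  n_rays <- as.integer(n_rays)
  run <- function() {
    out <- vector("list", nrow(scene$sensors))
    for (si in seq_len(nrow(scene$sensors))) {
      s <- scene$sensors[si, ]
      u1 <- stats::runif(n_rays)
      u2 <- stats::runif(n_rays)
      phi <- 2 * pi * u1
      r <- sqrt(u2)
      dx <- r * cos(phi)
      dy <- r * sin(phi)
      dz <- sqrt(1 - u2)
      # nearest emitter hit among the panels
      t_panel <- rep(Inf, n_rays)
      for (p in scene$panels) {
        nrm <- p$normal
        denom <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3]
        t <- ((p$origin[1] - s[1]) * nrm[1] + (p$origin[2] - s[2]) * nrm[2] +
                (p$origin[3] - s[3]) * nrm[3]) / denom
        t[!is.finite(t) | t <= 1e-9] <- Inf
        hx <- s[1] + t * dx - p$origin[1]
        hy <- s[2] + t * dy - p$origin[2]
        hz <- s[3] + t * dz - p$origin[3]
        d1 <- (hx * p$e1[1] + hy * p$e1[2] + hz * p$e1[3]) / sum(p$e1^2)
        d2 <- (hx * p$e2[1] + hy * p$e2[2] + hz * p$e2[3]) / sum(p$e2^2)
        ok <- d1 >= 0 & d1 <= 1 & d2 >= 0 & d2 <= 1
        t[!ok] <- Inf
        t_panel <- pmin(t_panel, t)
      }
      hit <- is.finite(t_panel)
      # occlusion by leaves between sensor and emitter
      if (!is.null(scene$leaves)) {
        for (j in seq_along(scene$leaves$a)) {
          t_leaf <- .ray_ellipse_t(s[1], s[2], s[3], dx, dy, dz,
                                   scene$leaves, j)
          hit <- hit & !(t_leaf < t_panel)
        }
      }
      p_hat <- mean(hit)
      out[[si]] <- tibble::tibble(
        sensor = si, x = s[1], y = s[2], z = s[3],
        ppfd = scene$source_output * p_hat,
        se = scene$source_output * stats::sd(hit) / sqrt(n_rays))
    }
    do.call(rbind, out)
  }
  withr::with_seed(as.integer(seed), run())
}

#' Place a plant canopy into a chamber scene
#'
#' Converts a structure table (cm, stem base at the origin) into absorbing
#' blade ellipses at the scene's `plant_origin`, so that subsequent sensor
#' estimates account for shading.
#'
#' @param scene A [chamber_scene()].
#' @param structure_tab A structure table from [export_structure()].
#' @return The scene with leaves attached.
#' @export
add_plant_to_scene <- function(scene, structure_tab) {
  stopifnot(inherits(scene, "chamber_scene"))
  scene$leaves <- .scene_leaves(scene, structure_tab)
  scene
}

#' Monte-Carlo absorbed light per leaf
#'
#' Rays are emitted from the lamp panels (uniform over the emitting area,
#' cosine-weighted about the inward normal, each carrying an equal share of
#' the total emitted flux `source_output x panel area`). The nearest leaf
#' ellipse along a ray absorbs the scene absorptance fraction of that ray's
#' flux; the remainder is lost (single interaction, no rescattering).
#' Occlusion is therefore resolved exactly by the nearest-hit rule, and the
#' total absorbed flux can never exceed the emitted flux.
#'
#' @param scene A [chamber_scene()].
#' @param structure_tab A plant structure table from [export_structure()]
#'   (cm; placed at the scene's `plant_origin`).
#' @param n_rays Total number of rays.
#' @param seed Integer seed.
#' @return A tibble with one row per phytomer: `rank`, `absorbed_umol_s`
#'   (umol s-1) and `se`. Empty structure yields an empty map.
#' @export
per_leaf_absorbed_par <- function(scene, structure_tab, n_rays = 20000,
                                  seed = 1L) {
  stopifnot(inherits(scene, "chamber_scene"))
  leaves <- .scene_leaves(scene, structure_tab)
  if (is.null(leaves)) {
    return(tibble::tibble(rank = integer(), absorbed_umol_s = numeric(),
                          se = numeric()))
  }
  n_rays <- as.integer(n_rays)
  areas <- vapply(scene$panels, `[[`, numeric(1), "area")
  total_flux <- scene$source_output * sum(areas)    # umol s-1
  ray_flux <- total_flux / n_rays
  run <- function() {
    # distribute rays across panels by area
    n_per <- stats::setNames(as.vector(stats::rmultinom(
      1, n_rays, areas / sum(areas))), NULL)
    counts <- numeric(length(leaves$a))
    for (pi in seq_along(scene$panels)) {
      np <- n_per[pi]
      if (np == 0) next
      p <- scene$panels[[pi]]
      q1 <- stats::runif(np)
      q2 <- stats::runif(np)
      ox <- p$origin[1] + q1 * p$e1[1] + q2 * p$e2[1]
      oy <- p$origin[2] + q1 * p$e1[2] + q2 * p$e2[2]
      oz <- p$origin[3] + q1 * p$e1[3] + q2 * p$e2[3]
      # cosine-weighted direction about the inward normal
      u1 <- stats::runif(np)
      u2 <- stats::runif(np)
      phi <- 2 * pi * u1
      r <- sqrt(u2)
      lx <- r * cos(phi)
      ly <- r * sin(phi)
      lz <- sqrt(1 - u2)
      nrm <- p$normal
      # build an orthonormal frame (t1, t2, nrm)
      t1 <- if (abs(nrm[3]) < 0.9) c(-nrm[2], nrm[1], 0) else c(1, 0, 0)
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
              nrm[3] * t1[1] - nrm[1] * t1[3],
              nrm[1] * t1[2] - nrm[2] * t1[1])
      dx <- lx * t1[1] + ly * t2[1] + lz * nrm[1]
      dy <- lx * t1[2] + ly * t2[2] + lz * nrm[2]
      dz <- lx * t1[3] + ly * t2[3] + lz * nrm[3]
      t_best <- rep(Inf, np)
      j_best <- rep(0L, np)
      for (j in seq_along(leaves$a)) {
        tj <- .ray_ellipse_t(ox, oy, oz, dx, dy, dz, leaves, j)
        closer <- tj < t_best
        t_best[closer] <- tj[closer]
        j_best[closer] <- j
      }
      tab <- tabulate(j_best, nbins = length(leaves$a))
      counts <- counts + tab
    }
    tibble::tibble(rank = leaves$rank,
                   absorbed_umol_s = scene$absorptance * ray_flux * counts,
                   se = scene$absorptance * ray_flux * sqrt(counts))
  }
  withr::with_seed(as.integer(seed), run())
}
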