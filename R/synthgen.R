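## Synthetic blastocyst models and multi-view renders with known ground truth.
## Every downstream stage (registration, stitching, segmentation, morphometry)
## is testable against these generators without any real data.

#' Generate a ground-truth 3D blastocyst model
#'
#' The blastocyst surface is a sphere of diameter `diameter_um`. The inner
#' cell mass (ICM) is a spherical cap of area `icm_area_um2` about a random
#' axis; the rest of the surface is tessellated into exactly `n_te_cells`
#' trophectoderm (TE) cells by a spherical Voronoi diagram whose generator
#' sites are moved by Lloyd-style relaxation until the coefficient of
#' variation (CV) of cell areas is within 0.05 of `size_cv_target`, or 200
#' iterations elapse. Plain Lloyd steps (site to area-weighted centroid)
#' reduce the CV; when the target exceeds the current CV, inverse steps (site
#' moved away from its centroid) raise it.
#'
#' Cell areas are computed by exact-bin-area quadrature on a fine
#' equirectangular grid (nearest-site assignment outside the cap) and then
#' rescaled by a single factor so that the partition identity
#' `sum(te_cell_areas) + icm_area == pi * diameter^2` holds exactly; the ICM
#' area itself is the closed-form cap area `2*pi*R^2*(1 - cos(theta))`.
#'
#' @param n_te_cells number of TE cells (>= 4).
#' @param diameter_um sphere diameter D in micrometres.
#' @param icm_area_um2 ICM cap area (must be < half the sphere area).
#' @param size_cv_target target CV of TE cell areas in `[0, 1]`.
#' @param seed integer RNG seed; the model is a pure function of its
#'   arguments.
#' @param icm_axis optional unit vector for the cap axis (default: random).
#' @param relax_shape,area_shape grid shapes (n_lat, n_lon) used during
#'   relaxation and for the final area quadrature.
#' @return An object of class `truth_model` with fields `diameter_um`,
#'   `te_sites` (n x 3 unit vectors), `te_cell_areas`, `icm_axis`,
#'   `icm_polar_half_angle`, `icm_area_um2`, `albedo`, `texture_params`,
#'   `realized_cv`, `seed`.
#' @export
make_truth <- function(n_te_cells, diameter_um, icm_area_um2,
                       size_cv_target = 0.3, seed = 1L, icm_axis = NULL,
                       relax_shape = c(192L, 384L),
                       area_shape = c(1536L, 3072L)) {
  stopifnot(n_te_cells >= 4, diameter_um > 0, icm_area_um2 > 0,
            size_cv_target >= 0, size_cv_target <= 1)
  R <- diameter_um / 2
  if (icm_area_um2 >= pi * diameter_um^2 / 2) {
    stop("make_truth: icm_area_um2 must be < pi * D^2 / 2 (half sphere)",
         call. = FALSE)
  }
  theta_c <- acos(1 - icm_area_um2 / (2 * pi * R^2))
  icm_area_exact <- 2 * pi * R^2 * (1 - cos(theta_c))
  rng <- local_rng(seed)
  if (is.null(icm_axis)) {
    icm_axis <- random_unit_vectors(1, rng)[1, ]
  } else {
    icm_axis <- icm_axis / sqrt(sum(icm_axis^2))
  }
  cos_c <- cos(theta_c)

  ## initial sites: uniform outside the cap (rejection sampling)
  sites <- matrix(NA_real_, 0, 3)
  while (nrow(sites) < n_te_cells) {
    cand <- random_unit_vectors(2 * n_te_cells + 16, rng)
    cand <- cand[cand %*% icm_axis < cos_c, , drop = FALSE]
    sites <- rbind(sites, cand)
  }
  sites <- sites[seq_len(n_te_cells), , drop = FALSE]
  min_sep <- 0.8 / sqrt(n_te_cells)
  sites <- enforce_min_separation(sites, min_sep)

  ## relaxation on a coarse quadrature grid
  grid <- quadrature_grid(relax_shape[1], relax_shape[2], R)
  out_cap <- as.numeric(grid$xyz %*% icm_axis) < cos_c
  gx <- grid$xyz[out_cap, , drop = FALSE]
  ga <- grid$areas[out_cap]
  cv_of <- function(a) stats::sd(a) / mean(a)
  areas <- cell_quadrature_areas(sites, gx, ga)
  cv <- cv_of(areas)
  best <- list(sites = sites, cv = cv)
  iter <- 0L
  while (abs(cv - size_cv_target) > 0.05 && iter < 200L) {
    iter <- iter + 1L
    assign_idx <- nearest_site(gx, sites)
    cx <- rowsum(gx * ga, assign_idx, reorder = FALSE)
    ord <- as.integer(rownames(cx))
    cent <- matrix(0, n_te_cells, 3)
    cent[ord, ] <- cx
    nrm <- sqrt(rowSums(cent^2))
    empty <- nrm < 1e-12
    cent[!empty, ] <- cent[!empty, ] / nrm[!empty]
    cent[empty, ] <- sites[empty, ]
    step <- if (cv > size_cv_target) 1 else -0.25
    sites_new <- sites + step * (cent - sites)
    sites_new <- sites_new / sqrt(rowSums(sites_new^2))
    sites_new <- enforce_min_separation(sites_new, min_sep)
    ## keep sites outside the cap
    inside <- as.numeric(sites_new %*% icm_axis) >= cos_c
    if (any(inside)) {
      sites_new[inside, ] <- push_outside_cap(sites_new[inside, , drop = FALSE],
                                              icm_axis, theta_c + 0.02)
    }
    sites <- sites_new
    areas <- cell_quadrature_areas(sites, gx, ga)
    cv <- cv_of(areas)
    if (abs(cv - size_cv_target) < abs(best$cv - size_cv_target)) {
      best <- list(sites = sites, cv = cv)
    }
  }
  if (abs(cv - size_cv_target) > 0.05) {
    sites <- best$sites
    warning(sprintf(
      "make_truth: size_cv_target %.2f not reached; best achieved CV %.3f",
      size_cv_target, best$cv), call. = FALSE)
  }
  ## degenerate-geometry guard also covers the no-iteration path
  sites <- enforce_min_separation(sites, min_sep)

  ## final areas on the fine grid, rescaled to the exact partition identity
  fine <- quadrature_grid(area_shape[1], area_shape[2], R)
  f_out <- as.numeric(fine$xyz %*% icm_axis) < cos_c
  areas <- cell_quadrature_areas(sites, fine$xyz[f_out, , drop = FALSE],
                                 fine$areas[f_out])
  areas <- areas * (pi * diameter_um^2 - icm_area_exact) / sum(areas)
  structure(list(
    diameter_um = diameter_um,
    te_sites = sites,
    te_cell_areas = as.numeric(areas),
    icm_axis = icm_axis,
    icm_polar_half_angle = theta_c,
    icm_area_um2 = icm_area_exact,
    albedo = 0.55 + 0.4 * rng$runif(n_te_cells),
    ## granular intracellular texture: several small off-center spots per
    ## cell (organelle-scale albedo variation)
    spot_dir = {
      nl <- 8L
      off <- matrix(rng$rnorm(3L * nl * n_te_cells, sd = 0.08),
                    nl * n_te_cells, 3)
      sd <- sites[rep(seq_len(n_te_cells), nl), , drop = FALSE] + off
      sd / sqrt(rowSums(sd^2))
    },
    spot_amp = rng$runif(8L * n_te_cells, -0.15, 0.15),
    spot_sigma_rad = (1.5 + 2.5 * rng$runif(8L * n_te_cells)) / (diameter_um / 2),
    texture_params = list(boundary_darkness = 0.25, boundary_width_um = 2,
                          icm_albedo = 0.42, shading_gain = 1, noise_sd = 0),
    realized_cv = cv_of(areas),
    seed = seed
  ), class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf(
    "<truth_model> D = %.1f um, %d TE cells (area CV %.3f), ICM %.0f um2\n",
    x$diameter_um, length(x$te_cell_areas), x$realized_cv, x$icm_area_um2))
  invisible(x)
}

## a self-contained RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    fn(...)
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}

random_unit_vectors <- function(n, rng) {
  v <- matrix(rng$rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

quadrature_grid <- function(n_lat, n_lon, radius_um) {
  map <- sphere_label_map(n_lat, n_lon, radius_um)
  xyz <- bin_center_xyz(n_lat, n_lon)
  areas <- rep(row_bin_areas(map), times = n_lon)
  list(xyz = xyz, areas = areas)
}

## nearest site by maximal dot product (C++ kernel)
nearest_site <- function(points, sites) {
  top2_dot(points, sites)$i1
}

cell_quadrature_areas <- function(sites, points, point_areas) {
  idx <- nearest_site(points, sites)
  a <- numeric(nrow(sites))
  s <- rowsum(point_areas, idx, reorder = FALSE)
  a[as.integer(rownames(s))] <- s
  a
}

## push apart any site pair closer than min_sep radians (near-coincident
## generators are degenerate: the shared bisector band swallows both cells)
enforce_min_separation <- function(sites, min_sep, passes = 5L) {
  for (p in seq_len(passes)) {
    d <- sites %*% t(sites)
    diag(d) <- -2
    close <- which(d > cos(min_sep), arr.ind = TRUE)
    close <- close[close[, 1] < close[, 2], , drop = FALSE]
    if (!nrow(close)) break
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      a <- acos(min(1, sum(sites[i, ] * sites[j, ])))
      mid <- sites[i, ] + sites[j, ]
      nm <- sqrt(sum(mid^2))
      if (nm < 1e-9) next
      mid <- mid / nm
      tang <- sites[i, ] - sum(sites[i, ] * mid) * mid
      nt <- sqrt(sum(tang^2))
      if (nt < 1e-9) {
        tang <- c(mid[2], -mid[1], 0)
        nt <- sqrt(sum(tang^2))
      }
      tang <- tang / nt
      half <- min_sep / 2
      sites[i, ] <- cos(half) * mid + sin(half) * tang
      sites[j, ] <- cos(half) * mid - sin(half) * tang
    }
  }
  sites
}

push_outside_cap <- function(v, axis, theta) {
  ## rotate each vector away from `axis` so its polar angle becomes theta
  t(apply(v, 1, function(p) {
    d <- sum(p * axis)
    perp <- p - d * axis
    np <- sqrt(sum(perp^2))
    if (np < 1e-12) {
      ## on the axis: pick an arbitrary perpendicular
      perp <- c(axis[2], -axis[1], 0)
      np <- sqrt(sum(perp^2))
      if (np < 1e-12) { perp <- c(0, axis[3], -axis[2]); np <- sqrt(sum(perp^2)) }
    }
    cos(theta) * axis + sin(theta) * perp / np
  }))
}

## ---- truth labels ------------------------------------------------------

#' Ground-truth surface label at 3D points
#'
#' @param truth a [make_truth()] model.
#' @param xyz n x 3 points in the global frame (any radius; direction used).
#' @param boundary_width_um width of the TE-TE boundary band; defaults to the
#'   model's texture parameter.
#' @return Integer labels: 1 = TE boundary, 2 = ICM, >= 3 = cell id + 2.
#' @export
truth_label_at <- function(truth, xyz, boundary_width_um = NULL) {
  if (is.null(boundary_width_um)) {
    boundary_width_um <- truth$texture_params$boundary_width_um
  }
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  u <- xyz / sqrt(rowSums(xyz^2))
  R <- truth$diameter_um / 2
  lab <- integer(nrow(u))
  icm <- as.numeric(u %*% truth$icm_axis) >= cos(truth$icm_polar_half_angle)
  ## top-two nearest sites -> exact geodesic distance to the bisector great
  ## circle (asin of the dot product with the plane normal), giving a
  ## constant-width membrane band along every cell border
  tt <- top2_dot(u, truth$te_sites)
  half_w_rad <- boundary_width_um / (2 * R)
  nrm <- truth$te_sites[tt$i1, , drop = FALSE] -
    truth$te_sites[tt$i2, , drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  dist_edge <- asin(pmin(1, abs(rowSums(u * nrm))))
  bnd <- dist_edge <= half_w_rad
  lab[] <- tt$i1 + 2L
  lab[bnd] <- 1L
  lab[icm] <- 2L
  lab
}

## ---- rendering ---------------------------------------------------------

#' Render one orthographic view of a truth model
#'
#' The camera-facing hemisphere is rendered orthographically with Lambertian
#' shading proportional to z/R, per-cell albedo texture, dark geodesic cell
#' boundaries and a darkened ICM cap; Gaussian noise of standard deviation
#' `noise_sd` is added. Rendering is supersampled (each pixel is the mean of
#' `supersample^2` subpixel samples), emulating the integration over the
#' pixel footprint of a real detector, so strongly foreshortened boundary
#' bands near the limb still darken their pixels. The returned mask holds
#' the true label at each pixel center (point-sampled, not averaged:
#' categorical labels at grazing angles would otherwise be destroyed by the
#' footprint mixing, and downstream area measurement relies on the mask
#' being an unbiased sample of the surface partition).
#'
#' @param truth a [make_truth()] model.
#' @param rotation 3 x 3 rotation mapping the view (camera) frame to the
#'   global frame: a camera-frame surface point c lies at global point
#'   `rotation %*% c`.
#' @param pixel_scale micrometres per pixel.
#' @param noise_sd Gaussian noise standard deviation (image units, `[0, 1]`
#'   dynamic range).
#' @param seed RNG seed for the noise (only used when `noise_sd > 0`).
#' @param supersample subpixel sampling factor per axis (default 3).
#' @return A list with `image` (matrix in `[0, 1]`), `mask` (integer matrix,
#'   0 = background), and `sphere` (the [blastocyst_sphere()] of the crop).
#' @export
render_view <- function(truth, rotation = diag(3), pixel_scale = 1,
                        noise_sd = 0, seed = 1L, supersample = 3L) {
  stopifnot(pixel_scale > 0, supersample >= 1)
  R <- truth$diameter_um / 2
  side <- ceiling(truth$diameter_um / pixel_scale)
  if (side %% 2 == 0) side <- side + 1L
  ctr <- (side + 1) / 2
  sphere <- blastocyst_sphere(c(ctr, ctr), truth$diameter_um, pixel_scale)
  ss <- as.integer(supersample)
  fside <- side * ss
  ## fine-grid coordinates: block means of fine centers equal pixel centers
  fcoord <- (rep(seq_len(side), each = ss) - ctr) +
    (rep(seq_len(ss), times = side) - (ss + 1) / 2) / ss
  u <- rep(fcoord, each = fside) * pixel_scale
  v <- rep(fcoord, times = fside) * pixel_scale
  h2 <- R^2 - u^2 - v^2
  keep <- h2 > 0
  vals_f <- rep(0.05, fside * fside)   # background
  lab_f <- integer(fside * fside)
  cam <- cbind(u[keep], v[keep], sqrt(h2[keep]))
  glob <- cam %*% t(rotation)
  lab <- truth_label_at(truth, glob)
  tp <- truth$texture_params
  alb <- numeric(length(lab))
  cellpix <- lab >= 3L
  cid <- lab[cellpix] - 2L
  alb[cellpix] <- truth$albedo[cid]
  if (!is.null(truth$spot_dir)) {
    gu <- glob[cellpix, , drop = FALSE]
    gu <- gu / sqrt(rowSums(gu^2))
    n_cells <- length(truth$albedo)
    n_layers <- nrow(truth$spot_dir) / n_cells
    for (l in seq_len(n_layers)) {
      sidx <- cid + (l - 1L) * n_cells
      d <- rowSums(gu * truth$spot_dir[sidx, , drop = FALSE])
      ang2 <- 2 * pmax(0, 1 - d)
      alb[cellpix] <- alb[cellpix] +
        truth$spot_amp[sidx] * exp(-ang2 / (2 * truth$spot_sigma_rad[sidx]^2))
    }
  }
  alb[lab == 1L] <- tp$boundary_darkness
  alb[lab == 2L] <- tp$icm_albedo
  shade <- pmax(0, cam[, 3] / R) * tp$shading_gain
  vals_f[keep] <- alb * shade
  lab_f[keep] <- lab
  ## box-filter the fine image down to the pixel grid (fine index layout:
  ## column-major over (v fast, u slow) = (row, col) like the image)
  fm <- matrix(vals_f, fside, fside)
  img <- pmin(pmax(block_mean(fm, ss), 0), 1)
  ## point-sampled mask: the label at the central subpixel of each pixel
  mid <- (ss + 1L) %/% 2L
  sel <- mid + ss * (seq_len(side) - 1L)
  msk <- matrix(lab_f, fside, fside)[sel, sel]
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    img <- img + matrix(rng$rnorm(side * side, sd = noise_sd), side, side)
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = msk, sphere = sphere)
}

## mean over ss x ss blocks
block_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  n <- nrow(m) / ss
  ## average rows within blocks, then columns
  r <- rowsum(m, rep(seq_len(n), each = ss)) / ss
  t(rowsum(t(r), rep(seq_len(n), each = ss)) / ss)
}

#' Render the mid-plane image of a truth model
#'
#' A bright disk with a dark rim of the same diameter as the sphere, as seen
#' when the focal plane bisects the blastocyst.
#'
#' @inheritParams render_view
#' @param rim_width_um width of the dark rim band.
#' @param margin_px background margin around the disk (the mid-plane capture
#'   is not pre-cropped, so the outer boundary must be visible).
#' @return Image matrix in `[0, 1]`.
#' @export
render_midplane <- function(truth, pixel_scale = 1, noise_sd = 0, seed = 1L,
                            rim_width_um = 3, margin_px = 10L) {
  R <- truth$diameter_um / 2
  side <- ceiling(truth$diameter_um / pixel_scale) + 2L * margin_px
  if (side %% 2 == 0) side <- side + 1L
  ctr <- (side + 1) / 2
  xs <- rep(seq_len(side), each = side)
  ys <- rep(seq_len(side), times = side)
  r <- sqrt((xs - ctr)^2 + (ys - ctr)^2) * pixel_scale
  ## bright culture medium, dark rim, bright blastocoel interior;
  ## edges anti-aliased over one pixel so transitions sit on the true radii
  aa <- function(r, edge) pmin(pmax(edge - r + 0.5, 0), 1)  # 1 inside edge
  out_mix <- aa(r, R)                      # 1 inside the outer boundary
  in_mix <- aa(r, R - rim_width_um)        # 1 inside the rim's inner edge
  vals <- 0.35 * (1 - out_mix) + (0.08 * (1 - in_mix) + 0.8 * in_mix) * out_mix
  img <- matrix(0.35, side, side)
  img[ys + (xs - 1L) * side] <- vals
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    img <- pmin(pmax(img + matrix(rng$rnorm(side * side, sd = noise_sd),
                                  side, side), 0), 1)
  }
  img
}

#' Render a full rotational multi-view sequence
#'
#' The default acquisition protocol mirrors the imaging procedure: the
#' blastocyst is turned about a fixed axis in steps of `360 / n_views`
#' degrees (plus optional uniform jitter), so that with the default 12 views
#' all steps are below 35 degrees and more than 10 images cover the full
#' revolution.
#'
#' @param truth a [make_truth()] model.
#' @param n_views number of views over the full 360-degree turn (>= 2; the
#'   step must stay below 90 degrees so adjacent views overlap).
#' @param axis rotation axis (default image-vertical, +y).
#' @param jitter_deg half-width of the uniform jitter added to each step.
#' @param pixel_scale micrometres per pixel.
#' @param noise_sd image noise standard deviation.
#' @param seed RNG seed for jitter and noise.
#' @return A list of class `rendered_sequence`: `views`, `masks`, `spheres`,
#'   `true_rotations` (view-to-global), `true_steps_deg`, `midplane`,
#'   `truth`.
#' @export
render_sequence <- function(truth, n_views = 12, axis = c(0, 1, 0),
                            jitter_deg = 0, pixel_scale = 1, noise_sd = 0,
                            seed = 1L) {
  stopifnot(n_views >= 2)
  base_step <- 360 / n_views
  if (base_step + jitter_deg >= 90) {
    stop("render_sequence: rotation step >= 90 degrees leaves no overlap",
         call. = FALSE)
  }
  rng <- local_rng(seed + 7L)
  steps <- base_step + if (jitter_deg > 0) {
    rng$runif(n_views, -jitter_deg, jitter_deg)
  } else rep(0, n_views)
  angles <- c(0, cumsum(steps))[seq_len(n_views)]
  axis <- axis / sqrt(sum(axis^2))
  views <- vector("list", n_views)
  masks <- vector("list", n_views)
  spheres <- vector("list", n_views)
  rots <- vector("list", n_views)
  for (i in seq_len(n_views)) {
    ## object turned by angles[i]: camera coords c = Rot(axis, a) %*% p,
    ## so the view-to-global rotation is the transpose
    Rw <- rot_axis_angle(axis, angles[i] * pi / 180)
    rots[[i]] <- t(Rw)
    rv <- render_view(truth, t(Rw), pixel_scale, noise_sd, seed = seed + i)
    views[[i]] <- rv$image
    masks[[i]] <- rv$mask
    spheres[[i]] <- rv$sphere
  }
  structure(list(
    views = views, masks = masks, spheres = spheres,
    true_rotations = rots, true_steps_deg = steps,
    midplane = render_midplane(truth, pixel_scale, noise_sd, seed = seed),
    pixel_scale = pixel_scale,
    truth = truth
  ), class = "rendered_sequence")
}

## ---- feature-table simulation -----------------------------------------

#' Default class-conditional feature distributions
#'
#' Per-class means and SDs of the five morphological parameters for euploid
#' and non-euploid blastocysts, matching the observed cohort moments
#' (euploid: diameter 190.4 (19.1) um, TE count 141.3 (38.5), size variance
#' 221.5 (119.2) um2, ICM 5883.4 (2303.1) um2; non-euploid: 175.2 (21.9),
#' 68.3 (27.1), 794.9 (937.0), 4973.2 (2154.3)). TE density is derived
#' deterministically from count and diameter and has no free parameters.
#'
#' @return Nested list with `euploid` and `non_euploid` entries.
#' @export
default_class_params <- function() {
  list(
    euploid = list(
      diameter = c(mean = 190.4, sd = 19.1),
      te_count = c(mean = 141.3, sd = 38.5),
      te_size_variance = c(mean = 221.5, sd = 119.2),
      icm_area = c(mean = 5883.4, sd = 2303.1)
    ),
    non_euploid = list(
      diameter = c(mean = 175.2, sd = 21.9),
      te_count = c(mean = 68.3, sd = 27.1),
      te_size_variance = c(mean = 794.9, sd = 937.0),
      icm_area = c(mean = 4973.2, sd = 2154.3)
    )
  )
}

#' Simulate a morphological feature table
#'
#' Draws class-conditional features: diameter and ICM area from truncated
#' normals, TE count from a truncated normal rounded to integer, TE size
#' variance from a lognormal matched to the class mean/SD (areas' dispersion
#' is right-skewed and positive), and TE density derived deterministically as
#' `1000 * count / (pi * diameter^2)`.
#'
#' @param n number of blastocysts.
#' @param euploid_fraction probability of the euploid class (default 0.571,
#'   the observed cohort euploidy rate).
#' @param class_params per-class means/SDs, see [default_class_params()].
#' @param seed integer RNG seed.
#' @return A `data.frame` with the canonical feature-table columns `id`,
#'   `diameter_um`, `te_count`, `te_density`, `te_size_variance`,
#'   `icm_area_um2`, `ploidy`.
#' @export
simulate_feature_table <- function(n, euploid_fraction = 0.571,
                                   class_params = default_class_params(),
                                   seed = 1L) {
  stopifnot(n >= 1, euploid_fraction > 0, euploid_fraction < 1)
  for (cl in class_params) for (p in cl) {
    if (p[["sd"]] <= 0) stop("simulate_feature_table: SDs must be > 0",
                             call. = FALSE)
  }
  rng <- local_rng(seed)
  is_eu <- rng$runif(n) < euploid_fraction
  draw_trunc_norm <- function(k, mean, sd, lower) {
    out <- numeric(k)
    todo <- seq_len(k)
    while (length(todo)) {
      out[todo] <- rng$rnorm(length(todo), mean, sd)
      todo <- todo[out[todo] <= lower]
    }
    out
  }
  draw_lognorm <- function(k, mean, sd) {
    s2 <- log(1 + (sd / mean)^2)
    stats::qlnorm(rng$runif(k), meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  }
  draw_class <- function(k, p) {
    data.frame(
      diameter_um = draw_trunc_norm(k, p$diameter[["mean"]], p$diameter[["sd"]], 120),
      te_count = round(draw_trunc_norm(k, p$te_count[["mean"]], p$te_count[["sd"]], 8)),
      te_size_variance = draw_lognorm(k, p$te_size_variance[["mean"]],
                                      p$te_size_variance[["sd"]]),
      icm_area_um2 = draw_trunc_norm(k, p$icm_area[["mean"]], p$icm_area[["sd"]], 0)
    )
  }
  tab <- data.frame(id = sprintf("synthetic_%04d", seq_len(n)))
  feats <- as.data.frame(matrix(NA_real_, n, 4))
  names(feats) <- c("diameter_um", "te_count", "te_size_variance", "icm_area_um2")
  if (any(is_eu)) feats[is_eu, ] <- draw_class(sum(is_eu), class_params$euploid)
  if (any(!is_eu)) feats[!is_eu, ] <- draw_class(sum(!is_eu), class_params$non_euploid)
  tab <- cbind(tab, feats)
  tab$te_density <- 1000 * tab$te_count / (pi * tab$diameter_um^2)
  tab$ploidy <- ifelse(is_eu, "euploid",
                       ifelse(rng$runif(n) < 0.29, "mosaic", "aneuploid"))
  tab <- tab[, c("id", "diameter_um", "te_count", "te_density",
                 "te_size_variance", "icm_area_um2", "ploidy")]
  tab$ploidy_binary <- as.integer(tab$ploidy == "euploid")
  tab
}

## ---- sequence I/O ------------------------------------------------------

#' Write a rendered sequence to a directory
#'
#' Views are written as numbered 16-bit TIFFs, masks as 16-bit label TIFFs,
#' the mid-plane image as `midplane.tif`, and the truth and true rotations
#' (as quaternions) as a JSON sidecar.
#'
#' @param seq a [render_sequence()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$views)) {
    tiff::writeTIFF(seq$views[[i]], file.path(dir, sprintf("view_%03d.tif", i)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(seq$masks[[i]] / 65535,
                    file.path(dir, sprintf("mask_%03d.tif", i)),
                    bits.per.sample = 16L)
  }
  tiff::writeTIFF(seq$midplane, file.path(dir, "midplane.tif"),
                  bits.per.sample = 16L)
  truth <- seq$truth
  jsonlite::write_json(list(
    pixel_scale = seq$pixel_scale,
    diameter_um = truth$diameter_um,
    n_views = length(seq$views),
    true_rotations_quat = lapply(seq$true_rotations, rot_to_quat),
    true_steps_deg = seq$true_steps_deg,
    icm_axis = truth$icm_axis,
    icm_area_um2 = truth$icm_area_um2,
    te_cell_areas = truth$te_cell_areas,
    te_sites = as.data.frame(truth$te_sites),
    seed = truth$seed
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multi-view image sequence from a directory
#'
#' Reads `view_*.tif` images (plus masks, mid-plane and JSON sidecar if
#' present) as written by [write_sequence()].
#'
#' @param dir directory path.
#' @return A list with `views`, `masks` (NULL when absent), `midplane`,
#'   `pixel_scale`, and `sidecar` (parsed JSON or NULL).
#' @export
read_sequence <- function(dir) {
  vf <- sort(list.files(dir, "^view_\\d+\\.tif$", full.names = TRUE))
  if (!length(vf)) stop("read_sequence: no view_*.tif files in ", dir, call. = FALSE)
  views <- lapply(vf, tiff::readTIFF)
  mf <- sort(list.files(dir, "^mask_\\d+\\.tif$", full.names = TRUE))
  masks <- if (length(mf) == length(vf)) {
    lapply(mf, function(f) {
      m <- tiff::readTIFF(f)
      matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
    })
  } else NULL
  mid <- file.path(dir, "midplane.tif")
  side <- file.path(dir, "truth.json")
  list(
    views = views,
    masks = masks,
    midplane = if (file.exists(mid)) tiff::readTIFF(mid) else NULL,
    sidecar = if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL,
    pixel_scale = if (file.exists(side)) {
      jsonlite::read_json(side, simplifyVector = TRUE)$pixel_scale
    } else 1
  )
}
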