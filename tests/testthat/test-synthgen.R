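test_that("truth models satisfy the surface partition identities", {
  tm <- ref_truth()
  total <- pi * tm$diameter_um^2
  expect_equal(sum(tm$te_cell_areas) + tm$icm_area_um2, total,
               tolerance = 1e-9)
  expect_equal(tm$icm_area_um2,
               2 * pi * (tm$diameter_um / 2)^2 *
                 (1 - cos(tm$icm_polar_half_angle)),
               tolerance = 1e-12)
  expect_true(all(tm$te_cell_areas > 0))
  expect_true(all(abs(sqrt(rowSums(tm$te_sites^2)) - 1) < 1e-9))
})

test_that("a 4-cell tessellation with a vanishing cap is near-regular", {
  tm <- make_truth(4, 100, 1e-6, 0, seed = 1)
  ## relaxation stops when the area CV is within 0.05 of the target (0), so
  ## each cell is within a few percent of the regular quarter-sphere area
  expect_equal(length(tm$te_cell_areas), 4L)
  expect_lt(tm$realized_cv, 0.05)
  expect_equal(tm$te_cell_areas, rep(pi * 100^2 / 4, 4), tolerance = 0.1)
})

test_that("quadrature cell areas agree with a Monte-Carlo assignment oracle", {
  tm <- ref_truth()
  set.seed(991)
  n_mc <- 4e6
  v <- matrix(rnorm(3 * n_mc), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  keep <- as.numeric(v %*% tm$icm_axis) < cos(tm$icm_polar_half_angle)
  idx <- top2_dot(v[keep, , drop = FALSE], tm$te_sites)$i1
  te_total <- pi * tm$diameter_um^2 - tm$icm_area_um2
  mc_areas <- tabulate(idx, length(tm$te_cell_areas)) / sum(keep) * te_total
  rel <- abs(mc_areas - tm$te_cell_areas) / tm$te_cell_areas
  ## MC binomial noise at 4e6 samples: per-cell relative SE ~ 0.55%, so the
  ## largest of 120 deviations stays below ~4 SE
  expect_lt(max(rel), 0.025)
  expect_lt(median(rel), 0.01)
})

test_that("infeasible area-CV targets warn and record the best CV", {
  ## four minimum-separated cells cannot reach an area CV of 1
  expect_warning(tm <- make_truth(4, 100, 100, 1, seed = 2),
                 "not reached")
  expect_true(tm$realized_cv < 0.95)
})

test_that("truth models are deterministic under a fixed seed", {
  a <- make_truth(30, 150, 3000, 0.3, seed = 11)
  b <- make_truth(30, 150, 3000, 0.3, seed = 11)
  expect_identical(a$te_sites, b$te_sites)
  expect_identical(a$te_cell_areas, b$te_cell_areas)
  c <- make_truth(30, 150, 3000, 0.3, seed = 12)
  expect_false(identical(a$te_sites, c$te_sites))
})

test_that("rendered views have correct limb geometry and mask visibility", {
  tm <- ref_truth()
  rv <- render_view(tm, diag(3))
  side <- nrow(rv$image)
  ctr <- (side + 1) / 2
  ## background outside the inscribed disk
  xs <- rep(seq_len(side), each = side)
  ys <- rep(seq_len(side), times = side)
  outside <- (xs - ctr)^2 + (ys - ctr)^2 > (tm$diameter_um / 2 + 1)^2
  expect_true(all(rv$mask[cbind(ys[outside], xs[outside])] == 0L))
  ## visibility oracle: visible cell ids = cells whose site has z > 0, up to
  ## boundary-width erosion (slivers near the limb may be eroded away)
  vis_ids <- sort(unique(rv$mask[rv$mask >= 3L])) - 2L
  site_vis <- which(tm$te_sites[, 3] > 0)
  expect_gt(length(intersect(vis_ids, site_vis)) / length(site_vis), 0.9)
  ## cells whose site is deep on the far side never appear
  far <- which(tm$te_sites[, 3] < -0.2)
  expect_length(intersect(vis_ids, far), 0)
})

test_that("rotating about the camera axis rotates the rendered view in-plane", {
  tm <- ref_truth()
  a <- render_view(tm, diag(3))
  b <- render_view(tm, rot_axis_angle(c(0, 0, 1), pi / 2))
  ## a quarter-turn about z maps (x, y) -> (-y, x): compare mask labels on
  ## the interior (boundary pixels shift by a subpixel under resampling)
  side <- nrow(a$mask)
  rot_b <- t(b$mask)[, rev(seq_len(side))]
  core <- a$mask >= 2L & rot_b >= 2L
  expect_gt(mean(a$mask[core] == rot_b[core]), 0.95)
})

test_that("the default acquisition protocol matches the imaging contract", {
  sq <- ref_sequence()
  expect_gt(length(sq$views), 10)            # more than 10 images per turn
  expect_true(all(sq$true_steps_deg < 35))   # every step below 35 degrees
  expect_equal(sq$true_steps_deg, rep(30, 12), tolerance = 1e-12)
  ## closure: composing all true steps returns to the identity
  comp <- diag(3)
  for (i in seq_along(sq$true_steps_deg)) {
    comp <- comp %*% rot_axis_angle(c(0, 1, 0), sq$true_steps_deg[i] * pi / 180)
  }
  expect_lt(rotation_angle(comp), 1e-9)
})

test_that("render_sequence refuses protocols without overlap", {
  expect_error(render_sequence(ref_truth(), n_views = 3), "overlap")
})

test_that("simulated feature tables match the configured class moments", {
  tab <- simulate_feature_table(10000, seed = 3)
  cp <- default_class_params()
  ## oracle: the truncated-normal mean mu + sigma * phi(a) / (1 - Phi(a))
  ## with a = (lower - mu) / sigma (lower bounds: diameter 120, count 8,
  ## ICM 0; the lognormal size variance is untruncated)
  trunc_mean <- function(mu, sigma, lower) {
    a <- (lower - mu) / sigma
    mu + sigma * dnorm(a) / (1 - pnorm(a))
  }
  lower_of <- c(diameter = 120, te_count = 8, te_size_variance = -Inf,
                icm_area = 0)
  for (cl in c("euploid", "non_euploid")) {
    sub <- tab[(tab$ploidy == "euploid") == (cl == "euploid"), ]
    n <- nrow(sub)
    for (f in c("diameter", "te_count", "te_size_variance", "icm_area")) {
      col <- c(diameter = "diameter_um", te_count = "te_count",
               te_size_variance = "te_size_variance",
               icm_area = "icm_area_um2")[[f]]
      mu <- cp[[cl]][[f]][["mean"]]
      sg <- cp[[cl]][[f]][["sd"]]
      expected <- if (is.finite(lower_of[[f]])) {
        trunc_mean(mu, sg, lower_of[[f]])
      } else mu
      se <- sg / sqrt(n)
      expect_lt(abs(mean(sub[[col]]) - expected), 3.5 * se,
                label = sprintf("|%s %s mean - truncated-normal oracle|", cl, f))
    }
  }
  ## density is derived, not drawn
  expect_equal(tab$te_density,
               1000 * tab$te_count / (pi * tab$diameter_um^2),
               tolerance = 1e-12)
})

test_that("euploid fraction follows the cohort rate within binomial noise", {
  tab <- simulate_feature_table(10000, euploid_fraction = 0.571, seed = 21)
  k <- sum(tab$ploidy == "euploid")
  expect_lt(abs(k - 0.571 * 10000), 3 * sqrt(10000 * 0.571 * 0.429))
})

test_that("feature-table simulation is byte-identical under a fixed seed", {
  a <- simulate_feature_table(50, seed = 4)
  b <- simulate_feature_table(50, seed = 4)
  expect_identical(a, b)
  expect_error(simulate_feature_table(
    10, class_params = within(default_class_params(), {
      euploid$diameter["sd"] <- 0
    })), "SDs must be > 0")
})

test_that("sequence round-trips through the on-disk format", {
  tm <- make_truth(20, 60, 500, 0.3, seed = 5)
  sq <- render_sequence(tm, n_views = 6, seed = 5)
  dir <- file.path(tempdir(), "seq_roundtrip")
  write_sequence(sq, dir)
  rd <- read_sequence(dir)
  expect_length(rd$views, 6)
  expect_lt(max(abs(rd$views[[1]] - sq$views[[1]])), 1e-4)  # 16-bit depth
  expect_identical(rd$masks[[2]], sq$masks[[2]])
  expect_equal(rd$sidecar$icm_area_um2, tm$icm_area_um2, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
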