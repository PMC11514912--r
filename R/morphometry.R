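## Quantification of the five 3D morphological parameters from the stitched,
## segmented spherical surface model and the mid-plane image: blastocyst
## diameter, TE cell number, TE cell density, TE cell size variance, and
## ICM area.

#' Fit the blastocyst diameter from the mid-plane image
#'
#' Rim pixels are extracted by gradient-magnitude thresholding; because the
#' mid-plane image shows both the inner and the outer edge of the dark rim,
#' only the outermost rim pixel per angular sector (the blastocyst/medium
#' transition) is kept, and an algebraic circle fit (Taubin) gives radius and
#' center O; the diameter is `2 * radius * pixel_scale`.
#'
#' @param midplane mid-plane image matrix.
#' @param pixel_scale micrometres per pixel.
#' @param gradient_quantile rim candidates are pixels above this quantile of
#'   the nonzero gradient magnitude.
#' @param n_sectors angular sectors for the outermost-pixel selection.
#' @return list with `diameter_um`, `center_px`, `n_rim`, and the fitted
#'   `sphere` ([blastocyst_sphere()]).
#' @export
fit_diameter <- function(midplane, pixel_scale = 1, gradient_quantile = 0.5,
                         n_sectors = 360L) {
  g <- image_gradients(as.matrix(EBImage::gblur(midplane, 0.7)))
  mag <- sqrt(g$gx^2 + g$gy^2)
  thr <- max(stats::quantile(mag[mag > 1e-6], gradient_quantile, names = FALSE),
             0.15 * max(mag))
  if (!is.finite(thr) || thr <= 0 || sum(mag > thr) < 20) {
    stop(structure(class = c("blastometry_fit_error", "error", "condition"),
                   list(message = "fit_diameter: fewer than 20 rim pixels",
                        call = NULL)))
  }
  idx <- which(mag > thr)
  nr <- nrow(midplane)
  y <- ((idx - 1L) %% nr) + 1L
  x <- ((idx - 1L) %/% nr) + 1L
  ## pass 1: outermost candidate per angular sector (the outer rim edge;
  ## provisional center = mean of candidates, the rim dominates the set)
  cx0 <- mean(x); cy0 <- mean(y)
  ang <- atan2(y - cy0, x - cx0)
  rad <- sqrt((x - cx0)^2 + (y - cy0)^2)
  sector <- floor((ang + pi) / (2 * pi) * n_sectors) + 1L
  keep <- unlist(lapply(split(seq_along(rad), sector), function(i) {
    i[which.max(rad[i])]
  }), use.names = FALSE)
  if (length(keep) < 20) {
    stop(structure(class = c("blastometry_fit_error", "error", "condition"),
                   list(message = "fit_diameter: fewer than 20 rim pixels",
                        call = NULL)))
  }
  fit0 <- taubin_circle_fit(x[keep], y[keep])
  ## pass 2: per sector, the gradient-weighted mean radius of the outermost
  ## candidate cluster (the above-threshold support of the outer edge, which
  ## is symmetric about its gradient peak)
  ang2 <- atan2(y - fit0$cy, x - fit0$cx)
  rad2 <- sqrt((x - fit0$cx)^2 + (y - fit0$cy)^2)
  sec2 <- floor((ang2 + pi) / (2 * pi) * n_sectors) + 1L
  w <- mag[idx]
  pts <- lapply(split(seq_along(sec2), sec2), function(i) {
    cl0 <- i[rad2[i] > max(rad2[i]) - 2.5]
    rpk <- rad2[cl0[which.max(w[cl0])]]
    cl <- i[abs(rad2[i] - rpk) <= 1.5]
    c(r = sum(rad2[cl] * w[cl]) / sum(w[cl]), th = mean(ang2[cl]))
  })
  rs <- vapply(pts, `[[`, numeric(1), "r")
  th <- vapply(pts, `[[`, numeric(1), "th")
  fit <- taubin_circle_fit(fit0$cx + rs * cos(th), fit0$cy + rs * sin(th))
  list(diameter_um = 2 * fit$r * pixel_scale,
       center_px = c(fit$cx, fit$cy),
       n_rim = length(keep),
       sphere = blastocyst_sphere(c(fit$cx, fit$cy), 2 * fit$r * pixel_scale,
                                  pixel_scale))
}

#' Taubin algebraic circle fit
#'
#' Chernov's Newton-based formulation of Taubin's gradient-weighted algebraic
#' fit; unbiased to first order for full and partial arcs.
#'
#' @param x,y point coordinates.
#' @return list with center `cx`, `cy` and radius `r`.
#' @export
taubin_circle_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, n == length(y))
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  z <- u^2 + v^2
  Muu <- mean(u^2); Mvv <- mean(v^2); Muv <- mean(u * v)
  Muz <- mean(u * z); Mvz <- mean(v * z); Mzz <- mean(z^2)
  Mz <- Muu + Mvv
  ## characteristic polynomial coefficients (Chernov, "Circular and linear
  ## regression", Taubin fit)
  Cov_xy <- Muu * Mvv - Muv^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- Mzz * Mz + 4 * Cov_xy * Mz - Muz^2 - Mvz^2 - Mz^3
  A0 <- Muz^2 * Mvv + Mvz^2 * Muu - Mzz * Cov_xy - 2 * Muz * Mvz * Muv +
    Mz^2 * Cov_xy
  xr <- 0
  for (i in 1:50) {
    f <- A0 + xr * (A1 + xr * (A2 + xr * A3))
    fp <- A1 + xr * (2 * A2 + 3 * A3 * xr)
    step <- f / fp
    if (!is.finite(step)) break
    xr <- xr - step
    if (abs(step) < 1e-12 * (abs(xr) + 1)) break
  }
  det <- xr^2 - xr * Mz + Cov_xy
  cx <- (Muz * (Mvv - xr) - Mvz * Muv) / det / 2
  cy <- (Mvz * (Muu - xr) - Muz * Muv) / det / 2
  list(cx = cx + mx, cy = cy + my, r = sqrt(cx^2 + cy^2 + Mz - 2 * xr))
}

#' Absorb boundary and unobserved bins into adjacent regions
#'
#' TE boundary bins (label 1) and unobserved bins (label 0) carry surface
#' area that belongs to the cells they separate; iterative nearest-neighbour
#' dilation on the sphere grid reassigns them to adjacent ICM/cell labels so
#' region areas reflect the full surface partition.
#'
#' @param map a [sphere_label_map()].
#' @param max_iter maximum dilation sweeps.
#' @return The map with labels 0/1 replaced by neighbouring region labels.
#' @export
absorb_boundary_bins <- function(map, max_iter = 100L) {
  lab <- map$labels
  nr <- nrow(lab); nc <- ncol(lab)
  for (it in seq_len(max_iter)) {
    todo <- lab < 2L
    if (!any(todo)) break
    up <- rbind(lab[1, ], lab[-nr, ])
    dn <- rbind(lab[-1, ], lab[nr, ])
    lf <- cbind(lab[, nc], lab[, -nc])
    rt <- cbind(lab[, -1], lab[, 1])
    cand <- pmax(ifelse(up >= 2L, up, -1L), ifelse(dn >= 2L, dn, -1L),
                 ifelse(lf >= 2L, lf, -1L), ifelse(rt >= 2L, rt, -1L))
    fill <- todo & cand >= 2L
    if (!any(fill)) break
    lab[fill] <- cand[fill]
  }
  map$labels <- lab
  map
}

#' Count distinct TE cells
#'
#' @param regions region list from [connected_regions()].
#' @param min_area_um2 minimum region area; smaller regions are treated as
#'   stitching slivers and ignored (default 10).
#' @return integer cell count.
#' @export
count_te_cells <- function(regions, min_area_um2 = 10) {
  if (!length(regions)) return(0L)
  sum(vapply(regions, function(r) {
    r$label >= 3L && r$area_um2 >= min_area_um2
  }, logical(1)))
}

#' TE cell density in cells per 1,000 square micrometres
#'
#' Defined as TE cell number per 1,000 um^2 of blastocyst surface; the
#' denominator is the full sphere surface area `pi * D^2`.
#'
#' @param te_count number of TE cells.
#' @param diameter_um blastocyst diameter.
#' @return density in cells / 1000 um^2.
#' @export
te_density <- function(te_count, diameter_um) {
  stopifnot(diameter_um > 0)
  1000 * te_count / (pi * diameter_um^2)
}

#' TE cell size variance (standard deviation of cell areas)
#'
#' @param areas_um2 per-cell areas; at least 2.
#' @param denominator `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return standard deviation in um^2.
#' @export
te_size_variance <- function(areas_um2, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (length(areas_um2) < 2L) {
    stop(structure(class = c("blastometry_variance_error", "error", "condition"),
                   list(message = "te_size_variance: need at least 2 cells",
                        call = NULL)))
  }
  s <- stats::sd(areas_um2)
  if (denominator == "n") {
    n <- length(areas_um2)
    s <- s * sqrt((n - 1) / n)
  }
  s
}

#' ICM area from the stitched surface map
#'
#' Bin-sum spherical area of the largest ICM-labeled region; smaller ICM
#' fragments are reported in a message.
#'
#' @param map a [sphere_label_map()] with ICM labels (2).
#' @return area in um^2.
#' @export
icm_area <- function(map) {
  regs <- connected_regions(map, labels = 2L)
  if (!length(regs)) {
    stop(structure(class = c("blastometry_missing_icm", "error", "condition"),
                   list(message = "icm_area: no ICM labels in map", call = NULL)))
  }
  areas <- vapply(regs, function(r) r$area_um2, numeric(1))
  if (length(areas) > 1L) {
    message(sprintf("icm_area: %d smaller ICM fragment(s) ignored (%.1f um2)",
                    length(areas) - 1L, sum(areas) - max(areas)))
  }
  max(areas)
}

#' Measure the five 3D morphological parameters of a blastocyst
#'
#' Orchestrates the full measurement pipeline: diameter fit from the
#' mid-plane image, cropping of all views to the sphere, inter-view rotation
#' estimation, projection and stitching onto the spherical surface map,
#' region extraction, and the four surface parameters.
#'
#' @param sequence list with `views` (list of images), `midplane`, optional
#'   `masks` (per-view label masks; when NULL, [segment_classical()] is
#'   applied per view), and `pixel_scale`; [render_sequence()] and
#'   [read_sequence()] both produce this shape.
#' @param map_shape stitched map grid (n_lat, n_lon), default c(256, 512).
#' @param min_cell_area_um2 minimum region area counted as a cell.
#' @param rotations optionally supply known view-to-global rotations and skip
#'   registration.
#' @param segmentation_params passed to [segment_classical()].
#' @param sd_denominator SD flavour for the size variance.
#' @param refine passed to [register_sequence()].
#' @param verbose print per-stage progress.
#' @return A `morphometry_record`: list with the five parameters, plus
#'   `n_views`, `map`, `registration` diagnostics.
#' @export
measure <- function(sequence, map_shape = c(256L, 512L),
                    min_cell_area_um2 = 10, rotations = NULL,
                    segmentation_params = list(),
                    sd_denominator = "n-1", refine = TRUE, verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("measure [%s]: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  fit <- stage("fit_diameter",
               fit_diameter(sequence$midplane, sequence$pixel_scale))
  if (verbose) message(sprintf("[measure] diameter %.2f um", fit$diameter_um))
  ## views sharing the mid-plane frame use the fitted center; pre-cropped
  ## views (different dimensions) are centered on their own frame
  v1 <- sequence$views[[1]]
  ctr <- if (all(dim(v1) == dim(sequence$midplane))) {
    fit$center_px
  } else {
    c((ncol(v1) + 1) / 2, (nrow(v1) + 1) / 2)
  }
  sphere0 <- blastocyst_sphere(ctr, fit$diameter_um, sequence$pixel_scale)
  views <- stage("crop", lapply(sequence$views, crop_to_sphere, sphere = sphere0))
  sphere <- attr(views[[1]], "sphere")
  masks <- if (!is.null(sequence$masks)) {
    stage("crop_masks", lapply(sequence$masks, function(m) {
      mm <- crop_to_sphere(m, sphere0)
      matrix(as.integer(round(mm)), nrow(mm), ncol(mm))
    }))
  } else {
    stage("segment", lapply(views, segment_classical, sphere = sphere,
                            params = segmentation_params))
  }
  if (is.null(rotations)) {
    reg <- stage("register", register_sequence(views, sphere, refine = refine,
                                               verbose = verbose))
    rotations <- reg$global
  } else {
    reg <- NULL
  }
  map <- stage("project",
               project_views(views, masks, rotations, sphere, map_shape))
  if (!is.null(sequence$masks)) {
    ## masks carry cell ids that are consistent across views (ground-truth
    ## or external masks): measure areas by fractional bin membership
    by_label <- soft_region_areas(map)
    lb <- as.integer(names(by_label))
    te_all <- by_label[lb >= 3L]
    areas <- unname(te_all[te_all >= min_cell_area_um2])
    n_te <- length(areas)
    icm_val <- if ("2" %in% names(by_label)) {
      by_label[["2"]]
    } else {
      stop(structure(
        class = c("blastometry_missing_icm", "error", "condition"),
        list(message = "measure: no ICM labels in the stitched map",
             call = NULL)))
    }
  } else {
    ## classical per-view segmentation: watershed ids are not comparable
    ## across views, so cells are the boundary-separated components of the
    ## collapsed cell class
    collapsed <- map
    collapsed$labels[map$labels >= 3L] <- 3L
    regions <- connected_regions(collapsed, labels = 3L)
    areas <- vapply(regions, function(r) r$area_um2, numeric(1))
    areas <- areas[areas >= min_cell_area_um2]
    n_te <- length(areas)
    icm_val <- stage("icm", icm_area(absorb_boundary_bins(map)))
  }
  rec <- structure(list(
    diameter_um = fit$diameter_um,
    te_count = n_te,
    te_density = te_density(n_te, fit$diameter_um),
    te_size_variance_um2 = if (n_te >= 2) {
      te_size_variance(areas, sd_denominator)
    } else NA_real_,
    icm_area_um2 = icm_val,
    n_views = length(views),
    te_cell_areas_um2 = areas,
    map = map,
    registration = reg
  ), class = "morphometry_record")
  rec
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(paste0(
    "<morphometry_record>\n",
    "  diameter        %8.1f um\n",
    "  TE cell count   %8d\n",
    "  TE density      %8.3f cells/1000 um2\n",
    "  TE size SD      %8.1f um2\n",
    "  ICM area        %8.1f um2\n"),
    x$diameter_um, x$te_count, x$te_density,
    x$te_size_variance_um2, x$icm_area_um2))
  invisible(x)
}

#' Morphometry record as a one-row feature-table data.frame
#' @param record a `morphometry_record`.
#' @param id identifier for the blastocyst.
#' @export
record_to_row <- function(record, id = "blastocyst") {
  data.frame(id = id,
             diameter_um = record$diameter_um,
             te_count = record$te_count,
             te_density = record$te_density,
             te_size_variance = record$te_size_variance_um2,
             icm_area_um2 = record$icm_area_um2)
}
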