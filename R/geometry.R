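#' Construct a blastocyst sphere
#'
#' The sphere Omega on which all 3D morphology is measured, defined by the
#' center `O` (pixel coordinates in the reference image) and diameter `D`
#' (micrometres), together with the pixel scale that links the two.
#'
#' Coordinate conventions used throughout the package: image origin top-left,
#' x to the right (columns), y downward (rows); sphere frame x right, y down,
#' z toward the camera. Latitude is measured from the equator toward the +y
#' pole, longitude from +x toward +z; all angles in radians.
#'
#' @param center_px numeric length-2, center O in pixels (x, y).
#' @param diameter_um blastocyst diameter D in micrometres.
#' @param pixel_scale micrometres per pixel.
#' @return An object of class `blastocyst_sphere`.
#' @export
blastocyst_sphere <- function(center_px, diameter_um, pixel_scale = 1) {
  stopifnot(length(center_px) == 2, diameter_um > 0, pixel_scale > 0)
  structure(list(
    center_px = as.numeric(center_px),
    diameter_um = as.numeric(diameter_um),
    radius_um = as.numeric(diameter_um) / 2,
    pixel_scale = as.numeric(pixel_scale)
  ), class = "blastocyst_sphere")
}

#' @export
print.blastocyst_sphere <- function(x, ...) {
  cat(sprintf("<blastocyst_sphere> O = (%.2f, %.2f) px, D = %.2f um, %.3f um/px\n",
              x$center_px[1], x$center_px[2], x$diameter_um, x$pixel_scale))
  invisible(x)
}

#' Back-project pixels onto the sphere
#'
#' Maps pixel coordinates to 3D points on the camera-facing hemisphere of the
#' sphere: with (u, v) = (pixel - O) * pixel_scale in micrometres, the point is
#' (u, v, +sqrt(R^2 - u^2 - v^2)).
#'
#' @param pixel numeric length-2 or an n x 2 matrix of (x, y) pixel coords.
#' @param sphere a [blastocyst_sphere()].
#' @return An n x 3 matrix of points in micrometres (view frame).
#' @export
backproject <- function(pixel, sphere) {
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  R <- sphere$radius_um
  u <- (p[, 1] - sphere$center_px[1]) * sphere$pixel_scale
  v <- (p[, 2] - sphere$center_px[2]) * sphere$pixel_scale
  h2 <- R^2 - u^2 - v^2
  if (any(h2 < -1e-9 * R^2)) {
    stop("backproject: pixel outside the sphere disk", call. = FALSE)
  }
  cbind(u, v, sqrt(pmax(h2, 0)), deparse.level = 0)
}

## ---- rotation algebra -------------------------------------------------

#' Rotation matrix from axis and angle
#'
#' @param axis length-3 vector (normalized internally).
#' @param angle_rad rotation angle in radians (right-handed about `axis`).
#' @return 3 x 3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Angle of a rotation matrix (radians)
#'
#' Computed as `atan2(|skew part|, (trace - 1) / 2)`, which stays accurate
#' near zero where the arccosine of the trace loses half the significant
#' digits.
#'
#' @param R a 3 x 3 rotation matrix.
#' @export
rotation_angle <- function(R) {
  s <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
              (R[2, 1] - R[1, 2])^2) / 2
  atan2(s, (sum(diag(R)) - 1) / 2)
}

#' Geodesic distance between two rotations (radians)
#' @param R1,R2 3 x 3 rotation matrices.
#' @export
rotation_distance <- function(R1, R2) rotation_angle(crossprod(R1, R2))

#' Check that a matrix is a proper rotation
#' @param R matrix; @param tol tolerance on orthogonality and determinant.
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Convert a rotation matrix to a unit quaternion (w, x, y, z)
#' @param R 3 x 3 rotation matrix.
#' @export
rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Convert a unit quaternion (w, x, y, z) to a rotation matrix
#' @param q length-4 numeric quaternion.
#' @export
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

## ---- lat/lon parameterization -----------------------------------------

#' Convert unit direction vectors to latitude/longitude
#'
#' Latitude phi = asin(y / |p|) in [-pi/2, pi/2] (poles along the y axis, the
#' default rotation axis), longitude lambda = atan2(z, x) in [-pi, pi).
#'
#' @param xyz n x 3 matrix of points (any radius).
#' @return n x 2 matrix with columns `lat`, `lon`.
#' @export
xyz_to_latlon <- function(xyz) {
  xyz <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  r <- sqrt(rowSums(xyz^2))
  lat <- asin(pmin(1, pmax(-1, xyz[, 2] / r)))
  lon <- atan2(xyz[, 3], xyz[, 1])
  lon[lon >= pi] <- -pi
  cbind(lat = lat, lon = lon)
}

#' Convert latitude/longitude to unit vectors
#' @param lat,lon vectors of angles in radians.
#' @return n x 3 matrix of unit vectors.
#' @export
latlon_to_xyz <- function(lat, lon) {
  cbind(cos(lat) * cos(lon), sin(lat), cos(lat) * sin(lon), deparse.level = 0)
}

## ---- sphere label map --------------------------------------------------

#' Create an empty spherical label map
#'
#' Equirectangular latitude-longitude grid holding the stitched 3D surface
#' model. Label alphabet: 0 = unobserved, 1 = TE boundary, 2 = ICM,
#' 3 and above = trophectoderm cell ids. Rows index latitude from -pi/2 (row 1) to
#' +pi/2 (row n_lat); columns index longitude from -pi to +pi.
#'
#' @param n_lat,n_lon grid dimensions (default 256 x 512).
#' @param radius_um sphere radius R in micrometres.
#' @return An object of class `sphere_label_map` with integer `labels`,
#'   numeric `weights` and `intensity` matrices.
#' @export
sphere_label_map <- function(n_lat = 256, n_lon = 512, radius_um) {
  stopifnot(n_lat >= 2, n_lon >= 4, radius_um > 0)
  structure(list(
    labels = matrix(0L, n_lat, n_lon),
    weights = matrix(0, n_lat, n_lon),
    intensity = matrix(NA_real_, n_lat, n_lon),
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    radius_um = radius_um
  ), class = "sphere_label_map")
}

#' @export
print.sphere_label_map <- function(x, ...) {
  obs <- mean(x$labels != 0L)
  cat(sprintf("<sphere_label_map> %d x %d, R = %.1f um, %.1f%% observed\n",
              x$n_lat, x$n_lon, x$radius_um, 100 * obs))
  invisible(x)
}

#' Exact area of a latitude-longitude bin
#'
#' For a bin spanning latitudes [phi_bottom, phi_top] and a longitude width
#' Delta-lambda, the spherical area is R^2 * Delta-lambda *
#' (sin phi_top - sin phi_bottom); exact for equirectangular bins.
#'
#' @param map a [sphere_label_map()].
#' @param lat_index,lon_index bin indices (vectorized; 1-based).
#' @return Bin areas in square micrometres.
#' @export
bin_area <- function(map, lat_index, lon_index) {
  stopifnot(all(lat_index >= 1), all(lat_index <= map$n_lat),
            all(lon_index >= 1), all(lon_index <= map$n_lon))
  dphi <- pi / map$n_lat
  dlam <- 2 * pi / map$n_lon
  bot <- -pi / 2 + (lat_index - 1) * dphi
  map$radius_um^2 * dlam * (sin(bot + dphi) - sin(bot))
}

#' Per-row bin areas (all longitudes share a latitude band)
#' @keywords internal
row_bin_areas <- function(map) {
  bin_area(map, seq_len(map$n_lat), rep(1L, map$n_lat))
}

#' Bin index of lat/lon coordinates
#' @keywords internal
latlon_bin <- function(map, lat, lon) {
  i <- pmin(map$n_lat, pmax(1L, as.integer(floor((lat + pi / 2) / (pi / map$n_lat))) + 1L))
  j <- pmin(map$n_lon, pmax(1L, as.integer(floor((lon + pi) / (2 * pi / map$n_lon))) + 1L))
  cbind(i, j)
}

#' Unit vectors at bin centers
#' @keywords internal
bin_center_xyz <- function(n_lat, n_lon) {
  lat <- -pi / 2 + (seq_len(n_lat) - 0.5) * pi / n_lat
  lon <- -pi + (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
  latlon_to_xyz(rep(lat, times = n_lon), rep(lon, each = n_lat))
}

#' Project multi-view images and masks onto the sphere
#'
#' Every in-disk pixel of every view is back-projected to the camera-facing
#' hemisphere, rotated into the global (reference-view) frame and deposited in
#' its latitude/longitude bin with weight w = z_view / R (the cosine of the
#' viewing angle). Each bin keeps the label of its highest-weight
#' contribution; ties break toward the lower view index, so re-projecting the
#' same view never changes labels. Bins with no contribution stay 0
#' (unobserved).
#'
#' @param views list of view images (matrices, values in `[0, 1]`), all cropped
#'   to the sphere (see [crop_to_sphere()]).
#' @param masks list of integer label masks aligned to `views` (same alphabet
#'   as [sphere_label_map()]); may be NULL to stitch intensity only.
#' @param rotations list of 3 x 3 rotations mapping each view frame to the
#'   global frame (view-to-global).
#' @param sphere a [blastocyst_sphere()] describing the cropped views.
#' @param map_shape integer length-2 (n_lat, n_lon).
#' @return A [sphere_label_map()] with stitched labels, weights and intensity.
#' @export
project_views <- function(views, masks, rotations, sphere,
                          map_shape = c(256L, 512L)) {
  if (!is.null(masks) && length(masks) != length(views)) {
    stop("project_views: length(masks) != length(views)", call. = FALSE)
  }
  if (length(rotations) != length(views)) {
    stop("project_views: length(rotations) != length(views)", call. = FALSE)
  }
  map <- sphere_label_map(map_shape[1], map_shape[2], sphere$radius_um)
  R <- sphere$radius_um
  n_bins <- map$n_lat * map$n_lon
  best_w <- matrix(0, map$n_lat, map$n_lon)
  cb_list <- vector("list", length(views))   # per-view (bin, label, weight)
  for (k in seq_along(views)) {
    img <- views[[k]]
    nc <- ncol(img); nr <- nrow(img)
    ## image stored as matrix[row=y, col=x]
    xs <- rep(seq_len(nc), each = nr)
    ys <- rep(seq_len(nr), times = nc)
    u <- (xs - sphere$center_px[1]) * sphere$pixel_scale
    v <- (ys - sphere$center_px[2]) * sphere$pixel_scale
    h2 <- R^2 - u^2 - v^2
    keep <- h2 > 0
    if (!any(keep)) next
    p <- cbind(u[keep], v[keep], sqrt(h2[keep]))
    w <- p[, 3] / R
    g <- p %*% t(rotations[[k]])
    ll <- xyz_to_latlon(g)
    ij <- latlon_bin(map, ll[, 1], ll[, 2])
    lin <- ij[, 1] + (ij[, 2] - 1L) * map$n_lat
    lab <- if (is.null(masks)) rep(3L, sum(keep)) else as.integer(masks[[k]])[keep]
    int <- as.numeric(img)[keep]
    ## fractional bin membership: accumulate weight mass per (bin, label)
    ## for region labels (>= 2); used for soft area measurement. Boundary
    ## band pixels are split between the two nearest region labels in
    ## inverse proportion to their surface distances (band_attribution).
    ## Grazing pixels cover a radially elongated surface footprint (length
    ## ~ R/z per pixel), so their weight is splatted along that footprint
    ## rather than deposited at the centre point, keeping high-latitude
    ## bins covered.
    reg <- lab >= 2L
    pu <- p[reg, 1]; pv <- p[reg, 2]; pz <- p[reg, 3]
    wr <- w[reg]; lr <- lab[reg]
    lin_r <- lin[reg]
    if (!is.null(masks) && any(lab == 1L)) {
      att <- band_attribution(masks[[k]], sphere)
      if (length(att$idx)) {
        pos <- match(att$idx, which(keep))
        ok_p <- !is.na(pos)
        pos <- pos[ok_p]
        f1 <- att$frac1[ok_p]; f2 <- att$frac2[ok_p]
        lb1 <- att$lab1[ok_p]; lb2 <- att$lab2[ok_p]
        pu <- c(pu, p[pos, 1]); pv <- c(pv, p[pos, 2]); pz <- c(pz, p[pos, 3])
        wr <- c(wr, w[pos] * f1); lr <- c(lr, lb1)
        lin_r <- c(lin_r, lin[pos])
        sec <- lb2 >= 2L
        if (any(sec)) {
          pu <- c(pu, p[pos[sec], 1]); pv <- c(pv, p[pos[sec], 2])
          pz <- c(pz, p[pos[sec], 3])
          wr <- c(wr, w[pos[sec]] * f2[sec]); lr <- c(lr, lb2[sec])
          lin_r <- c(lin_r, lin[pos[sec]])
        }
      }
    }
    if (length(lr)) {
      zr <- pz / R
      m_sub <- pmin(8L, pmax(1L, ceiling(0.35 / pmax(zr, 0.04))))
      ord_groups <- split(seq_along(m_sub), m_sub)
      all_lin <- integer(0); all_lab <- integer(0); all_w <- numeric(0)
      for (g in names(ord_groups)) {
        gi <- ord_groups[[g]]
        m <- as.integer(g)
        if (m == 1L) {
          all_lin <- c(all_lin, lin_r[gi])
          all_lab <- c(all_lab, lr[gi])
          all_w <- c(all_w, wr[gi])
        } else {
          r2d <- sqrt(pu[gi]^2 + pv[gi]^2)
          dux <- ifelse(r2d > 0, pu[gi] / r2d, 1)
          duy <- ifelse(r2d > 0, pv[gi] / r2d, 0)
          for (j in seq_len(m)) {
            t_off <- ((j - (m + 1) / 2) / m) * sphere$pixel_scale
            uu <- pu[gi] + t_off * dux
            vv <- pv[gi] + t_off * duy
            hh <- R^2 - uu^2 - vv^2
            okk <- hh > 0
            if (!any(okk)) next
            q <- cbind(uu[okk], vv[okk], sqrt(hh[okk])) %*% t(rotations[[k]])
            ll2 <- xyz_to_latlon(q)
            gl <- latlon_bin(map, ll2[, 1], ll2[, 2])
            all_lin <- c(all_lin, gl[, 1] + (gl[, 2] - 1L) * map$n_lat)
            all_lab <- c(all_lab, lr[gi][okk])
            all_w <- c(all_w, wr[gi][okk] / m)
          }
        }
      }
      key <- as.numeric(all_lin) + as.numeric(all_lab) * n_bins
      agg <- rowsum(all_w, key)
      kk <- as.numeric(rownames(agg))
      bin_of <- as.integer(kk %% n_bins)
      lab_of <- as.integer(kk %/% n_bins)
      fixup <- bin_of == 0L
      bin_of[fixup] <- n_bins
      lab_of[fixup] <- lab_of[fixup] - 1L
      cb_list[[k]] <- data.frame(bin = bin_of, label = lab_of,
                                 weight = as.numeric(agg), view = k)
    }
    ## within this view, keep the highest-weight contribution per bin
    o <- order(lin, -w)
    first <- !duplicated(lin[o])
    lin1 <- lin[o][first]; w1 <- w[o][first]
    lab1 <- lab[o][first]; int1 <- int[o][first]
    ## across views, strict improvement required (first-come tie break)
    upd <- w1 > best_w[lin1]
    if (any(upd)) {
      idx <- lin1[upd]
      best_w[idx] <- w1[upd]
      map$labels[idx] <- lab1[upd]
      map$weights[idx] <- w1[upd]
      map$intensity[idx] <- int1[upd]
    }
  }
  cb_all <- do.call(rbind, cb_list[!vapply(cb_list, is.null, logical(1))])
  if (!is.null(cb_all) && nrow(cb_all)) {
    ## per bin keep only the best-quality view: every surface point away
    ## from the rotation poles is seen near face-on in some view, and that
    ## view's label composition is free of the foreshortening erosion that
    ## biases oblique observations
    qual_key <- paste(cb_all$bin, cb_all$view)
    qual <- rowsum(cb_all$weight, qual_key)
    best_by_bin <- tapply(
      as.numeric(qual),
      as.integer(sub(" .*", "", rownames(qual))),
      max)
    qual_of <- as.numeric(qual[match(qual_key, rownames(qual))])
    is_best <- qual_of >= best_by_bin[as.character(cb_all$bin)] - 1e-12
    cb <- cb_all[is_best, , drop = FALSE]
    map$contributions <- cb[, c("bin", "label", "weight")]
  }
  map
}

## Fractional attribution of boundary-band pixels (label 1) to the two
## geodesically nearest distinct region labels within a local window,
## inversely proportional to their surface distances. The surface metric
## matters (foreshortening compresses the limb side of the band in the
## image), and the soft split avoids the curvature bias of hard
## nearest-neighbour assignment, which systematically erodes the concave
## (small-cell) side of a curved border.
## Returns a list with `idx` (band pixel indices into `mk`), `lab1`,
## `frac1`, `lab2`, `frac2` (lab2 = 0 where only one side was found).
band_attribution <- function(mk, sphere, window = 4L) {
  nr <- nrow(mk); nc <- ncol(mk)
  band <- which(mk == 1L)
  if (!length(band)) {
    return(list(idx = integer(0), lab1 = integer(0), frac1 = numeric(0),
                lab2 = integer(0), frac2 = numeric(0)))
  }
  R <- sphere$radius_um
  by <- ((band - 1L) %% nr) + 1L
  bx <- ((band - 1L) %/% nr) + 1L
  p3 <- function(x, y) {
    u <- (x - sphere$center_px[1]) * sphere$pixel_scale
    v <- (y - sphere$center_px[2]) * sphere$pixel_scale
    h2 <- pmax(R^2 - u^2 - v^2, 0)
    cbind(u, v, sqrt(h2))
  }
  pb <- p3(bx, by)
  offs <- expand.grid(dx = -window:window, dy = -window:window)
  offs <- offs[offs$dx != 0L | offs$dy != 0L, ]
  d1 <- rep(Inf, length(band)); l1 <- integer(length(band))
  d2 <- rep(Inf, length(band)); l2 <- integer(length(band))
  for (o in seq_len(nrow(offs))) {
    xo <- bx + offs$dx[o]; yo <- by + offs$dy[o]
    ok <- xo >= 1L & xo <= nc & yo >= 1L & yo <= nr
    if (!any(ok)) next
    lo <- rep(0L, length(band))
    lo[ok] <- mk[cbind(yo[ok], xo[ok])]
    cand <- which(ok & lo >= 2L)
    if (!length(cand)) next
    pn <- p3(xo[cand], yo[cand])
    d <- rowSums((pb[cand, , drop = FALSE] - pn)^2)
    ## update the best and second-best distinct labels
    better1 <- d < d1[cand]
    same1 <- lo[cand] == l1[cand]
    ## case: improves best with the same label
    i <- cand[better1 & same1]
    d1[i] <- d[better1 & same1]
    ## case: improves best with a new label (old best demoted)
    j <- cand[better1 & !same1]
    dj <- d[better1 & !same1]
    keep2 <- d1[j] < d2[j]
    d2[j][keep2] <- d1[j][keep2]; l2[j][keep2] <- l1[j][keep2]
    d1[j] <- dj; l1[j] <- lo[j]
    ## case: not best, but improves second-best with a distinct label
    rest <- cand[!better1]
    dr <- d[!better1]
    upd2 <- dr < d2[rest] & lo[rest] != l1[rest]
    d2[rest[upd2]] <- dr[upd2]
    l2[rest[upd2]] <- lo[rest[upd2]]
  }
  found1 <- l1 >= 2L
  two <- found1 & l2 >= 2L
  s1 <- sqrt(d1); s2 <- sqrt(d2)
  frac1 <- ifelse(two, s2 / (s1 + s2), 1)
  list(idx = band[found1], lab1 = l1[found1], frac1 = frac1[found1],
       lab2 = ifelse(two, l2, 0L)[found1],
       frac2 = (1 - frac1)[found1])
}

#' Soft per-label region areas from fractional bin membership
#'
#' Splits each bin's exact area among the region labels (ICM and cells)
#' using the weight mass each label deposited there during
#' [project_views()]. The boundary band is centred on the cell-cell border,
#' so its weight fraction of each bin is split *equally* among the region
#' labels present in that bin (allocating it proportionally to presence
#' would systematically transfer border area from small cells to large
#' ones); bins carrying only band or no weight at all are assigned whole to
#' the dominant label of the geodesically nearest weighted bin. The label
#' areas partition the sphere exactly, and the per-cell quantization noise
#' of hard argmax assignment is averaged away over the many pixel
#' contributions per bin.
#'
#' @param map a [sphere_label_map()] produced by [project_views()].
#' @param collapse_cells treat all cell labels (3 and above) as one class
#'   (for masks whose cell ids are not consistent across views).
#' @return named numeric vector of areas in square micrometres (names are
#'   label values).
#' @export
soft_region_areas <- function(map, collapse_cells = FALSE) {
  if (is.null(map$contributions)) {
    stop("soft_region_areas: map lacks contribution weights", call. = FALSE)
  }
  cb <- map$contributions
  cb <- cb[cb$label >= 2L, , drop = FALSE]
  if (collapse_cells) cb$label[cb$label >= 3L] <- 3L
  areas_row <- row_bin_areas(map)
  bin_rows <- ((cb$bin - 1L) %% map$n_lat) + 1L
  bin_area_of <- areas_row[bin_rows]
  wtot <- rowsum(cb$weight, cb$bin)
  share <- cb$weight / as.numeric(wtot[match(as.character(cb$bin),
                                             rownames(wtot))])
  soft <- rowsum(share * bin_area_of, cb$label)
  out <- as.numeric(soft)
  names(out) <- rownames(soft)
  ## bins with no region weight (unattributed band, unobserved polar caps):
  ## assign each to the dominant region label of its geodesically nearest
  ## region-weighted bin -- iterative grid dilation would sweep whole polar
  ## rows in a few steps because longitude bins shrink toward the poles
  cbr <- cb
  covered <- sort(unique(cbr$bin))
  all_bins <- seq_len(map$n_lat * map$n_lon)
  left <- setdiff(all_bins, covered)
  if (length(left)) {
    dom <- vapply(split(seq_len(nrow(cbr)), cbr$bin), function(i) {
      cbr$label[i][which.max(cbr$weight[i])]
    }, integer(1))
    bin_xyz <- function(bins) {
      rows <- ((bins - 1L) %% map$n_lat) + 1L
      cols <- ((bins - 1L) %/% map$n_lat) + 1L
      latlon_to_xyz(-pi / 2 + (rows - 0.5) * pi / map$n_lat,
                    -pi + (cols - 0.5) * 2 * pi / map$n_lon)
    }
    nn <- top2_dot(bin_xyz(left), bin_xyz(covered))$i1
    lab_left <- dom[as.character(covered[nn])]
    if (collapse_cells) lab_left[lab_left >= 3L] <- 3L
    rows_left <- ((left - 1L) %% map$n_lat) + 1L
    extra <- rowsum(areas_row[rows_left], lab_left)
    for (i in seq_len(nrow(extra))) {
      lb <- rownames(extra)[i]
      if (lb %in% names(out)) {
        out[lb] <- out[lb] + extra[i, 1]
      } else {
        out[lb] <- extra[i, 1]
      }
    }
  }
  out
}

## ---- connected regions -------------------------------------------------

#' Connected regions of a spherical label map
#'
#' Connected components on the sphere topology: 4-neighbour connectivity on
#' the grid, longitude column 1 adjacent to column n_lon, and all bins of the
#' top (bottom) row mutually adjacent through the pole. Components are
#' computed per label value, so regions touching across a different
#' (e.g. boundary) label are never merged.
#'
#' @param map a [sphere_label_map()].
#' @param labels integer labels to extract regions for; defaults to all
#'   labels of 2 and above present in the map (ICM and cells).
#' @return A list of regions; each has `label`, `area_um2`, `n_bins` and the
#'   linear `bins` indices into the label grid.
#' @export
connected_regions <- function(map, labels = NULL) {
  present <- sort(unique(as.integer(map$labels)))
  if (is.null(labels)) labels <- present[present >= 2L]
  areas_row <- row_bin_areas(map)
  out <- list()
  for (lb in labels) {
    m <- map$labels == lb
    if (!any(m)) next
    comp <- label_components_sphere(m)
    for (cid in seq_len(attr(comp, "n"))) {
      bins <- which(comp == cid)
      rows <- ((bins - 1L) %% map$n_lat) + 1L
      out[[length(out) + 1L]] <- list(
        label = lb,
        area_um2 = sum(areas_row[rows]),
        n_bins = length(bins),
        bins = bins
      )
    }
  }
  out
}

#' Connected components of a logical grid with sphere topology
#'
#' @param m logical matrix (n_lat x n_lon).
#' @return integer matrix of component ids (0 where `m` is FALSE), with
#'   attribute `n` = number of components.
#' @keywords internal
label_components_sphere <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  idx <- which(m)
  if (length(idx) == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  ## union-find over TRUE bins
  parent <- seq_along(idx)
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  ## vertical neighbours (same column, row+1)
  v <- which(rows < nr & m[pmin(idx + 1L, nr * nc)])
  for (k in v) union(pos[idx[k]], pos[idx[k] + 1L])
  ## horizontal neighbours (same row, col+1), plus wraparound
  right <- ifelse(cols < nc, idx + nr, idx - (nc - 1L) * nr)
  h <- which(m[right])
  for (k in h) union(pos[idx[k]], pos[right[k]])
  ## pole adjacency: all TRUE bins in the top row are mutually adjacent;
  ## same for the bottom row
  top <- which(rows == 1L)
  if (length(top) > 1L) for (k in top[-1L]) union(pos[idx[top[1L]]], pos[idx[k]])
  bot <- which(rows == nr)
  if (length(bot) > 1L) for (k in bot[-1L]) union(pos[idx[bot[1L]]], pos[idx[k]])
  roots <- vapply(seq_along(idx), find, integer(1))
  ids <- match(roots, unique(roots))
  lab[idx] <- ids
  attr(lab, "n") <- length(unique(roots))
  lab
}

## ---- serialization -----------------------------------------------------

#' Write a spherical label map to disk
#'
#' Serialized as a two-layer 32-bit float TIFF (labels, weights) plus a JSON
#' header with the radius, grid shape and coordinate conventions.
#'
#' @param map a [sphere_label_map()].
#' @param path_prefix output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_label_map <- function(map, path_prefix) {
  tiff::writeTIFF(list(map$labels / 65535, map$weights),
                  paste0(path_prefix, ".tif"), bits.per.sample = 32L)
  jsonlite::write_json(list(
    radius_um = map$radius_um, n_lat = map$n_lat, n_lon = map$n_lon,
    conventions = "lat from equator toward +y pole; lon = atan2(z, x); radians"
  ), paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' Read a spherical label map written by [write_label_map()]
#' @param path_prefix path without extension.
#' @return A [sphere_label_map()].
#' @export
read_label_map <- function(path_prefix) {
  hdr <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  layers <- tiff::readTIFF(paste0(path_prefix, ".tif"), all = TRUE)
  map <- sphere_label_map(hdr$n_lat, hdr$n_lon, hdr$radius_um)
  map$labels <- matrix(as.integer(round(layers[[1]] * 65535)), hdr$n_lat, hdr$n_lon)
  map$weights <- matrix(as.numeric(layers[[2]]), hdr$n_lat, hdr$n_lon)
  map
}
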