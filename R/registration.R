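## Inter-view rotation estimation on the sphere: local features matched
## between adjacent views are back-projected to 3D and aligned by a robust
## (RANSAC + orthogonal Procrustes) rotation fit. This realizes the
## transformation-matrix stage of the measurement pipeline with a fully
## testable construction: planar scale/rotation-invariant features,
## back-projection through the sphere, and a two-point RANSAC hypothesis
## solver refined by the SVD (Kabsch) solution.

#' Crop a view image to the sphere disk
#'
#' Output is a square of side `ceil(D / pixel_scale)` pixels (rounded up to
#' odd) centered on O; pixels outside the disk are set to the background
#' sentinel 0. Re-cropping a cropped image is the identity.
#'
#' @param image image matrix (rows = y, cols = x).
#' @param sphere [blastocyst_sphere()] locating O and D in `image`.
#' @param max_pad_px the disk may exceed the image bounds by up to this many
#'   pixels (padded with background; the overhang is beyond the limb when the
#'   diameter is estimated); a larger clipping extent is an error.
#' @return Cropped image matrix with attribute `sphere`, the sphere re-centered
#'   on the crop.
#' @export
crop_to_sphere <- function(image, sphere, max_pad_px = 3L) {
  side <- ceiling(sphere$diameter_um / sphere$pixel_scale)
  if (side %% 2 == 0) side <- side + 1L
  half <- (side - 1L) / 2
  cx <- round(sphere$center_px[1]); cy <- round(sphere$center_px[2])
  x0 <- cx - half; x1 <- cx + half
  y0 <- cy - half; y1 <- cy + half
  pad <- max(0L, 1L - x0, 1L - y0, x1 - ncol(image), y1 - nrow(image))
  if (pad > max_pad_px) {
    stop(sprintf(
      "crop_to_sphere: disk exceeds image bounds by %d px (needs cols %d..%d, rows %d..%d of %d x %d)",
      pad, x0, x1, y0, y1, nrow(image), ncol(image)), call. = FALSE)
  }
  if (pad > 0L) {
    big <- matrix(0, nrow(image) + 2L * pad, ncol(image) + 2L * pad)
    big[pad + seq_len(nrow(image)), pad + seq_len(ncol(image))] <- image
    image <- big
    x0 <- x0 + pad; x1 <- x1 + pad; y0 <- y0 + pad; y1 <- y1 + pad
  }
  out <- image[y0:y1, x0:x1]
  ctr <- half + 1
  xs <- rep(seq_len(side), each = side)
  ys <- rep(seq_len(side), times = side)
  r2 <- ((xs - ctr)^2 + (ys - ctr)^2) * sphere$pixel_scale^2
  out[ys + (xs - 1L) * side] <- ifelse(r2 > sphere$radius_um^2,
                                       0, out[ys + (xs - 1L) * side])
  attr(out, "sphere") <- blastocyst_sphere(c(ctr, ctr), sphere$diameter_um,
                                           sphere$pixel_scale)
  out
}

## central-difference gradients; x along columns, y along rows
image_gradients <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  gx <- (M[, c(2:nc, nc)] - M[, c(1, 1:(nc - 1))]) / 2
  gy <- (M[c(2:nr, nr), ] - M[c(1, 1:(nr - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

## vectorized bilinear sampling; x = column coord, y = row coord
bilinear_sample <- function(M, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  x <- pmin(pmax(x, 1), nc - 1e-9)
  y <- pmin(pmax(y, 1), nr - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(x0, nc - 1); y0 <- pmin(y0, nr - 1)
  i00 <- y0 + (x0 - 1) * nr
  M[i00] * (1 - fx) * (1 - fy) + M[i00 + nr] * fx * (1 - fy) +
    M[i00 + 1] * (1 - fx) * fy + M[i00 + nr + 1] * fx * fy
}

#' Detect scale-space keypoints in a cropped view
#'
#' Difference-of-Gaussian extrema over a small scale pyramid, restricted to
#' the sphere disk with a margin excluding the unreliable limb zone.
#'
#' @param image cropped view (from [crop_to_sphere()]).
#' @param sphere the crop's [blastocyst_sphere()].
#' @param sigmas Gaussian scales of the pyramid.
#' @param contrast_threshold minimum |DoG| response.
#' @param limb_margin_deg keypoints closer than this to the limb (in polar
#'   angle) are discarded at detection time.
#' @return data.frame with columns `x`, `y`, `sigma`, `response`.
#' @export
detect_keypoints <- function(image, sphere,
                             sigmas = 1.6 * 2^(seq(-0.5, 2.5, by = 0.5)),
                             contrast_threshold = 0.004,
                             limb_margin_deg = 5) {
  blurred <- lapply(sigmas, function(s) {
    as.matrix(EBImage::gblur(image, sigma = s))
  })
  dogs <- lapply(seq_len(length(sigmas) - 1L), function(i) {
    blurred[[i + 1L]] - blurred[[i]]
  })
  nr <- nrow(image); nc <- ncol(image)
  brush <- EBImage::makeBrush(3, "box")
  dil <- lapply(dogs, function(d) {
    mx <- as.matrix(EBImage::dilate(d - min(d), brush)) + min(d)
    mn <- -(as.matrix(EBImage::dilate(-(d - max(d)), brush)) - max(d))
    list(mx = mx, mn = mn)
  })
  out <- list()
  for (i in seq_along(dogs)[-c(1L, length(dogs))]) {
    d <- dogs[[i]]
    up <- dil[[i + 1L]]; dn <- dil[[i - 1L]]; sm <- dil[[i]]
    is_max <- d >= sm$mx & d >= up$mx & d >= dn$mx & d > contrast_threshold
    is_min <- d <= sm$mn & d <= up$mn & d <= dn$mn & d < -contrast_threshold
    idx <- which(is_max | is_min)
    if (!length(idx)) next
    y <- ((idx - 1L) %% nr) + 1L
    x <- ((idx - 1L) %/% nr) + 1L
    out[[length(out) + 1L]] <- data.frame(
      x = x, y = y, sigma = sqrt(sigmas[i] * sigmas[i + 1L]),
      response = d[idx])
  }
  kp <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
               response = numeric(0))
  if (nrow(kp)) {
    R_px <- sphere$radius_um / sphere$pixel_scale
    r <- sqrt((kp$x - sphere$center_px[1])^2 + (kp$y - sphere$center_px[2])^2)
    keep <- r < R_px * sin((90 - limb_margin_deg) * pi / 180)
    kp <- kp[keep, , drop = FALSE]
  }
  rownames(kp) <- NULL
  kp
}

#' Divide out the orthographic Lambertian shading field
#'
#' Under orthographic viewing of a Lambertian sphere, the shading at a pixel
#' is proportional to z/R, which is known exactly from the sphere geometry.
#' Dividing it out makes the texture approximately viewpoint-invariant and is
#' applied before feature detection and description.
#'
#' @param image cropped view.
#' @param sphere the crop's [blastocyst_sphere()].
#' @param floor minimum shading value (limb regularization).
#' @return Flattened image matrix (0 outside the disk).
#' @export
flatten_shading <- function(image, sphere, floor = 0.1) {
  side <- nrow(image)
  xs <- rep(seq_len(ncol(image)), each = side)
  ys <- rep(seq_len(side), times = ncol(image))
  R <- sphere$radius_um
  h2 <- R^2 - ((xs - sphere$center_px[1])^2 +
                 (ys - sphere$center_px[2])^2) * sphere$pixel_scale^2
  shade <- rep(0, length(h2))
  shade[h2 > 0] <- pmax(sqrt(h2[h2 > 0]) / R, floor)
  out <- matrix(0, side, ncol(image))
  ok <- shade > 0
  out[ok] <- as.numeric(image)[ok] / shade[ok]
  out
}

#' Compute tangent-plane gradient-histogram descriptors
#'
#' Each keypoint is back-projected to the sphere; a sampling grid is laid out
#' in the local tangent plane of the surface (geodesic offsets in
#' micrometres) and projected back into the image, which removes the
#' orthographic foreshortening between views. From the sampled patch a
#' dominant gradient orientation is estimated, and a 4 x 4 grid of 8-bin
#' gradient-orientation histograms (128 dimensions) is accumulated in
#' orientation-normalized coordinates, giving invariance to the in-plane
#' component of the inter-view rotation.
#'
#' @param image cropped view, ideally shading-flattened
#'   (see [flatten_shading()]).
#' @param keypoints data.frame from [detect_keypoints()].
#' @param sphere the crop's [blastocyst_sphere()].
#' @return numeric matrix (nrow(keypoints) x 128), L2-normalized with 0.2
#'   clamping.
#' @export
compute_descriptors <- function(image, keypoints, sphere) {
  n <- nrow(keypoints)
  desc <- matrix(0, n, 128)
  if (n == 0L) return(desc)
  R <- sphere$radius_um
  p3 <- backproject(cbind(keypoints$x, keypoints$y), sphere)
  u <- p3 / R
  ## tangent basis at each keypoint (e_x projected, completed by cross product)
  ex <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  deg <- abs(u[, 1]) > 0.9
  ex[deg, ] <- matrix(rep(c(0, 1, 0), each = sum(deg)), ncol = 3)
  t1 <- ex - u * rowSums(ex * u)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(u[, 2] * t1[, 3] - u[, 3] * t1[, 2],
              u[, 3] * t1[, 1] - u[, 1] * t1[, 3],
              u[, 1] * t1[, 2] - u[, 2] * t1[, 1])
  for (s in unique(keypoints$sigma)) {
    rows <- which(keypoints$sigma == s)
    sm <- as.matrix(EBImage::gblur(image, sigma = max(0.8, s / 2)))
    sp_um <- 0.75 * s * sphere$pixel_scale   # tangent sample spacing
    half <- 8.5                              # samples at -8.5..8.5 units
    ax <- seq(-half, half, by = 1)
    nsamp <- length(ax)
    patch <- array(0, c(length(rows), nsamp, nsamp))
    for (ii in seq_len(nsamp)) for (jj in seq_len(nsamp)) {
      off_um <- ax[ii] * sp_um
      off2_um <- ax[jj] * sp_um
      q <- u[rows, , drop = FALSE] * R +
        t1[rows, , drop = FALSE] * off_um + t2[rows, , drop = FALSE] * off2_um
      q <- q / sqrt(rowSums(q^2)) * R
      px <- sphere$center_px[1] + q[, 1] / sphere$pixel_scale
      py <- sphere$center_px[2] + q[, 2] / sphere$pixel_scale
      val <- bilinear_sample(sm, px, py)
      val[q[, 3] <= 0] <- 0
      patch[, ii, jj] <- val
    }
    ## gradients on the tangent grid (central differences)
    gi <- (patch[, 3:nsamp, 2:(nsamp - 1), drop = FALSE] -
             patch[, 1:(nsamp - 2), 2:(nsamp - 1), drop = FALSE]) / 2
    gj <- (patch[, 2:(nsamp - 1), 3:nsamp, drop = FALSE] -
             patch[, 2:(nsamp - 1), 1:(nsamp - 2), drop = FALSE]) / 2
    ng <- nsamp - 2L                         # 16 x 16 gradient grid
    coord <- ax[2:(nsamp - 1)]
    ci <- rep(coord, times = ng)
    cj <- rep(coord, each = ng)
    wgauss <- exp(-(ci^2 + cj^2) / (2 * 8^2))
    gi <- matrix(gi, length(rows), ng * ng)
    gj <- matrix(gj, length(rows), ng * ng)
    mag <- sqrt(gi^2 + gj^2) * rep(wgauss, each = length(rows))
    ang <- atan2(gj, gi)
    ## dominant orientation per keypoint (36 bins)
    obin36 <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1L
    hist36 <- matrix(0, length(rows), 36)
    for (k in seq_len(ncol(mag))) {
      hist36[cbind(seq_along(rows), obin36[, k])] <-
        hist36[cbind(seq_along(rows), obin36[, k])] + mag[, k]
    }
    theta0 <- (max.col(hist36, ties.method = "first") - 0.5) / 36 * 2 * pi - pi
    ct <- cos(theta0); st <- sin(theta0)
    ## accumulate the 4 x 4 x 8 descriptor in rotated coordinates
    for (k in seq_len(ncol(mag))) {
      ri <- ci[k] * ct + cj[k] * st
      rj <- -ci[k] * st + cj[k] * ct
      inside <- abs(ri) < 8 & abs(rj) < 8
      if (!any(inside)) next
      a <- ang[, k] - theta0
      obin <- (floor((a + 3 * pi) / (2 * pi) * 8) %% 8) + 1L
      cell_i <- pmin(3L, pmax(0L, floor((ri + 8) / 4)))
      cell_j <- pmin(3L, pmax(0L, floor((rj + 8) / 4)))
      col <- cell_j * 32L + cell_i * 8L + obin
      w <- which(inside)
      desc[cbind(rows[w], col[w])] <- desc[cbind(rows[w], col[w])] + mag[w, k]
    }
  }
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc <- pmin(desc / nrm, 0.2)
  nrm <- sqrt(rowSums(desc^2)); nrm[nrm == 0] <- 1
  desc / nrm
}

#' Detect and match features between two views
#'
#' Features are detected in both cropped views, matched by descriptor
#' distance with the Lowe ratio test, and back-projected to 3D sphere points;
#' matches within `limb_margin_deg` of the limb are discarded because the
#' back-projected z coordinate is unreliable there.
#'
#' @param viewA,viewB cropped views (see [crop_to_sphere()]).
#' @param sphere the crop's [blastocyst_sphere()].
#' @param ratio Lowe ratio-test threshold on nearest/second-nearest
#'   descriptor distance.
#' @param limb_margin_deg limb exclusion zone in degrees.
#' @param min_matches minimum surviving matches before an
#'   insufficient-overlap error is thrown.
#' @return A `match_set`: list with `a`, `b` (n x 3 sphere points in the two
#'   view frames, micrometres), `scores`, and the pixel coordinates `px_a`,
#'   `px_b`.
#' @export
detect_and_match <- function(viewA, viewB, sphere, ratio = 0.75,
                             limb_margin_deg = 5, min_matches = 4L) {
  fa <- flatten_shading(viewA, sphere)
  fb <- flatten_shading(viewB, sphere)
  kpa <- detect_keypoints(fa, sphere, limb_margin_deg = limb_margin_deg)
  kpb <- detect_keypoints(fb, sphere, limb_margin_deg = limb_margin_deg)
  if (nrow(kpa) < min_matches || nrow(kpb) < min_matches) {
    stop_overlap(nrow(kpa), nrow(kpb))
  }
  da <- compute_descriptors(fa, kpa, sphere)
  db <- compute_descriptors(fb, kpb, sphere)
  match_from_precomputed(kpa, da, kpb, db, sphere, ratio,
                         limb_margin_deg, min_matches)
}

stop_overlap <- function(na, nb, nm = 0L) {
  stop(structure(class = c("blastometry_overlap_error", "error", "condition"),
                 list(message = sprintf(
                   "insufficient overlap: %d/%d keypoints, %d surviving matches",
                   na, nb, nm), call = NULL)))
}

## exact rotation aligning two (non-collinear) unit-vector pairs a -> b
two_point_rotation <- function(a1, a2, b1, b2) {
  ua <- orthonormal_triad(a1, a2)
  ub <- orthonormal_triad(b1, b2)
  ub %*% t(ua)
}

orthonormal_triad <- function(v1, v2) {
  u1 <- v1 / sqrt(sum(v1^2))
  u2 <- v2 - sum(v2 * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  cbind(u1, u2, c(u1[2] * u2[3] - u1[3] * u2[2],
                  u1[3] * u2[1] - u1[1] * u2[3],
                  u1[1] * u2[2] - u1[2] * u2[1]))
}

## orthogonal Procrustes (Kabsch) with det = +1 enforced; maps a -> b
kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Estimate the rotation between two views from matched sphere points
#'
#' RANSAC with two-point hypotheses: each hypothesis is the exact rotation
#' aligning two sampled correspondence pairs, scored by the angular residual;
#' the final rotation is refit on all inliers by the orthogonal-Procrustes
#' (SVD) solution with det = +1 enforced.
#'
#' @param matches a `match_set` (or any list with unit-directional `a`, `b`
#'   n x 3 matrices); must contain at least 3 pairs.
#' @param ransac list of RANSAC settings: `threshold_deg` (inlier angular
#'   residual, default 2), `max_iter` (default 1000), `min_inliers`
#'   (default 6), `seed`.
#' @return list with `rotation` (3 x 3, maps frame A to frame B), `inliers`
#'   (logical mask), `n_inliers`, `mean_residual_deg`.
#' @export
estimate_rotation <- function(matches,
                              ransac = list()) {
  rs <- utils::modifyList(list(threshold_deg = 2, max_iter = 1000,
                               min_inliers = 6L, seed = 1L), ransac)
  A <- matches$a / sqrt(rowSums(matches$a^2))
  B <- matches$b / sqrt(rowSums(matches$b^2))
  n <- nrow(A)
  if (n < 3L) stop("estimate_rotation: need at least 3 pairs", call. = FALSE)
  cos_thr <- cos(rs$threshold_deg * pi / 180)
  rng <- local_rng(rs$seed)
  best_inl <- rep(FALSE, n); best_n <- -1L; best_score <- -Inf
  for (it in seq_len(rs$max_iter)) {
    ij <- floor(rng$runif(2) * n) + 1L
    if (ij[1] == ij[2]) next
    a1 <- A[ij[1], ]; a2 <- A[ij[2], ]
    if (abs(sum(a1 * a2)) > 0.999) next
    R <- two_point_rotation(a1, a2, B[ij[1], ], B[ij[2], ])
    if (any(!is.finite(R))) next
    resid_cos <- rowSums((A %*% t(R)) * B)
    inl <- resid_cos >= cos_thr
    sc <- sum(inl) + mean(pmax(resid_cos, 0))  # tie-break: tighter residuals
    if (is.finite(sc) && sc > best_score) {
      best_score <- sc; best_inl <- inl; best_n <- sum(inl)
    }
  }
  if (best_n < rs$min_inliers) {
    stop(structure(
      class = c("blastometry_registration_error", "error", "condition"),
      list(message = sprintf(
        "registration failure: %d inliers < min_inliers = %d",
        max(best_n, 0L), rs$min_inliers), call = NULL)))
  }
  R <- kabsch_rotation(A[best_inl, , drop = FALSE], B[best_inl, , drop = FALSE])
  ## one re-scoring pass after refit
  resid_cos <- rowSums((A %*% t(R)) * B)
  inl <- resid_cos >= cos_thr
  if (sum(inl) >= rs$min_inliers) {
    R <- kabsch_rotation(A[inl, , drop = FALSE], B[inl, , drop = FALSE])
    best_inl <- inl
  }
  resid <- acos(pmin(1, pmax(-1, rowSums((A %*% t(R)) * B))))
  list(rotation = R, inliers = best_inl, n_inliers = sum(best_inl),
       mean_residual_deg = mean(resid[best_inl]) * 180 / pi)
}

#' Chain pairwise rotations into global (view-to-reference) rotations
#'
#' Given pairwise rotations `P_i` mapping view i to view i+1, returns the
#' global rotations `G_i` mapping view i to the view-1 (reference) frame:
#' `G_1 = I`, `G_(i+1) = G_i %*% t(P_i)`.
#'
#' @param pairwise list of 3 x 3 rotations, `pairwise[[i]]` maps view i to
#'   view i+1.
#' @return list of `length(pairwise) + 1` global rotations.
#' @export
chain_rotations <- function(pairwise) {
  G <- vector("list", length(pairwise) + 1L)
  G[[1L]] <- diag(3)
  for (i in seq_along(pairwise)) {
    G[[i + 1L]] <- G[[i]] %*% t(pairwise[[i]])
  }
  G
}

#' Photometric refinement of an inter-view rotation
#'
#' Refines a feature-based rotation estimate by minimizing the mean squared
#' difference between the shading-flattened view B and the reprojection of
#' view A through the rotation, over the 3-parameter rotation group (local
#' exponential-map parameterization, derivative-free optimization). On
#' well-textured views this reduces the pairwise error well below the
#' keypoint localization noise.
#'
#' @param flatA,flatB shading-flattened views ([flatten_shading()]).
#' @param sphere the crop's [blastocyst_sphere()].
#' @param R0 initial rotation (maps view A frame to view B frame).
#' @param z_min minimum z/R for a sample point to contribute (both views).
#' @param stride pixel subsampling stride of the sample grid.
#' @return Refined 3 x 3 rotation.
#' @export
refine_rotation <- function(flatA, flatB, sphere, R0, z_min = 0.35,
                            stride = 2L) {
  R_um <- sphere$radius_um
  side <- nrow(flatA)
  xs <- seq(1L, side, by = stride)
  pts <- expand.grid(x = xs, y = xs)
  u <- (pts$x - sphere$center_px[1]) * sphere$pixel_scale
  v <- (pts$y - sphere$center_px[2]) * sphere$pixel_scale
  h2 <- R_um^2 - u^2 - v^2
  keep <- h2 > (z_min * R_um)^2
  a <- cbind(u[keep], v[keep], sqrt(h2[keep]))
  va <- flatA[cbind(pts$y[keep], pts$x[keep])]
  obj <- function(w) {
    Rw <- if (sum(w^2) < 1e-20) R0 else rot_axis_angle(w, sqrt(sum(w^2))) %*% R0
    b <- a %*% t(Rw)
    ok <- b[, 3] > z_min * R_um
    if (sum(ok) < 50) return(1e6)
    px <- sphere$center_px[1] + b[ok, 1] / sphere$pixel_scale
    py <- sphere$center_px[2] + b[ok, 2] / sphere$pixel_scale
    vb <- bilinear_sample(flatB, px, py)
    mean((va[ok] - vb)^2)
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  w <- opt$par
  if (sum(w^2) < 1e-20) R0 else rot_axis_angle(w, sqrt(sum(w^2))) %*% R0
}

#' Register a full multi-view sequence
#'
#' Detects and matches features between each adjacent pair of views,
#' estimates the pairwise rotations, and chains them into global
#' view-to-reference rotations ready for [project_views()].
#'
#' @param views list of cropped view images.
#' @param sphere the crop's [blastocyst_sphere()].
#' @param ratio Lowe ratio threshold.
#' @param ransac RANSAC settings, see [estimate_rotation()].
#' @param refine apply photometric refinement ([refine_rotation()]) to each
#'   pairwise estimate (default TRUE).
#' @param verbose emit one message per registered pair.
#' @return list with `global` (view-to-global rotations), `pairwise`
#'   (estimates with inlier counts and residuals), `info` per pair.
#' @export
register_sequence <- function(views, sphere, ratio = 0.75, ransac = list(),
                              refine = TRUE, verbose = FALSE) {
  n <- length(views)
  stopifnot(n >= 2)
  flat <- lapply(views, flatten_shading, sphere = sphere)
  kps <- lapply(flat, detect_keypoints, sphere = sphere)
  dsc <- lapply(seq_len(n), function(i) {
    compute_descriptors(flat[[i]], kps[[i]], sphere)
  })
  pairwise <- vector("list", n - 1L)
  info <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    ms <- match_from_precomputed(kps[[i]], dsc[[i]], kps[[i + 1L]],
                                 dsc[[i + 1L]], sphere, ratio)
    est <- estimate_rotation(ms, ransac)
    pairwise[[i]] <- est$rotation
    if (refine) {
      pairwise[[i]] <- refine_rotation(flat[[i]], flat[[i + 1L]], sphere,
                                       pairwise[[i]])
    }
    info[[i]] <- list(n_matches = nrow(ms$a), n_inliers = est$n_inliers,
                      mean_residual_deg = est$mean_residual_deg)
    if (verbose) {
      message(sprintf(
        "[register] pair %d-%d: %d matches, %d inliers, residual %.3f deg",
        i, i + 1L, nrow(ms$a), est$n_inliers, est$mean_residual_deg))
    }
  }
  list(global = chain_rotations(pairwise), pairwise = pairwise, info = info)
}

## matching with precomputed keypoints/descriptors (shared by
## register_sequence to avoid re-detecting per pair); Lowe ratio test plus
## mutual-best cross-check
match_from_precomputed <- function(kpa, da, kpb, db, sphere, ratio = 0.75,
                                   limb_margin_deg = 5, min_matches = 4L) {
  if (nrow(kpa) < min_matches || nrow(kpb) < min_matches) {
    stop_overlap(nrow(kpa), nrow(kpb))
  }
  d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  d1v <- d2[cbind(seq_len(nrow(d2)), best)]
  d2m <- d2
  d2m[cbind(seq_len(nrow(d2)), best)] <- Inf
  second <- apply(d2m, 1, min)
  best_ba <- max.col(-t(d2), ties.method = "first")
  mutual <- best_ba[best] == seq_len(nrow(d2))
  ok <- sqrt(d1v) < ratio * sqrt(second) & mutual
  ia <- which(ok); ib <- best[ok]
  if (!length(ia)) stop_overlap(nrow(kpa), nrow(kpb), 0L)
  pa <- backproject(cbind(kpa$x[ia], kpa$y[ia]), sphere)
  pb <- backproject(cbind(kpb$x[ib], kpb$y[ib]), sphere)
  zmin <- sphere$radius_um * cos((90 - limb_margin_deg) * pi / 180)
  keep <- pa[, 3] > zmin & pb[, 3] > zmin
  pa <- pa[keep, , drop = FALSE]; pb <- pb[keep, , drop = FALSE]
  if (nrow(pa) < min_matches) stop_overlap(nrow(kpa), nrow(kpb), nrow(pa))
  structure(list(a = pa, b = pb,
                 scores = 1 - sqrt(d1v[ia][keep]) / sqrt(second[ia][keep]),
                 px_a = cbind(kpa$x[ia], kpa$y[ia])[keep, , drop = FALSE],
                 px_b = cbind(kpb$x[ib], kpb$y[ib])[keep, , drop = FALSE]),
            class = "match_set")
}
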