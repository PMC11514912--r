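## Classical per-view segmentation of TE cell boundaries and the ICM, plus a
## strict contract for ingesting externally produced (e.g. neural-network)
## masks. Canonical label alphabet: 0 = background, 1 = TE boundary,
## 2 = ICM, >= 3 = cell interiors (individual watershed ids).

#' Segment TE cell boundaries and ICM in one view
#'
#' Deterministic classical pipeline: background suppression outside the
#' sphere disk, shading flattening by low-pass division, darkness-ridge
#' enhancement at `ridge_scale`, hysteresis thresholding to a boundary band,
#' watershed from cell-interior maxima to close the cells, and detection of
#' the ICM as the largest dark compact region exceeding `icm_min_area_frac`
#' of the disk.
#'
#' @param view cropped view image ([crop_to_sphere()]).
#' @param sphere the crop's [blastocyst_sphere()].
#' @param params list overriding any of: `smoothing_sigma` (px, default 0.5),
#'   `ridge_scale` (px, default 3; scale of the surround used for the
#'   darkness ridge), `hysteresis_hi`, `hysteresis_lo` (darkness thresholds),
#'   `ridge_rel` (keep pixels at least this fraction of the local darkness
#'   peak, so the detected band tracks the membrane width at half maximum),
#'   `icm_albedo_threshold` (flattened-intensity threshold for ICM
#'   candidates), `icm_min_area_frac` (default 0.03), `watershed_tolerance`
#'   (default 0.1), `min_cell_area_px` (default 12).
#' @return Integer mask matrix (same shape as `view`) in the canonical
#'   alphabet, with attribute `icm_found` (logical); a warning is raised when
#'   no ICM candidate is present (it may face away in this view).
#' @export
segment_classical <- function(view, sphere, params = list()) {
  p <- utils::modifyList(list(
    smoothing_sigma = 0.5, ridge_scale = 3,
    hysteresis_hi = 0.2, hysteresis_lo = 0.08, ridge_rel = 0.3,
    icm_albedo_threshold = 0.5, icm_min_area_frac = 0.03,
    watershed_tolerance = 0.1, min_cell_area_px = 12
  ), params)
  side <- nrow(view)
  xs <- rep(seq_len(ncol(view)), each = side)
  ys <- rep(seq_len(side), times = ncol(view))
  R_px <- sphere$radius_um / sphere$pixel_scale
  r2 <- (xs - sphere$center_px[1])^2 + (ys - sphere$center_px[2])^2
  disk <- matrix(r2 < R_px^2, side, ncol(view))
  ## shading flattening: divide by the known orthographic shading field
  flat <- flatten_shading(view, sphere)
  flat[!disk] <- 0
  sm <- if (p$smoothing_sigma > 0) {
    as.matrix(EBImage::gblur(flat, p$smoothing_sigma))
  } else flat
  inner <- disk & matrix(r2 < (0.985 * R_px)^2, side, ncol(view))
  if (stats::sd(sm[inner]) < 1e-3) {
    ## featureless input: no boundaries, no ICM
    out <- matrix(0L, side, ncol(view))
    attr(out, "icm_found") <- FALSE
    warning("segment_classical: featureless view, no boundaries or ICM found",
            call. = FALSE)
    return(out)
  }
  ## darkness ridge: darker than the local surround; normalized convolution
  ## so the dark exterior does not bias the surround near the limb
  wdisk <- matrix(as.numeric(inner), side, ncol(view))
  surround <- as.matrix(EBImage::gblur(sm * wdisk, p$ridge_scale * 3)) /
    pmax(as.matrix(EBImage::gblur(wdisk, p$ridge_scale * 3)), 1e-6)
  dark <- surround - sm
  dark[!inner] <- 0
  ## ICM: largest dark compact region by flattened intensity at a coarse
  ## scale (thin membrane lines average out; the compact cap stays dark)
  sm_icm <- as.matrix(EBImage::gblur(flat, 4))
  icm_cand <- inner & sm_icm < p$icm_albedo_threshold
  icm <- matrix(FALSE, side, ncol(view))
  icm_found <- FALSE
  if (any(icm_cand)) {
    lbl <- EBImage::bwlabel(icm_cand)
    sizes <- tabulate(lbl[lbl > 0])
    big <- which(sizes > p$icm_min_area_frac * sum(disk))
    if (length(big)) {
      main <- big[which.max(sizes[big])]
      icm <- lbl == main
      icm <- as.matrix(EBImage::fillHull(icm))
      icm_found <- TRUE
    }
  }
  ## hysteresis threshold on the darkness ridge (outside the ICM), kept to
  ## the half-maximum band of the local ridge so the detected width tracks
  ## the membrane width regardless of per-cell contrast
  locmax <- as.matrix(EBImage::dilate(dark, EBImage::makeBrush(7, "disc")))
  weak <- dark > p$hysteresis_lo & dark > p$ridge_rel * locmax & !icm
  strong <- dark > p$hysteresis_hi & !icm
  boundary <- matrix(FALSE, side, ncol(view))
  if (any(weak)) {
    wl <- EBImage::bwlabel(weak)
    keep <- unique(wl[strong & wl > 0])
    boundary <- matrix(wl %in% keep & wl > 0, side, ncol(view))
  }
  ## close cells by watershed on the flattened intensity (interior maxima)
  height <- sm
  height[!inner | icm | boundary] <- 0
  ws <- EBImage::watershed(EBImage::as.Image(height),
                           tolerance = p$watershed_tolerance, ext = 1)
  ws <- matrix(as.integer(EBImage::imageData(ws)), side, ncol(view))
  ## drop slivers below the minimum cell area
  sizes <- tabulate(ws[ws > 0])
  small <- which(sizes < p$min_cell_area_px)
  if (length(small)) ws[ws %in% small] <- 0L
  ws <- match(ws, sort(unique(ws[ws > 0])))  # compact ids
  ws[is.na(ws)] <- 0L
  out <- matrix(0L, side, ncol(view))
  out[ws > 0] <- ws[ws > 0] + 2L
  out[boundary] <- 1L
  out[icm] <- 2L
  out[!disk] <- 0L
  attr(out, "icm_found") <- icm_found
  if (!icm_found) {
    warning("segment_classical: no ICM candidate found in this view",
            call. = FALSE)
  }
  out
}

#' Load externally produced segmentation masks
#'
#' Validates label images produced outside the package (for example by a
#' trained network) and maps their label values onto the canonical alphabet.
#'
#' @param paths character vector of mask files (PNG or TIFF label images).
#' @param alphabet_mapping named list or vector mapping each label value
#'   present in the files to one of `"background"`, `"te_boundary"`,
#'   `"cell"`, `"icm"`, or directly to a canonical integer (>= 3 allowed for
#'   individual cell ids); names are the raw integer values as strings.
#' @param views optional list of view images to check shapes against.
#' @return list of integer mask matrices in the canonical alphabet.
#' @export
load_external_masks <- function(paths, alphabet_mapping, views = NULL) {
  canon <- c(background = 0L, te_boundary = 1L, icm = 2L, cell = 3L)
  masks <- lapply(paths, function(f) {
    if (!file.exists(f)) stop("load_external_masks: no such file: ", f,
                              call. = FALSE)
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      m <- png::readPNG(f)
      depth <- 255
    } else {
      m <- tiff::readTIFF(f)
      depth <- 65535
    }
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * depth)), nrow(m), ncol(m))
  })
  for (k in seq_along(masks)) {
    vals <- sort(unique(as.integer(masks[[k]])))
    unmapped <- setdiff(as.character(vals), names(alphabet_mapping))
    if (length(unmapped)) {
      stop(sprintf("load_external_masks: unmapped label value(s) %s in %s",
                   paste(unmapped, collapse = ", "), paths[k]), call. = FALSE)
    }
    lut <- vapply(alphabet_mapping, function(v) {
      if (is.character(v)) {
        if (!v %in% names(canon)) {
          stop("load_external_masks: unknown alphabet name: ", v, call. = FALSE)
        }
        canon[[v]]
      } else as.integer(v)
    }, integer(1))
    m <- masks[[k]]
    mapped <- lut[match(as.character(m), names(lut))]
    masks[[k]] <- matrix(as.integer(mapped), nrow(m), ncol(m))
    if (!is.null(views)) {
      if (!all(dim(masks[[k]]) == dim(views[[k]]))) {
        stop(sprintf(
          "load_external_masks: mask %d shape %dx%d does not match view %dx%d",
          k, nrow(masks[[k]]), ncol(masks[[k]]),
          nrow(views[[k]]), ncol(views[[k]])), call. = FALSE)
      }
    }
  }
  masks
}

#' Write a label mask to disk
#'
#' TIFF masks are 16-bit (labels up to 65535); PNG masks are 8-bit (labels
#' up to 255).
#'
#' @param mask integer label matrix.
#' @param path output path; format chosen by extension.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(mask) > 255L) {
      stop("write_mask: PNG masks are 8-bit; use TIFF for labels above 255",
           call. = FALSE)
    }
    png::writePNG(mask / 255, path)
  } else {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}
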