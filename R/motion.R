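# Variational optical flow and elastic ROI propagation for dynamic MRI.
#
# Convention used throughout: the estimated field (u, v) maps reference
# coordinates to moving-frame coordinates, i.e. mov(x + u(x), y + v(x))
# ~= ref(x, y), so warping the moving frame by (u, v) reproduces the
# reference, and pushing a reference ROI voxel through (u, v) lands on the
# corresponding voxel of the moving frame.

shift_mat <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
  ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
  m[xs, ys]
}

# Horn-Schunck neighborhood average (standard 8-neighbor weights).
hs_average <- function(m) {
  (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
   shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
  (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
   shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
}

central_diff_x <- function(m) (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / 2
central_diff_y <- function(m) (shift_mat(m, 0, 1) - shift_mat(m, 0, -1)) / 2

downsample2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  nx2 <- ceiling(nx / 2); ny2 <- ceiling(ny / 2)
  if (nx %% 2) m <- rbind(m, m[nx, , drop = FALSE])
  if (ny %% 2) m <- cbind(m, m[, ncol(m), drop = FALSE])
  (m[seq(1, 2 * nx2, 2), seq(1, 2 * ny2, 2)] +
   m[seq(2, 2 * nx2, 2), seq(1, 2 * ny2, 2)] +
   m[seq(1, 2 * nx2, 2), seq(2, 2 * ny2, 2)] +
   m[seq(2, 2 * nx2, 2), seq(2, 2 * ny2, 2)]) / 4
}

upsample2 <- function(m, shape) {
  nx <- nrow(m); ny <- ncol(m)
  xs <- (seq_len(shape[1]) + 0.5) / 2
  ys <- (seq_len(shape[2]) + 0.5) / 2
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  x0 <- floor(xs); x1 <- pmin(x0 + 1, nx); fx <- xs - x0
  y0 <- floor(ys); y1 <- pmin(y0 + 1, ny); fy <- ys - y0
  out <- outer((1 - fx), (1 - fy)) * m[x0, y0] +
         outer(fx, (1 - fy)) * m[x1, y0] +
         outer((1 - fx), fy) * m[x0, y1] +
         outer(fx, fy) * m[x1, y1]
  out
}

hs_iterate <- function(ref, mov, u, v, lambda, max_iter, tol = 1e-4) {
  warped <- warp_bilinear(mov, u, v)
  avg_img <- (ref + warped) / 2
  Ix <- central_diff_x(avg_img)
  Iy <- central_diff_y(avg_img)
  It <- warped - ref
  du <- matrix(0, nrow(ref), ncol(ref))
  dv <- du
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dub <- hs_average(du); dvb <- hs_average(dv)
    common <- (Ix * dub + Iy * dvb + It) / (lambda + Ix^2 + Iy^2)
    du_new <- dub - Ix * common
    dv_new <- dvb - Iy * common
    delta <- mean(abs(du_new - du) + abs(dv_new - dv))
    du <- du_new; dv <- dv_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(u = u + du, v = v + dv, converged = converged)
}

#' Estimate inter-frame motion by coarse-to-fine Horn-Schunck optical flow
#'
#' Quadratic-regularized variational flow with a 3-level coarse-to-fine
#' warping scheme, used to track organ motion through a dynamic MRI session
#' and to detect shifts between the echoes of a multi-echo acquisition.
#' Images are rescaled internally to unit peak, so `lambda` has the same
#' meaning whatever the signal units.
#'
#' @param ref reference frame (matrix).
#' @param mov moving frame, same shape.
#' @param lambda regularization weight (> 0); larger gives a smoother
#'   field. On unit-scaled images the default 0.05 favors smooth fields of
#'   a few voxels, appropriate for respiratory motion.
#' @param max_iter iteration cap per pyramid level.
#' @param n_levels pyramid depth.
#' @return An object of class `motion_field`: matrices `u`, `v`
#'   (displacement in voxels, reference-to-moving convention) and
#'   `converged` (FALSE if any level hit the iteration cap; the best field
#'   found is still returned, with a warning).
#' @export
estimate_motion <- function(ref, mov, lambda = 0.05, max_iter = 200,
                            n_levels = 3) {
  if (!all(dim(ref) == dim(mov))) stop("frame shapes differ")
  if (lambda <= 0) stop("regularization weight must be > 0")
  scale <- max(abs(ref), abs(mov), 1e-12)
  ref <- ref / scale; mov <- mov / scale

  pyr_ref <- list(ref); pyr_mov <- list(mov)
  for (l in seq_len(n_levels - 1)) {
    if (min(dim(pyr_ref[[l]])) < 16) break
    pyr_ref[[l + 1]] <- downsample2(pyr_ref[[l]])
    pyr_mov[[l + 1]] <- downsample2(pyr_mov[[l]])
  }
  L <- length(pyr_ref)
  u <- matrix(0, nrow(pyr_ref[[L]]), ncol(pyr_ref[[L]]))
  v <- u
  conv_all <- TRUE
  for (l in rev(seq_len(L))) {
    r <- pyr_ref[[l]]; m <- pyr_mov[[l]]
    if (l < L) {
      u <- 2 * upsample2(u, dim(r))
      v <- 2 * upsample2(v, dim(r))
    }
    res <- hs_iterate(r, m, u, v, lambda, max_iter)
    u <- res$u; v <- res$v
    conv_all <- conv_all && res$converged
  }
  if (!conv_all)
    warning("optical flow hit the iteration cap; returning best field")
  structure(list(u = u, v = v, converged = conv_all),
            class = "motion_field")
}

# 3x3 binary dilation / erosion by matrix shifts.
dilate3 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1)
    if (dx || dy) out <- out | shift_mat(mask, dx, dy)
  out
}
erode3 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1)
    if (dx || dy) out <- out & shift_mat(mask, dx, dy)
  out
}

#' Erode a binary mask
#'
#' Repeated 3x3 binary erosion; used to pull an organ ROI away from
#' partial-volume boundary voxels before signal extraction.
#'
#' @param mask logical matrix.
#' @param n number of erosion passes.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, n = 1) {
  for (i in seq_len(n)) mask <- erode3(mask)
  mask
}

#' Propagate a reference ROI elastically through per-frame motion fields
#'
#' Each reference ROI voxel is pushed through that frame's displacement
#' field and rounded to the nearest voxel; a 3x3 morphological closing
#' fills rounding holes. A one-voxel ROI is guaranteed to survive via a
#' nearest-voxel fallback on the pushed centroid.
#'
#' @param roi logical matrix: the ROI on the reference frame.
#' @param fields list of `motion_field` objects (or `list(u =, v =)`), one
#'   per frame; the reference frame's field is zero.
#' @param label organ label stored with the result.
#' @return An object of class `roi_track`: `label` and `masks`, a list of
#'   logical matrices (one per frame).
#' @export
propagate_roi <- function(roi, fields, label = "organ") {
  stopifnot(is.matrix(roi))
  if (!any(roi)) stop("reference ROI is empty")
  nx <- nrow(roi); ny <- ncol(roi)
  idx <- which(roi, arr.ind = TRUE)
  masks <- vector("list", length(fields))
  for (f in seq_along(fields)) {
    fu <- fields[[f]]$u; fv <- fields[[f]]$v
    px <- round(idx[, 1] + fu[idx])
    py <- round(idx[, 2] + fv[idx])
    keep <- px >= 1 & px <= nx & py >= 1 & py <= ny
    m <- matrix(FALSE, nx, ny)
    if (!any(keep)) {
      cx <- round(mean(idx[, 1] + fu[idx]))
      cy <- round(mean(idx[, 2] + fv[idx]))
      if (cx < 1 || cx > nx || cy < 1 || cy > ny)
        stop("ROI pushed fully outside the grid at frame ", f)
      m[cx, cy] <- TRUE
    } else {
      m[cbind(px[keep], py[keep])] <- TRUE
      if (sum(m) > 2) m <- erode3(dilate3(m))  # closing
      if (!any(m)) m[cbind(px[keep][1], py[keep][1])] <- TRUE
    }
    masks[[f]] <- m
  }
  structure(list(label = label, masks = masks), class = "roi_track")
}

#' Estimate motion for every frame of a dynamic series
#'
#' Runs [estimate_motion()] of each frame against the reference frame
#' (default: the first pre-injection frame, on which the initial ROI is
#' drawn).
#'
#' @param series a `dynamic_series`.
#' @param reference index of the reference frame.
#' @param ... passed to [estimate_motion()].
#' @return List of `motion_field` objects, one per frame (zero field at the
#'   reference).
#' @export
estimate_series_motion <- function(series, reference = 1L, ...) {
  stopifnot(inherits(series, "dynamic_series"))
  nf <- dim(series$data)[3]
  ref <- series$data[, , reference]
  zero <- matrix(0, nrow(ref), ncol(ref))
  n_warn <- 0L
  fields <- lapply(seq_len(nf), function(f) {
    if (f == reference)
      return(structure(list(u = zero, v = zero, converged = TRUE),
                       class = "motion_field"))
    withCallingHandlers(
      estimate_motion(ref, series$data[, , f], ...),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
  })
  if (n_warn > 0)
    warning(n_warn, " of ", nf,
            " frames hit the optical-flow iteration cap")
  fields
}

#' Extract the mean signal time course over tracked ROIs
#'
#' @param series a `dynamic_series`.
#' @param rois a `roi_track` from [propagate_roi()], or a single logical
#'   matrix used statically on every frame.
#' @return An object of class `signal_timecourse`: `times_min`, `mean`,
#'   `sd`, `n_voxels` per frame, plus the number of pre-injection frames.
#' @export
extract_mean_timecourse <- function(series, rois) {
  stopifnot(inherits(series, "dynamic_series"))
  nf <- dim(series$data)[3]
  masks <- if (inherits(rois, "roi_track")) rois$masks
           else if (is.matrix(rois)) rep(list(rois), nf)
           else stop("rois must be a roi_track or a logical matrix")
  if (length(masks) != nf) stop("ROI must be defined on every frame")
  mu <- sdev <- nv <- numeric(nf)
  for (f in seq_len(nf)) {
    vals <- series$data[, , f][masks[[f]]]
    if (!length(vals)) stop("empty ROI at frame ", f)
    mu[f] <- mean(vals)
    sdev[f] <- if (length(vals) > 1) stats::sd(vals) else 0
    nv[f] <- length(vals)
  }
  structure(list(times_min = series$times_min, mean = mu, sd = sdev,
                 n_voxels = nv, n_pre = series$n_pre),
            class = "signal_timecourse")
}

#' Motion-tracked organ time course from a dynamic series
#'
#' Convenience wrapper: build the organ ROI from the series labels on the
#' reference frame (optionally eroded away from boundary voxels), estimate
#' per-frame motion, propagate the ROI elastically, and extract the mean
#' signal.
#'
#' @param series a `dynamic_series`.
#' @param organ organ name (see [organ_codes]).
#' @param erode erosion passes applied to the reference ROI before
#'   tracking (default 2, to avoid partial-volume boundary voxels).
#' @param track if `FALSE`, skip motion estimation and use the static
#'   reference ROI on every frame.
#' @param ... passed to [estimate_motion()].
#' @return A `signal_timecourse`.
#' @export
track_organ_timecourse <- function(series, organ = "liver", erode = 2,
                                   track = TRUE, ...) {
  roi <- series$labels == organ_codes[[organ]]
  if (erode > 0) {
    eroded <- erode_mask(roi, erode)
    if (any(eroded)) roi <- eroded
  }
  if (!track) return(extract_mean_timecourse(series, roi))
  fields <- estimate_series_motion(series, ...)
  extract_mean_timecourse(series, propagate_roi(roi, fields, label = organ))
}
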