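## Focus detection and chromosome-axis segmentation.
##
## Foci are local maxima of a scale-normalized Laplacian-of-Gaussian (LoG)
## response at the PSF scale, after large-scale background subtraction, kept
## when the response exceeds a robust background threshold. The axis is
## segmented by Hessian ridge enhancement followed by hysteresis
## thresholding inside the nucleus mask, then thinned to a skeleton whose
## polylines give the axis length in micrometres.

gaussian_kernel_1d <- function(sigma, half = ceiling(4 * sigma)) {
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## scale-normalized LoG kernel (negated so that bright blobs give positive
## response after convolution)
log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  x <- seq(-half, half)
  g1 <- exp(-x^2 / (2 * sigma^2))
  g <- outer(g1, g1) / (2 * pi * sigma^2)
  r2 <- outer(x^2, x^2, "+")
  -sigma^2 * (r2 - 2 * sigma^2) / sigma^4 * g
}

## second-derivative-of-Gaussian kernels, scale-normalized by sigma^2
hessian_kernels <- function(sigma) {
  half <- ceiling(4 * sigma)
  x <- seq(-half, half)
  g1 <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  d1 <- -x / sigma^2 * g1
  d2 <- (x^2 - sigma^2) / sigma^4 * g1
  ## image axes: rows = y, cols = x
  list(
    yy = sigma^2 * outer(d2, g1),
    xx = sigma^2 * outer(g1, d2),
    xy = sigma^2 * outer(d1, d1)
  )
}

convolve2 <- function(img, kernel) {
  as.matrix(EBImage::filter2(EBImage::Image(img), kernel,
                             boundary = "replicate"))
}

#' Focus detection parameters
#'
#' @param psf_sigma_um detection scale: standard deviation of the PSF in
#'   micrometres (the LoG is applied at this scale).
#' @param k robust threshold factor: maxima are kept when the LoG response
#'   exceeds `median + k * mad` of the response.
#' @param min_separation_px minimum separation between accepted foci, pixels.
#' @param background_sigma_um scale of the Gaussian background estimate
#'   subtracted before detection (replaces deconvolution).
#' @param centroid_halfwidth_px half-width of the window used for the
#'   intensity-weighted sub-pixel centroid.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(psf_sigma_um = 0.13, k = 5,
                          min_separation_px = 3L,
                          background_sigma_um = 2,
                          centroid_halfwidth_px = 3L) {
  structure(list(psf_sigma_um = psf_sigma_um, k = k,
                 min_separation_px = as.integer(min_separation_px),
                 background_sigma_um = background_sigma_um,
                 centroid_halfwidth_px = as.integer(centroid_halfwidth_px)),
            class = "detect_params")
}

#' Detect diffraction-limited foci in one channel
#'
#' Local maxima of a scale-normalized Laplacian-of-Gaussian response at the
#' PSF scale, computed on the background-subtracted channel, retained when
#' the response exceeds `median + k * mad` of the response and separated by
#' at least `min_separation_px`. Centroids are refined to sub-pixel accuracy
#' by an intensity-weighted mean in a small window.
#'
#' @param stack an [image_stack()].
#' @param channel channel name (typically `"foci"`).
#' @param params a [detect_params()].
#' @return An object of class `focus_set`: a list with `foci` (data frame
#'   with columns `x_um`, `y_um`, `peak_intensity`, `radius_um`),
#'   `source_channel` and `detection_params`.
#' @export
detect_foci <- function(stack, channel = "foci", params = detect_params()) {
  img <- get_channel(stack, channel)
  px <- stack$pixel_size_um
  sigma_px <- params$psf_sigma_um / px
  if (!is.finite(sigma_px) || sigma_px <= 0) {
    stop("non-positive detection scale: psf_sigma_um must be > 0")
  }
  bg <- gaussian_blur(img, params$background_sigma_um / px)
  diffimg <- img - bg            # unclipped: noise stays symmetric
  sub <- pmax(diffimg, 0)        # clipped copy for centroid weights
  resp <- convolve2(diffimg, log_kernel(sigma_px))
  ## the small absolute floor guards noise-free images, where mad(resp)
  ## collapses and numerical convolution ripple would otherwise pass
  thr <- max(stats::median(resp) + params$k * stats::mad(resp),
             1e-6 * max(abs(resp)))

  win <- 2L * params$min_separation_px + 1L
  dil <- as.matrix(EBImage::dilate(EBImage::Image(resp),
                                   EBImage::makeBrush(win, shape = "box")))
  cand <- which(resp >= dil & resp > thr & sub > 0, arr.ind = TRUE)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      peak_intensity = numeric(0), radius_um = numeric(0))
  if (nrow(cand) == 0L) {
    return(structure(list(foci = empty, source_channel = channel,
                          detection_params = params), class = "focus_set"))
  }
  ## greedy minimum-separation enforcement, strongest response first
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0L, 2L)
  min_sep2 <- as.numeric(params$min_separation_px)^2
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) == 0L ||
        min((keep[, 1L] - p[1L])^2 + (keep[, 2L] - p[2L])^2) > min_sep2) {
      keep <- rbind(keep, p)
    }
  }
  h <- nrow(img); w <- ncol(img)
  hw <- params$centroid_halfwidth_px
  out <- lapply(seq_len(nrow(keep)), function(i) {
    r0 <- keep[i, 1L]; c0 <- keep[i, 2L]
    ii <- max(1L, r0 - hw):min(h, r0 + hw)
    jj <- max(1L, c0 - hw):min(w, c0 + hw)
    wts <- sub[ii, jj, drop = FALSE]
    sw <- sum(wts)
    if (sw <= 0) { ci <- r0; cj <- c0; s_hat <- sigma_px }
    else {
      ci <- sum(outer(ii, rep(1, length(jj))) * wts) / sw
      cj <- sum(outer(rep(1, length(ii)), jj) * wts) / sw
      r2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
      s_hat <- sqrt(max(sum(r2 * wts) / sw, 1e-12) / 2)
    }
    s_hat <- min(max(s_hat, 0.5 * sigma_px), 2 * sigma_px)
    c(x_um = (cj - 1) * px, y_um = (ci - 1) * px,
      peak_intensity = sub[r0, c0], radius_um = 2 * s_hat * px)
  })
  foci <- as.data.frame(do.call(rbind, out))
  structure(list(foci = foci, source_channel = channel,
                 detection_params = params), class = "focus_set")
}

#' @export
print.focus_set <- function(x, ...) {
  cat("focus_set:", nrow(x$foci), "foci from channel '",
      x$source_channel, "'\n", sep = "")
  invisible(x)
}

#' Axis segmentation parameters
#'
#' @param psf_sigma_um PSF scale, micrometres.
#' @param ridge_sigma_factor ridge-filter scale as a multiple of the PSF.
#' @param low_fraction low hysteresis threshold as a fraction of the high
#'   (the high threshold is the Otsu split of the ridge response inside the
#'   nucleus).
#' @param background_sigma_um background-estimate scale, micrometres.
#' @param nucleus_smooth_um smoothing scale used for the nucleus mask.
#' @param prune_um skeleton spur branches shorter than this are removed.
#' @param nucleus_channel channel used for the nucleus mask; when absent the
#'   segmented channel's convex hull is used instead.
#' @return A list of class `axis_params`.
#' @export
axis_params <- function(psf_sigma_um = 0.13, ridge_sigma_factor = 1.4,
                        low_fraction = 0.4,
                        background_sigma_um = 2, nucleus_smooth_um = 0.8,
                        prune_um = 0.5, nucleus_channel = "chromatin") {
  structure(list(psf_sigma_um = psf_sigma_um,
                 ridge_sigma_factor = ridge_sigma_factor,
                 low_fraction = low_fraction,
                 background_sigma_um = background_sigma_um,
                 nucleus_smooth_um = nucleus_smooth_um, prune_um = prune_um,
                 nucleus_channel = nucleus_channel),
            class = "axis_params")
}

## Nucleus mask: smooth + Otsu threshold + fill holes + largest component.
nucleus_mask_from_channel <- function(img, px, smooth_um, convex = FALSE) {
  if (max(img) <= min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
  sm <- gaussian_blur(img, smooth_um / px)
  nm <- (sm - min(sm)) / (max(sm) - min(sm))
  t <- EBImage::otsu(EBImage::Image(nm))
  mask <- EBImage::fillHull(EBImage::Image(nm > t))
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(as.integer(lab))
  if (!length(tab)) return(matrix(FALSE, nrow(img), ncol(img)))
  out <- as.matrix(lab) == which.max(tab)
  if (convex) out <- convex_fill(out)
  out
}

## Fill the convex hull of a binary mask (scanline point-in-polygon).
convex_fill <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(mask)
  hull <- pts[grDevices::chull(pts[, 2L], pts[, 1L]), , drop = FALSE]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  hr <- hull[, 1L]; hc <- hull[, 2L]
  nh <- length(hr)
  for (r in min(hr):max(hr)) {
    xs <- numeric(0)
    for (k in seq_len(nh)) {
      k2 <- if (k == nh) 1L else k + 1L
      r1 <- hr[k]; r2 <- hr[k2]
      if ((r1 <= r && r2 > r) || (r2 <= r && r1 > r)) {
        xs <- c(xs, hc[k] + (r - r1) / (r2 - r1) * (hc[k2] - hc[k]))
      } else if (r1 == r && r2 == r) {
        xs <- c(xs, hc[k], hc[k2])
      }
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        out[r, ceiling(xs[k]):floor(xs[k + 1L])] <- TRUE
      }
    }
  }
  out | mask
}

#' Segment the chromosome axis and measure its length
#'
#' Enhances curvilinear bright ridges with a Hessian eigenvalue filter at
#' ~1.4x the PSF scale, applies hysteresis thresholding inside the nucleus
#' mask, thins the result to a one-pixel skeleton (pruning spurs shorter
#' than `prune_um`), and measures total length in micrometres on the traced,
#' lightly smoothed skeleton polylines.
#'
#' An empty (constant) channel yields an empty segmentation of length 0.
#'
#' @param stack an [image_stack()].
#' @param channel channel name (typically `"axis"`).
#' @param params an [axis_params()].
#' @return An object of class `axis_segmentation` with elements `mask`,
#'   `skeleton`, `skeleton_polylines` (micrometre coordinates), `length_um`,
#'   `chain_length_um` (raw 8-connected chain length), `n_components`
#'   (connected skeleton components), `nucleus_mask`,
#'   `nucleus_centroid_um`, `dist_to_skeleton_px` and `pixel_size_um`.
#' @export
segment_axis <- function(stack, channel = "axis", params = axis_params()) {
  img <- get_channel(stack, channel)
  px <- stack$pixel_size_um
  sigma_px <- params$psf_sigma_um / px
  if (!is.finite(sigma_px) || sigma_px <= 0) {
    stop("non-positive detection scale: psf_sigma_um must be > 0")
  }

  if (params$nucleus_channel %in% names(stack$channels)) {
    nucleus <- nucleus_mask_from_channel(
      get_channel(stack, params$nucleus_channel), px,
      params$nucleus_smooth_um)
  } else {
    nucleus <- nucleus_mask_from_channel(img, px, params$nucleus_smooth_um,
                                         convex = TRUE)
  }

  empty_seg <- function() {
    structure(list(
      mask = matrix(FALSE, nrow(img), ncol(img)),
      skeleton = matrix(0L, nrow(img), ncol(img)),
      skeleton_polylines = list(), length_um = 0, chain_length_um = 0,
      n_components = 0L,
      nucleus_mask = nucleus,
      nucleus_centroid_um = nucleus_centroid(nucleus, px),
      dist_to_skeleton_px = matrix(Inf, nrow(img), ncol(img)),
      pixel_size_um = px, params = params
    ), class = "axis_segmentation")
  }
  if (max(img) <= min(img) || !any(nucleus)) return(empty_seg())

  bg <- gaussian_blur(img, params$background_sigma_um / px)
  sub <- pmax(img - bg, 0)
  kk <- hessian_kernels(params$ridge_sigma_factor * sigma_px)
  hxx <- convolve2(sub, kk$xx)
  hyy <- convolve2(sub, kk$yy)
  hxy <- convolve2(sub, kk$xy)
  lam_min <- ((hxx + hyy) - sqrt((hxx - hyy)^2 + 4 * hxy^2)) / 2
  ridge <- pmax(-lam_min, 0)
  ridge[!nucleus] <- 0

  v <- ridge[nucleus]
  if (max(v) <= 0) return(empty_seg())
  hi <- max(v) * EBImage::otsu(EBImage::Image(matrix(v / max(v), ncol = 1L)))
  if (!is.finite(hi) || hi <= 0 || !any(v > hi)) return(empty_seg())
  lo <- params$low_fraction * hi
  lab <- EBImage::bwlabel(EBImage::Image((ridge > lo) & nucleus))
  lab_m <- as.matrix(lab)
  strong <- unique(lab_m[ridge > hi])
  strong <- strong[strong > 0]
  if (!length(strong)) return(empty_seg())
  mask <- matrix(lab_m %in% strong, nrow(img), ncol(img))

  sk <- skeletonize_mask(mask, px, prune_um = params$prune_um)
  dist_px <- if (any(sk$skeleton > 0)) {
    as.matrix(EBImage::distmap(EBImage::Image(1 - sk$skeleton)))
  } else matrix(Inf, nrow(img), ncol(img))

  structure(list(
    mask = mask, skeleton = sk$skeleton,
    skeleton_polylines = sk$polylines, length_um = sk$length_um,
    chain_length_um = sk$chain_length_um,
    n_components = sk$n_components,
    nucleus_mask = nucleus,
    nucleus_centroid_um = nucleus_centroid(nucleus, px),
    dist_to_skeleton_px = dist_px,
    pixel_size_um = px, params = params
  ), class = "axis_segmentation")
}

nucleus_centroid <- function(nucleus, px) {
  if (!any(nucleus)) return(c(NA_real_, NA_real_))
  idx <- which(nucleus, arr.ind = TRUE)
  c((mean(idx[, 2L]) - 1) * px, (mean(idx[, 1L]) - 1) * px)  # (x, y)
}

#' @export
print.axis_segmentation <- function(x, ...) {
  cat("axis_segmentation:", x$n_components, "skeleton component(s),",
      length(x$skeleton_polylines), "traced polyline(s), total length",
      round(x$length_um, 2), "um\n")
  invisible(x)
}
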