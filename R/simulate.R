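#' Simulation configuration for a synthetic meiocyte nucleus
#'
#' Defines the study conditions under which synthetic chromosome-spread images
#' are generated: a disc-shaped nucleus, a set of smooth curvilinear axis
#' paths (optionally fragmented into short stretches, as in cohesin-defective
#' spreads), diffraction-limited foci planted on the axis with probability
#' `p_on_axis`, a Gaussian point-spread function, Poisson shot noise and
#' Gaussian read noise. Intensities are in camera counts (ADU); the final
#' channels are integer-valued.
#'
#' @param image_size_px integer pair (height, width) in pixels.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param nucleus_radius_um radius of the disc-shaped nucleus, micrometres.
#' @param n_axis_paths number of axis paths.
#' @param axis_path_length_um arc length of each axis path before
#'   fragmentation, micrometres. The default (6 paths of 36 um) gives a total
#'   close to the ~220 um axis of an Arabidopsis leptotene nucleus.
#' @param axis_retained_fraction fraction of axis length retained after
#'   fragmentation into ~`fragment_chunk_um` stretches; 1 keeps paths intact.
#' @param fragment_chunk_um approximate stretch length used when fragmenting.
#' @param n_foci number of planted foci (default anchored to the ~179 foci
#'   regime of wild-type leptotene SPO11-1 staining).
#' @param p_on_axis probability that a planted focus sits on the axis.
#' @param uniform_foci if `TRUE`, ignore `p_on_axis` and place all foci
#'   uniformly in the nucleus (the placement used to calibrate the rotation
#'   null); the `on_axis` flag then records whether a focus happens to fall
#'   within `psf_sigma_um / 2` of an axis path.
#' @param min_focus_separation_um minimum separation between planted foci.
#' @param psf_sigma_um standard deviation of the Gaussian PSF, micrometres.
#' @param focus_amplitude,axis_amplitude,chromatin_amplitude,background_level
#'   photon-scale intensities (counts).
#' @param shot_noise apply Poisson noise to signal + background.
#' @param gaussian_read_noise_sd standard deviation of additive Gaussian read
#'   noise, counts.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return An object of class `sim_config`.
#' @seealso [simulate_nucleus()], [generate_axis_paths()]
#' @export
sim_config <- function(image_size_px = c(1024L, 1024L),
                       pixel_size_um = 0.064,
                       nucleus_radius_um = 12,
                       n_axis_paths = 6L,
                       axis_path_length_um = 36,
                       axis_retained_fraction = 1,
                       fragment_chunk_um = 2,
                       n_foci = 180L,
                       p_on_axis = 0.5,
                       uniform_foci = FALSE,
                       min_focus_separation_um = 0.52,
                       psf_sigma_um = 0.13,
                       focus_amplitude = 200,
                       axis_amplitude = 600,
                       chromatin_amplitude = 60,
                       background_level = 10,
                       shot_noise = TRUE,
                       gaussian_read_noise_sd = 2,
                       seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    nucleus_radius_um = nucleus_radius_um,
    n_axis_paths = as.integer(n_axis_paths),
    axis_path_length_um = axis_path_length_um,
    axis_retained_fraction = axis_retained_fraction,
    fragment_chunk_um = fragment_chunk_um,
    n_foci = as.integer(n_foci),
    p_on_axis = p_on_axis,
    uniform_foci = isTRUE(uniform_foci),
    min_focus_separation_um = min_focus_separation_um,
    psf_sigma_um = psf_sigma_um,
    focus_amplitude = focus_amplitude,
    axis_amplitude = axis_amplitude,
    chromatin_amplitude = chromatin_amplitude,
    background_level = background_level,
    shot_noise = isTRUE(shot_noise),
    gaussian_read_noise_sd = gaussian_read_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$image_size_px) == 2L, all(cfg$image_size_px >= 16L),
    cfg$pixel_size_um > 0, cfg$nucleus_radius_um > 0,
    cfg$n_axis_paths >= 0L, cfg$axis_path_length_um > 0,
    cfg$axis_retained_fraction >= 0, cfg$axis_retained_fraction <= 1,
    cfg$n_foci >= 0L, cfg$p_on_axis >= 0, cfg$p_on_axis <= 1,
    cfg$min_focus_separation_um >= 0, cfg$psf_sigma_um > 0,
    cfg$focus_amplitude >= 0, cfg$axis_amplitude >= 0,
    cfg$chromatin_amplitude >= 0, cfg$background_level >= 0,
    cfg$gaussian_read_noise_sd >= 0
  )
  extent <- (cfg$image_size_px - 1L) * cfg$pixel_size_um
  if (cfg$nucleus_radius_um > min(extent) / 2) {
    stop("nucleus does not fit the image: nucleus_radius_um = ",
         cfg$nucleus_radius_um, " um exceeds half the smaller image extent (",
         signif(min(extent) / 2, 4), " um)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$image_size_px[1L], "x", x$image_size_px[2L], "px @",
      x$pixel_size_um, "um/px\n")
  cat("  nucleus radius", x$nucleus_radius_um, "um;", x$n_axis_paths,
      "axis paths x", x$axis_path_length_um,
      "um (retained fraction", x$axis_retained_fraction, ")\n")
  cat("  ", x$n_foci, " foci, p_on_axis ", x$p_on_axis,
      if (x$uniform_foci) " (uniform placement)", "; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

nucleus_centre_um <- function(cfg) {
  (rev(cfg$image_size_px) - 1L) / 2 * cfg$pixel_size_um  # (x, y)
}

## Fraction of a path's vertices closer than `d` to the vertices of
## previously accepted paths, or to non-neighbouring vertices of itself
## (arc separation > ~1.2 um). Used when re-drawing candidate paths:
## distinct chromosome axes should not run together, and a path folded onto
## itself would merge in the rendered image, making planted length
## ambiguous.
path_overlap_fraction <- function(path, prev_verts, d = 0.3) {
  if (!is.null(prev_verts) && nrow(prev_verts) == 0L) prev_verts <- NULL
  .path_overlap_fraction_cpp(as.matrix(path), prev_verts, d, 12L)
}

## One axis path: a smoothed random walk (AR(1)-correlated heading
## increments, fixed 0.1 um steps) steered back from the nucleus boundary
## and softly repelled by already placed paths and by its own earlier
## vertices, then lightly smoothed, resampled at 0.1 um and trimmed to the
## exact target arc length.
random_axis_path <- function(cfg, centre, blocked = NULL) {
  R <- cfg$nucleus_radius_um
  target <- cfg$axis_path_length_um
  step <- 0.1
  ## heading dynamics: AR(1)-correlated turns; the turn-rate cap keeps the
  ## minimum turning radius ~0.7 um so avoidance arcs never fold the path
  ## back onto itself at the PSF scale
  turn_sd <- 0.10; ar <- 0.95; max_turn <- 0.15
  rep_dist <- min(1.2, 0.12 * R); k_rep <- 1.0; k_bnd <- 1.2
  n_steps <- ceiling(1.35 * target / step)

  ## start away from existing paths
  pos <- NULL
  for (try in seq_len(200L)) {
    r <- 0.8 * R * sqrt(stats::runif(1L))
    th <- stats::runif(1L, 0, 2 * pi)
    cand <- centre + r * c(cos(th), sin(th))
    if (is.null(blocked) || nrow(blocked) == 0L ||
        min_dist_to_vertices(rbind(cand), blocked) > 1.2) {
      pos <- cand; break
    }
  }
  if (is.null(pos)) pos <- centre
  h0 <- stats::runif(1L, 0, 2 * pi)
  ## the stepping itself (with summed soft repulsion, so that a pocket of
  ## surrounding paths pushes the walk back out instead of trapping it) is
  ## compiled; own vertices closer than ~2 um of arc do not repel. The
  ## repulsion field only needs ~0.2 um resolution, so blocked vertices are
  ## subsampled for stepping (candidate acceptance still checks them all).
  blocked_walk <- if (is.null(blocked)) NULL else
    as.matrix(blocked[seq(1L, nrow(blocked), by = 2L), , drop = FALSE])
  out <- .axis_walk_cpp(centre, R, pos, h0, n_steps, blocked_walk,
                        step, turn_sd, ar, max_turn, rep_dist, k_rep,
                        k_bnd, 22L)
  path <- resample_polyline(smooth_polyline(out, half = 3L), 0.1)
  if (polyline_length(path) < target) {
    return(path)  # boundary-trapped walk; slightly short, still valid
  }
  trim_polyline(path, target)
}

## Fragment one path into ~chunk_um stretches and keep a random subset
## totalling approximately `fraction` of its length.
fragment_path <- function(path, fraction, chunk_um) {
  if (fraction >= 1) return(list(path))
  total <- polyline_length(path)
  target <- fraction * total
  if (target <= 0) return(list())
  chunks <- split_polyline_chunks(path, chunk_um)
  ord <- sample.int(length(chunks))
  kept <- list(); kept_len <- 0
  for (k in ord) {
    if (kept_len >= target) break
    kept[[length(kept) + 1L]] <- chunks[[k]]
    kept_len <- kept_len + polyline_length(chunks[[k]])
  }
  kept
}

#' Generate random chromosome-axis paths
#'
#' Draws `n_axis_paths` smooth curvilinear paths inside the nucleus disc
#' (smoothed random walks with soft mutual repulsion, resampled at 0.1 um
#' and standardized to `axis_path_length_um`; distinct axes avoid running
#' together, keeping the planted length unambiguous in the rendered image),
#' then, when `axis_retained_fraction < 1`, fragments each into short
#' stretches and retains a random subset of the stated total length
#' fraction — emulating the short axis stretches of cohesin-defective
#' nuclei.
#'
#' Uses the current R random number generator state; [simulate_nucleus()]
#' seeds it from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List of two-column matrices of (x, y) vertices in micrometres.
#' @export
generate_axis_paths <- function(config) {
  validate_sim_config(config)
  if (config$n_axis_paths == 0L) return(list())
  centre <- nucleus_centre_um(config)
  ## paths are drawn sequentially and re-drawn when they run alongside an
  ## already placed path (or themselves): chromosome axes are distinct
  ## structures, and overlapping paths would also merge in the rendered
  ## image, making planted length ambiguous
  paths <- vector("list", config$n_axis_paths)
  prev <- NULL
  for (i in seq_len(config$n_axis_paths)) {
    best <- NULL; best_ov <- Inf
    for (attempt in seq_len(10L)) {
      cand <- random_axis_path(config, centre, prev)
      ov <- path_overlap_fraction(cand, prev)
      if (ov < best_ov) { best <- cand; best_ov <- ov }
      if (ov <= 0.02) break
    }
    paths[[i]] <- best
    prev <- if (is.null(prev)) best else rbind(prev, best)
  }
  if (config$axis_retained_fraction < 1) {
    paths <- unlist(lapply(paths, fragment_path,
                           fraction = config$axis_retained_fraction,
                           chunk_um = config$fragment_chunk_um),
                    recursive = FALSE)
  }
  paths
}

## Plant focus positions. On-axis foci sit exactly on a random axis point
## (path chosen with probability proportional to its length); off-axis foci
## are uniform in the nucleus at distance > 2 * psf_sigma from every path,
## so planted labels are unambiguous at the PSF scale. A minimum separation
## between foci keeps planted spots resolvable.
plant_foci <- function(cfg, paths, centre, nucleus_mask) {
  n <- cfg$n_foci
  if (n == 0L) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      on_axis = logical(0)))
  }
  verts <- if (length(paths)) do.call(rbind, paths) else NULL
  lens <- vapply(paths, polyline_length, numeric(1))
  have_axis <- length(paths) > 0L && sum(lens) > 0
  R <- cfg$nucleus_radius_um
  sigma <- cfg$psf_sigma_um
  min_sep <- cfg$min_focus_separation_um
  excl <- 2 * sigma + 0.06  # vertex spacing is 0.1 um; margin covers it

  rand_in_disc <- function() {
    r <- 0.98 * R * sqrt(stats::runif(1L))
    th <- stats::runif(1L, 0, 2 * pi)
    c(centre[1L] + r * cos(th), centre[2L] + r * sin(th))
  }
  ## uniform mode samples the whole nucleus mask (not the 0.98 R disc), so
  ## the realized placement matches the per-pixel chance oracle exactly
  rand_in_mask <- function() {
    px <- cfg$pixel_size_um
    repeat {
      r <- R * sqrt(stats::runif(1L))
      th <- stats::runif(1L, 0, 2 * pi)
      p <- c(centre[1L] + r * cos(th), centre[2L] + r * sin(th))
      i <- round(p[2L] / px) + 1L; j <- round(p[1L] / px) + 1L
      if (i >= 1L && i <= nrow(nucleus_mask) && j >= 1L &&
          j <= ncol(nucleus_mask) && nucleus_mask[i, j]) return(p)
    }
  }
  placed <- matrix(numeric(0), ncol = 2L)
  sep_ok <- function(p) {
    nrow(placed) == 0L || min_sep <= 0 ||
      min(sqrt(rowSums((placed - matrix(p, nrow(placed), 2L,
                                        byrow = TRUE))^2))) > min_sep
  }
  on_axis <- logical(n)
  for (i in seq_len(n)) {
    want_on <- !cfg$uniform_foci && have_axis && stats::runif(1L) < cfg$p_on_axis
    p <- NULL
    for (try in seq_len(500L)) {
      if (cfg$uniform_foci) {
        cand <- rand_in_mask()
        if (sep_ok(cand)) {
          p <- cand
          on_axis[i] <- is.finite(d <- min_dist_to_vertices(rbind(cand), verts)) &&
            d <= sigma / 2
          break
        }
      } else if (want_on) {
        k <- sample.int(length(paths), 1L, prob = lens)
        cand <- point_at_arclength(paths[[k]], stats::runif(1L) * lens[k])
        if (sep_ok(cand)) { p <- cand; on_axis[i] <- TRUE; break }
      } else {
        cand <- rand_in_disc()
        if (min_dist_to_vertices(rbind(cand), verts) > excl && sep_ok(cand)) {
          p <- cand; on_axis[i] <- FALSE; break
        }
      }
    }
    if (is.null(p)) stop("could not place focus ", i,
                         ": nucleus too crowded for the requested separation")
    placed <- rbind(placed, p)
  }
  data.frame(x_um = placed[, 1L], y_um = placed[, 2L], on_axis = on_axis)
}

## Rasterize polylines into a binary pixel mask (resampled at half-pixel
## spacing so the drawn line is continuous).
rasterize_polylines <- function(paths, dim_px, pixel_size_um) {
  mask <- matrix(0, dim_px[1L], dim_px[2L])
  for (p in paths) {
    if (nrow(p) < 2L) next
    dense <- resample_polyline(p, pixel_size_um / 2)
    i <- pmin(pmax(round(dense[, 2L] / pixel_size_um) + 1L, 1L), dim_px[1L])
    j <- pmin(pmax(round(dense[, 1L] / pixel_size_um) + 1L, 1L), dim_px[2L])
    mask[cbind(i, j)] <- 1
  }
  mask
}

## Add isotropic Gaussian spots (evaluated in +-4 sigma windows).
add_gaussian_spots <- function(img, foci_xy, amplitude, sigma_px,
                               pixel_size_um) {
  if (nrow(foci_xy) == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma_px)
  for (i in seq_len(nrow(foci_xy))) {
    cj <- foci_xy[i, 1L] / pixel_size_um + 1  # fractional 1-based col
    ci <- foci_xy[i, 2L] / pixel_size_um + 1
    jj <- max(1L, floor(cj - half)):min(w, ceiling(cj + half))
    ii <- max(1L, floor(ci - half)):min(h, ceiling(ci + half))
    if (!length(ii) || !length(jj)) next
    gi <- exp(-((ii - ci)^2) / (2 * sigma_px^2))
    gj <- exp(-((jj - cj)^2) / (2 * sigma_px^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gi, gj)
  }
  img
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_px))
}

## Widefield camera model: Poisson shot noise on signal + background, then
## Gaussian read noise, digitized to integer counts.
apply_camera_noise <- function(signal, cfg) {
  x <- signal + cfg$background_level
  if (cfg$shot_noise) {
    x <- matrix(stats::rpois(length(x), lambda = pmax(x, 0)),
                nrow(signal), ncol(signal))
  }
  if (cfg$gaussian_read_noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, cfg$gaussian_read_noise_sd),
                    nrow(signal), ncol(signal))
  }
  pmax(round(x), 0)
}

#' Simulate a synthetic meiocyte nucleus image with ground truth
#'
#' Generates a three-channel image stack (axis, foci, chromatin) emulating an
#' immunostained chromosome spread, together with the complete ground truth:
#' the planted axis polylines and their total length, every focus position
#' with its on-axis label, and the nucleus mask. Channels are integer camera
#' counts. Two calls with the same configuration are bit-identical.
#'
#' @param config a [sim_config()].
#' @param render if `FALSE`, skip rasterization and return only the ground
#'   truth (fast; used when only planted quantities are needed). The random
#'   draws for paths and foci are unaffected.
#' @param truth optionally, a `ground_truth` from a previous call: the
#'   planted geometry is reused and only the rendering noise is redrawn
#'   (from `config$seed`), giving independent noise realizations of one
#'   ground truth.
#' @return A list with elements `image` (an [image_stack()], `NULL` when
#'   `render = FALSE`) and `truth` (class `ground_truth`).
#' @export
simulate_nucleus <- function(config, render = TRUE, truth = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  dim_px <- config$image_size_px
  px <- config$pixel_size_um
  centre <- nucleus_centre_um(config)

  if (is.null(truth)) {
    xg <- (seq_len(dim_px[2L]) - 1L) * px
    yg <- (seq_len(dim_px[1L]) - 1L) * px
    nucleus_mask <- outer(yg, xg, function(y, x)
      (x - centre[1L])^2 + (y - centre[2L])^2 <= config$nucleus_radius_um^2)

    paths <- generate_axis_paths(config)
    foci <- plant_foci(config, paths, centre, nucleus_mask)

    truth <- structure(list(
      axis_polylines = paths,
      total_axis_length_um = sum(vapply(paths, polyline_length, numeric(1))),
      foci = foci,
      p_on_axis_planted = if (config$uniform_foci) NA_real_
                          else config$p_on_axis,
      nucleus_centroid_um = centre,
      nucleus_mask_reference = nucleus_mask
    ), class = "ground_truth")
  } else {
    stopifnot(inherits(truth, "ground_truth"),
              all(dim(truth$nucleus_mask_reference) == dim_px))
    paths <- truth$axis_polylines
    foci <- truth$foci
    nucleus_mask <- truth$nucleus_mask_reference
  }

  if (!render) return(list(image = NULL, truth = truth))

  sigma_px <- config$psf_sigma_um / px
  axis_sig <- gaussian_blur(
    rasterize_polylines(paths, dim_px, px) * config$axis_amplitude, sigma_px)
  foci_sig <- add_gaussian_spots(matrix(0, dim_px[1L], dim_px[2L]),
                                 as.matrix(foci[, c("x_um", "y_um")]),
                                 config$focus_amplitude, sigma_px, px)
  chrom_sig <- gaussian_blur(nucleus_mask * config$chromatin_amplitude,
                             3 * sigma_px)

  channels <- list(
    axis = apply_camera_noise(axis_sig, config),
    foci = apply_camera_noise(foci_sig, config),
    chromatin = apply_camera_noise(chrom_sig, config)
  )
  list(image = image_stack(channels, px), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$axis_polylines), "axis polylines, total",
      round(x$total_axis_length_um, 2), "um;", nrow(x$foci), "foci (",
      sum(x$foci$on_axis), "on-axis )\n")
  invisible(x)
}
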