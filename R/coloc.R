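## Object-based colocalization of foci with the chromosome axis.
##
## Each focus is scored either by the cross-section line-profile rule (is
## there above-threshold axis signal within one focus radius of the focus
## centre along a horizontal section through it?) or by the oracle-friendly
## distance rule (is the focus centroid within d_max of the axis skeleton?).
## The chance baseline is the 180-degree rotation randomization: focus
## positions are point-reflected through the nucleus centroid and re-scored
## against the unrotated axis.

#' Colocalization scoring parameters
#'
#' @param criterion `"profile"` (cross-section line profile, the default) or
#'   `"distance"` (centroid-to-skeleton distance).
#' @param section_halfwidth_px half-width of the horizontal cross-section
#'   used by the profile criterion, pixels.
#' @param d_max_um overlap tolerance of the distance criterion (default
#'   `2 * psf_sigma_um`).
#' @param axis_threshold axis-presence intensity threshold (counts) for the
#'   profile criterion; computed by [axis_presence_threshold()] (Otsu inside
#'   the nucleus) when `NULL`.
#' @param psf_sigma_um PSF scale, used for defaults.
#' @return A list of class `coloc_params`.
#' @export
coloc_params <- function(criterion = c("profile", "distance"),
                         section_halfwidth_px = 10L,
                         d_max_um = NULL, axis_threshold = NULL,
                         psf_sigma_um = 0.13) {
  criterion <- match.arg(criterion)
  if (is.null(d_max_um)) d_max_um <- 2 * psf_sigma_um
  structure(list(criterion = criterion,
                 section_halfwidth_px = as.integer(section_halfwidth_px),
                 d_max_um = d_max_um, axis_threshold = axis_threshold,
                 psf_sigma_um = psf_sigma_um),
            class = "coloc_params")
}

#' Axis-presence intensity threshold
#'
#' Otsu threshold of the axis channel restricted to the nucleus mask, on the
#' original intensity scale. Profile overlap calls count axis signal above
#' this threshold as axis presence.
#'
#' @param stack an [image_stack()].
#' @param seg an [segment_axis()] result (for the nucleus mask).
#' @param channel axis channel name.
#' @return Scalar threshold in counts.
#' @export
axis_presence_threshold <- function(stack, seg, channel = "axis") {
  img <- get_channel(stack, channel)
  v <- img[seg$nucleus_mask]
  if (!length(v) || max(v) <= min(v)) return(Inf)
  nm <- (v - min(v)) / (max(v) - min(v))
  t <- EBImage::otsu(EBImage::Image(matrix(nm, ncol = 1L)))
  min(v) + t * (max(v) - min(v))
}

focus_pixel <- function(x_um, y_um, px, dim_hw) {
  i <- round(y_um / px) + 1L
  j <- round(x_um / px) + 1L
  if (i < 1L || i > dim_hw[1L] || j < 1L || j > dim_hw[2L]) {
    stop("focus at (", x_um, ", ", y_um, ") um lies outside the image")
  }
  c(i, j)
}

## Score one focus position. Returns a one-row data frame (a ColocCall).
score_one_focus <- function(x_um, y_um, radius_um, axis_img, seg, params) {
  px <- seg$pixel_size_um
  ij <- focus_pixel(x_um, y_um, px, dim(axis_img))
  i <- ij[1L]; j <- ij[2L]
  dist_um <- seg$dist_to_skeleton_px[i, j] * px
  if (is.na(radius_um) || !is.finite(radius_um)) {
    radius_um <- 2 * params$psf_sigma_um
  }
  if (params$criterion == "distance") {
    overlaps <- is.finite(dist_um) && dist_um <= params$d_max_um
  } else {
    w <- params$section_halfwidth_px
    jj <- max(1L, j - w):min(ncol(axis_img), j + w)
    profile <- axis_img[i, jj]
    within <- abs((jj - 1L) * px - x_um) <= radius_um
    overlaps <- any(profile[within] >= params$axis_threshold)
  }
  data.frame(x_um = x_um, y_um = y_um, overlaps = overlaps,
             axis_signal_at_focus = axis_img[i, j],
             distance_to_skeleton_um = dist_um,
             criterion = params$criterion)
}

#' Score all foci of a nucleus for overlap with the axis
#'
#' Applies the configured overlap criterion to every focus. Foci falling
#' outside the nucleus mask are flagged (`in_nucleus = FALSE`) and excluded
#' from scoring (their `overlaps` is `NA`).
#'
#' @param foci a `focus_set` (from [detect_foci()]) or a data frame with
#'   columns `x_um`, `y_um` and optionally `radius_um`.
#' @param stack an [image_stack()] (axis channel is read from it).
#' @param seg an [segment_axis()] result.
#' @param params a [coloc_params()].
#' @param channel axis channel name.
#' @return Data frame of per-focus calls with columns `focus_index`, `x_um`,
#'   `y_um`, `in_nucleus`, `overlaps`, `axis_signal_at_focus`,
#'   `distance_to_skeleton_um`, `criterion`.
#' @export
score_foci <- function(foci, stack, seg, params = coloc_params(),
                       channel = "axis") {
  df <- if (inherits(foci, "focus_set")) foci$foci else as.data.frame(foci)
  if (!all(c("x_um", "y_um") %in% names(df))) {
    stop("foci must have columns x_um and y_um")
  }
  if (!"radius_um" %in% names(df)) df$radius_um <- NA_real_
  axis_img <- get_channel(stack, channel)
  if (is.null(params$axis_threshold) && params$criterion == "profile") {
    params$axis_threshold <- axis_presence_threshold(stack, seg, channel)
  }
  px <- seg$pixel_size_um
  n <- nrow(df)
  i <- round(df$y_um / px) + 1L
  j <- round(df$x_um / px) + 1L
  bad <- i < 1L | i > nrow(axis_img) | j < 1L | j > ncol(axis_img)
  if (any(bad)) {
    stop("focus at (", df$x_um[which(bad)[1L]], ", ",
         df$y_um[which(bad)[1L]], ") um lies outside the image")
  }
  ij <- cbind(i, j)
  in_nucleus <- seg$nucleus_mask[ij]
  dist_um <- seg$dist_to_skeleton_px[ij] * px
  radius <- ifelse(is.finite(df$radius_um), df$radius_um,
                   2 * params$psf_sigma_um)
  overlaps <- rep(NA, n)
  if (params$criterion == "distance") {
    overlaps[in_nucleus] <- is.finite(dist_um[in_nucleus]) &
      dist_um[in_nucleus] <= params$d_max_um
  } else {
    w <- params$section_halfwidth_px
    for (k in which(in_nucleus)) {
      jj <- max(1L, j[k] - w):min(ncol(axis_img), j[k] + w)
      within <- abs((jj - 1L) * px - df$x_um[k]) <= radius[k]
      overlaps[k] <- any(axis_img[i[k], jj][within] >= params$axis_threshold)
    }
  }
  data.frame(focus_index = seq_len(n), x_um = df$x_um, y_um = df$y_um,
             in_nucleus = in_nucleus, overlaps = overlaps,
             axis_signal_at_focus = axis_img[ij],
             distance_to_skeleton_um = dist_um,
             criterion = params$criterion)
}

#' Single-focus profile overlap call
#'
#' Cross-section line-profile rule for one focus: the axis-channel intensity
#' along a horizontal section of half-width `section_halfwidth_px` through
#' the focus centroid is compared against the axis-presence threshold; the
#' focus overlaps if above-threshold signal occurs within one focus radius
#' of its centre along the section.
#'
#' @inheritParams score_foci
#' @param focus a one-row data frame or list with `x_um`, `y_um` and
#'   optionally `radius_um`.
#' @return One-row data frame (the colocalization call).
#' @export
profile_overlap <- function(focus, stack, seg, params = coloc_params(),
                            channel = "axis") {
  params$criterion <- "profile"
  if (is.null(params$axis_threshold)) {
    params$axis_threshold <- axis_presence_threshold(stack, seg, channel)
  }
  score_one_focus(focus$x_um, focus$y_um,
                  if ("radius_um" %in% names(focus)) focus$radius_um
                  else NA_real_,
                  get_channel(stack, channel), seg, params)
}

#' 180-degree rotation randomization null
#'
#' Each focus position is mapped by the exact point reflection through the
#' (pixel-rounded) nucleus centroid; reflected positions falling outside the
#' nucleus mask are discarded and counted; the overlap criterion is re-run on
#' the surviving positions against the unrotated axis.
#'
#' @inheritParams score_foci
#' @return List with `random_overlap_fraction`, `n_discarded`, and the
#'   per-focus `calls` for the surviving rotated positions.
#' @export
rotation_null <- function(foci, stack, seg, params = coloc_params(),
                          channel = "axis") {
  df <- if (inherits(foci, "focus_set")) foci$foci else as.data.frame(foci)
  if (nrow(df) == 0L) stop("no foci to rotate")
  px <- seg$pixel_size_um
  ## reflection centre: the nucleus centroid rounded to a pixel centre, so
  ## the reflection maps the pixel grid onto itself exactly
  c0 <- round(seg$nucleus_centroid_um / px) * px
  rx <- 2 * c0[1L] - df$x_um
  ry <- 2 * c0[2L] - df$y_um
  h <- nrow(seg$nucleus_mask); w <- ncol(seg$nucleus_mask)
  i <- round(ry / px) + 1L
  j <- round(rx / px) + 1L
  inside <- i >= 1L & i <= h & j >= 1L & j <= w
  inside[inside] <- seg$nucleus_mask[cbind(i[inside], j[inside])]
  n_discarded <- sum(!inside)
  if (!any(inside)) {
    return(list(random_overlap_fraction = NA_real_,
                n_discarded = n_discarded, calls = NULL))
  }
  rot <- data.frame(x_um = rx[inside], y_um = ry[inside],
                    radius_um = if ("radius_um" %in% names(df))
                      df$radius_um[inside] else NA_real_)
  calls <- score_foci(rot, stack, seg, params, channel)
  list(random_overlap_fraction = mean(calls$overlaps, na.rm = TRUE),
       n_discarded = n_discarded, calls = calls)
}

#' Chance overlap level from the segmentation masks
#'
#' The probability that a randomly placed focus overlaps the axis under the
#' distance criterion: the fraction of nucleus pixels within `d_max_um` of
#' the axis skeleton. `exclude_um > 0` conditions the placement on staying
#' farther than that distance from the skeleton (the placement null of a
#' simulation whose off-axis foci avoid the axis neighbourhood); with the
#' default 0 the plain area fraction is returned, appropriate for uniform
#' placement and for real data.
#'
#' @param seg an [segment_axis()] result.
#' @param d_max_um overlap tolerance (default `2 * psf_sigma_um` of the
#'   segmentation parameters).
#' @param exclude_um placement exclusion distance (see above).
#' @return Scalar chance overlap fraction.
#' @export
chance_overlap_fraction <- function(seg, d_max_um = NULL, exclude_um = 0) {
  if (is.null(d_max_um)) d_max_um <- 2 * seg$params$psf_sigma_um
  d <- seg$dist_to_skeleton_px * seg$pixel_size_um
  elig <- if (exclude_um > 0) seg$nucleus_mask & d > exclude_um
          else seg$nucleus_mask
  if (!any(elig)) return(NA_real_)
  sum(elig & d <= d_max_um) / sum(elig)
}

#' Chance-corrected on-axis fraction
#'
#' Corrects an observed overlap fraction for chance overlap:
#' `(observed - chance) / (1 - chance)` — the estimated fraction of foci
#' genuinely placed on the axis when off-axis foci overlap by chance at rate
#' `chance` (e.g. the rotation-null fraction or
#' [chance_overlap_fraction()]).
#'
#' @param observed observed overlap fraction.
#' @param chance chance overlap level in `[0, 1)`.
#' @return Corrected fraction (may fall slightly outside `[0, 1]` by
#'   sampling noise).
#' @export
corrected_overlap_fraction <- function(observed, chance) {
  stopifnot(chance < 1)
  (observed - chance) / (1 - chance)
}

#' Per-nucleus summary of focus counts, overlap and axis density
#'
#' @param calls per-focus calls from [score_foci()].
#' @param seg an [segment_axis()] result.
#' @param null_result optional result of [rotation_null()].
#' @param group_label,stage_label free-text labels carried through to group
#'   statistics (e.g. genotype and meiotic stage).
#' @return An object of class `nucleus_result` (also a one-row data frame
#'   via [as.data.frame()]): `n_foci` (foci inside the nucleus),
#'   `n_overlapping`, `overlap_fraction` (NA when `n_foci` is 0),
#'   `random_overlap_fraction`, `n_random_discarded`, `axis_length_um`,
#'   `on_axis_density_per_um` (overlapping foci per micrometre of axis; 0
#'   when there are no foci, NA when there is no axis).
#' @export
nucleus_summary <- function(calls, seg, null_result = NULL,
                            group_label = "", stage_label = "") {
  scored <- calls[calls$in_nucleus, , drop = FALSE]
  n_foci <- nrow(scored)
  n_overlapping <- sum(scored$overlaps, na.rm = TRUE)
  axis_len <- seg$length_um
  if (axis_len <= 0 && n_overlapping > 0) {
    stop("inconsistent nucleus: ", n_overlapping,
         " overlapping foci but axis length 0")
  }
  density <- if (n_foci == 0L) 0
             else if (axis_len > 0) n_overlapping / axis_len
             else NA_real_
  structure(list(
    n_foci = n_foci,
    n_overlapping = n_overlapping,
    overlap_fraction = if (n_foci > 0L) n_overlapping / n_foci else NA_real_,
    random_overlap_fraction =
      if (!is.null(null_result)) null_result$random_overlap_fraction
      else NA_real_,
    n_random_discarded =
      if (!is.null(null_result)) null_result$n_discarded else NA_integer_,
    axis_length_um = axis_len,
    on_axis_density_per_um = density,
    group_label = group_label,
    stage_label = stage_label
  ), class = "nucleus_result")
}

#' @export
as.data.frame.nucleus_result <- function(x, ...) {
  data.frame(n_foci = x$n_foci, n_overlapping = x$n_overlapping,
             overlap_fraction = x$overlap_fraction,
             random_overlap_fraction = x$random_overlap_fraction,
             n_random_discarded = x$n_random_discarded,
             axis_length_um = x$axis_length_um,
             on_axis_density_per_um = x$on_axis_density_per_um,
             group_label = x$group_label, stage_label = x$stage_label,
             stringsAsFactors = FALSE)
}

#' @export
print.nucleus_result <- function(x, ...) {
  cat("nucleus_result:", x$n_foci, "foci,", x$n_overlapping,
      "overlapping (fraction", signif(x$overlap_fraction, 3),
      "; null", signif(x$random_overlap_fraction, 3), ")\n")
  cat("  axis", round(x$axis_length_um, 2), "um; on-axis density",
      signif(x$on_axis_density_per_um, 3), "foci/um\n")
  invisible(x)
}
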