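## Shared fixtures and independent oracles for the test suite.

## Compact simulation used by most unit tests: 256 px (16.3 um field),
## 7 um nucleus, three 25 um axis paths, 60 foci.
small_config <- function(seed = 1L, ...) {
  defaults <- list(image_size_px = c(256L, 256L), nucleus_radius_um = 7,
                   n_axis_paths = 3L, axis_path_length_um = 25,
                   n_foci = 60L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## The 512 px configuration matching the main simulated study conditions
## (12 um nucleus, 6 x 36 um axis, ~150 foci).
study_config <- function(seed = 1L, ...) {
  defaults <- list(image_size_px = c(512L, 512L), seed = seed, n_foci = 150L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## Independent polyline length (plain cumulative segment sum, written apart
## from the package's implementation).
oracle_polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  dx <- xy[-1L, 1L] - xy[-nrow(xy), 1L]
  dy <- xy[-1L, 2L] - xy[-nrow(xy), 2L]
  sum(sqrt(dx^2 + dy^2))
}

## Independent minimum distance from points to a set of polylines, via
## dense resampling of each polyline.
oracle_dist_to_paths <- function(pts, paths, ds = 0.02) {
  verts <- do.call(rbind, lapply(paths, function(p) {
    if (nrow(p) < 2L) return(p)
    seg <- sqrt(rowSums(diff(p)^2)); s <- c(0, cumsum(seg))
    ss <- seq(0, s[length(s)], by = ds)
    cbind(approx(s, p[, 1L], xout = ss)$y, approx(s, p[, 2L], xout = ss)$y)
  }))
  apply(pts, 1L, function(q)
    min(sqrt((verts[, 1L] - q[1L])^2 + (verts[, 2L] - q[2L])^2)))
}

## Brute-force bipartite nearest-neighbour matching between detected and
## true points: repeatedly match the globally closest unmatched pair within
## `tol`. Returns the number of matched pairs.
oracle_match_count <- function(detected, truth, tol) {
  if (nrow(detected) == 0L || nrow(truth) == 0L) return(0L)
  d <- sqrt(outer(detected[, 1L], truth[, 1L], "-")^2 +
            outer(detected[, 2L], truth[, 2L], "-")^2)
  n <- 0L
  while (TRUE) {
    m <- which.min(d)
    if (!length(m) || d[m] > tol) break
    ij <- arrayInd(m, dim(d))
    d[ij[1L], ] <- Inf; d[, ij[2L]] <- Inf
    n <- n + 1L
  }
  n
}

## Brute-force two-sided Mann-Whitney-Wilcoxon p-value by full enumeration:
## every split of the combined sample is scored by directly counting pairs.
oracle_mww <- function(a, b) {
  comb <- c(a, b)
  n <- length(comb); n_a <- length(a)
  u_of <- function(xs, ys) {
    u <- 0
    for (x in xs) for (y in ys) {
      u <- u + (x > y) + 0.5 * (x == y)
    }
    u
  }
  u_obs <- u_of(a, b)
  mu <- n_a * (n - n_a) / 2
  splits <- utils::combn(n, n_a)
  u_all <- apply(splits, 2L, function(ii) u_of(comb[ii], comb[-ii]))
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

## Closed-form exact binomial two-sided interval for a pooled proportion.
oracle_binom_interval <- function(n, p, level = 0.95) {
  alpha <- 1 - level
  c(qbinom(alpha / 2, n, p), qbinom(1 - alpha / 2, n, p)) / n
}

## A minimal synthetic stack built directly from matrices (bypassing the
## simulator): a disc-shaped chromatin channel plus caller-provided axis
## and foci channels.
manual_stack <- function(axis, foci = NULL, px = 0.064, radius_um = NULL) {
  h <- nrow(axis); w <- ncol(axis)
  if (is.null(radius_um)) radius_um <- 0.45 * (min(h, w) - 1L) * px
  cx <- (w - 1L) / 2 * px; cy <- (h - 1L) / 2 * px
  xg <- (seq_len(w) - 1L) * px; yg <- (seq_len(h) - 1L) * px
  disc <- outer(yg, xg, function(y, x) (x - cx)^2 + (y - cy)^2 <= radius_um^2)
  chrom <- round(meiofoci:::gaussian_blur(disc * 60, 6) + 10)
  if (is.null(foci)) foci <- matrix(10, h, w)
  image_stack(list(axis = round(axis), foci = round(foci),
                   chromatin = chrom), px)
}

## Draw a straight horizontal line of given length into a blank axis
## channel (blurred to PSF width), returning the stack.
line_stack <- function(length_um, row_frac = 0.5, px = 0.064,
                       dim_px = c(256L, 256L), amplitude = 600,
                       x0_um = NULL) {
  axis <- matrix(0, dim_px[1L], dim_px[2L])
  r <- round(row_frac * dim_px[1L])
  extent <- (dim_px[2L] - 1L) * px
  if (is.null(x0_um)) x0_um <- (extent - length_um) / 2
  j0 <- round(x0_um / px) + 1L
  j1 <- round((x0_um + length_um) / px) + 1L
  axis[r, j0:j1] <- 1
  axis <- meiofoci:::gaussian_blur(axis * amplitude, 0.13 / px) + 10
  manual_stack(axis, px = px)
}
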