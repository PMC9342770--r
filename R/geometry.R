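#' Polyline arc length
#'
#' Total length of an ordered (x, y) vertex sequence, in the units of the
#' coordinates (micrometres throughout this package).
#'
#' @param xy two-column numeric matrix of ordered vertices.
#' @return Non-negative scalar length.
#' @export
polyline_length <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Resample a polyline at (approximately) uniform arc-length spacing
#'
#' @param xy two-column matrix of vertices.
#' @param spacing target spacing between resampled vertices.
#' @return Two-column matrix; endpoints are preserved.
#' @export
resample_polyline <- function(xy, spacing) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) return(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(xy[1L, , drop = FALSE])
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  cbind(
    stats::approx(s, xy[, 1L], xout = s_out, ties = "ordered")$y,
    stats::approx(s, xy[, 2L], xout = s_out, ties = "ordered")$y
  )
}

## Point at arc length s along the polyline (s clamped to [0, L]).
point_at_arclength <- function(xy, s_query) {
  xy <- as.matrix(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  s_query <- pmin(pmax(s_query, 0), s[length(s)])
  c(
    stats::approx(s, xy[, 1L], xout = s_query, ties = "ordered")$y,
    stats::approx(s, xy[, 2L], xout = s_query, ties = "ordered")$y
  )
}

## Trim a polyline to a target arc length measured from its first vertex.
trim_polyline <- function(xy, target_length) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) return(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= target_length) return(xy)
  keep <- s < target_length
  last <- point_at_arclength(xy, target_length)
  rbind(xy[keep, , drop = FALSE], last)
}

## Minimum distance from each query point to any vertex of a vertex cloud.
## Vertices are densely spaced (<= 0.1 um) so the vertex cloud stands in for
## the continuous curve to within half the vertex spacing.
min_dist_to_vertices <- function(points, vertices) {
  points <- as.matrix(points)
  if (is.null(vertices) || nrow(vertices) == 0L) {
    return(rep(Inf, nrow(points)))
  }
  .min_dist_to_vertices_cpp(points, as.matrix(vertices))
}

## Split a polyline into consecutive chunks of ~chunk_length arc length.
split_polyline_chunks <- function(xy, chunk_length) {
  xy <- as.matrix(xy)
  total <- polyline_length(xy)
  if (total <= chunk_length) return(list(xy))
  n_chunks <- max(1L, round(total / chunk_length))
  cuts <- seq(0, total, length.out = n_chunks + 1L)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  out <- vector("list", n_chunks)
  for (k in seq_len(n_chunks)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    inner <- which(s > a & s < b)
    pts <- rbind(
      point_at_arclength(xy, a),
      xy[inner, , drop = FALSE],
      point_at_arclength(xy, b)
    )
    out[[k]] <- pts
  }
  out
}
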