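## Skeletonization and skeleton geometry.
##
## A binary mask is thinned to a one-pixel-wide 8-connected skeleton
## (Guo-Hall, in C++), short spur branches are pruned, and the skeleton is
## decomposed into polylines by walking the pixel adjacency graph. Length is
## measured on lightly smoothed polylines (moving average of vertex
## coordinates, endpoints kept), which removes the positive staircase bias
## of raw 1 / sqrt(2) chain-step sums on smooth curves; the raw chain length
## is retained for comparison.

## Build the skeleton pixel graph. Diagonal adjacencies that short-cut an
## existing orthogonal 2-step path are dropped so the graph is free of
## triangles and path tracing is unambiguous.
skeleton_graph <- function(skel) {
  pix <- which(skel > 0, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0L) {
    return(list(pix = pix, edges = matrix(integer(0), 0, 2L),
                adj = list(), deg = integer(0)))
  }
  idm <- matrix(0L, nrow(skel), ncol(skel))
  idm[pix] <- seq_len(n)
  h <- nrow(skel); w <- ncol(skel)
  at <- function(r, c) {
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    out <- integer(length(r)); out[ok] <- idm[cbind(r[ok], c[ok])]
    out
  }
  r <- pix[, 1L]; c <- pix[, 2L]
  e <- list()
  add_edges <- function(nb, keep = TRUE) {
    sel <- nb > 0L & keep
    if (any(sel)) cbind(seq_len(n)[sel], nb[sel]) else NULL
  }
  e[[1L]] <- add_edges(at(r + 1L, c))            # down
  e[[2L]] <- add_edges(at(r, c + 1L))            # right
  dr <- at(r + 1L, c + 1L)                       # down-right diagonal
  e[[3L]] <- add_edges(dr, !(at(r, c + 1L) > 0L | at(r + 1L, c) > 0L))
  dl <- at(r + 1L, c - 1L)                       # down-left diagonal
  e[[4L]] <- add_edges(dl, !(at(r, c - 1L) > 0L | at(r + 1L, c) > 0L))
  edges <- do.call(rbind, e)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2L)
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      adj[[a]] <- c(adj[[a]], k)
      adj[[b]] <- c(adj[[b]], k)
    }
  }
  deg <- lengths(adj)
  list(pix = pix, edges = edges, adj = adj, deg = deg)
}

edge_other <- function(edges, k, v) {
  a <- edges[k, 1L]
  if (a == v) edges[k, 2L] else a
}

## Walk from vertex v along edge k until a vertex of degree != 2 (or until
## the walk closes on itself). Returns the visited vertex and edge sequences.
walk_branch <- function(g, v, k) {
  verts <- v; eds <- integer(0)
  cur <- v; ek <- k
  repeat {
    nxt <- edge_other(g$edges, ek, cur)
    verts <- c(verts, nxt); eds <- c(eds, ek)
    if (g$deg[nxt] != 2L || nxt == verts[1L]) break
    ek <- setdiff(g$adj[[nxt]], ek)[1L]
    cur <- nxt
  }
  list(verts = verts, edges = eds)
}

branch_length_px <- function(g, verts) {
  p <- g$pix[verts, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

## Remove spur branches (endpoint-to-junction) shorter than prune_px, and
## isolated components shorter than prune_px, iterating until stable.
prune_skeleton <- function(skel, prune_px) {
  if (prune_px <= 0) return(skel)
  repeat {
    g <- skeleton_graph(skel)
    if (nrow(g$pix) == 0L) return(skel)
    ends <- which(g$deg == 1L)
    removed <- FALSE
    drop_pix <- integer(0)
    for (v in ends) {
      if (v %in% drop_pix) next
      br <- walk_branch(g, v, g$adj[[v]][1L])
      if (branch_length_px(g, br$verts) >= prune_px) next
      tail_v <- br$verts[length(br$verts)]
      drop <- if (g$deg[tail_v] >= 3L) br$verts[-length(br$verts)] else br$verts
      drop_pix <- c(drop_pix, drop)
      removed <- TRUE
    }
    iso <- which(g$deg == 0L)  # single-pixel specks
    if (length(iso)) { drop_pix <- c(drop_pix, iso); removed <- TRUE }
    if (!removed) return(skel)
    skel[g$pix[unique(drop_pix), , drop = FALSE]] <- 0L
  }
}

## Moving-average smoothing of polyline vertices (window 2*half+1), with the
## endpoints kept fixed.
smooth_polyline <- function(xy, half = 2L) {
  n <- nrow(xy)
  if (n <= 2L * half) return(xy)
  sm <- xy
  for (d in 1:2) {
    cs <- c(0, cumsum(xy[, d]))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm[, d] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  sm[1L, ] <- xy[1L, ]; sm[n, ] <- xy[n, ]
  sm
}

## Thin a binary mask, prune spurs, and decompose into measured polylines.
## Returns skeleton raster, polylines in micrometres, smoothed length and
## raw chain length.
skeletonize_mask <- function(mask, pixel_size_um, prune_um = 0.5) {
  storage.mode(mask) <- "integer"
  skel <- .guo_hall_thin(mask)
  skel <- prune_skeleton(skel, prune_px = prune_um / pixel_size_um)
  g <- skeleton_graph(skel)
  polylines <- list()
  if (nrow(g$pix)) {
    used <- rep(FALSE, nrow(g$edges))
    terminals <- which(g$deg != 2L & g$deg > 0L)
    emit <- function(verts) {
      xy <- cbind((g$pix[verts, 2L] - 1L) * pixel_size_um,
                  (g$pix[verts, 1L] - 1L) * pixel_size_um)
      polylines[[length(polylines) + 1L]] <<- xy
    }
    for (v in terminals) {
      for (k in g$adj[[v]]) {
        if (used[k]) next
        br <- walk_branch(g, v, k)
        used[br$edges] <- TRUE
        emit(br$verts)
      }
    }
    ## closed loops: every vertex has degree 2
    for (k in which(!used)) {
      if (used[k]) next
      br <- walk_branch(g, g$edges[k, 1L], k)
      used[br$edges] <- TRUE
      emit(br$verts)
    }
  }
  smoothed <- lapply(polylines, smooth_polyline)
  list(
    skeleton = skel,
    polylines = smoothed,
    length_um = sum(vapply(smoothed, polyline_length, numeric(1))),
    chain_length_um = sum(vapply(polylines, polyline_length, numeric(1))),
    n_components = count_components(g)
  )
}

## connected components of the (8-connected) skeleton pixel graph
count_components <- function(g) {
  n <- nrow(g$pix)
  if (n == 0L) return(0L)
  comp <- integer(n)
  n_comp <- 0L
  for (v0 in seq_len(n)) {
    if (comp[v0] > 0L) next
    n_comp <- n_comp + 1L
    queue <- v0
    comp[v0] <- n_comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (k in g$adj[[v]]) {
        w <- edge_other(g$edges, k, v)
        if (comp[w] == 0L) { comp[w] <- n_comp; queue <- c(queue, w) }
      }
    }
  }
  n_comp
}
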