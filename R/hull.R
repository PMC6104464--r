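# Minimal 3D convex hull (quickhull) over voxel centers, used only for
# solidity. Returns the hull as half-spaces so that point-membership tests
# vectorize over query points. Planar voxel sets (single-slice masks) are
# handled by a 2D hull in their plane; collinear sets degenerate and the
# caller falls back.

.hull_eps <- function(P) 1e-7 * max(1, max(abs(P)))

# Half-space representation {normals (f x 3), offsets (f)} of conv(P), with
# outward normals: x inside iff normals %*% x <= offsets (+tol).
# Returns NULL when the points have no 3D extent.
convex_hull_3d <- function(P) {
  P <- unique(round(P, 9))
  n <- nrow(P)
  if (n < 4) return(NULL)
  eps <- .hull_eps(P)
  # initial simplex: two extreme points, farthest-from-line, farthest-from-plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (max(abs(P[i1, ] - P[i2, ])) < eps) {
    rng <- apply(P, 2, function(c) diff(range(c)))
    ax <- which.max(rng)
    i1 <- which.min(P[, ax]); i2 <- which.max(P[, ax])
  }
  a <- P[i1, ]; b <- P[i2, ]
  ab <- b - a
  d_line <- sqrt(rowSums((P - matrix(a, n, 3, byrow = TRUE) -
    outer(drop((P - matrix(a, n, 3, byrow = TRUE)) %*% ab) / sum(ab^2), ab))^2))
  i3 <- which.max(d_line)
  if (d_line[i3] < eps) return(NULL)  # collinear
  c_ <- P[i3, ]
  nrm <- .cross(b - a, c_ - a)
  d_plane <- abs(drop((P - matrix(a, n, 3, byrow = TRUE)) %*% nrm)) /
    sqrt(sum(nrm^2))
  i4 <- which.max(d_plane)
  if (d_plane[i4] < eps) return(NULL)  # coplanar
  d_ <- P[i4, ]
  centroid <- (a + b + c_ + d_) / 4
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  mk_facet <- function(tri) {
    v <- P[tri, , drop = FALSE]
    nn <- .cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
    len <- sqrt(sum(nn^2))
    if (len < 1e-14) return(NULL)
    nn <- nn / len
    off <- sum(nn * v[1, ])
    if (sum(nn * centroid) > off) { nn <- -nn; off <- -off; tri <- tri[c(1, 3, 2)] }
    list(tri = tri, normal = nn, offset = off)
  }
  facets <- lapply(faces, mk_facet)
  # assign points to the facet they are outside of
  alive <- rep(TRUE, length(facets))
  outside <- vector("list", length(facets))
  assign_pts <- function(f_ids, pts_idx) {
    for (fi in f_ids) {
      if (!length(pts_idx)) break
      f <- facets[[fi]]
      dist <- drop(P[pts_idx, , drop = FALSE] %*% f$normal) - f$offset
      sel <- dist > eps
      if (any(sel)) {
        outside[[fi]] <<- rbind(outside[[fi]],
                                cbind(pts_idx[sel], dist[sel]))
        pts_idx <- pts_idx[!sel]
      }
    }
    invisible(NULL)
  }
  assign_pts(seq_along(facets), seq_len(n))
  repeat {
    fi <- which(alive & vapply(outside, function(o) !is.null(o) && nrow(o) > 0,
                               logical(1)))
    if (!length(fi)) break
    fi <- fi[1]
    o <- outside[[fi]]
    p_idx <- o[which.max(o[, 2]), 1]
    p <- P[p_idx, ]
    # visible facets
    vis <- which(alive & vapply(seq_along(facets), function(k) {
      alive[k] && sum(facets[[k]]$normal * p) - facets[[k]]$offset > eps
    }, logical(1)))
    # horizon edges: edges of visible facets shared with no other visible facet
    edge_key <- function(u, v) paste(min(u, v), max(u, v))
    ecount <- new.env()
    edir <- new.env()
    for (k in vis) {
      tri <- facets[[k]]$tri
      for (e in list(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])) {
        key <- edge_key(e[1], e[2])
        cnt <- mget(key, envir = ecount, ifnotfound = 0)[[1]]
        assign(key, cnt + 1, envir = ecount)
        assign(key, e, envir = edir)
      }
    }
    horizon <- list()
    for (key in ls(ecount)) {
      if (get(key, envir = ecount) == 1) {
        horizon[[length(horizon) + 1]] <- get(key, envir = edir)
      }
    }
    cand <- unique(c(unlist(lapply(vis, function(k) outside[[k]][, 1])),
                     integer(0)))
    cand <- setdiff(cand, p_idx)
    for (k in vis) { alive[k] <- FALSE; outside[k] <- list(NULL) }
    new_ids <- integer(0)
    for (e in horizon) {
      f <- mk_facet(c(e[1], e[2], p_idx))
      if (is.null(f)) next
      # orient outward: every remaining point should be behind; use centroid
      facets[[length(facets) + 1]] <- f
      alive[length(facets)] <- TRUE
      outside[length(facets)] <- list(NULL)
      new_ids <- c(new_ids, length(facets))
    }
    if (length(cand)) assign_pts(new_ids, cand)
  }
  keep <- which(alive)
  list(normals = do.call(rbind, lapply(facets[keep], `[[`, "normal")),
       offsets = vapply(facets[keep], `[[`, numeric(1), "offset"))
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Inclusive membership of query points Q in a hull from convex_hull_3d().
in_hull_3d <- function(hull, Q, tol = 1e-9) {
  tol <- tol * max(1, max(abs(Q)))
  d <- Q %*% t(hull$normals) -
    matrix(hull$offsets, nrow(Q), length(hull$offsets), byrow = TRUE)
  rowSums(d > tol) == 0
}

# 2D convex-polygon membership for planar voxel sets: P and Q are 2D coords.
in_hull_2d <- function(P, Q, tol = 1e-9) {
  P <- unique(round(P, 9))
  h <- grDevices::chull(P)
  V <- P[h, , drop = FALSE]  # counter-clockwise or clockwise polygon
  m <- nrow(V)
  if (m < 3) {
    # collinear: inclusive segment test
    d <- V[m, ] - V[1, ]
    t_ <- ((Q[, 1] - V[1, 1]) * d[1] + (Q[, 2] - V[1, 2]) * d[2]) / sum(d^2)
    perp <- abs((Q[, 1] - V[1, 1]) * d[2] - (Q[, 2] - V[1, 2]) * d[1])
    return(perp < tol & t_ >= -tol & t_ <= 1 + tol)
  }
  tol <- tol * max(1, max(abs(P)))
  inside <- rep(TRUE, nrow(Q))
  # orientation sign of the polygon
  or_sign <- sign(sum(vapply(seq_len(m), function(i) {
    j <- i %% m + 1
    V[i, 1] * V[j, 2] - V[j, 1] * V[i, 2]
  }, numeric(1))))
  for (i in seq_len(m)) {
    j <- i %% m + 1
    cr <- (V[j, 1] - V[i, 1]) * (Q[, 2] - V[i, 2]) -
      (V[j, 2] - V[i, 2]) * (Q[, 1] - V[i, 1])
    inside <- inside & (or_sign * cr >= -tol)
  }
  inside
}
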