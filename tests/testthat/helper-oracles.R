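# Independent brute-force oracles: naive per-voxel / per-pair loops,
# deliberately unrelated to the package's vectorized implementations.

.all_offsets26 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
.all_offsets26 <- .all_offsets26[rowSums(abs(.all_offsets26)) > 0, ]

# Symmetric co-occurrence counts by looping over every ordered voxel pair.
oracle_cooc <- function(q) {
  d <- dim(q$levels)
  cnt <- matrix(0, q$N, q$N)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- q$levels[i, j, k]
    if (a == 0) next
    for (r in seq_len(nrow(.all_offsets26))) {
      ii <- i + .all_offsets26[r, 1]
      jj <- j + .all_offsets26[r, 2]
      kk <- k + .all_offsets26[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      b <- q$levels[ii, jj, kk]
      if (b == 0) next
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  cnt
}

# Zone labelling by breadth-first flood fill over equal-level voxels.
oracle_glszm <- function(q) {
  d <- dim(q$levels)
  seen <- array(FALSE, d)
  zones <- list()
  for (v in which(q$levels > 0)) {
    if (seen[v]) next
    lev <- q$levels[v]
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      members <- c(members, cur)
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(.all_offsets26))) {
        ni <- ci + .all_offsets26[r, , drop = FALSE]
        if (any(ni < 1) || any(ni > d)) next
        lin <- ni[1] + (ni[2] - 1) * d[1] + (ni[3] - 1) * d[1] * d[2]
        if (!seen[lin] && q$levels[lin] == lev) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = length(members))
  }
  z <- do.call(rbind, zones)
  S <- max(z[, "size"])
  m <- matrix(0, q$N, S)
  for (r in seq_len(nrow(z))) {
    m[z[r, "level"], z[r, "size"]] <- m[z[r, "level"], z[r, "size"]] + 1
  }
  m
}

# Per-level occurrence counts and summed |level - neighbourhood mean|.
oracle_ngtdm <- function(q) {
  d <- dim(q$levels)
  n_i <- numeric(q$N)
  s_i <- numeric(q$N)
  for (v in which(q$levels > 0)) {
    ci <- arrayInd(v, d)
    nb <- integer(0)
    for (r in seq_len(nrow(.all_offsets26))) {
      ni <- ci + .all_offsets26[r, , drop = FALSE]
      if (any(ni < 1) || any(ni > d)) next
      lv <- q$levels[ni[1], ni[2], ni[3]]
      if (lv > 0) nb <- c(nb, lv)
    }
    if (!length(nb)) next
    lev <- q$levels[v]
    n_i[lev] <- n_i[lev] + 1
    s_i[lev] <- s_i[lev] + abs(lev - mean(nb))
  }
  list(n = n_i, s = s_i)
}

# Dependence counts by per-voxel neighbour scan.
oracle_ngldm <- function(q) {
  d <- dim(q$levels)
  m <- matrix(0, q$N, 27)
  for (v in which(q$levels > 0)) {
    ci <- arrayInd(v, d)
    dep <- 0
    for (r in seq_len(nrow(.all_offsets26))) {
      ni <- ci + .all_offsets26[r, , drop = FALSE]
      if (any(ni < 1) || any(ni > d)) next
      if (q$levels[ni[1], ni[2], ni[3]] == q$levels[v]) dep <- dep + 1
    }
    m[q$levels[v], dep + 1] <- m[q$levels[v], dep + 1] + 1
  }
  m
}

# Point-in-convex-hull by Frank-Wolfe minimization of ||S'w - p|| over the
# simplex — independent of the package's facet-based hull.
oracle_in_hull <- function(S, p, iters = 5000, tol = 1e-3) {
  w <- rep(1 / nrow(S), nrow(S))
  for (t in seq_len(iters)) {
    x <- drop(t(S) %*% w)
    g <- drop(S %*% (x - p))          # gradient wrt w
    j <- which.min(g)
    gamma <- 2 / (t + 2)
    w <- (1 - gamma) * w
    w[j] <- w[j] + gamma
  }
  sqrt(sum((drop(t(S) %*% w) - p)^2)) < tol * max(1, max(abs(S)))
}

# Mann-Whitney U by explicit pair counting (ties = 1/2).
oracle_u_stat <- function(pos, neg) {
  u <- 0
  for (a in pos) for (b in neg) {
    u <- u + (a > b) + 0.5 * (a == b)
  }
  u
}
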