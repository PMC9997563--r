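# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the mathematical definition, not from package code.

# Flood-fill connected components on a logical matrix. Returns a list of
# n x 2 matrices of 0-based (x, y) pixel positions.
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  comps <- list()
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      pix <- NULL
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        pix <- rbind(pix, p)
        for (k in seq_len(nrow(nb))) {
          r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
                mask[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
      comps[[length(comps) + 1]] <- cbind(x = pix[, 2] - 1, y = pix[, 1] - 1)
    }
  }
  comps
}

# Winding-number point-in-polygon: sum of signed angles subtended by the
# edges is +/- 2*pi inside, ~0 outside. Boundary handled separately by an
# explicit on-segment check (the inclusion rule under test counts boundary
# points as inside).
oracle_point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  nv <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      ax <- poly[i, 1]; ay <- poly[i, 2]
      bx <- poly[j, 1]; by <- poly[j, 2]
      cross <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
      if (abs(cross) <= eps * max(1, sqrt((bx - ax)^2 + (by - ay)^2)) &&
            x >= min(ax, bx) - eps && x <= max(ax, bx) + eps &&
            y >= min(ay, by) - eps && y <= max(ay, by) + eps) {
        return(TRUE)
      }
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_boundary(x, y)) return(TRUE)
    total <- 0
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      a1 <- atan2(poly[i, 2] - y, poly[i, 1] - x)
      a2 <- atan2(poly[j, 2] - y, poly[j, 1] - x)
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      total <- total + d
    }
    abs(total) > pi  # ~2*pi inside, ~0 outside
  }, logical(1))
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all rank
# assignments (no ties). p = P(U as or more extreme in either tail).
oracle_exact_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  us <- apply(sets, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  lo <- min(u_obs, n1 * n2 - u_obs)
  mean(us <= lo | us >= n1 * n2 - lo)
}

# Hand-applied Benjamini-Hochberg step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Single-frame-at-a-time reference for the two-pass bout denoising rule: for
# every frame, decide its post-pass value by scanning outward to the ends of
# its run, without run-length encoding.
oracle_denoise <- function(flags, min_on = 27, min_off = 10) {
  n <- length(flags)
  run_extent <- function(f, i) {
    s <- i; while (s > 1 && f[s - 1] == f[i]) s <- s - 1
    e <- i; while (e < n && f[e + 1] == f[i]) e <- e + 1
    c(s, e)
  }
  # pass 1: flip 0-frames in interior 0-runs shorter than min_off
  a <- flags
  for (i in seq_len(n)) {
    if (flags[i] != 0) next
    ext <- run_extent(flags, i)
    if (ext[1] > 1 && ext[2] < n && (ext[2] - ext[1] + 1) < min_off) {
      a[i] <- 1L
    }
  }
  # pass 2: flip 1-frames in 1-runs shorter than min_on
  b <- a
  for (i in seq_len(n)) {
    if (a[i] != 1) next
    ext <- run_extent(a, i)
    if ((ext[2] - ext[1] + 1) < min_on) b[i] <- 0L
  }
  b
}

# Naive per-frame interval accumulation: loop over frames, assign each to
# its interval, accumulate flag counts and centroid step distances.
oracle_intervals <- function(frame, flag, cx, cy, fps, interval_s = 120) {
  fpi <- interval_s * fps
  ord <- order(frame)
  frame <- frame[ord]; flag <- flag[ord]; cx <- cx[ord]; cy <- cy[ord]
  iv <- floor(frame / fpi)
  out <- NULL
  for (k in sort(unique(iv))) {
    sel <- which(iv == k)
    dist <- 0
    for (i in sel) {
      j <- which(frame == frame[i] - 1)
      if (length(j) == 1 && !is.na(cx[i]) && !is.na(cx[j])) {
        dist <- dist + sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      }
    }
    out <- rbind(out, data.frame(interval = k, n_frames = length(sel),
                                 food_fraction = mean(flag[sel]),
                                 distance_px = dist))
  }
  out
}

# Closed-form least squares through the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}

# Small random flag series under a fixed seed.
random_flag_series <- function(n, p = 0.5) {
  as.integer(runif(n) < p)
}
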