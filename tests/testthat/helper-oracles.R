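# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from its definition by a
# different route than the package code.

# ICQ by naive per-voxel enumeration of deviation-product signs.
oracle_icq <- function(a, b, roi = NULL) {
  av <- as.numeric(a)
  bv <- as.numeric(b)
  if (!is.null(roi)) {
    av <- av[as.logical(roi)]
    bv <- bv[as.logical(roi)]
  }
  ma <- mean(av)
  mb <- mean(bv)
  npos <- 0L
  nused <- 0L
  for (i in seq_along(av)) {
    p <- (av[i] - ma) * (bv[i] - mb)
    if (p != 0) {
      nused <- nused + 1L
      if (p > 0) npos <- npos + 1L
    }
  }
  npos / nused - 0.5
}

# Otsu by exhaustive between-class-variance maximization over the same
# 256-level discretization of the intensity range.
oracle_otsu_mask <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  cuts <- seq(rng[1], rng[2], length.out = 257)[2:256]
  best <- -Inf
  best_thr <- cuts[1]
  for (thr in cuts) {
    lo <- v[v <= thr]
    hi <- v[v > thr]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best) {
      best <- bc
      best_thr <- thr
    }
  }
  array(v > best_thr, dim(x))
}

# Connected components via igraph on the voxel-adjacency graph.
oracle_label_components <- function(mask, connectivity) {
  if (is.matrix(mask)) mask <- array(mask, c(1, dim(mask)))
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list(n = 0L, membership = integer(0)))
  pos <- arrayInd(idx, d)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- stats::setNames(seq_along(idx), key(pos))
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off) > 0) <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off <- off[keep, ]
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- cbind(pos[, 1] + off$dz[k], pos[, 2] + off$dy[k],
                pos[, 3] + off$dx[k])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- match(key(nb[ok, , drop = FALSE]), names(lut))
    found <- !is.na(j)
    if (any(found)) {
      edges <- c(edges, rbind(which(ok)[found], j[found]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  list(n = comp$no, membership = comp$membership)
}

# Weibull-5 least squares by coarse grid over (x0, b, c) with an exact
# linear solve for (y0, a) at each grid point, then local grid refinement.
oracle_weibull5_rss <- function(wl, y, n_refine = 3) {
  basis <- function(x0, b, cc) {
    k <- ((cc - 1) / cc)^(1 / cc)
    u <- (wl - x0) / b + k
    g <- numeric(length(wl))
    pos <- u > 0
    g[pos] <- ((cc - 1) / cc)^((1 - cc) / cc) * u[pos]^(cc - 1) *
      exp(-u[pos]^cc + (cc - 1) / cc)
    g
  }
  rss_at <- function(x0, b, cc) {
    g <- basis(x0, b, cc)
    X <- cbind(1, g)
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) return(Inf)
    sum((y - X %*% beta)^2)
  }
  grid <- list(x0 = seq(min(wl), max(wl), length.out = 25),
               b = seq(10, 200, length.out = 20),
               cc = seq(1.2, 4, length.out = 15))
  best <- c(NA, NA, NA)
  best_rss <- Inf
  for (x0 in grid$x0) for (b in grid$b) for (cc in grid$cc) {
    r <- rss_at(x0, b, cc)
    if (r < best_rss) {
      best_rss <- r
      best <- c(x0, b, cc)
    }
  }
  widths <- c(diff(grid$x0[1:2]), diff(grid$b[1:2]), diff(grid$cc[1:2]))
  for (i in seq_len(n_refine)) {
    g2 <- lapply(1:3, function(k) {
      seq(best[k] - widths[k], best[k] + widths[k], length.out = 9)
    })
    g2[[2]] <- pmax(g2[[2]], 1e-2)
    g2[[3]] <- pmax(g2[[3]], 1.001)
    for (x0 in g2[[1]]) for (b in g2[[2]]) for (cc in g2[[3]]) {
      r <- rss_at(x0, b, cc)
      if (r < best_rss) {
        best_rss <- r
        best <- c(x0, b, cc)
      }
    }
    widths <- widths / 4
  }
  best_rss
}

# Eigendecomposition oracle for PCA on standardized data.
oracle_pca_cor <- function(x) {
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors)
}
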