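# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# convex hull area by the half-plane edge method: an ordered pair (i, j) is a
# hull edge iff every other point lies on (or left of) the line i -> j; the
# area is then the sum of triangle cross-products from an interior anchor.
oracle_hull_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- cbind(xy[, 1] - xy[i, 1], xy[, 2] - xy[i, 2])
    ex <- xy[j, 1] - xy[i, 1]; ey <- xy[j, 2] - xy[i, 2]
    cr <- ex * d[, 2] - ey * d[, 1]
    if (all(cr >= -1e-12)) edges[[length(edges) + 1]] <- c(i, j)
  }
  if (!length(edges)) return(0)
  em <- do.call(rbind, edges)
  # chain edges into a cycle starting from any edge
  start <- em[1, 1]; cur <- em[1, 2]; ordered <- c(start, cur)
  while (cur != start) {
    nxt <- em[em[, 1] == cur, 2]
    nxt <- nxt[!(nxt %in% ordered[-1])][1]
    if (is.na(nxt)) break
    if (nxt == start) break
    ordered <- c(ordered, nxt)
    cur <- nxt
  }
  v <- xy[ordered, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(0.5 * sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1])))
}

# direct O(n^2) Gaussian-weighted smoothing with edge-repeated reflection
oracle_smooth <- function(x, h) {
  n <- length(x)
  r <- max(1L, as.integer(ceiling(4 * h)))
  k <- dnorm(seq(-r, r), sd = h)
  k <- k / sum(k)
  refl <- function(i) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  sapply(seq_len(n), function(i) {
    idx <- refl(i + seq(-r, r))
    sum(k * x[idx])
  })
}

# scalar vegetation-index formulas, written independently
oracle_index <- function(name, g, r, e, n) {
  switch(name,
    NG = g / (n + r + g), NR = r / (n + r + g),
    NDVI = (n - r) / (n + r), GNDVI = (n - g) / (n + g),
    DVI = n - r, CIG = n / g - 1,
    OSAVI = 1.16 * (n - r) / (n + r + 0.16),
    RDVI = (n - r) / sqrt(n + r),
    NLI = (n^2 - r) / (n^2 + r),
    WDRVI = (0.2 * n - r) / (0.2 * n + r))
}

# naive double-loop Haralick features from a normalized GLCM
oracle_texture <- function(p) {
  N <- nrow(p)
  CON <- ASM <- INM <- sij <- si <- sj <- vi <- vj <- 0
  for (a in 0:(N - 1)) for (b in 0:(N - 1)) {
    q <- p[a + 1, b + 1]
    CON <- CON + abs(a - b)^2 * q
    ASM <- ASM + q^2
    INM <- INM + q / (1 + abs(a - b))
    sij <- sij + a * b * q
    si <- si + a * q; sj <- sj + b * q
  }
  for (a in 0:(N - 1)) for (b in 0:(N - 1)) {
    q <- p[a + 1, b + 1]
    vi <- vi + q * (a - si)^2
    vj <- vj + q * (b - sj)^2
  }
  COR <- if (vi > 0 && vj > 0) (sij - si * sj) / sqrt(vi * vj) else NA
  list(CON = CON, COR = COR, ASM = ASM, INM = INM)
}

# direct moments of a pixel vector
oracle_moments <- function(p) {
  p <- as.numeric(p)
  mu <- sum(p) / length(p)
  m2 <- sum((p - mu)^2) / length(p)
  m3 <- sum((p - mu)^3) / length(p)
  list(mu = mu, sigma = sqrt(m2), s = sign(m3) * abs(m3)^(1 / 3))
}

# exhaustive center-in-cell containment count for detection scoring; cells
# are [lo, hi) except the last cell along each axis, which is closed at the
# extent edge
oracle_containment <- function(seg, trees) {
  reg <- seg$regions
  last_band <- max(reg$row)
  counts <- integer(nrow(reg))
  for (k in seq_len(nrow(trees))) {
    t <- seg$m_3D - trees$center_y[k]
    x <- trees$center_x[k]
    for (r in seq_len(nrow(reg))) {
      last_col <- reg$col[r] == max(reg$col[reg$row == reg$row[r]])
      in_t <- t >= reg$t0[r] &&
        (t < reg$t1[r] || (reg$row[r] == last_band && t <= reg$t1[r]))
      in_x <- x >= reg$x0[r] &&
        (x < reg$x1[r] || (last_col && x <= reg$x1[r]))
      if (in_t && in_x) counts[r] <- counts[r] + 1L
    }
  }
  counts
}
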