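# loop-based brute-force oracles for the voxel features; deliberately
# naive and independent of the compiled kernels

oracle_moments <- function(a, v, size) {
  h <- (size - 1) / 2
  d <- dim(a)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  vals <- c()
  for (dz in -h:h) for (dy in -h:h) for (dx in -h:h)
    vals <- c(vals, a[refl(v[1] + dx, d[1]), refl(v[2] + dy, d[2]),
                      refl(v[3] + dz, d[3])])
  mu <- mean(vals); m2 <- mean((vals - mu)^2)
  c(mu, sqrt(m2),
    if (m2 > 0) mean((vals - mu)^3) / m2^1.5 else 0,
    if (m2 > 0) mean((vals - mu)^4) / m2^2 - 3 else 0)
}

oracle_haralick <- function(a, v, box, levels) {
  d <- dim(a)
  rng <- range(a)
  q <- pmin(floor((a - rng[1]) / diff(rng) * levels), levels - 1)
  h <- (box - 1) / 2
  lo <- pmax(v - h, 1); hi <- pmin(v + h, d)
  offs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
                c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
                c(1,-1,1), c(1,-1,-1))
  feats <- matrix(0, 0, 5)
  for (o in seq_len(nrow(offs))) {
    glcm <- matrix(0, levels, levels)
    for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
      p2 <- c(x, y, z) + offs[o, ]
      if (all(p2 >= lo) && all(p2 <= hi)) {
        i <- q[x, y, z] + 1; j <- q[p2[1], p2[2], p2[3]] + 1
        glcm[i, j] <- glcm[i, j] + 1
        glcm[j, i] <- glcm[j, i] + 1
      }
    }
    if (sum(glcm) == 0) next
    p <- glcm / sum(glcm)
    lv <- 0:(levels - 1)
    pi_ <- rowSums(p)
    mi <- sum(lv * pi_); vi <- sum((lv - mi)^2 * pi_)
    ii <- matrix(lv, levels, levels); jj <- t(ii)
    corr <- if (vi > 0) sum((ii - mi) * (jj - mi) * p) / vi else 0
    feats <- rbind(feats, c(
      sum(p^2), sum((ii - jj)^2 * p), corr,
      sum(p / (1 + (ii - jj)^2)), -sum(p[p > 0] * log(p[p > 0]))))
  }
  colMeans(feats)
}

oracle_haar <- function(a, v, size) {
  d <- dim(a)
  h <- (size - 1) / 2
  lo <- pmax(v - h, 1); hi <- pmin(v + h, d)
  bx <- function(l, u) {
    l <- pmax(l, 1); u <- pmin(u, d)
    if (any(l > u)) return(c(0, 0))
    c(sum(a[l[1]:u[1], l[2]:u[2], l[3]:u[3]]), prod(u - l + 1))
  }
  half <- function(ax) {
    l1 <- lo; u1 <- hi; l2 <- lo; u2 <- hi
    u1[ax] <- v[ax] - 1; l2[ax] <- v[ax] + 1
    if (u1[ax] < lo[ax] || l2[ax] > hi[ax]) return(0)
    s1 <- bx(l1, u1); s2 <- bx(l2, u2)
    s1[1] / s1[2] - s2[1] / s2[2]
  }
  ie <- (size + 1) %/% 2; if (ie %% 2 == 0) ie <- ie - 1
  hin <- (ie - 1) / 2
  si <- bx(pmax(v - hin, lo), pmin(v + hin, hi))
  sa <- bx(lo, hi)
  cs <- if (sa[2] - si[2] > 0)
    si[1] / si[2] - (sa[1] - si[1]) / (sa[2] - si[2]) else 0
  c(half(1), half(2), half(3), cs)
}

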