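# Independent reference implementations used to check the package's
# computational kernels. These share no code with the implementation paths
# they validate.

# Gradient-correlation by direct summation: explicit 3x3 Sobel convolution
# loops and hand-written normalized cross-correlation of both gradient
# pairs over the interior window.
gc_bruteforce <- function(A, B) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/du
  ky <- t(kx)                                                # d/dv
  conv <- function(img, k) {
    n <- nrow(img); m <- ncol(img)
    out <- matrix(0, n, m)
    for (i in 2:(n - 1)) for (j in 2:(m - 1)) {
      s <- 0
      for (a in -1:1) for (b in -1:1)
        s <- s + img[i + a, j + b] * k[a + 2, b + 2]
      out[i, j] <- s
    }
    out
  }
  term <- function(ga, gb) {
    ga <- ga[2:(nrow(ga) - 1), 2:(ncol(ga) - 1)]
    gb <- gb[2:(nrow(gb) - 1), 2:(ncol(gb) - 1)]
    ga <- ga - mean(ga); gb <- gb - mean(gb)
    sum(ga * gb) / sqrt(sum(ga^2) * sum(gb^2))
  }
  term(conv(A, kx), conv(B, kx)) + term(conv(A, ky), conv(B, ky))
}

# Exact scalar point-to-triangle distance (Eberly's region decomposition).
p2t_oracle <- function(p, a, b, c) {
  E0 <- b - a; E1 <- c - a; D <- a - p
  aa <- sum(E0 * E0); bb <- sum(E0 * E1); cc <- sum(E1 * E1)
  dd <- sum(E0 * D); ee <- sum(E1 * D)
  s <- bb * ee - cc * dd; t <- bb * dd - aa * ee
  det <- aa * cc - bb * bb
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { s <- max(0, min(1, -dd / aa)); t <- 0
        if (-ee > 0) { t <- min(1, -ee / cc); s <- 0 }
      } else { s <- 0; t <- max(0, min(1, -ee / cc)) }
    } else if (t < 0) { t <- 0; s <- max(0, min(1, -dd / aa))
    } else { s <- s / det; t <- t / det }
  } else {
    if (s < 0) { s <- 0; t <- max(0, min(1, -ee / cc))
    } else if (t < 0) { t <- 0; s <- max(0, min(1, -dd / aa))
    } else {
      num <- (cc + ee) - (bb + dd)
      s <- max(0, min(1, num / (aa - 2 * bb + cc)))
      t <- 1 - s
    }
  }
  q <- a + s * E0 + t * E1
  sqrt(sum((p - q)^2))
}

# Brute-force point-to-surface: minimum of the exact distance over every
# triangle, vectorized over triangles (clamped-projection case analysis).
p2s_bruteforce <- function(p, mesh) {
  V <- mesh$vertices; f <- mesh$faces
  A <- V[f[, 1], , drop = FALSE]
  E0 <- V[f[, 2], , drop = FALSE] - A
  E1 <- V[f[, 3], , drop = FALSE] - A
  D <- sweep(-A, 2, p, "+")  # p - A per triangle
  aa <- rowSums(E0 * E0); bb <- rowSums(E0 * E1); cc <- rowSums(E1 * E1)
  dd <- -rowSums(E0 * D); ee <- -rowSums(E1 * D)
  det <- pmax(aa * cc - bb * bb, 1e-300)
  s <- (bb * ee - cc * dd) / det
  t <- (bb * dd - aa * ee) / det
  inside <- s >= 0 & t >= 0 & s + t <= 1
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  # candidate closest points: interior projection and the three edges
  cand_dist2 <- function(si, ti) {
    q <- A + E0 * si + E1 * ti
    rowSums(sweep(q, 2, p, "-")^2)
  }
  d2 <- ifelse(inside, cand_dist2(s, t), Inf)
  # edge AB (t = 0), edge AC (s = 0), edge BC (s + t = 1)
  sab <- clamp01(-dd / pmax(aa, 1e-300))
  d2 <- pmin(d2, cand_dist2(sab, 0))
  tac <- clamp01(-ee / pmax(cc, 1e-300))
  d2 <- pmin(d2, cand_dist2(0, tac))
  sbc <- clamp01(((cc + ee) - (bb + dd)) / pmax(aa - 2 * bb + cc, 1e-300))
  d2 <- pmin(d2, cand_dist2(sbc, 1 - sbc))
  sqrt(min(d2))
}
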