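# Shape constructors and independent oracles shared by the test files.
# Oracles are deliberately written as direct, slow transcriptions so they
# stay independent of the package's vectorized implementations.

make_circle <- function(n = 1000, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# Equal-parameter sampling of an axis-aligned ellipse (pure first harmonic
# in its generating parameter).
make_ellipse <- function(n = 1000, a = 2, b = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

make_rect <- function(w = 1, h = 2) {
  cbind(c(-w / 2, -w / 2, w / 2, w / 2), c(-h / 2, h / 2, h / 2, -h / 2))
}

# Random smooth star-shaped contour from a low-order radial Fourier series.
make_smooth_contour <- function(n = 400, max_harm = 5, amp = 0.15, seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rep(1, n)
  for (h in seq_len(max_harm)) {
    r <- r + amp / h * (runif(1, -1, 1) * cos(h * th) +
                          runif(1, -1, 1) * sin(h * th))
  }
  cbind(r * cos(th), r * sin(th))
}

# Dense-matrix AR(1) multivariate normal log-density.
ar1_dense_loglik <- function(e, sigma2, rho) {
  k <- length(e)
  S <- sigma2 * rho^abs(outer(seq_len(k), seq_len(k), "-"))
  -k / 2 * log(2 * pi) - 0.5 * determinant(S, logarithm = TRUE)$modulus -
    0.5 * drop(t(e) %*% solve(S, e))
}

# Elliptic Fourier coefficients by direct quadrature of the piecewise-linear
# interpolant of the polygon, chord-length parameterization.
efd_quadrature_oracle <- function(pts, order, n_quad = 200000) {
  pts2 <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts2)^2))
  t_knots <- c(0, cumsum(seg))
  T <- t_knots[length(t_knots)]
  tq <- seq(0, T, length.out = n_quad + 1)[-(n_quad + 1)]
  xq <- approx(t_knots, pts2[, 1], xout = tq)$y
  yq <- approx(t_knots, pts2[, 2], xout = tq)$y
  dt <- T / n_quad
  out <- matrix(NA_real_, order, 4)
  for (nn in seq_len(order)) {
    cn <- cos(2 * pi * nn * tq / T)
    sn <- sin(2 * pi * nn * tq / T)
    out[nn, ] <- 2 / T * dt * c(sum(xq * cn), sum(xq * sn),
                                sum(yq * cn), sum(yq * sn))
  }
  list(dc = c(mean(xq), mean(yq)), coeffs = out)
}

# Weir & Cockerham (1984) theta, scalar per-locus transcription.
wc_theta_oracle <- function(geno, demes) {
  demes <- factor(demes)
  r <- nlevels(demes)
  num <- den <- 0
  for (l in seq_len(nrow(geno))) {
    g <- geno[l, ]
    ni <- pi <- hi <- numeric(r)
    for (j in seq_len(r)) {
      gj <- g[demes == levels(demes)[j]]
      gj <- gj[!is.na(gj)]
      ni[j] <- length(gj)
      pi[j] <- sum(gj) / (2 * length(gj))
      hi[j] <- mean(gj == 1)
    }
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Exact HWE p-value by full enumeration over heterozygote counts.
hwe_enum_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- sapply(hets, function(h) {
    nr <- (rare - h) / 2
    nc <- n - nr - h
    exp(lfactorial(n) - lfactorial(nr) - lfactorial(h) - lfactorial(nc) +
          h * log(2) - (lfactorial(2 * n) - lfactorial(rare) -
                          lfactorial(2 * n - rare)))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == nAB]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Build a shape_pheno directly from a list of landmark matrices.
pheno_from_matrices <- function(mats, deme = NULL) {
  shapes <- lapply(seq_along(mats), function(i)
    outline(mats[[i]], id = paste0("s", i), line_id = sprintf("L%03d", i)))
  shape_phenotypes(shapes, deme = deme)
}
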