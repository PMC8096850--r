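# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

# A single ring of `n` atoms of radius `r` in the z = z0 plane.
ring_model <- function(n = 14, r = 10, z0 = 0, vdw = 1.7) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  atomic_model(tibble::tibble(
    chain = "A", resid = seq_len(n), resname = "RNG",
    atom = "X", element = "X",
    x = r * cos(ang), y = r * sin(ang), z = z0,
    vdw = vdw
  ))
}

# Tiny 3-blob point model for LDP tests.
blob_model <- function(centers) {
  atomic_model(tibble::tibble(
    chain = "A", resid = seq_len(nrow(centers)), resname = "BLB",
    atom = "X", element = "X",
    x = centers[, 1], y = centers[, 2], z = centers[, 3]
  ))
}

# Exact draws from the biased Boltzmann law exp(-beta (A*(q) + c/2 (q-a)^2))
# by numerical inverse-CDF on a fine grid: the independent sampling oracle.
sample_biased_exact <- function(pmf, anchor, n, force_const = 20,
                                beta = thermo_state()$beta, span = 1.5) {
  g <- seq(anchor - span, anchor + span, length.out = 4001)
  u <- pmf_value(pmf, g) + force_const / 2 * (g - anchor)^2
  p <- exp(-beta * (u - min(u)))
  cdf <- cumsum(p)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, g, stats::runif(n), ties = "ordered")$y
}

# Brute-force WHAM fixed-point oracle: textbook direct iteration on the
# histogram equations (bin-centre bias), independent of the package solver.
wham_fixed_point_oracle <- function(counts, n_i, centers, anchors,
                                    force_const, beta, tol = 1e-10,
                                    max_iter = 2e5) {
  R <- length(anchors)
  K <- length(centers)
  U <- matrix(0, R, K)
  for (i in seq_len(R)) U[i, ] <- force_const / 2 * (centers - anchors[i])^2
  f <- rep(1, R)  # f_i = exp(beta A_i)
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_i * f * exp(-beta * U))
    P <- ifelse(counts > 0, counts / denom, 0)
    f_new <- 1 / (colSums(t(exp(-beta * U)) * P))
    f_new <- f_new / f_new[1]
    delta <- max(abs(log(f_new) - log(f))) / beta
    f <- f_new
    if (delta < tol) break
  }
  A <- ifelse(P > 0, -log(P) / beta, NA_real_)
  A <- A - min(A, na.rm = TRUE)
  list(A = A, A_i = log(f) / beta, iterations = it)
}

# Direct (non-FFT) 3-D discrete Fourier transform, the FSC oracle.
dft3_oracle <- function(x) {
  d <- dim(x)
  W <- function(n) {
    exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  }
  w1 <- W(d[1]); w2 <- W(d[2]); w3 <- W(d[3])
  out <- array(0i, dim = d)
  # transform along each axis in turn by explicit matrix products
  for (k in seq_len(d[3])) out[, , k] <- w1 %*% x[, , k] %*% t(w2)
  arr <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
  arr <- arr %*% t(w3)
  array(arr, dim = d)
}

# Exhaustive in-plane grid-search oracle for the pore radius.
grid_search_radius_oracle <- function(model, z, axis, span = 12,
                                      step = 0.05, r_cap = 30) {
  fr <- cptk:::to_axis_frame(cptk:::model_xyz(model), axis)
  slab <- abs(fr[, "w"] - z) <= r_cap + max(model$vdw)
  au <- fr[slab, "u"]; av <- fr[slab, "v"]; adz <- fr[slab, "w"] - z
  avdw <- model$vdw[slab]
  gx <- seq(-span, span, by = step)
  best <- -Inf
  for (cy in gx) {
    cl <- sqrt(outer(au, gx, function(a, c) (a - c)^2) +
                 (av - cy)^2 + adz^2)
    cl <- sweep(cl, 1, avdw)
    cand <- apply(cl, 2, min)
    m <- max(cand)
    if (m > best) best <- m
  }
  min(max(best, 0), r_cap)
}
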