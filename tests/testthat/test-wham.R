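test_that("thermal energy at 310 K from the printed Boltzmann constant", {
  th <- thermo_state(310)
  # k_B * T * N_A / 4184 J/kcal
  expect_equal(th$kT, 0.616, tolerance = 1e-3)
  expect_equal(th$beta * th$kT, 1)
})

test_that("harmonic bias values follow c/2 (q - q_i)^2", {
  expect_equal(bias_potential(3, 3, 20), 0)
  expect_equal(bias_potential(4, 3, 20), 10)
  expect_equal(bias_potential(3.5, 3, 20), 2.5)
  expect_equal(bias_potential(c(0, 2), 1, 2), c(1, 1))
})

test_that("window grid covers the protocol inclusively", {
  w <- make_windows(55, -55, 1, replicas = 5)
  expect_equal(length(unique(w$anchor)), 111)
  expect_equal(nrow(w), 555)
  expect_equal(range(w$anchor), c(-55, 55))
  expect_equal(nrow(make_windows(3, 3, 1, replicas = 1)), 1)
  w2 <- make_windows(0, 5, 10, replicas = 1)
  expect_equal(sort(unique(w2$anchor)), c(0, 5))
})

test_that("histograms conserve counts and use half-open bins", {
  win <- tibble::tibble(
    anchor = c(0, 1), force_const = 20,
    series = list(time_series(1:4, c(0.1, 0.2, 0.6, 1.0)),
                  time_series(1:3, c(1.0, 1.2, 1.9))))
  h <- build_histograms(win, bin_width = 0.5)
  expect_equal(sum(h$counts), sum(h$n_i))
  expect_equal(h$n_i, c(4, 3))
  # sample exactly on the 1.0 edge lands in the right-hand bin
  k <- findInterval(1.0, h$edges, rightmost.closed = FALSE)
  expect_equal(h$centers[k], 1.25)
  expect_equal(h$counts[k], 3)  # 1.0, 1.0, 1.2
})

test_that("a single unbiased window with a uniform histogram gives a flat PMF", {
  set.seed(1)
  win <- tibble::tibble(
    anchor = 0, force_const = 0,
    series = list(time_series(1:4000, rep(seq(0.05, 3.95, by = 0.1), 100))))
  r <- wham_solve(win, bin_width = 0.5)
  expect_true(all(abs(r$bins$A) < 1e-9))
  expect_equal(sum(r$bins$P) * r$bin_width, 1, tolerance = 1e-9)
})

test_that("solver matches the brute-force fixed-point oracle on a 12-bin toy", {
  th <- thermo_state()
  set.seed(42)
  anchors <- c(-1, 0, 1)
  win <- tibble::tibble(
    anchor = anchors, force_const = 3,
    series = lapply(anchors, function(a) {
      time_series(1:2000, rnorm(2000, a, sqrt(th$kT / 3)))
    }))
  # refine = 1 solves the identical textbook equations the oracle iterates
  r <- wham_solve(win, th, bin_width = 0.5, refine = 1)
  expect_lte(nrow(r$bins), 12)
  h <- build_histograms(win, 0.5)
  oracle <- wham_fixed_point_oracle(h$counts, h$n_i, h$centers, anchors,
                                    force_const = 3, beta = th$beta)
  keep <- is.finite(r$bins$A) & !is.na(oracle$A)
  expect_lt(max(abs(r$bins$A[keep] - oracle$A[keep])), 1e-6)
  expect_true(r$converged)
})

test_that("exact biased Gaussians from a flat PMF unbias to within 0.2 kcal/mol", {
  th <- thermo_state()
  set.seed(7)
  flat <- analytic_pmf("flat")
  win <- make_windows(-5, 5, 1, replicas = 1, force_const = 20)
  win$series <- lapply(win$anchor, function(a) {
    time_series(1:1e4, sample_biased_exact(flat, a, 1e4))
  })
  r <- wham_solve(win, th, bin_width = 0.5)
  b <- r$bins[r$bins$q > -5 & r$bins$q < 5, ]
  expect_lt(max(abs(b$A - mean(b$A))), 0.2)
})

test_that("WHAM is invariant to uniform duplication of every sample", {
  th <- thermo_state()
  set.seed(3)
  win <- tibble::tibble(
    anchor = c(-1, 0, 1), force_const = 5,
    series = lapply(c(-1, 0, 1), function(a) {
      time_series(1:500, rnorm(500, a, sqrt(th$kT / 5)))
    }))
  win2 <- win
  win2$series <- lapply(win$series, function(s) {
    time_series(seq_len(2 * nrow(s)), rep(s$q, 2))
  })
  r1 <- wham_solve(win, th, 0.5)
  r2 <- wham_solve(win2, th, 0.5)
  expect_equal(r2$bins$A, r1$bins$A, tolerance = 1e-6)
})

test_that("WHAM is invariant to a constant added to all bias potentials", {
  # adding a constant to every window bias rescales all window weights by a
  # common factor, which the offsets absorb; checked at the solver core
  set.seed(8)
  counts <- c(5, 40, 90, 40, 5)
  ni <- c(90, 90)
  logc <- rbind(c(-3, -1, 0, -1, -3), c(-2.5, -0.5, -0.1, -1.5, -3.5))
  f1 <- cptk:::wham_core(counts, ni, logc)
  f2 <- cptk:::wham_core(counts, ni, logc - 7)
  # the constant shifts the unnormalised log-probabilities uniformly; the
  # anchored PMF shape is unchanged
  expect_equal(f1$logP - f1$logP[1], f2$logP - f2$logP[1], tolerance = 1e-8)
})

test_that("disconnected window groups raise an error naming the gap", {
  th <- thermo_state()
  set.seed(5)
  win <- tibble::tibble(
    anchor = c(-10, 10), force_const = 20,
    series = lapply(c(-10, 10), function(a) {
      time_series(1:1000, rnorm(1000, a, 0.15))
    }))
  expect_error(wham_solve(win, th, 0.5), "disconnected sampling")
})

test_that("quadratic smoothing is exact on quadratics and reduces noise", {
  th <- thermo_state()
  mk_result <- function(A) {
    structure(list(bins = tibble::tibble(q = seq_along(A), A = A,
                                         P = exp(-A), N = 10),
                   bin_width = 1, thermo = th), class = "pmf_result")
  }
  q <- seq(-5, 5, by = 0.5)
  quad <- 2 * q^2 - 3 * q + 1
  sm <- smooth_pmf(mk_result(quad), 5)
  expect_equal(sm$bins$A_smooth, quad, tolerance = 1e-9)
  const <- rep(2, 21)
  expect_equal(smooth_pmf(mk_result(const), 5)$bins$A_smooth, const,
               tolerance = 1e-10)
  # a window wider than the profile degrades to one global quadratic
  short <- mk_result(q[1:7]^2)
  expect_equal(smooth_pmf(short, 21)$bins$A_smooth, q[1:7]^2,
               tolerance = 1e-9)
  # noisy double-well: smoothing reduces the residual to the noiseless curve
  set.seed(2)
  dw <- analytic_pmf("double_well", height = 5, width = 10)
  qq <- seq(-12, 12, by = 0.5)
  truth <- pmf_value(dw, qq)
  noisy <- truth + rnorm(length(qq), sd = 0.25)
  sm2 <- smooth_pmf(mk_result(noisy), 5)
  expect_lt(mean((sm2$bins$A_smooth - truth)^2), mean((noisy - truth)^2))
})

test_that("convergence deviation is zero for the full block and duplicates", {
  th <- thermo_state()
  set.seed(9)
  win <- tibble::tibble(
    anchor = c(-1, 0, 1), force_const = 5,
    series = lapply(c(-1, 0, 1), function(a) {
      time_series(seq(0.01, 20, length.out = 2000),
                  rnorm(2000, a, sqrt(th$kT / 5)))
    }))
  conv <- convergence_profile(win, block_ends = c(10, 20), thermo = th,
                              bin_width = 0.5)
  expect_equal(conv$deviation[2], 0, tolerance = 1e-9)
  # half-data block deviates by a finite, modest amount (sparse edge bins
  # dominate the max metric)
  expect_lt(conv$deviation[1], 1.5)
  expect_gte(conv$deviation[1], 0)
})

test_that("barrier report finds constructed peaks in z-order with residues", {
  th <- thermo_state()
  q <- seq(-20, 20, by = 0.5)
  A <- 5 * exp(-0.5 * (q / 2)^2) + 3 * exp(-0.5 * ((q - 12) / 2)^2)
  res <- structure(list(bins = tibble::tibble(q = q, A = A, P = exp(-A), N = 10),
                        bin_width = 0.5, thermo = th), class = "pmf_result")
  ch <- build_toy_channel(channel_profile_two_waist(
    r_open = 8, waist_radius = c(3, 3), waist_z = c(0, 12)), c(-20, 20), 2, 14, 1.5, 7)
  rep <- barrier_report(res, model = ch, prominence = 1, slab = 2)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$z, c(0, 12), tolerance = 0.3)
  expect_equal(rep$height, c(5, 3), tolerance = 0.05)
  # peaks map to the rings nearest the waists
  waist_res_1 <- which.min(abs(seq(-20, 20, by = 2) - 0))
  expect_match(rep$residues[1], paste0(":", waist_res_1))
  # a flat PMF has no peaks
  flat <- res
  flat$bins$A <- rep(0, length(q))
  expect_equal(nrow(barrier_report(flat, prominence = 0.5)), 0)
})

test_that("a window manifest reads series files and flags missing rows", {
  dir <- withr::local_tempdir()
  ts <- time_series(1:3, c(0.1, 0.2, 0.3))
  write_timeseries(ts, file.path(dir, "w1.dat"))
  man <- file.path(dir, "windows.tsv")
  writeLines(c("anchor force_const series_path",
               "0.0 20 w1.dat"), man)
  win <- read_windows(man)
  expect_equal(nrow(win), 1)
  expect_equal(win$series[[1]]$q, ts$q)
  writeLines(c("anchor force_const series_path",
               "0.0 20 w1.dat",
               "1.0 20 missing.dat"), man)
  expect_error(read_windows(man), "row 2")
})
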