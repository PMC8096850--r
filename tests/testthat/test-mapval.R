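test_that("model maps peak at atom positions, respect symmetry, conserve mass", {
  g <- grid_spec(c(21, 21, 21), 1, c(-10, -10, -10))
  one <- blob_model(matrix(c(0, 0, 0), 1))
  m <- model_to_map(one, g, blur_width = 2)
  expect_equal(which(m$values == max(m$values)), 11 + 10 * 21 + 10 * 21^2)
  # two atoms mirror-symmetric about the x = 0 grid plane
  two <- blob_model(rbind(c(-4, 0, 0), c(4, 0, 0)))
  m2 <- model_to_map(two, g, blur_width = 2)
  expect_equal(m2$values, m2$values[21:1, , ], tolerance = 1e-12)
  # grid mass is the atom count up to truncation loss
  set.seed(1)
  many <- blob_model(cbind(runif(100, -4, 4), runif(100, -4, 4),
                           runif(100, -4, 4)))
  m3 <- model_to_map(many, g, blur_width = 1.5)
  expect_equal(sum(m3$values) * prod(m3$voxel_size), 100, tolerance = 0.01)
  expect_warning(model_to_map(blob_model(matrix(c(50, 0, 0), 1)), g, 2),
                 "outside the grid")
})

test_that("FSC equals one on self, minus one on sign flip, and the DFT oracle", {
  set.seed(3)
  vals <- array(rnorm(8^3), dim = c(8, 8, 8))
  m <- density_map(vals, voxel_size = 1.2)
  self <- fsc(m, m)
  expect_true(all(abs(self$fsc - 1) < 1e-10))
  neg <- density_map(-vals, m$voxel_size)
  expect_true(all(abs(fsc(m, neg)$fsc + 1) < 1e-10))

  # correlate against an independent direct-summation DFT on the 8^3 grid
  vals2 <- array(rnorm(8^3), dim = c(8, 8, 8))
  m2 <- density_map(vals2, voxel_size = 1.2)
  got <- fsc(m, m2)
  fa <- dft3_oracle(vals)
  fb <- dft3_oracle(vals2)
  sh <- cptk:::fsc_shells(c(8, 8, 8), rep(1.2, 3))
  idx <- sh$shell + 1L
  num <- tapply(as.vector(Re(fa * Conj(fb))), idx, sum)
  den <- sqrt(tapply(as.vector(Mod(fa)^2), idx, sum) *
                tapply(as.vector(Mod(fb)^2), idx, sum))
  expected <- as.vector(num / den)
  freq <- (sort(unique(as.vector(idx))) - 1) * sh$width
  keep <- freq <= sh$nyquist + 1e-12
  expect_equal(got$fsc, expected[keep], tolerance = 1e-10)
})

test_that("FSC is symmetric and scale-invariant, and masks clamp to [0,1]", {
  set.seed(4)
  a <- density_map(array(rnorm(6^3), dim = c(6, 6, 6)))
  b <- density_map(array(rnorm(6^3), dim = c(6, 6, 6)))
  f_ab <- fsc(a, b)
  expect_equal(f_ab$fsc, fsc(b, a)$fsc, tolerance = 1e-12)
  b_scaled <- density_map(3.7 * b$values, b$voxel_size)
  expect_equal(fsc(a, b_scaled)$fsc, f_ab$fsc, tolerance = 1e-12)
  mask <- density_map(array(2, dim = c(6, 6, 6)))  # clamped to 1
  expect_equal(fsc(a, b, mask)$fsc, f_ab$fsc, tolerance = 1e-12)
})

test_that("resolution thresholding interpolates, with sentinel and coarse cases", {
  curve <- structure(tibble::tibble(
    freq = c(0, 0.1, 0.2, 0.3, 0.4), fsc = c(1, 1, 0.8, 0.2, 0.05),
    n_voxels = 10L, flag = ""), class = c("fsc_curve", class(tibble::tibble())))
  # crossing 0.5 between 0.2 and 0.3: f* = 0.2 + (0.3/0.6)*0.1 = 0.25
  expect_equal(resolution_at(curve, 0.5), 4)
  flat1 <- curve; flat1$fsc <- rep(1, 5)
  r <- resolution_at(flat1, 0.143)
  expect_true(is.na(r))
  expect_equal(attr(r, "sentinel"), "better_than_nyquist")
  expect_equal(resolution_at(curve, 1.5), 1 / 0.1)
})

test_that("model perturbation is bounded, seeded, and identity at zero", {
  ch <- build_toy_channel(5, c(-6, 6), 2, 14, 1.5, 7)
  expect_identical(perturb_model(ch, 0), ch)
  p1 <- perturb_model(ch, 0.5, seed = 11)
  p2 <- perturb_model(ch, 0.5, seed = 11)
  expect_identical(p1, p2)
  d <- sqrt((p1$x - ch$x)^2 + (p1$y - ch$y)^2 + (p1$z - ch$z)^2)
  expect_true(all(d <= 0.5 + 1e-12))
  expect_gt(max(d), 0.2)  # displacements actually happen
  p3 <- perturb_model(ch, 0.5, seed = 12)
  expect_false(identical(p1$x, p3$x))
})

test_that("identical half maps give identical curves and zero gap", {
  ch <- build_toy_channel(5, c(-6, 6), 2, 14, 1.5, 7)
  maps <- synth_map(ch, voxel_size = 2, pad = 6, blur_width = 3.15,
                    noise_sd = 0, halves = TRUE)
  cv <- crossval_fsc(ch, maps$half1, maps$half2, maps$full)
  expect_equal(cv$gap, 0, tolerance = 1e-12)
  expect_equal(cv$fsc_half1$fsc, cv$fsc_half2$fsc)
  # noiseless self-consistent trio: all curves at 1 in populated shells
  ok <- cv$fsc_full$flag == ""
  expect_true(all(abs(cv$fsc_full$fsc[ok] - 1) < 1e-6))
})

test_that("a model built from one half's noise shows a positive FSC gap", {
  ch <- build_toy_channel(5, c(-6, 6), 2, 14, 1.5, 7)
  maps <- synth_map(ch, voxel_size = 2, pad = 6, blur_width = 3.15,
                    noise_sd = 0.002, halves = TRUE, seed = 5)
  # "refine into half1": a model map biased towards half1's realization
  biased <- density_map(0.7 * cptk:::model_to_map(ch, maps$half1, 3.15)$values +
                          0.3 * maps$half1$values,
                        maps$half1$voxel_size, maps$half1$origin)
  f1 <- fsc(biased, maps$half1)
  f2 <- fsc(biased, maps$half2)
  expect_gt(max(abs(f1$fsc - f2$fsc)), 0)
  expect_gt(mean(f1$fsc) - mean(f2$fsc), 0)
})

test_that("increasing perturbation degrades the map-model resolution", {
  ch <- build_toy_channel(5, c(-6, 6), 2, 14, 1.5, 7)
  ref <- synth_map(ch, voxel_size = 1.5, pad = 6, blur_width = 2)
  res_at <- function(disp, seed) {
    pm <- perturb_model(ch, disp, seed = seed)
    f <- fsc(model_to_map(pm, ref, blur_width = 2), ref)
    r <- resolution_at(f, 0.5)
    if (is.na(r)) 2 * max(ref$voxel_size) else r
  }
  res <- sapply(c(0, 1, 2), function(d) mean(sapply(1:3, function(s) res_at(d, s))))
  expect_true(all(diff(res) >= -1e-9))
  expect_gt(res[3], res[1])
})

test_that("per-residue Z-scores pool to mean 0, sd 1, and rank a displaced residue last", {
  ch <- build_toy_channel(5, c(-8, 8), 2, 14, 1.5, 7)
  moved <- ch
  sel <- moved$chain == "A" & moved$resid == 5
  moved$x[sel] <- moved$x[sel] + 5
  map <- synth_map(ch, voxel_size = 1.5, pad = 6, blur_width = 3.15)
  z <- local_fit_z(moved, map, blur_width = 3.15)
  ok <- z$flag == "" & !is.na(z$z)
  expect_equal(mean(z$z[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(z$z[ok]), 1, tolerance = 1e-9)
  worst <- z[which.min(z$z), ]
  expect_equal(worst$chain, "A")
  expect_equal(worst$resid, 5)
})

test_that("a map generated from the model itself flags degenerate pooling", {
  ch <- build_toy_channel(5, c(-4, 4), 2, 7, 1.5, 7)
  map <- synth_map(ch, voxel_size = 1.5, pad = 6, blur_width = 3.15)
  z <- local_fit_z(ch, map, blur_width = 3.15)
  # all residues fit equally well: raw scores equal, Z forced to 0
  expect_true(all(z$flag == "degenerate_pooling"))
  expect_true(all(z$z == 0))
})

test_that("local scaling is identity on self and recovers a uniform scale", {
  ch <- build_toy_channel(5, c(-6, 6), 2, 14, 1.5, 7)
  ref <- synth_map(ch, voxel_size = 1.5, pad = 6, blur_width = 2.5)
  out_same <- local_scale(ref, ref, window = 12)
  expect_equal(out_same$values, ref$values, tolerance = 1e-6)
  halfmap <- density_map(0.5 * ref$values, ref$voxel_size, ref$origin)
  out <- local_scale(halfmap, ref, window = 12)
  # amplitudes restored to the reference within 5 percent
  expect_lt(max(abs(out$values - ref$values)) / max(abs(ref$values)), 0.05)
  # phase structure preserved: near-perfect correlation with the input
  expect_gt(cor(as.vector(out$values), as.vector(halfmap$values)), 0.99)
})
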