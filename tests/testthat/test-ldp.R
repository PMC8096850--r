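test_that("mean shift converges to the centre of a single Gaussian blob", {
  m <- blob_model(matrix(c(5, 5, 5), 1))
  map <- synth_map(m, grid_spec(c(21, 21, 21), 0.5, c(0, 0, 0)),
                   blur_width = 1.5)
  y <- c(3.4, 6.1, 4.2)
  for (i in 1:100) y <- mean_shift_step(y, map, bandwidth = 1)
  expect_equal(as.numeric(y), c(5, 5, 5), tolerance = 0.05)
})

test_that("a constant map returns the position unchanged", {
  map <- density_map(array(1, dim = c(15, 15, 15)), voxel_size = 1)
  y0 <- c(7, 7, 7)
  y1 <- mean_shift_step(y0, map, bandwidth = 2)
  expect_equal(as.numeric(y1), y0, tolerance = 1e-9)
})

test_that("zero-weight neighbourhoods raise the null-shift flag", {
  map <- density_map(array(0, dim = c(10, 10, 10)), voxel_size = 1)
  y1 <- mean_shift_step(c(5, 5, 5), map, bandwidth = 1)
  expect_true(attr(y1, "null_shift"))
  expect_equal(as.numeric(y1), c(5, 5, 5))
})

test_that("with two equal blobs the iteration converges to the nearer mode", {
  centers <- rbind(c(5, 10, 10), c(25, 10, 10))
  m <- blob_model(centers)
  map <- synth_map(m, grid_spec(c(31, 21, 21), 1, c(0, 0, 0)),
                   blur_width = 1.5)
  y <- c(11, 10, 10)  # 6 A from blob A, 14 A from blob B
  for (i in 1:200) y <- mean_shift_step(y, map, bandwidth = 2)
  expect_equal(as.numeric(y), centers[1, ], tolerance = 0.5)
})

test_that("mean-shift ascent never decreases the kernel-smoothed density", {
  set.seed(4)
  centers <- matrix(runif(9, 5, 20), 3)
  map <- synth_map(blob_model(centers), grid_spec(c(26, 26, 26), 1),
                   blur_width = 2)
  for (start in list(c(8, 8, 8), c(14, 15, 12), c(18, 18, 18))) {
    y <- start
    d_prev <- cptk:::kernel_density_at(y, map, 2)
    for (i in 1:60) {
      y <- mean_shift_step(y, map, bandwidth = 2)
      d_now <- cptk:::kernel_density_at(y, map, 2)
      # ascent up to the tiny non-monotonicity the 3-sigma kernel
      # truncation can introduce
      expect_gte(d_now, d_prev * (1 - 2e-4))
      d_prev <- d_now
    }
  }
})

test_that("k well-separated blobs give exactly k LDPs at the blob centres", {
  centers <- rbind(c(6, 6, 6), c(22, 6, 6), c(6, 22, 6), c(14, 14, 20))
  map <- synth_map(blob_model(centers), grid_spec(c(29, 29, 27), 1),
                   blur_width = 1.5)
  ldps <- extract_ldps(map, threshold = 0.3 * max(map$values), bandwidth = 2)
  expect_equal(nrow(ldps), 4)
  got <- as.matrix(ldps[, c("x", "y", "z")])
  ord <- apply(got, 1, function(p) which.min(colSums((t(centers) - p)^2)))
  expect_equal(sort(ord), 1:4)
  expect_true(all(sqrt(rowSums((got - centers[ord, ])^2)) < 0.5))
  expect_true(all(ldps$members >= 1))
})

test_that("a threshold above the map maximum yields an empty LDP set", {
  map <- synth_map(blob_model(matrix(c(5, 5, 5), 1)),
                   grid_spec(c(11, 11, 11), 1), blur_width = 1.5)
  ldps <- extract_ldps(map, threshold = 2 * max(map$values))
  expect_equal(nrow(ldps), 0)
})

test_that("k-sigma threshold notation matches the explicit level", {
  map <- synth_map(blob_model(matrix(c(5, 5, 5), 1)),
                   grid_spec(c(11, 11, 11), 1), blur_width = 1.5)
  lvl <- resolve_threshold(map, "2sigma")
  expect_equal(lvl, mean(map$values) + 2 * sd(as.vector(map$values)))
  expect_equal(nrow(extract_ldps(map, "2sigma")),
               nrow(extract_ldps(map, lvl)))
})

test_that("LDP extraction is equivariant under integer-voxel translation", {
  centers <- rbind(c(8, 8, 8), c(16, 12, 10))
  map <- synth_map(blob_model(centers), grid_spec(c(25, 25, 25), 1),
                   blur_width = 1.5)
  shifted <- density_map(map$values, map$voxel_size, map$origin + c(3, -2, 5))
  a <- extract_ldps(map, "1sigma")
  b <- extract_ldps(shifted, "1sigma")
  expect_equal(nrow(a), nrow(b))
  sort_pts <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  expect_equal(sort_pts(as.matrix(b[, c("x", "y", "z")])),
               sort_pts(sweep(as.matrix(a[, c("x", "y", "z")]), 2,
                              c(-3, 2, -5))),
               tolerance = 1e-6)
})

test_that("LDPs trace a blurred helix close to the generating backbone", {
  # synthetic Ca helix: rise 1.5 A, radius 2.3 A, 100 deg/residue, blurred
  # to 3.15 A resolution (FWHM -> sigma) as for a mid-resolution map
  n_res <- 30
  t_ang <- (seq_len(n_res) - 1) * 100 * pi / 180
  bb <- cbind(2.3 * cos(t_ang), 2.3 * sin(t_ang), 1.5 * (seq_len(n_res) - 1))
  helix <- atomic_model(tibble::tibble(
    chain = "A", resid = seq_len(n_res), resname = "ALA", atom = "CA",
    element = "C", x = bb[, 1], y = bb[, 2], z = bb[, 3]))
  map <- synth_map(helix, voxel_size = 1, pad = 7,
                   blur_width = 3.15 / (2 * sqrt(2 * log(2))))
  # trail-tracing bandwidth narrow enough to resolve the helical pitch
  ldps <- extract_ldps(map, "1sigma", bandwidth = 1.5)
  expect_gt(nrow(ldps), 3)
  # distance from each LDP to the backbone polyline (dense interpolation)
  tt <- seq(0, 1, length.out = 2000)
  seg <- apply(bb, 2, function(col) approx(seq_len(n_res), col, tt * (n_res - 1) + 1)$y)
  d <- apply(as.matrix(ldps[, c("x", "y", "z")]), 1, function(p) {
    sqrt(min(colSums((t(seg) - p)^2)))
  })
  expect_gte(mean(d <= 1.5), 0.9)
})

test_that("the LDP graph connects points under the cutoff symmetrically", {
  ldps <- structure(tibble::tibble(
    x = c(0, 3, 10), y = c(0, 0, 0), z = c(0, 0, 0),
    density_at_point = c(3, 2, 1), members = c(1L, 1L, 1L)),
    class = c("ldp_set", class(tibble::tibble())))
  g <- ldp_graph(ldps, cutoff = 5)
  expect_equal(nrow(g), 1)
  expect_equal(g$distance, 3)
  expect_equal(nrow(ldp_graph(ldps, cutoff = 0.1)), 0)
})

test_that("helix LDPs form one connected trail at a 4 A cutoff", {
  n_res <- 20
  t_ang <- (seq_len(n_res) - 1) * 100 * pi / 180
  helix <- atomic_model(tibble::tibble(
    chain = "A", resid = seq_len(n_res), resname = "ALA", atom = "CA",
    element = "C", x = 2.3 * cos(t_ang), y = 2.3 * sin(t_ang),
    z = 1.5 * (seq_len(n_res) - 1)))
  map <- synth_map(helix, voxel_size = 1, pad = 6, blur_width = 2.5)
  ldps <- extract_ldps(map, "1sigma", bandwidth = 2)
  g <- ldp_graph(ldps, cutoff = 4)
  # label propagation connectivity over the edge list
  comp <- seq_len(nrow(ldps))
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(g))) {
      a <- comp[g$from[e]]; b <- comp[g$to[e]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  expect_equal(length(unique(comp)), 1)
})
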