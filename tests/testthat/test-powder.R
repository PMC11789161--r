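test_that("a single atom at the origin gives |F|^2 = f(s)^2 everywhere", {
  s <- crystal_structure(lattice_cell(6, 6, 6),
                         sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  refl <- reflections(s, two_theta_max = 40)
  sv <- sin(refl$two_theta / 2 * pi / 180) / attr(refl, "wavelength")
  th <- refl$two_theta / 2 * pi / 180
  lp <- (1 + cos(2 * th)^2) / (sin(th)^2 * cos(th))
  f2 <- vapply(sv, function(x) cspmatch:::scattering_factor("C", x)^2, 0)
  expect_equal(refl$intensity, f2 * lp * refl$multiplicity, tolerance = 1e-9)
})

test_that("a centrosymmetric structure has equal Friedel intensities", {
  s <- crystal_structure(lattice_cell(8, 9, 10), spacegroup_symops("P-1"),
                         atoms_df(c("C", "O"),
                                  matrix(c(0.13, 0.21, 0.33,
                                           0.4, 0.11, 0.09), 2, byrow = TRUE)))
  ex <- expand_to_cell(s)
  F2 <- function(h, k, l) {
    ph <- 2 * pi * (h * ex$x + k * ex$y + l * ex$z)
    f <- vapply(ex$element, function(e)
      cspmatch:::scattering_factor(e, 0.1), 0)
    sum(f * cos(ph))^2 + sum(f * sin(ph))^2
  }
  for (hkl in list(c(1, 2, 1), c(2, 0, 1), c(1, 1, 3))) {
    expect_equal(F2(hkl[1], hkl[2], hkl[3]),
                 F2(-hkl[1], -hkl[2], -hkl[3]), tolerance = 1e-9)
    # imaginary part vanishes: F real
    ph <- 2 * pi * (hkl[1] * ex$x + hkl[2] * ex$y + hkl[3] * ex$z)
    f <- vapply(ex$element, function(e)
      cspmatch:::scattering_factor(e, 0.1), 0)
    expect_equal(sum(f * sin(ph)), 0, tolerance = 1e-9)
  }
})

test_that("P21/c systematic absences emerge from the structure-factor sum", {
  s <- make_toy_crystal("toy7", "P21/c")
  refl <- reflections(s, two_theta_max = 35)
  r0k0 <- refl[refl$h == 0 & refl$l == 0, ]
  odd <- r0k0[abs(r0k0$k) %% 2 == 1, ]
  even <- r0k0[abs(r0k0$k) %% 2 == 0, ]
  expect_gt(nrow(odd), 0)
  expect_lt(max(odd$intensity) / max(even$intensity), 1e-12)
  # h0l with l odd also absent (c glide)
  rh0l <- refl[refl$k == 0 & abs(refl$l) %% 2 == 1, ]
  expect_lt(max(rh0l$intensity) / max(refl$intensity), 1e-12)
  # against a brute-force direct sum on a few reflections
  ex <- expand_to_cell(s)
  for (i in sample(nrow(refl), 5)) {
    h <- refl$h[i]; k <- refl$k[i]; l <- refl$l[i]
    sv <- sin(refl$two_theta[i] / 2 * pi / 180) / attr(refl, "wavelength")
    f <- vapply(ex$element, function(e)
      cspmatch:::scattering_factor(e, sv), 0)
    ph <- 2 * pi * (h * ex$x + k * ex$y + l * ex$z)
    F2 <- sum(f * cos(ph))^2 + sum(f * sin(ph))^2
    th <- refl$two_theta[i] / 2 * pi / 180
    lp <- (1 + cos(2 * th)^2) / (sin(th)^2 * cos(th))
    expect_equal(refl$intensity[i] / refl$multiplicity[i], F2 * lp,
                 tolerance = 1e-9)
  }
})

test_that("Bragg's law places the cubic (100) peak", {
  s <- crystal_structure(lattice_cell(10, 10, 10),
                         sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  p <- simulate_pattern(s, two_theta_range = c(3, 20), step = 0.005)
  want <- 2 * asin(1.54056 / 20) * 180 / pi
  got <- p$two_theta[which.max(p$intensity)]
  expect_equal(got, want, tolerance = 0.01)
})

test_that("patterns are invariant to occupancy scaling and supercells", {
  s <- make_toy_crystal("toy7", "P21/c")
  p1 <- simulate_pattern(s)
  s2 <- s; s2$sites$occupancy <- 0.5
  p2 <- simulate_pattern(s2)
  expect_equal(p2$intensity, p1$intensity, tolerance = 1e-9)
  p3 <- simulate_pattern(supercell(s, 2, 1, 1))
  expect_equal(p3$intensity, p1$intensity, tolerance = 1e-8)
})

test_that("peak areas scale with merged reflection intensity", {
  # two well-separated peaks: integrated areas must be in intensity ratio
  s <- crystal_structure(lattice_cell(9, 9, 14),
                         sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  refl <- reflections(s, two_theta_max = 16)
  use <- refl[refl$two_theta > 3 & refl$two_theta < 16, ]
  use <- use[order(use$two_theta), ]
  p <- simulate_pattern(s, two_theta_range = c(3, 16), step = 0.002)
  # area around each of the two lowest-angle peaks by trapezoid quadrature
  area_near <- function(t0) {
    w <- abs(p$two_theta - t0) < 0.45
    sum(p$intensity[w]) * p$step
  }
  a1 <- area_near(use$two_theta[1]); a2 <- area_near(use$two_theta[2])
  expect_equal(a1 / a2, use$intensity[1] / use$intensity[2],
               tolerance = 0.02)
})

test_that("de Gelder similarity: identity, scaling, symmetry, monotone shift", {
  s <- make_toy_crystal("toy7", "P21/c")
  p <- simulate_pattern(s)
  expect_equal(degelder_similarity(p, p), 1, tolerance = 1e-12)
  p3 <- powder_pattern(p$two_theta, 3 * p$intensity, p$wavelength)
  expect_equal(degelder_similarity(p, p3), 1, tolerance = 1e-12)
  q <- simulate_pattern(perturb(s, strain = 0.01), )
  expect_equal(degelder_similarity(p, q), degelder_similarity(q, p),
               tolerance = 1e-12)
  # single Gaussian peak shifted by increasing amounts: similarity decreases
  grid <- seq(5, 25, by = 0.02)
  gauss <- function(mu) exp(-(grid - mu)^2 / (2 * 0.05^2))
  base <- powder_pattern(grid, gauss(15))
  sims <- vapply(c(0, 0.5, 1, 2, 3), function(d)
    degelder_similarity(base, powder_pattern(grid, gauss(15 + d))), 0)
  expect_true(all(diff(sims) < 0))
})

test_that("de Gelder similarity equals direct summation for offset Gaussians", {
  grid <- seq(5, 25, by = 0.02)
  l <- 1.5
  gauss <- function(mu) exp(-(grid - mu)^2 / (2 * 0.1^2))
  for (delta in c(0, l / 2, 2 * l)) {
    p <- powder_pattern(grid, gauss(12))
    q <- powder_pattern(grid, gauss(12 + delta))
    got <- degelder_similarity(p, q, l)
    want <- oracle_degelder(gauss(12), gauss(12 + delta), 0.02, l)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("all-zero and non-overlapping patterns are rejected", {
  grid <- seq(5, 10, by = 0.01)
  p <- powder_pattern(grid, rep(0, length(grid)))
  q <- powder_pattern(grid, runif(length(grid)))
  expect_error(degelder_similarity(p, q), "all-zero")
  r <- powder_pattern(seq(20, 25, by = 0.01), runif(501))
  expect_error(degelder_similarity(q, r), "overlap")
})

test_that("cell refinement is a no-op at the optimum and recovers strain", {
  s0 <- make_toy_crystal("toy7", "P21/c",
                         cell = lattice_cell(10.5, 11.5, 12.5, 90, 98, 90),
                         position = c(0.22, 0.28, 0.24),
                         orientation = c(20, 35, 10))
  target <- simulate_pattern(s0)
  same <- refine_cell(s0, target)
  expect_equal(unname(same$structure$cell$a), 10.5, tolerance = 1e-6)
  expect_gte(same$similarity, 1 - 1e-9)
  strained <- perturb(s0, strain = 0.02)
  rec <- refine_cell(strained, target)
  expect_gte(rec$similarity, rec$start_similarity)  # monotone acceptance
  expect_equal(unname(rec$structure$cell$a), 10.5, tolerance = 1e-3)
  expect_equal(unname(rec$structure$cell$b), 11.5, tolerance = 1e-3)
  expect_equal(unname(rec$structure$cell$c), 12.5, tolerance = 1e-3)
  # monoclinic constraints: only beta among angles is free
  expect_setequal(rec$free$lengths, c("a", "b", "c"))
  expect_equal(rec$free$angles, "beta")
})

test_that("March-Dollase correction: identity at r=1, unit spherical mean", {
  s <- make_toy_crystal("toy7", "P21/c")
  refl <- reflections(s, two_theta_max = 25)
  expect_equal(preferred_orientation(refl, s, c(0, 0, 1), 1)$intensity,
               refl$intensity)
  # spherical average of the March-Dollase factor is 1 for any r
  for (r in c(0.5, 0.8, 1.5)) {
    fac <- function(mu) (r^2 * mu^2 + (1 - mu^2) / r)^(-3 / 2)
    expect_equal(stats::integrate(fac, 0, 1, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-6)
  }
  # r < 1 enhances the aligned axis reflection relative to r > 1
  lo <- preferred_orientation(refl, s, c(0, 0, 1), 0.6)
  hi <- preferred_orientation(refl, s, c(0, 0, 1), 1.6)
  ax <- which(refl$h == 0 & refl$k == 0 & abs(refl$l) == 2)[1]
  expect_gt(lo$intensity[ax], refl$intensity[ax])
  expect_lt(hi$intensity[ax], refl$intensity[ax])
})

test_that("xy pattern files round-trip with their wavelength", {
  s <- make_toy_crystal("toy7", "P21/c")
  p <- simulate_pattern(s, wavelength = 0.7)
  f <- tempfile(fileext = ".xy")
  write_xy(p, f)
  p2 <- read_xy(f)
  expect_equal(p2$wavelength, 0.7, tolerance = 1e-9)
  expect_equal(p2$two_theta, p$two_theta, tolerance = 1e-9)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-9)
})
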