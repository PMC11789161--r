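test_that("simple cubic PDD matches the analytic shell structure", {
  s <- crystal_structure(lattice_cell(1, 1, 1),
                         sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  p <- compute_pdd(s, 26)
  expect_length(p$weights, 1)
  expect_equal(p$weights, 1)
  want <- c(rep(1, 6), rep(sqrt(2), 12), rep(sqrt(3), 8))
  expect_equal(p$distances[1, ], want, tolerance = 1e-9)
  # and against brute-force supercell enumeration
  brute <- oracle_pdd_rows(s, 26)
  expect_equal(p$distances[1, ], brute[1, ], tolerance = 1e-12)
})

test_that("PDD rows equal brute-force enumeration on general structures", {
  fixtures <- list(
    make_toy_crystal("toy7", "P1"),
    make_toy_crystal("toy7", "P21/c"),
    perturb(make_toy_crystal("toy7h", "P1"), jitter = 0.05, seed = 3)
  )
  for (s in fixtures) {
    k <- 12
    p <- compute_pdd(s, k)
    brute <- oracle_pdd_rows(s, k)
    # reconstruct per-atom rows from the collapsed matrix by weight
    got <- p$distances[rep(seq_along(p$weights),
                           round(p$weights * nrow(brute))), , drop = FALSE]
    ord <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
    expect_equal(ord(got), ord(brute), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("PDD is invariant under unit-cell re-settings", {
  s <- make_toy_crystal("toy7", "P21/c")
  p0 <- compute_pdd(s, 20)
  # supercell
  p2 <- compute_pdd(supercell(s, 2, 1, 1), 20)
  expect_equal(pdd_distance(p0, p2), 0, tolerance = 1e-9)
  # origin shift (on the P1 re-expression, where it is symmetry-preserving)
  sp1 <- supercell(s, 1, 1, 1)
  s3 <- sp1; s3$sites$x <- (s3$sites$x + 0.31) %% 1
  expect_equal(pdd_distance(p0, compute_pdd(s3, 20)), 0, tolerance = 1e-9)
  # axis relabel: rebuild as P1 with permuted axes
  ex <- expand_to_cell(s)
  cell4 <- lattice_cell(s$cell$b, s$cell$a, s$cell$c,
                        s$cell$beta, s$cell$alpha, s$cell$gamma)
  s4 <- crystal_structure(cell4,
                          sites = data.frame(
                            label = paste0(ex$element, seq_len(nrow(ex))),
                            element = ex$element,
                            x = ex$y, y = ex$x, z = ex$z))
  expect_equal(pdd_distance(p0, compute_pdd(s4, 20)), 0, tolerance = 1e-9)
})

test_that("inequivalent environments keep separate rows with count weights", {
  # any two-atom P1 cell is centrosymmetric, so its two rows coincide:
  s2 <- crystal_structure(lattice_cell(4, 5, 6),
                          sites = atoms_df(c("C", "C"),
                                           matrix(c(0, 0, 0, 0.5, 0.37, 0.21),
                                                  2, byrow = TRUE)))
  p2 <- compute_pdd(s2, 8)
  expect_length(p2$weights, 1)
  expect_equal(p2$weights, 1)
  # three unevenly spaced atoms have three distinct environments
  s3 <- crystal_structure(lattice_cell(10, 7, 8),
                          sites = atoms_df(c("C", "C", "C"),
                                           matrix(c(0, 0.1, 0.1,
                                                    0.1, 0.1, 0.1,
                                                    0.5, 0.1, 0.1), 3,
                                                  byrow = TRUE)))
  p3 <- compute_pdd(s3, 6)
  expect_length(p3$weights, 3)
  expect_equal(p3$weights, rep(1 / 3, 3))
  # rows sorted lexicographically
  expect_true(all(diff(p3$distances[, 1]) >= 0))
})

test_that("EMD between PDDs: identity, single rows, and LP oracle", {
  s <- make_toy_crystal("toy7", "P1")
  p <- compute_pdd(s, 10)
  expect_equal(pdd_distance(p, p), 0, tolerance = 1e-12)
  # single-row matrices: EMD = L-infinity row distance
  r1 <- structure(list(weights = 1, distances = matrix(1:5, 1), k = 5L),
                  class = "pdd_matrix")
  r2 <- structure(list(weights = 1,
                       distances = matrix(c(1.5, 2, 3.4, 4, 5.2), 1), k = 5L),
                  class = "pdd_matrix")
  expect_equal(pdd_distance(r1, r2), 0.5, tolerance = 1e-12)
  expect_error(pdd_distance(r1, structure(list(weights = 1,
    distances = matrix(1:4, 1), k = 4L), class = "pdd_matrix")),
    "different k")
  # random weighted instances vs exact LP solve
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(2:4, 1); n <- sample(2:4, 1); k <- 6
    A <- t(apply(matrix(runif(m * k, 1, 5), m), 1, sort))
    B <- t(apply(matrix(runif(n * k, 1, 5), n), 1, sort))
    w1 <- runif(m); w1 <- w1 / sum(w1)
    w2 <- runif(n); w2 <- w2 / sum(w2)
    C <- cspmatch:::.linf_cost(A, B)
    got <- emd_transport(w1, w2, C)$cost
    want <- oracle_emd(w1, w2, C)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("EMD is symmetric and satisfies the triangle inequality on fixtures", {
  fixtures <- list(
    make_toy_crystal("toy7", "P1"),
    perturb(make_toy_crystal("toy7", "P1"), jitter = 0.05, seed = 1),
    make_toy_crystal("toy7", "P1", cell = lattice_cell(8.8, 9.6, 10.4)),
    make_toy_crystal("toy7", "P21/c")
  )
  pdds <- lapply(fixtures, compute_pdd, k = 15)
  D <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    D[i, j] <- pdd_distance(pdds[[i]], pdds[[j]])
  expect_equal(D, t(D), tolerance = 1e-9)
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
})

test_that("perturbing all atoms by eps moves the PDD by at most 2*eps", {
  s <- make_toy_crystal("toy7", "P21/c")
  p0 <- compute_pdd(s, 15)
  for (eps in c(0.02, 0.05, 0.1)) {
    s2 <- perturb(s, jitter = eps / 3, seed = 8)  # 3-sigma below eps mostly
    maxdisp <- attr(s2, "max_displacement")
    d <- pdd_distance(p0, compute_pdd(s2, 15))
    expect_lte(d, 2 * maxdisp + 1e-9)
  }
})

test_that("volume normalization rescales exactly and helps strained pairs", {
  ref <- make_toy_crystal("toy7", "P21/c")
  expect_equal(volume_normalize(ref, ref)$cell$a, ref$cell$a)
  # cube-root scaling
  a10 <- crystal_structure(lattice_cell(10, 10, 10),
                           sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  a11 <- crystal_structure(lattice_cell(11, 11, 11),
                           sites = atoms_df("C", matrix(c(0, 0, 0), 1)))
  vn <- volume_normalize(a10, a11)
  expect_equal(vn$cell$a, 11, tolerance = 1e-9)
  expect_equal(vn$cell$volume, a11$cell$volume, tolerance = 1e-6)
  # isotropic strain: normalization reduces the PDD distance
  strained <- perturb(ref, strain = 0.02)
  before <- pdd_distance(compute_pdd(ref, 15), compute_pdd(strained, 15))
  after <- pdd_distance(compute_pdd(volume_normalize(ref, strained), 15),
                        compute_pdd(strained, 15))
  expect_lte(after, before)
  expect_lt(after, 1e-9)  # pure isotropic strain is removed entirely
})

test_that("PDD match verdicts behave at the cutoff and ignore H consistently", {
  ref <- make_toy_crystal("toy7h", "P21/c", cell = lattice_cell(11, 12, 13))
  near <- perturb(ref, strain = 0.01, jitter = 0.02, seed = 2)
  far <- make_toy_crystal("toy7h", "P21/c",
                          cell = lattice_cell(12.5, 10.8, 14.2, 90, 104, 90),
                          orientation = c(45, 80, 160))
  expect_true(is_pdd_match(ref, ref, k = 30))
  expect_true(is_pdd_match(ref, near, k = 30))
  m_far <- is_pdd_match(ref, far, k = 30)
  expect_false(m_far)
  expect_gt(attr(m_far, "distance"), 0.225)
  # verdict identical whether both structures include H or neither does
  v_all <- is_pdd_match(ref, near, k = 30, include_hydrogen = TRUE)
  v_heavy <- is_pdd_match(strip_atoms(ref, elements = "H"),
                          strip_atoms(near, elements = "H"), k = 30)
  expect_equal(as.logical(v_all), as.logical(v_heavy))
})

test_that("raising the cutoff never flips a match to a non-match", {
  ref <- make_toy_crystal("toy7", "P21/c")
  probe <- perturb(ref, strain = 0.015, jitter = 0.04, seed = 6)
  cuts <- c(0.05, 0.15, 0.3, 0.6)
  verdicts <- vapply(cuts, function(ct)
    as.logical(is_pdd_match(ref, probe, k = 20, cutoff = ct)), TRUE)
  expect_true(all(diff(verdicts) >= 0))
})
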