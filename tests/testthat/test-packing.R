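test_that("molecule equivalence is a labelled graph isomorphism", {
  s <- make_toy_crystal("toy7", "P1")
  m <- perceive_molecules(s)[[1]]
  expect_equal(molecules_equivalent(m, m), seq_along(m$elements))
  s2 <- make_toy_crystal("coform3", "P1")
  m2 <- perceive_molecules(s2)[[1]]
  expect_null(molecules_equivalent(m, m2))
  # hydrogens excluded on request: toy7h vs toy7 agree on heavy atoms
  sh <- make_toy_crystal("toy7h", "P1")
  mh <- perceive_molecules(sh)[[1]]
  expect_false(is.null(molecules_equivalent(mh, m, ignore_hydrogen = TRUE)))
})

test_that("automorphism count of a symmetric ring equals brute force", {
  # square C4 ring: dihedral symmetry of the labelled graph = 8 automorphisms
  ring <- crystal_structure(
    lattice_cell(12, 12, 12),
    sites = atoms_df(rep("C", 4),
                     cspmatch:::cart_to_frac(lattice_cell(12, 12, 12),
                       matrix(c(0, 0, 0, 1.5, 0, 0, 1.5, 1.5, 0, 0, 1.5, 0),
                              4, 3, byrow = TRUE) + 4)))
  m <- perceive_molecules(ring)[[1]]
  maps <- molecules_equivalent(m, m, all_mappings = TRUE)
  # brute force over all 4! permutations preserving adjacency
  adj <- matrix(FALSE, 4, 4)
  for (r in seq_len(nrow(m$bonds)))
    adj[m$bonds[r, 1], m$bonds[r, 2]] <- adj[m$bonds[r, 2], m$bonds[r, 1]] <- TRUE
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  nauto <- sum(apply(perms, 1, function(p)
    all(adj[p, p] == adj)))
  expect_equal(length(maps), nauto)
  expect_equal(length(maps), 8)
})

test_that("self-comparison is a perfect match at any shell size", {
  fixtures <- list(
    make_toy_crystal("toy7", "P1"),
    make_toy_crystal("toy7", "P21/c"),
    make_toy_crystal("toy7h", "P212121", cell = lattice_cell(11, 12, 13))
  )
  for (s in fixtures) for (n in c(5, 15)) {
    pm <- compare_packing(s, s, tolerance_spec(n_molecules = n))
    expect_equal(pm$n_matched, n)
    expect_equal(pm$rmsd, 0, tolerance = 1e-10)
  }
})

test_that("packing comparison equals the exhaustive oracle on small clusters", {
  tolc <- tolerance_spec(n_molecules = 4)
  pairs <- list(
    list(make_toy_crystal("toy7", "P1"),
         perturb(make_toy_crystal("toy7", "P1"), jitter = 0.03, seed = 2)),
    list(make_toy_crystal("toy7", "P21/c"),
         perturb(make_toy_crystal("toy7", "P21/c"), strain = 0.01,
                 jitter = 0.02, seed = 5)),
    list(make_toy_crystal("toy7", "P1"),
         make_toy_crystal("toy7", "P1", cell = lattice_cell(9, 8, 10),
                          orientation = c(40, 70, 10)))
  )
  for (pr in pairs) {
    got <- compare_packing(pr[[1]], pr[[2]], tolc)
    want <- oracle_compare_packing(pr[[1]], pr[[2]], tolc)
    expect_equal(got$n_matched, want$n_matched)
    if (want$n_matched > 0)
      expect_equal(got$rmsd, want$rmsd, tolerance = 1e-8)
  }
})

test_that("n_matched is monotone in the tolerances", {
  s <- make_toy_crystal("toy7", "P21/c")
  p <- perturb(s, strain = c(0.04, -0.02, 0.03), jitter = 0.05, seed = 9)
  tight <- compare_packing(s, p, tolerance_spec(dist_tol = 0.10,
                                                angle_tol = 10,
                                                n_molecules = 12))
  loose <- compare_packing(s, p, tolerance_spec(dist_tol = 0.35,
                                                angle_tol = 35,
                                                n_molecules = 12))
  expect_lte(tight$n_matched, loose$n_matched)
})

test_that("small jitter keeps a full match with proportional RMSD", {
  s <- make_toy_crystal("toy7", "P21/c")
  for (sg in c(0.01, 0.03, 0.05)) {
    p <- perturb(s, jitter = sg, seed = 11)
    pm <- compare_packing(s, p, tolerance_spec(n_molecules = 10))
    expect_equal(pm$n_matched, 10)
    expect_lt(pm$rmsd, sqrt(3) * sg * 3)
  }
})

test_that("the comparison is invariant to a supercell re-expression", {
  s <- make_toy_crystal("toy7", "P21/c")
  p <- perturb(s, jitter = 0.02, seed = 4)
  pm1 <- compare_packing(s, p, tolerance_spec(n_molecules = 8))
  pm2 <- compare_packing(s, supercell(p, 2, 1, 1),
                         tolerance_spec(n_molecules = 8))
  expect_equal(pm1$n_matched, pm2$n_matched)
  expect_equal(pm1$rmsd, pm2$rmsd, tolerance = 1e-8)
})

test_that("unrelated packings give a low, non-growing matched fraction", {
  a <- make_toy_crystal("toy7", "P1", cell = lattice_cell(8, 9, 10))
  b <- make_toy_crystal("toy7", "P1", cell = lattice_cell(10.5, 12.8, 9.3),
                        orientation = c(55, 100, 210))
  scan <- cluster_size_scan(a, b, c(4, 8, 12),
                            tolerance_spec(trial_cap = 1e7))
  frac <- scan$n_matched / scan$n
  expect_true(all(diff(frac) <= 1e-12))
  expect_lt(frac[3], 1)
})

test_that("an inverted probe matches when improper overlays are allowed", {
  s <- make_toy_crystal("toy7", "P1")
  inv <- s
  inv$sites$x <- (-inv$sites$x) %% 1
  inv$sites$y <- (-inv$sites$y) %% 1
  inv$sites$z <- (-inv$sites$z) %% 1
  pm <- compare_packing(s, inv, tolerance_spec(n_molecules = 6,
                                               allow_inversion = TRUE))
  expect_equal(pm$n_matched, 6)
  expect_equal(pm$rmsd, 0, tolerance = 1e-9)
  expect_false(pm$transform$proper)
})

test_that("the trial cap surfaces as an explicit error, never a silent zero", {
  s <- make_toy_crystal("toy7", "P21/c")
  expect_error(
    compare_packing(s, perturb(s, jitter = 0.03, seed = 1),
                    tolerance_spec(n_molecules = 20, trial_cap = 3)),
    "comparison limit")
})

test_that("landscape dedupe recovers planted duplicate clusters", {
  base1 <- make_toy_crystal("toy7", "P21/c")
  base2 <- make_toy_crystal("toy7", "P21/c",
                            cell = lattice_cell(11.5, 10.2, 14.1, 90, 105, 90),
                            orientation = c(60, 20, 80))
  landscape <- list(
    perturb(base1, jitter = 0.01, seed = 1),
    perturb(base2, jitter = 0.01, seed = 2),
    perturb(base1, jitter = 0.012, seed = 3),
    perturb(base1, jitter = 0.008, seed = 4),
    perturb(base2, jitter = 0.01, seed = 5)
  )
  for (i in seq_along(landscape))
    landscape[[i]]$meta$energy <- c(5, 3, 4, 6, 2)[i]
  part <- dedupe_key(landscape, tolerance_spec(n_molecules = 8),
                     rmsd_threshold = 0.5)
  expect_equal(part$cluster[1], part$cluster[3])
  expect_equal(part$cluster[1], part$cluster[4])
  expect_equal(part$cluster[2], part$cluster[5])
  expect_false(part$cluster[1] == part$cluster[2])
  # representatives are the lowest-energy members
  expect_equal(unique(part$representative[part$cluster == part$cluster[1]]), 3)
  expect_equal(unique(part$representative[part$cluster == part$cluster[2]]), 5)
})

test_that("five near-identical copies collapse to one cluster", {
  base <- make_toy_crystal("toy7", "P21/c")
  landscape <- lapply(1:5, function(k) perturb(base, jitter = 0.01, seed = k))
  part <- dedupe_key(landscape, tolerance_spec(n_molecules = 8),
                     rmsd_threshold = 0.5)
  expect_equal(length(unique(part$cluster)), 1)
})
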