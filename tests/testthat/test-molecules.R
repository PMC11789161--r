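test_that("molecule perception finds the template bond graph", {
  s <- make_toy_crystal("toy7", "P1")
  mols <- perceive_molecules(s)
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]$bonds), 6)   # acyclic 7-atom chain w/ branches
  expect_equal(molecular_formula(mols[[1]]), "C4ClNO")
  expect_equal(mols[[1]]$centroid, colMeans(mols[[1]]$xyz))
})

test_that("a cocrystal yields molecules of two chemical species", {
  tm1 <- template_molecule("toy7"); tm2 <- template_molecule("coform3")
  cell <- lattice_cell(9, 10, 16)
  place <- function(tm, zoff) {
    xyz <- as.matrix(tm[c("x", "y", "z")])
    fr <- cspmatch:::cart_to_frac(cell, xyz)
    fr[, 3] <- fr[, 3] + zoff
    data.frame(label = paste0(tm$element, seq_len(nrow(tm)), "_", zoff),
               element = tm$element, x = fr[, 1] %% 1, y = fr[, 2] %% 1,
               z = fr[, 3] %% 1)
  }
  s <- crystal_structure(cell, sites = rbind(place(tm1, 0.15),
                                             place(tm2, 0.6)))
  mols <- perceive_molecules(s)
  forms <- sort(vapply(mols, molecular_formula, ""))
  expect_equal(forms, c("C4ClNO", "CNO"))
})

test_that("jitter below the bond margin preserves the bond graph", {
  s <- make_toy_crystal("toy7h", "P21/c", cell = lattice_cell(11, 12, 13))
  m0 <- perceive_molecules(s)
  for (seed in 1:5) {
    s2 <- perturb(s, jitter = 0.05, seed = seed)
    m2 <- perceive_molecules(s2)
    expect_length(m2, length(m0))
    for (i in seq_along(m0)) {
      expect_equal(sort(m2[[i]]$elements), sort(m0[[i]]$elements))
      expect_equal(nrow(m2[[i]]$bonds), nrow(m0[[i]]$bonds))
    }
  }
})

test_that("an atom chain crossing the cell is unwrapped contiguously", {
  # molecule placed across the cell boundary: centroid near the origin corner
  s <- make_toy_crystal("toy7", "P1", position = c(0.02, 0.01, 0.98))
  mols <- perceive_molecules(s)
  expect_length(mols, 1)
  d <- as.matrix(dist(mols[[1]]$xyz))
  expect_lt(max(d), 8)  # contiguous, not split across images
})

test_that("a covalently connected periodic network is flagged as non-molecular", {
  # atoms 1.5 A apart along a 3 A axis bond into an infinite chain
  s <- crystal_structure(lattice_cell(3, 8, 8),
                         sites = atoms_df(c("C", "C"),
                                          matrix(c(0, 0.1, 0.1,
                                                   0.5, 0.1, 0.1), 2,
                                                 byrow = TRUE)))
  expect_error(perceive_molecules(s), "non-molecular")
})

test_that("Z' is 1 for a P1 one-molecule crystal and 3 for Z'=3 fixtures", {
  expect_equal(as.numeric(z_prime(make_toy_crystal("toy7", "P1"))), 1)
  # three independent molecules in P1
  cell <- lattice_cell(9, 10, 18)
  tm <- template_molecule("toy7")
  rows <- do.call(rbind, lapply(1:3, function(k) {
    xyz <- as.matrix(tm[c("x", "y", "z")])
    fr <- cspmatch:::cart_to_frac(cell, xyz)
    fr[, 3] <- fr[, 3] + (k - 1) / 3 + 0.05
    data.frame(label = paste0(tm$element, seq_len(nrow(tm)), "_", k),
               element = tm$element, x = fr[, 1] %% 1, y = fr[, 2] %% 1,
               z = fr[, 3] %% 1)
  }))
  s3 <- crystal_structure(cell, sites = rows)
  expect_equal(as.numeric(z_prime(s3)), 3)
})

test_that("Z' is fractional for a molecule on a special position", {
  # centrosymmetric diatomic straddling the inversion centre in P-1:
  # one site expands to the two-atom molecule, so half a molecule is
  # symmetry-independent
  s <- crystal_structure(lattice_cell(8, 9, 10), spacegroup_symops("P-1"),
                         atoms_df("O", matrix(c(0.08, 0, 0), 1)))
  zp <- z_prime(s)
  expect_equal(as.numeric(zp), 0.5)
  expect_equal(names(zp), "O2")
})

test_that("Z' of a cocrystal is reported per species with formula units", {
  pairdat <- make_disorder_pair()
  s <- pairdat$components[[1]]
  zp <- z_prime(s)
  expect_equal(attr(zp, "formula_units"), 1)
})

test_that("disorder splitting recovers the planted components exactly", {
  pairdat <- make_disorder_pair(occupancies = c(0.6, 0.4))
  comps <- split_disorder(pairdat$disordered)
  expect_length(comps, 2)
  for (k in 1:2) {
    got <- comps[[k]]$sites
    want <- pairdat$components[[k]]$sites
    expect_equal(as.matrix(got[c("x", "y", "z")]),
                 as.matrix(want[c("x", "y", "z")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(got$occupancy == 1))
  }
  # ordered structure: singleton
  s <- make_toy_crystal("toy7", "P1")
  expect_length(split_disorder(s), 1)
})

test_that("a chemically incomplete disorder component errors", {
  pairdat <- make_disorder_pair()
  s <- pairdat$disordered
  # drop one atom of component 2's arm: that component loses an atom
  s$sites <- s$sites[s$sites$label != "F8B", ]
  expect_error(split_disorder(s), "incomplete")
})

test_that("strip_atoms removes hydrogens and whole matched fragments", {
  s <- make_toy_crystal("toy7h", "P21/c", cell = lattice_cell(11, 12, 13))
  sh <- strip_atoms(s, elements = "H")
  expect_false(any(sh$sites$element == "H"))
  expect_equal(nrow(sh$sites), 7)
  # fragment strip: remove the C-F arm tip from the toycore crystal
  sc <- make_toy_crystal("toycore", "P21/c", cell = lattice_cell(11, 12, 13))
  m <- perceive_molecules(sc)[[1]]
  frag <- cspmatch:::.mol_subset(m, which(m$labels %in% c("C7", "F8")))
  s2 <- strip_atoms(sc, fragment = frag)
  expect_equal(sort(s2$sites$label),
               sort(setdiff(sc$sites$label, c("C7", "F8"))))
  expect_error(strip_atoms(sc, elements = c("C", "N", "O", "F")),
               "all atoms")
})

test_that("stripping before comparison equals masking inside the comparison", {
  # core-equal pair differing only in the arm: after stripping the arm from
  # both, the packing comparison must see identical structures
  sc <- make_toy_crystal("toycore", "P21/c", cell = lattice_cell(11, 12, 13))
  m <- perceive_molecules(sc)[[1]]
  frag <- cspmatch:::.mol_subset(m, which(m$labels %in% c("C7", "F8")))
  s1 <- strip_atoms(sc, fragment = frag)
  pm <- compare_packing(s1, s1, tolerance_spec(n_molecules = 6))
  expect_equal(pm$n_matched, 6)
  expect_equal(pm$rmsd, 0, tolerance = 1e-9)
})

test_that("build_cluster is exact against supercell enumeration", {
  s <- make_toy_crystal("toy7", "P1")
  mols <- perceive_molecules(s)
  cl <- build_cluster(s, 15, mols = mols)
  expect_length(cl, 15)
  d_pkg <- sort(vapply(cl[-1], function(m)
    sqrt(sum((m$centroid - cl[[1]]$centroid)^2)), 0))
  # brute force over a 5^3 supercell
  c0 <- mols[[1]]$centroid
  sh <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  dall <- sort(apply(sh, 1, function(v)
    sqrt(sum((as.numeric(s$cell$ortho %*% v))^2))))
  dall <- dall[dall > 1e-9][1:14]
  expect_equal(d_pkg, dall, tolerance = 1e-9)
  # trivial cases
  expect_length(build_cluster(s, 1, mols = mols), 1)
  expect_length(build_cluster(s, 30, mols = mols), 30)
})

test_that("cluster construction is deterministic under repeated calls", {
  s <- make_toy_crystal("toy7", "P21/c")
  c1 <- build_cluster(s, 12)
  c2 <- build_cluster(s, 12)
  for (i in seq_along(c1))
    expect_equal(c1[[i]]$xyz, c2[[i]]$xyz)
})

test_that("molecule perception is invariant under asymmetric-unit re-origin", {
  s <- make_toy_crystal("toy7", "P21/c")
  s2 <- s
  s2$sites$x <- (s2$sites$x + 1) %% 1   # integer lattice translation
  s3 <- s
  s3$sites$x <- (s3$sites$x + 0.5) %% 1 # origin shift of the contents
  f0 <- sort(vapply(perceive_molecules(s), molecular_formula, ""))
  expect_equal(sort(vapply(perceive_molecules(s2), molecular_formula, "")), f0)
  expect_equal(sort(vapply(perceive_molecules(s3), molecular_formula, "")), f0)
  expect_length(perceive_molecules(s3), length(perceive_molecules(s)))
})
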