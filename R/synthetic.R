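# Deterministic synthetic-structure generators: toy crystals, perturbed
# near-duplicates, layered polytypes, disorder pairs, landscapes with planted
# duplicate clusters, and hull datasets with planted stable stoichiometries.

# Template molecules: hard-coded idealized rigid geometries (angstrom),
# chosen asymmetric so their bond graphs have no automorphisms and their
# inertial axes are well resolved.
.templates <- list(
  # 7 heavy atoms, planar-ish, one out-of-plane chlorine
  toy7 = data.frame(
    element = c("C", "C", "C", "N", "O", "C", "Cl"),
    x = c(0.0, 1.40, 2.10, 3.50, -0.70, 1.90, 3.05),
    y = c(0.0, 0.00, 1.20, 1.20, 1.10, -1.30, -2.25),
    z = c(0.0, 0.00, 0.00, 0.00, 0.00, 0.00, 0.55)
  ),
  # 7 heavy atoms with two hydrogens
  toy7h = data.frame(
    element = c("C", "C", "C", "N", "O", "C", "Cl", "H", "H"),
    x = c(0.0, 1.40, 2.10, 3.50, -0.70, 1.90, 3.05, 1.62, -0.55),
    y = c(0.0, 0.00, 1.20, 1.20, 1.10, -1.30, -2.25, 2.10, -0.95),
    z = c(0.0, 0.00, 0.00, 0.00, 0.00, 0.00, 0.55, 0.35, -0.30)
  ),
  # small 3-atom bent coformer
  coform3 = data.frame(
    element = c("N", "C", "O"),
    x = c(0.0, 1.30, 2.00),
    y = c(0.0, 0.00, 1.10),
    z = c(0.0, 0.00, 0.00)
  ),
  # a core with a substituent arm (for strip/conformer exercises): the arm
  # is atoms 6-8 (C-C-F chain off atom 2)
  toycore = data.frame(
    element = c("C", "C", "C", "N", "O", "C", "C", "F"),
    x = c(0.0, 1.40, 2.10, 3.50, -0.70, 1.90, 2.60, 3.95),
    y = c(0.0, 0.00, 1.20, 1.20, 1.10, -1.30, -2.55, -2.60),
    z = c(0.0, 0.00, 0.00, 0.00, 0.00, 0.00, 0.30, 0.55)
  )
)

#' Template molecule geometries
#' @param name One of \code{"toy7"}, \code{"toy7h"}, \code{"coform3"},
#'   \code{"toycore"}.
#' @return Data frame with columns \code{element, x, y, z} (Cartesian
#'   angstrom).
#' @export
template_molecule <- function(name = "toy7") {
  tm <- .templates[[name]]
  if (is.null(tm)) stop("unknown template: ", name)
  tm
}

# named substream: every generator derives its own RNG stream from
# (seed, name) so adding one generator never shifts another's output
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_len(nchar(name)) * 131))
  (as.numeric(seed) * 48271 + h) %% 2147483629
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rotmat <- function(alpha, beta, gamma) {
  # intrinsic z-y-x Euler rotations, angles in degrees
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3)
  Rz %*% Ry %*% Rx
}

#' Build a toy molecular crystal
#'
#' Places a (rotated) template molecule in the asymmetric unit of the
#' requested space group and verifies that no intermolecular contact is
#' shorter than \code{min_contact}.
#'
#' @param template Template name (see \code{\link{template_molecule}}) or a
#'   data frame of atoms.
#' @param spacegroup Hermann-Mauguin symbol resolved against the internal
#'   table (default \code{"P1"}).
#' @param cell A \code{\link{lattice_cell}}; a roomy default is chosen per
#'   space group if missing.
#' @param position Fractional centroid position of the molecule.
#' @param orientation Euler angles (degrees) applied to the template.
#' @param min_contact Minimum allowed intermolecular contact in angstrom
#'   (default 2.0).
#' @param meta Metadata list stored on the structure.
#' @return A \code{crystal_structure}.
#' @export
make_toy_crystal <- function(template = "toy7", spacegroup = "P1",
                             cell = NULL, position = c(0.25, 0.25, 0.25),
                             orientation = c(0, 0, 0), min_contact = 2.0,
                             meta = list()) {
  tm <- if (is.data.frame(template)) template else template_molecule(template)
  symops <- if (identical(toupper(spacegroup), "P1"))
    list(parse_symop("x,y,z")) else spacegroup_symops(spacegroup)
  if (is.null(cell)) {
    mult <- length(symops)
    base <- if (mult == 1) c(8, 9, 10) else if (mult == 2) c(9, 10, 11)
            else c(10, 12, 13)
    cell <- lattice_cell(base[1], base[2], base[3])
  }
  R <- .rotmat(orientation[1], orientation[2], orientation[3])
  xyz <- as.matrix(tm[c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- xyz %*% t(R)
  cart0 <- frac_to_cart(cell, matrix(position, 1))[1, ]
  xyz <- sweep(xyz, 2, cart0, "+")
  frac <- cart_to_frac(cell, xyz)
  sites <- data.frame(
    label = paste0(tm$element, seq_len(nrow(tm))),
    element = tm$element,
    x = frac[, 1] %% 1, y = frac[, 2] %% 1, z = frac[, 3] %% 1,
    stringsAsFactors = FALSE
  )
  s <- crystal_structure(cell, symops, sites, meta)
  .check_contacts(s, min_contact, nrow(tm))
  s
}

.check_contacts <- function(s, min_contact, atoms_per_mol) {
  mols <- tryCatch(perceive_molecules(s), error = function(e)
    stop("steric overlap: molecules bond into a periodic network (",
         conditionMessage(e), ")", call. = FALSE))
  sizes <- vapply(mols, function(m) length(m$elements), 0L)
  if (any(sizes != atoms_per_mol)) {
    stop(sprintf(
      "steric overlap: molecules fused (sizes %s, expected %d)",
      paste(unique(sizes), collapse = "/"), atoms_per_mol))
  }
  cl <- build_cluster(s, min(8, 1 + 4), mols = mols)
  dmin <- Inf
  for (i in seq_along(cl)[-1]) {
    dd <- sqrt(outer(rowSums(cl[[1]]$xyz^2), rowSums(cl[[i]]$xyz^2), "+") -
                 2 * tcrossprod(cl[[1]]$xyz, cl[[i]]$xyz))
    dmin <- min(dmin, dd)
  }
  if (dmin < min_contact)
    stop(sprintf("steric overlap: closest intermolecular contact %.3f A", dmin))
  invisible(TRUE)
}

#' Perturb a crystal structure
#'
#' Applies lattice strain and/or Gaussian atomic jitter. Deterministic for a
#' given seed.
#'
#' @param s A \code{crystal_structure}.
#' @param strain A single number (isotropic fractional strain on all
#'   lengths) or a length-3 vector of per-axis fractional strains.
#' @param jitter Standard deviation (angstrom) of isotropic Gaussian atomic
#'   displacement.
#' @param seed Integer seed for the jitter stream.
#' @return The perturbed structure; attribute \code{"max_displacement"}
#'   holds the largest atomic displacement applied (angstrom).
#' @export
perturb <- function(s, strain = 0, jitter = 0, seed = 1) {
  if (length(strain) == 1) strain <- rep(strain, 3)
  cell2 <- lattice_cell(s$cell$a * (1 + strain[1]),
                        s$cell$b * (1 + strain[2]),
                        s$cell$c * (1 + strain[3]),
                        s$cell$alpha, s$cell$beta, s$cell$gamma)
  s2 <- s; s2$cell <- cell2
  maxdisp <- 0
  if (jitter > 0) {
    n <- nrow(s2$sites)
    disp <- .with_seed(.substream_seed(seed, "perturb"),
                       matrix(stats::rnorm(3 * n, sd = jitter), n, 3))
    maxdisp <- max(sqrt(rowSums(disp^2)))
    dfrac <- t(cell2$frac %*% t(disp))
    s2$sites$x <- (s2$sites$x + dfrac[, 1]) %% 1
    s2$sites$y <- (s2$sites$y + dfrac[, 2]) %% 1
    s2$sites$z <- (s2$sites$z + dfrac[, 3]) %% 1
  }
  attr(s2, "max_displacement") <- maxdisp
  s2
}

#' Generate a layered polytype pair
#'
#' Two P1 structures built from identical molecular layers: a uniform
#' stacking, and a variant in which every m-th layer is inverted (rotated
#' half a turn about the lab a-axis, about its own centroid). The template
#' is deliberately tilted so the inversion axis is not an inertial axis of
#' the molecule. Layers are identical to machine precision, so cluster
#' comparisons spanning fewer than m layers cannot distinguish the pair.
#'
#' @param m Inversion period in layers (>= 2; default 6).
#' @param a,b In-layer cell lengths (angstrom).
#' @param spacing Layer spacing (angstrom).
#' @param template Template molecule name.
#' @return List with \code{uniform} (one-layer P1 cell) and \code{polytype}
#'   (m-layer P1 cell with the m-th layer inverted).
#' @export
make_polytypes <- function(m = 6, a = 6.5, b = 6.5, spacing = 3.5,
                           template = "toy7") {
  stopifnot(m >= 2)
  tm <- template_molecule(template)
  xyz0 <- as.matrix(tm[c("x", "y", "z")])
  xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
  # orient the molecule flat in the layer plane with its two in-plane
  # principal axes along the xy diagonals: a half-turn about the lab a-axis
  # then rotates both axes by 90 degrees, so inverted-layer molecules are
  # cleanly distinguishable from uniform ones at any sensible angle tolerance
  ev <- eigen(crossprod(xyz0), symmetric = TRUE)
  axes <- ev$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  r2 <- sqrt(2)
  target <- cbind(c(1, 1, 0) / r2, c(1, -1, 0) / r2, c(0, 0, 1))
  xyz0 <- xyz0 %*% axes %*% t(target) * 0.72
  flip <- diag(c(1, -1, -1))   # half-turn about lab a

  layer_sites <- function(xyz, cellm, zfrac, tag) {
    fr <- cart_to_frac(cellm, sweep(xyz, 2, c(a / 2, b / 2, 0), "+"))
    data.frame(
      label = paste0(tm$element, seq_len(nrow(tm)), "_", tag),
      element = tm$element,
      x = fr[, 1] %% 1, y = fr[, 2] %% 1, z = (fr[, 3] + zfrac) %% 1,
      stringsAsFactors = FALSE
    )
  }
  cell1 <- lattice_cell(a, b, spacing)
  s_uniform <- crystal_structure(cell1, sites = layer_sites(xyz0, cell1, 0, "L1"),
                                 meta = list(id = "uniform"))
  cellm <- lattice_cell(a, b, m * spacing)
  rows <- lapply(seq_len(m), function(li) {
    xyz <- if (li == m) xyz0 %*% t(flip) else xyz0
    layer_sites(xyz, cellm, (li - 1) / m, paste0("L", li))
  })
  s_poly <- crystal_structure(cellm, sites = do.call(rbind, rows),
                              meta = list(id = paste0("polytype", m)))
  list(uniform = s_uniform, polytype = s_poly)
}

#' Generate a two-component disorder fixture
#'
#' A crystal whose asymmetric unit superimposes two conformations of the
#' substituent arm of the \code{"toycore"} template, tagged as disorder
#' groups with the given occupancies. \code{\link{split_disorder}} recovers
#' the two planted ordered structures exactly.
#'
#' @param occupancies Length-2 occupancies summing to 1 (default
#'   \code{c(0.6, 0.4)}).
#' @param arm_rotation Torsion-like rotation (degrees) distinguishing the
#'   minor conformer's arm (default 110).
#' @return List with \code{disordered} (the tagged structure) and
#'   \code{components} (the two planted ordered structures).
#' @export
make_disorder_pair <- function(occupancies = c(0.6, 0.4),
                               arm_rotation = 110) {
  if (abs(sum(occupancies) - 1) > 1e-9)
    stop("occupancies must sum to 1")
  if (any(occupancies < 0) || any(occupancies > 1))
    stop("occupancies must lie in [0, 1]")
  tm <- template_molecule("toycore")
  arm <- 7:8          # the C-F tip of the arm rotates between conformers
  pivot <- as.numeric(tm[6, c("x", "y", "z")])
  xyzA <- as.matrix(tm[c("x", "y", "z")])
  R <- .rotmat(0, 0, arm_rotation)
  xyzB <- xyzA
  xyzB[arm, ] <- sweep(sweep(xyzB[arm, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, "+")
  cell <- lattice_cell(9, 10, 11)
  mk_sites <- function(xyz, suffix, occ, grp, which_rows) {
    fr <- cart_to_frac(cell, sweep(xyz[which_rows, , drop = FALSE], 2,
                                   frac_to_cart(cell, matrix(c(.3, .3, .3), 1))[1, ] -
                                     colMeans(as.matrix(tm[c("x", "y", "z")])),
                                   "+"))
    data.frame(
      label = paste0(tm$element[which_rows], which_rows, suffix),
      element = tm$element[which_rows],
      x = fr[, 1] %% 1, y = fr[, 2] %% 1, z = fr[, 3] %% 1,
      occupancy = occ, disorder_group = grp, stringsAsFactors = FALSE
    )
  }
  shared <- 1:6
  sA <- mk_sites(xyzA, "", 1, NA_character_, shared)
  armA <- mk_sites(xyzA, "A", occupancies[1], "1", arm)
  armB <- mk_sites(xyzB, "B", occupancies[2], "2", arm)
  if (occupancies[2] == 0) {
    sites <- rbind(sA, mk_sites(xyzA, "A", 1, NA_character_, arm))
    dis <- crystal_structure(cell, sites = sites,
                             meta = list(id = "ordered"))
    return(list(disordered = dis, components = list(dis)))
  }
  dis <- crystal_structure(cell, sites = rbind(sA, armA, armB),
                           meta = list(id = "disordered"))
  compA <- crystal_structure(cell, sites = {
    z <- rbind(sA, armA); z$occupancy <- 1; z$disorder_group <- NA; z
  }, meta = list(id = "component1"))
  compB <- crystal_structure(cell, sites = {
    z <- rbind(sA, armB); z$occupancy <- 1; z$disorder_group <- NA; z
  }, meta = list(id = "component2"))
  list(disordered = dis, components = list(compA, compB))
}

#' Generate a CSP-like landscape with planted structure
#'
#' Builds \code{n} structures: planted duplicate clusters of a reference
#' packing (lattice-strained/jittered copies), one optional true match to a
#' designated "experimental" structure, and decoy packings with distinct
#' molecular arrangements. Ranks and pseudo-energies are assigned.
#'
#' @param n Total structure count.
#' @param n_true_match How many entries duplicate the experimental packing
#'   (default 1).
#' @param duplicate_clusters Integer vector: sizes of planted duplicate
#'   clusters among the decoys (default none).
#' @param seed Integer seed.
#' @param match_rank Rank at which the (first) true match is placed
#'   (default 1).
#' @param template Template molecule name.
#' @return List with \code{experimental} (the designated reference
#'   structure), \code{landscape} (list of structures with rank/energy
#'   metadata), and \code{truth} (data frame: index, rank, cluster id, and
#'   \code{is_match}).
#' @export
make_landscape <- function(n = 100, n_true_match = 1,
                           duplicate_clusters = integer(0), seed = 1,
                           match_rank = 1, template = "toy7") {
  stopifnot(n >= 1, n_true_match <= n)
  sseed <- .substream_seed(seed, "landscape")
  exp_s <- make_toy_crystal(template, "P21/c",
                            cell = lattice_cell(10.5, 11.5, 12.5, 90, 98, 90),
                            position = c(0.22, 0.28, 0.24),
                            orientation = c(20, 35, 10),
                            meta = list(id = "experimental"))
  # decoy pool: same molecule, distinct packings (varied cell + orientation)
  decoy_params <- .with_seed(sseed, {
    ncfg <- n  # more than enough distinct configurations
    list(ab = matrix(stats::runif(3 * ncfg, 8.6, 13.8), ncol = 3),
         beta = stats::runif(ncfg, 92, 118),
         ori = matrix(stats::runif(3 * ncfg, 0, 360), ncol = 3),
         pos = matrix(stats::runif(3 * ncfg, 0.15, 0.35), ncol = 3),
         jit = matrix(stats::rnorm(3 * n, sd = 0.02), ncol = 3))
  })
  n_cluster_extra <- sum(pmax(duplicate_clusters - 1, 0))
  n_decoy_distinct <- n - n_true_match - n_cluster_extra
  if (n_decoy_distinct < length(duplicate_clusters))
    stop("landscape too small for the requested duplicate plan")
  structures <- vector("list", n)
  cluster_id <- integer(n)
  is_match <- logical(n)
  slot <- 1
  mk_decoy <- function(cfg, jseed) {
    for (attempt in 0:25) {
      s <- try(make_toy_crystal(
        template, "P21/c",
        cell = lattice_cell(decoy_params$ab[cfg, 1] + attempt * 0.37,
                            decoy_params$ab[cfg, 2] + attempt * 0.23,
                            decoy_params$ab[cfg, 3] + attempt * 0.41,
                            90, decoy_params$beta[cfg], 90),
        position = decoy_params$pos[cfg, ],
        orientation = decoy_params$ori[cfg, ]), silent = TRUE)
      if (!inherits(s, "try-error")) return(s)
    }
    stop("could not place a sterically valid decoy")
  }
  cl_counter <- 1
  # planted true matches: perturbed copies of the experimental packing
  for (t in seq_len(n_true_match)) {
    structures[[slot]] <- perturb(exp_s, strain = 0.004 * t,
                                  jitter = 0.015, seed = sseed + t)
    cluster_id[slot] <- 0; is_match[slot] <- TRUE
    slot <- slot + 1
  }
  # planted duplicate clusters among decoys
  cfg <- 1
  for (csize in duplicate_clusters) {
    base <- mk_decoy(cfg, cfg); cfg <- cfg + 1
    for (kk in seq_len(csize)) {
      structures[[slot]] <- perturb(base, strain = 0.003 * kk,
                                    jitter = 0.01, seed = sseed + 1000 + slot)
      cluster_id[slot] <- cl_counter
      slot <- slot + 1
    }
    cl_counter <- cl_counter + 1
  }
  # remaining distinct decoys
  while (slot <= n) {
    structures[[slot]] <- mk_decoy(cfg, cfg); cfg <- cfg + 1
    cluster_id[slot] <- cl_counter; cl_counter <- cl_counter + 1
    slot <- slot + 1
  }
  # ranks: true match placed at match_rank, others shuffled deterministically
  ord <- .with_seed(sseed + 7, sample(n))
  rank_of <- integer(n)
  others <- setdiff(ord, which(is_match))
  ranks_avail <- setdiff(seq_len(n), match_rank + seq_len(n_true_match) - 1)
  rank_of[which(is_match)] <- match_rank + seq_len(n_true_match) - 1
  rank_of[others] <- ranks_avail
  energies <- 10 + 0.25 * rank_of +
    .with_seed(sseed + 11, stats::rnorm(n, sd = 0.05))
  for (i in seq_len(n)) {
    structures[[i]]$meta$rank <- rank_of[i]
    structures[[i]]$meta$energy <- energies[i]
    structures[[i]]$meta$id <- paste0("cand", i)
  }
  truth <- data.frame(index = seq_len(n), rank = rank_of,
                      cluster = cluster_id, is_match = is_match)
  list(experimental = exp_s, landscape = structures, truth = truth)
}

#' Generate a hull dataset with planted stable stoichiometries
#'
#' Constructs per-stoichiometry energies such that exactly the requested
#' stoichiometries lie on the lower convex hull, with the given stability
#' margin; other candidate stoichiometries sit above the hull.
#'
#' @param stable Character vector of stable stoichiometries, e.g.
#'   \code{c("1:1", "2:1")} (x:y); pure endpoints are implicit.
#' @param candidates All candidate stoichiometries to emit (defaults to
#'   \code{c("1:2", "1:1", "2:1", "3:1", "1:3")}).
#' @param margin Stability margin in kJ/mol per molecule (default 1).
#' @param decoys_per_stoich Extra higher-energy structures per stoichiometry
#'   (default 2).
#' @param seed Integer seed.
#' @return List with \code{energies} (data frame id, x, y, E per formula
#'   unit), \code{E_A}, \code{E_B}, and \code{truth} (the planted stable
#'   set, sorted).
#' @export
make_hull_dataset <- function(stable = c("1:1", "2:1"),
                              candidates = c("1:2", "1:1", "2:1", "3:1", "1:3"),
                              margin = 1, decoys_per_stoich = 2, seed = 1) {
  stopifnot(all(stable %in% candidates))
  sseed <- .substream_seed(seed, "hull")
  E_A <- -100; E_B <- -80
  parse_st <- function(s) as.numeric(strsplit(s, ":")[[1]])
  xy <- t(vapply(candidates, parse_st, numeric(2)))
  comp <- xy[, 2] / rowSums(xy)
  # deltaf on the planted hull: piecewise-linear through stable points
  st_xy <- t(vapply(stable, parse_st, numeric(2)))
  st_comp <- st_xy[, 2] / rowSums(st_xy)
  depth <- .with_seed(sseed, stats::runif(length(stable), 2, 5))
  hull_x <- c(0, sort(st_comp), 1)
  hull_y <- c(0, -depth[order(st_comp)], 0)
  # convexify the planted depths so every requested point is a hull vertex
  while (length(hull_x) >= 3) {
    bad <- FALSE
    for (i in 2:(length(hull_x) - 1)) {
      lin <- hull_y[i - 1] + (hull_y[i + 1] - hull_y[i - 1]) *
        (hull_x[i] - hull_x[i - 1]) / (hull_x[i + 1] - hull_x[i - 1])
      if (hull_y[i] > lin - margin) {
        hull_y[i] <- lin - margin - 0.5
        bad <- TRUE
      }
    }
    if (!bad) break
  }
  hull_at <- function(xq) stats::approx(hull_x, hull_y, xq)$y
  deltaf <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    if (candidates[i] %in% stable) {
      deltaf[i] <- hull_y[match(round(comp[i], 9), round(hull_x, 9))]
    } else {
      deltaf[i] <- hull_at(comp[i]) + margin +
        .with_seed(sseed + i, stats::runif(1, 0.2, 2))
    }
  }
  E <- deltaf * rowSums(xy) + xy[, 1] * E_A + xy[, 2] * E_B
  rows <- data.frame(id = paste0(candidates, "#1"),
                     x = xy[, 1], y = xy[, 2], E = E,
                     stringsAsFactors = FALSE)
  if (decoys_per_stoich > 0) {
    extra <- .with_seed(sseed + 99, {
      do.call(rbind, lapply(seq_along(candidates), function(i)
        data.frame(id = paste0(candidates[i], "#", 1 + seq_len(decoys_per_stoich)),
                   x = xy[i, 1], y = xy[i, 2],
                   E = E[i] + stats::runif(decoys_per_stoich, 0.5, 8),
                   stringsAsFactors = FALSE, row.names = NULL)))
    })
    rows <- rbind(rows, extra)
  }
  list(energies = rows, E_A = E_A, E_B = E_B,
       truth = sort(stable))
}
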