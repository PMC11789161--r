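# Periodic molecule perception, Z', disorder splitting, atom stripping and
# coordination-cluster construction.

#' Perceive molecules in a crystal
#'
#' Expands the cell, assigns covalent bonds under periodic boundary conditions
#' (interatomic distance below the summed covalent radii plus \code{margin}),
#' and unwraps each connected component across cell boundaries into a
#' contiguous Cartesian molecule. Each molecule is translated so that its
#' centroid lies in the [0,1)^3 fractional box.
#'
#' @param s A \code{crystal_structure}.
#' @param component Disorder handling: \code{"all-major"} (default) keeps
#'   ordered atoms plus the highest-occupancy disorder component; a specific
#'   \code{disorder_group} tag keeps ordered atoms plus that component;
#'   \code{"all"} keeps everything (only sensible for ordered structures).
#' @param margin Bond tolerance added to summed covalent radii, in angstrom.
#' @param include_hydrogen Keep hydrogen atoms (default \code{TRUE}).
#' @return List of molecules; each is a list with \code{elements},
#'   \code{xyz} (Cartesian angstrom matrix), \code{labels} (source site
#'   labels), \code{sites} (source site indices), \code{bonds} (2-column
#'   index matrix), \code{centroid}.
#' @export
perceive_molecules <- function(s, component = "all-major", margin = 0.4,
                               include_hydrogen = TRUE) {
  ex <- expand_to_cell(s)
  if (!include_hydrogen) ex <- ex[ex$element != "H", , drop = FALSE]
  ex <- .select_component(ex, component)
  if (nrow(ex) == 0) stop("no atoms after component selection")
  frac <- as.matrix(ex[c("x", "y", "z")])
  n <- nrow(frac)
  radii <- covalent_radius(ex$element)
  cart0 <- frac_to_cart(s$cell, frac)

  # bonds under PBC: compare each pair across the 27 neighbor images
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  bond_i <- integer(0); bond_j <- integer(0); bond_shift <- NULL
  cutmax <- (outer(radii, radii, "+") + margin)
  for (r in seq_len(nrow(shifts))) {
    disp <- frac_to_cart(s$cell, matrix(shifts[r, ], 1))[1, ]
    cart_s <- sweep(cart0, 2, disp, "+")
    d2 <- outer(rowSums(cart0^2), rowSums(cart_s^2), "+") -
      2 * tcrossprod(cart0, cart_s)
    hit <- which(d2 < cutmax^2 & d2 > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      bond_i <- c(bond_i, hit[, 1]); bond_j <- c(bond_j, hit[, 2])
      bond_shift <- rbind(bond_shift,
                          matrix(rep(shifts[r, ], nrow(hit)),
                                 ncol = 3, byrow = TRUE))
    }
  }

  # unwrap: BFS over (atom, integer image) pairs
  assigned <- matrix(NA_real_, n, 3)
  comp <- rep(NA_integer_, n)
  adj <- split(seq_along(bond_i), bond_i)
  ncomp <- 0
  for (seed in seq_len(n)) {
    if (!is.na(comp[seed])) next
    ncomp <- ncomp + 1
    comp[seed] <- ncomp
    assigned[seed, ] <- c(0, 0, 0)
    queue <- seed
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (e in adj[[as.character(a)]]) {
        b <- bond_j[e]
        img <- assigned[a, ] + bond_shift[e, ]
        if (is.na(comp[b])) {
          comp[b] <- ncomp
          assigned[b, ] <- img
          queue <- c(queue, b)
        } else if (any(abs(assigned[b, ] - img) > 1e-9)) {
          stop("non-molecular solid: a bonded component spans a lattice translation")
        }
      }
    }
  }

  lapply(seq_len(ncomp), function(k) {
    idx <- which(comp == k)
    fr <- frac[idx, , drop = FALSE] + assigned[idx, , drop = FALSE]
    cen_f <- colMeans(fr)
    shift_back <- floor(cen_f)
    fr <- sweep(fr, 2, shift_back, "-")
    xyz <- frac_to_cart(s$cell, fr)
    sel <- which(bond_i %in% idx & bond_j %in% idx & bond_i < bond_j)
    bonds <- cbind(match(bond_i[sel], idx), match(bond_j[sel], idx))
    # drop duplicate bonds found via several images
    bonds <- unique(bonds)
    mol <- list(elements = ex$element[idx], xyz = xyz,
                labels = ex$label[idx], sites = ex$site[idx],
                bonds = bonds, centroid = colMeans(xyz))
    class(mol) <- "molecule"
    mol
  })
}

.select_component <- function(ex, component) {
  grp <- ex$disorder_group
  if (identical(component, "all")) return(ex)
  if (all(is.na(grp))) return(ex)
  groups <- unique(grp[!is.na(grp)])
  if (identical(component, "all-major")) {
    occ <- vapply(groups, function(g) mean(ex$occupancy[!is.na(grp) & grp == g]), 0)
    keep_grp <- groups[order(-occ, groups)][1]
  } else {
    if (!component %in% groups)
      stop("unknown disorder component: ", component)
    keep_grp <- component
  }
  ex[is.na(grp) | grp == keep_grp, , drop = FALSE]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %s (%d atoms, %d bonds)\n",
              molecular_formula(x), length(x$elements), nrow(x$bonds)))
  invisible(x)
}

#' Molecular formula (Hill order)
#' @param m A molecule.
#' @return Formula string, e.g. \code{"C6H6"}.
#' @export
molecular_formula <- function(m) {
  tab <- table(m$elements)
  els <- names(tab)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(tab[ord] > 1, tab[ord], ""), collapse = "")
}

# canonical, isometry-invariant hash of a molecule used for deterministic
# tie-breaking: formula plus the sorted intramolecular distance multiset
molecule_hash <- function(m, digits = 4) {
  d <- stats::dist(m$xyz)
  paste(molecular_formula(m),
        paste(sort(round(as.numeric(d), digits)), collapse = ","))
}

#' Z' per chemical species
#'
#' The number of symmetry-independent molecules of each species: molecules in
#' the unit cell divided by the symop count. Fractional values indicate
#' molecules on special positions.
#'
#' @param s A \code{crystal_structure}.
#' @param ... Passed to \code{\link{perceive_molecules}}.
#' @return Named numeric vector (one entry per species, named by formula)
#'   with attribute \code{"formula_units"}: the greatest common count across
#'   species, i.e. Z' counted in formula units.
#' @export
z_prime <- function(s, ...) {
  mols <- perceive_molecules(s, ...)
  formulas <- vapply(mols, molecular_formula, "")
  counts <- table(formulas)
  zp <- as.numeric(counts) / length(s$symops)
  names(zp) <- names(counts)
  # formula-unit Z': gcd of per-species molecule counts over |symops|
  g <- Reduce(.gcd, as.numeric(counts))
  attr(zp, "formula_units") <- g / length(s$symops)
  zp
}

.gcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b) { t <- b; b <- a %% b; a <- t }
  a
}

#' Split a disordered structure into ordered components
#'
#' One fully ordered structure per disorder component; ordered (untagged)
#' atoms appear in every component and all occupancies are reset to 1.
#'
#' @param s A \code{crystal_structure}.
#' @return List of ordered \code{crystal_structure}s (singleton list when
#'   \code{s} carries fewer than two disorder components). Component tags are
#'   recorded in \code{meta$component}.
#' @export
split_disorder <- function(s) {
  grp <- s$sites$disorder_group
  groups <- sort(unique(grp[!is.na(grp)]))
  if (length(groups) < 2) return(list(s))
  comps <- lapply(groups, function(g) {
    keep <- is.na(grp) | grp == g
    st <- s$sites[keep, , drop = FALSE]
    st$occupancy <- 1
    st$disorder_group <- NA_character_
    meta <- s$meta; meta$component <- g
    crystal_structure(s$cell, s$symops, st, meta)
  })
  # completeness: every component must carry the same molecular content
  forms <- lapply(comps, function(cs)
    sort(vapply(perceive_molecules(cs), molecular_formula, "")))
  for (k in seq_along(comps)[-1])
    if (!identical(forms[[k]], forms[[1]]))
      stop("disorder component '", groups[k],
           "' is chemically incomplete relative to '", groups[1], "'")
  names(comps) <- groups
  comps
}

#' Remove atoms from a structure or molecule
#'
#' Element-based or fragment-based stripping. For structures the selection is
#' made on perceived molecules and mapped back to asymmetric-unit sites, so
#' all symmetry images are removed consistently. For fragment selectors the
#' removal is by whole matched connected fragment.
#'
#' @param x A \code{crystal_structure} or molecule.
#' @param elements Character vector of element symbols to remove, or
#' @param labels Character vector of site labels to remove, or
#' @param fragment A molecule whose element-labelled bond graph selects the
#'   fragments to remove (every match removed).
#' @return Object of the same class with the selected atoms removed.
#' @export
strip_atoms <- function(x, elements = NULL, labels = NULL, fragment = NULL) {
  if (inherits(x, "molecule")) {
    drop <- .mol_strip_index(x, elements, labels, fragment)
    if (length(drop) == 0) return(x)
    if (length(drop) >= length(x$elements))
      stop("predicate removes all atoms")
    return(.mol_subset(x, setdiff(seq_along(x$elements), drop)))
  }
  stopifnot(inherits(x, "crystal_structure"))
  drop_labels <- character(0)
  if (!is.null(elements))
    drop_labels <- c(drop_labels, x$sites$label[x$sites$element %in% elements])
  if (!is.null(labels))
    drop_labels <- c(drop_labels, intersect(labels, x$sites$label))
  if (!is.null(fragment)) {
    mols <- perceive_molecules(x)
    for (m in mols) {
      idx <- .mol_strip_index(m, NULL, NULL, fragment)
      drop_labels <- c(drop_labels, m$labels[idx])
    }
  }
  drop_labels <- unique(drop_labels)
  keep <- !(x$sites$label %in% drop_labels)
  if (all(keep) ) return(x)
  if (!any(keep)) stop("predicate removes all atoms")
  crystal_structure(x$cell, x$symops, x$sites[keep, , drop = FALSE], x$meta)
}

.mol_strip_index <- function(m, elements, labels, fragment) {
  drop <- integer(0)
  if (!is.null(elements)) drop <- c(drop, which(m$elements %in% elements))
  if (!is.null(labels)) drop <- c(drop, which(m$labels %in% labels))
  if (!is.null(fragment)) {
    maps <- .fragment_matches(m, fragment)
    drop <- c(drop, unlist(maps))
  }
  unique(drop)
}

.mol_subset <- function(m, keep) {
  sel <- m$bonds[, 1] %in% keep & m$bonds[, 2] %in% keep
  bonds <- cbind(match(m$bonds[sel, 1], keep), match(m$bonds[sel, 2], keep))
  out <- list(elements = m$elements[keep],
              xyz = m$xyz[keep, , drop = FALSE],
              labels = m$labels[keep], sites = m$sites[keep],
              bonds = bonds,
              centroid = colMeans(m$xyz[keep, , drop = FALSE]))
  class(out) <- "molecule"
  out
}

# subgraph matches of a fragment inside molecule m (element-labelled);
# returns list of integer index vectors into m's atoms
.fragment_matches <- function(m, fragment) {
  gm <- .mol_graph(m); gf <- .mol_graph(fragment)
  maps <- igraph::graph.get.subisomorphisms.vf2(
    gm, gf,
    vertex.color1 = igraph::V(gm)$color, vertex.color2 = igraph::V(gf)$color)
  uniq <- unique(lapply(maps, function(mp) sort(as.integer(mp))))
  uniq
}

.mol_graph <- function(m) {
  g <- igraph::make_empty_graph(n = length(m$elements), directed = FALSE)
  if (nrow(m$bonds))
    g <- igraph::add_edges(g, t(m$bonds))
  igraph::V(g)$color <- match(m$elements, c(names(.covalent_radii)))
  g
}

#' Build an n-molecule coordination cluster
#'
#' The central molecule plus its n-1 nearest neighbours by centroid-centroid
#' distance over all periodic images. Ties in distance are broken by the
#' molecule's canonical hash, then by the lattice image vector in
#' lexicographic order, so cluster construction is deterministic.
#'
#' @param s A \code{crystal_structure}.
#' @param n Cluster size (molecule count), at least 1.
#' @param central Index of the central molecule among
#'   \code{perceive_molecules(s)} (default 1).
#' @param mols Optional precomputed molecule list for \code{s}.
#' @param ... Passed to \code{\link{perceive_molecules}}.
#' @return List of \code{n} molecules, the central one first, ordered by
#'   increasing centroid distance.
#' @export
build_cluster <- function(s, n, central = 1, mols = NULL, ...) {
  stopifnot(n >= 1)
  if (is.null(mols)) mols <- perceive_molecules(s, ...)
  if (central > length(mols)) stop("central index out of range")
  c0 <- mols[[central]]$centroid
  hashes <- vapply(mols, molecule_hash, "")
  # minimum slab thickness bounds the guaranteed-complete search radius
  ortho <- s$cell$ortho
  va <- ortho[, 1]; vb <- ortho[, 2]; vc <- ortho[, 3]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  tmin <- min(s$cell$volume / sqrt(sum(cr(vb, vc)^2)),
              s$cell$volume / sqrt(sum(cr(va, vc)^2)),
              s$cell$volume / sqrt(sum(cr(va, vb)^2)))
  r <- 1
  repeat {
    shifts <- as.matrix(expand.grid(a = -r:r, b = -r:r, k = -r:r))
    cand <- do.call(rbind, lapply(seq_along(mols), function(mi) {
      disp <- t(ortho %*% t(shifts))
      d <- sqrt(colSums((t(disp) + mols[[mi]]$centroid - c0)^2))
      data.frame(mol = mi, sa = shifts[, 1], sb = shifts[, 2],
                 sc = shifts[, 3], dist = d)
    }))
    cand <- cand[cand$dist > 1e-9 | cand$mol != central |
                   cand$sa != 0 | cand$sb != 0 | cand$sc != 0, ]
    # drop the central molecule at zero shift itself
    is_central <- cand$mol == central & cand$sa == 0 & cand$sb == 0 &
      cand$sc == 0
    cand <- cand[!is_central, ]
    ord <- order(round(cand$dist, 8), hashes[cand$mol],
                 cand$sa, cand$sb, cand$sc)
    cand <- cand[ord, ]
    if (n == 1 || nrow(cand) >= n - 1 && cand$dist[n - 1] < r * tmin) break
    r <- r + 1
    if (r > 8) stop("cluster search radius exceeded")
  }
  out <- vector("list", n)
  out[[1]] <- mols[[central]]
  for (k in seq_len(n - 1)) {
    row <- cand[k, ]
    m <- mols[[row$mol]]
    disp <- as.numeric(ortho %*% c(row$sa, row$sb, row$sc))
    m$xyz <- sweep(m$xyz, 2, disp, "+")
    m$centroid <- m$centroid + disp
    out[[k + 1]] <- m
  }
  out
}
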