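# COMPACK-style packing similarity: n-molecule cluster correspondence search
# under relative-distance and absolute-angle tolerances, followed by a joint
# rigid least-squares overlay.

#' Tolerances for packing comparison
#'
#' @param dist_tol Relative tolerance on centroid-centroid distances
#'   (fraction, default 0.35).
#' @param angle_tol Absolute tolerance on inter-centroid-vector angles in
#'   degrees (default 35).
#' @param n_molecules Cluster size (default 30).
#' @param ignore_hydrogen Exclude hydrogen atoms from perception and overlay
#'   (default \code{TRUE}).
#' @param allow_molecular_differences Reserved for future use; must be
#'   \code{FALSE} (molecules are required to be bond-graph isomorphic).
#' @param allow_inversion Allow improper overlays (default \code{TRUE}).
#' @param trial_cap Maximum number of correspondence trials before the
#'   comparison aborts with an explicit error (default 1e6).
#' @return A list of class \code{"tolerance_spec"}.
#' @export
tolerance_spec <- function(dist_tol = 0.35, angle_tol = 35, n_molecules = 30,
                           ignore_hydrogen = TRUE,
                           allow_molecular_differences = FALSE,
                           allow_inversion = TRUE, trial_cap = 1e6) {
  stopifnot(dist_tol > 0, dist_tol < 1, angle_tol > 0, angle_tol < 180,
            n_molecules >= 1)
  structure(list(dist_tol = dist_tol, angle_tol = angle_tol,
                 n_molecules = n_molecules,
                 ignore_hydrogen = ignore_hydrogen,
                 allow_molecular_differences = allow_molecular_differences,
                 allow_inversion = allow_inversion, trial_cap = trial_cap),
            class = "tolerance_spec")
}

#' Test two molecules for chemical equivalence
#'
#' Element-labelled bond-graph isomorphism; hydrogen atoms can be excluded.
#'
#' @param m1,m2 Molecules from \code{\link{perceive_molecules}}.
#' @param ignore_hydrogen Exclude hydrogens before comparing.
#' @param all_mappings Return every isomorphism rather than the first.
#' @return \code{NULL} when the molecules differ; otherwise an integer vector
#'   mapping atoms of \code{m1} to atoms of \code{m2} (or a list of all such
#'   mappings when \code{all_mappings = TRUE}).
#' @export
molecules_equivalent <- function(m1, m2, ignore_hydrogen = TRUE,
                                 all_mappings = FALSE) {
  if (ignore_hydrogen) {
    if (any(m1$elements == "H")) m1 <- strip_atoms(m1, elements = "H")
    if (any(m2$elements == "H")) m2 <- strip_atoms(m2, elements = "H")
  }
  if (length(m1$elements) != length(m2$elements)) return(NULL)
  if (!identical(sort(m1$elements), sort(m2$elements))) return(NULL)
  g1 <- .mol_graph(m1); g2 <- .mol_graph(m2)
  maps <- igraph::graph.get.isomorphisms.vf2(
    g1, g2, vertex.color1 = igraph::V(g1)$color,
    vertex.color2 = igraph::V(g2)$color)
  if (length(maps) == 0) return(NULL)
  maps <- lapply(maps, as.integer)
  if (all_mappings) maps else maps[[1]]
}

#' Compare the molecular packing of two crystals
#'
#' Builds an n-molecule cluster around each symmetry-independent reference
#' molecule and searches, over probe central molecules and molecule
#' correspondences, for the largest common cluster whose centroid-centroid
#' distances agree relatively within \code{dist_tol} and whose
#' inter-centroid-vector angles agree within \code{angle_tol}. Among maximal
#' correspondences the minimum joint-overlay RMSD is reported.
#'
#' @param ref,probe \code{crystal_structure}s.
#' @param tol A \code{\link{tolerance_spec}}.
#' @param full_only Only search for full-shell correspondences (the verdict
#'   question); partial matches then report \code{n_matched = 0}. Much
#'   faster on non-matching pairs (default \code{FALSE}).
#' @param keep Maximum number of maximal correspondences overlaid when
#'   minimizing the RMSD (default 256).
#' @return A \code{"packing_match"}: list with \code{n_matched},
#'   \code{n_requested}, \code{rmsd} (angstrom; \code{NA} when nothing
#'   matched), \code{correspondence}, \code{transform} (list rot/trans/proper)
#'   and \code{trials}.
#' @export
compare_packing <- function(ref, probe, tol = tolerance_spec(),
                            full_only = FALSE, keep = 256L) {
  mols_ref <- perceive_molecules(ref, include_hydrogen = !tol$ignore_hydrogen)
  mols_probe <- perceive_molecules(probe,
                                   include_hydrogen = !tol$ignore_hydrogen)
  .compare_packing_mols(ref, probe, mols_ref, mols_probe, tol,
                        full_only = full_only, keep = keep)
}

.compare_packing_mols <- function(ref, probe, mols_ref, mols_probe, tol,
                                  full_only = FALSE, keep = 256L) {
  n <- tol$n_molecules
  empty <- structure(list(n_matched = 0L, n_requested = n, rmsd = NA_real_,
                          correspondence = NULL, transform = NULL,
                          trials = 0L),
                     class = "packing_match")
  # isomorphism cache shared by all overlay evaluations, keyed by the
  # molecules' canonical hashes
  iso_cache <- new.env(hash = TRUE)

  # every molecule in the unit cell is a candidate central on both sides:
  # tie-breaking can give symmetry images genuinely different tie-broken
  # cluster memberships, so none can be skipped a priori
  n_shell_probe <- n + max(10L, ceiling(0.5 * n))
  ref_clusters <- lapply(seq_along(mols_ref), function(i)
    build_cluster(ref, n, central = i, mols = mols_ref))
  probe_shells <- lapply(seq_along(mols_probe), function(j)
    build_cluster(probe, min(n_shell_probe,
                             .max_cluster(probe, mols_probe)),
                  central = j, mols = mols_probe))

  best <- empty
  total_trials <- 0L
  done <- FALSE
  # incumbent bound: once some central pair achieves m matched molecules,
  # later pairs need only be searched up to the same number of skipped
  # molecules (ties are kept for the RMSD minimum); hopeless centrals then
  # exit at their first infeasibility check
  bound_skips <- if (full_only) 0L else n
  for (ref_cluster in ref_clusters) {
    if (done) break
    for (psh in probe_shells) {
      if (done) break
      # central molecules must be chemically equivalent
      isoc <- molecules_equivalent(ref_cluster[[1]], psh[[1]],
                                   ignore_hydrogen = FALSE,
                                   all_mappings = FALSE)
      if (is.null(isoc)) next
      res <- .match_clusters(ref_cluster, psh, tol,
                             budget = tol$trial_cap - total_trials,
                             keep = keep, max_skips = bound_skips)
      total_trials <- total_trials + res$trials
      for (assign in res$assignments) {
        nm <- 1L + sum(!is.na(assign))
        if (nm < best$n_matched) next
        ov <- .overlay_assignment(ref_cluster, psh, assign, tol, iso_cache)
        if (is.null(ov)) next
        if (nm > best$n_matched ||
            (nm == best$n_matched &&
             (is.na(best$rmsd) || ov$rmsd < best$rmsd - 1e-12))) {
          best <- structure(list(
            n_matched = nm, n_requested = n, rmsd = ov$rmsd,
            correspondence = ov$correspondence, transform = ov$transform,
            trials = total_trials), class = "packing_match")
        }
        # a full exact overlay cannot be improved upon
        if (best$n_matched == n && !is.na(best$rmsd) && best$rmsd < 1e-10) {
          done <- TRUE; break
        }
      }
      if (!full_only && best$n_matched > 0)
        bound_skips <- min(bound_skips, n - best$n_matched)
    }
  }
  best$trials <- total_trials
  best
}

# inertial principal axes of a molecule (unit masses); axes with a clear
# eigenvalue separation only, columns ordered by decreasing eigenvalue
.mol_axes <- function(m) {
  X <- sweep(m$xyz, 2, m$centroid)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  vals <- ev$values
  span <- max(vals) + 1e-12
  ok <- rep(TRUE, 3)
  for (ax in 1:3) {
    gaps <- abs(vals[ax] - vals[-ax]) / span
    if (min(gaps) < 1e-3) ok[ax] <- FALSE
  }
  list(vectors = ev$vectors, ok = ok)
}

# folded-angle orientation descriptor matrix for a cluster: for molecule i
# (excluding the central), angles (deg, in [0,90]) between its unit centroid
# vector and its own axes, and between its axes and the central molecule's
# axes, rank-matched. Columns for unresolved axes are dropped; NULL when
# nothing is resolvable.
.orientation_descriptors <- function(cluster, uvec) {
  axc <- .mol_axes(cluster[[1]])
  n <- length(cluster) - 1L
  out <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    axi <- .mol_axes(cluster[[i + 1]])
    for (ax in 1:3) {
      if (axi$ok[ax]) {
        ca <- abs(sum(uvec[i, ] * axi$vectors[, ax]))
        out[i, ax] <- acos(pmin(1, ca)) * 180 / pi
      }
      if (axi$ok[ax] && axc$ok[ax]) {
        ca <- abs(sum(axc$vectors[, ax] * axi$vectors[, ax]))
        out[i, 3 + ax] <- acos(pmin(1, ca)) * 180 / pi
      }
    }
  }
  keep <- colSums(!is.na(out)) == n
  if (!any(keep)) return(NULL)
  structure(out[, keep, drop = FALSE], cols = which(keep))
}

.max_cluster <- function(s, mols) {
  # a generous upper bound on sensible shell size given cell content
  length(mols) * 5L^3L
}

.unique_molecule_indices <- function(mols) {
  keys <- vapply(mols, function(m) paste(sort(m$sites), collapse = ","), "")
  which(!duplicated(keys))
}

# correspondence search between a reference cluster (list of molecules,
# central first) and a probe shell. Returns maximal assignments: integer
# vectors a with a[i] = probe shell index matched to ref cluster molecule
# i+1 (NA = unmatched); the central pair (1,1) is implicit.
.match_clusters <- function(ref_cluster, probe_shell, tol,
                            budget = 1e6, keep = 256L,
                            max_skips = .Machine$integer.max) {
  nr <- length(ref_cluster) - 1L
  np <- length(probe_shell) - 1L
  if (nr == 0)
    return(list(assignments = list(integer(0)), trials = 0L))
  c0r <- ref_cluster[[1]]$centroid
  c0p <- probe_shell[[1]]$centroid
  vr <- t(vapply(ref_cluster[-1], function(m) m$centroid - c0r, numeric(3)))
  vp <- t(vapply(probe_shell[-1], function(m) m$centroid - c0p, numeric(3)))
  dr <- sqrt(rowSums(vr^2)); dp <- sqrt(rowSums(vp^2))
  hr <- vapply(ref_cluster[-1], molecule_hash, "")
  hp <- vapply(probe_shell[-1], molecule_hash, "")

  # species compatibility via graph isomorphism, cached by hash pair
  iso_ok <- new.env(hash = TRUE)
  compatible <- function(i, j) {
    key <- paste0(hr[i], "|", hp[j])
    v <- iso_ok[[key]]
    if (is.null(v)) {
      v <- !is.null(molecules_equivalent(ref_cluster[[i + 1]],
                                         probe_shell[[j + 1]],
                                         ignore_hydrogen = FALSE))
      iso_ok[[key]] <- v
    }
    v
  }

  # pairwise angle (degrees) and centroid-centroid distance matrices over
  # the whole cluster: correspondences must preserve every inter-molecular
  # distance relatively within dist_tol and every angle within angle_tol
  ur <- vr / dr; up <- vp / dp
  Ar <- tcrossprod(ur); Ar[] <- acos(pmin(1, pmax(-1, Ar))) * 180 / pi
  Ap <- tcrossprod(up); Ap[] <- acos(pmin(1, pmax(-1, Ap))) * 180 / pi
  Dr <- as.matrix(stats::dist(vr))
  Dp <- as.matrix(stats::dist(vp))

  # per-molecule orientation descriptors: folded angles between the centroid
  # vector and the molecule's inertial axes, and between the molecule's axes
  # and the central molecule's axes (fold to [0, 90] so descriptors stay
  # inversion-blind)
  desc_r <- .orientation_descriptors(ref_cluster, ur)
  desc_p <- .orientation_descriptors(probe_shell, up)
  if (!is.null(desc_r) && !is.null(desc_p) &&
      !identical(attr(desc_r, "cols"), attr(desc_p, "cols"))) {
    desc_r <- desc_p <- NULL
  }

  cand <- lapply(seq_len(nr), function(i) {
    js <- which(abs(dr[i] - dp) / dr[i] <= tol$dist_tol)
    js <- js[vapply(js, function(j) compatible(i, j), TRUE)]
    if (length(js) && !is.null(desc_r) && !is.null(desc_p)) {
      dev <- abs(sweep(desc_p[js, , drop = FALSE], 2, desc_r[i, ]))
      js <- js[apply(dev, 1, max) <= tol$angle_tol]
    }
    js
  })

  # depth-first search with forward checking, iteratively deepened on the
  # number of unmatched reference molecules (compiled kernel); the first
  # skip budget admitting a complete traversal yields all maximal
  # correspondences (nr - budget matched, plus the central pair)
  res <- .match_clusters_cpp(Ar, Ap, Dr, Dp, cand, tol$angle_tol,
                             tol$dist_tol, budget, as.integer(keep),
                             as.integer(np),
                             as.integer(min(max_skips, nr)))
  if (isTRUE(res$limit))
    stop("comparison limit: correspondence trial cap (",
         format(budget), ") exceeded; raise trial_cap")
  list(assignments = res$assignments, trials = res$trials)
}

# joint overlay of a molecule-level assignment; returns rmsd, atom-level
# correspondence and the rigid transform, or NULL if mapping fails
.overlay_assignment <- function(ref_cluster, probe_shell, assign, tol,
                                iso_cache = new.env(hash = TRUE)) {
  pairs <- cbind(1L, 1L)
  for (i in seq_along(assign))
    if (!is.na(assign[i])) pairs <- rbind(pairs, c(i + 1L, assign[i] + 1L))
  # isomorphisms per pair, cached by canonical molecule hashes
  get_isos <- function(mr, mp) {
    key <- paste0(molecule_hash(mr), "|", molecule_hash(mp))
    v <- iso_cache[[key]]
    if (is.null(v)) {
      v <- list(maps = molecules_equivalent(mr, mp, ignore_hydrogen = FALSE,
                                            all_mappings = TRUE))
      iso_cache[[key]] <- v
    }
    v$maps
  }
  isos <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    isos[[r]] <- get_isos(ref_cluster[[pairs[r, 1]]],
                          probe_shell[[pairs[r, 2]]])
    if (is.null(isos[[r]])) return(NULL)
  }
  refit <- function(mapping) {
    X <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
      ref_cluster[[pairs[r, 1]]]$xyz))
    Y <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r)
      probe_shell[[pairs[r, 2]]]$xyz[mapping[[r]], , drop = FALSE]))
    kabsch(X, Y, allow_inversion = tol$allow_inversion)
  }
  best <- NULL
  for (iso0 in isos[[1]]) {
    mapping <- vector("list", nrow(pairs))
    mapping[[1]] <- iso0
    fit <- refit_central <- {
      X <- ref_cluster[[1]]$xyz
      Y <- probe_shell[[1]]$xyz[iso0, , drop = FALSE]
      kabsch(X, Y, allow_inversion = tol$allow_inversion)
    }
    for (pass in 1:2) {
      # choose, under the current transform, the best isomorphism per pair
      for (r in seq_len(nrow(pairs))[-1]) {
        X <- ref_cluster[[pairs[r, 1]]]$xyz
        Xt <- X %*% t(fit$rot) + matrix(fit$trans, nrow(X), 3, byrow = TRUE)
        errs <- vapply(isos[[r]], function(mp) {
          Y <- probe_shell[[pairs[r, 2]]]$xyz[mp, , drop = FALSE]
          sum((Xt - Y)^2)
        }, 0)
        mapping[[r]] <- isos[[r]][[which.min(errs)]]
      }
      fit <- refit(mapping)
    }
    if (is.null(best) || fit$rmsd < best$fit$rmsd)
      best <- list(fit = fit, mapping = mapping)
  }
  list(rmsd = best$fit$rmsd,
       transform = list(rot = best$fit$rot, trans = best$fit$trans,
                        proper = best$fit$proper),
       correspondence = lapply(seq_len(nrow(pairs)), function(r)
         list(ref = pairs[r, 1], probe = pairs[r, 2],
              atom_map = best$mapping[[r]])))
}

#' @export
print.packing_match <- function(x, ...) {
  cat(sprintf("packing match: %d/%d molecules overlaid%s\n",
              x$n_matched, x$n_requested,
              if (!is.na(x$rmsd)) sprintf(", RMSD %.4f A", x$rmsd) else ""))
  invisible(x)
}

#' Packing comparison across cluster sizes
#'
#' Runs \code{\link{compare_packing}} at each requested shell size and
#' reports the largest size at which a full-cluster match holds.
#'
#' @param ref,probe \code{crystal_structure}s.
#' @param sizes Ascending integer vector of cluster sizes.
#' @param tol A \code{\link{tolerance_spec}}; its \code{n_molecules} is
#'   overridden by each size in turn.
#' @return Data frame with columns \code{n, n_matched, rmsd, full_match};
#'   attribute \code{"largest_full_match"} gives the largest size fully
#'   matched (\code{NA} if none).
#' @export
cluster_size_scan <- function(ref, probe, sizes, tol = tolerance_spec()) {
  stopifnot(!is.unsorted(sizes))
  rows <- lapply(sizes, function(nn) {
    tol$n_molecules <- nn
    pm <- compare_packing(ref, probe, tol)
    data.frame(n = nn, n_matched = pm$n_matched, rmsd = pm$rmsd,
               full_match = pm$n_matched == nn)
  })
  out <- do.call(rbind, rows)
  full <- out$n[out$full_match]
  attr(out, "largest_full_match") <- if (length(full)) max(full) else NA
  out
}

#' Cluster a landscape by packing similarity
#'
#' Partitions a list of structures by the transitive closure of "full
#' packing match with RMSD below \code{rmsd_threshold}". The representative
#' of each cluster is its lowest-energy member when energies are present in
#' \code{meta}, else the first by input order.
#'
#' @param landscape List of \code{crystal_structure}s.
#' @param tol A \code{\link{tolerance_spec}} (use a small
#'   \code{n_molecules}, e.g. 10-15, for landscape work).
#' @param rmsd_threshold RMSD below which a full match is a duplicate
#'   (angstrom, default 0.5).
#' @return Data frame with columns \code{index, cluster, representative}.
#' @export
dedupe_key <- function(landscape, tol = tolerance_spec(n_molecules = 10),
                       rmsd_threshold = 0.5) {
  L <- length(landscape)
  parent <- seq_len(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j <= i) next
    if (find(i) == find(j)) next
    pm <- compare_packing(landscape[[i]], landscape[[j]], tol,
                          full_only = TRUE, keep = 32L)
    if (pm$n_matched == tol$n_molecules && !is.na(pm$rmsd) &&
        pm$rmsd < rmsd_threshold)
      parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(L), find, 0L)
  cluster <- match(root, unique(root))
  energy <- vapply(landscape, function(s)
    if (!is.null(s$meta$energy)) s$meta$energy else NA_real_, 0)
  rep_of <- vapply(seq_len(max(cluster)), function(cl) {
    members <- which(cluster == cl)
    if (all(is.na(energy[members]))) members[1]
    else members[which.min(energy[members])]
  }, 0L)
  data.frame(index = seq_len(L), cluster = cluster,
             representative = rep_of[cluster])
}
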