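# Independent oracles used to validate the package's algorithms on small
# instances. These share the package's declared metric definitions but never
# its search / solver code paths.

# --- rigid superposition, written directly from the SVD normal equations ---
oracle_superpose <- function(X, Y, allow_inversion = TRUE) {
  X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
  sv <- svd(t(X0) %*% Y0)
  d <- sign(det(sv$v %*% t(sv$u)))
  rmsd_for <- function(D) {
    R <- sv$v %*% diag(D) %*% t(sv$u)
    sqrt(mean(rowSums((Y0 - X0 %*% t(R))^2)))
  }
  r <- rmsd_for(c(1, 1, d))
  if (allow_inversion) r <- min(r, rmsd_for(c(1, 1, -d)))
  r
}

# --- exhaustive packing-correspondence oracle (clusters <= 5 molecules) ----
# Enumerates every probe central, every injective molecule mapping and every
# subset size, checking the package's declared feasibility criteria
# directly: species isomorphism, pairwise centroid distances within
# dist_tol (relative), pairwise inter-centroid angles within angle_tol, and
# folded orientation descriptors within angle_tol. Returns max molecules
# matched and the minimum joint-overlay RMSD among maximal correspondences.
oracle_compare_packing <- function(ref, probe, tol) {
  n <- tol$n_molecules
  mols_ref <- perceive_molecules(ref, include_hydrogen = !tol$ignore_hydrogen)
  mols_probe <- perceive_molecules(probe,
                                   include_hydrogen = !tol$ignore_hydrogen)
  fold_angle <- function(u, v) {
    ca <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
    acos(min(1, ca)) * 180 / pi
  }
  full_angle <- function(u, v) {
    ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(min(1, max(-1, ca))) * 180 / pi
  }
  axes_of <- function(m) {
    X <- sweep(m$xyz, 2, m$centroid)
    ev <- eigen(crossprod(X), symmetric = TRUE)
    span <- max(ev$values) + 1e-12
    ok <- vapply(1:3, function(ax)
      min(abs(ev$values[ax] - ev$values[-ax])) / span >= 1e-3, TRUE)
    list(v = ev$vectors, ok = ok)
  }
  desc_of <- function(cluster) {
    axc <- axes_of(cluster[[1]])
    lapply(seq_along(cluster)[-1], function(i) {
      m <- cluster[[i]]
      u <- m$centroid - cluster[[1]]$centroid
      axi <- axes_of(m)
      vals <- rep(NA_real_, 6)
      for (ax in 1:3) {
        if (axi$ok[ax]) vals[ax] <- fold_angle(u, axi$v[, ax])
        if (axi$ok[ax] && axc$ok[ax])
          vals[3 + ax] <- fold_angle(axc$v[, ax], axi$v[, ax])
      }
      vals
    })
  }
  best_n <- 0L; best_rmsd <- NA_real_
  for (rc in seq_along(mols_ref)) {
    refc <- build_cluster(ref, n, central = rc, mols = mols_ref)
    dref <- desc_of(refc)
    vref <- lapply(refc[-1], function(m) m$centroid - refc[[1]]$centroid)
    for (pc in seq_along(mols_probe)) {
      nprobe <- min(n + 10, length(mols_probe) * 27)
      prc <- build_cluster(probe, nprobe, central = pc, mols = mols_probe)
      if (is.null(molecules_equivalent(refc[[1]], prc[[1]],
                                       ignore_hydrogen = FALSE))) next
      dprobe <- desc_of(prc)
      vprobe <- lapply(prc[-1], function(m) m$centroid - prc[[1]]$centroid)
      nr <- length(refc) - 1; np <- length(prc) - 1
      # all injective partial mappings via recursion over ref molecules
      explore <- function(i, assign) {
        if (i > nr) {
          cnt <- 1L + sum(!is.na(assign))
          if (cnt < best_n) return()
          rm <- oracle_overlay(refc, prc, assign, tol)
          if (is.null(rm)) return()
          if (cnt > best_n || is.na(best_rmsd) || rm < best_rmsd) {
            if (cnt > best_n) { best_n <<- cnt; best_rmsd <<- rm }
            else best_rmsd <<- min(best_rmsd, rm)
          }
          return()
        }
        explore(i + 1L, assign)       # leave i unmatched
        for (j in seq_len(np)) {
          if (j %in% assign) next
          if (is.null(molecules_equivalent(refc[[i + 1]], prc[[j + 1]],
                                           ignore_hydrogen = FALSE))) next
          dri <- sqrt(sum(vref[[i]]^2)); dpj <- sqrt(sum(vprobe[[j]]^2))
          if (abs(dri - dpj) / dri > tol$dist_tol) next
          dev <- abs(dref[[i]] - dprobe[[j]])
          if (any(dev > tol$angle_tol, na.rm = TRUE)) next
          ok <- TRUE
          for (k in seq_len(i - 1L)) {
            if (is.na(assign[k])) next
            jk <- assign[k]
            if (abs(full_angle(vref[[i]], vref[[k]]) -
                    full_angle(vprobe[[j]], vprobe[[jk]])) > tol$angle_tol) {
              ok <- FALSE; break
            }
            drik <- sqrt(sum((vref[[i]] - vref[[k]])^2))
            dpjk <- sqrt(sum((vprobe[[j]] - vprobe[[jk]])^2))
            if (abs(drik - dpjk) > tol$dist_tol * drik) { ok <- FALSE; break }
          }
          if (!ok) next
          assign[i] <- j
          explore(i + 1L, assign)
          assign[i] <- NA_integer_
        }
      }
      explore(1L, rep(NA_integer_, nr))
    }
  }
  list(n_matched = best_n, rmsd = best_rmsd)
}

# joint-overlay RMSD of a molecule assignment, via graph-isomorphism atom
# maps and direct SVD superposition (assumes automorphism-free molecules)
oracle_overlay <- function(refc, prc, assign, tol) {
  pairs <- cbind(1L, 1L)
  for (i in seq_along(assign))
    if (!is.na(assign[i])) pairs <- rbind(pairs, c(i + 1L, assign[i] + 1L))
  X <- NULL; Y <- NULL
  for (r in seq_len(nrow(pairs))) {
    mp <- molecules_equivalent(refc[[pairs[r, 1]]], prc[[pairs[r, 2]]],
                               ignore_hydrogen = FALSE)
    if (is.null(mp)) return(NULL)
    X <- rbind(X, refc[[pairs[r, 1]]]$xyz)
    Y <- rbind(Y, prc[[pairs[r, 2]]]$xyz[mp, , drop = FALSE])
  }
  oracle_superpose(X, Y, allow_inversion = tol$allow_inversion)
}

# --- brute-force PDD over an explicit supercell -----------------------------
oracle_pdd_rows <- function(s, k, cells = 5) {
  ex <- expand_to_cell(s)
  frac <- as.matrix(ex[c("x", "y", "z")])
  cart <- t(s$cell$ortho %*% t(frac))
  half <- (cells - 1) / 2
  sh <- as.matrix(expand.grid(-half:half, -half:half, -half:half))
  imgs <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i)
    sweep(cart, 2, as.numeric(s$cell$ortho %*% sh[i, ]), "+")))
  t(vapply(seq_len(nrow(cart)), function(i) {
    d <- sqrt(colSums((t(imgs) - cart[i, ])^2))
    sort(d[d > 1e-9])[1:k]
  }, numeric(k)))
}

# --- exact EMD by linear programming (boot::simplex) ------------------------
oracle_emd <- function(w1, w2, C) {
  m <- length(w1); n <- length(w2)
  # variables f_ij >= 0, minimize sum C f subject to row/col sums; the last
  # column constraint is implied by balance and must be dropped so the
  # equality system has full rank
  A3 <- matrix(0, m + n - 1, m * n)
  for (i in seq_len(m)) A3[i, (i - 1) * n + seq_len(n)] <- 1
  for (j in seq_len(n - 1)) A3[m + j, (seq_len(m) - 1) * n + j] <- 1
  b3 <- c(w1, w2[seq_len(n - 1)])
  res <- boot::simplex(a = as.numeric(t(C)), A3 = A3, b3 = b3, maxi = FALSE)
  unname(res$value)
}

# --- O(n^2) line-test lower hull oracle ------------------------------------
oracle_stable_points <- function(comp, deltaf, tol = 1e-9) {
  n <- length(comp)
  stable <- logical(n)
  for (i in seq_len(n)) {
    # i is stable iff no convex combination of two other points (or a single
    # point at the same composition) lies strictly below it
    beaten <- FALSE
    for (a in seq_len(n)) {
      if (a == i) next
      if (abs(comp[a] - comp[i]) < 1e-12 && deltaf[a] < deltaf[i] - tol)
        beaten <- TRUE
      for (b in seq_len(n)) {
        if (b <= a || b == i) next
        lo <- min(comp[a], comp[b]); hi <- max(comp[a], comp[b])
        if (comp[i] < lo - 1e-12 || comp[i] > hi + 1e-12 ||
            abs(hi - lo) < 1e-12) next
        t <- (comp[i] - comp[a]) / (comp[b] - comp[a])
        y <- deltaf[a] + t * (deltaf[b] - deltaf[a])
        if (y < deltaf[i] - tol) beaten <- TRUE
      }
      if (beaten) break
    }
    stable[i] <- !beaten
  }
  stable
}

# --- direct-summation de Gelder similarity ---------------------------------
# Literal evaluation of S = sum_r w(r) c_fg(r) / sqrt(...) by an explicit
# double loop over signed shifts, independent of the package's vectorized
# evaluation.
oracle_degelder <- function(f, g, step, l) {
  n <- length(f)
  nsh <- floor(l / step)
  corr <- function(u, v) {
    tot <- 0
    for (s in -nsh:nsh) {
      w <- 1 - abs(s) * step / l
      cc <- 0
      for (t in seq_len(n)) {
        t2 <- t + s
        if (t2 >= 1 && t2 <= n) cc <- cc + u[t] * v[t2]
      }
      tot <- tot + w * cc
    }
    tot
  }
  corr(f, g) / sqrt(corr(f, f) * corr(g, g))
}

# convenience: sites data frame for a handful of atoms
atoms_df <- function(elements, coords) {
  data.frame(label = paste0(elements, seq_along(elements)),
             element = elements,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}
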