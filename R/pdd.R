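# Pointwise distance distribution (PDD) fingerprints and their Earth Mover's
# Distance comparison.

#' Compute the pointwise distance distribution of a crystal
#'
#' For every atom in the unit cell, the ordered distances to its k nearest
#' neighbours in the infinite crystal. Identical rows (within
#' \code{collapse_tol} in the L-infinity sense) are collapsed with summed
#' weights, making the descriptor independent of the choice of unit cell.
#'
#' @param s A \code{crystal_structure}.
#' @param k Number of neighbour distances per row (k >= 1).
#' @param include_hydrogen Include hydrogen atoms (default \code{TRUE}).
#' @param collapse_tol Row-collapse tolerance in angstrom (default 1e-4).
#' @return Object of class \code{"pdd_matrix"}: list with \code{weights}
#'   (summing to 1), \code{distances} (rows x k matrix, each row
#'   non-decreasing, rows in lexicographic order), \code{k}.
#' @export
compute_pdd <- function(s, k, include_hydrogen = TRUE, collapse_tol = 1e-4) {
  if (k < 1) stop("k must be at least 1")
  ex <- expand_to_cell(s)
  if (!include_hydrogen) ex <- ex[ex$element != "H", , drop = FALSE]
  if (nrow(ex) == 0) stop("expanded cell is empty")
  frac <- as.matrix(ex[c("x", "y", "z")])
  cart <- frac_to_cart(s$cell, frac)
  n <- nrow(cart)
  ortho <- s$cell$ortho
  va <- ortho[, 1]; vb <- ortho[, 2]; vc <- ortho[, 3]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  tmin <- min(s$cell$volume / sqrt(sum(cr(vb, vc)^2)),
              s$cell$volume / sqrt(sum(cr(va, vc)^2)),
              s$cell$volume / sqrt(sum(cr(va, vb)^2)))
  r <- max(1L, ceiling((k / n)^(1 / 3)))
  repeat {
    shifts <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    imgs <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i)
      sweep(cart, 2, as.numeric(ortho %*% shifts[i, ]), "+")))
    rows <- matrix(0, n, k)
    ok <- TRUE
    for (i in seq_len(n)) {
      d <- sqrt(colSums((t(imgs) - cart[i, ])^2))
      d <- sort(d[d > 1e-9])
      if (length(d) < k || d[k] >= r * tmin) { ok <- FALSE; break }
      rows[i, ] <- d[1:k]
    }
    if (ok) break
    r <- r + 1L
    if (r > 12L) stop("PDD neighbour search radius exceeded")
  }
  .collapse_pdd_rows(rows, collapse_tol)
}

.collapse_pdd_rows <- function(rows, collapse_tol, weights = NULL) {
  n <- nrow(rows)
  if (is.null(weights)) weights <- rep(1 / n, n)
  ord <- do.call(order, as.data.frame(rows))
  rows <- rows[ord, , drop = FALSE]
  weights <- weights[ord]
  reps <- list(); w <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(reps)) {
      j <- length(reps)  # lexicographic sort puts near-equal rows adjacent
      while (j >= 1 && max(abs(rows[i, ] - reps[[j]])) <= collapse_tol * 10) {
        if (max(abs(rows[i, ] - reps[[j]])) <= collapse_tol) {
          w[j] <- w[j] + weights[i]; placed <- TRUE; break
        }
        j <- j - 1
      }
    }
    if (!placed) { reps[[length(reps) + 1]] <- rows[i, ]; w <- c(w, weights[i]) }
  }
  D <- do.call(rbind, reps)
  structure(list(weights = w / sum(w), distances = D, k = ncol(rows)),
            class = "pdd_matrix")
}

#' @export
print.pdd_matrix <- function(x, ...) {
  cat(sprintf("PDD matrix: %d row(s), k = %d\n", length(x$weights), x$k))
  invisible(x)
}

#' Earth Mover's Distance between two PDD matrices
#'
#' Exact optimal-transport cost between the weighted row sets, with ground
#' cost the L-infinity distance between rows. Solved by a successive
#' shortest-path transportation solver.
#'
#' @param p,q \code{pdd_matrix} objects with equal k.
#' @return Distance in angstrom (>= 0; 0 iff the matrices coincide).
#' @export
pdd_distance <- function(p, q) {
  if (p$k != q$k) stop("PDD matrices have different k")
  C <- .linf_cost(p$distances, q$distances)
  emd_transport(p$weights, q$weights, C)$cost
}

.linf_cost <- function(A, B) {
  m <- nrow(A); n <- nrow(B)
  C <- matrix(0, m, n)
  for (i in seq_len(m))
    C[i, ] <- apply(abs(sweep(B, 2, A[i, ])), 1, max)
  C
}

#' Exact transportation problem solver
#'
#' Minimizes \code{sum(flow * cost)} subject to row sums \code{supply} and
#' column sums \code{demand} (which must balance). Successive shortest
#' augmenting paths on the bipartite residual network; exact for real-valued
#' supplies.
#'
#' @param supply,demand Non-negative weights with equal sums.
#' @param cost m x n cost matrix.
#' @return List with \code{cost} (optimal objective) and \code{flow}
#'   (m x n matrix).
#' @export
emd_transport <- function(supply, demand, cost) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n)
  tot <- sum(supply)
  if (abs(tot - sum(demand)) > 1e-9 * max(tot, 1))
    stop("supply and demand must balance")
  # work on an exact integer grid when the weights admit one (PDD weights
  # are occurrence counts over the cell, so they always do); this removes
  # the degenerate fractional augmentations that stall the float path
  D <- .common_denominator(c(supply / tot, demand / tot))
  if (!is.null(D)) {
    sup <- round(supply / tot * D)
    dem <- round(demand / tot * D)
    scale_back <- tot / D
  } else {
    sup <- supply; dem <- demand
    scale_back <- 1
  }
  flow <- matrix(0, m, n)
  # successive shortest paths with node potentials: Dijkstra on reduced
  # costs (non-negative by the potential invariant). Nodes: rows 1..m,
  # cols m+1..m+n; forward edges i->j cost C, residual edges j->i cost -C
  # where flow[i,j] > 0.
  V <- m + n
  pot <- rep(0, V)
  eps <- 1e-12
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * V + 100L)
      stop("EMD solver failed to converge")
    src <- which(sup > eps)
    if (length(src) == 0) break
    distv <- rep(Inf, V)
    prev <- rep(NA_integer_, V)
    done <- rep(FALSE, V)
    distv[src] <- 0
    repeat {
      cand <- which(!done & is.finite(distv))
      if (length(cand) == 0) break
      u <- cand[which.min(distv[cand])]
      done[u] <- TRUE
      if (u <= m) {
        rc <- pmax(cost[u, ] + pot[u] - pot[m + seq_len(n)], 0)
        nd <- distv[u] + rc
        upd <- !done[m + seq_len(n)] & nd < distv[m + seq_len(n)]
        if (any(upd)) {
          distv[m + which(upd)] <- nd[upd]
          prev[m + which(upd)] <- u
        }
      } else {
        j <- u - m
        back <- which(flow[, j] > eps & !done[seq_len(m)])
        if (length(back)) {
          rc <- pmax(-cost[back, j] + pot[u] - pot[back], 0)
          nd <- distv[u] + rc
          upd <- nd < distv[back]
          if (any(upd)) {
            distv[back[upd]] <- nd[upd]
            prev[back[upd]] <- u
          }
        }
      }
    }
    snk <- which(dem > eps)
    j_best <- snk[which.min(distv[m + snk])]
    if (!is.finite(distv[m + j_best]))
      stop("transportation network disconnected")
    reach <- is.finite(distv)
    pot[reach] <- pot[reach] + distv[reach]
    # trace the path back and find the bottleneck
    path <- integer(0)
    node <- m + j_best
    while (!is.na(prev[node])) { path <- c(node, path); node <- prev[node] }
    path <- c(node, path)
    bott <- min(sup[path[1]], dem[j_best])
    for (t in seq_len(length(path) - 1)) {
      u <- path[t]; v <- path[t + 1]
      if (u > m) bott <- min(bott, flow[v, u - m])   # residual edge
    }
    for (t in seq_len(length(path) - 1)) {
      u <- path[t]; v <- path[t + 1]
      if (u <= m) flow[u, v - m] <- flow[u, v - m] + bott
      else flow[v, u - m] <- flow[v, u - m] - bott
    }
    sup[path[1]] <- sup[path[1]] - bott
    dem[j_best] <- dem[j_best] - bott
  }
  flow <- flow * scale_back
  list(cost = sum(flow * cost), flow = flow)
}

# smallest common denominator D <= cap with w*D integral for all weights,
# found by continued-fraction approximation; NULL when none exists
.common_denominator <- function(w, cap = 1e6, tol = 1e-9) {
  den_of <- function(x) {
    a <- x; p0 <- 0; p1 <- 1; q0 <- 1; q1 <- 0
    for (it in 1:40) {
      k <- floor(a)
      p <- k * p1 + p0; q <- k * q1 + q0
      if (q > cap) return(NULL)
      if (abs(x - p / q) < tol) return(q)
      fr <- a - k
      if (fr < 1e-12) return(q)
      a <- 1 / fr
      p0 <- p1; p1 <- p; q0 <- q1; q1 <- q
    }
    NULL
  }
  L <- 1
  for (x in w[w > 0]) {
    d <- den_of(x)
    if (is.null(d)) return(NULL)
    g <- .gcd(L, d)
    L <- L / g * d
    if (L > cap) return(NULL)
  }
  L
}

#' Isotropically normalize a reference cell to a probe volume
#'
#' Scales the reference cell lengths by the cube root of the volume ratio so
#' that its volume equals the probe's; angles and fractional coordinates are
#' unchanged. Used to factor out thermal expansion before PDD comparison.
#'
#' @param ref,probe \code{crystal_structure}s.
#' @return The rescaled reference structure.
#' @export
volume_normalize <- function(ref, probe) {
  sc <- (probe$cell$volume / ref$cell$volume)^(1 / 3)
  ref$cell <- cell_scale(ref$cell, sc)
  ref
}

#' PDD-based structure match verdict
#'
#' Volume-normalizes the reference to the probe, computes both PDDs at
#' \code{k}, and compares the Earth Mover's Distance against \code{cutoff}.
#'
#' @param ref,probe \code{crystal_structure}s.
#' @param k Neighbour count (default 100).
#' @param cutoff Match cutoff in angstrom (default 0.225).
#' @param include_hydrogen Include hydrogens in the PDD (default
#'   \code{TRUE}).
#' @return Logical; attribute \code{"distance"} carries the EMD.
#' @export
is_pdd_match <- function(ref, probe, k = 100, cutoff = 0.225,
                         include_hydrogen = TRUE) {
  refn <- volume_normalize(ref, probe)
  d <- pdd_distance(compute_pdd(refn, k, include_hydrogen),
                    compute_pdd(probe, k, include_hydrogen))
  structure(d <= cutoff, distance = d)
}
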