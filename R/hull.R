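# Convex-hull stability analysis for two-component (cocrystal) systems.

#' Normalized formation energy of an AxBy compound
#'
#' \deqn{\Delta_f = (E_{AxBy} - x E_A - y E_B) / (x + y)}
#' where \code{E_A}, \code{E_B} are the lowest energies per molecule of the
#' pure components. By construction the pure components have
#' \code{deltaf = 0}.
#'
#' @param E Energy of the compound per formula unit (kJ/mol).
#' @param E_A,E_B Lowest pure-component energies per molecule (kJ/mol).
#' @param x,y Non-negative component counts per formula unit, x + y >= 1.
#' @return Formation energy per molecule (kJ/mol).
#' @export
formation_energy <- function(E, E_A, E_B, x, y) {
  if (any(x < 0) || any(y < 0) || any(x + y < 1))
    stop("need x, y >= 0 and x + y >= 1")
  (E - x * E_A - y * E_B) / (x + y)
}

#' Composition points for hull analysis
#'
#' @param x,y Component counts per formula unit.
#' @param deltaf Normalized formation energies (kJ/mol per molecule).
#' @param id Optional structure identifiers.
#' @return Data frame of class \code{"composition_points"} with columns
#'   \code{id, x, y, composition, deltaf}; \code{composition = y/(x+y)}.
#' @export
composition_points <- function(x, y, deltaf, id = NULL) {
  if (is.null(id)) id <- paste0(x, ":", y)
  out <- data.frame(id = id, x = x, y = y,
                    composition = y / (x + y), deltaf = deltaf,
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_points", "data.frame")
  out
}

# lower convex hull of (x, y) points by Andrew's monotone chain;
# returns indices of hull vertices in increasing x
.lower_hull <- function(x, y, eps = 1e-12) {
  ord <- order(x, y)
  hx <- x[ord]; hy <- y[ord]
  hull <- integer(0)
  for (i in seq_along(hx)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      crossp <- (hx[b] - hx[a]) * (hy[i] - hy[a]) -
        (hy[b] - hy[a]) * (hx[i] - hx[a])
      if (crossp <= eps) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  ord[hull]
}

#' Thermodynamically stable points on the lower convex hull
#'
#' Keeps the minimum-deltaf point at each composition, adds the pure
#' endpoints at deltaf = 0 if absent, and returns the points lying on the
#' lower convex hull of (composition, deltaf): no returned point can be
#' beaten by a convex combination of other phases at its composition.
#'
#' @param points A \code{\link{composition_points}} data frame.
#' @param tol Vertical tolerance (kJ/mol) for lying on the hull.
#' @return The subset of \code{points} (with endpoints possibly added) on
#'   the lower hull, with an \code{above_hull} column (0 for stable points);
#'   attribute \code{"all"} carries every point with its hull distance.
#' @export
stable_set <- function(points, tol = 1e-9) {
  pts <- points
  if (!any(abs(pts$composition) < 1e-12))
    pts <- rbind(pts, composition_points(1, 0, 0, id = "pure_A"))
  if (!any(abs(pts$composition - 1) < 1e-12))
    pts <- rbind(pts, composition_points(0, 1, 0, id = "pure_B"))
  # minimum per composition
  comp_key <- round(pts$composition, 12)
  best <- unlist(lapply(split(seq_len(nrow(pts)), comp_key), function(ix)
    ix[which.min(pts$deltaf[ix])]))
  cand <- pts[sort(best), , drop = FALSE]
  hull_idx <- .lower_hull(cand$composition, cand$deltaf)
  hx <- cand$composition[hull_idx]; hy <- cand$deltaf[hull_idx]
  hull_at <- function(xq) stats::approx(hx, hy, xq, rule = 2)$y
  pts$above_hull <- pts$deltaf - hull_at(pts$composition)
  pts$above_hull[abs(pts$above_hull) < tol] <- 0
  stable <- pts[pts$above_hull == 0 &
                  seq_len(nrow(pts)) %in% sort(best)[hull_idx], , drop = FALSE]
  # a hull vertex at the same composition as a duplicate: keep only minima
  rownames(stable) <- NULL
  attr(stable, "all") <- pts
  stable
}

#' Stoichiometry prediction from per-stoichiometry landscapes
#'
#' Takes the minimum-energy structure of each candidate stoichiometry,
#' converts to normalized formation energies against the pure-component
#' references, and reports the stable set plus every point's energy above
#' the hull.
#'
#' @param energies Data frame with columns \code{id, x, y, E} (energy per
#'   formula unit, kJ/mol). Multiple entries per stoichiometry are allowed;
#'   the minimum is used.
#' @param E_A,E_B Lowest pure-component energies per molecule (kJ/mol).
#' @return List with \code{stable} (stable stoichiometry labels "x:y"
#'   excluding the pure endpoints), \code{points} (per-stoichiometry
#'   composition points with \code{above_hull}), and \code{hull} (the
#'   stable-set data frame).
#' @export
hull_report <- function(energies, E_A, E_B) {
  if (missing(E_A) || missing(E_B) || is.na(E_A) || is.na(E_B))
    stop("pure-component energies E_A and E_B are required: they define the hull endpoints")
  need <- c("id", "x", "y", "E")
  if (!all(need %in% names(energies)))
    stop("energies must have columns: ", paste(need, collapse = ", "))
  key <- paste0(energies$x, ":", energies$y)
  idx <- unlist(lapply(split(seq_len(nrow(energies)), key), function(ix)
    ix[which.min(energies$E[ix])]))
  e <- energies[idx, , drop = FALSE]
  pts <- composition_points(
    e$x, e$y, formation_energy(e$E, E_A, E_B, e$x, e$y),
    id = paste0(e$x, ":", e$y))
  st <- stable_set(pts)
  allp <- attr(st, "all")
  mixed <- st$x > 0 & st$y > 0
  list(stable = st$id[mixed], points = allp, hull = st)
}

#' Stoichiometry screening by simple energy criteria
#'
#' The one-formula alternatives to the hull construction: the cocrystal
#' formation energy against the stoichiometric sum of pure components,
#' \deqn{\Delta E_{CC} = E_{AxBy} - x E_A - y E_B,}
#' reported both per formula unit and per molecule.
#'
#' @inheritParams formation_energy
#' @return List with \code{delta_cc} (per formula unit) and
#'   \code{delta_cc_per_molecule}; negative values favour cocrystal
#'   formation.
#' @export
cocrystal_delta <- function(E, E_A, E_B, x, y) {
  d <- E - x * E_A - y * E_B
  list(delta_cc = d, delta_cc_per_molecule = d / (x + y))
}

#' Plot a formation-energy hull
#' @param x Result of \code{\link{hull_report}} or a stable-set data frame.
#' @param ... Passed to \code{plot}.
#' @export
plot_hull <- function(x, ...) {
  pts <- if (is.list(x) && !is.null(x$points)) x$points else attr(x, "all")
  hull <- if (is.list(x) && !is.null(x$hull)) x$hull else x
  graphics::plot(pts$composition, pts$deltaf,
                 xlab = "composition y/(x+y)",
                 ylab = expression(Delta[f] * E ~ "(kJ/mol per molecule)"),
                 pch = 19, ...)
  ord <- order(hull$composition)
  graphics::lines(hull$composition[ord], hull$deltaf[ord], col = "grey40")
  graphics::points(hull$composition, hull$deltaf, pch = 21, bg = "red")
  invisible(x)
}
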