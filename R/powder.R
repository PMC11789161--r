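# Powder X-ray pattern simulation, de Gelder cross-correlation similarity,
# and variable-cell similarity maximization against a target pattern.

#' Enumerate reflections of a crystal
#'
#' All lattice reflections with 2-theta up to \code{two_theta_max}.
#' Structure-factor magnitudes are computed by direct summation over the
#' expanded unit cell, so systematic absences emerge from the phase sum
#' rather than from space-group tables. The Lorentz-polarization factor is
#' applied; reflections sharing d-spacing and intensity are merged with a
#' multiplicity count.
#'
#' @param s A \code{crystal_structure}.
#' @param wavelength X-ray wavelength in angstrom (default Cu K-alpha1,
#'   1.54056).
#' @param two_theta_max Upper 2-theta limit in degrees (default 40).
#' @param B Isotropic displacement parameter (angstrom^2, default 0).
#' @return Data frame of class \code{"reflection_list"} with columns
#'   \code{h, k, l, d, two_theta, intensity, multiplicity}, sorted by
#'   2-theta.
#' @export
reflections <- function(s, wavelength = 1.54056, two_theta_max = 40, B = 0) {
  if (wavelength <= 0) stop("wavelength must be positive")
  ex <- expand_to_cell(s)
  # reciprocal metric: d*^2 = h' G* h
  Gstar <- solve(cell_metric(s$cell))
  smax <- sin(two_theta_max / 2 * pi / 180) / wavelength  # = 1/(2 d_min)
  dstar_max <- 2 * smax
  # conservative index bounds from the reciprocal cell diagonal
  hmax <- ceiling(dstar_max / sqrt(Gstar[1, 1]))
  kmax <- ceiling(dstar_max / sqrt(Gstar[2, 2]))
  lmax <- ceiling(dstar_max / sqrt(Gstar[3, 3]))
  hkl <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax,
                               l = -lmax:lmax))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  dstar2 <- rowSums((hkl %*% Gstar) * hkl)
  keep <- dstar2 <= dstar_max^2 + 1e-12
  hkl <- hkl[keep, , drop = FALSE]
  dstar2 <- dstar2[keep]
  d <- 1 / sqrt(dstar2)
  sinth <- wavelength / (2 * d)
  two_theta <- 2 * asin(pmin(1, sinth)) * 180 / pi
  sv <- sinth / wavelength   # sin(theta)/lambda

  frac <- as.matrix(ex[c("x", "y", "z")])
  phase <- hkl %*% t(frac)           # nrefl x natom, in cycles
  occ <- ex$occupancy
  els <- unique(ex$element)
  f <- matrix(0, nrow(hkl), nrow(ex))
  for (el in els) {
    idx <- ex$element == el
    f[, idx] <- scattering_factor(el, sv) * exp(-B * sv^2)
  }
  Fre <- rowSums(f * cos(2 * pi * phase) * rep(occ, each = nrow(hkl)))
  Fim <- rowSums(f * sin(2 * pi * phase) * rep(occ, each = nrow(hkl)))
  F2 <- Fre^2 + Fim^2
  th <- two_theta / 2 * pi / 180
  lp <- (1 + cos(2 * th)^2) / (sin(th)^2 * cos(th))
  I <- F2 * lp

  # merge symmetry/degeneracy-equivalent reflections: same d and same raw |F|^2
  key <- paste(round(d, 8), signif(F2, 8))
  grp <- match(key, unique(key))
  agg <- function(v) as.numeric(tapply(v, grp, function(z) z[1]))
  mult <- as.integer(table(grp)[as.character(seq_len(max(grp)))])
  out <- data.frame(
    h = agg(hkl[, 1]), k = agg(hkl[, 2]), l = agg(hkl[, 3]),
    d = agg(d), two_theta = agg(two_theta),
    intensity = agg(I) * mult, multiplicity = mult
  )
  out <- out[order(out$two_theta), ]
  rownames(out) <- NULL
  class(out) <- c("reflection_list", "data.frame")
  attr(out, "wavelength") <- wavelength
  out
}

#' Create a powder pattern object
#'
#' @param two_theta Strictly increasing uniform 2-theta grid (degrees).
#' @param intensity Non-negative intensities, same length.
#' @param wavelength Wavelength in angstrom.
#' @return Object of class \code{"powder_pattern"}.
#' @export
powder_pattern <- function(two_theta, intensity, wavelength = 1.54056) {
  stopifnot(length(two_theta) == length(intensity))
  if (any(diff(two_theta) <= 0)) stop("2-theta grid must be increasing")
  step <- diff(two_theta)
  if (diff(range(step)) > 1e-9 * mean(step))
    stop("2-theta grid must be uniform")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(two_theta = two_theta, intensity = intensity,
                 wavelength = wavelength, step = mean(step)),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("powder pattern: %d points, 2theta %.3f-%.3f deg (step %.4f), lambda %.5f A\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$step, x$wavelength))
  invisible(x)
}

#' @export
plot.powder_pattern <- function(x, ...) {
  graphics::plot(x$two_theta, x$intensity, type = "l",
                 xlab = expression(2 * theta ~ "(deg)"),
                 ylab = "intensity (norm.)", ...)
  invisible(x)
}

#' Simulate a powder pattern
#'
#' Reflection intensities convolved with a pseudo-Voigt profile and
#' normalized to unit maximum.
#'
#' @param s A \code{crystal_structure}.
#' @param wavelength Wavelength in angstrom (default Cu K-alpha1 1.54056).
#' @param two_theta_range Length-2 range in degrees (default \code{c(3, 40)}).
#' @param step Grid step in degrees (default 0.017).
#' @param fwhm Profile full width at half maximum in degrees 2-theta
#'   (default 0.1).
#' @param eta Gaussian fraction of the pseudo-Voigt (default 0.5; 1 = pure
#'   Gaussian, 0 = pure Lorentzian).
#' @param B Isotropic displacement parameter passed to
#'   \code{\link{reflections}}.
#' @param refl Optional precomputed \code{reflection_list}.
#' @return A \code{\link{powder_pattern}}.
#' @export
simulate_pattern <- function(s, wavelength = 1.54056,
                             two_theta_range = c(3, 40), step = 0.017,
                             fwhm = 0.1, eta = 0.5, B = 0, refl = NULL) {
  if (is.null(refl))
    refl <- reflections(s, wavelength, two_theta_max = two_theta_range[2] +
                          5 * fwhm, B = B)
  use <- refl$two_theta >= two_theta_range[1] - 5 * fwhm &
    refl$two_theta <= two_theta_range[2] + 5 * fwhm
  if (!any(refl$two_theta >= two_theta_range[1] &
           refl$two_theta <= two_theta_range[2]))
    stop("no reflections in the requested 2-theta range")
  refl <- refl[use, , drop = FALSE]
  grid <- seq(two_theta_range[1], two_theta_range[2], by = step)
  y <- numeric(length(grid))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  for (r in seq_len(nrow(refl))) {
    dx <- grid - refl$two_theta[r]
    prof <- eta * exp(-dx^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) +
      (1 - eta) * gamma / (pi * (dx^2 + gamma^2))
    y <- y + refl$intensity[r] * prof
  }
  if (max(y) <= 0) stop("simulated pattern is identically zero")
  powder_pattern(grid, y / max(y), wavelength)
}

#' de Gelder cross-correlation similarity of two powder patterns
#'
#' Normalized weighted cross-correlation
#' \deqn{S(f,g) = \int w(r) c_{fg}(r) dr / \sqrt{\int w c_{ff} \cdot \int w c_{gg}}}
#' with a triangular weight of half-width \code{l} degrees. S(f,f) = 1 and S
#' is invariant under positive scaling of either pattern.
#'
#' @param p,q \code{\link{powder_pattern}}s with equal wavelength.
#' @param l Triangular weight half-width in degrees 2-theta (default 1.5).
#' @return Similarity in [-1, 1].
#' @export
degelder_similarity <- function(p, q, l = 1.5) {
  if (abs(p$wavelength - q$wavelength) > 1e-9)
    stop("patterns have different wavelengths")
  lo <- max(min(p$two_theta), min(q$two_theta))
  hi <- min(max(p$two_theta), max(q$two_theta))
  if (hi <= lo) stop("patterns do not overlap in 2-theta")
  step <- max(p$step, q$step)
  grid <- seq(lo, hi, by = step)
  f <- stats::approx(p$two_theta, p$intensity, grid)$y
  g <- stats::approx(q$two_theta, q$intensity, grid)$y
  if (all(f == 0) || all(g == 0)) stop("all-zero pattern")
  nsh <- floor(l / step)
  w <- 1 - (0:nsh) * step / l
  xcorr <- function(u, v) {
    n <- length(u)
    tot <- w[1] * sum(u * v)
    for (sft in seq_len(nsh)) {
      cc <- sum(u[1:(n - sft)] * v[(1 + sft):n]) +
        sum(u[(1 + sft):n] * v[1:(n - sft)])
      tot <- tot + w[sft + 1] * cc
    }
    tot
  }
  xcorr(f, g) / sqrt(xcorr(f, f) * xcorr(g, g))
}

#' Refine cell parameters against a target pattern
#'
#' Derivative-free maximization of the de Gelder similarity between the
#' re-simulated pattern of \code{s} and \code{target}, varying only the cell
#' parameters allowed by the crystal system implied by the symmetry
#' operators; fractional coordinates are held fixed. The returned similarity
#' is never below the starting similarity.
#'
#' @param s A \code{crystal_structure}.
#' @param target A \code{\link{powder_pattern}}.
#' @param l de Gelder window half-width (degrees).
#' @param two_theta_range,step,fwhm,eta Simulation settings (see
#'   \code{\link{simulate_pattern}}).
#' @param max_strain Bound on the relative change of each free length and
#'   the absolute change (degrees) of each free angle (default 0.1).
#' @return List with \code{structure} (refined), \code{similarity},
#'   \code{start_similarity}, \code{free} (names of refined parameters).
#' @export
refine_cell <- function(s, target, l = 1.5, two_theta_range = c(3, 40),
                        step = 0.017, fwhm = 0.1, eta = 0.5,
                        max_strain = 0.1) {
  free <- .free_cell_params(s)
  cl <- s$cell
  p0 <- c(a = cl$a, b = cl$b, c = cl$c,
          alpha = cl$alpha, beta = cl$beta, gamma = cl$gamma)
  sim_of <- function(p) {
    cell_new <- try(lattice_cell(p["a"], p["b"], p["c"],
                                 p["alpha"], p["beta"], p["gamma"]),
                    silent = TRUE)
    if (inherits(cell_new, "try-error")) return(-2)
    s2 <- s; s2$cell <- cell_new
    pat <- try(simulate_pattern(s2, target$wavelength, two_theta_range,
                                step, fwhm, eta), silent = TRUE)
    if (inherits(pat, "try-error")) return(-2)
    degelder_similarity(pat, target, l)
  }
  expand <- function(theta) {
    p <- p0
    p[free$lengths] <- p0[free$lengths] * (1 + theta[seq_along(free$lengths)])
    if (length(free$angles))
      p[free$angles] <- p0[free$angles] +
        theta[length(free$lengths) + seq_along(free$angles)]
    if (length(free$tied))
      for (tie in free$tied) p[tie$to] <- p[tie$from]
    p
  }
  nfree <- length(free$lengths) + length(free$angles)
  s0 <- sim_of(p0)
  obj <- function(theta) {
    if (any(abs(theta[seq_along(free$lengths)]) > max_strain)) return(2)
    if (length(free$angles) &&
        any(abs(theta[-seq_along(free$lengths)]) > 45)) return(2)
    -sim_of(expand(theta))
  }
  opt <- stats::optim(rep(0, nfree), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  # polish with a tighter restart around the optimum
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-12,
                                      parscale = rep(1e-2, nfree)))
  if (opt2$value < opt$value) opt <- opt2
  s_best <- -opt$value
  if (s_best <= s0) {
    return(list(structure = s, similarity = s0, start_similarity = s0,
                free = free))
  }
  p <- expand(opt$par)
  s2 <- s
  s2$cell <- lattice_cell(p["a"], p["b"], p["c"],
                          p["alpha"], p["beta"], p["gamma"])
  list(structure = s2, similarity = s_best, start_similarity = s0,
       free = free)
}

# crystal-system constraints from the symop rotations: which cell parameters
# are free, and which lengths are tied together
.free_cell_params <- function(s) {
  cl <- s$cell
  eq <- function(x, y) abs(x - y) < 1e-6
  rots <- lapply(s$symops, function(op) op$rot)
  n_ops <- length(rots)
  is90 <- c(eq(cl$alpha, 90), eq(cl$beta, 90), eq(cl$gamma, 90))
  if (all(is90) && eq(cl$a, cl$b) && eq(cl$b, cl$c) && n_ops >= 12) {
    return(list(lengths = "a", angles = character(0),
                tied = list(list(from = "a", to = "b"),
                            list(from = "a", to = "c"))))
  }
  if (all(is90) && eq(cl$a, cl$b) && n_ops >= 8) {
    return(list(lengths = c("a", "c"), angles = character(0),
                tied = list(list(from = "a", to = "b"))))
  }
  if (all(is90) && n_ops >= 4) {
    return(list(lengths = c("a", "b", "c"), angles = character(0),
                tied = list()))
  }
  if (is90[1] && is90[3] && n_ops >= 2) {
    return(list(lengths = c("a", "b", "c"), angles = "beta", tied = list()))
  }
  list(lengths = c("a", "b", "c"), angles = c("alpha", "beta", "gamma"),
       tied = list())
}

#' March-Dollase preferred-orientation correction
#'
#' Multiplies each reflection intensity by the March-Dollase factor for a
#' given preferred-orientation axis, averaged over the reflection's symmetry
#' equivalents. \code{r = 1} leaves intensities unchanged.
#'
#' @param refl A \code{reflection_list}.
#' @param s The source \code{crystal_structure} (for the reciprocal metric
#'   and symmetry equivalents).
#' @param axis Integer hkl of the preferred-orientation axis.
#' @param r March-Dollase parameter (> 0; < 1 for plates on the axis).
#' @return The reflection list with corrected intensities.
#' @export
preferred_orientation <- function(refl, s, axis, r) {
  stopifnot(r > 0)
  if (r == 1) return(refl)
  Gstar <- solve(cell_metric(s$cell))
  nax <- as.numeric(axis %*% Gstar %*% axis)
  md <- function(hkl) {
    # equivalents of hkl under the rotation parts of the symops
    eqs <- unique(t(vapply(s$symops, function(op)
      as.numeric(t(op$rot) %*% hkl), numeric(3))))
    fac <- apply(eqs, 1, function(e) {
      ca <- as.numeric(e %*% Gstar %*% axis) /
        sqrt(as.numeric(e %*% Gstar %*% e) * nax)
      ca <- pmin(1, pmax(-1, ca))
      (r^2 * ca^2 + (1 - ca^2) / r)^(-3 / 2)
    })
    mean(fac)
  }
  fac <- vapply(seq_len(nrow(refl)), function(i)
    md(c(refl$h[i], refl$k[i], refl$l[i])), 0)
  refl$intensity <- refl$intensity * fac
  refl
}

#' Read a two-column ASCII powder pattern
#'
#' Format: optional \code{# wavelength=<A>} header, then 2-theta and
#' intensity columns.
#'
#' @param path File path.
#' @param wavelength Fallback wavelength when no header is present.
#' @return A \code{\link{powder_pattern}}.
#' @export
read_xy <- function(path, wavelength = 1.54056) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  wl <- wavelength
  for (h in hdr) {
    m <- regmatches(h, regexec("wavelength\\s*=\\s*([0-9.]+)", h))[[1]]
    if (length(m) == 2) wl <- as.numeric(m[2])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  powder_pattern(dat[[1]], dat[[2]], wl)
}

#' Write a powder pattern as two-column ASCII
#' @param p A \code{\link{powder_pattern}}.
#' @param path Output path.
#' @return Invisibly \code{path}.
#' @export
write_xy <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength=%.6f", p$wavelength), con)
  utils::write.table(data.frame(p$two_theta, p$intensity), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
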