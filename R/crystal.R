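#' Construct a crystal structure
#'
#' The universal input record of the package: a unit cell, a set of symmetry
#' operators, and the asymmetric-unit atom sites as a data frame.
#'
#' @param cell A \code{\link{lattice_cell}}.
#' @param symops List of symops (see \code{\link{parse_symop}}); defaults to
#'   the identity only (P1).
#' @param sites Data frame with columns \code{label} (unique atom label),
#'   \code{element}, \code{x,y,z} (fractional), and optionally
#'   \code{occupancy} (default 1) and \code{disorder_group}
#'   (\code{NA} = ordered).
#' @param meta Named list of metadata: \code{id}, \code{group}, \code{rank},
#'   \code{energy} (kJ/mol per formula unit), \code{stoichiometry}, etc.
#' @return An object of class \code{"crystal_structure"}.
#' @examples
#' s <- crystal_structure(
#'   lattice_cell(5, 5, 5),
#'   sites = data.frame(label = "C1", element = "C", x = 0, y = 0, z = 0)
#' )
#' @export
crystal_structure <- function(cell, symops = list(parse_symop("x,y,z")),
                              sites, meta = list()) {
  stopifnot(inherits(cell, "lattice_cell"), is.data.frame(sites))
  need <- c("label", "element", "x", "y", "z")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  if (is.null(sites$occupancy)) sites$occupancy <- 1
  sites$occupancy[is.na(sites$occupancy)] <- 1
  if (any(sites$occupancy <= 0 | sites$occupancy > 1))
    stop("occupancies must lie in (0, 1]")
  if (is.null(sites$disorder_group)) sites$disorder_group <- NA_character_
  sites$label <- as.character(sites$label)
  sites$element <- as.character(sites$element)
  if (anyDuplicated(sites$label)) stop("atom site labels must be unique")
  covalent_radius(unique(sites$element))  # errors on unknown elements
  structure(list(cell = cell, symops = symops, sites = sites, meta = meta),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d site(s) in asymmetric unit, %d symop(s)\n",
              nrow(x$sites), length(x$symops)))
  print(x$cell)
  if (length(x$meta)) {
    m <- x$meta[!vapply(x$meta, is.null, TRUE)]
    cat("meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                       collapse = "  "), "\n")
  }
  invisible(x)
}

#' Expand the asymmetric unit to the full cell
#'
#' Applies every symmetry operator to every site, reduces the images to
#' [0, 1), and collapses duplicates closer than \code{merge_tol} (atoms on
#' special positions).
#'
#' @param s A \code{crystal_structure}.
#' @param merge_tol Cartesian merge tolerance in angstrom for special
#'   positions (default 0.3).
#' @return Data frame with columns \code{label, element, x, y, z, occupancy,
#'   disorder_group, site} (index of the generating site) — one row per atom
#'   in the unit cell.
#' @export
expand_to_cell <- function(s, merge_tol = 0.3) {
  st <- s$sites
  n <- nrow(st)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xf <- c(st$x[i], st$y[i], st$z[i])
    imgs <- t(vapply(s$symops,
                     function(op) (op$rot %*% xf + op$trans) %% 1,
                     numeric(3)))
    # collapse symmetry images of this site that coincide (special positions);
    # wrap-around handled by comparing minimum-image Cartesian distance
    keep <- rep(TRUE, nrow(imgs))
    for (a in seq_len(nrow(imgs))) {
      if (!keep[a]) next
      for (b in seq_len(nrow(imgs))) {
        if (b <= a || !keep[b]) next
        d <- imgs[b, ] - imgs[a, ]
        d <- d - round(d)
        if (sqrt(sum((s$cell$ortho %*% d)^2)) < merge_tol) keep[b] <- FALSE
      }
    }
    imgs <- imgs[keep, , drop = FALSE]
    rows[[i]] <- data.frame(
      label = st$label[i], element = st$element[i],
      x = imgs[, 1], y = imgs[, 2], z = imgs[, 3],
      occupancy = st$occupancy[i],
      disorder_group = st$disorder_group[i],
      site = i, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-express a structure in a supercell
#'
#' Builds the na x nb x nc supercell as a P1 structure: cell vectors are
#' multiplied and every unit-cell atom is replicated at each lattice
#' translation.
#'
#' @param s A \code{crystal_structure}.
#' @param na,nb,nc Positive integer multipliers along a, b, c.
#' @return A P1 \code{crystal_structure} describing the same crystal.
#' @export
supercell <- function(s, na = 1, nb = 1, nc = 1) {
  stopifnot(na >= 1, nb >= 1, nc >= 1)
  ex <- expand_to_cell(s)
  mult <- c(na, nb, nc)
  shifts <- as.matrix(expand.grid(i = 0:(na - 1), j = 0:(nb - 1),
                                  k = 0:(nc - 1)))
  rows <- vector("list", nrow(shifts))
  for (r in seq_len(nrow(shifts))) {
    e <- ex
    e$x <- (e$x + shifts[r, 1]) / na
    e$y <- (e$y + shifts[r, 2]) / nb
    e$z <- (e$z + shifts[r, 3]) / nc
    e$label <- paste0(e$label, "_", r, "_", seq_len(nrow(e)))
    rows[[r]] <- e
  }
  allsites <- do.call(rbind, rows)
  cell2 <- lattice_cell(s$cell$a * na, s$cell$b * nb, s$cell$c * nc,
                        s$cell$alpha, s$cell$beta, s$cell$gamma)
  crystal_structure(cell2, sites = allsites[c("label", "element", "x", "y",
                                              "z", "occupancy",
                                              "disorder_group")],
                    meta = s$meta)
}

#' Validate a crystal structure's invariants
#'
#' Checks symop group closure, expansion finiteness, and that no two expanded
#' atoms of the same disorder component sit closer than \code{merge_tol}
#' without coinciding.
#'
#' @param s A \code{crystal_structure}.
#' @param merge_tol Special-position merge tolerance in angstrom.
#' @return Invisibly \code{TRUE}; stops with a message on violation.
#' @export
validate_structure <- function(s, merge_tol = 0.3) {
  keys <- vapply(s$symops, symop_key, "")
  for (i in seq_along(s$symops)) for (j in seq_along(s$symops)) {
    k <- symop_key(symop_compose(s$symops[[i]], s$symops[[j]]))
    if (!k %in% keys) stop("symop set not closed under composition")
  }
  ex <- expand_to_cell(s, merge_tol)
  xyz <- frac_to_cart(s$cell, as.matrix(ex[c("x", "y", "z")]))
  grp <- ex$disorder_group
  for (a in seq_len(nrow(ex))) for (b in seq_len(nrow(ex))) {
    if (b <= a) next
    same_comp <- is.na(grp[a]) || is.na(grp[b]) || grp[a] == grp[b]
    if (!same_comp) next
    d <- ex[b, c("x", "y", "z")] - ex[a, c("x", "y", "z")]
    d <- unlist(d); d <- d - round(d)
    dc <- sqrt(sum((s$cell$ortho %*% d)^2))
    if (dc < merge_tol && !(ex$site[a] == ex$site[b]))
      stop(sprintf("expanded atoms %s and %s only %.3f A apart",
                   ex$label[a], ex$label[b], dc))
  }
  invisible(TRUE)
}
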