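# Symmetry operators on fractional coordinates and a small space-group table.
#
# A symop is a list(rot = 3x3 integer matrix, trans = length-3 vector with
# entries reduced mod 1). Operators act as x' = rot %*% x + trans.

#' Parse a symmetry operator in xyz notation
#'
#' Accepts the CIF convention, e.g. \code{"-x, y+1/2, -z+1/2"}.
#'
#' @param xyz A single operator string.
#' @return A symop: \code{list(rot, trans)} with \code{trans} reduced mod 1.
#' @export
parse_symop <- function(xyz) {
  parts <- strsplit(gsub("[ ']", "", tolower(xyz)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", xyz)
  rot <- matrix(0L, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sgn <- 1
      if (startsWith(tm, "-")) { sgn <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        rot[i, match(tm, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        fr <- as.numeric(strsplit(tm, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sgn * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        trans[i] <- trans[i] + sgn * as.numeric(tm)
      } else stop("cannot parse symmetry term '", tm, "' in: ", xyz)
    }
  }
  list(rot = rot, trans = trans %% 1)
}

#' Format a symop back to xyz notation
#' @param op A symop.
#' @return A string such as \code{"-x,y+1/2,-z+1/2"}.
#' @export
symop_xyz <- function(op) {
  axes <- c("x", "y", "z")
  out <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rot[i, j]
      if (r == 1) s <- paste0(s, if (nzchar(s)) "+" else "", axes[j])
      if (r == -1) s <- paste0(s, "-", axes[j])
    }
    tr <- op$trans[i] %% 1
    if (abs(tr) > 1e-9 && abs(tr - 1) > 1e-9) {
      fr <- .as_fraction(tr)
      s <- paste0(s, "+", fr)
    }
    if (!nzchar(s)) s <- "0"
    out[i] <- s
  }
  paste(out, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6, 8, 12)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(paste0(n, "/", d))
  }
  format(x)
}

symop_compose <- function(op1, op2) {
  # op1 after op2: x -> op1(op2(x))
  list(rot = op1$rot %*% op2$rot,
       trans = (op1$rot %*% op2$trans + op1$trans) %% 1)
}

symop_key <- function(op) {
  paste(c(op$rot, round(op$trans * 24) %% 24), collapse = ",")
}

#' Close a set of symmetry operators under composition
#'
#' Repeatedly composes generators until no new operators (mod lattice
#' translations) appear.
#'
#' @param ops List of symops (generators).
#' @return The full group as a list of symops.
#' @export
symop_closure <- function(ops) {
  seen <- new.env(hash = TRUE)
  out <- list()
  add <- function(op) {
    k <- symop_key(op)
    if (is.null(seen[[k]])) { seen[[k]] <- TRUE; out[[length(out) + 1]] <<- op; TRUE } else FALSE
  }
  for (op in ops) add(op)
  repeat {
    grew <- FALSE
    n <- length(out)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (add(symop_compose(out[[i]], out[[j]]))) grew <- TRUE
      if (length(out) > 192) stop("symmetry closure did not converge")
    }
    if (!grew) break
  }
  out
}

# Space-group table: generators in xyz notation, keyed by a normalized
# Hermann-Mauguin symbol. Covers the common molecular space groups; CIFs with
# an explicit operator loop bypass this table entirely.
.spacegroup_generators <- list(
  "P1"       = list(num = 1,  gen = c("x,y,z")),
  "P-1"      = list(num = 2,  gen = c("x,y,z", "-x,-y,-z")),
  "P21"      = list(num = 4,  gen = c("x,y,z", "-x,y+1/2,-z")),
  "PC"       = list(num = 7,  gen = c("x,y,z", "x,-y,z+1/2")),
  "P21/M"    = list(num = 11, gen = c("x,y,z", "-x,y+1/2,-z", "-x,-y,-z")),
  "CC"       = list(num = 9,  gen = c("x,y,z", "x,-y,z+1/2", "x+1/2,y+1/2,z")),
  "C2"       = list(num = 5,  gen = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z")),
  "P21/C"    = list(num = 14, gen = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z")),
  "C2/C"     = list(num = 15, gen = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z",
                                      "x+1/2,y+1/2,z")),
  "P212121"  = list(num = 19, gen = c("x,y,z", "-x+1/2,-y,z+1/2",
                                      "x+1/2,-y+1/2,-z")),
  "PCA21"    = list(num = 29, gen = c("x,y,z", "-x,-y,z+1/2",
                                      "x+1/2,-y,z")),
  "PNA21"    = list(num = 33, gen = c("x,y,z", "-x,-y,z+1/2",
                                      "x+1/2,-y+1/2,z")),
  "PBCA"     = list(num = 61, gen = c("x,y,z", "-x+1/2,-y,z+1/2",
                                      "x+1/2,-y+1/2,-z", "-x,-y,-z")),
  "PBCN"     = list(num = 60, gen = c("x,y,z", "-x+1/2,-y+1/2,z+1/2",
                                      "-x,y,-z+1/2", "-x,-y,-z"))
)

.normalize_hm <- function(symbol) {
  s <- toupper(gsub("[ _]", "", symbol))
  # subscripts like P2(1)/c
  s <- gsub("[()]", "", s)
  s
}

#' Symmetry operators for a space group
#'
#' Looks up a Hermann-Mauguin symbol or International Tables number in the
#' internal table of common molecular space groups and returns the full
#' operator set generated from the stored generators.
#'
#' @param symbol Hermann-Mauguin symbol (e.g. \code{"P21/c"}); spaces and
#'   underscores are ignored, case-insensitive. May be \code{NULL} when
#'   \code{number} is given.
#' @param number International Tables space-group number.
#' @return List of symops.
#' @export
spacegroup_symops <- function(symbol = NULL, number = NULL) {
  entry <- NULL
  if (!is.null(symbol)) {
    entry <- .spacegroup_generators[[.normalize_hm(symbol)]]
  }
  if (is.null(entry) && !is.null(number)) {
    nums <- vapply(.spacegroup_generators, function(e) e$num, 0)
    hit <- which(nums == number)
    if (length(hit)) entry <- .spacegroup_generators[[hit[1]]]
  }
  if (is.null(entry))
    stop("unrecognized space group: ",
         if (!is.null(symbol)) symbol else number,
         " (no operator loop given and symbol not in internal table)")
  symop_closure(lapply(entry$gen, parse_symop))
}
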