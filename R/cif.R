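# CIF input/output for the core-dictionary subset used across the package:
# cell parameters, symmetry (operator loop, H-M symbol, or IT number), and
# the atom-site loop with occupancies and disorder tags. Multi-block files
# are supported; one crystal_structure per data block.

.cif_tokenize <- function(lines) {
  # split a CIF body into tokens, honoring quoted strings and comments
  toks <- list()
  for (ln in lines) {
    ln <- sub("^\\s+", "", ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, ";")) stop("multi-line text fields are not supported")
    i <- 1; nch <- nchar(ln)
    while (i <= nch) {
      ch <- substr(ln, i, i)
      if (grepl("\\s", ch)) { i <- i + 1; next }
      if (ch == "#") break
      if (ch == "'" || ch == '"') {
        j <- i + 1
        while (j <= nch && substr(ln, j, j) != ch) j <- j + 1
        toks[[length(toks) + 1]] <- substr(ln, i + 1, j - 1)
        i <- j + 1
      } else {
        j <- i
        while (j <= nch && !grepl("\\s", substr(ln, j, j))) j <- j + 1
        toks[[length(toks) + 1]] <- substr(ln, i, j - 1)
        i <- j
      }
    }
  }
  unlist(toks)
}

.cif_number <- function(x) {
  # strip standard uncertainty "1.234(5)" and parse
  as.numeric(sub("\\(\\d+\\)$", "", x))
}

.parse_cif_block <- function(tokens, block_name) {
  items <- list()   # single tag -> value
  loops <- list()   # list of list(tags, values matrix)
  i <- 1; n <- length(tokens)
  while (i <= n) {
    tk <- tokens[i]
    if (tolower(tk) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && startsWith(tokens[i], "_")) {
        tags <- c(tags, tolower(tokens[i])); i <- i + 1
      }
      vals <- character(0)
      while (i <= n && !startsWith(tokens[i], "_") &&
             tolower(tokens[i]) != "loop_" &&
             !startsWith(tolower(tokens[i]), "data_")) {
        vals <- c(vals, tokens[i]); i <- i + 1
      }
      if (length(tags) == 0 || length(vals) %% length(tags) != 0)
        stop("malformed loop in CIF block ", block_name)
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      colnames(m) <- tags
      loops[[length(loops) + 1]] <- m
    } else if (startsWith(tk, "_")) {
      if (i + 1 > n) stop("dangling tag ", tk, " in CIF block ", block_name)
      items[[tolower(tk)]] <- tokens[i + 1]
      i <- i + 2
    } else {
      stop("unexpected token '", tk, "' in CIF block ", block_name)
    }
  }
  list(items = items, loops = loops)
}

.loop_with <- function(loops, tag) {
  for (m in loops) if (tag %in% colnames(m)) return(m)
  NULL
}

.first_item <- function(items, tags) {
  for (tg in tags) if (!is.null(items[[tg]])) return(items[[tg]])
  NULL
}

#' Read crystal structures from a CIF file
#'
#' Parses the core-dictionary subset: cell parameters, symmetry (an explicit
#' operator loop, or a Hermann-Mauguin symbol / IT number resolved against the
#' internal space-group table), and the atom-site loop with occupancies and
#' disorder assembly/group tags. Missing occupancies default to 1.
#'
#' @param path Path to a CIF file (one or more data blocks).
#' @return A list of \code{\link{crystal_structure}} objects, one per data
#'   block, named by block name. The block name is stored in
#'   \code{meta$id}.
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- .cif_tokenize(lines)
  starts <- which(startsWith(tolower(toks), "data_"))
  if (length(starts) == 0) stop("no data block found in ", path)
  out <- list()
  for (bi in seq_along(starts)) {
    from <- starts[bi] + 1
    to <- if (bi < length(starts)) starts[bi + 1] - 1 else length(toks)
    name <- substring(toks[starts[bi]], 6)
    blk <- .parse_cif_block(toks[from:to], name)
    out[[name]] <- .block_to_structure(blk, name)
  }
  out
}

.block_to_structure <- function(blk, name) {
  it <- blk$items
  cpar <- lapply(c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                   "_cell_angle_alpha", "_cell_angle_beta",
                   "_cell_angle_gamma"),
                 function(tg) it[[tg]])
  if (any(vapply(cpar, is.null, TRUE)))
    stop("CIF block '", name, "': missing cell parameters")
  cpar <- vapply(cpar, .cif_number, 0)
  cell <- lattice_cell(cpar[1], cpar[2], cpar[3], cpar[4], cpar[5], cpar[6])

  symloop <- .loop_with(blk$loops, "_symmetry_equiv_pos_as_xyz")
  symcol <- "_symmetry_equiv_pos_as_xyz"
  if (is.null(symloop)) {
    symloop <- .loop_with(blk$loops, "_space_group_symop_operation_xyz")
    symcol <- "_space_group_symop_operation_xyz"
  }
  if (!is.null(symloop)) {
    symops <- lapply(symloop[, symcol], parse_symop)
  } else {
    hm <- .first_item(it, c("_symmetry_space_group_name_h-m",
                            "_space_group_name_h-m_alt"))
    num <- .first_item(it, c("_symmetry_int_tables_number",
                             "_space_group_it_number"))
    if (is.null(hm) && is.null(num))
      stop("CIF block '", name, "': no symmetry operators or space group")
    symops <- spacegroup_symops(symbol = hm,
                                number = if (!is.null(num))
                                  as.integer(.cif_number(num)) else NULL)
  }

  atoms <- .loop_with(blk$loops, "_atom_site_fract_x")
  if (is.null(atoms))
    stop("CIF block '", name, "': missing atom-site coordinates")
  getc <- function(tag) if (tag %in% colnames(atoms)) atoms[, tag] else NULL
  lab <- getc("_atom_site_label")
  el <- getc("_atom_site_type_symbol")
  if (is.null(el)) el <- gsub("[0-9'*]+.*$", "", lab)
  occ <- getc("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(atoms)) else {
    v <- .cif_number(occ); v[!is.finite(v)] <- 1; v
  }
  dg <- getc("_atom_site_disorder_group")
  da <- getc("_atom_site_disorder_assembly")
  disorder <- rep(NA_character_, nrow(atoms))
  if (!is.null(dg)) {
    tagd <- !(dg %in% c(".", "?", "")) & !is.na(dg)
    disorder[tagd] <- if (!is.null(da))
      paste0(ifelse(da[tagd] %in% c(".", "?", ""), "", da[tagd]), dg[tagd])
    else dg[tagd]
  } else if (any(occ < 1)) {
    # untagged partial occupancy: group sites sharing an occupancy value
    warning("CIF block '", name,
            "': partial occupancies without disorder tags; grouping by occupancy")
    part <- occ < 1
    disorder[part] <- paste0("occ", match(round(occ[part], 4),
                                          unique(round(occ[part], 4))))
  }
  sites <- data.frame(
    label = lab, element = el,
    x = .cif_number(atoms[, "_atom_site_fract_x"]) %% 1,
    y = .cif_number(atoms[, "_atom_site_fract_y"]) %% 1,
    z = .cif_number(atoms[, "_atom_site_fract_z"]) %% 1,
    occupancy = occ, disorder_group = disorder,
    stringsAsFactors = FALSE
  )
  meta <- list(id = name)
  crystal_structure(cell, symops, sites, meta)
}

#' Write crystal structures to a CIF file
#'
#' Inverse of \code{\link{read_cif}} for the same subset; symmetry is written
#' as an explicit operator loop so round-trips never depend on the
#' space-group table.
#'
#' @param structures A \code{crystal_structure} or list of them.
#' @param path Output path.
#' @param digits Decimal digits for fractional coordinates (default 6).
#' @return Invisibly \code{path}.
#' @export
write_cif <- function(structures, path, digits = 6) {
  if (inherits(structures, "crystal_structure"))
    structures <- list(structures)
  lines <- character(0)
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    nm <- names(structures)[i]
    if (is.null(nm) || !nzchar(nm))
      nm <- if (!is.null(s$meta$id)) s$meta$id else paste0("block", i)
    fmt <- function(x) formatC(x, digits = digits, format = "f")
    lines <- c(lines,
      paste0("data_", nm),
      paste("_cell_length_a", fmt(s$cell$a)),
      paste("_cell_length_b", fmt(s$cell$b)),
      paste("_cell_length_c", fmt(s$cell$c)),
      paste("_cell_angle_alpha", fmt(s$cell$alpha)),
      paste("_cell_angle_beta", fmt(s$cell$beta)),
      paste("_cell_angle_gamma", fmt(s$cell$gamma)),
      "loop_",
      "_symmetry_equiv_pos_as_xyz",
      vapply(s$symops, function(op) paste0("'", symop_xyz(op), "'"), ""),
      "loop_",
      "_atom_site_label",
      "_atom_site_type_symbol",
      "_atom_site_fract_x",
      "_atom_site_fract_y",
      "_atom_site_fract_z",
      "_atom_site_occupancy",
      "_atom_site_disorder_group",
      sprintf("%s %s %s %s %s %s %s",
              s$sites$label, s$sites$element,
              fmt(s$sites$x %% 1), fmt(s$sites$y %% 1), fmt(s$sites$z %% 1),
              fmt(s$sites$occupancy),
              ifelse(is.na(s$sites$disorder_group), ".",
                     s$sites$disorder_group)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
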