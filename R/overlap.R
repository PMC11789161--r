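# Cross-landscape coverage matrices by PDD matching, and landscape
# deduplication.

#' Landscape-vs-landscape overlap matrix
#'
#' Entry (i, j) is the percentage of group i's query set matched within
#' group j's target set under the PDD criterion
#' (\code{\link{is_pdd_match}}). Query sets are the top-\code{top} ranked
#' structures of each group; target sets are the top-\code{top}
#' (\code{"100v100"} mode) or the group's full set (\code{"100vAll"}).
#' Groups submitting fewer than \code{top} structures contribute all of
#' them, with the denominator equal to the actual query-set size.
#'
#' @param landscapes Named list: one list of \code{crystal_structure}s per
#'   group. Rank metadata (\code{meta$rank}) is required in
#'   \code{"100v100"} mode (input order is used as rank when absent in
#'   \code{"100vAll"}).
#' @param mode \code{"100v100"} or \code{"100vAll"}.
#' @param k PDD neighbour count (default 100).
#' @param cutoff PDD match cutoff in angstrom (default 0.225).
#' @param top Query truncation (default 100).
#' @return Object of class \code{"overlap_matrix"}: the percentage matrix
#'   with group names, plus attributes \code{mode}, \code{k},
#'   \code{cutoff}.
#' @export
overlap_matrix <- function(landscapes, mode = c("100v100", "100vAll"),
                           k = 100, cutoff = 0.225, top = 100) {
  mode <- match.arg(mode)
  G <- length(landscapes)
  if (is.null(names(landscapes)))
    names(landscapes) <- paste0("group", seq_len(G))
  ranked <- lapply(names(landscapes), function(g) {
    L <- landscapes[[g]]
    r <- vapply(L, function(s)
      if (!is.null(s$meta$rank)) s$meta$rank else NA_real_, 0)
    if (any(is.na(r))) {
      if (mode == "100v100")
        stop("missing ranks in 100v100 mode for group(s): ", g)
      r <- seq_along(L)
    }
    L[order(r)]
  })
  names(ranked) <- names(landscapes)
  queries <- lapply(ranked, function(L) L[seq_len(min(top, length(L)))])
  targets <- if (mode == "100v100") queries else ranked
  M <- matrix(0, G, G, dimnames = list(names(landscapes), names(landscapes)))
  for (i in seq_len(G)) for (j in seq_len(G)) {
    q <- queries[[i]]; tset <- targets[[j]]
    hit <- vapply(q, function(qs)
      any(vapply(tset, function(ts)
        isTRUE(is_pdd_match(qs, ts, k = k, cutoff = cutoff)), TRUE)),
      TRUE)
    M[i, j] <- 100 * mean(hit)
  }
  structure(M, mode = mode, k = k, cutoff = cutoff,
            class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("landscape overlap matrix (%s, k=%d, cutoff=%.3f A), %%:\n",
              attr(x, "mode"), attr(x, "k"), attr(x, "cutoff")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Plot an overlap matrix as a heat map
#' @param x An \code{overlap_matrix}.
#' @param ... Passed to \code{image}.
#' @export
plot.overlap_matrix <- function(x, ...) {
  G <- nrow(x)
  graphics::image(seq_len(G), seq_len(G), t(unclass(x))[, G:1],
                  zlim = c(0, 100), axes = FALSE, xlab = "target group",
                  ylab = "query group", ...)
  graphics::axis(1, seq_len(G), colnames(x))
  graphics::axis(2, G:1, rownames(x))
  invisible(x)
}

#' Deduplicate a landscape
#'
#' Single-linkage clustering under either the PDD metric (EMD below
#' \code{threshold}) or the packing metric (full match with RMSD below
#' \code{threshold}). Representatives are the lowest-energy members when
#' energies are present, else the first by input order.
#'
#' @param landscape List of \code{crystal_structure}s.
#' @param method \code{"pdd"} or \code{"packing"}.
#' @param threshold Linkage threshold: angstrom of EMD (pdd) or RMSD
#'   (packing).
#' @param k PDD neighbour count (pdd method).
#' @param tol \code{\link{tolerance_spec}} for the packing method.
#' @return Data frame \code{index, cluster, representative}; attribute
#'   \code{"sizes"} is the cluster-size histogram.
#' @export
dedupe <- function(landscape, method = c("pdd", "packing"), threshold,
                   k = 100, tol = tolerance_spec(n_molecules = 10)) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  L <- length(landscape)
  if (method == "packing") {
    out <- dedupe_key(landscape, tol = tol, rmsd_threshold = threshold)
  } else {
    pdds <- lapply(landscape, compute_pdd, k = k)
    vols <- vapply(landscape, function(s) s$cell$volume, 0)
    parent <- seq_len(L)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (j <= i || find(i) == find(j)) next
      # volume-normalize i to j before comparing, as in is_pdd_match
      pi_n <- compute_pdd(volume_normalize(landscape[[i]], landscape[[j]]), k)
      if (pdd_distance(pi_n, pdds[[j]]) <= threshold)
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
    out <- data.frame(index = seq_len(L), cluster = cluster,
                      representative = rep_of[cluster])
  }
  attr(out, "sizes") <- as.integer(table(table(out$cluster)))
  names(attr(out, "sizes")) <- names(table(table(out$cluster)))
  out
}
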