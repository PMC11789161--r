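# The staged match-assessment pipeline: powder-similarity gate, packing
# comparison, verdict; batch assessment of a landscape against experimental
# forms, with disorder splitting and core-only mode.

#' Parameters of the match-assessment protocol
#'
#' Defaults follow the standard assessment settings: a 70% powder-similarity
#' gate, a 30-molecule shell with 35%/35 deg tolerances excluding hydrogens,
#' and a 1.0 angstrom RMSD match threshold.
#'
#' @param gate Powder-similarity gate in [0, 1] (default 0.70).
#' @param shell Packing cluster size (default 30).
#' @param dist_tol,angle_tol Packing tolerances (default 0.35 and 35).
#' @param rmsd_threshold Match RMSD threshold in angstrom (default 1.0).
#' @param l de Gelder window half-width in degrees (default 1.5).
#' @param two_theta_range,step Powder simulation grid (defaults 3-40 deg,
#'   0.017 deg).
#' @param ignore_hydrogen Exclude hydrogens from packing comparison
#'   (default \code{TRUE}).
#' @param trial_cap Packing correspondence trial cap.
#' @return List of class \code{"protocol_params"}.
#' @export
protocol_params <- function(gate = 0.70, shell = 30, dist_tol = 0.35,
                            angle_tol = 35, rmsd_threshold = 1.0, l = 1.5,
                            two_theta_range = c(3, 40), step = 0.017,
                            ignore_hydrogen = TRUE, trial_cap = 1e6) {
  structure(list(gate = gate, shell = shell, dist_tol = dist_tol,
                 angle_tol = angle_tol, rmsd_threshold = rmsd_threshold,
                 l = l, two_theta_range = two_theta_range, step = step,
                 ignore_hydrogen = ignore_hydrogen, trial_cap = trial_cap),
            class = "protocol_params")
}

.protocol_tol <- function(params) {
  tolerance_spec(dist_tol = params$dist_tol, angle_tol = params$angle_tol,
                 n_molecules = params$shell,
                 ignore_hydrogen = params$ignore_hydrogen,
                 trial_cap = params$trial_cap)
}

.one_assessment <- function(pred, exp_comp, params, component, mode,
                            skip_gate = FALSE, pred_pattern = NULL) {
  gate_sim <- NA_real_
  if (!skip_gate) {
    if (is.null(pred_pattern))
      pred_pattern <- simulate_pattern(pred,
                                       two_theta_range = params$two_theta_range,
                                       step = params$step)
    exp_pattern <- simulate_pattern(exp_comp,
                                    two_theta_range = params$two_theta_range,
                                    step = params$step)
    gate_sim <- degelder_similarity(pred_pattern, exp_pattern, params$l)
    if (gate_sim < params$gate) {
      return(structure(list(gate_similarity = gate_sim, packing = NULL,
                            verdict = "gate-fail", component = component,
                            mode = mode), class = "match_report"))
    }
  }
  pm <- tryCatch(
    compare_packing(exp_comp, pred, .protocol_tol(params),
                    full_only = TRUE, keep = 32L),
    error = function(e) {
      if (grepl("comparison limit", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(pm)) {
    return(structure(list(gate_similarity = gate_sim, packing = NULL,
                          verdict = "limit-error", component = component,
                          mode = mode), class = "match_report"))
  }
  verdict <- if (pm$n_matched == params$shell && !is.na(pm$rmsd) &&
                 pm$rmsd < params$rmsd_threshold) "match" else "no-match"
  structure(list(gate_similarity = gate_sim, packing = pm, verdict = verdict,
                 component = component, mode = mode),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match report [%s%s]: verdict = %s", x$mode,
              if (!is.na(x$component)) paste0(", component ", x$component)
              else "", x$verdict))
  if (!is.na(x$gate_similarity))
    cat(sprintf(", gate similarity %.3f", x$gate_similarity))
  if (!is.null(x$packing))
    cat(sprintf(", %d/%d overlaid, RMSD %.4f A", x$packing$n_matched,
                x$packing$n_requested, x$packing$rmsd))
  cat("\n")
  invisible(x)
}

#' Assess whether a predicted structure matches an experimental form
#'
#' Step (a): simulate both powder patterns and gate on the de Gelder
#' similarity. Step (b): packing comparison at the configured shell and
#' tolerances. Step (c): verdict \code{"match"} when the full shell overlays
#' with RMSD below the threshold. A disordered experimental structure is
#' split into ordered components and each component is assessed separately.
#'
#' @param pred,exp \code{crystal_structure}s (prediction and experimental
#'   form).
#' @param params A \code{\link{protocol_params}}.
#' @return A \code{"match_report"} (fields \code{gate_similarity},
#'   \code{packing}, \code{verdict}, \code{component}, \code{mode}), or a
#'   list of them (one per disorder component).
#' @export
assess_match <- function(pred, exp, params = protocol_params()) {
  comps <- split_disorder(exp)
  pred_pattern <- simulate_pattern(pred,
                                   two_theta_range = params$two_theta_range,
                                   step = params$step)
  reports <- lapply(seq_along(comps), function(i) {
    tag <- if (length(comps) > 1) {
      if (!is.null(comps[[i]]$meta$component)) comps[[i]]$meta$component
      else as.character(i)
    } else NA_character_
    .one_assessment(pred, comps[[i]], params, component = tag,
                    mode = "all-atoms", pred_pattern = pred_pattern)
  })
  if (length(reports) == 1) reports[[1]] else reports
}

#' Core-only match assessment
#'
#' Strips the selected atoms from both structures and runs the packing
#' comparison with the powder gate skipped (the pattern of a stripped
#' structure is not physical). The verdict is labelled
#' \code{mode = "core-only"}.
#'
#' @param pred,exp \code{crystal_structure}s.
#' @param core_selector List with any of \code{elements}, \code{labels},
#'   \code{fragment}, passed to \code{\link{strip_atoms}} — these select the
#'   atoms to REMOVE from both structures.
#' @param params A \code{\link{protocol_params}}.
#' @return A \code{"match_report"}.
#' @export
core_only_assess <- function(pred, exp, core_selector,
                             params = protocol_params()) {
  strip1 <- function(s) do.call(strip_atoms, c(list(s), core_selector))
  predc <- strip1(pred); expc <- strip1(exp)
  .one_assessment(predc, expc, params, component = NA_character_,
                  mode = "core-only", skip_gate = TRUE)
}

#' Assess a landscape of predictions against experimental forms
#'
#' Runs the staged protocol for every (form, disorder component) over the
#' landscape, in submitted-rank order when ranks are present, and reports the
#' first matching structure and summary counts.
#'
#' @param landscape List of predicted \code{crystal_structure}s.
#' @param forms List of experimental \code{crystal_structure}s (or a single
#'   one).
#' @param params A \code{\link{protocol_params}}.
#' @param first_only Stop scanning a component after its first match
#'   (default \code{TRUE}).
#' @return Data frame with one row per (form, component): the matched entry
#'   index and rank, its RMSD and gate similarity, and the number of
#'   structures that passed the gate. Attribute \code{"verdicts"} holds the
#'   full verdict matrix (component x landscape entry).
#' @export
assess_landscape <- function(landscape, forms, params = protocol_params(),
                             first_only = TRUE) {
  if (inherits(forms, "crystal_structure")) forms <- list(forms)
  if (length(landscape) > 1500)
    warning("landscape exceeds 1500 structures")
  ranks <- vapply(landscape, function(s)
    if (!is.null(s$meta$rank)) s$meta$rank else NA_real_, 0)
  ord <- if (all(!is.na(ranks))) order(ranks) else seq_along(landscape)
  rows <- list()
  verdicts <- list()
  for (fi in seq_along(forms)) {
    comps <- split_disorder(forms[[fi]])
    for (ci in seq_along(comps)) {
      tag <- if (length(comps) > 1) {
        if (!is.null(comps[[ci]]$meta$component)) comps[[ci]]$meta$component
        else as.character(ci)
      } else NA_character_
      vrow <- rep(NA_character_, length(landscape))
      hit_idx <- NA_integer_; hit_rmsd <- NA_real_; hit_gate <- NA_real_
      n_gate_pass <- 0L
      for (li in ord) {
        rep1 <- .one_assessment(landscape[[li]], comps[[ci]], params,
                                component = tag, mode = "all-atoms")
        vrow[li] <- rep1$verdict
        if (rep1$verdict != "gate-fail") n_gate_pass <- n_gate_pass + 1L
        if (rep1$verdict == "match" && is.na(hit_idx)) {
          hit_idx <- li
          hit_rmsd <- rep1$packing$rmsd
          hit_gate <- rep1$gate_similarity
          if (first_only) break
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        form = fi, component = tag, matched = !is.na(hit_idx),
        match_index = hit_idx,
        match_rank = if (!is.na(hit_idx)) ranks[hit_idx] else NA_real_,
        rmsd = hit_rmsd, gate_similarity = hit_gate,
        n_gate_pass = n_gate_pass, stringsAsFactors = FALSE)
      verdicts[[length(verdicts) + 1]] <- vrow
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "verdicts") <- do.call(rbind, verdicts)
  out
}
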