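# Blocked-metabolite detection (GapFind-style, via per-metabolite production
# maximization) and flux-coupling classification of reactions and enzymes
# relative to growth (Charnes-Cooper linear-fractional programs).

#' Metabolites that cannot carry net production
#'
#' A metabolite is blocked when no feasible steady-state flux distribution
#' (exchange bounds at their declared limits) gives it strictly positive net
#' production. Tested per metabolite by adding a temporary sink and
#' maximizing its flux.
#'
#' @param model a [metabolic_model()].
#' @param tol_zero production threshold.
#' @return character vector of blocked metabolite ids.
#' @export
find_blocked_metabolites <- function(model, tol_zero = 1e-6) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  blocked <- character(0)
  for (i in seq_len(nrow(S))) {
    sink <- rep(0, nrow(S)); sink[i] <- -1
    res <- tryCatch(
      lp_solve(c(rep(0, n), 1), cbind(S, sink), rep(0, nrow(S)), NULL, NULL,
               c(lb, 0), c(ub, 1000), maximize = TRUE),
      error = function(e) NULL)
    if (is.null(res) || res$status != "optimal" || res$objective <= tol_zero) {
      blocked <- c(blocked, rownames(S)[i])
    }
  }
  blocked
}

#' Reactions unable to carry flux
#'
#' A reaction is blocked when its flux range, with no objective constraint
#' and bounds at their declared limits, is `[0, 0]`.
#'
#' @inheritParams find_blocked_metabolites
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, tol_zero = 1e-6) {
  rng <- unconstrained_fva(model)
  rng$reaction[abs(rng$vmin) <= tol_zero & abs(rng$vmax) <= tol_zero]
}

unconstrained_fva <- function(model, fix = NULL) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(fix)) {
    k <- rxn_index(model, names(fix))
    lb[k] <- unlist(fix); ub[k] <- unlist(fix)
  }
  n <- ncol(S)
  purrr::map_dfr(seq_len(n), function(j) {
    obj <- rep(0, n); obj[j] <- 1
    lo <- lp_solve(obj, S, rep(0, nrow(S)), NULL, NULL, lb, ub, maximize = FALSE)
    hi <- lp_solve(obj, S, rep(0, nrow(S)), NULL, NULL, lb, ub, maximize = TRUE)
    tibble::tibble(reaction = colnames(S)[j],
                   vmin = if (lo$status == "optimal") lo$objective else NA_real_,
                   vmax = if (hi$status == "optimal") hi$objective else NA_real_)
  })
}

#' Flux-coupling classification relative to a target reaction
#'
#' For each reaction computes the attainable extremes of the flux ratio
#' `v_j / v_target` over the steady-state polytope (Charnes-Cooper
#' substitution, two LPs per reaction) and classifies each reaction as
#' `blocked`, `full` (fixed non-zero ratio), `partial` (ratio bounded away
#' from 0), `directional` (the reaction can be off while the target runs, but
#' cannot run when the target is off), or `uncoupled`. Reversible reactions
#' are classified on `|v_j|`.
#'
#' @param model a [metabolic_model()].
#' @param target reaction id; defaults to the biomass reaction.
#' @param tol_zero zero-flux threshold; `tol_ratio` relative tolerance for
#'   ratio equality.
#' @return a `coupling_report`: list with `reactions` (tibble: `reaction`,
#'   `rmin`, `rmax` signed ratio bounds, `class`, `ec`), `enzymes` (see
#'   [classify_enzymes()]) and `target`.
#' @export
flux_coupling <- function(model, target = NULL, tol_zero = 1e-6,
                          tol_ratio = 1e-5) {
  target <- target %||% model$biomass_reaction_id
  rxn_ids <- model$reactions$id
  if (!target %in% rxn_ids) stop("unknown target reaction: ", target)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  it <- match(target, rxn_ids)
  blocked <- find_blocked_reactions(model, tol_zero)
  if (target %in% blocked) stop("target reaction is blocked; coupling undefined")

  # Charnes-Cooper: y = t v, t = 1/v_target >= 0, y_target = 1
  #   S y = 0;  y_k - ub_k t <= 0;  -y_k + lb_k t <= 0
  Aeq <- rbind(cbind(S, 0), c(as.numeric(seq_len(n) == it), 0))
  beq <- c(rep(0, nrow(S)), 1)
  rows <- list()
  for (k in seq_len(n)) {
    if (is.finite(ub[k])) rows[[length(rows) + 1L]] <- c(as.numeric(seq_len(n) == k), -ub[k])
    if (is.finite(lb[k])) rows[[length(rows) + 1L]] <- c(-as.numeric(seq_len(n) == k), lb[k])
  }
  Aub <- do.call(rbind, rows)
  bub <- rep(0, nrow(Aub))
  lo_y <- c(rep(-Inf, n), 0); hi_y <- rep(Inf, n + 1)

  # can each reaction run while the target is off?
  off_rng <- unconstrained_fva(model, fix = stats::setNames(list(0), target))

  out <- purrr::map_dfr(seq_len(n), function(j) {
    rid <- rxn_ids[j]
    if (rid %in% blocked) {
      return(tibble::tibble(reaction = rid, rmin = 0, rmax = 0, class = "blocked"))
    }
    obj <- c(as.numeric(seq_len(n) == j), 0)
    lo <- lp_solve(obj, Aeq, beq, Aub, bub, lo_y, hi_y, maximize = FALSE)
    hi <- lp_solve(obj, Aeq, beq, Aub, bub, lo_y, hi_y, maximize = TRUE)
    rmin <- if (lo$status == "optimal") lo$objective else if (lo$status == "unbounded") -Inf else NA_real_
    rmax <- if (hi$status == "optimal") hi$objective else if (hi$status == "unbounded") Inf else NA_real_
    # magnitude-based bounds for classification
    spans_zero <- !is.na(rmin) && !is.na(rmax) && rmin < tol_ratio && rmax > -tol_ratio
    rmin_abs <- if (spans_zero) 0 else min(abs(rmin), abs(rmax))
    rmax_abs <- max(abs(rmin), abs(rmax))
    k <- match(rid, off_rng$reaction)
    runs_without <- !is.na(off_rng$vmax[k]) &&
      max(abs(c(off_rng$vmin[k], off_rng$vmax[k]))) > tol_zero
    cls <- if (rmin_abs > tol_ratio && is.finite(rmax_abs) &&
               rmax_abs - rmin_abs <= tol_ratio * (1 + rmax_abs)) "full"
      else if (rmin_abs > tol_ratio) "partial"
      else if (!runs_without) "directional"
      else "uncoupled"
    tibble::tibble(reaction = rid, rmin = rmin, rmax = rmax, class = cls)
  })
  out$ec <- model$reactions$ec[match(out$reaction, rxn_ids)]
  report <- structure(list(reactions = out, target = target), class = "coupling_report")
  report$enzymes <- classify_enzymes(report, model)
  report
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report> target:", x$target, "\n")
  print(table(x$reactions$class))
  invisible(x)
}

#' Aggregate reaction coupling classes to enzymes
#'
#' An enzyme's class is the strongest coupling among the reactions it
#' catalyzes (`full > partial > directional > uncoupled`); it is `blocked`
#' only when every catalyzed reaction is blocked.
#'
#' @param report a `coupling_report` from [flux_coupling()].
#' @param model the model the report was computed on.
#' @return tibble with `ec`, `class`, `n_reactions`.
#' @export
classify_enzymes <- function(report, model) {
  rxn <- model$reactions
  ec_map <- tibble::tibble(
    ec = unlist(rxn$ec),
    reaction = rep(rxn$id, lengths(rxn$ec)))
  if (nrow(ec_map) == 0) {
    return(tibble::tibble(ec = character(0), class = character(0),
                          n_reactions = integer(0)))
  }
  strength <- c(blocked = 0, uncoupled = 1, directional = 2, partial = 3, full = 4)
  cls <- stats::setNames(report$reactions$class, report$reactions$reaction)
  ec_map |>
    dplyr::mutate(class = unname(cls[.data$reaction])) |>
    dplyr::group_by(.data$ec) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      class = {
        nb <- .data$class[.data$class != "blocked"]
        if (length(nb) == 0) "blocked" else nb[which.max(strength[nb])]
      },
      .groups = "drop") |>
    dplyr::select("ec", "class", "n_reactions") |>
    dplyr::arrange(.data$ec)
}
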