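# Flux variability analysis: per-reaction flux extremes subject to the FBA
# constraints plus the objective held within a relaxation (5% by default) of
# its optimum. For the linear biomass objective each subproblem is an LP; for
# the fractional objectives the relaxed objective is a smooth inequality
# handled by SLSQP.

#' Flux variability analysis with a relaxed objective
#'
#' Solves the FBA problem first, then per target reaction minimizes and
#' maximizes its flux subject to all FBA constraints plus
#' `Z >= (1 - relaxation) * Z_opt` (for maximized objectives; the symmetric
#' `<= (1 + relaxation)` bound is used when minimizing).
#'
#' @inheritParams solve_fba
#' @param targets reaction ids to range; default all reactions.
#' @param relaxation fractional objective relaxation (default 0.05).
#' @param incumbent optional pre-solved `flux_state` for this
#'   model/condition/objective, to avoid re-solving.
#' @return tibble with `reaction`, `vmin`, `vmax`, `flux` (the incumbent FBA
#'   flux), `relaxation`.
#' @export
fva <- function(model, condition = culture_condition(),
                objective = objective_spec("lp_biomass"),
                targets = NULL, relaxation = 0.05, incumbent = NULL,
                seed = 1) {
  targets <- targets %||% model$reactions$id
  missing <- setdiff(targets, model$reactions$id)
  if (length(missing) > 0) stop("unknown target ids: ", paste(missing, collapse = ", "))
  targets <- targets[order(match(targets, model$reactions$id))]
  flux <- incumbent %||% solve_fba(model, condition, objective, seed = seed)
  if (!flux$status %in% c("optimal", "local_optimum")) {
    stop("FBA did not solve (status ", flux$status, "); cannot run FVA")
  }
  S <- stoich_matrix(model)
  bnd <- condition_bounds(model, condition)
  n <- ncol(S)
  idx <- match(targets, colnames(S))
  if (objective$kind == "lp_biomass") {
    zrel <- (1 - relaxation) * flux$objective_value
    crow <- matrix(0, 1, n); crow[1, match(model$biomass_reaction_id, colnames(S))] <- -1
    ranges <- purrr::map_dfr(seq_along(targets), function(k) {
      obj <- rep(0, n); obj[idx[k]] <- 1
      lo <- lp_solve(obj, S, rep(0, nrow(S)), crow, -zrel, bnd$lb, bnd$ub, maximize = FALSE)
      hi <- lp_solve(obj, S, rep(0, nrow(S)), crow, -zrel, bnd$lb, bnd$ub, maximize = TRUE)
      tibble::tibble(reaction = targets[k],
                     vmin = if (lo$status == "optimal") lo$objective else NA_real_,
                     vmax = if (hi$status == "optimal") hi$objective else NA_real_)
    })
  } else {
    fo <- fractional_objective(model, objective)
    zrel <- (1 - relaxation) * flux$objective_value
    # Z(v) >= zrel  <=>  zrel * D(v) - mu <= 0: a convex feasible set, so the
    # linear FVA subproblems have no spurious local optima
    g_ineq <- function(v) zrel * fo$denom(v) - v[fo$ib]
    g_ineq_jac <- function(v) {
      g <- zrel * fo$grad_denom(v); g[fo$ib] <- g[fo$ib] - 1
      matrix(g, 1, n)
    }
    x0 <- unname(flux$fluxes)
    ranges <- purrr::map_dfr(seq_along(targets), function(k) {
      one <- function(maximize) {
        sgn <- if (maximize) -1 else 1
        fit <- tryCatch(
          nloptr::nloptr(
            x0 = x0,
            eval_f = function(v) sgn * v[idx[k]],
            eval_grad_f = function(v) { g <- rep(0, n); g[idx[k]] <- sgn; g },
            lb = bnd$lb, ub = bnd$ub,
            eval_g_ineq = g_ineq, eval_jac_g_ineq = g_ineq_jac,
            eval_g_eq = function(v) as.numeric(S %*% v),
            eval_jac_g_eq = function(v) S,
            opts = list(algorithm = "NLOPT_LD_SLSQP", xtol_rel = 1e-10,
                        maxeval = 2000)),
          error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        v <- pmin(pmax(fit$solution, bnd$lb), bnd$ub)
        if (max(abs(S %*% v)) > 1e-5 || g_ineq(v) > 1e-6) return(NA_real_)
        v[idx[k]]
      }
      tibble::tibble(reaction = targets[k], vmin = one(FALSE), vmax = one(TRUE))
    })
    # the incumbent itself is feasible: ranges can never exclude it
    ranges$vmin <- pmin(ranges$vmin, unname(flux$fluxes[targets]), na.rm = TRUE)
    ranges$vmax <- pmax(ranges$vmax, unname(flux$fluxes[targets]), na.rm = TRUE)
  }
  ranges$flux <- unname(flux$fluxes[targets])
  ranges$relaxation <- relaxation
  ranges
}

#' Product yield ranges from FVA
#'
#' Yields are product flux ranges divided by the substrate uptake magnitude
#' at the FBA optimum.
#'
#' @inheritParams fva
#' @param products product reaction ids (exchanges or the biomass reaction).
#' @param substrate substrate exchange id.
#' @return tibble with `product`, `y_point`, `y_min`, `y_max`, `uptake`.
#' @export
yield_ranges <- function(model, condition = culture_condition(),
                         objective = objective_spec("lp_biomass"),
                         products, substrate, relaxation = 0.05, seed = 1) {
  flux <- solve_fba(model, condition, objective, seed = seed)
  if (!flux$status %in% c("optimal", "local_optimum")) {
    stop("FBA did not solve (status ", flux$status, ")")
  }
  rng <- fva(model, condition, objective, targets = products,
             relaxation = relaxation, incumbent = flux, seed = seed)
  up <- abs(flux$fluxes[[substrate]])
  tibble::tibble(product = rng$reaction,
                 y_point = if (up > 0) rng$flux / up else NaN,
                 y_min = if (up > 0) rng$vmin / up else NaN,
                 y_max = if (up > 0) rng$vmax / up else NaN,
                 uptake = up)
}
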