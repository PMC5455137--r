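# Steady-state flux prediction. Three objective functions are supported:
#  * lp_biomass     - maximize growth rate mu (linear program),
#  * yield_per_flux - maximize mu / sum(v^2), the biomass-yield-per-enzyme-
#                     usage hypothesis for substrate-limited growth,
#  * weighted       - maximize mu / (w*sum(v^2) + (1-w)*v_ATP^2), which also
#                     penalizes ATP production and captures sub-optimal growth
#                     under substrate excess (w in (0,1); 0.04 for glycerol
#                     excess).

#' Objective specification for flux balance analysis
#'
#' @param kind `"lp_biomass"`, `"yield_per_flux"` or `"weighted"`.
#' @param w weight in (0, 1), only for `"weighted"`: the enzyme-usage term is
#'   weighted `w`, the squared ATP production `1 - w`. The glycerol-excess
#'   calibration in the source analysis is `w = 0.04`.
#' @param enzyme_usage_set reaction ids entering the squared-flux sum;
#'   default `NULL` means every reaction (exchanges included).
#' @return an `objective_spec`.
#' @export
objective_spec <- function(kind = c("lp_biomass", "yield_per_flux", "weighted"),
                           w = NULL, enzyme_usage_set = NULL) {
  kind <- match.arg(kind)
  if (kind == "weighted") {
    if (is.null(w) || !is.numeric(w) || w <= 0 || w >= 1) {
      stop("'w' must lie strictly inside (0, 1) for the weighted objective")
    }
  } else if (!is.null(w)) {
    stop("'w' only applies to the weighted objective")
  }
  structure(list(kind = kind, w = w, enzyme_usage_set = enzyme_usage_set),
            class = "objective_spec")
}

#' Allosteric parameters for the acetate secretion bound
#'
#' @param v0 initial (zero-uptake) acetate secretion bound, mmol gDW^-1 h^-1.
#' @param vmax saturation bound, mmol gDW^-1 h^-1.
#' @param rate logistic accumulation rate, g h mmol^-1. The published value
#'   inside the bound equation is 0.0859 while the surrounding text prints
#'   0.0879; the equation's value is the default and either can be supplied.
#' @return an `acetate_params` list.
#' @export
acetate_params <- function(v0 = 0.158, vmax = 11.5, rate = 0.0859) {
  stopifnot(v0 > 0, vmax > v0, rate > 0)
  structure(list(v0 = v0, vmax = vmax, rate = rate), class = "acetate_params")
}

#' Logistic upper bound on acetate secretion
#'
#' Acetate secretion by glycerol-fermenting *Clostridium* saturates
#' allosterically with the glycerol uptake flux; the bound follows a logistic
#' curve from `v0` at zero uptake toward `vmax`:
#' \deqn{v_{ac} \le \frac{v_{max} v_0 e^{r u}}{v_{max} + v_0 (e^{r u} - 1)}}
#' with `u` the glycerol uptake magnitude. Monotone non-decreasing in `u`,
#' range `[v0, vmax)`.
#'
#' @param v_glycerol_uptake uptake magnitude(s), mmol gDW^-1 h^-1 (>= 0).
#' @param params an [acetate_params()].
#' @return upper bound(s) on acetate secretion flux.
#' @examples
#' acetate_upper_bound(0)     # 0.158
#' acetate_upper_bound(200)   # ~11.5
#' @export
acetate_upper_bound <- function(v_glycerol_uptake, params = acetate_params()) {
  if (any(v_glycerol_uptake < 0)) stop("uptake magnitude must be >= 0")
  # numerically stable equivalent of vmax*v0*e^(ru) / (vmax + v0*(e^(ru)-1)):
  # dividing through by e^(ru) avoids overflow and keeps the curve monotone
  # in floating point
  em <- exp(-params$rate * v_glycerol_uptake)
  unname(params$vmax / (1 + (params$vmax / params$v0 - 1) * em))
}

#' Culture condition: substrate uptakes and secretion constraints
#'
#' @param uptake named numeric vector of uptake magnitudes (>= 0) keyed by
#'   exchange reaction id, e.g. `c(EX_glyc = 14)`. The exchange lower bound is
#'   set to `-magnitude` (negative flux = uptake).
#' @param acetate_constraint logical; apply the allosteric
#'   [acetate_upper_bound()] to the acetate exchange. Only meaningful for
#'   glycerol cultures; keep off for other carbon sources.
#' @param fix_uptake logical; when `TRUE` the named uptakes are fixed fluxes
#'   (`lb = ub = -magnitude`) rather than bounds. Robustness analyses "as a
#'   function of the uptake flux" use fixed uptakes.
#' @param blocked_products exchange reaction ids forced to zero flux.
#' @param acetate_exchange,glycerol_exchange reaction ids used by the acetate
#'   constraint; guessed from ids containing "ac"/"glyc" when `NULL`.
#' @param params an [acetate_params()].
#' @return a `culture_condition`.
#' @export
culture_condition <- function(uptake = c(EX_glyc = 10),
                              acetate_constraint = FALSE,
                              fix_uptake = FALSE,
                              blocked_products = character(0),
                              acetate_exchange = NULL,
                              glycerol_exchange = NULL,
                              params = acetate_params()) {
  if (length(uptake) > 0 && (is.null(names(uptake)) || any(!nzchar(names(uptake))))) {
    stop("'uptake' must be named by exchange reaction id")
  }
  if (any(uptake < 0)) stop("uptake magnitudes must be >= 0")
  structure(list(uptake = uptake, acetate_constraint = acetate_constraint,
                 fix_uptake = fix_uptake,
                 blocked_products = blocked_products,
                 acetate_exchange = acetate_exchange,
                 glycerol_exchange = glycerol_exchange, params = params),
            class = "culture_condition")
}

find_exchange <- function(model, pattern, exclude = NULL) {
  ids <- model$reactions$id[model$reactions$is_exchange]
  hit <- grep(pattern, ids, ignore.case = TRUE, value = TRUE)
  if (!is.null(exclude)) hit <- hit[!grepl(exclude, hit, ignore.case = TRUE)]
  if (length(hit) == 0) return(NULL)
  hit[[1]]
}

glycerol_uptake_magnitude <- function(model, condition) {
  gid <- condition$glycerol_exchange %||%
    find_exchange(model, "glyc", exclude = "glc")
  if (is.null(gid) || !gid %in% names(condition$uptake)) return(0)
  unname(condition$uptake[[gid]])
}

# reaction bounds after applying a culture condition
condition_bounds <- function(model, condition) {
  rxn <- model$reactions
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  names(lb) <- names(ub) <- rxn$id
  # named substrates get their uptake bound; all other exchanges keep the
  # model's declared bounds
  for (ex in names(condition$uptake)) {
    if (!ex %in% rxn$id) stop("uptake exchange '", ex, "' not in model")
    lb[ex] <- -condition$uptake[[ex]]
    if (isTRUE(condition$fix_uptake)) ub[ex] <- -condition$uptake[[ex]]
  }
  # substrates not mentioned stay at their declared bounds
  for (ex in condition$blocked_products) {
    if (!ex %in% rxn$id) stop("blocked product '", ex, "' not in model")
    lb[ex] <- max(lb[ex], 0); ub[ex] <- 0; lb[ex] <- min(lb[ex], 0)
  }
  if (!is.null(model$ngam_reaction_id)) {
    lb[model$ngam_reaction_id] <- model$ngam
    ub[model$ngam_reaction_id] <- model$ngam
  }
  if (isTRUE(condition$acetate_constraint)) {
    aid <- condition$acetate_exchange %||% find_exchange(model, "^EX_ac$|acetate")
    if (is.null(aid)) stop("acetate exchange not found; set 'acetate_exchange'")
    cap <- acetate_upper_bound(glycerol_uptake_magnitude(model, condition),
                               condition$params)
    ub[aid] <- min(ub[aid], cap)
    lb[aid] <- min(lb[aid], ub[aid])
  }
  list(lb = unname(lb[rxn$id]), ub = unname(ub[rxn$id]))
}

new_flux_state <- function(fluxes, objective_value, status, objective = NULL) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, objective = objective),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status,
      "  objective: ", format(x$objective_value, digits = 6),
      "  (", length(x$fluxes), " reactions)\n", sep = "")
  invisible(x)
}

#' Solve flux balance analysis
#'
#' Predicts a steady-state flux distribution maximizing the chosen objective
#' subject to mass balance (`S v = 0`) and flux bounds. Linear biomass
#' maximization is solved exactly by the simplex; the two fractional
#' objectives are solved as non-linear programs with multi-start SLSQP (the
#' LP-biomass optimum plus random feasible vertices), returning the best
#' local optimum found.
#'
#' @param model a [metabolic_model()].
#' @param condition a [culture_condition()].
#' @param objective an [objective_spec()].
#' @param n_starts number of NLP starts (first is the LP-biomass solution).
#' @param seed seed for the random starts.
#' @param tol_balance steady-state residual tolerance.
#' @return a `flux_state`: named `fluxes`, `objective_value` (growth rate for
#'   `lp_biomass`, the ratio objective otherwise), `status` one of `optimal`,
#'   `local_optimum`, `infeasible`, `unbounded`.
#' @examples
#' m <- toy_glycerol_model()
#' f <- solve_fba(m, culture_condition(c(EX_glyc = 10)))
#' growth_rate(f, m)
#' @export
solve_fba <- function(model, condition = culture_condition(),
                      objective = objective_spec("lp_biomass"),
                      n_starts = 5, seed = 1, tol_balance = 1e-6) {
  switch(objective$kind,
         lp_biomass = solve_fba_lp_(model, condition, tol_balance),
         solve_fba_nlp_(model, condition, objective, n_starts, seed, tol_balance))
}

solve_fba_lp_ <- function(model, condition, tol_balance = 1e-6) {
  S <- stoich_matrix(model)
  bnd <- condition_bounds(model, condition)
  obj <- as.numeric(model$reactions$id == model$biomass_reaction_id)
  res <- lp_solve(obj, S, rep(0, nrow(S)), NULL, NULL, bnd$lb, bnd$ub,
                  maximize = TRUE)
  if (res$status != "optimal") {
    return(new_flux_state(stats::setNames(rep(NA_real_, ncol(S)), colnames(S)),
                          NA_real_, res$status,
                          objective_spec("lp_biomass")))
  }
  v <- stats::setNames(res$x, colnames(S))
  stopifnot(max(abs(S %*% v)) <= tol_balance * max(1, max(abs(v))))
  new_flux_state(v, res$objective, "optimal", objective_spec("lp_biomass"))
}

#' Growth rate of a flux state
#'
#' @param flux a `flux_state`.
#' @param model the model it was solved on.
#' @return the biomass reaction flux (h^-1).
#' @export
growth_rate <- function(flux, model) {
  unname(flux$fluxes[[model$biomass_reaction_id]])
}

#' Summed ATP-producing flux
#'
#' Sum of fluxes through the model's designated ATP-producing reactions,
#' counting only the ATP-forming direction of each.
#'
#' @inheritParams growth_rate
#' @return flux sum, mmol gDW^-1 h^-1.
#' @export
atp_production <- function(flux, model) {
  ids <- model$atp_producing_ids
  if (length(ids) == 0) return(0)
  sum(pmax(flux$fluxes[ids], 0))
}

#' Product yields of a flux state
#'
#' Secretion (or growth) flux divided by the uptake magnitude of the
#' substrate at the optimum.
#'
#' @inheritParams growth_rate
#' @param products character vector of reaction ids (typically exchanges, or
#'   the biomass reaction).
#' @param substrate exchange reaction id of the substrate.
#' @return tibble with `product`, `flux`, `uptake`, `yield` (`NaN` when the
#'   uptake is zero).
#' @export
flux_yields <- function(flux, model, products, substrate) {
  up <- abs(flux$fluxes[[substrate]])
  v <- unname(flux$fluxes[products])
  tibble::tibble(product = products, flux = v, uptake = up,
                 yield = if (up > 0) v / up else rep(NaN, length(v)))
}

#' Hydrogen to reduced-ferredoxin formation ratio
#'
#' Diagnostic of ferredoxin-reductase directionality: the ratio of hydrogen
#' formation flux to reduced-ferredoxin formation flux. Under substrate
#' limitation the reductase consumes NADH and the ratio is high; under excess
#' it runs toward NADH and the ratio drops.
#'
#' @inheritParams growth_rate
#' @param h2_metabolite,fdred_metabolite metabolite ids; guessed from ids
#'   matching `"h2"` / `"fdred"` when `NULL`.
#' @return the ratio (`NaN` when no reduced ferredoxin is formed).
#' @export
hydrogen_ferredoxin_ratio <- function(flux, model, h2_metabolite = NULL,
                                      fdred_metabolite = NULL) {
  met_ids <- model$metabolites$id
  h2 <- h2_metabolite %||% grep("^h2([_-]|$)", met_ids, value = TRUE)[1]
  fd <- fdred_metabolite %||% grep("fdred|fd_red", met_ids, value = TRUE)[1]
  if (is.na(h2) || is.na(fd)) stop("could not identify H2/ferredoxin metabolites")
  formation <- function(mid) {
    sto <- model$stoichiometry[model$stoichiometry$metabolite_id == mid, ]
    sto <- sto[!model$reactions$is_exchange[match(sto$reaction_id, model$reactions$id)], ]
    sum(pmax(sto$coefficient * flux$fluxes[sto$reaction_id], 0))
  }
  fd_form <- formation(fd)
  if (fd_form <= 1e-12) return(NaN)
  formation(h2) / fd_form
}

#' Robustness scan over substrate uptake
#'
#' One FBA solve per uptake grid point; the allosteric acetate bound is
#' re-evaluated at each point when enabled.
#'
#' @inheritParams solve_fba
#' @param uptake_grid numeric vector of uptake magnitudes.
#' @param exchange exchange reaction id scanned; defaults to the first (or
#'   only) substrate in `condition$uptake`.
#' @param track extra reaction ids to record (defaults to the PDO exchange
#'   when present).
#' @return tibble with `uptake`, `status`, `mu`, one column per tracked
#'   reaction; failed points carry `NA`.
#' @export
robustness_scan <- function(model, condition = culture_condition(),
                            objective = objective_spec("lp_biomass"),
                            uptake_grid = seq(0, 20, by = 2),
                            exchange = NULL, track = NULL, seed = 1) {
  exchange <- exchange %||% names(condition$uptake)[1]
  track <- track %||% stats::na.omit(find_exchange(model, "pdo"))
  out <- purrr::map_dfr(uptake_grid, function(u) {
    cond <- condition
    cond$uptake[[exchange]] <- u
    f <- solve_fba(model, cond, objective, seed = seed)
    row <- tibble::tibble(uptake = u, status = f$status,
                          mu = if (f$status %in% c("optimal", "local_optimum"))
                            growth_rate(f, model) else NA_real_)
    for (tr in track) {
      row[[tr]] <- if (f$status %in% c("optimal", "local_optimum"))
        unname(f$fluxes[[tr]]) else NA_real_
    }
    row
  })
  class(out) <- c("robustness_scan", class(out))
  out
}

#' Calibrate the weighted-objective weight against experimental yields
#'
#' Grid search for the weight `w` minimizing the mean relative error between
#' predicted and experimental yields.
#'
#' @inheritParams solve_fba
#' @param experimental_yields tibble with columns `product` (reaction id),
#'   `yield` (experimental, per unit substrate uptake) and `substrate`
#'   (exchange id; may also be given once via the `substrate` argument).
#' @param w_grid weights to evaluate, all in (0, 1).
#' @param substrate default substrate exchange id.
#' @return list with `w_star`, and `errors` (tibble of `w`, mean relative
#'   error).
#' @export
calibrate_weight <- function(model, condition, experimental_yields,
                             w_grid = seq(0.02, 0.98, by = 0.08),
                             substrate = NULL, seed = 1) {
  if (length(w_grid) == 0) stop("empty weight grid")
  if (nrow(experimental_yields) == 0) stop("empty experimental yield table")
  if (!"substrate" %in% names(experimental_yields)) {
    if (is.null(substrate)) stop("supply 'substrate' column or argument")
    experimental_yields$substrate <- substrate
  }
  errors <- purrr::map_dfr(w_grid, function(w) {
    f <- solve_fba(model, condition, objective_spec("weighted", w = w),
                   seed = seed)
    if (!f$status %in% c("optimal", "local_optimum")) {
      return(tibble::tibble(w = w, mean_rel_error = NA_real_))
    }
    rel <- purrr::map2_dbl(experimental_yields$product,
                           seq_len(nrow(experimental_yields)), function(p, i) {
      y <- flux_yields(f, model, p, experimental_yields$substrate[i])$yield
      abs(y - experimental_yields$yield[i]) /
        max(abs(experimental_yields$yield[i]), 1e-12)
    })
    tibble::tibble(w = w, mean_rel_error = mean(rel))
  })
  ok <- which(!is.na(errors$mean_rel_error))
  if (length(ok) == 0) stop("no feasible weight in grid")
  list(w_star = errors$w[ok[which.min(errors$mean_rel_error[ok])]],
       errors = errors)
}

#' Detect internal cycles carrying flux
#'
#' Searches the active (non-exchange, `|v| > tol_zero`) subnetwork for
#' thermodynamically infeasible loops: sets of internal reactions that can
#' sustain non-zero flux with every exchange closed, oriented as in the given
#' flux state. An empty result certifies the distribution loopless.
#'
#' @inheritParams growth_rate
#' @param tol_zero activity threshold.
#' @return list of character vectors, one per detected cycle (reaction ids).
#' @export
loopless_check <- function(flux, model, tol_zero = 1e-6) {
  rxn <- model$reactions
  active <- rxn$id[!rxn$is_exchange & abs(flux$fluxes[rxn$id]) > tol_zero]
  if (length(active) == 0) return(list())
  S <- stoich_matrix(model)
  # orient each active reaction along its flux; can the oriented subnetwork
  # carry flux with all exchanges closed?
  sgn <- sign(flux$fluxes[active])
  n <- length(active)
  lb <- rep(0, n); ub <- rep(1, n)
  Ssub <- S[, active, drop = FALSE] %*% diag(sgn, n, n)
  res <- lp_solve(rep(1, n), Ssub, rep(0, nrow(S)), NULL, NULL, lb, ub,
                  maximize = TRUE)
  if (res$status != "optimal" || res$objective <= tol_zero) return(list())
  support <- active[res$x > tol_zero]
  # split the loop support into directed cycles over metabolites
  g_edges <- list()
  for (rid in support) {
    s <- model$stoichiometry[model$stoichiometry$reaction_id == rid, ]
    co <- s$coefficient * sign(flux$fluxes[[rid]])
    from <- s$metabolite_id[co < 0]; to <- s$metabolite_id[co > 0]
    for (a in from) for (b in to) {
      g_edges[[length(g_edges) + 1L]] <- c(a, b, rid)
    }
  }
  em <- do.call(rbind, g_edges)
  g <- igraph::graph_from_edgelist(em[, 1:2, drop = FALSE], directed = TRUE)
  igraph::E(g)$reaction <- em[, 3]
  comp <- igraph::components(g, mode = "strong")
  cycles <- list()
  for (k in seq_len(comp$no)) {
    mem <- names(comp$membership)[comp$membership == k]
    if (length(mem) < 2) next
    sub <- igraph::subgraph_from_edges(
      g, igraph::E(g)[igraph::tail_of(g, igraph::E(g))$name %in% mem &
                        igraph::head_of(g, igraph::E(g))$name %in% mem],
      delete.vertices = TRUE)
    rids <- sort(unique(igraph::E(sub)$reaction))
    rids <- intersect(rids, support)
    if (length(rids) >= 2) cycles[[length(cycles) + 1L]] <- rids
  }
  if (length(cycles) == 0 && length(support) >= 2) cycles <- list(sort(support))
  cycles
}
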