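# Mutant phenotype prediction by regulatory on/off minimization (ROOM): a
# mixed-binary program minimizing the number of reactions whose mutant flux
# leaves a tolerance band around the wild-type flux, subject to steady state
# and the knockout bounds.

#' ROOM tolerance parameters
#'
#' @param delta relative band half-width (default 0.05).
#' @param epsilon absolute band half-width, mmol gDW^-1 h^-1 (default 0.001).
#' @return a `room_params` list.
#' @export
room_params <- function(delta = 0.05, epsilon = 0.001) {
  stopifnot(delta >= 0, epsilon >= 0)
  structure(list(delta = delta, epsilon = epsilon), class = "room_params")
}

#' Apply enzyme deletions to a model
#'
#' Reactions catalyzed exclusively by the deleted enzymes get bounds
#' `[0, 0]`; reactions with a surviving isozyme (any EC not in the deleted
#' set) keep their bounds. ECs absent from the model produce a warning and
#' are ignored.
#'
#' @param model a [metabolic_model()].
#' @param ecs character vector of EC numbers to delete.
#' @return the model with knockout bounds applied.
#' @export
delete_enzymes <- function(model, ecs) {
  all_ecs <- unique(unlist(model$reactions$ec))
  missing <- setdiff(ecs, all_ecs)
  if (length(missing) > 0) {
    warning("ECs not in model (ignored): ", paste(missing, collapse = ", "))
  }
  ecs <- intersect(ecs, all_ecs)
  hit <- vapply(model$reactions$ec, function(e)
    length(e) > 0 && all(e %in% ecs), logical(1))
  model$reactions$lower_bound[hit] <- 0
  model$reactions$upper_bound[hit] <- 0
  model
}

#' Predict a knockout phenotype by ROOM
#'
#' Solves the mixed-binary program minimizing the count of reactions outside
#' the wild-type confidence band `[v_wild - delta*|v_wild| - epsilon,
#' v_wild + delta*|v_wild| + epsilon]`, subject to steady state and the
#' deletion bounds.
#'
#' @inheritParams solve_fba
#' @param deletions EC numbers to delete (empty vector = wild type).
#' @param params a [room_params()].
#' @param wild_reference optional pre-solved wild-type `flux_state`; when
#'   `NULL` the wild type is solved under `wild_objective`.
#' @param wild_objective objective for the wild-type reference; the fractional
#'   biomass-per-enzyme-usage objective by default, which is the validated
#'   choice for substrate-limited cultures.
#' @param fva_targets optional reaction ids; when given, mutant flux ranges
#'   are computed by MILP-FVA with the ROOM optimum relaxed by
#'   `fva_relaxation` (interpreting the 5% objective relaxation on the
#'   integral on/off count).
#' @param fva_relaxation relaxation of the ROOM optimum for mutant ranges.
#' @return a `room_result`: list with `flux` (mutant `flux_state`),
#'   `n_changed`, `viable`, `deletions`, `wild` and optionally `ranges`.
#' @export
room <- function(model, condition = culture_condition(), deletions = character(0),
                 params = room_params(), wild_reference = NULL,
                 wild_objective = objective_spec("yield_per_flux"),
                 fva_targets = NULL, fva_relaxation = 0.05,
                 tol_zero = 1e-6, seed = 1) {
  wild <- wild_reference %||% solve_fba(model, condition, wild_objective, seed = seed)
  if (!wild$status %in% c("optimal", "local_optimum")) {
    stop("wild-type FBA did not solve (status ", wild$status, ")")
  }
  mut <- delete_enzymes(model, deletions)
  S <- stoich_matrix(mut)
  bnd <- condition_bounds(mut, condition)
  n <- ncol(S)
  vw <- unname(wild$fluxes[colnames(S)])
  vu <- vw + params$delta * abs(vw) + params$epsilon
  vl <- vw - params$delta * abs(vw) - params$epsilon
  prob <- room_program(S, bnd$lb, bnd$ub, vu, vl)
  res <- milp_solve(prob$obj, prob$Aeq, prob$beq, prob$Aub, prob$bub,
                    prob$lower, prob$upper, binary = prob$binary,
                    integral_objective = TRUE)
  if (res$status != "optimal") {
    flux <- new_flux_state(stats::setNames(rep(NA_real_, n), colnames(S)),
                           NA_real_, "infeasible")
    return(structure(list(flux = flux, n_changed = NA_integer_, viable = FALSE,
                          deletions = deletions, wild = wild, params = params),
                     class = "room_result"))
  }
  v <- stats::setNames(res$x[seq_len(n)], colnames(S))
  n_changed <- as.integer(round(res$objective))
  flux <- new_flux_state(v, n_changed, "optimal")
  out <- structure(list(flux = flux, n_changed = n_changed,
                        viable = unname(v[model$biomass_reaction_id]) > tol_zero,
                        deletions = deletions, wild = wild, params = params),
                   class = "room_result")
  if (!is.null(fva_targets)) {
    cap <- floor((1 + fva_relaxation) * n_changed + 1e-9)
    brow <- c(rep(0, n), rep(1, n))
    out$ranges <- purrr::map_dfr(fva_targets, function(rid) {
      j <- rxn_index(mut, rid)
      obj <- rep(0, 2 * n); obj[j] <- 1
      lo <- milp_solve(obj, prob$Aeq, prob$beq, rbind(prob$Aub, brow),
                       c(prob$bub, cap), prob$lower, prob$upper,
                       binary = prob$binary)
      hi <- milp_solve(-obj, prob$Aeq, prob$beq, rbind(prob$Aub, brow),
                       c(prob$bub, cap), prob$lower, prob$upper,
                       binary = prob$binary)
      tibble::tibble(reaction = rid,
                     vmin = if (lo$status == "optimal") lo$objective else NA_real_,
                     vmax = if (hi$status == "optimal") -hi$objective else NA_real_)
    })
  }
  out
}

#' @export
print.room_result <- function(x, ...) {
  cat("<room_result> deletions:",
      if (length(x$deletions) == 0) "(none)" else paste(x$deletions, collapse = ", "),
      "\n  n_changed:", x$n_changed, " viable:", x$viable, "\n")
  invisible(x)
}

# assemble the ROOM mixed-binary program: variables (v, b)
room_program <- function(S, lb, ub, vu, vl) {
  n <- ncol(S)
  Aeq <- cbind(S, matrix(0, nrow(S), n))
  rows <- matrix(0, 2 * n, 2 * n)
  bub <- numeric(2 * n)
  for (j in seq_len(n)) {
    rows[j, j] <- 1; rows[j, n + j] <- -(ub[j] - vu[j]); bub[j] <- vu[j]
    rows[n + j, j] <- -1; rows[n + j, n + j] <- (lb[j] - vl[j]); bub[n + j] <- -vl[j]
  }
  list(obj = c(rep(0, n), rep(1, n)), Aeq = Aeq, beq = rep(0, nrow(S)),
       Aub = rows, bub = bub,
       lower = c(lb, rep(0, n)), upper = c(ub, rep(1, n)),
       binary = n + seq_len(n))
}

screen_row <- function(res, model, condition, ecs, pdo_id, substrate) {
  mu <- if (!anyNA(res$flux$fluxes))
    unname(res$flux$fluxes[model$biomass_reaction_id]) else NA_real_
  y_pdo <- NA_real_
  if (!is.null(pdo_id) && !anyNA(res$flux$fluxes)) {
    y_pdo <- flux_yields(res$flux, model, pdo_id, substrate)$yield
  }
  tibble::tibble(deletions = paste(ecs, collapse = "+"),
                 viable = res$viable,
                 n_changed = res$n_changed,
                 mu = mu, y_pdo = y_pdo)
}

#' Single enzyme-deletion screen
#'
#' One ROOM solve per candidate enzyme. Candidates default to the enzymes
#' directionally coupled to growth (deleting fully/partially coupled enzymes
#' would slow the culture, so they are not candidates for yield
#' improvement).
#'
#' @inheritParams room
#' @param candidate_ecs enzymes to screen; when `NULL`, derived from
#'   [flux_coupling()].
#' @param coupling optional pre-computed `coupling_report`.
#' @return tibble with `deletions`, `viable`, `n_changed`, `mu`, `y_pdo`
#'   (PDO yield per substrate, `NA` when the model has no PDO exchange).
#' @export
single_deletion_screen <- function(model, condition = culture_condition(),
                                   candidate_ecs = NULL, coupling = NULL,
                                   params = room_params(),
                                   wild_objective = objective_spec("yield_per_flux"),
                                   seed = 1) {
  if (is.null(candidate_ecs)) {
    coupling <- coupling %||% flux_coupling(model)
    candidate_ecs <- coupling$enzymes$ec[coupling$enzymes$class == "directional"]
  }
  wild <- solve_fba(model, condition, wild_objective, seed = seed)
  pdo_id <- find_exchange(model, "pdo")
  substrate <- names(condition$uptake)[1]
  purrr::map_dfr(candidate_ecs, function(ec) {
    res <- tryCatch(
      room(model, condition, deletions = ec, params = params,
           wild_reference = wild, seed = seed),
      error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(deletions = ec, viable = NA, n_changed = NA_integer_,
                            mu = NA_real_, y_pdo = NA_real_))
    }
    screen_row(res, model, condition, ec, pdo_id, substrate)
  })
}

#' Double enzyme-deletion screen
#'
#' Pairwise ROOM solves over candidate enzymes, excluding enzymes already
#' essential in the single-deletion screen. Reports the PDO yield change
#' against the wild type.
#'
#' @inheritParams single_deletion_screen
#' @param single optional result of [single_deletion_screen()] used to
#'   exclude essential enzymes.
#' @param max_pairs cap on the number of evaluated pairs (pairs are taken in
#'   lexicographic order); `Inf` screens all.
#' @return tibble as in [single_deletion_screen()] plus `y_pdo_change`
#'   (relative to wild type).
#' @export
double_deletion_screen <- function(model, condition = culture_condition(),
                                   candidate_ecs = NULL, coupling = NULL,
                                   single = NULL, params = room_params(),
                                   wild_objective = objective_spec("yield_per_flux"),
                                   max_pairs = Inf, seed = 1) {
  if (is.null(candidate_ecs)) {
    coupling <- coupling %||% flux_coupling(model)
    candidate_ecs <- coupling$enzymes$ec[coupling$enzymes$class == "directional"]
  }
  single <- single %||% single_deletion_screen(
    model, condition, candidate_ecs, params = params,
    wild_objective = wild_objective, seed = seed)
  essential <- single$deletions[!is.na(single$viable) & !single$viable]
  keep <- setdiff(candidate_ecs, essential)
  if (length(keep) < 2) {
    return(tibble::tibble(deletions = character(0), viable = logical(0),
                          n_changed = integer(0), mu = numeric(0),
                          y_pdo = numeric(0), y_pdo_change = numeric(0)))
  }
  pairs <- utils::combn(sort(keep), 2, simplify = FALSE)
  if (length(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs)]
  wild <- solve_fba(model, condition, wild_objective, seed = seed)
  pdo_id <- find_exchange(model, "pdo")
  substrate <- names(condition$uptake)[1]
  y_wild <- if (!is.null(pdo_id))
    flux_yields(wild, model, pdo_id, substrate)$yield else NA_real_
  purrr::map_dfr(pairs, function(p) {
    res <- tryCatch(
      room(model, condition, deletions = p, params = params,
           wild_reference = wild, seed = seed),
      error = function(e) NULL)
    row <- if (is.null(res)) {
      tibble::tibble(deletions = paste(p, collapse = "+"), viable = NA,
                     n_changed = NA_integer_, mu = NA_real_, y_pdo = NA_real_)
    } else {
      screen_row(res, model, condition, p, pdo_id, substrate)
    }
    row$y_pdo_change <- if (!is.na(y_wild) && y_wild > 0)
      (row$y_pdo - y_wild) / y_wild else NA_real_
    row
  })
}
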