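# Scenario screens: biomass-composition perturbation with yield correlations,
# and glucose-glycerol co-fermentation yield surfaces.

# biomass precursors eligible for perturbation: consumed metabolites of the
# biomass reaction minus energy/water currency (GAM ATP and its water)
biomass_precursors <- function(model) {
  bid <- model$biomass_reaction_id
  sto <- model$stoichiometry[model$stoichiometry$reaction_id == bid &
                               model$stoichiometry$coefficient < 0, ]
  currency <- grepl("^(atp|adp|amp|h2o|h|pi|ppi|nad|nadh|nadp|nadph)([_-]|$)",
                    sto$metabolite_id, ignore.case = TRUE)
  sto[!currency, c("metabolite_id", "coefficient")]
}

#' Sample perturbed biomass compositions
#'
#' Draws each perturbed precursor coefficient from a normal distribution with
#' mean at its nominal value and standard deviation `rsd` times the nominal
#' value. Samples containing any non-positive coefficient are excluded (not
#' redrawn), mirroring the rejection bookkeeping of random biomass-composition
#' screens.
#'
#' @param model a [metabolic_model()].
#' @param n number of draws.
#' @param rsd relative standard deviation (default 0.30).
#' @param seed integer seed; a fixed seed gives a bit-identical sample set.
#' @return tibble with `sample`, `metabolite_id`, `multiplier` (perturbed /
#'   nominal); attributes `n_total`, `n_excluded`.
#' @export
sample_biomass_compositions <- function(model, n, rsd = 0.30, seed = 1) {
  if (n <= 0) stop("n must be positive")
  if (rsd < 0) stop("rsd must be >= 0")
  prec <- biomass_precursors(model)
  k <- nrow(prec)
  if (k == 0) stop("biomass reaction has no perturbable precursors")
  with_seed(seed, {
    mult <- matrix(stats::rnorm(n * k, mean = 1, sd = rsd), n, k)
    ok <- rowSums(mult <= 0) == 0
    out <- tibble::tibble(
      sample = rep(seq_len(sum(ok)), each = k),
      metabolite_id = rep(prec$metabolite_id, sum(ok)),
      multiplier = as.numeric(t(mult[ok, , drop = FALSE])))
    attr(out, "n_total") <- n
    attr(out, "n_excluded") <- sum(!ok)
    attr(out, "rsd") <- rsd
    out
  })
}

# rebuild the model with perturbed biomass precursor coefficients,
# renormalized by molar mass so one unit of biomass flux still makes 1 gDW
perturb_biomass <- function(model, multipliers) {
  bid <- model$biomass_reaction_id
  prec <- biomass_precursors(model)
  mult <- stats::setNames(rep(1, nrow(prec)), prec$metabolite_id)
  unknown <- setdiff(names(multipliers), prec$metabolite_id)
  if (length(unknown) > 0) {
    stop("not perturbable biomass precursors: ", paste(unknown, collapse = ", "))
  }
  mult[names(multipliers)] <- multipliers
  sto <- model$stoichiometry
  idx <- which(sto$reaction_id == bid &
                 sto$metabolite_id %in% prec$metabolite_id &
                 sto$coefficient < 0)
  mid <- sto$metabolite_id[idx]
  coef_new <- sto$coefficient[idx] * mult[mid]
  fw <- vapply(model$metabolites$formula[match(mid, model$metabolites$id)],
               formula_weight, numeric(1))
  mass <- sum(abs(coef_new) * fw) / 1000          # g per unit biomass flux
  if (mass <= 0) stop("perturbed biomass has zero mass; cannot renormalize")
  sto$coefficient[idx] <- coef_new / mass
  model$stoichiometry <- sto
  model
}

#' Biomass-composition perturbation screen
#'
#' One FBA solve per composition sample (perturbed precursor coefficients,
#' renormalized to 1 gDW per unit biomass flux), followed by Pearson
#' correlation of every precursor multiplier against the biomass and PDO
#' yields.
#'
#' @inheritParams solve_fba
#' @param samples output of [sample_biomass_compositions()].
#' @param substrate substrate exchange id; defaults to the first uptake in
#'   `condition`.
#' @return a `perturbation_result`: list with `yields` (per sample `mu`,
#'   `y_x`, `y_pdo`), `correlations` (per precursor `r_yx`, `r_ypdo`; `NA`
#'   when a yield is constant), `yield_rsd`, `n_failed`.
#' @export
perturbation_screen <- function(model, condition = culture_condition(),
                                objective = objective_spec("yield_per_flux"),
                                samples, substrate = NULL, seed = 1) {
  substrate <- substrate %||% names(condition$uptake)[1]
  pdo_id <- find_exchange(model, "pdo")
  wide <- tidyr::pivot_wider(samples, names_from = "metabolite_id",
                             values_from = "multiplier")
  prec_ids <- setdiff(names(wide), "sample")
  yields <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    mult <- unlist(wide[i, prec_ids])
    f <- tryCatch(
      solve_fba(perturb_biomass(model, mult), condition, objective, seed = seed),
      error = function(e) NULL)
    ok <- !is.null(f) && f$status %in% c("optimal", "local_optimum")
    up <- if (ok) abs(f$fluxes[[substrate]]) else NA_real_
    tibble::tibble(
      sample = wide$sample[i],
      status = if (ok) f$status else "failed",
      mu = if (ok) growth_rate(f, model) else NA_real_,
      y_x = if (ok && up > 0) growth_rate(f, model) / up else NA_real_,
      y_pdo = if (ok && !is.null(pdo_id) && up > 0)
        unname(f$fluxes[[pdo_id]]) / up else NA_real_)
  })
  ok <- yields$status != "failed"
  safe_cor <- function(a, b) {
    if (sum(ok) < 3 || stats::sd(b[ok]) == 0 || stats::sd(a[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  correlations <- purrr::map_dfr(prec_ids, function(p) {
    tibble::tibble(metabolite_id = p,
                   r_yx = safe_cor(wide[[p]], yields$y_x),
                   r_ypdo = safe_cor(wide[[p]], yields$y_pdo))
  })
  rsd_of <- function(y) if (sum(ok) > 1 && mean(y[ok]) != 0)
    stats::sd(y[ok]) / abs(mean(y[ok])) else NA_real_
  structure(list(yields = yields, correlations = correlations,
                 yield_rsd = c(y_x = rsd_of(yields$y_x),
                               y_pdo = rsd_of(yields$y_pdo)),
                 n_failed = sum(!ok)),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> ", nrow(x$yields), " samples (",
      x$n_failed, " failed)\n", sep = "")
  print(x$correlations)
  invisible(x)
}

#' Co-fermentation yield surface
#'
#' Maximum PDO yield on glycerol (FVA maximum of the PDO exchange divided by
#' the glycerol uptake) over a grid of glucose and glycerol uptake fluxes.
#' With `objective = NULL` the PDO maximum is unconstrained by growth
#' optimality (the pure capability surface); otherwise the FVA relaxation
#' applies.
#'
#' @param model a model with both glucose and glycerol exchanges.
#' @param glucose_grid,glycerol_grid uptake magnitudes.
#' @param objective `NULL` or an [objective_spec()].
#' @param glucose_exchange,glycerol_exchange exchange ids, guessed when `NULL`.
#' @param relaxation FVA objective relaxation when `objective` is given.
#' @return tibble with `glucose`, `glycerol`, `y_pdo_max`, `status`.
#' @export
cofermentation_surface <- function(model, glucose_grid, glycerol_grid,
                                   objective = NULL,
                                   glucose_exchange = NULL,
                                   glycerol_exchange = NULL,
                                   relaxation = 0.05, seed = 1) {
  glc <- glucose_exchange %||% find_exchange(model, "glc($|[^y])|glucose")
  gly <- glycerol_exchange %||% find_exchange(model, "glyc", exclude = "glc($|[^y])")
  pdo <- find_exchange(model, "pdo")
  if (is.null(glc) || is.null(gly) || is.null(pdo)) {
    stop("model must expose glucose, glycerol and PDO exchanges")
  }
  grid <- tidyr::expand_grid(glucose = glucose_grid, glycerol = glycerol_grid)
  purrr::pmap_dfr(grid, function(glucose, glycerol) {
    cond <- culture_condition(stats::setNames(c(glucose, glycerol), c(glc, gly)))
    ymax <- tryCatch({
      if (is.null(objective)) {
        S <- stoich_matrix(model)
        bnd <- condition_bounds(model, cond)
        obj <- as.numeric(model$reactions$id == pdo)
        res <- lp_solve(obj, S, rep(0, nrow(S)), NULL, NULL, bnd$lb, bnd$ub,
                        maximize = TRUE)
        if (res$status == "optimal") res$objective else NA_real_
      } else {
        fva(model, cond, objective, targets = pdo, relaxation = relaxation,
            seed = seed)$vmax
      }
    }, error = function(e) NA_real_)
    tibble::tibble(glucose = glucose, glycerol = glycerol,
                   y_pdo_max = if (glycerol > 0 && !is.na(ymax)) ymax / glycerol
                               else if (glycerol == 0) 0 else NA_real_,
                   status = if (is.na(ymax)) "failed" else "ok")
  })
}

#' Minimal glucose/glycerol uptake ratio for complete PDO conversion
#'
#' Bisects the glucose/glycerol uptake-flux ratio for the smallest value at
#' which the maximum PDO yield on glycerol reaches `1 - tol` (complete
#' conversion of glycerol to PDO).
#'
#' @inheritParams cofermentation_surface
#' @param glycerol_uptake fixed glycerol uptake magnitude.
#' @param bracket ratio interval searched.
#' @param tol yield shortfall regarded as complete conversion.
#' @param ratio_tol bisection resolution on the ratio axis.
#' @return list with `ratio` (NA when no ratio in the bracket converts
#'   completely), `achieved` (logical) and `y_at_ratio`.
#' @export
minimal_conversion_ratio <- function(model, objective = NULL,
                                     glycerol_uptake = 10,
                                     bracket = c(0, 2), tol = 1e-3,
                                     ratio_tol = 5e-4, ...) {
  ymax_at <- function(ratio) {
    cofermentation_surface(model, glucose_grid = ratio * glycerol_uptake,
                           glycerol_grid = glycerol_uptake,
                           objective = objective, ...)$y_pdo_max
  }
  lo <- bracket[1]; hi <- bracket[2]
  y_hi <- ymax_at(hi)
  if (is.na(y_hi) || y_hi < 1 - tol) {
    return(list(ratio = NA_real_, achieved = FALSE, y_at_ratio = y_hi))
  }
  y_lo <- ymax_at(lo)
  if (!is.na(y_lo) && y_lo >= 1 - tol) {
    return(list(ratio = lo, achieved = TRUE, y_at_ratio = y_lo))
  }
  while (hi - lo > ratio_tol) {
    mid <- (lo + hi) / 2
    y_mid <- ymax_at(mid)
    if (!is.na(y_mid) && y_mid >= 1 - tol) hi <- mid else lo <- mid
  }
  list(ratio = hi, achieved = TRUE, y_at_ratio = ymax_at(hi))
}
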