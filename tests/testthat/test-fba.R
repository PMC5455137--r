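# FBA under the three objectives, the allosteric acetate bound, diagnostics
# and scans.

test_that("acetate bound follows the logistic closed form", {
  p <- acetate_params()
  expect_equal(acetate_upper_bound(0), 0.158)
  expect_equal(acetate_upper_bound(200), 11.5, tolerance = 1e-3 / 11.5)
  # independent oracle: the logistic ODE solution v(u) = vmax / (1 + (vmax/v0
  # - 1) exp(-r u)) is an algebraically independent form of the same bound
  u <- c(0, 0.5, 1, 5, 10, 20, 50, 100)
  oracle <- p$vmax / (1 + (p$vmax / p$v0 - 1) * exp(-p$rate * u))
  expect_equal(acetate_upper_bound(u, p), oracle, tolerance = 1e-12)
  # frozen value at u = 20 from a 30-digit arbitrary-precision evaluation
  expect_equal(acetate_upper_bound(20, p), 0.82853243143496, tolerance = 1e-12)
  # monotone non-decreasing, range [v0, vmax) (vmax only reached at the
  # resolution of double precision)
  grid <- acetate_upper_bound(seq(0, 500, by = 0.5), p)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= p$v0 & grid <= p$vmax))
  expect_true(all(acetate_upper_bound(seq(0, 100, by = 0.5), p) < p$vmax))
  expect_error(acetate_upper_bound(-1), ">= 0")
  # the prose rate constant variant is accepted as a parameter
  expect_equal(acetate_upper_bound(0, acetate_params(rate = 0.0879)), 0.158)
})

test_that("LP biomass maximization solves simple and degenerate cases", {
  # single pathway with yield gamma: mu = uptake * gamma
  for (gamma in c(0.05, 0.2)) {
    f <- solve_fba(chain_model(gamma), culture_condition(c(EX_up = 10), fix_uptake = TRUE))
    expect_equal(f$status, "optimal")
    expect_equal(f$objective_value, 10 * gamma, tolerance = 1e-9)
  }
  # all exchanges closed with NGAM > 0: infeasible
  m <- toy_full()
  closed <- culture_condition(stats::setNames(
    rep(0, sum(m$reactions$is_exchange)),
    m$reactions$id[m$reactions$is_exchange]), fix_uptake = FALSE)
  closed$blocked_products <- m$reactions$id[m$reactions$is_exchange]
  f2 <- solve_fba(m, closed)
  expect_equal(f2$status, "infeasible")
})

test_that("every optimal flux state satisfies bounds and mass balance", {
  m <- toy_full()
  S <- pdoflux:::stoich_matrix(m)
  for (obj in list(objective_spec("lp_biomass"), objective_spec("yield_per_flux"),
                   objective_spec("weighted", w = 0.04))) {
    f <- solve_fba(m, toy_condition(10), obj)
    expect_true(f$status %in% c("optimal", "local_optimum"))
    v <- f$fluxes[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6 * max(1, max(abs(v))))
    bnd <- pdoflux:::condition_bounds(m, toy_condition(10))
    expect_true(all(v >= bnd$lb - 1e-7 & v <= bnd$ub + 1e-7))
  }
})

test_that("LP optimum dominates random feasible points", {
  m <- toy_full()
  cond <- toy_condition(10)
  f <- solve_fba(m, cond)
  pts <- random_feasible_points(m, cond, 1000, seed = 8)
  ib <- match(m$biomass_reaction_id, m$reactions$id)
  expect_true(all(pts[, ib] <= f$objective_value + 1e-7))
})

test_that("fractional objective matches the dense-grid oracle on the Y-network", {
  y <- y_network(10)
  cond <- culture_condition(c(EX_up = 10), fix_uptake = TRUE)
  f <- solve_fba(y, cond, objective_spec("yield_per_flux"))
  # one free dimension: v1 in [0, 10], v2 = 10 - v1
  v1 <- seq(0, 10, by = 1e-4)
  z <- v1 / (100 + 2 * v1^2 + 2 * (10 - v1)^2)
  expect_equal(f$objective_value, max(z), tolerance = 0.01)
  expect_equal(unname(f$fluxes[["R1"]]), v1[which.max(z)], tolerance = 1e-3)
  # analytic optimum of the same ratio: v1* = sqrt(75)
  expect_equal(unname(f$fluxes[["R1"]]), sqrt(75), tolerance = 1e-6)
})

test_that("fractional and weighted optima dominate feasible reference points", {
  m <- toy_full()
  cond <- toy_condition(10)
  for (obj in list(objective_spec("yield_per_flux"),
                   objective_spec("weighted", w = 0.3))) {
    f <- solve_fba(m, cond, obj)
    fo <- pdoflux:::fractional_objective(m, obj)
    f_lp <- solve_fba(m, cond)
    expect_gte(f$objective_value, fo$Z(unname(f_lp$fluxes[m$reactions$id])) - 1e-12)
    pts <- random_feasible_points(m, cond, 300, seed = 9)
    zs <- apply(pts, 1, fo$Z)
    expect_true(all(zs <= f$objective_value + 1e-9))
  }
})

test_that("unique-pathway networks give identical LP and fractional fluxes", {
  m <- chain_model(0.1)
  cond <- culture_condition(c(EX_up = 10), fix_uptake = TRUE)
  f_lp <- solve_fba(m, cond)
  f_nl <- solve_fba(m, cond, objective_spec("yield_per_flux"))
  expect_equal(f_nl$fluxes, f_lp$fluxes, tolerance = 1e-6)
})

test_that("weighted objective validates w and approaches the w -> 1 limit", {
  expect_error(objective_spec("weighted", w = 0), "strictly inside")
  expect_error(objective_spec("weighted", w = 1), "strictly inside")
  expect_error(objective_spec("weighted"), "strictly inside")
  expect_error(objective_spec("yield_per_flux", w = 0.5), "only applies")
  m <- toy_full()
  cond <- toy_condition(10)
  f1 <- solve_fba(m, cond, objective_spec("yield_per_flux"))
  f999 <- solve_fba(m, cond, objective_spec("weighted", w = 1 - 1e-6))
  expect_equal(unname(f999$fluxes), unname(f1$fluxes), tolerance = 1e-3)
  # stronger ATP penalty never raises ATP production (grid-oracle property)
  f05 <- solve_fba(m, cond, objective_spec("weighted", w = 0.5))
  expect_lte(atp_production(f05, m), atp_production(f999, m) + 1e-6)
})

test_that("hydrogen / reduced-ferredoxin ratio diagnoses reductase direction", {
  m <- toy_full()
  # hand-built flux: HYD forms 2 H2, PFOR + forward FNR form 2 Fdred
  v <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  v[c("HYD", "PFOR", "FNR")] <- c(2, 1, 1)
  expect_equal(hydrogen_ferredoxin_ratio(list(fluxes = v), m), 1)
  v2 <- v; v2["FNR"] <- -1  # reverse reductase: only PFOR forms Fdred
  expect_equal(hydrogen_ferredoxin_ratio(list(fluxes = v2), m), 2)
  # hydrogenase knocked out: ratio 0
  v3 <- v; v3["HYD"] <- 0
  expect_equal(hydrogen_ferredoxin_ratio(list(fluxes = v3), m), 0)
  # no ferredoxin turnover: undefined
  v4 <- 0 * v
  expect_true(is.nan(hydrogen_ferredoxin_ratio(list(fluxes = v4), m)))
})

test_that("robustness scan records failures and respects LP monotonicity", {
  # with maintenance off, zero uptake gives mu = 0
  m0 <- toy_glycerol_model(ngam = 0)
  rs0 <- robustness_scan(m0, culture_condition(c(EX_glyc = 0)),
                         uptake_grid = 0)
  expect_equal(rs0$mu, 0, tolerance = 1e-9)
  # with maintenance on, the zero-uptake point fails but the scan continues
  m <- toy_full()
  rs <- robustness_scan(m, toy_condition(10), objective_spec("lp_biomass"),
                        uptake_grid = c(0, 4, 8, 12, 16))
  expect_equal(rs$status[1], "infeasible")
  ok <- rs$status == "optimal"
  expect_true(all(diff(rs$mu[ok]) >= -1e-8))   # mu non-decreasing in uptake
  expect_true("EX_pdo" %in% names(rs))
})

test_that("weight calibration recovers a planted weight and handles edge cases", {
  m <- toy_full()
  cond <- toy_condition(10)
  yields_at <- function(obj) {
    f <- solve_fba(m, cond, obj)
    tibble::tibble(product = c("BIOMASS", "EX_pdo"),
                   yield = flux_yields(f, m, c("BIOMASS", "EX_pdo"), "EX_glyc")$yield,
                   substrate = "EX_glyc")
  }
  grid <- seq(0.1, 0.9, by = 0.1)
  cal <- calibrate_weight(m, cond, yields_at(objective_spec("weighted", w = 0.3)),
                          w_grid = grid)
  expect_equal(cal$w_star, 0.3, tolerance = 0.1 + 1e-9)  # within one grid step
  # experimental yields from the pure fractional objective: w* at grid maximum
  cal2 <- calibrate_weight(m, cond, yields_at(objective_spec("yield_per_flux")),
                           w_grid = grid)
  expect_equal(cal2$w_star, max(grid))
  # a single-row table still calibrates
  one <- yields_at(objective_spec("weighted", w = 0.3))[1, ]
  expect_no_error(calibrate_weight(m, cond, one, w_grid = c(0.2, 0.5)))
  expect_error(calibrate_weight(m, cond, one, w_grid = numeric(0)), "empty")
  expect_error(calibrate_weight(m, cond, one[0, ], w_grid = grid), "empty")
})

test_that("loopless check finds flux-carrying internal cycles", {
  # 3-reaction futile cycle A -> B -> C -> A plus a throughput chain
  met <- tibble::tibble(id = c("A", "B", "C"), name = id, formula = "C",
                        charge = 0, compartment = "c")
  rxn <- tibble::tibble(
    id = c("EX_in", "C1", "C2", "C3", "EX_out"), name = id,
    lower_bound = c(-10, 0, 0, 0, 0), upper_bound = c(0, 1000, 1000, 1000, 1000),
    gpr = "", ec = list(character(0)), kegg_id = NA_character_)
  sto <- tibble::tibble(
    reaction_id = c("EX_in", "C1", "C1", "C2", "C2", "C3", "C3", "EX_out"),
    metabolite_id = c("A", "A", "B", "B", "C", "C", "A", "A"),
    coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1))
  m <- metabolic_model(met, rxn, sto, biomass_reaction_id = "EX_out",
                       gam = 0, ngam = 0)
  v <- stats::setNames(c(-2, 5, 5, 5, 2), rxn$id)   # cycle at 5, throughput 2
  cycles <- loopless_check(list(fluxes = v), m)
  expect_length(cycles, 1)
  expect_setequal(cycles[[1]], c("C1", "C2", "C3"))
  # acyclic active flux: empty
  v2 <- stats::setNames(c(-2, 2, 0, 0, 2), rxn$id)
  expect_length(loopless_check(list(fluxes = v2), m), 0)
  # reversible pair both active is a 2-cycle
  met2 <- met[1:2, ]
  rxn2 <- tibble::tibble(id = c("F", "Bk"), name = id,
                         lower_bound = 0, upper_bound = 10, gpr = "",
                         ec = list(character(0)), kegg_id = NA_character_)
  sto2 <- tibble::tibble(reaction_id = c("F", "F", "Bk", "Bk"),
                         metabolite_id = c("A", "B", "B", "A"),
                         coefficient = c(-1, 1, -1, 1))
  m2 <- metabolic_model(met2, rxn2, sto2, biomass_reaction_id = "F",
                        gam = 0, ngam = 0)
  cyc2 <- loopless_check(list(fluxes = c(F = 3, Bk = 3)), m2)
  expect_length(cyc2, 1)
  expect_setequal(cyc2[[1]], c("F", "Bk"))
})

test_that("blocking hydrogen and formate makes LP and fractional phenotypes coincide", {
  m <- toy_full()
  cond <- toy_condition(10)
  cond$blocked_products <- c("EX_h2", "EX_for")
  f_lp <- solve_fba(m, cond)
  f_eq1 <- solve_fba(m, cond, objective_spec("yield_per_flux"))
  expect_equal(growth_rate(f_eq1, m), growth_rate(f_lp, m), tolerance = 1e-6)
  expect_equal(unname(f_eq1$fluxes[["EX_pdo"]]), unname(f_lp$fluxes[["EX_pdo"]]),
               tolerance = 1e-6)
})
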