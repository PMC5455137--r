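# Shared fixtures and independent oracles. Everything is built in code; no
# stored binary fixtures.

# memoised expensive fixtures (flux coupling on the toy takes seconds)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

toy_full <- function() cached("toy_full", toy_glycerol_model())
toy_condition <- function(uptake = 10, ...) {
  culture_condition(c(EX_glyc = uptake), acetate_constraint = TRUE,
                    fix_uptake = TRUE, ...)
}
toy_coupling <- function() cached("toy_coupling", flux_coupling(toy_full()))
toy_eq1_flux <- function() cached(
  "toy_eq1_flux",
  solve_fba(toy_full(), toy_condition(), objective_spec("yield_per_flux")))

# 3-metabolite Y-network: fixed uptake 10 splits into two sinks; the growth
# sink is R1/EX_B. Small enough for dense-grid and vertex oracles.
y_network <- function(uptake = 10) {
  met <- tibble::tibble(id = c("A", "B", "C"), name = id, formula = "C",
                        charge = 0, compartment = "c")
  rxn <- tibble::tibble(
    id = c("EX_up", "R1", "R2", "EX_B", "EX_C"), name = id,
    lower_bound = c(-uptake, 0, 0, 0, 0),
    upper_bound = c(-uptake, 1000, 1000, 1000, 1000),
    gpr = "", ec = list("1.1.1.1", "2.2.2.2", "3.3.3.3", character(0), character(0))[c(4, 1, 2, 4, 4)],
    kegg_id = NA_character_)
  sto <- tibble::tibble(
    reaction_id = c("EX_up", "R1", "R1", "R2", "R2", "EX_B", "EX_C"),
    metabolite_id = c("A", "A", "B", "A", "C", "B", "C"),
    coefficient = c(-1, -1, 1, -1, 1, -1, -1))
  metabolic_model(met, rxn, sto, biomass_reaction_id = "EX_B",
                  gam = 0, ngam = 0, id = "y_network")
}

# linear chain with a biomass yield gamma: uptake (fixed u) -> A -> biomass
chain_model <- function(gamma = 0.1, uptake = 10) {
  met <- tibble::tibble(id = c("A", "X"), name = id, formula = c("C", NA),
                        charge = c(0, NA), compartment = "c")
  rxn <- tibble::tibble(
    id = c("EX_up", "BIO", "EX_X"), name = id,
    lower_bound = c(-uptake, 0, 0), upper_bound = c(-uptake, 1000, 1000),
    gpr = "", ec = list(character(0)), kegg_id = NA_character_)
  sto <- tibble::tibble(
    reaction_id = c("EX_up", "BIO", "BIO", "EX_X"),
    metabolite_id = c("A", "A", "X", "X"),
    coefficient = c(-1, -1 / gamma, 1, -1))
  metabolic_model(met, rxn, sto, biomass_reaction_id = "BIO",
                  gam = 0, ngam = 0, id = "chain")
}

# two parallel equal branches feeding growth; for ROOM oracle tests
parallel_model <- function(uptake = 10) {
  met <- tibble::tibble(id = c("A", "B"), name = id, formula = "C",
                        charge = 0, compartment = "c")
  rxn <- tibble::tibble(
    id = c("EX_up", "R1", "R2", "BIO"), name = id,
    lower_bound = c(-uptake, 0, 0, 0), upper_bound = c(-uptake, 1000, 1000, 1000),
    gpr = c("", "g1", "g2", ""),
    ec = list(character(0), "1.1.1.10", "1.1.1.20", character(0)),
    kegg_id = NA_character_)
  sto <- tibble::tibble(
    reaction_id = c("EX_up", "R1", "R1", "R2", "R2", "BIO"),
    metabolite_id = c("A", "A", "B", "A", "B", "B"),
    coefficient = c(-1, -1, 1, -1, 1, -1))
  metabolic_model(met, rxn, sto, biomass_reaction_id = "BIO",
                  gam = 0, ngam = 0, id = "parallel")
}

# exact vertex enumeration of {S v = b, lb <= v <= ub} for small networks:
# fix n - rank(S) variables at bound combinations and solve for the rest
enumerate_vertices <- function(S, lb, ub, b = NULL, tol = 1e-8) {
  n <- ncol(S)
  if (is.null(b)) b <- rep(0, nrow(S))
  r <- qr(S)$rank
  d <- n - r
  if (d < 0) stop("overdetermined system")
  verts <- list()
  for (nb in utils::combn(n, d, simplify = FALSE)) {
    basics <- setdiff(seq_len(n), nb)
    Sb <- S[, basics, drop = FALSE]
    if (qr(Sb)$rank < r) next
    combos <- expand.grid(rep(list(c(1, 2)), d))
    for (ci in seq_len(nrow(combos))) {
      vals <- ifelse(unlist(combos[ci, ]) == 1, lb[nb], ub[nb])
      if (any(!is.finite(vals))) next
      rhs <- b - S[, nb, drop = FALSE] %*% vals
      sol <- tryCatch(qr.solve(Sb, rhs, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[nb] <- vals; v[basics] <- sol
      if (max(abs(S %*% v - b)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (length(verts) == 0) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# random feasible points: convex combinations of random vertices
random_feasible_points <- function(model, condition, k, seed = 1) {
  S <- pdoflux:::stoich_matrix(model)
  bnd <- pdoflux:::condition_bounds(model, condition)
  verts <- pdoflux:::random_vertices(S, bnd$lb, bnd$ub, 25, seed)
  stopifnot(length(verts) > 0)
  V <- do.call(rbind, verts)
  set.seed(seed)
  W <- matrix(stats::rexp(k * nrow(V)), k, nrow(V))
  W <- W / rowSums(W)
  W %*% V
}

# exhaustive ROOM oracle: smallest number of reactions that must leave the
# wild band for the mutant model to stay feasible
room_oracle <- function(model, condition, deletions, wild, delta = 0.05,
                        epsilon = 0.001) {
  mut <- delete_enzymes(model, deletions)
  S <- pdoflux:::stoich_matrix(mut)
  bnd <- pdoflux:::condition_bounds(mut, condition)
  n <- ncol(S)
  vw <- unname(wild$fluxes[colnames(S)])
  vu <- vw + delta * abs(vw) + epsilon
  vl <- vw - delta * abs(vw) - epsilon
  feasible <- function(off_band) {
    lo <- bnd$lb; hi <- bnd$ub
    keep <- setdiff(seq_len(n), off_band)
    lo[keep] <- pmax(lo[keep], vl[keep])
    hi[keep] <- pmin(hi[keep], vu[keep])
    if (any(lo > hi + 1e-12)) return(FALSE)
    res <- pdoflux:::lp_solve(rep(0, n), S, rep(0, nrow(S)), NULL, NULL, lo, hi)
    res$status == "optimal"
  }
  for (k in 0:n) {
    for (off in utils::combn(n, k, simplify = FALSE)) {
      if (feasible(off)) return(k)
    }
  }
  NA_integer_
}
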