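# Non-linear FBA objectives. Both fractional objectives - growth per squared
# flux, and the ATP-penalized weighted form - have a linear numerator and a
# convex denominator, so the ratio maximization is a concave-convex fractional
# program. It is solved by Dinkelbach iteration: each subproblem
# max mu - lambda * D(v) is a strictly convex QP (quadprog), and the iteration
# converges to the global optimum. The ATP production term sum(max(sigma*v,0))
# is handled exactly with auxiliary variables p >= sigma*v, p >= 0.

# orientation of each ATP-producing reaction toward ATP synthesis
atp_orientation <- function(model) {
  ids <- model$atp_producing_ids
  if (length(ids) == 0) return(stats::setNames(numeric(0), character(0)))
  atp_met <- grep("^atp([_-]|$)|_atp$", model$metabolites$id,
                  ignore.case = TRUE, value = TRUE)[1]
  sgn <- rep(1, length(ids))
  if (!is.na(atp_met)) {
    for (k in seq_along(ids)) {
      co <- model$stoichiometry$coefficient[
        model$stoichiometry$reaction_id == ids[k] &
          model$stoichiometry$metabolite_id == atp_met]
      if (length(co) == 1 && co < 0) sgn[k] <- -1
    }
  }
  stats::setNames(sgn, ids)
}

# closures evaluating the fractional objective Z(v), its denominator and
# gradient (used by FVA's relaxed-objective constraint)
fractional_objective <- function(model, objective) {
  rxn_ids <- model$reactions$id
  n <- length(rxn_ids)
  ib <- match(model$biomass_reaction_id, rxn_ids)
  w <- if (objective$kind == "weighted") objective$w else 1
  set <- objective$enzyme_usage_set %||% rxn_ids
  in_set <- as.numeric(rxn_ids %in% set)
  sigma <- rep(0, n)
  if (objective$kind == "weighted") {
    ori <- atp_orientation(model)
    sigma[match(names(ori), rxn_ids)] <- ori
  }
  denom <- function(v) {
    P <- sum(pmax(sigma * v, 0))
    w * sum(in_set * v^2) + (1 - w) * P^2
  }
  grad_denom <- function(v) {
    P <- sum(pmax(sigma * v, 0))
    2 * w * in_set * v + 2 * (1 - w) * P * sigma * (sigma * v > 0)
  }
  Z <- function(v) {
    D <- denom(v)
    if (D <= 1e-12) return(0)
    v[ib] / D
  }
  list(Z = Z, denom = denom, grad_denom = grad_denom, ib = ib,
       w = w, in_set = in_set, sigma = sigma)
}

# strictly convex QP:  min 1/2 x' Q x - d' x  s.t. Seq x = beq, lb <= x <= ub,
# Ain x <= bin.  Fixed variables are substituted out and redundant equality
# rows dropped (stoichiometric matrices carry conserved-moiety dependencies).
qp_solve <- function(Q, d, Seq, beq, lb, ub, Ain = NULL, bin = NULL) {
  n <- length(d)
  fixed <- which(ub - lb <= 1e-12)
  free <- setdiff(seq_len(n), fixed)
  xf <- lb[fixed]
  beq2 <- beq - as.numeric(Seq[, fixed, drop = FALSE] %*% xf)
  Sf <- Seq[, free, drop = FALSE]
  qrS <- qr(t(Sf))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  Sr <- Sf[keep, , drop = FALSE]; br <- beq2[keep]
  Qf <- Q[free, free, drop = FALSE]
  df <- d[free] - as.numeric(Q[free, fixed, drop = FALSE] %*% xf)
  Amat <- cbind(t(Sr), diag(length(free)), -diag(length(free)))
  bvec <- c(br, lb[free], -ub[free])
  if (!is.null(Ain) && NROW(Ain) > 0) {
    bin2 <- bin - as.numeric(Ain[, fixed, drop = FALSE] %*% xf)
    Amat <- cbind(Amat, -t(Ain[, free, drop = FALSE]))
    bvec <- c(bvec, -bin2)
  }
  # clamp infinite bounds for quadprog
  bvec[!is.finite(bvec)] <- -1e7
  sol <- quadprog::solve.QP(Qf, df, Amat, bvec, meq = nrow(Sr))
  x <- numeric(n); x[free] <- sol$solution; x[fixed] <- xf
  x
}

solve_fba_nlp_ <- function(model, condition, objective, n_starts = 5,
                           seed = 1, tol_balance = 1e-6) {
  S <- stoich_matrix(model)
  bnd <- condition_bounds(model, condition)
  n <- ncol(S)
  lp <- solve_fba_lp_(model, condition)
  if (lp$status != "optimal") return(lp)
  fo <- fractional_objective(model, objective)
  v_lp <- unname(lp$fluxes)
  if (lp$objective_value <= 1e-12) {
    # no growth possible: ratio objective is 0 everywhere feasible
    return(new_flux_state(lp$fluxes, 0, "optimal", objective))
  }
  n_atp <- sum(fo$sigma != 0)
  use_aux <- fo$w < 1 && n_atp > 0
  nv <- n + if (use_aux) n_atp else 0L
  d <- numeric(nv); d[fo$ib] <- 1
  Seq <- cbind(S, matrix(0, nrow(S), nv - n))
  lbx <- c(bnd$lb, rep(0, nv - n))
  ubx <- c(bnd$ub, rep(Inf, nv - n))
  Ain <- NULL; bin <- NULL
  if (use_aux) {
    # p_k >= sigma_j v_j  ->  sigma_j v_j - p_k <= 0
    js <- which(fo$sigma != 0)
    Ain <- matrix(0, n_atp, nv)
    for (k in seq_along(js)) {
      Ain[k, js[k]] <- fo$sigma[js[k]]
      Ain[k, n + k] <- -1
    }
    bin <- rep(0, n_atp)
  }
  qmat <- function(lam) {
    qd <- c(2 * lam * fo$w * fo$in_set + 1e-9, rep(1e-9, nv - n))
    Q <- diag(qd, nv)
    if (use_aux) {
      pp <- n + seq_len(n_atp)
      Q[pp, pp] <- Q[pp, pp] + 2 * lam * (1 - fo$w)   # rank-one (sum p)^2 term
    }
    Q
  }
  lam <- max(fo$Z(v_lp), 1e-8)
  v <- v_lp
  for (it in 1:200) {
    x <- tryCatch(qp_solve(qmat(lam), d, Seq, rep(0, nrow(S)), lbx, ubx, Ain, bin),
                  error = function(e) NULL)
    if (is.null(x)) break
    v_new <- x[seq_len(n)]
    z <- fo$Z(v_new)
    if (z >= fo$Z(v)) v <- v_new
    if (abs(z - lam) <= 1e-12 * (1 + abs(lam))) break
    lam <- max(fo$Z(v), 1e-12)
  }
  v <- pmin(pmax(v, bnd$lb), bnd$ub)
  if (max(abs(S %*% v)) > tol_balance * max(1, max(abs(v)))) {
    return(new_flux_state(stats::setNames(rep(NA_real_, n), colnames(S)),
                          NA_real_, "infeasible", objective))
  }
  new_flux_state(stats::setNames(v, colnames(S)), fo$Z(v), "optimal", objective)
}

# random vertices of {S v = 0, lb <= v <= ub} via random LP objectives;
# used by property tests as feasible reference points
random_vertices <- function(S, lb, ub, k, seed) {
  n <- ncol(S)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(k)) {
      cobj <- stats::rnorm(n)
      res <- lp_solve(cobj, S, rep(0, nrow(S)), NULL, NULL, lb, ub,
                      maximize = TRUE)
      if (res$status == "optimal") out[[length(out) + 1L]] <- res$x
    }
    out
  })
}
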