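# Dense two-phase simplex for bounded-variable linear programs, plus a small
# branch-and-bound layer for mixed-binary programs (ROOM). All problems in this
# package are toy- to genome-scale-subset sized (tens of variables), so a dense
# O(m^3)-per-iteration implementation is deliberate: deterministic, dependency
# free, easy to audit.

# Solve: min/max  c'x  s.t.  Aeq x = beq,  Aub x <= bub,  lower <= x <= upper.
# Returns list(status, x, objective). Status one of
# "optimal", "infeasible", "unbounded", "maxit".
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lower, upper, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(lower > upper + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  if (is.null(Aeq)) Aeq <- matrix(0, 0, n)
  Aeq <- matrix(as.numeric(Aeq), nrow = NROW(Aeq), ncol = n)
  if (is.null(beq)) beq <- numeric(0)
  n_slack <- 0L
  if (!is.null(Aub) && NROW(Aub) > 0) {
    Aub <- matrix(as.numeric(Aub), nrow = NROW(Aub), ncol = n)
    n_slack <- NROW(Aub)
    Aeq <- rbind(cbind(Aeq, matrix(0, NROW(Aeq), n_slack)),
                 cbind(Aub, diag(n_slack)))
    beq <- c(beq, bub)
    lower <- c(lower, rep(0, n_slack))
    upper <- c(upper, rep(Inf, n_slack))
  }
  cvec <- c(if (maximize) -obj else obj, rep(0, n_slack))
  res <- simplex_bounded(cvec, Aeq, beq, lower, upper)
  x <- res$x[seq_len(n)]
  objective <- if (res$status == "optimal") sum(obj * x) else NA_real_
  list(status = res$status, x = x, objective = objective)
}

# Core bounded simplex: min c'x s.t. A x = b, l <= x <= u.
simplex_bounded <- function(cvec, A, b, l, u, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # box-only problem
    x <- ifelse(cvec > 0, l, ifelse(cvec < 0, u, ifelse(is.finite(l), l, 0)))
    if (any(cvec > 0 & !is.finite(l)) || any(cvec < 0 & !is.finite(u))) {
      return(list(status = "unbounded", x = rep(NA_real_, n)))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x))
  }
  # initial nonbasic values at a finite bound nearest zero (0 if free)
  x0 <- ifelse(is.finite(l) & is.finite(u),
               ifelse(abs(l) <= abs(u), l, u),
               ifelse(is.finite(l), l, ifelse(is.finite(u), u, 0)))
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  A1 <- cbind(A, diag(sgn, m, m))
  l1 <- c(l, rep(0, m))
  u1 <- c(u, rep(Inf, m))
  x1 <- c(x0, abs(r))
  basis <- n + seq_len(m)
  at_upper <- is.finite(u1) & x1 == u1 & !(is.finite(l1) & x1 == l1)
  c_phase1 <- c(rep(0, n), rep(1, m))

  run <- simplex_iterate(c_phase1, A1, b, l1, u1, basis, x1, at_upper, tol, maxit)
  if (run$status == "maxit") return(list(status = "maxit", x = run$x[seq_len(n)]))
  if (sum(run$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n)))
  }
  # phase 2: pin artificials to zero, restore true costs
  u1[n + seq_len(m)] <- 0
  x1 <- run$x
  x1[n + seq_len(m)] <- 0
  run2 <- simplex_iterate(c(cvec, rep(0, m)), A1, b, l1, u1,
                          run$basis, x1, run$at_upper, tol, maxit)
  list(status = run2$status, x = run2$x[seq_len(n)])
}

simplex_iterate <- function(cvec, A, b, l, u, basis, x, at_upper, tol, maxit) {
  n <- ncol(A)
  stall <- 0L
  obj_prev <- Inf
  for (it in seq_len(maxit)) {
    B <- A[, basis, drop = FALSE]
    nb <- setdiff(seq_len(n), basis)
    # one inversion per iteration serves the primal, dual and direction solves
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) {
      return(list(status = "maxit", x = x, basis = basis, at_upper = at_upper))
    }
    # recompute basic values from nonbasic ones (keeps drift in check)
    x[basis] <- as.numeric(Binv %*% (b - A[, nb, drop = FALSE] %*% x[nb]))
    obj <- sum(cvec * x)
    if (obj < obj_prev - tol) { stall <- 0L } else { stall <- stall + 1L }
    obj_prev <- obj
    bland <- stall > 60L
    y <- as.numeric(crossprod(Binv, cvec[basis]))
    d <- cvec[nb] - as.numeric(t(A[, nb, drop = FALSE]) %*% y)
    can_inc <- !at_upper[nb] & d < -tol      # at lower bound (or free), increase
    can_dec <- (at_upper[nb] | !is.finite(l[nb])) & d > tol   # decrease
    cand <- which(can_inc | can_dec)
    if (length(cand) == 0L) {
      return(list(status = "optimal", x = x, basis = basis, at_upper = at_upper))
    }
    pick <- if (bland) cand[which.min(nb[cand])] else cand[which.max(abs(d[cand]))]
    j <- nb[pick]
    increasing <- can_inc[pick]
    w <- as.numeric(Binv %*% A[, j])
    # step t >= 0; x_j moves by +t (increasing) or -t; basics move by -t*w or +t*w
    dir_b <- if (increasing) -w else w
    t_max <- if (increasing) u[j] - x[j] else x[j] - l[j]
    if (!is.finite(t_max)) t_max <- Inf
    leave <- 0L        # 0 = bound flip on entering variable
    leave_to_upper <- FALSE
    for (k in seq_along(basis)) {
      bi <- basis[k]
      if (dir_b[k] < -tol) {
        if (is.finite(l[bi])) {
          tk <- (x[bi] - l[bi]) / (-dir_b[k])
          if (tk < t_max - 1e-12) { t_max <- tk; leave <- k; leave_to_upper <- FALSE }
        }
      } else if (dir_b[k] > tol) {
        if (is.finite(u[bi])) {
          tk <- (u[bi] - x[bi]) / dir_b[k]
          if (tk < t_max - 1e-12) { t_max <- tk; leave <- k; leave_to_upper <- TRUE }
        }
      }
    }
    if (!is.finite(t_max)) {
      return(list(status = "unbounded", x = x, basis = basis, at_upper = at_upper))
    }
    t_max <- max(t_max, 0)
    x[j] <- x[j] + if (increasing) t_max else -t_max
    x[basis] <- x[basis] + t_max * dir_b
    if (leave == 0L) {
      # entering variable flipped to its other bound
      at_upper[j] <- increasing && is.finite(u[j]) && abs(x[j] - u[j]) < 1e-9
    } else {
      bi <- basis[leave]
      at_upper[bi] <- leave_to_upper
      x[bi] <- if (leave_to_upper) u[bi] else l[bi]
      basis[leave] <- j
      at_upper[j] <- FALSE
    }
  }
  list(status = "maxit", x = x, basis = basis, at_upper = at_upper)
}

# Mixed-binary LP by depth-first branch and bound. `binary` indexes variables
# restricted to {0,1}. Used for ROOM where the objective is the integral count
# of reactions pushed outside the wild-type band.
milp_solve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                       lower, upper, binary = integer(0), maximize = FALSE,
                       integral_objective = FALSE, tol_int = 1e-6) {
  best <- list(objective = Inf, x = NULL)
  sense <- if (maximize) -1 else 1
  obj_s <- sense * obj
  recurse <- function(lo, hi) {
    rel <- lp_solve(obj_s, Aeq, beq, Aub, bub, lo, hi, maximize = FALSE)
    if (rel$status != "optimal") return(invisible(NULL))
    bound <- rel$objective
    if (integral_objective) bound <- ceiling(bound - 1e-6)
    if (bound >= best$objective - 1e-9) return(invisible(NULL))
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (length(frac) == 0L || max(frac) <= tol_int) {
      best <<- list(objective = rel$objective, x = rel$x)
      return(invisible(NULL))
    }
    j <- binary[which.max(frac)]
    v <- rel$x[j]
    # explore the nearer-integer side first
    sides <- if (v - floor(v) <= 0.5) c(0, 1) else c(1, 0)
    for (s in sides) {
      lo2 <- lo; hi2 <- hi
      lo2[j] <- s; hi2[j] <- s
      recurse(lo2, hi2)
    }
    invisible(NULL)
  }
  recurse(lower, upper)
  if (is.null(best$x)) {
    return(list(status = "infeasible", x = rep(NA_real_, length(obj)), objective = NA_real_))
  }
  list(status = "optimal", x = best$x, objective = sense * best$objective)
}
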