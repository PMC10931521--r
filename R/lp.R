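## Linear-programming layer.
##
## All flux computations go through solveLP(), an abstraction over the
## in-package two-phase simplex (see simplex.R) for
##     max/min  obj' v   s.t.  S v = 0,  lb <= v <= ub,  A v >= rhs
## Variables are shifted to x = v - lb >= 0 before the solve. Tolerances:
## 1e-9 primal feasibility on bounds, 1e-6 on the steady-state residual
## check (see fba()).

LP_BIG_BOUND <- 1e8

#' Solve a bounded linear program over a stoichiometric polytope
#'
#' @param obj Objective coefficient vector (length = number of reactions).
#' @param S Constraint matrix for the equality system `S v = 0`
#'   (typically the stoichiometric matrix); may have zero rows.
#' @param lb,ub Variable bounds. Infinite bounds are clamped to
#'   `+-1e8` and a solution pressing against a clamped bound is reported as
#'   `"unbounded"`.
#' @param ineq Optional list with elements `A` (matrix) and `rhs`
#'   (vector) adding rows `A v >= rhs`.
#' @param maximize Maximize (default) or minimize.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `value`, and the solution vector `v`.
#' @keywords internal
solveLP <- function(obj, S, lb, ub, ineq = NULL, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  S <- as.matrix(S)
  clamped_lo <- !is.finite(lb)
  clamped_hi <- !is.finite(ub)
  lb[clamped_lo] <- -LP_BIG_BOUND
  ub[clamped_hi] <- LP_BIG_BOUND

  # shift: x = v - lb in [0, ub - lb]
  Arows <- rbind(S, diag(n))
  dirs <- c(rep("=", nrow(S)), rep("<=", n))
  rhss <- c(if (nrow(S)) as.vector(-S %*% lb) else numeric(0), ub - lb)
  if (!is.null(ineq) && length(ineq$rhs)) {
    A <- matrix(ineq$A, ncol = n)
    Arows <- rbind(Arows, A)
    dirs <- c(dirs, rep(">=", length(ineq$rhs)))
    rhss <- c(rhss, ineq$rhs - as.vector(A %*% lb))
  }

  res <- lpSimplex(obj, Arows, dirs, rhss, maximize = maximize)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", value = NA_real_,
                v = rep(NA_real_, n)))
  }
  if (res$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_,
                v = rep(NA_real_, n)))
  }
  v <- res$x + lb
  at_clamp <- (clamped_hi & v > 0.99 * LP_BIG_BOUND) |
    (clamped_lo & v < -0.99 * LP_BIG_BOUND)
  if (any(at_clamp & obj != 0)) {
    return(list(status = "unbounded", value = NA_real_, v = v))
  }
  list(status = "optimal", value = sum(obj * v), v = v)
}

## Split-variable LP for weighted absolute-flux minimization:
##   min  cost' (p + q)  s.t.  S(p - q) = 0, extra ineqs on v = p - q,
##        0 <= p <= max(ub, 0), 0 <= q <= max(-lb, 0),
##        plus explicit rows where lb > 0 or ub < 0.
solveWeightedAbsFluxLP <- function(cost, S, lb, ub, ineq = NULL) {
  n <- length(cost)
  S <- as.matrix(S)
  lb2 <- pmax(lb, -LP_BIG_BOUND)
  ub2 <- pmin(ub, LP_BIG_BOUND)
  obj <- c(cost, cost)
  Ssplit <- cbind(S, -S)
  lo <- rep(0, 2 * n)
  hi <- c(pmax(ub2, 0), pmax(-lb2, 0))

  extraA <- NULL
  extraR <- NULL
  pos_lb <- which(lb2 > 0)
  neg_ub <- which(ub2 < 0)
  if (length(pos_lb)) {
    A <- matrix(0, length(pos_lb), 2 * n)
    A[cbind(seq_along(pos_lb), pos_lb)] <- 1
    A[cbind(seq_along(pos_lb), n + pos_lb)] <- -1
    extraA <- rbind(extraA, A)
    extraR <- c(extraR, lb2[pos_lb])
  }
  if (length(neg_ub)) {
    A <- matrix(0, length(neg_ub), 2 * n)
    A[cbind(seq_along(neg_ub), neg_ub)] <- -1
    A[cbind(seq_along(neg_ub), n + neg_ub)] <- 1
    extraA <- rbind(extraA, A)
    extraR <- c(extraR, -ub2[neg_ub])
  }
  if (!is.null(ineq) && length(ineq$rhs)) {
    A <- matrix(ineq$A, ncol = n)
    extraA <- rbind(extraA, cbind(A, -A))
    extraR <- c(extraR, ineq$rhs)
  }
  sol <- solveLP(obj, Ssplit, lo, hi,
                 ineq = if (is.null(extraA)) NULL else
                   list(A = extraA, rhs = extraR),
                 maximize = FALSE)
  if (sol$status != "optimal") return(sol)
  v <- sol$v[seq_len(n)] - sol$v[n + seq_len(n)]
  list(status = "optimal", value = sol$value, v = v)
}
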