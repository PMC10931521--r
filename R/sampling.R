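#' Sample flux distributions from the constraint polytope
#'
#' Coordinate-free hit-and-run sampling of the flux polytope
#' `{v : S v = 0, lb <= v <= ub, A v >= rhs}`. Directions are drawn
#' isotropically in the null space of `S`, so every step preserves the
#' steady-state constraint exactly; the chord through the current point is
#' intersected with the bounds (and any extra inequality rows) and the next
#' point drawn uniformly on it. The chain starts from a parsimonious
#' solution and records every `thinning`-th state.
#'
#' @param model A [MetabolicModel-class], feasible under its current
#'   constraints.
#' @param n Number of samples (default 50).
#' @param seed Integer seed; identical seeds give bitwise-identical sample
#'   matrices.
#' @param thinning Steps between recorded samples (default 100).
#' @param ineq Optional extra inequality constraints,
#'   `list(A =, rhs =)` for `A v >= rhs`, kept active during sampling (used
#'   for the objective-fraction constraint of condition sampling).
#' @param condition Condition label stored on the result.
#' @return A [FluxSampleSet-class] (`n` rows). For a fully determined
#'   network (point polytope) all rows are identical.
#' @export
fluxSample <- function(model, n = 50, seed = 1, thinning = 100,
                       ineq = NULL, condition = "condition") {
  stopifnot(n >= 1, thinning >= 1)
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  S <- as.matrix(model@stoichiometry)

  # starting point: maximum-margin interior point (a vertex start would
  # leave every hit-and-run chord with zero length)
  start <- findInteriorPoint(S, lb, ub, ineq)
  if (is.null(start)) stop("model is infeasible; cannot sample")

  # directions must preserve S v = 0 and leave fixed reactions
  # (lb == ub) untouched, else every chord has zero length
  fixed <- which(ub - lb < 1e-12)
  constraint_rows <- S
  if (length(fixed)) {
    unit_rows <- matrix(0, length(fixed), length(lb))
    unit_rows[cbind(seq_along(fixed), fixed)] <- 1
    constraint_rows <- rbind(S, unit_rows)
  }
  nullspace <- MASS::Null(t(constraint_rows))
  k <- ncol(nullspace)
  A <- if (!is.null(ineq) && length(ineq$rhs)) matrix(ineq$A, ncol = length(lb))
  rhs <- if (!is.null(ineq)) ineq$rhs

  out <- matrix(NA_real_, n, length(lb),
                dimnames = list(NULL, model@reactions$id))
  withr::with_seed(seed, {
    x <- start
    tol <- 1e-12
    for (i in seq_len(n)) {
      if (k > 0) {
        for (step in seq_len(thinning)) {
          d <- as.vector(nullspace %*% stats::rnorm(k))
          nd <- sqrt(sum(d * d))
          if (nd < tol) next
          d <- d / nd
          # chord limits from bounds
          hi <- Inf
          lo <- -Inf
          pos <- d > 1e-11
          neg <- d < -1e-11
          if (any(pos)) {
            hi <- min(hi, (ub[pos] - x[pos]) / d[pos])
            lo <- max(lo, (lb[pos] - x[pos]) / d[pos])
          }
          if (any(neg)) {
            hi <- min(hi, (lb[neg] - x[neg]) / d[neg])
            lo <- max(lo, (ub[neg] - x[neg]) / d[neg])
          }
          if (!is.null(A)) {
            ad <- as.vector(A %*% d)
            slack <- as.vector(A %*% x) - rhs
            p2 <- ad < -1e-11   # moving against the inequality
            n2 <- ad > 1e-11
            if (any(p2)) hi <- min(hi, (-slack[p2]) / ad[p2])
            if (any(n2)) lo <- max(lo, (-slack[n2]) / ad[n2])
          }
          lo <- min(lo, 0)
          hi <- max(hi, 0)
          if (!is.finite(lo) || !is.finite(hi) || hi - lo < tol) next
          x <- x + stats::runif(1, lo, hi) * d
        }
      }
      out[i, ] <- x
    }
  })
  new("FluxSampleSet", condition = condition,
      reaction_ids = model@reactions$id, samples = out,
      seed = as.integer(seed))
}

# Maximum-margin (Chebyshev-style) interior point of
# {v : S v = 0, lb <= v <= ub, A v >= rhs}: maximize t subject to
# v_i - t >= lb_i and v_i + t <= ub_i for every non-fixed reaction, and
# a' v - t >= rhs for every extra inequality. Returns NULL when
# infeasible; when the polytope has an empty interior the margin is 0 and
# the returned point is an ordinary feasible point.
findInteriorPoint <- function(S, lb, ub, ineq = NULL) {
  n <- length(lb)
  free <- which(ub - lb > 1e-12)
  n_rows <- 2 * length(free) + (if (is.null(ineq)) 0 else length(ineq$rhs))
  A <- matrix(0, n_rows, n + 1)
  rhs <- numeric(n_rows)
  r <- 0L
  for (i in free) {
    r <- r + 1L
    A[r, i] <- 1; A[r, n + 1] <- -1; rhs[r] <- lb[i]    # v_i - t >= lb
    r <- r + 1L
    A[r, i] <- -1; A[r, n + 1] <- -1; rhs[r] <- -ub[i]  # -v_i - t >= -ub
  }
  if (!is.null(ineq) && length(ineq$rhs)) {
    Ai <- matrix(ineq$A, ncol = n)
    for (k in seq_along(ineq$rhs)) {
      r <- r + 1L
      A[r, seq_len(n)] <- Ai[k, ]; A[r, n + 1] <- -1; rhs[r] <- ineq$rhs[k]
    }
  }
  margin_cap <- max(1, max(ub[is.finite(ub)], -lb[is.finite(lb)], 0))
  sol <- solveLP(obj = c(rep(0, n), 1),
                 S = cbind(S, 0),
                 lb = c(lb, 0), ub = c(ub, margin_cap),
                 ineq = list(A = A, rhs = rhs), maximize = TRUE)
  if (sol$status != "optimal") return(NULL)
  sol$v[seq_len(n)]
}
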