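## Dense two-phase primal simplex.
##
## Solves   min/max  obj' x   s.t.  A x (<=, >=, =) rhs,  x >= 0
## by full-tableau pivoting: phase 1 minimizes the sum of artificial
## variables, phase 2 the true objective. Pricing is Dantzig's rule with a
## switch to Bland's rule after a pivot budget, which guarantees
## termination on degenerate problems. Tolerances: 1e-9 on pivots and
## reduced costs, 1e-7 on the phase-1 feasibility test.

lpSimplex <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(dir) == m, length(rhs) == m, length(obj) == n)

  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  # columns: [x | slacks/surplus | artificials], rhs appended last
  n_slack <- sum(dir != "=")
  n_art <- sum(dir != "<=")
  N <- n + n_slack + n_art
  Tm <- matrix(0, m, N + 1)
  Tm[, seq_len(n)] <- A
  Tm[, N + 1] <- rhs
  basis <- integer(m)
  art_cols <- integer(0)
  s_ptr <- n
  a_ptr <- n + n_slack
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      s_ptr <- s_ptr + 1L
      Tm[i, s_ptr] <- 1
      basis[i] <- s_ptr
    } else if (dir[i] == ">=") {
      s_ptr <- s_ptr + 1L
      Tm[i, s_ptr] <- -1
      a_ptr <- a_ptr + 1L
      Tm[i, a_ptr] <- 1
      basis[i] <- a_ptr
      art_cols <- c(art_cols, a_ptr)
    } else {
      a_ptr <- a_ptr + 1L
      Tm[i, a_ptr] <- 1
      basis[i] <- a_ptr
      art_cols <- c(art_cols, a_ptr)
    }
  }

  # phase 1
  if (n_art > 0) {
    cost1 <- rep(0, N)
    cost1[art_cols] <- 1
    allowed <- rep(TRUE, N)
    ph1 <- simplexPhase(Tm, basis, cost1, allowed, tol)
    if (ph1$status != "optimal") {
      stop("phase 1 cannot be unbounded; solver invariant violated")
    }
    Tm <- ph1$Tm
    basis <- ph1$basis
    infeas <- sum(Tm[basis %in% art_cols, N + 1])
    if (infeas > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n),
                  value = NA_real_))
    }
    # drive residual artificials out of the (degenerate) basis
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        entry <- which(abs(Tm[i, seq_len(n + n_slack)]) > tol)
        if (length(entry)) {
          Tm <- simplexPivot(Tm, i, entry[1])
          basis[i] <- entry[1]
        } else {
          drop_rows <- c(drop_rows, i)   # redundant constraint
        }
      }
    }
    if (length(drop_rows)) {
      Tm <- Tm[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(Tm)
    }
  }

  # phase 2
  cost2 <- rep(0, N)
  cost2[seq_len(n)] <- if (maximize) -obj else obj
  allowed <- rep(TRUE, N)
  allowed[art_cols] <- FALSE
  ph2 <- simplexPhase(Tm, basis, cost2, allowed, tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                value = NA_real_))
  }
  Tm <- ph2$Tm
  basis <- ph2$basis
  x <- rep(0, N)
  x[basis] <- Tm[, ncol(Tm)]
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}

simplexPivot <- function(Tm, row, col) {
  prow <- Tm[row, ] / Tm[row, col]
  Tm <- Tm - tcrossprod(Tm[, col], prow)
  Tm[row, ] <- prow
  Tm
}

simplexPhase <- function(Tm, basis, cost, allowed, tol) {
  N <- ncol(Tm) - 1L
  bland_after <- 2000L
  maxit <- 50000L
  for (it in seq_len(maxit)) {
    red <- cost - as.vector(cost[basis] %*% Tm[, seq_len(N), drop = FALSE])
    red[!allowed] <- Inf     # never enters
    red[basis] <- Inf
    if (it <= bland_after) {
      enter <- which.min(red)
      if (red[enter] >= -tol) {
        return(list(Tm = Tm, basis = basis, status = "optimal"))
      }
    } else {
      cand <- which(red < -tol)     # Bland's rule: lowest eligible index
      if (!length(cand)) {
        return(list(Tm = Tm, basis = basis, status = "optimal"))
      }
      enter <- cand[1]
    }
    col <- Tm[, enter]
    ok <- col > tol
    if (!any(ok)) {
      return(list(Tm = Tm, basis = basis, status = "unbounded"))
    }
    ratio <- ifelse(ok, Tm[, N + 1L] / col, Inf)
    mr <- min(ratio)
    if (!is.finite(mr)) stop("numerical breakdown in simplex ratio test")
    leave_rows <- which(ratio <= mr + tol + 1e-9 * abs(mr) & ok)
    # prefer large pivot elements for stability; Bland mode uses the
    # lowest basis index to guarantee termination
    leave <- if (it <= bland_after) {
      leave_rows[which.max(col[leave_rows])]
    } else {
      leave_rows[which.min(basis[leave_rows])]
    }
    Tm <- simplexPivot(Tm, leave, enter)
    basis[leave] <- enter
  }
  stop("simplex iteration limit reached")
}
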