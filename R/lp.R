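#' Solve a small dense linear program
#'
#' Two-phase primal simplex on the tableau, with Bland's rule throughout so the
#' iteration cannot cycle on degenerate problems. Intended for the small, dense
#' and frequently degenerate envelopment programs that radial DEA generates
#' (tens of variables, a handful of constraints); it is not a general-purpose
#' large-scale solver.
#'
#' Minimises (or maximises) `obj %*% x` subject to `A x (dir) rhs` and `x >= 0`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix, m x n.
#' @param dir character vector of constraint directions, each `"<="`, `">="`
#'   or `"=="`.
#' @param rhs numeric right-hand sides, length m.
#' @param maximize logical; maximise instead of minimise.
#' @param tol numerical feasibility/pivot tolerance.
#' @param maxit iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `solution` (length n, `NA` unless optimal) and `value`.
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, maximize = FALSE,
                     tol = 1e-9, maxit = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  if (!all(dir %in% c("<=", ">=", "=="))) {
    stop("constraint directions must be one of '<=', '>=', '=='")
  }
  obj0 <- if (maximize) -obj else obj

  # normalise rhs >= 0 by flipping rows
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  # augment: slack (<=), surplus+artificial (>=), artificial (==)
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  N <- n + n_slack + n_surp + n_art
  T <- matrix(0, m, N + 1L)
  T[, seq_len(n)] <- A
  T[, N + 1L] <- rhs
  basis <- integer(m)
  is_art <- rep(FALSE, N)
  sl <- n
  su <- n + n_slack
  ar <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sl <- sl + 1L
      T[i, sl] <- 1
      basis[i] <- sl
    } else {
      if (dir[i] == ">=") {
        su <- su + 1L
        T[i, su] <- -1
      }
      ar <- ar + 1L
      T[i, ar] <- 1
      is_art[ar] <- TRUE
      basis[i] <- ar
    }
  }

  pivot <- function(T, basis, pr, pc) {
    T[pr, ] <- T[pr, ] / T[pr, pc]
    other <- setdiff(seq_len(nrow(T)), pr)
    T[other, ] <- T[other, , drop = FALSE] -
      outer(T[other, pc], T[pr, ])
    basis[pr] <- pc
    list(T = T, basis = basis)
  }

  # one simplex phase under Bland's rule; cost is length-N vector (minimise)
  run_phase <- function(T, basis, cost, active) {
    for (it in seq_len(maxit)) {
      z <- cost - as.vector(crossprod(cost[basis], T[, seq_len(N), drop = FALSE]))
      z[!active] <- 0
      enter_cand <- which(active & z < -tol)
      if (length(enter_cand) == 0L) {
        return(list(T = T, basis = basis, status = "optimal"))
      }
      pc <- enter_cand[1L]                       # Bland: smallest index enters
      col <- T[, pc]
      rows <- which(col > tol)
      if (length(rows) == 0L) {
        return(list(T = T, basis = basis, status = "unbounded"))
      }
      ratio <- T[rows, N + 1L] / col[rows]
      best <- rows[ratio <= min(ratio) + tol]
      pr <- best[which.min(basis[best])]         # Bland: smallest basis leaves
      p <- pivot(T, basis, pr, pc)
      T <- p$T
      basis <- p$basis
    }
    stop("simplex iteration limit reached")
  }

  # phase 1
  active <- rep(TRUE, N)
  cost1 <- as.numeric(is_art)
  ph1 <- run_phase(T, basis, cost1, active)
  T <- ph1$T
  basis <- ph1$basis
  p1val <- sum(T[is_art[basis], N + 1L])
  if (p1val > 1e-7) {
    return(list(status = "infeasible", solution = rep(NA_real_, n),
                value = NA_real_))
  }
  # drive remaining artificials out of the basis (they sit at level ~0)
  for (i in which(is_art[basis])) {
    row <- T[i, seq_len(N)]
    cand <- which(!is_art & abs(row) > tol)
    if (length(cand) > 0L) {
      p <- pivot(T, basis, i, cand[1L])
      T <- p$T
      basis <- p$basis
    }
    # else the row is redundant; leaving the artificial basic at 0 is harmless
    # because artificial columns are deactivated below
  }
  active <- !is_art

  # phase 2
  cost2 <- c(obj0, rep(0, N - n))
  ph2 <- run_phase(T, basis, cost2, active)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", solution = rep(NA_real_, n),
                value = if (maximize) Inf else -Inf))
  }
  T <- ph2$T
  basis <- ph2$basis
  x <- numeric(N)
  x[basis] <- T[, N + 1L]
  sol <- x[seq_len(n)]
  val <- sum(obj0 * sol)
  list(status = "optimal", solution = sol,
       value = if (maximize) -val else val)
}
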