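#' Solve a bounded linear program
#'
#' Solves `max (or min) c'x  subject to  A x = b,  lb <= x <= ub` with a
#' dense two-phase revised simplex on bounded variables. Bland's smallest-
#' index rule is used for both the entering and the leaving choice, so the
#' iteration cannot cycle on the (highly degenerate) flux polytopes that
#' signaling networks produce. All structural bounds must be finite; the
#' model dialect guarantees this by using 1000 as the unconstrained
#' sentinel, which also means every flux LP is bounded and the solver only
#' ever reports `optimal` or `infeasible` for them.
#'
#' This is the numerical core behind [fba()], [fva()] and the robustness
#' scans; it is deliberately dependency-free and is cross-checked in the
#' test suite against an exhaustive vertex-enumeration oracle.
#'
#' @param c_obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds (finite, `lb <= ub`).
#' @param sense `"max"` or `"min"`.
#' @param tol Reduced-cost / pivot tolerance.
#' @param max_iter Iteration cap (an error if exceeded).
#' @return A list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `x` (solution, `NULL` unless optimal) and `objval`.
#' @export
lp_solve <- function(c_obj, A, b, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(c_obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("structural variable bounds must be finite", call. = FALSE)
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  cc <- if (sense == "min") -c_obj else c_obj

  if (m == 0) {
    x <- ifelse(cc > 0, ub, lb)
    obj <- sum(cc * x)
    return(list(status = "optimal", x = x,
                objval = if (sense == "min") -obj else obj))
  }

  # start structural variables at the bound nearest zero
  start <- ifelse(abs(lb) <= abs(ub), lb, ub)
  resid <- as.vector(b - A %*% start)
  # one artificial per row, signed so its initial value is >= 0
  art_sign <- ifelse(resid >= 0, 1, -1)
  Am <- cbind(A, diag(art_sign, nrow = m))
  L <- c(lb, rep(0, m))
  U <- c(ub, rep(Inf, m))
  ntot <- n + m
  at_ub <- c(abs(lb) > abs(ub), rep(FALSE, m))
  basis <- (n + 1L):ntot
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  phase <- 1L
  cost <- c(rep(0, n), rep(-1, m))   # maximize -(sum of artificials)

  run_simplex <- function() {
    for (it in seq_len(max_iter)) {
      nonbasic <- which(!is_basic)
      xN <- ifelse(at_ub[nonbasic], U[nonbasic], L[nonbasic])
      B <- Am[, basis, drop = FALSE]
      xB <- tryCatch(
        solve(B, b - Am[, nonbasic, drop = FALSE] %*% xN),
        error = function(e) stop("singular basis in simplex", call. = FALSE))
      xB <- as.vector(xB)
      y <- as.vector(solve(t(B), cost[basis]))
      d <- cost[nonbasic] - as.vector(crossprod(Am[, nonbasic, drop = FALSE], y))
      span <- U[nonbasic] - L[nonbasic]
      elig <- span > tol &
        ((!at_ub[nonbasic] & d > tol) | (at_ub[nonbasic] & d < -tol))
      if (!any(elig)) {
        return(list(basis = basis, xB = xB, converged = TRUE))
      }
      jj <- nonbasic[elig][which.min(nonbasic[elig])]  # Bland: smallest index
      delta <- if (at_ub[jj]) -1 else 1
      w <- as.vector(solve(B, Am[, jj]))
      coef <- delta * w
      lim <- rep(Inf, m)
      dec <- coef > tol
      inc <- coef < -tol
      lim[dec] <- pmax((xB[dec] - L[basis[dec]]) / coef[dec], 0)
      lim[inc] <- pmax((U[basis[inc]] - xB[inc]) / (-coef[inc]), 0)
      t_enter <- U[jj] - L[jj]
      t_star <- min(c(lim, t_enter))
      if (!is.finite(t_star)) {
        return(list(converged = FALSE, unbounded = TRUE))
      }
      if (t_star >= t_enter - tol && is.finite(t_enter)) {
        at_ub[jj] <<- !at_ub[jj]     # bound flip, basis unchanged
        next
      }
      cand <- which(abs(lim - t_star) <= tol)
      ii <- cand[which.min(basis[cand])]  # Bland on the leaving variable
      leave <- basis[ii]
      at_ub[leave] <<- coef[ii] < 0       # hit upper bound if it was rising
      is_basic[leave] <<- FALSE
      is_basic[jj] <<- TRUE
      basis[ii] <<- jj
    }
    stop("simplex iteration limit (", max_iter, ") exceeded", call. = FALSE)
  }

  res1 <- run_simplex()
  if (!isTRUE(res1$converged)) {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  art_val <- rep(0, m)
  bmask <- basis > n
  art_val[basis[bmask] - n] <- res1$xB[bmask]
  if (sum(abs(art_val)) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }

  # phase 2: pin artificials at zero, switch to the real objective
  U[(n + 1L):ntot] <- 0
  cost <- c(cc, rep(0, m))
  res2 <- run_simplex()
  if (!isTRUE(res2$converged)) {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  x <- ifelse(at_ub[seq_len(ntot)], U, L)
  x[res2$basis] <- res2$xB
  x <- x[seq_len(n)]
  # snap tiny bound violations from finite-precision pivoting
  x <- pmin(pmax(x, lb), ub)
  obj <- sum(cc * x)
  list(status = "optimal", x = x,
       objval = if (sense == "min") -obj else obj)
}
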