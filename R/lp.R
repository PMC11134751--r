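#' Solve a bounded linear program
#'
#' Solves `max (or min) c'x  subject to  A x = b,  lb <= x <= ub` with a
#' two-phase bounded-variable primal simplex using Bland's anti-cycling rule.
#' All bounds must be finite; constraint-based models keep every flux inside
#' finite default bounds, so unboundedness cannot arise and every solve
#' terminates with either an optimal vertex or a proof of infeasibility.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m x n`), dense or anything coercible by
#'   `as.matrix()`.
#' @param b right-hand side, length `m`.
#' @param lb,ub finite variable bounds, length `n`.
#' @param direction `"max"` or `"min"`.
#' @param tol feasibility/optimality tolerance on reduced costs and ratios.
#'
#' @return A list with elements `status` (`"optimal"` or `"infeasible"`),
#'   `objective` (numeric, `NA` unless optimal) and `x` (primal solution at an
#'   optimal vertex, `NULL` unless optimal).
#' @export
solve_lp <- function(obj, A, b, lb, ub, direction = c("max", "min"),
                     tol = 1e-9) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite variable bounds", call. = FALSE)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  obj <- if (direction == "max") as.numeric(obj) else -as.numeric(obj)

  ## Phase 1: append one artificial per row, signed so it starts feasible.
  start_at_lb <- abs(lb) <= abs(ub)
  x <- ifelse(start_at_lb, lb, ub)
  r <- b - as.vector(A %*% x)
  Aext <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, abs(r) + 1)           # room to start; shrunk to 0 in phase 2
  status_at_lb <- c(start_at_lb, rep(FALSE, m))  # artificials start basic
  basis <- n + seq_len(m)
  xval <- c(x, abs(r))

  p1 <- c(rep(0, n), rep(-1, m))     # maximize -(sum of artificials)
  res <- simplex_iterate(p1, Aext, b, lbe, ube, basis, xval, tol)
  if (res$unbounded)
    stop("internal LP error: phase 1 unbounded", call. = FALSE)
  if (sum(res$x[n + seq_len(m)]) > 1e-6)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  ## Phase 2: pin artificials at zero (keeps redundant rows harmless).
  ube2 <- c(ub, rep(0, m))
  xv <- res$x
  xv[n + seq_len(m)] <- 0
  p2 <- c(obj, rep(0, m))
  res <- simplex_iterate(p2, Aext, b, lbe, ube2, res$basis, xv, tol)
  if (res$unbounded)
    stop("internal LP error: phase 2 unbounded under finite bounds",
         call. = FALSE)
  xopt <- res$x[seq_len(n)]
  val <- sum(obj * xopt)
  list(status = "optimal",
       objective = if (direction == "max") val else -val,
       x = xopt)
}

## Core bounded-variable simplex loop. `basis` indexes the m basic columns,
## `xval` a basic solution consistent with it; nonbasic variables sit at one
## of their bounds. Maximizes obj'x. Bland's rule on both entering and
## leaving choices guarantees finite termination.
simplex_iterate <- function(obj, A, b, lb, ub, basis, xval, tol) {
  m <- nrow(A)
  n <- ncol(A)
  maxit <- 50L * (n + m) + 5000L
  refresh_basics <- function(basis, xval) {
    ## recompute basic values exactly from the nonbasic bounds, shedding
    ## the numerical drift of incremental pivot updates
    nb <- setdiff(seq_len(n), basis)
    rhs <- b - if (length(nb)) as.vector(A[, nb, drop = FALSE] %*% xval[nb]) else b * 0
    xb <- tryCatch(solve(A[, basis, drop = FALSE], rhs), error = function(e) NULL)
    if (!is.null(xb)) xval[basis] <- xb
    xval
  }
  for (it in seq_len(maxit)) {
    if (it %% 40L == 0L) xval <- refresh_basics(basis, xval)
    in_basis <- logical(n)
    in_basis[basis] <- TRUE
    B <- A[, basis, drop = FALSE]
    Binv_t <- tryCatch(solve(t(B), obj[basis]), error = function(e) NULL)
    if (is.null(Binv_t))
      stop("internal LP error: singular basis", call. = FALSE)
    d <- obj - as.vector(crossprod(A, Binv_t))   # reduced costs

    nb <- which(!in_basis)
    nb <- nb[ub[nb] - lb[nb] > tol]              # fixed vars never move
    at_lb <- abs(xval[nb] - lb[nb]) < abs(xval[nb] - ub[nb])
    improving <- (at_lb & d[nb] > tol) | (!at_lb & d[nb] < -tol)
    if (!any(improving))
      return(list(x = refresh_basics(basis, xval), basis = basis,
                  unbounded = FALSE))
    j <- nb[improving][1L]                       # Bland: smallest index
    sigma <- if (abs(xval[j] - lb[j]) < abs(xval[j] - ub[j])) 1 else -1

    w <- as.vector(solve(B, A[, j]))             # basic response to x_j
    ## step limits: each basic variable hitting a bound, then j's own span
    delta <- -sigma * w
    xb <- xval[basis]
    tmax <- ub[j] - lb[j]
    leave <- 0L                                   # 0 = bound flip of j
    for (k in seq_len(m)) {
      if (delta[k] < -tol) {
        tk <- (xb[k] - lb[basis[k]]) / (-delta[k])
      } else if (delta[k] > tol) {
        tk <- (ub[basis[k]] - xb[k]) / delta[k]
      } else next
      if (tk < tmax - tol ||
          (tk < tmax + tol && leave > 0L && basis[k] < basis[leave])) {
        tmax <- tk
        leave <- k
      }
    }
    tmax <- max(tmax, 0)
    ## apply the step
    xval[basis] <- xb - sigma * tmax * w
    xval[j] <- xval[j] + sigma * tmax
    if (leave > 0L) {
      lv <- basis[leave]
      ## snap the leaving variable exactly onto the bound it hit
      xval[lv] <- if (-sigma * w[leave] < 0) lb[lv] else ub[lv]
      basis[leave] <- j
    } else {
      xval[j] <- if (sigma > 0) ub[j] else lb[j]  # bound-to-bound flip
    }
  }
  stop("internal LP error: simplex iteration limit reached", call. = FALSE)
}
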