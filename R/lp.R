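# Dense two-phase simplex for small linear programs.
#
# Solves  max/min c'v  s.t.  A v = b,  lb <= v <= ub  for the problem sizes
# this package meets (toy-to-desk-scale metabolic models, the proton/water
# repair relaxation). Bounded variables are shifted to x = v - lb >= 0 and
# the upper bounds added as slack rows; Bland's rule makes the pivot sequence
# deterministic and cycle-free. Infinite bounds are capped at a large box and
# a solution pressing against that box is reported as "unbounded".

.LP_BIG <- 1e9
.LP_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' @param obj objective coefficient vector `c`.
#' @param A equality constraint matrix (may have zero rows).
#' @param b right-hand side.
#' @param lb,ub variable bounds (infinities allowed).
#' @param maximize maximize (default) or minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and `x` (solution on the original variable scale).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  A <- matrix(A, ncol = n)
  .check(length(b) == nrow(A), "lp_solve: b does not match A")
  .check(length(lb) == n && length(ub) == n, "lp_solve: bad bounds")
  .check(all(lb <= ub), "lp_solve: lb > ub")

  capped <- !is.finite(lb) | !is.finite(ub)
  lb2 <- pmax(lb, -.LP_BIG)
  ub2 <- pmin(ub, .LP_BIG)

  # shift: x = v - lb2, 0 <= x <= r, A x = b - A lb2
  r <- ub2 - lb2
  b2 <- b - as.numeric(A %*% lb2)

  # standard form: variables [x, s] with x + s = r appended
  m1 <- nrow(A)
  Afull <- rbind(cbind(A, matrix(0, m1, n)),
                 cbind(diag(n), diag(n)))
  bfull <- c(b2, r)
  # make b nonnegative for phase 1
  neg <- bfull < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]
  # run_simplex minimizes its cost vector (entering rule z_j - c_j > 0)
  cfull <- c(if (maximize) -obj else obj, rep(0, n))

  mm <- nrow(Afull); nn <- ncol(Afull)

  # tableau with artificial basis
  Tb <- cbind(Afull, diag(mm), bfull)
  basis <- nn + seq_len(mm)
  ncols <- nn + mm

  run_simplex <- function(Tb, basis, cost, ncols_active) {
    repeat {
      cb <- cost[basis]
      # reduced costs (minimization): z_j - c_j
      red <- as.numeric(cb %*% Tb[, seq_len(ncols_active), drop = FALSE]) -
        cost[seq_len(ncols_active)]
      enter <- which(red > .LP_TOL)
      if (!length(enter)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- min(enter)                       # Bland
      col <- Tb[, j]
      pos <- which(col > .LP_TOL)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratios <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + .LP_TOL]
      i <- cand[which.min(basis[cand])]     # Bland tie-break
      # pivot on (i, j)
      Tb[i, ] <- Tb[i, ] / Tb[i, j]
      for (k in seq_len(nrow(Tb))) {
        if (k != i && abs(Tb[k, j]) > 0)
          Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
      }
      basis[i] <- j
    }
  }

  # phase 1: minimize the sum of artificials
  cost1 <- c(rep(0, nn), rep(1, mm))
  res1 <- run_simplex(Tb, basis, cost1, ncols)
  Tb <- res1$Tb; basis <- res1$basis
  p1 <- sum(Tb[basis > nn, ncol(Tb)])
  if (p1 > 1e-6) return(list(status = "infeasible", objective = NA_real_,
                             x = rep(NA_real_, n)))
  # drive lingering artificials out of the basis where possible
  for (i in which(basis > nn)) {
    row <- Tb[i, seq_len(nn)]
    j <- which(abs(row) > .LP_TOL)
    if (length(j)) {
      j <- min(j)
      Tb[i, ] <- Tb[i, ] / Tb[i, j]
      for (k in seq_len(nrow(Tb)))
        if (k != i && abs(Tb[k, j]) > 0) Tb[k, ] <- Tb[k, ] - Tb[k, j] * Tb[i, ]
      basis[i] <- j
    }
  }

  # phase 2 on original columns only; artificials cannot re-enter (they are
  # outside the active column range) and any left basic sit at value 0 on
  # redundant rows, so their phase-2 cost is immaterial
  cost2 <- c(cfull, rep(0, mm))
  res2 <- run_simplex(Tb, basis, cost2, nn)
  Tb <- res2$Tb; basis <- res2$basis
  if (res2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))

  xfull <- numeric(ncols)
  xfull[basis] <- Tb[, ncol(Tb)]
  x <- xfull[seq_len(n)] + lb2
  objective <- sum(obj * x)

  # a solution pressing against the artificial box means the true LP is
  # unbounded in that direction
  pressed <- (capped & (abs(x - lb2) < 1e-3 & !is.finite(lb))) |
             (capped & (abs(x - ub2) < 1e-3 & !is.finite(ub)))
  if (any(pressed))
    return(list(status = "unbounded", objective = objective, x = x))

  list(status = "optimal", objective = objective, x = x)
}
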