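## Dense bounded-variable two-phase primal simplex.
##
## Solves  min c'x  s.t.  A x = b,  lb <= x <= ub  with all bounds finite.
## This is the LP kernel behind solve_fba(); FBA problems here are small
## (tens of variables), so a dense basis solve per iteration is cheap and
## numerically transparent. Anti-cycling: Dantzig pricing switches to
## Bland's rule after a stall. Basic solutions are recomputed from the
## basis every iteration, so there is no accumulated update drift.

lp_solve <- function(cc, A, b, lb, ub, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(lb) == n,
            length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    stop("lp_solve: lower bound exceeds upper bound")

  ## start with structural variables nonbasic at the bound nearest zero,
  ## artificials basic carrying the residual
  at_ub <- abs(ub) < abs(lb)
  x0 <- ifelse(at_ub, ub, lb)
  r <- as.numeric(b - A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, m, m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  status <- c(ifelse(at_ub, 1L, 0L), rep(2L, m)) # 0 at lb, 1 at ub, 2 basic
  basis <- n + seq_len(m)

  core <- function(cost, basis, status, uba) {
    iter <- 0L
    bland <- FALSE
    last_obj <- Inf
    stall <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxit)
        return(list(code = "maxit"))
      B <- Aa[, basis, drop = FALSE]
      nonbasic <- which(status != 2L)
      xN <- ifelse(status[nonbasic] == 1L, uba[nonbasic], lba[nonbasic])
      rhs <- b - if (length(nonbasic))
        as.numeric(Aa[, nonbasic, drop = FALSE] %*% xN) else 0
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(xB) || is.null(y))
        return(list(code = "singular"))
      obj <- sum(cost[basis] * xB) + sum(cost[nonbasic] * xN)
      if (obj < last_obj - tol) {
        last_obj <- obj
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall > 2L * (n + m)) bland <- TRUE
      }

      d <- cost[nonbasic] -
        as.numeric(crossprod(Aa[, nonbasic, drop = FALSE], y))
      improving <- (status[nonbasic] == 0L & d < -tol) |
                   (status[nonbasic] == 1L & d > tol)
      if (!any(improving))
        return(list(code = "optimal", basis = basis, status = status,
                    xB = xB))
      cand <- nonbasic[improving]
      j <- if (bland) min(cand) else cand[which.max(abs(d[improving]))]
      dirj <- if (status[j] == 0L) 1 else -1
      w <- as.numeric(solve(B, Aa[, j]))
      delta <- -dirj * w                      # xB change per unit step
      tmax <- uba[j] - lba[j]                 # bound-flip limit
      leave <- 0L
      leave_to <- NA_integer_
      for (i in seq_len(m)) {
        if (delta[i] > tol) {
          t_i <- (uba[basis[i]] - xB[i]) / delta[i]
          if (t_i < tmax - 1e-12) {
            tmax <- t_i; leave <- i; leave_to <- 1L
          }
        } else if (delta[i] < -tol) {
          t_i <- (lba[basis[i]] - xB[i]) / delta[i]
          if (t_i < tmax - 1e-12) {
            tmax <- t_i; leave <- i; leave_to <- 0L
          }
        }
      }
      if (!is.finite(tmax))
        return(list(code = "unbounded"))
      if (leave == 0L) {
        status[j] <- if (status[j] == 0L) 1L else 0L
      } else {
        status[basis[leave]] <- leave_to
        status[j] <- 2L
        basis[leave] <- j
      }
    }
  }

  ## phase 1: drive artificial infeasibility to zero
  r1 <- core(c(rep(0, n), rep(1, m)), basis, status, uba)
  if (r1$code != "optimal")
    return(list(status = paste0("phase1_", r1$code)))
  xf <- numeric(n + m)
  nb <- which(r1$status != 2L)
  xf[nb] <- ifelse(r1$status[nb] == 1L, uba[nb], lba[nb])
  xf[r1$basis] <- r1$xB
  if (sum(xf[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible"))

  ## phase 2: pin artificials at zero, optimize the true objective
  uba2 <- uba
  uba2[n + seq_len(m)] <- 0
  stat <- r1$status
  art <- n + seq_len(m)
  stat[art][stat[art] == 1L] <- 0L
  r2 <- core(c(cc, rep(0, m)), r1$basis, stat, uba2)
  if (r2$code != "optimal")
    return(list(status = paste0("phase2_", r2$code)))
  xfull <- numeric(n + m)
  nb <- which(r2$status != 2L)
  xfull[nb] <- ifelse(r2$status[nb] == 1L, uba2[nb], lba[nb])
  xfull[r2$basis] <- r2$xB
  x <- xfull[seq_len(n)]
  ## snap to bounds within tolerance
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, objective = sum(cc * x))
}
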