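#' Bounded-variable two-phase simplex
#'
#' Solves the linear program
#' \deqn{\min_x\; c^\top x \quad \mathrm{s.t.}\quad A x = b,\; l \le x \le u}
#' with a dense, two-phase primal simplex that keeps variable bounds implicit
#' (non-basic variables rest at a bound instead of being split into slack
#' rows).  Phase 1 drives artificial variables out of the basis; phase 2
#' optimises the supplied objective.  Entering variables are chosen by the
#' Dantzig rule with an automatic switch to Bland's rule once the iteration
#' count suggests degenerate cycling, which guarantees termination.
#'
#' This routine exists because the flux-analysis layer needs a deterministic,
#' dependency-free solver for problems of a few hundred variables; it is not
#' intended for genome-scale matrices.
#'
#' @param obj numeric objective coefficients (length \code{ncol(A)}).
#' @param A dense or sparse constraint matrix; coerced to base matrix.
#' @param b right-hand side of the equality constraints.
#' @param lb,ub variable bounds; every lower bound must be finite, upper
#'   bounds may be \code{Inf}.
#' @param tol numerical tolerance on reduced costs and ratio tests.
#' @param feas_tol feasibility tolerance applied to the phase-1 objective.
#' @param max_iter iteration cap across both phases.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"} or \code{"maxiter"}), \code{x} (primal solution, or
#'   \code{NULL} when not optimal) and \code{objective}.
#' @keywords internal
simplex_solve <- function(obj, A, b, lb, ub,
                          tol = 1e-9, feas_tol = 1e-7, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("simplex_solve() requires finite lower bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  ub <- pmax(ub, lb)

  ## augmented system with one artificial column per row
  r0 <- as.vector(b - A %*% lb)
  s <- ifelse(r0 >= 0, 1, -1)
  Afull <- cbind(A, diag(s, nrow = m))
  N <- n + m
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))

  ## status: 0 basic, 1 at lower bound, 2 at upper bound
  status <- c(rep(1L, n), rep(0L, m))
  basis <- (n + 1L):N

  nonbasic_values <- function() {
    x <- numeric(N)
    at_l <- status == 1L; at_u <- status == 2L
    x[at_l] <- lbf[at_l]; x[at_u] <- ubf[at_u]
    x
  }

  run_phase <- function(cost, iter_used) {
    iter <- iter_used
    bland <- FALSE
    no_progress <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        return(list(code = "maxiter", iter = iter))
      B <- Afull[, basis, drop = FALSE]
      xN <- nonbasic_values()
      rhs <- b - Afull %*% xN
      ok <- TRUE
      xB <- tryCatch(solve(B, rhs), error = function(e) { ok <<- FALSE; NULL })
      if (!ok) return(list(code = "singular", iter = iter))
      xB <- as.vector(xB)
      y <- as.vector(solve(t(B), cost[basis]))
      d <- cost - as.vector(crossprod(Afull, y))

      fixed <- (ubf - lbf) <= tol
      cand <- which((status == 1L & d < -tol & !fixed) |
                    (status == 2L & d >  tol & !fixed))
      if (!length(cand))
        return(list(code = "optimal", iter = iter))
      if (!bland && no_progress > 2L * N) bland <- TRUE
      e <- if (bland) min(cand) else cand[which.max(abs(d[cand]))]
      sigma <- if (status[e] == 1L) 1 else -1

      w <- as.vector(solve(B, Afull[, e]))
      wt <- sigma * w
      lB <- lbf[basis]; uB <- ubf[basis]
      ratio <- rep(Inf, m)
      up <- wt > tol; dn <- wt < -tol
      ratio[up] <- (xB[up] - lB[up]) / wt[up]
      ratio[dn] <- (xB[dn] - uB[dn]) / wt[dn]
      ratio[ratio < 0] <- 0           # degenerate: do not step backwards
      t_flip <- ubf[e] - lbf[e]
      t_min <- min(ratio, t_flip)
      if (!is.finite(t_min))
        return(list(code = "unbounded", iter = iter))

      no_progress <- if (t_min <= tol) no_progress + 1L else 0L

      if (t_flip <= t_min + tol && t_flip <= min(ratio)) {
        ## bound flip: entering variable crosses to its other bound
        status[e] <<- if (status[e] == 1L) 2L else 1L
        next
      }
      ties <- which(ratio <= t_min + tol)
      leave <- if (bland) ties[which.min(basis[ties])]
               else ties[which.max(abs(wt[ties]))]
      leaving_var <- basis[leave]
      hit_lower <- wt[leave] > 0
      status[leaving_var] <<- if (hit_lower) 1L else 2L
      status[e] <<- 0L
      basis[leave] <<- e
    }
  }

  ## phase 1: minimise the artificial mass
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, 0L)
  if (ph1$code %in% c("maxiter", "singular"))
    return(list(status = ph1$code, x = NULL, objective = NA_real_))
  xN <- nonbasic_values()
  B <- Afull[, basis, drop = FALSE]
  xB <- as.vector(solve(B, b - Afull %*% xN))
  xfull <- xN; xfull[basis] <- xB
  scale1 <- max(1, max(abs(b)))
  if (sum(xfull[(n + 1L):N]) > feas_tol * scale1)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  ## phase 2: pin artificials to zero and optimise the real objective
  ubf[(n + 1L):N] <- 0
  cost2 <- c(obj, rep(0, m))
  ph2 <- run_phase(cost2, ph1$iter)
  if (ph2$code %in% c("maxiter", "singular", "unbounded"))
    return(list(status = if (ph2$code == "singular") "maxiter" else ph2$code,
                x = NULL, objective = NA_real_))

  xN <- nonbasic_values()
  B <- Afull[, basis, drop = FALSE]
  xB <- as.vector(solve(B, b - Afull %*% xN))
  xfull <- xN; xfull[basis] <- xB
  x <- xfull[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(obj * x))
}
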