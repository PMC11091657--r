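#' Linear-programming problem description
#'
#' The flux-analysis routines (FBA, parsimonious FBA, least-absolute-deviation
#' fitting) all reduce to linear programs.  They are expressed through this
#' small solver-agnostic container and handed to a pluggable backend, so that
#' the same problem can be solved by two independent implementations and the
#' results compared.
#'
#' Rows may be equalities or inequalities; inequalities are canonicalised to
#' equalities with slack variables before a backend sees the problem.
#'
#' @param objective numeric vector of objective coefficients.
#' @param A constraint matrix (dense or \pkg{Matrix} sparse), one row per
#'   constraint.
#' @param rhs right-hand-side vector.
#' @param lb,ub variable bounds (recycled if scalar).
#' @param sense character vector of row senses, each one of \code{"="},
#'   \code{"<="}, \code{">="}; defaults to all equalities.
#' @param maximize logical; maximise instead of minimise.
#' @param var_names optional variable names carried through to the solution.
#' @return object of class \code{lp_problem}.
#' @export
lp_problem <- function(objective, A, rhs, lb, ub,
                       sense = rep("=", length(rhs)),
                       maximize = FALSE, var_names = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  stopifnot(length(objective) == n, length(rhs) == nrow(A),
            length(sense) == nrow(A), all(sense %in% c("=", "<=", ">=")))
  structure(list(objective = as.numeric(objective), A = A,
                 rhs = as.numeric(rhs), lb = lb, ub = ub,
                 sense = as.character(sense), maximize = isTRUE(maximize),
                 var_names = var_names),
            class = "lp_problem")
}

## canonical equality form: append one slack column per inequality row
lp_canonical <- function(lp, big = 1e7) {
  ineq <- which(lp$sense != "=")
  A <- lp$A; obj <- lp$objective; lb <- lp$lb; ub <- lp$ub
  if (length(ineq)) {
    Sl <- matrix(0, nrow(A), length(ineq))
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      Sl[i, k] <- if (lp$sense[i] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, length(ineq)))
    lb <- c(lb, rep(0, length(ineq)))
    ub <- c(ub, rep(Inf, length(ineq)))
  }
  ## finite lower bounds are required by the simplex core; genuinely free
  ## variables are boxed at +-big, far outside any flux scale used here
  lb[!is.finite(lb)] <- -big
  if (lp$maximize) obj <- -obj
  list(obj = obj, A = A, b = lp$rhs, lb = lb, ub = ub,
       n_orig = ncol(lp$A), flip = lp$maximize)
}

#' Solve a linear program through a pluggable backend
#'
#' @param lp an [lp_problem()].
#' @param backend \code{"simplex"} for the built-in bounded-variable simplex
#'   or \code{"highs"} for SciPy's HiGHS solver run through the system
#'   \command{python} (used in the test-suite as an independent
#'   cross-check).  The default can be set via
#'   \code{options(fluxgaba.lp_backend = ...)}.
#' @param tol numerical tolerance forwarded to the backend.
#' @return list with \code{status}, \code{x} (named when the problem carries
#'   variable names) and \code{objective} on the original (pre-negation)
#'   scale.
#' @export
solve_lp <- function(lp, backend = getOption("fluxgaba.lp_backend", "simplex"),
                     tol = 1e-9) {
  stopifnot(inherits(lp, "lp_problem"))
  backend <- match.arg(backend, c("simplex", "highs"))
  cn <- lp_canonical(lp)
  res <- switch(backend,
                simplex = simplex_solve(cn$obj, cn$A, cn$b, cn$lb, cn$ub,
                                        tol = tol),
                highs = highs_solve(cn$obj, cn$A, cn$b, cn$lb, cn$ub))
  out <- list(status = res$status, x = NULL, objective = NA_real_,
              backend = backend)
  if (identical(res$status, "optimal")) {
    x <- res$x[seq_len(cn$n_orig)]
    if (!is.null(lp$var_names)) names(x) <- lp$var_names
    out$x <- x
    out$objective <- if (cn$flip) -res$objective else res$objective
  }
  out
}

## SciPy/HiGHS backend over a python subprocess (JSON on stdin/stdout)
highs_solve <- function(obj, A, b, lb, ub) {
  script <- system.file("python", "solve_lp.py", package = "fluxgaba")
  if (script == "" || Sys.which("python") == "")
    stop("the 'highs' backend needs the bundled python helper and a python ",
         "interpreter with scipy on the PATH")
  nz <- which(A != 0, arr.ind = TRUE)
  payload <- jsonlite::toJSON(list(
    obj = obj, m = nrow(A), n = ncol(A),
    i = nz[, 1] - 1L, j = nz[, 2] - 1L, x = A[nz],
    b = b, lb = lb, ub = ub), digits = NA, auto_unbox = FALSE,
    null = "null", na = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(payload, tmp)
  out <- suppressWarnings(system2("python", shQuote(script), stdin = tmp,
                                  stdout = TRUE, stderr = FALSE))
  st <- attr(out, "status")
  if (!is.null(st) && st != 0)
    stop("python LP helper exited with status ", st)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  list(status = res$status,
       x = if (identical(res$status, "optimal")) as.numeric(res$x) else NULL,
       objective = if (identical(res$status, "optimal"))
         as.numeric(res$objective) else NA_real_)
}
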