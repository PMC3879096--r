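#' Solve a linear program
#'
#' Thin interface to the package's dense two-phase simplex.  All LP work in
#' the package (flux variability analysis, feasibility filters, Farkas
#' certificate checks, MILP relaxations) goes through this function.
#'
#' @param obj numeric objective coefficients, length \code{ncol(mat)}.
#' @param mat constraint matrix (dense numeric).
#' @param dir character vector of row senses: \code{"<="}, \code{"="},
#'   \code{">="}.
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed (default:
#'   free variables).
#' @param maximize logical; maximize instead of minimize.
#' @return A list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"maxiter"}),
#'   \code{x} (primal solution or \code{NULL}) and \code{objval}.
#' @examples
#' # max x1 + x2 s.t. x1 + 2 x2 <= 4, x1 <= 3, x >= 0
#' solve_lp(c(1, 1), rbind(c(1, 2), c(1, 0)), c("<=", "<="), c(4, 3),
#'          lb = c(0, 0), maximize = TRUE)
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb = rep(-Inf, length(obj)),
                     ub = rep(Inf, length(obj)), maximize = FALSE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  n <- ncol(mat)
  stopifnot(length(obj) == n, nrow(mat) == length(rhs),
            length(dir) == length(rhs))
  if (length(lb) == 1L) lb <- rep(lb, n)
  if (length(ub) == 1L) ub <- rep(ub, n)
  stopifnot(length(lb) == n, length(ub) == n)
  dcode <- match(dir, c("<=", "=", ">="))
  if (anyNA(dcode)) stop("row senses must be one of '<=', '=', '>='")
  res <- .cpp_lp_solve(as.double(obj), mat, as.integer(dcode - 2L),
                       as.double(rhs), as.double(lb), as.double(ub),
                       isTRUE(maximize))
  status <- c("optimal", "infeasible", "unbounded", "maxiter")[res$status + 1L]
  list(status = status, x = res$x, objval = res$objval)
}

#' Test feasibility of a linear system
#'
#' @inheritParams solve_lp
#' @return \code{TRUE}, \code{FALSE}, or \code{NA} if the solver failed
#'   numerically (iteration limit).
#' @keywords internal
lp_feasible <- function(mat, dir, rhs, lb = rep(-Inf, ncol(mat)),
                        ub = rep(Inf, ncol(mat))) {
  res <- solve_lp(rep(0, ncol(mat)), mat, dir, rhs, lb, ub)
  switch(res$status,
         optimal = TRUE, unbounded = TRUE,
         infeasible = FALSE,
         NA)
}
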