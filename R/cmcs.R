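#' Is a cut set a constrained MCS?
#'
#' A cut set qualifies as a constrained MCS when, with its reactions
#' removed, the steady-state system intersected with the desired flux
#' polyhedron is still feasible — one LP per cut set.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param desired a \code{\link{flux_constraints}} describing the
#'   behaviours of which at least one must remain possible.
#' @param cutset character vector of reaction ids.
#' @return \code{TRUE}/\code{FALSE}; an LP numerical failure raises an
#'   error rather than silently passing the cut set.
#' @export
is_cmcs <- function(net, desired, cutset) {
  lpd <- network_lp(net, constraints = desired, fix_zero = cutset)
  feas <- lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub)
  if (is.na(feas))
    stop("LP did not converge while testing cut set {",
         paste(cutset, collapse = ","), "}: result indeterminate")
  feas
}

#' Filter cut sets against a desired flux polyhedron
#'
#' Keeps exactly those cut sets that leave the desired polyhedron
#' non-empty, preserving the input order.
#'
#' @inheritParams is_cmcs
#' @param cutsets list of character vectors.
#' @return The retained sublist, with attribute \code{"cmcs"} set to
#'   \code{TRUE} entries for bookkeeping.
#' @export
filter_cmcs <- function(net, desired, cutsets) {
  keep <- vapply(cutsets, function(cs) is_cmcs(net, desired, cs), TRUE)
  out <- cutsets[keep]
  attr(out, "tested") <- length(cutsets)
  out
}

#' Strain-design performance metrics for a cut set
#'
#' Evaluates a knockout strategy on the bounded model (flux bounds of
#' \code{net} are honoured): the mutant's maximal growth rate, its
#' guaranteed (minimal) product yield at the stated maximal substrate
#' uptake, and the substrate-specific productivity (SSP), the product of
#' growth rate and product yield, evaluated at the mutant's
#' maximum-growth flux state.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param cutset character vector of reaction ids (may be empty for the
#'   unmodified network).
#' @param product_rxn,substrate_rxn,growth_rxn reaction ids of the
#'   product-forming, substrate-uptake and biomass reactions.  Substrate
#'   uptake is measured as a non-negative uptake-direction flux of
#'   \code{substrate_rxn}.
#' @param uptake_limit maximal substrate uptake rate (e.g. mmol/gDW/h).
#' @param extra optional additional \code{\link{flux_constraints}}
#'   (maintenance demands, medium limits).
#' @return A list of class \code{cutset_evaluation}: \code{feasible},
#'   \code{max_growth}, \code{min_guaranteed_yield}, \code{ssp}.
#' @export
evaluate_cutset <- function(net, cutset, product_rxn, substrate_rxn,
                            growth_rxn, uptake_limit, extra = NULL) {
  n <- n_rxn(net)
  jp <- rxn_index(net, product_rxn)
  js <- rxn_index(net, substrate_rxn)
  jg <- rxn_index(net, growth_rxn)
  lpd <- network_lp(net, constraints = extra, fix_zero = cutset)
  # uptake-direction flux capped at the stated limit
  cap <- rep(0, n); cap[js] <- 1
  mat <- rbind(lpd$mat, cap)
  dir <- c(lpd$dir, "<=")
  rhs <- c(lpd$rhs, uptake_limit)
  objg <- rep(0, n); objg[jg] <- 1
  g <- solve_lp(objg, mat, dir, rhs, lpd$lb, lpd$ub, maximize = TRUE)
  if (g$status == "infeasible")
    return(structure(list(feasible = FALSE, max_growth = NA_real_,
                          min_guaranteed_yield = NA_real_, ssp = NA_real_),
                     class = "cutset_evaluation"))
  max_growth <- if (g$status == "optimal") g$objval else Inf
  # guaranteed yield: minimal product flux at full substrate uptake
  matf <- rbind(mat, cap)
  dirf <- c(dir, "=")
  rhsf <- c(rhs, uptake_limit)
  objp <- rep(0, n); objp[jp] <- 1
  y <- solve_lp(objp, matf, dirf, rhsf, lpd$lb, lpd$ub, maximize = FALSE)
  min_yield <- if (y$status == "optimal") y$objval / uptake_limit else NA_real_
  # SSP at the mutant's maximum-growth state: fix growth, take the
  # guaranteed (minimal) yield there
  ssp <- NA_real_
  if (is.finite(max_growth) && !is.na(min_yield)) {
    fixg <- rep(0, n); fixg[jg] <- 1
    matg <- rbind(matf, fixg)
    dirg <- c(dirf, ">=")
    rhsg <- c(rhsf, max_growth - 1e-9)
    yg <- solve_lp(objp, matg, dirg, rhsg, lpd$lb, lpd$ub, maximize = FALSE)
    if (yg$status == "optimal")
      ssp <- max_growth * (yg$objval / uptake_limit)
  }
  structure(list(feasible = TRUE, max_growth = max_growth,
                 min_guaranteed_yield = min_yield, ssp = ssp),
            class = "cutset_evaluation")
}

#' @export
print.cutset_evaluation <- function(x, ...) {
  if (!x$feasible) {
    cat("cutset_evaluation: infeasible mutant\n")
  } else {
    cat(sprintf("cutset_evaluation: max growth %.4g, guaranteed yield %.4g, SSP %.4g\n",
                x$max_growth, x$min_guaranteed_yield, x$ssp))
  }
  invisible(x)
}

#' Tabulate cut sets with evaluation columns
#'
#' @param cutsets list of character vectors.
#' @param cmcs optional logical vector (constrained status).
#' @param evaluations optional list of \code{cutset_evaluation}s.
#' @return data frame with one row per cut set: members (pipe-separated),
#'   size, cmcs flag and metrics; ordered by size then lexicographically.
#' @export
cutset_table <- function(cutsets, cmcs = NULL, evaluations = NULL) {
  members <- vapply(cutsets, function(cs) paste(sort(cs), collapse = "|"), "")
  tab <- data.frame(members = members, size = lengths(cutsets))
  tab$cmcs <- if (is.null(cmcs)) NA else as.integer(cmcs)
  if (!is.null(evaluations)) {
    tab$max_growth <- vapply(evaluations, function(e) e$max_growth, 0)
    tab$min_guaranteed_yield <-
      vapply(evaluations, function(e) e$min_guaranteed_yield, 0)
    tab$ssp <- vapply(evaluations, function(e) e$ssp, 0)
  }
  tab[order(tab$size, tab$members), , drop = FALSE]
}

#' Linearized minimal-yield target rows
#'
#' A yield demand \eqn{product/substrate \ge Y} is not linear in the
#' fluxes; the standard linearization \eqn{product - Y \cdot uptake \ge 0}
#' is, with uptake measured as a non-negative uptake-direction flux.  To
#' \emph{target} all low-yield behaviours (yield below \code{y_min}) use
#' \code{sense = "<="} on the returned row's yield, i.e. the row
#' \eqn{product - y_{min} uptake \le -\epsilon}; to \emph{desire}
#' high-yield behaviour use the opposite row.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param product_rxn,substrate_rxn reaction ids.
#' @param y_min the yield threshold (mol product per mol substrate).
#' @param direction \code{"target_low_yield"} or
#'   \code{"desire_high_yield"}.
#' @param eps strict-inequality margin for the target form.
#' @return A one-row \code{\link{flux_constraints}}.
#' @export
yield_constraint <- function(net, product_rxn, substrate_rxn, y_min,
                             direction = c("target_low_yield",
                                           "desire_high_yield"),
                             eps = 1e-3) {
  direction <- match.arg(direction)
  M <- matrix(0, 1, 2, dimnames = list(NULL, c(product_rxn, substrate_rxn)))
  M[1, 1] <- 1; M[1, 2] <- -y_min
  if (direction == "target_low_yield")
    flux_constraints(M, rhs = -eps, dir = "<=", label = "target")
  else
    flux_constraints(M, rhs = 0, dir = ">=", label = "desired")
}
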