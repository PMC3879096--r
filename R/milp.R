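#' Enumeration configuration
#'
#' Settings shared by the elementary-mode and cut-set enumeration engines.
#'
#' @param algorithm \code{"fixed_size"} (find the smallest support size,
#'   then enumerate size class by size class as pure feasibility problems)
#'   or \code{"iterative"} (repeatedly minimize the support size, adding
#'   one integer cut per solution).
#' @param size_lb,size_ub inclusive bounds on the support size.
#' @param max_solutions stop after this many solutions.
#' @param time_limit_s wall-clock budget; on expiry the current size class
#'   is flagged incomplete.
#' @param mode \code{"indicator"} (exact binary-continuous links enforced
#'   by branching) or \code{"bigM"} (links emulated by big-M rows in the
#'   relaxation).  Both modes return identical families; big-M is the
#'   classic fallback for backends without indicator support.
#' @param big_m the big-M constant (only used in \code{"bigM"} mode).  It
#'   must exceed the dynamic range of the dual certificates; the default
#'   of 1e3 keeps the link rows well conditioned for the bundled dense
#'   simplex backend.
#' @param threshold the activity threshold c > 0 linking a binary to its
#'   continuous variable; solutions are scale-invariant, so c = 1 is safe.
#' @param threads,seed kept for interface compatibility; the bundled
#'   branch-and-bound backend is single-threaded and deterministic.
#' @return A list of class \code{enumeration_config}.
#' @export
enumeration_config <- function(algorithm = c("fixed_size", "iterative"),
                               size_lb = 1L, size_ub = NULL,
                               max_solutions = Inf, time_limit_s = Inf,
                               mode = c("indicator", "bigM"),
                               big_m = 1e3, threshold = 1,
                               threads = 1L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  stopifnot(size_lb >= 1L, is.null(size_ub) || size_ub >= size_lb,
            threshold > 0, big_m > threshold)
  structure(list(algorithm = algorithm, size_lb = as.integer(size_lb),
                 size_ub = size_ub, max_solutions = max_solutions,
                 time_limit_s = time_limit_s, mode = mode, big_m = big_m,
                 threshold = threshold, threads = as.integer(threads),
                 seed = as.integer(seed)),
            class = "enumeration_config")
}

#' Attach indicator binaries to a continuous system
#'
#' Builds the MILP skeleton used by both enumeration modes: one binary per
#' designated continuous column with the link semantics
#' \code{binary = 1  <=>  continuous >= threshold},
#' \code{binary = 0  <=>  continuous = 0},
#' plus a mutual-exclusion row \code{sum of member binaries <= 1} for every
#' multi-member group (forward/backward split pairs in elementary-mode
#' search, \code{vp}/\code{vn} pairs in the dual cut-set search).
#'
#' @param A,dir,rhs,lb,ub the continuous LP blocks (columns must include
#'   every linked column; linked columns must be non-negative).
#' @param link_cols integer indices of continuous columns that receive a
#'   binary.
#' @param groups named list of integer vectors over \code{link_cols}
#'   values; each group is one support unit (a reaction).  Singleton
#'   groups are allowed.
#' @param pairs list of 2-vectors of \code{link_cols} values that may not
#'   be active simultaneously (forward/backward directions, \code{vp}/
#'   \code{vn} pairs); each adds a row \code{z_s + z_t <= 1}.
#' @param threshold activity threshold c.
#' @return An object of class \code{milp_system}.
#' @export
attach_indicators <- function(A, dir, rhs, lb, ub, link_cols, groups,
                              pairs = list(), threshold = 1) {
  stopifnot(all(lb[link_cols] >= 0))
  nb <- length(link_cols)
  bin_of_col <- stats::setNames(seq_len(nb), link_cols)
  grp_bins <- lapply(groups, function(g) unname(bin_of_col[as.character(g)]))
  excl <- NULL
  for (p in pairs) {
    row <- rep(0, nb); row[unname(bin_of_col[as.character(p)])] <- 1
    excl <- rbind(excl, row)
  }
  structure(list(A = A, dir = dir, rhs = rhs, lb = lb, ub = ub,
                 link_cols = link_cols, threshold = threshold,
                 groups = grp_bins,
                 bin_rows = list(mat = excl,
                                 dir = rep("<=", NROW(excl)),
                                 rhs = rep(1, NROW(excl))),
                 n_bin = nb),
            class = "milp_system")
}

# append a row over the binaries
add_binary_row <- function(sys, row, dir, rhs) {
  sys$bin_rows$mat <- rbind(sys$bin_rows$mat, row)
  sys$bin_rows$dir <- c(sys$bin_rows$dir, dir)
  sys$bin_rows$rhs <- c(sys$bin_rows$rhs, rhs)
  sys
}

#' Add an integer-cut (exclusion) constraint
#'
#' Forbids a previously found support and all of its supersets: the sum of
#' the binaries representing the support's units must stay at or below
#' \code{|support| - 1}.  In the dual cut-set search a unit is represented
#' by its whole \code{vp}/\code{vn} indicator pair, so both signs of the
#' dual variable count towards membership.
#'
#' @param sys a \code{milp_system}.
#' @param support integer vector of group indices (into \code{sys$groups}).
#' @return The augmented \code{milp_system}.
#' @export
add_exclusion_constraint <- function(sys, support) {
  if (length(support) == 0L) stop("empty support cannot be excluded")
  row <- rep(0, sys$n_bin)
  for (g in support) row[sys$groups[[g]]] <- 1
  add_binary_row(sys, row, "<=", length(support) - 1)
}

# -- branch and bound --------------------------------------------------------

# Assemble the node LP.  Columns: continuous block then binaries.
# In bigM mode the link rows  x - M z <= 0  and  x - c z >= 0  are part of
# the relaxation; in indicator mode links act through bounds once fixed.
milp_node_lp <- function(sys, mode, big_m) {
  nc <- ncol(sys$A); nb <- sys$n_bin
  nrow_cont <- nrow(sys$A)
  nrow_bin <- NROW(sys$bin_rows$mat)
  nrow_link <- if (mode == "bigM") 2L * nb else 0L
  A <- matrix(0, nrow_cont + nrow_bin + nrow_link, nc + nb)
  A[seq_len(nrow_cont), seq_len(nc)] <- sys$A
  dir <- sys$dir; rhs <- sys$rhs
  if (nrow_bin > 0) {
    A[nrow_cont + seq_len(nrow_bin), nc + seq_len(nb)] <- sys$bin_rows$mat
    dir <- c(dir, sys$bin_rows$dir)
    rhs <- c(rhs, sys$bin_rows$rhs)
  }
  if (nrow_link > 0) {
    for (j in seq_len(nb)) {
      r1 <- nrow_cont + nrow_bin + 2L * j - 1L
      A[r1, sys$link_cols[j]] <- 1; A[r1, nc + j] <- -big_m      # x <= M z
      A[r1 + 1L, sys$link_cols[j]] <- 1
      A[r1 + 1L, nc + j] <- -sys$threshold                       # x >= c z
    }
    dir <- c(dir, rep(c("<=", ">="), nb))
    rhs <- c(rhs, rep(0, 2L * nb))
  }
  list(A = A, dir = dir, rhs = rhs, nc = nc, nb = nb)
}

# Depth-first branch and bound over the binaries.
#   objective = "min": minimize sum of binaries, return one optimum.
#   objective = "feasible": return the first fully-fixed feasible solution.
# Returns list(status, z, x, objval). Deterministic: branch variable is the
# unfixed binary with the largest linked continuous value, ties by index;
# the z = 1 child is explored first.
milp_bb <- function(sys, mode = "indicator", big_m = 1e5,
                    objective = "min", deadline = Inf) {
  node <- milp_node_lp(sys, mode, big_m)
  nc <- node$nc; nb <- node$nb
  obj <- c(rep(0, nc), rep(1, nb))
  lb0 <- c(sys$lb, rep(0, nb))
  ub0 <- c(sys$ub, rep(1, nb))
  best <- list(status = "infeasible", z = NULL, x = NULL, objval = Inf)
  intol <- 1e-6
  stack <- list(list(lb = lb0, ub = ub0, fixed = rep(NA, nb)))
  while (length(stack) > 0L) {
    if (is.finite(deadline) && Sys.time() > deadline)
      return(c(best, list(timed_out = TRUE)))
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    res <- solve_lp(obj, node$A, node$dir, node$rhs, nd$lb, nd$ub)
    if (res$status == "infeasible") next
    if (res$status != "optimal") {
      warning("LP relaxation did not converge; node dropped")
      next
    }
    # all attainable objective values are integers, so the bound can be
    # rounded up with a tolerance well above LP noise
    if (objective == "min" && res$objval > best$objval - 1 + 1e-2) next
    zrel <- res$x[nc + seq_len(nb)]
    xrel <- res$x[seq_len(nc)]
    unfixed <- which(is.na(nd$fixed))
    done <- if (mode == "bigM") {
      all(abs(zrel - round(zrel)) <= intol)
    } else {
      length(unfixed) == 0L
    }
    if (done) {
      z <- as.integer(round(zrel))
      val <- sum(z)
      if (objective == "feasible") {
        return(list(status = "optimal", z = z, x = xrel, objval = val))
      }
      if (val < best$objval - intol) {
        best <- list(status = "optimal", z = z, x = xrel, objval = val)
      }
      next
    }
    # branch: unfixed binary whose continuous partner is most active
    act <- xrel[sys$link_cols[unfixed]]
    if (mode == "bigM") {
      frac <- abs(zrel[unfixed] - round(zrel[unfixed]))
      cand <- unfixed[frac > intol]
      j <- if (length(cand)) cand[which.max(act[frac > intol])] else
        unfixed[which.max(act)]
    } else {
      j <- unfixed[which.max(act)]
    }
    child0 <- nd; child1 <- nd
    child0$fixed[j] <- 0L
    child0$ub[nc + j] <- 0
    child0$ub[sys$link_cols[j]] <- 0          # z = 0 forces x = 0
    child1$fixed[j] <- 1L
    child1$lb[nc + j] <- 1
    child1$lb[sys$link_cols[j]] <- max(child1$lb[sys$link_cols[j]],
                                       sys$threshold)  # z = 1 forces x >= c
    # DFS, z = 1 first (explore active support early)
    stack[[length(stack) + 1L]] <- child0
    stack[[length(stack) + 1L]] <- child1
  }
  best
}

# support (group indices) of a binary assignment
support_of <- function(sys, z) {
  which(vapply(sys$groups, function(g) sum(z[g]) > 0L, TRUE))
}

#' Iterative shortest-support enumeration (integer-cut loop)
#'
#' Repeatedly solves the minimization MILP, records the optimal support,
#' adds its integer cut and resumes, so the k-th round returns the k-th
#' shortest support.  Stops on infeasibility (family exhausted) or when a
#' size, solution-count or time limit is hit.
#'
#' @param sys a \code{milp_system} (see \code{\link{attach_indicators}}).
#' @param config an \code{\link{enumeration_config}}.
#' @return An \code{enumeration_state}: \code{found} (list of integer
#'   group-index supports in non-decreasing size order), \code{status}
#'   (\code{complete}, \code{size_limit}, \code{solution_limit},
#'   \code{time_limit}), and \code{complete_sizes}.
#' @export
enumerate_iterative <- function(sys, config = enumeration_config("iterative")) {
  deadline <- if (is.finite(config$time_limit_s))
    Sys.time() + config$time_limit_s else Inf
  size_ub <- if (is.null(config$size_ub)) sys$n_bin else config$size_ub
  # at least one active unit (excludes the zero solution), plus size bounds
  sys <- add_binary_row(sys, rep(1, sys$n_bin), ">=", max(1, config$size_lb))
  sys <- add_binary_row(sys, rep(1, sys$n_bin), "<=", size_ub)
  found <- list()
  status <- "complete"
  repeat {
    res <- milp_bb(sys, mode = config$mode, big_m = config$big_m,
                   objective = "min", deadline = deadline)
    if (isTRUE(res$timed_out)) { status <- "time_limit"; break }
    if (res$status != "optimal") break
    supp <- support_of(sys, res$z)
    found[[length(found) + 1L]] <- supp
    sys <- add_exclusion_constraint(sys, supp)
    if (length(found) >= config$max_solutions) { status <- "solution_limit"; break }
  }
  sizes <- lengths(found)
  enumeration_state(found, status,
                    complete_sizes = if (status == "complete") seq_len(size_ub)
                                     else setdiff(seq_len(max(c(0, sizes))), max(c(0, sizes))))
}

#' Fixed-size enumeration (solution-pool scheme)
#'
#' First solves one minimization to find the smallest support size s, then
#' walks the size classes s, s+1, ... up to the size bound.  Within a size
#' class the size-control row is fixed (lower = upper = s), the objective
#' is dropped and all feasible supports are enumerated as pure feasibility
#' problems; since the bundled backend has no native solution pool, the
#' class is exhausted by repeated feasibility solves with one integer cut
#' per found support (the cuts are kept for all later classes, which also
#' guarantees that later classes contain no supersets).
#'
#' @inheritParams enumerate_iterative
#' @return An \code{enumeration_state}; supports are grouped by size class
#'   and \code{complete_sizes} records which classes finished within the
#'   time budget.
#' @export
enumerate_fixed_size <- function(sys, config = enumeration_config("fixed_size")) {
  deadline <- if (is.finite(config$time_limit_s))
    Sys.time() + config$time_limit_s else Inf
  size_ub <- if (is.null(config$size_ub)) sys$n_bin else config$size_ub
  base <- add_binary_row(sys, rep(1, sys$n_bin), ">=", max(1, config$size_lb))
  base <- add_binary_row(base, rep(1, sys$n_bin), "<=", size_ub)
  first <- milp_bb(base, mode = config$mode, big_m = config$big_m,
                   objective = "min", deadline = deadline)
  if (isTRUE(first$timed_out))
    return(enumeration_state(list(), "time_limit", integer(0)))
  if (first$status != "optimal")
    return(enumeration_state(list(), "complete", seq_len(size_ub)))
  s <- sum(first$z)
  found <- list()
  complete <- seq_len(s - 1L)[seq_len(s - 1L) >= config$size_lb]
  status <- "complete"
  sys_s <- base
  pending_first <- support_of(sys_s, first$z)
  while (s <= size_ub) {
    # fix the size-control row: sz_lb = sz_ub = s
    sized <- add_binary_row(sys_s, rep(1, sys_s$n_bin), "=", s)
    newsupps <- list()
    if (!is.null(pending_first) && length(pending_first) == s) {
      newsupps[[1L]] <- pending_first
      sized <- add_exclusion_constraint(sized, pending_first)
      pending_first <- NULL
    }
    repeat {
      if (length(found) + length(newsupps) >= config$max_solutions) {
        status <- "solution_limit"; break
      }
      res <- milp_bb(sized, mode = config$mode, big_m = config$big_m,
                     objective = "feasible", deadline = deadline)
      if (isTRUE(res$timed_out)) { status <- "time_limit"; break }
      if (res$status != "optimal") break    # size class exhausted
      supp <- support_of(sized, res$z)
      newsupps[[length(newsupps) + 1L]] <- supp
      sized <- add_exclusion_constraint(sized, supp)
    }
    found <- c(found, newsupps)
    if (status != "complete") break
    complete <- c(complete, s)
    # carry the integer cuts of this class into all further classes
    for (supp in newsupps) sys_s <- add_exclusion_constraint(sys_s, supp)
    s <- s + 1L
  }
  enumeration_state(found, status, complete)
}

enumeration_state <- function(found, status, complete_sizes) {
  ord <- order(lengths(found))
  structure(list(found = found[ord], status = status,
                 complete_sizes = complete_sizes),
            class = "enumeration_state")
}

#' @export
print.enumeration_state <- function(x, ...) {
  sz <- table(lengths(x$found))
  cat(sprintf("enumeration_state: %d support(s), status %s\n",
              length(x$found), x$status))
  if (length(sz))
    cat("  per size:", paste(sprintf("%s:%d", names(sz), sz), collapse = ", "), "\n")
  invisible(x)
}
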