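#' Build the Farkas-dual system of a target flux polyhedron
#'
#' The primal system "steady state + irreversibilities + target rows +
#' all rates zero" is infeasible whenever the target polyhedron excludes
#' the zero flux vector.  Its Farkas dual is therefore feasible, and the
#' support-minimal dual solutions in the \code{v}-block (the multipliers of
#' the per-reaction zero-rate equalities) correspond one-to-one to the
#' minimal cut sets of the primal network.  This function assembles that
#' dual system:
#'
#' \itemize{
#'   \item one free column \code{u} per metabolite (dual to the
#'     steady-state equalities),
#'   \item one split pair \code{vp}/\code{vn} \eqn{\ge 0} per primal
#'     reaction (dual to the zero-rate equalities; both signs of \code{v}
#'     must be representable),
#'   \item one column \code{w} \eqn{\ge 0} per target row,
#'   \item one structural row per primal reaction,
#'     \eqn{(N^T u + vp - vn + T^T w)_i}, with sense \eqn{\ge 0} for
#'     irreversible and \eqn{= 0} for reversible primal reactions,
#'   \item the inhomogeneity row \eqn{b^T w \le -c} with \eqn{c > 0}
#'     fixing the scale of the infeasibility certificate.
#' }
#'
#' Reversible reactions carrying a nonzero target coefficient are split
#' into forward/backward parts before dualization; their parts share one
#' reaction-level group so that cut sets are reported on the unsplit
#' reaction.  Non-knockable reactions get upper bound 0 on \code{vp}/
#' \code{vn} (equivalently, their indicators are fixed to zero).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}} that excludes the zero
#'   flux vector (see \code{\link{validate_target}}).
#' @param knockable reaction ids allowed in cut sets (default: the
#'   network's knockable set).
#' @param c_scale the positive constant scaling the certificate; any
#'   positive value yields the same family of cut sets.
#' @return An object of class \code{dual_system}: the LP blocks
#'   (\code{A}, \code{dir}, \code{rhs}, \code{lb}, \code{ub}), the column
#'   index blocks (\code{u_cols}, \code{vp_cols}, \code{vn_cols},
#'   \code{w_cols}), and \code{groups} mapping each knockable original
#'   reaction to its \code{vp}/\code{vn} column indices.
#' @export
build_dual_system <- function(net, target,
                              knockable = net$reaction_ids[net$knockable],
                              c_scale = 1) {
  stopifnot(c_scale > 0)
  tb <- bind_constraints(target, net)
  # split reversible reactions that the target touches
  touch <- colSums(tb$coeffs != 0) > 0
  to_split <- net$reversible & touch
  part_of <- seq_len(n_rxn(net))        # part index -> original reaction index
  Tmat <- tb$coeffs
  pnet <- net
  if (any(to_split)) {
    idx <- which(to_split)
    S <- cbind(net$stoich, -net$stoich[, idx, drop = FALSE])
    ids <- net$reaction_ids
    ids_f <- ids; ids_f[idx] <- paste0(ids[idx], "_fwd")
    ids_b <- paste0(ids[idx], "_bwd")
    colnames(S) <- c(ids_f, ids_b)
    revs <- c(net$reversible, rep(FALSE, length(idx)))
    revs[idx] <- FALSE
    pnet <- metabolic_network(S, reversible = revs,
                              knockable = c(net$knockable, net$knockable[idx]),
                              exchange = c(net$exchange, net$exchange[idx]),
                              spontaneous = c(net$spontaneous, net$spontaneous[idx]))
    Tmat <- cbind(tb$coeffs, -tb$coeffs[, idx, drop = FALSE])
    part_of <- c(part_of, idx)
  }
  np <- n_rxn(pnet); m <- n_met(pnet); k <- nrow(Tmat)
  u_cols <- seq_len(m)
  vp_cols <- m + seq_len(np)
  vn_cols <- m + np + seq_len(np)
  w_cols <- m + 2L * np + seq_len(k)
  ncols <- m + 2L * np + k
  A <- matrix(0, np + 1L, ncols)
  A[seq_len(np), u_cols] <- t(pnet$stoich)
  A[cbind(seq_len(np), vp_cols)] <- 1
  A[cbind(seq_len(np), vn_cols)] <- -1
  A[seq_len(np), w_cols] <- t(Tmat)
  A[np + 1L, w_cols] <- tb$rhs
  dir <- c(ifelse(pnet$reversible, "=", ">="), "<=")
  rhs <- c(rep(0, np), -c_scale)
  lb <- rep(-Inf, ncols); lb[c(vp_cols, vn_cols, w_cols)] <- 0
  ub <- rep(Inf, ncols)
  kn_orig <- net$reaction_ids %in% knockable
  kn_part <- kn_orig[part_of] & net$knockable[part_of]
  ub[vp_cols[!kn_part]] <- 0
  ub[vn_cols[!kn_part]] <- 0
  groups <- list()
  for (i in which(kn_orig & net$knockable)) {
    parts <- which(part_of == i)
    groups[[net$reaction_ids[i]]] <- c(vp_cols[parts], vn_cols[parts])
  }
  structure(list(A = A, dir = dir, rhs = rhs, lb = lb, ub = ub,
                 u_cols = u_cols, vp_cols = vp_cols, vn_cols = vn_cols,
                 w_cols = w_cols, part_of = part_of, groups = groups,
                 c_scale = c_scale,
                 reaction_ids = net$reaction_ids),
            class = "dual_system")
}

#' @export
print.dual_system <- function(x, ...) {
  cat(sprintf("dual_system: %d rows, %d columns (u: %d, vp/vn: %d pairs, w: %d), c = %g\n",
              nrow(x$A), ncol(x$A), length(x$u_cols), length(x$vp_cols),
              length(x$w_cols), x$c_scale))
  invisible(x)
}

#' Collapse a dual indicator assignment into a cut set
#'
#' A dual solution marks reaction membership through the indicator pair of
#' its split dual variable: reaction \eqn{i} is in the cut set iff
#' \eqn{zp_i + zn_i = 1}.  Both indicators active at once violates the
#' mutual-exclusion constraint and is rejected.
#'
#' @param dual a \code{\link{build_dual_system}} result.
#' @param zp,zn 0/1 vectors over the dual's \code{vp}/\code{vn} columns
#'   (one entry per primal reaction part).
#' @return character vector of original reaction ids (the cut set).
#' @export
collapse_solution <- function(dual, zp, zn) {
  stopifnot(inherits(dual, "dual_system"),
            length(zp) == length(dual$vp_cols),
            length(zn) == length(dual$vn_cols))
  if (any(zp + zn > 1L))
    stop("internal consistency error: zp and zn active simultaneously")
  act <- which(zp + zn == 1L)
  sort(unique(dual$reaction_ids[dual$part_of[act]]))
}

#' Dump the dual matrix in MatrixMarket coordinate format
#'
#' @param dual a \code{dual_system}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dual_mtx <- function(dual, path) {
  A <- dual$A
  nz <- which(A != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(A), ncol(A), nrow(nz))), con)
  writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], A[nz]), con)
  invisible(path)
}

#' Farkas self-validation of a cut set
#'
#' Soundness/minimality check used throughout the test-suite: a valid
#' minimal cut set renders the primal target LP (steady state +
#' irreversibilities + target rows, with the cut rates fixed to zero)
#' infeasible, while dropping any single member restores feasibility.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}}.
#' @param cutset character vector of reaction ids.
#' @return list with logicals \code{blocks} and \code{minimal}.
#' @export
check_cutset <- function(net, target, cutset) {
  # same polyhedron the dual is built from: the steady-state cone plus
  # target rows, without finite box bounds
  lpd <- network_lp(net, constraints = target, fix_zero = cutset,
                    use_bounds = FALSE)
  blocks <- isFALSE(lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub))
  minimal <- TRUE
  if (blocks && length(cutset) > 0L) {
    for (drop1 in seq_along(cutset)) {
      sub <- cutset[-drop1]
      lps <- network_lp(net, constraints = target, fix_zero = sub,
                        use_bounds = FALSE)
      if (!isTRUE(lp_feasible(lps$mat, lps$dir, lps$rhs, lps$lb, lps$ub))) {
        minimal <- FALSE
        break
      }
    }
  }
  list(blocks = blocks, minimal = minimal)
}
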