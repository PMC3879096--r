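#' Flux variability analysis
#'
#' Per-reaction minimum and maximum steady-state flux under the network
#' constraints plus an optional context constraint set (medium conditions,
#' regulatory shut-offs encoded as zero-bound rows, ...).  Each objective
#' reaction is bounded at \code{+/-big} during its own two LPs so that an
#' otherwise unbounded model still yields a finite witness; blockedness only
#' needs a nonzero witness, not a tight range.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param context optional \code{\link{flux_constraints}}.
#' @param reactions reaction ids to analyze (default: all).
#' @param big artificial objective bound for unbounded models.
#' @return data frame with columns \code{reaction_id}, \code{min},
#'   \code{max}.
#' @export
fva <- function(net, context = NULL, reactions = net$reaction_ids,
                big = 1e6) {
  lpd <- network_lp(net, constraints = context)
  if (!isTRUE(lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub)))
    stop("context polyhedron empty")
  idx <- rxn_index(net, reactions)
  n <- n_rxn(net)
  res <- vapply(idx, function(j) {
    obj <- rep(0, n); obj[j] <- 1
    lb <- lpd$lb; ub <- lpd$ub
    lb[j] <- max(lb[j], -big); ub[j] <- min(ub[j], big)
    up <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs, lb, ub, maximize = TRUE)
    lo <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs, lb, ub, maximize = FALSE)
    c(if (lo$status == "optimal") lo$objval else NA_real_,
      if (up$status == "optimal") up$objval else NA_real_)
  }, c(0, 0))
  data.frame(reaction_id = reactions, min = res[1, ], max = res[2, ])
}

#' Blocked reactions by FVA
#'
#' A reaction is blocked when both its maximal and minimal steady-state
#' flux under the given context are within tolerance of zero; such
#' reactions can never carry flux and are removed before dualization.  Two
#' LPs per reaction, with an early exit once a nonzero flux is witnessed.
#'
#' @inheritParams fva
#' @param tol zero tolerance on the flux witness.
#' @return character vector of blocked reaction ids.
#' @export
fva_blocked_reactions <- function(net, context = NULL, tol = 1e-6,
                                  big = 1e6) {
  lpd <- network_lp(net, constraints = context)
  if (!isTRUE(lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub)))
    stop("context polyhedron empty")
  n <- n_rxn(net)
  blocked <- logical(n)
  for (j in seq_len(n)) {
    obj <- rep(0, n); obj[j] <- 1
    lb <- lpd$lb; ub <- lpd$ub
    lb[j] <- max(lb[j], -big); ub[j] <- min(ub[j], big)
    up <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs, lb, ub, maximize = TRUE)
    if (up$status == "optimal" && up$objval > tol) next   # early exit
    lo <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs, lb, ub, maximize = FALSE)
    blocked[j] <- (up$status == "optimal" && abs(up$objval) <= tol) &&
                  (lo$status == "optimal" && abs(lo$objval) <= tol)
  }
  net$reaction_ids[blocked]
}

#' Drop reactions from a network
#'
#' Removes the given reaction columns (and any metabolite rows left without
#' a nonzero entry).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param ids reaction ids to remove.
#' @return The reduced \code{\link{metabolic_network}}.
#' @export
drop_reactions <- function(net, ids) {
  if (length(ids) == 0L) return(net)
  keep <- !(net$reaction_ids %in% ids)
  S <- net$stoich[, keep, drop = FALSE]
  keepm <- rowSums(S != 0) > 0
  metabolic_network(S[keepm, , drop = FALSE],
                    reversible = net$reversible[keep],
                    lb = net$lb[keep], ub = net$ub[keep],
                    knockable = net$knockable[keep],
                    exchange = net$exchange[keep],
                    spontaneous = net$spontaneous[keep])
}

# nullspace of a matrix by SVD, tolerance-based rank decision
nullspace_basis <- function(A, tol = 1e-9) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  pos <- sv$d > tol * max(sv$d[1], 1)
  r <- sum(pos)
  if (r == ncol(A)) matrix(0, ncol(A), 0) else sv$v[, (r + 1):ncol(A), drop = FALSE]
}

#' Compress a network by lumping fully coupled reactions
#'
#' Reactions whose steady-state fluxes are correlated with a fixed ratio
#' (fully coupled subsets) are merged into single lumped reactions; the
#' compressed flux space is in one-to-one linear correspondence with the
#' original one.  Coupling is detected on a kernel (right-nullspace) basis
#' of the stoichiometric matrix: two reactions are fully coupled iff their
#' kernel rows are proportional.  Blocked reactions (zero kernel rows)
#' should have been removed beforehand (see
#' \code{\link{fva_blocked_reactions}}); any remaining ones are dropped
#' into the map's \code{removed_blocked} record.  A lumped reaction is
#' knockable iff at least one member is knockable.  Parallel reactions
#' (identical columns) are \emph{not} merged: they are distinct cut
#' candidates, not flux-coupled ones.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param tol proportionality tolerance on kernel rows.
#' @return A list: \code{network} (compressed) and \code{map}
#'   (a \code{compression_map}: \code{subsets}, \code{removed_blocked}).
#' @export
compress_network <- function(net, tol = 1e-9) {
  n <- n_rxn(net)
  K <- nullspace_basis(net$stoich, tol = tol)
  rown <- sqrt(rowSums(K^2))
  kblocked <- rown <= tol
  group <- rep(NA_integer_, n)
  ratio <- rep(NA_real_, n)
  g <- 0L
  for (j in seq_len(n)) {
    if (kblocked[j] || !is.na(group[j])) next
    g <- g + 1L
    group[j] <- g; ratio[j] <- 1
    if (j < n) for (k in seq((j + 1L), n)) {
      if (kblocked[k] || !is.na(group[k])) next
      # proportional kernel rows <=> |cos angle| == 1
      dotp <- sum(K[j, ] * K[k, ])
      if (abs(abs(dotp) - rown[j] * rown[k]) <= tol * rown[j] * rown[k] + tol) {
        # fixed flux ratio r_k / r_j
        piv <- which.max(abs(K[j, ]))
        group[k] <- g
        ratio[k] <- K[k, piv] / K[j, piv]
      }
    }
  }
  subsets <- list()
  cols <- NULL; rv <- lb <- ub <- kn <- ex <- sp <- NULL
  ids <- character(0)
  for (gi in seq_len(g)) {
    mem <- which(group == gi)
    rt <- ratio[mem]
    # orient the lump so that irreversible members impose v >= 0
    irr <- !net$reversible[mem]
    if (any(irr & rt < 0) && !any(irr & rt > 0)) rt <- -rt
    if (any(irr & rt < 0) && any(irr & rt > 0))
      stop("inconsistently oriented coupled subset (blocked reactions not removed?): ",
           paste(net$reaction_ids[mem], collapse = ", "))
    lump_rev <- !any(irr)
    col <- as.numeric(net$stoich[, mem, drop = FALSE] %*% rt)
    # member bounds induce lump bounds: ratio * v in [lb, ub]
    lo <- -Inf; hi <- Inf
    for (t in seq_along(mem)) {
      b1 <- net$lb[mem[t]] / rt[t]; b2 <- net$ub[mem[t]] / rt[t]
      lo <- max(lo, min(b1, b2)); hi <- min(hi, max(b1, b2))
    }
    if (!lump_rev) lo <- max(lo, 0)
    id <- paste(net$reaction_ids[mem], collapse = "/")
    ids <- c(ids, id)
    cols <- cbind(cols, col)
    rv <- c(rv, lump_rev); lb <- c(lb, lo); ub <- c(ub, hi)
    kn <- c(kn, any(net$knockable[mem]))
    ex <- c(ex, all(net$exchange[mem]))
    sp <- c(sp, all(net$spontaneous[mem]))
    subsets[[id]] <- list(lumped_id = id,
                          members = net$reaction_ids[mem],
                          ratios = rt,
                          knockable = net$knockable[mem])
  }
  rownames(cols) <- net$metabolite_ids
  colnames(cols) <- ids
  keepm <- rowSums(abs(cols) > tol) > 0
  cnet <- metabolic_network(cols[keepm, , drop = FALSE],
                            reversible = rv, lb = lb, ub = ub,
                            knockable = kn, exchange = ex, spontaneous = sp)
  map <- structure(list(subsets = subsets,
                        removed_blocked = net$reaction_ids[kblocked]),
                   class = "compression_map")
  list(network = cnet, map = map)
}

#' @export
print.compression_map <- function(x, ...) {
  cat(sprintf("compression_map: %d lumped subsets, %d blocked removed\n",
              length(x$subsets), length(x$removed_blocked)))
  invisible(x)
}

#' Translate a constraint set into compressed-network coordinates
#'
#' A row \eqn{\sum_i c_i r_i \le b} becomes \eqn{\sum_g (\sum_{i \in g}
#' c_i \rho_i) v_g \le b} using the fixed member ratios \eqn{\rho}.
#'
#' @param cs a \code{\link{flux_constraints}} with named columns.
#' @param cmap a \code{compression_map}.
#' @return A \code{\link{flux_constraints}} over the lumped reactions.
#' @export
compress_constraints <- function(cs, cmap) {
  stopifnot(inherits(cs, "flux_constraints"), inherits(cmap, "compression_map"))
  if (is.null(colnames(cs$coeffs)))
    stop("constraint columns must be named to be compressible")
  lumps <- names(cmap$subsets)
  M <- matrix(0, nrow(cs$coeffs), length(lumps),
              dimnames = list(NULL, lumps))
  orig <- colnames(cs$coeffs)
  for (L in lumps) {
    sub <- cmap$subsets[[L]]
    hit <- match(sub$members, orig)
    sel <- which(!is.na(hit))
    if (length(sel))
      M[, L] <- cs$coeffs[, hit[sel], drop = FALSE] %*% sub$ratios[sel]
  }
  covered <- orig %in% unlist(lapply(cmap$subsets, `[[`, "members"))
  if (any(!covered & colSums(cs$coeffs != 0) > 0)) {
    lost <- orig[!covered & colSums(abs(cs$coeffs)) > 0]
    stop("constraint references reaction(s) removed by compression: ",
         paste(lost, collapse = ", "))
  }
  flux_constraints(M, cs$rhs, label = cs$label)
}

#' Decompress cut sets found in a compressed network
#'
#' Each lumped member of a compressed cut set is expanded to its knockable
#' original reactions, taking the Cartesian product across members; all
#' expanded sets keep the compressed size and the family stays
#' duplicate-free and minimality-preserving (lumped subsets are disjoint).
#'
#' @param cutsets list of character vectors of lumped ids.
#' @param cmap a \code{compression_map}.
#' @return list of character vectors of original reaction ids.
#' @export
decompress_cutsets <- function(cutsets, cmap) {
  stopifnot(inherits(cmap, "compression_map"))
  out <- list()
  for (cs in cutsets) {
    choices <- lapply(cs, function(L) {
      sub <- cmap$subsets[[L]]
      if (is.null(sub)) stop("unknown lumped reaction id: ", L)
      mem <- sub$members[sub$knockable]
      if (length(mem) == 0L)
        stop("lumped reaction ", L, " has no knockable member")
      names(mem) <- NULL
      mem
    })
    grid <- expand.grid(choices, stringsAsFactors = FALSE)
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(i) sort(as.character(unlist(grid[i, ])))))
  }
  unique(out)
}

#' Knockable reactions essential for the desired behaviour
#'
#' A knockable reaction is desired-essential when fixing its rate to zero
#' makes the steady-state system intersected with the desired polyhedron
#' infeasible.  Such reactions can never be part of a constrained cut set
#' and are excluded from the search space up front.
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param desired a \code{\link{flux_constraints}}.
#' @param knockable reaction ids considered for knockout (default: the
#'   network's knockable set).
#' @return character vector of essential reaction ids.
#' @export
desired_essential_reactions <- function(net, desired,
                                        knockable = net$reaction_ids[net$knockable]) {
  lpd <- network_lp(net, constraints = desired)
  if (!isTRUE(lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lpd$lb, lpd$ub)))
    stop("desired polyhedron empty")
  ess <- vapply(knockable, function(rid) {
    lb <- lpd$lb; ub <- lpd$ub
    j <- rxn_index(net, rid)
    lb[j] <- 0; ub[j] <- 0
    !isTRUE(lp_feasible(lpd$mat, lpd$dir, lpd$rhs, lb, ub))
  }, TRUE)
  knockable[ess]
}
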