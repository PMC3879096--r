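#' Brute-force enumeration of elementary-mode supports
#'
#' Independent ground truth for the MILP path on small networks: walks all
#' reaction subsets in increasing size and keeps those that carry a
#' nonzero steady-state flux active on the whole subset while no proper
#' subset does (support minimality); supersets of recorded supports are
#' skipped.  One LP per candidate subset.
#'
#' @param net an all-irreversible \code{\link{metabolic_network}} with at
#'   most \code{max_reactions} reactions.
#' @param max_reactions size guard; beyond it the MILP path is the only
#'   practical route.
#' @return list of character support vectors, sizes non-decreasing.
#' @export
enumerate_ems_bruteforce <- function(net, max_reactions = 15L) {
  if (any(net$reversible))
    stop("network contains reversible reactions; apply split_reversible() first")
  n <- n_rxn(net)
  if (n > max_reactions)
    stop("network too large for subset enumeration; use shortest_ems()")
  found <- list()
  A <- net$stoich
  # supports using both directions of a split reversible pair are spurious
  # two-cycles, never elementary modes of the unsplit network
  pr <- detect_split_pairs(net)
  pair_idx <- lapply(seq_len(nrow(pr)), function(i)
    c(rxn_index(net, pr$fwd[i]), rxn_index(net, pr$bwd[i])))
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size, simplify = FALSE)
    for (S in combs) {
      if (any(vapply(pair_idx, function(p) all(p %in% S), TRUE))) next
      if (any(vapply(found, function(f) all(f %in% S), TRUE))) next
      lb <- rep(0, n); ub <- rep(0, n)
      lb[S] <- 1; ub[S] <- Inf          # active on all of S (scalable)
      if (isTRUE(lp_feasible(A, rep("=", nrow(A)), rep(0, nrow(A)), lb, ub)))
        found[[length(found) + 1L]] <- S
    }
  }
  lapply(found, function(S) net$reaction_ids[S])
}

#' Minimal hitting sets (hypergraph transversal)
#'
#' Berge-style incremental transversal: processes the support family one
#' member set at a time, extending the current minimal hitting sets by
#' the member's elements and discarding non-minimal or oversized
#' candidates.  Cut sets of a network are exactly the minimal hitting
#' sets of its target elementary modes, which makes this the reference
#' oracle for the dual MILP path.
#'
#' @param sets family of character vectors to hit.
#' @param universe elements allowed in hitting sets (knockable set).
#' @param max_size largest hitting-set size to return.
#' @return list of character vectors, sizes non-decreasing.
#' @export
minimal_hitting_sets <- function(sets, universe, max_size = Inf) {
  if (length(sets) == 0L) stop("empty support family")
  H <- list(character(0))
  for (S in sets) {
    Su <- intersect(S, universe)
    if (length(Su) == 0L)
      stop("untargetable mode: {", paste(S, collapse = ","),
           "} shares no element with the universe")
    H2 <- list()
    for (h in H) {
      if (length(intersect(h, Su)) > 0L) {
        H2[[length(H2) + 1L]] <- h
      } else {
        for (e in Su) {
          cand <- sort(c(h, e))
          if (length(cand) <= max_size) H2[[length(H2) + 1L]] <- cand
        }
      }
    }
    # minimalize: drop duplicates and supersets
    H2 <- unique(H2)
    ord <- order(lengths(H2))
    H2 <- H2[ord]
    keep <- rep(TRUE, length(H2))
    for (i in seq_along(H2)) {
      if (!keep[i]) next
      for (j in seq_along(H2)) {
        if (j == i || !keep[j]) next
        if (length(H2[[i]]) < length(H2[[j]]) && all(H2[[i]] %in% H2[[j]]))
          keep[j] <- FALSE
      }
    }
    H <- H2[keep]
  }
  H[order(lengths(H), vapply(H, paste, "", collapse = "|"))]
}

#' Named toy networks
#'
#' Small hand-checkable fixtures used throughout the examples and tests:
#' \describe{
#'   \item{chain}{R1: -> A; R2: A -> B; R3: B ->; a single pathway.}
#'   \item{diamond}{R1: -> A; R2/R3: A -> B (parallel); R4: B ->.}
#'   \item{branch}{R1: -> A; R2: A -> B; R3: A -> C; R4: B ->; R5: C ->.}
#'   \item{cycle_rev}{chain with a reversible middle step, whose split
#'     introduces a spurious two-cycle that mode enumeration must reject.}
#' }
#'
#' @param name one of \code{"chain"}, \code{"diamond"}, \code{"branch"},
#'   \code{"cycle_rev"}.
#' @return A \code{\link{metabolic_network}} with all reactions knockable.
#' @export
make_toy <- function(name = c("chain", "diamond", "branch", "cycle_rev")) {
  name <- match.arg(name)
  build <- function(mets, cols, rev = rep(FALSE, length(cols))) {
    S <- matrix(0, length(mets), length(cols),
                dimnames = list(mets, names(cols)))
    for (j in seq_along(cols)) S[names(cols[[j]]), j] <- cols[[j]]
    metabolic_network(S, reversible = rev,
                      knockable = rep(TRUE, length(cols)))
  }
  switch(name,
    chain = build(c("A", "B"),
                  list(R1 = c(A = 1), R2 = c(A = -1, B = 1), R3 = c(B = -1))),
    diamond = build(c("A", "B"),
                    list(R1 = c(A = 1), R2 = c(A = -1, B = 1),
                         R3 = c(A = -1, B = 1), R4 = c(B = -1))),
    branch = build(c("A", "B", "C"),
                   list(R1 = c(A = 1), R2 = c(A = -1, B = 1),
                        R3 = c(A = -1, C = 1), R4 = c(B = -1),
                        R5 = c(C = -1))),
    cycle_rev = build(c("A", "B"),
                      list(R1 = c(A = 1), R2 = c(A = -1, B = 1),
                           R3 = c(B = -1)),
                      rev = c(FALSE, TRUE, FALSE)))
}

#' Random small test networks
#'
#' Reproducible random fixtures for property-style tests: a core of
#' internal conversions with small integer coefficients plus import and
#' export reactions guaranteeing that the network can carry nonzero
#' steady-state flux; resampled until some reaction is unblocked.
#'
#' @param n_metabolites,n_reactions core dimensions (total reaction count
#'   includes one import and one export; kept at or below 12 in tests).
#' @param reversible_fraction fraction of core reactions drawn reversible.
#' @param density expected nonzero metabolites per core reaction column
#'   (at least 2: one consumed, one produced).
#' @param seed RNG seed; identical seeds give identical networks.
#' @return A \code{\link{metabolic_network}} with all reactions knockable.
#' @export
make_random <- function(n_metabolites = 4L, n_reactions = 8L,
                        reversible_fraction = 0.2, density = 2.5,
                        seed = 1L) {
  stopifnot(n_metabolites >= 2L, n_reactions >= 4L)
  set.seed(seed)
  n_core <- n_reactions - 2L
  for (attempt in seq_len(50L)) {
    S <- matrix(0, n_metabolites, n_reactions)
    for (j in seq_len(n_core)) {
      k <- max(2L, min(n_metabolites, stats::rpois(1, density)))
      mets <- sample.int(n_metabolites, k)
      nin <- sample.int(k - 1L, 1L)
      S[mets[seq_len(nin)], j] <- -sample(1:2, nin, replace = TRUE)
      S[mets[(nin + 1L):k], j] <- sample(1:2, k - nin, replace = TRUE)
    }
    S[1L, n_core + 1L] <- 1                       # import of metabolite 1
    S[n_metabolites, n_core + 2L] <- -1           # export of the last one
    rev <- c(stats::runif(n_core) < reversible_fraction, FALSE, FALSE)
    net <- metabolic_network(
      S, reaction_ids = sprintf("R%02d", seq_len(n_reactions)),
      metabolite_ids = sprintf("M%d", seq_len(n_metabolites)),
      reversible = rev, knockable = rep(TRUE, n_reactions))
    lpd <- network_lp(net, use_bounds = FALSE)
    n <- n_rxn(net)
    ok <- any(vapply(seq_len(n), function(j) {
      obj <- rep(0, n); obj[j] <- 1
      ub <- rep(1, n); lb <- ifelse(net$reversible, -1, 0)
      r <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs, lb, ub, maximize = TRUE)
      r$status == "optimal" && r$objval > 1e-6
    }, TRUE))
    if (ok) return(net)
  }
  stop("could not sample a network with nonzero steady-state flux")
}

#' Cut-set oracle via target modes and hitting sets
#'
#' The classical two-step route kept as ground truth: enumerate all
#' elementary modes by brute force, select the target modes (those whose
#' support carries activity through the target-defining reactions under
#' the homogeneous part of the target rows), and take minimal hitting
#' sets over the knockable universe.  Valid for homogeneous targets;
#' inhomogeneous targets are validated through LP soundness instead.
#'
#' @param net all-irreversible \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}}.
#' @param universe knockable reaction ids.
#' @param max_size largest cut-set size.
#' @param max_reactions size guard passed to the brute-force enumerator.
#' @return list of character vectors (the oracle's cut-set family).
#' @export
oracle_mcs <- function(net, target, universe = net$reaction_ids[net$knockable],
                       max_size = Inf, max_reactions = 15L) {
  ems <- enumerate_ems_bruteforce(net, max_reactions = max_reactions)
  tb <- bind_constraints(target, net)
  # a mode is a target mode if its flux vector violates no steady-state
  # constraint and satisfies all target rows for some scaling: test by LP
  is_target <- vapply(ems, function(supp) {
    lb <- rep(0, n_rxn(net)); ub <- rep(0, n_rxn(net))
    idx <- rxn_index(net, supp)
    lb[idx] <- 1e-3; ub[idx] <- Inf
    mat <- rbind(net$stoich, tb$coeffs)
    dir <- c(rep("=", n_met(net)), rep("<=", length(tb$rhs)))
    rhs <- c(rep(0, n_met(net)), tb$rhs)
    isTRUE(lp_feasible(mat, dir, rhs, lb, ub))
  }, TRUE)
  if (!any(is_target)) return(list())
  # a knockout removes both directions of a formerly reversible reaction:
  # collapse split ids back to the original reaction before the transversal
  tmodes <- unique(lapply(ems[is_target], function(s)
    sort(unique(sub("_(fwd|bwd)$", "", s)))))
  minimal_hitting_sets(tmodes, universe, max_size = max_size)
}
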