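#' Define an intervention problem
#'
#' Bundles a network, a target (undesired) flux polyhedron, an optional
#' desired polyhedron, the knockable reaction set and enumeration limits.
#'
#' @param network a \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}}.
#' @param desired optional \code{\link{flux_constraints}} of behaviours of
#'   which at least one must survive the cuts.
#' @param knockable reaction ids allowed in cut sets.
#' @param max_size largest cut-set size to enumerate.
#' @param max_solutions,time_limit_s optional limits.
#' @return An object of class \code{intervention_problem}.
#' @export
intervention_problem <- function(network, target, desired = NULL,
                                 knockable = network$reaction_ids[network$knockable],
                                 max_size = 3L, max_solutions = Inf,
                                 time_limit_s = Inf) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(target, "flux_constraints"))
  if (!all(knockable %in% network$reaction_ids))
    stop("knockable set contains unknown reaction(s): ",
         paste(setdiff(knockable, network$reaction_ids), collapse = ", "))
  if (max_size < 1L) stop("max_size must be >= 1")
  if (max_size > length(knockable))
    stop("max_size exceeds the number of knockable reactions")
  structure(list(network = network, target = target, desired = desired,
                 knockable = knockable, max_size = as.integer(max_size),
                 max_solutions = max_solutions, time_limit_s = time_limit_s),
            class = "intervention_problem")
}

# detect forward/backward pairs created by split_reversible from ids
detect_split_pairs <- function(net) {
  ids <- net$reaction_ids
  fwd <- grep("_fwd$", ids, value = TRUE)
  orig <- sub("_fwd$", "", fwd)
  bwd <- paste0(orig, "_bwd")
  keep <- bwd %in% ids
  data.frame(fwd = fwd[keep], bwd = bwd[keep], orig = orig[keep])
}

#' Enumerate the k-shortest elementary modes
#'
#' Shortest-first enumeration of the elementary modes (support-minimal
#' nonzero steady-state flux patterns) of an all-irreversible network:
#' minimize the number of active reactions subject to the steady-state
#' constraints, with indicator binaries linking activity to flux, the
#' trivial zero solution excluded, two-cycles from split reversible pairs
#' forbidden, and previously found modes removed by integer cuts.
#'
#' @param net an all-irreversible \code{\link{metabolic_network}}
#'   (apply \code{\link{split_reversible}} first); forward/backward pairs
#'   are recognized by their \code{_fwd}/\code{_bwd} identifier suffixes.
#' @param config an \code{\link{enumeration_config}}.
#' @return A list: \code{ems} (list of character support vectors, sizes
#'   non-decreasing) and \code{state} (the \code{enumeration_state}).
#' @export
shortest_ems <- function(net, config = enumeration_config()) {
  if (any(net$reversible))
    stop("network contains reversible reactions; apply split_reversible() first")
  n <- n_rxn(net)
  A <- net$stoich
  groups <- stats::setNames(as.list(seq_len(n)), net$reaction_ids)
  pr <- detect_split_pairs(net)
  pairs <- lapply(seq_len(nrow(pr)), function(i)
    c(rxn_index(net, pr$fwd[i]), rxn_index(net, pr$bwd[i])))
  sys <- attach_indicators(A, dir = rep("=", nrow(A)), rhs = rep(0, nrow(A)),
                           lb = rep(0, n), ub = rep(Inf, n),
                           link_cols = seq_len(n), groups = groups,
                           pairs = pairs, threshold = config$threshold)
  state <- if (config$algorithm == "iterative")
    enumerate_iterative(sys, config) else enumerate_fixed_size(sys, config)
  ems <- lapply(state$found, function(s) net$reaction_ids[s])
  list(ems = ems, state = state)
}

#' Enumerate the smallest minimal cut sets
#'
#' The central routine: builds the Farkas-dual system of the problem's
#' target polyhedron, enumerates its shortest elementary modes restricted
#' to the \code{vp}/\code{vn} support with the configured MILP scheme,
#' collapses the indicator solutions into reaction sets, and (when a
#' compression map is supplied) expands lumped reactions back to original
#' ones.  Every returned set renders the target polyhedron infeasible and
#' is support-minimal.
#'
#' @param problem an \code{\link{intervention_problem}} (preprocessing,
#'   if wanted, is applied before building the problem).
#' @param config an \code{\link{enumeration_config}}; size and solution
#'   limits default to the problem's.
#' @param cmap optional \code{compression_map} when the problem's network
#'   is a compressed one; cut sets are decompressed before return.
#' @param c_scale positive scaling constant of the dual inhomogeneity row.
#' @param verify gate every collapsed support by the Farkas
#'   self-validation LP (the cut must render the target system infeasible
#'   and be minimal); supports failing the gate are dropped with a
#'   warning.  The dual construction is validated by this property rather
#'   than trusted blindly.
#' @return A list: \code{cutsets} (list of character vectors, sizes
#'   non-decreasing), \code{state}, and \code{target_validation}.
#' @export
smallest_mcs <- function(problem, config = NULL, cmap = NULL, c_scale = 1,
                         verify = TRUE) {
  stopifnot(inherits(problem, "intervention_problem"))
  net <- problem$network
  if (is.null(config))
    config <- enumeration_config(size_ub = problem$max_size,
                                 max_solutions = problem$max_solutions,
                                 time_limit_s = problem$time_limit_s)
  if (is.null(config$size_ub)) config$size_ub <- problem$max_size
  val <- validate_target(net, problem$target)
  if (val$zero_in_polyhedron)
    stop("invalid target: the zero flux vector satisfies all target rows, ",
         "no knockout can block it")
  if (!val$nonempty) {
    # nothing to cut: the target polyhedron is already unreachable
    return(list(cutsets = list(),
                state = enumeration_state(list(), "complete",
                                          seq_len(config$size_ub)),
                target_validation = val))
  }
  dual <- build_dual_system(net, problem$target,
                            knockable = problem$knockable, c_scale = c_scale)
  sys <- dual_milp_system(dual, threshold = config$threshold)
  state <- if (config$algorithm == "iterative")
    enumerate_iterative(sys, config) else enumerate_fixed_size(sys, config)
  cuts <- lapply(state$found, function(s) sort(names(dual$groups)[s]))
  if (verify) {
    ok <- vapply(cuts, function(cs) {
      chk <- check_cutset(net, problem$target, cs)
      chk$blocks && chk$minimal
    }, TRUE)
    if (any(!ok)) {
      warning(sum(!ok), " enumerated support(s) failed the Farkas ",
              "self-validation gate and were dropped")
      cuts <- cuts[ok]
    }
  }
  if (!is.null(cmap)) cuts <- decompress_cutsets(cuts, cmap)
  list(cutsets = cuts, state = state, target_validation = val)
}

# milp_system over the dual LP blocks: binaries on the vp/vn columns of
# knockable reactions, one group per original reaction, vp/vn mutual
# exclusion within each split part (both signs cannot certify at once).
dual_milp_system <- function(dual, threshold = 1) {
  link_cols <- unlist(dual$groups, use.names = FALSE)
  np <- length(dual$vp_cols)
  pairs <- list()
  for (g in dual$groups) {
    # g holds vp columns then vn columns of the reaction's parts
    half <- length(g) / 2L
    for (t in seq_len(half))
      pairs[[length(pairs) + 1L]] <- c(g[t], g[half + t])
  }
  attach_indicators(dual$A, dual$dir, dual$rhs, dual$lb, dual$ub,
                    link_cols = link_cols, groups = dual$groups,
                    pairs = pairs, threshold = threshold)
}

#' One-call pipeline: preprocess, enumerate, filter
#'
#' Convenience wrapper realizing the full five-step procedure: (1) take
#' the network, (2) take target and optional desired constraint sets,
#' with optional blocked-reaction removal (FVA) and compression of fully
#' coupled subsets, (3) build the dual system, (4) enumerate the smallest
#' cut sets by MILP, (5) decompress and, when a desired set is given,
#' keep only constrained cut sets (and exclude desired-essential
#' reactions from the search space up front).
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param target a \code{\link{flux_constraints}}.
#' @param desired optional \code{\link{flux_constraints}}.
#' @param knockable knockable reaction ids.
#' @param max_size largest cut-set size.
#' @param compress lump fully coupled reactions before dualization.
#' @param remove_blocked drop FVA-blocked reactions first.
#' @param config optional \code{\link{enumeration_config}}.
#' @param ... passed to \code{\link{enumeration_config}} when
#'   \code{config} is NULL.
#' @return As \code{\link{smallest_mcs}}, with an extra \code{cmcs}
#'   logical vector when \code{desired} was given.
#' @export
enumerate_mcs <- function(net, target, desired = NULL,
                          knockable = net$reaction_ids[net$knockable],
                          max_size = 3L, compress = TRUE,
                          remove_blocked = TRUE, config = NULL, ...) {
  if (is.null(config)) config <- enumeration_config(size_ub = max_size, ...)
  work <- net
  blocked <- character(0)
  if (remove_blocked) {
    blocked <- fva_blocked_reactions(work)
    work <- drop_reactions(work, blocked)
    knockable <- setdiff(knockable, blocked)
  }
  if (!is.null(desired)) {
    ess <- desired_essential_reactions(work, desired,
                                       intersect(knockable, work$reaction_ids))
    knockable <- setdiff(knockable, ess)
  }
  cmap <- NULL
  target_w <- target; desired_w <- desired
  if (compress) {
    cm <- compress_network(work)
    cmap <- cm$map
    work <- cm$network
    target_w <- compress_constraints(target, cmap)
    if (!is.null(desired)) desired_w <- compress_constraints(desired, cmap)
    # restrict the map's knockable flags to the problem's knockable set so
    # that decompression only expands into allowed reactions
    cmap$subsets <- lapply(cmap$subsets, function(s) {
      s$knockable <- s$knockable & (s$members %in% knockable)
      s
    })
    knockable <- vapply(cmap$subsets, function(s)
      if (any(s$knockable)) s$lumped_id else NA_character_, "")
    knockable <- unname(knockable[!is.na(knockable)])
  }
  if (length(knockable) == 0L)
    return(list(cutsets = list(),
                state = enumeration_state(list(), "complete", integer(0)),
                blocked = blocked))
  max_size_eff <- min(max_size, length(knockable))
  prob <- intervention_problem(work, target_w, desired = desired_w,
                               knockable = knockable, max_size = max_size_eff)
  config$size_ub <- min(config$size_ub, max_size_eff)
  res <- smallest_mcs(prob, config = config, cmap = cmap)
  res$blocked <- blocked
  if (!is.null(desired)) {
    res$cmcs <- vapply(res$cutsets, function(cs) is_cmcs(net, desired, cs), TRUE)
  }
  res
}
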