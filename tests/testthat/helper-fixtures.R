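# Shared helpers: canonical keys for order-free family comparison and a
# generator of random intervention instances with a guaranteed non-empty
# target polyhedron.

family_key <- function(fam) {
  sort(vapply(fam, function(s) paste(sort(s), collapse = "+"), ""))
}

expect_same_family <- function(a, b) {
  expect_identical(family_key(a), family_key(b))
}

# random network whose export reaction can carry flux, plus its target
# constraint set "export active"; draws fresh seeds until `n_instances`
# valid instances are collected (deterministic for a fixed base seed)
random_instances <- function(n_instances, n_metabolites = 4, n_reactions = 8,
                             reversible_fraction = 0.25, base_seed = 100) {
  out <- list()
  seed <- base_seed
  while (length(out) < n_instances) {
    seed <- seed + 1L
    net <- make_random(n_metabolites, n_reactions, reversible_fraction,
                       seed = seed)
    exp_id <- tail(net$reaction_ids, 1)
    tgt <- parse_constraints(sprintf("1 %s >= 1", exp_id))
    if (validate_target(net, tgt)$nonempty)
      out[[length(out) + 1L]] <- list(net = net, target = tgt, seed = seed)
  }
  out
}
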