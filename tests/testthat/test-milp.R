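test_that("attach_indicators builds binaries, pairs and exclusion rows", {
  A <- matrix(0, 1, 3)
  sys <- attach_indicators(A, "=", 0, lb = rep(0, 3), ub = rep(Inf, 3),
                           link_cols = 1:3,
                           groups = list(a = 1, b = 2, c = 3))
  expect_equal(sys$n_bin, 3)
  expect_null(sys$bin_rows$mat)          # no pairs: no exclusion rows

  sys2 <- attach_indicators(A, "=", 0, lb = rep(0, 3), ub = rep(Inf, 3),
                            link_cols = 1:3,
                            groups = list(a = c(1, 2), b = 3),
                            pairs = list(c(1, 2)))
  expect_equal(nrow(sys2$bin_rows$mat), 1)
  expect_equal(unname(sys2$bin_rows$mat[1, ]), c(1, 1, 0))
  expect_equal(sys2$bin_rows$rhs, 1)
})

test_that("integer cuts exclude a support and all its supersets", {
  A <- matrix(0, 1, 3)
  sys <- attach_indicators(A, "=", 0, lb = rep(0, 3), ub = rep(Inf, 3),
                           link_cols = 1:3,
                           groups = list(a = 1, b = 2, c = 3))
  s1 <- add_exclusion_constraint(sys, c(1, 2))
  lastrow <- nrow(s1$bin_rows$mat)
  expect_equal(unname(s1$bin_rows$mat[lastrow, ]), c(1, 1, 0))
  expect_equal(s1$bin_rows$rhs[lastrow], 1)

  # single-member support over a vp/vn group: zp + zn <= 0
  sys2 <- attach_indicators(A, "=", 0, lb = rep(0, 3), ub = rep(Inf, 3),
                            link_cols = 1:3,
                            groups = list(r3 = c(1, 2), r4 = 3))
  s2 <- add_exclusion_constraint(sys2, 1)
  lastrow <- nrow(s2$bin_rows$mat)
  expect_equal(unname(s2$bin_rows$mat[lastrow, ]), c(1, 1, 0))
  expect_equal(s2$bin_rows$rhs[lastrow], 0)

  expect_error(add_exclusion_constraint(sys, integer(0)), "empty support")
})

test_that("after excluding a set no superset is ever returned", {
  di <- make_toy("diamond")
  tgt <- parse_constraints("1 R4 >= 1")
  res <- smallest_mcs(intervention_problem(di, tgt, max_size = 4))
  fam <- res$cutsets
  # {R1} is found; nothing like {R1, R5} may appear
  expect_true(any(vapply(fam, identical, TRUE, "R1")))
  for (i in seq_along(fam)) for (j in seq_along(fam)) {
    if (i != j) expect_false(all(fam[[i]] %in% fam[[j]]))
  }
})

test_that("iterative enumeration returns shortest modes first", {
  # single pathway: one mode, then exhaustion
  ch <- make_toy("chain")
  r <- shortest_ems(ch, enumeration_config("iterative"))
  expect_same_family(r$ems, list(c("R1", "R2", "R3")))
  expect_equal(r$state$status, "complete")

  # diamond: two modes of size 3
  di <- make_toy("diamond")
  r2 <- shortest_ems(di, enumeration_config("iterative"))
  expect_same_family(r2$ems, list(c("R1", "R2", "R4"), c("R1", "R3", "R4")))

  # dual search in size order
  res <- smallest_mcs(intervention_problem(di, parse_constraints("1 R4 >= 1"),
                                           max_size = 3),
                      enumeration_config("iterative"))
  expect_same_family(res$cutsets, list("R1", "R4", c("R2", "R3")))
  expect_equal(lengths(res$cutsets), c(1, 1, 2))
})

test_that("fixed-size enumeration walks size classes exhaustively", {
  di <- make_toy("diamond")
  res <- smallest_mcs(intervention_problem(di, parse_constraints("1 R4 >= 1"),
                                           max_size = 2),
                      enumeration_config("fixed_size"))
  expect_same_family(res$cutsets, list("R1", "R4", c("R2", "R3")))
  sizes <- lengths(res$cutsets)
  expect_true(all(diff(sizes) >= 0))
  expect_equal(res$state$status, "complete")
  expect_setequal(res$state$complete_sizes, 1:2)

  # exhaustion with nothing to find: complete and empty
  ch <- make_toy("chain")
  resk <- smallest_mcs(intervention_problem(ch, parse_constraints("1 R3 >= 1"),
                                            knockable = "R2", max_size = 1))
  expect_same_family(resk$cutsets, list("R2"))
})

test_that("both algorithms and link modes agree on random networks", {
  insts <- random_instances(6, base_seed = 400)
  for (inst in insts) {
    fams <- list()
    for (algo in c("fixed_size", "iterative"))
      for (mode in c("indicator", "bigM")) {
        res <- smallest_mcs(
          intervention_problem(inst$net, inst$target, max_size = 3),
          enumeration_config(algo, size_ub = 3, mode = mode))
        fams[[paste(algo, mode)]] <- family_key(res$cutsets)
      }
    for (k in seq_along(fams)[-1])
      expect_identical(fams[[k]], fams[[1]])
  }
})

test_that("k-shortest modes equal the k smallest brute-force supports", {
  for (inst in random_instances(4, base_seed = 500)) {
    sp <- split_reversible(inst$net)$network
    bf <- enumerate_ems_bruteforce(sp, max_reactions = 18)
    ml <- shortest_ems(sp, enumeration_config("fixed_size"))
    expect_same_family(ml$ems, bf)
    expect_true(all(diff(lengths(ml$ems)) >= 0))
  }
})

test_that("split two-cycles never appear as modes", {
  sp <- split_reversible(make_toy("cycle_rev"))
  r <- shortest_ems(sp$network, enumeration_config("fixed_size"))
  for (em in r$ems)
    expect_false(all(c("R2_fwd", "R2_bwd") %in% em))
  expect_same_family(r$ems, list(c("R1", "R2_fwd", "R3")))
})

test_that("solution and size limits surface in the state", {
  di <- make_toy("diamond")
  res <- smallest_mcs(intervention_problem(di, parse_constraints("1 R4 >= 1"),
                                           max_size = 3, max_solutions = 2),
                      enumeration_config("iterative", size_ub = 3,
                                         max_solutions = 2))
  expect_equal(res$state$status, "solution_limit")
  expect_length(res$cutsets, 2)
})

test_that("enlarging the target polyhedron never shrinks the smallest cut", {
  for (inst in random_instances(4, n_reactions = 7, base_seed = 600)) {
    net <- inst$net
    exp_id <- tail(net$reaction_ids, 1)
    imp_id <- net$reaction_ids[length(net$reaction_ids) - 1L]
    small <- parse_constraints(sprintf("1 %s >= 1", exp_id))
    big <- parse_constraints(sprintf("1 %s + 1 %s >= 1", exp_id, imp_id))
    f1 <- smallest_mcs(intervention_problem(net, small, max_size = 4))$cutsets
    v <- validate_target(net, big)
    if (!v$nonempty) next
    f2 <- smallest_mcs(intervention_problem(net, big, max_size = 4))$cutsets
    if (length(f1) && length(f2))
      expect_gte(min(lengths(f2)), min(lengths(f1)))
  }
})
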