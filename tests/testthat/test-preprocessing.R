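test_that("FVA finds blocked reactions", {
  # chain without its import: nothing can flow
  net <- drop_reactions(make_toy("chain"), "R1")
  expect_setequal(fva_blocked_reactions(net), c("R2", "R3"))

  # diamond: every reaction can carry flux
  expect_length(fva_blocked_reactions(make_toy("diamond")), 0)

  # a reaction producing a metabolite without consumer is blocked
  S <- matrix(c(1, 0, -1, 0, -1, 1), 2, 3,
              dimnames = list(c("A", "D"), c("R1", "R2", "RD")))
  net <- metabolic_network(S, knockable = rep(TRUE, 3))
  expect_equal(fva_blocked_reactions(net), "RD")

  # infeasible context is reported, not silently ignored
  expect_error(
    fva_blocked_reactions(make_toy("chain"),
                          parse_constraints(c("1 R3 >= 1", "1 R3 <= -1"))),
    "context polyhedron empty")
})

test_that("FVA result does not depend on reaction ordering", {
  net <- make_random(4, 8, 0.3, seed = 5)
  blocked <- fva_blocked_reactions(net)
  perm <- rev(seq_along(net$reaction_ids))
  net2 <- metabolic_network(net$stoich[, perm],
                            reversible = net$reversible[perm],
                            knockable = net$knockable[perm])
  expect_setequal(fva_blocked_reactions(net2), blocked)
})

test_that("compression lumps fully coupled reactions", {
  # a linear chain collapses into one lumped reaction of 3 members
  cc <- compress_network(make_toy("chain"))
  expect_length(cc$map$subsets, 1)
  expect_setequal(cc$map$subsets[[1]]$members, c("R1", "R2", "R3"))

  # diamond: R1 and R4 couple 1:1, the parallel R2/R3 stay separate
  cd <- compress_network(make_toy("diamond"))
  expect_length(cd$map$subsets, 3)
  lump14 <- Filter(function(s) "R1" %in% s$members, cd$map$subsets)[[1]]
  expect_setequal(lump14$members, c("R1", "R4"))
  expect_equal(unname(lump14$ratios), c(1, 1))
  singles <- setdiff(names(cd$map$subsets), lump14$lumped_id)
  expect_length(singles, 2)

  # compressed steady-state space corresponds 1:1 with the original:
  # same minimal cut sets after decompression (checked further below)
  expect_true(cd$network$knockable[colnames(cd$network$stoich) ==
                                   lump14$lumped_id])
})

test_that("decompression expands lumped members as Cartesian products", {
  cc <- compress_network(make_toy("chain"))
  L <- names(cc$map$subsets)[1]
  expect_same_family(decompress_cutsets(list(L), cc$map),
                     list("R1", "R2", "R3"))

  # counting: |L1 knockable| = 2 and |L2 knockable| = 3 give 6 pairs
  map <- structure(list(subsets = list(
    L1 = list(lumped_id = "L1", members = c("A1", "A2"), ratios = c(1, 1),
              knockable = c(TRUE, TRUE)),
    L2 = list(lumped_id = "L2", members = c("B1", "B2", "B3"),
              ratios = c(1, 1, 1), knockable = rep(TRUE, 3))),
    removed_blocked = character(0)), class = "compression_map")
  out <- decompress_cutsets(list(c("L1", "L2")), map)
  expect_length(out, 6)
  expect_true(all(lengths(out) == 2))

  # only knockable members are expanded
  map$subsets$L1$knockable <- c(FALSE, TRUE)
  out2 <- decompress_cutsets(list("L1"), map)
  expect_same_family(out2, list("A2"))

  expect_error(decompress_cutsets(list("NOPE"), map), "unknown lumped")
})

test_that("compress-then-decompress of singleton cut sets is lossless", {
  net <- make_random(4, 9, 0, seed = 21)
  net <- drop_reactions(net, fva_blocked_reactions(net))
  cc <- compress_network(net)
  fam <- lapply(names(cc$map$subsets), function(L) L)
  expanded <- decompress_cutsets(fam, cc$map)
  expect_setequal(unlist(expanded), net$reaction_ids[net$knockable])
})

test_that("desired-essential reactions are found by single-knockout LPs", {
  br <- make_toy("branch")
  des <- parse_constraints("1 R4 >= 1", label = "desired")
  expect_setequal(desired_essential_reactions(br, des), c("R1", "R2", "R4"))

  # single pathway: everything is essential
  ch <- make_toy("chain")
  expect_setequal(
    desired_essential_reactions(ch, parse_constraints("1 R3 >= 1")),
    c("R1", "R2", "R3"))

  # unconstrained desired set in a redundant network: nothing essential
  di <- make_toy("diamond")
  des0 <- flux_constraints(matrix(0, 1, 4,
                                  dimnames = list(NULL, di$reaction_ids)),
                           rhs = 1, label = "desired")
  expect_setequal(desired_essential_reactions(di, des0,
                                              knockable = c("R2", "R3")),
                  character(0))

  expect_error(
    desired_essential_reactions(br, parse_constraints(c("1 R4 >= 1",
                                                        "1 R4 <= -1"))),
    "desired polyhedron empty")
})
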