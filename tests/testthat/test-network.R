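test_that("tabular model reading transcribes a simple chain", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\treversible",
               "R1\t-> A\t0", "R2\tA -> B\t0", "R3\tB ->\t0"), f)
  net <- read_network(f, "tabular")
  expect_equal(length(net$metabolite_ids), 2)
  expect_equal(length(net$reaction_ids), 3)
  expect_false(any(net$reversible))
  expect_equal(unname(net$stoich[, "R2"]), c(-1, 1))
  expect_true(all(net$exchange[c(1, 3)]))
})

test_that("duplicate identifiers and bad records are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\t-> A", "R1\tA ->"), f)
  expect_error(read_network(f, "tabular"), "duplicate reaction")
  writeLines(c("reaction_id\tequation", "R1\tA B"), f)
  expect_error(read_network(f, "tabular"), "R1")
  expect_error(metabolic_network(matrix(0, 1, 2),
                                 reaction_ids = c("X", "X")),
               "duplicate")
  expect_error(metabolic_network(matrix(0, 1, 1), reversible = FALSE,
                                 lb = -1), "lower_bound")
})

test_that("SBML reading takes reversibility, bounds and boundary species", {
  f <- system.file("extdata", "toy_model.xml", package = "fluxcuts")
  net <- read_network(f)
  expect_equal(length(net$metabolite_ids), 3)   # A_ext is boundary
  expect_equal(net$reversible,
               net$reaction_ids == "R_ab")      # flag passthrough
  expect_equal(net$ub[net$reaction_ids == "R_upt"], 10)
  expect_equal(net$lb[net$reaction_ids == "R_ab"], -1000)
  expect_true(net$exchange[net$reaction_ids == "R_upt"])
})

test_that("write/read round-trip preserves the model", {
  for (name in c("chain", "diamond", "branch", "cycle_rev")) {
    net <- make_toy(name)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_network_tab(net, f)
    back <- read_network(f, "tabular")
    expect_equal(back$stoich[net$metabolite_ids, ], net$stoich,
                 tolerance = 1e-9)
    expect_equal(back$reversible, net$reversible)
    expect_equal(back$lb, net$lb)
    expect_equal(back$ub, net$ub)
  }
})

test_that("split_reversible produces suffixed irreversible pairs", {
  net <- make_toy("cycle_rev")
  sp <- split_reversible(net)
  expect_equal(nrow(sp$pairs), 1)
  expect_equal(sp$pairs$fwd, "R2_fwd")
  expect_equal(sp$pairs$bwd, "R2_bwd")
  expect_false(any(sp$network$reversible))
  expect_equal(unname(sp$network$stoich[, "R2_bwd"]),
               unname(-sp$network$stoich[, "R2_fwd"]))

  # identity on an all-irreversible network
  ir <- make_toy("chain")
  sp2 <- split_reversible(ir)
  expect_identical(sp2$network$reaction_ids, ir$reaction_ids)
  expect_equal(nrow(sp2$pairs), 0)

  # counting: 2 reversible of 5 -> 7 columns, 2 pairs
  br <- make_toy("branch")
  br$reversible[c(2, 3)] <- TRUE
  br$lb[c(2, 3)] <- -Inf
  sp3 <- split_reversible(br)
  expect_equal(length(sp3$network$reaction_ids), 7)
  expect_equal(nrow(sp3$pairs), 2)
})

test_that("splitting preserves the steady-state flux space", {
  # net fluxes of random steady states of the split network satisfy the
  # original constraints, and vice versa via LP feasibility of matched rows
  for (seed in c(11, 12, 13)) {
    net <- make_random(4, 8, 0.5, seed = seed)
    sp <- split_reversible(net)
    n <- length(net$reaction_ids)
    # sample a steady state of the original by maximizing a random objective
    lpd <- fluxcuts:::network_lp(net, use_bounds = FALSE)
    set.seed(seed)
    obj <- runif(n) - 0.5
    r <- solve_lp(obj, lpd$mat, lpd$dir, lpd$rhs,
                  pmax(lpd$lb, -5), pmin(lpd$ub, 5), maximize = TRUE)
    expect_equal(r$status, "optimal")
    # decompose into non-negative fwd/bwd parts and verify steady state
    v <- r$x
    spn <- sp$network
    vs <- stats::setNames(rep(0, length(spn$reaction_ids)),
                          spn$reaction_ids)
    for (j in seq_len(n)) {
      id <- net$reaction_ids[j]
      if (id %in% sp$pairs$orig) {
        vs[paste0(id, "_fwd")] <- max(v[j], 0)
        vs[paste0(id, "_bwd")] <- max(-v[j], 0)
      } else vs[id] <- v[j]
    }
    expect_lt(max(abs(spn$stoich %*% vs)), 1e-7)
    expect_true(all(vs >= -1e-9))
  }
})
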