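test_that("is_cmcs runs one feasibility LP per cut set", {
  br <- make_toy("branch")
  des <- parse_constraints("1 R4 >= 1", label = "desired")
  expect_true(is_cmcs(br, des, "R3"))     # flux survives through R2, R4
  expect_false(is_cmcs(br, des, "R1"))    # no substrate entry
  expect_true(is_cmcs(br, des, character(0)))
})

test_that("filter_cmcs keeps admissible sets in input order", {
  br <- make_toy("branch")
  des <- parse_constraints("1 R4 >= 1", label = "desired")
  mcs <- list("R1", "R3", "R5")
  kept <- filter_cmcs(br, des, mcs)
  expect_same_family(kept, list("R3", "R5"))
  expect_identical(kept[[1]], "R3")       # order preserved
  expect_lte(length(kept), length(mcs))

  # all sets failing the desired check is a valid outcome
  des_hard <- parse_constraints(c("1 R4 >= 1", "1 R5 >= 1"),
                                label = "desired")
  expect_length(filter_cmcs(br, des_hard, list("R2", "R3")), 0)
})

test_that("cut-set evaluation computes growth, guaranteed yield and SSP", {
  # forced pathway: A -> 2 P + X with X as 'biomass'
  S <- matrix(c(1, 0, 0, -1, 2, 1, 0, -1, 0, 0, 0, -1), 3, 4,
              dimnames = list(c("A", "P", "X"),
                              c("R_up", "R_conv", "R_exP", "R_exX")))
  net <- metabolic_network(S, knockable = rep(TRUE, 4))
  ev <- evaluate_cutset(net, character(0), "R_exP", "R_up", "R_exX",
                        uptake_limit = 10)
  expect_true(ev$feasible)
  expect_equal(ev$min_guaranteed_yield, 2)   # stoichiometry forces yield 2
  expect_equal(ev$max_growth, 10)
  expect_equal(ev$ssp, 20)

  # cutting the conversion kills growth entirely
  ev2 <- evaluate_cutset(net, "R_conv", product_rxn = "R_exP",
                         substrate_rxn = "R_up", growth_rxn = "R_exX",
                         uptake_limit = 10)
  expect_equal(ev2$max_growth, 0)

  # a growth floor as desired constraint rejects such a mutant
  des <- parse_constraints(c("1 R_exX + -0.1 R_up >= 0",
                             "1 R_exX >= 0.001"), label = "desired")
  expect_false(is_cmcs(net, des, "R_conv"))
  # and the linearized yield row builder produces the matching form
  yc <- yield_constraint(net, "R_exX", "R_up", y_min = 0.1,
                         direction = "desire_high_yield")
  expect_equal(unname(yc$coeffs[1, ]), c(-1, 0.1))  # normalized to <= form
})

test_that("a stricter desired space yields no supersets the lax one lacks", {
  # richer toy: two substrates, two routes to product, one to byproduct
  S <- matrix(0, 4, 8,
              dimnames = list(c("A", "B", "P", "Q"),
                              c("U1", "U2", "C1", "C2", "C3", "EP", "EQ", "EB")))
  S["A", "U1"] <- 1; S["B", "U2"] <- 1
  S["A", "C1"] <- -1; S["P", "C1"] <- 1
  S["B", "C2"] <- -1; S["P", "C2"] <- 1
  S["A", "C3"] <- -1; S["Q", "C3"] <- 1
  S["P", "EP"] <- -1; S["Q", "EQ"] <- -1; S["B", "EB"] <- -1
  net <- metabolic_network(S, knockable = rep(TRUE, 8))
  tgt <- parse_constraints("1 EQ >= 1")
  lax <- parse_constraints("1 EP >= 1", label = "desired")
  strict <- parse_constraints(c("1 EP >= 1", "1 C1 <= 0"), label = "desired")
  res <- smallest_mcs(intervention_problem(net, tgt, max_size = 3))
  cl <- filter_cmcs(net, lax, res$cutsets)
  cstr <- filter_cmcs(net, strict, res$cutsets)
  # every strict-scenario cMCS is admissible in the lax scenario, and no
  # strict cMCS is a strict superset of a lax one of smaller size
  for (cs in cstr) {
    expect_true(any(vapply(cl, function(x) setequal(x, cs), TRUE)))
  }
  # cMCSs inherit MCS soundness and minimality
  for (cs in cstr) {
    chk <- check_cutset(net, tgt, cs)
    expect_true(chk$blocks && chk$minimal)
  }
})
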