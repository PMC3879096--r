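test_that("dual system dimensions follow the construction", {
  ch <- make_toy("chain")
  tgt <- parse_constraints("1 R3 >= 1")
  dual <- build_dual_system(ch, tgt)
  # 2 metabolite columns, 3 vp/vn pairs, 1 target-row column
  expect_length(dual$u_cols, 2)
  expect_length(dual$vp_cols, 3)
  expect_length(dual$vn_cols, 3)
  expect_length(dual$w_cols, 1)
  # 3 structural rows (one per reaction) + the inhomogeneity row
  expect_equal(nrow(dual$A), 4)
  expect_equal(dual$dir, c(">=", ">=", ">=", "<="))
  expect_equal(dual$rhs, c(0, 0, 0, -1))
  # vp and vn columns are negatives of each other in structural rows
  expect_equal(dual$A[1:3, dual$vp_cols], -dual$A[1:3, dual$vn_cols])
})

test_that("non-knockable reactions have their dual variables fixed to zero", {
  ch <- make_toy("chain")
  dual <- build_dual_system(ch, parse_constraints("1 R3 >= 1"),
                            knockable = c("R2", "R3"))
  expect_equal(dual$ub[dual$vp_cols[1]], 0)
  expect_equal(dual$ub[dual$vn_cols[1]], 0)
  expect_false("R1" %in% names(dual$groups))
})

test_that("collapse_solution maps indicator pairs to reaction sets", {
  ch <- make_toy("chain")
  dual <- build_dual_system(ch, parse_constraints("1 R3 >= 1"))
  expect_equal(collapse_solution(dual, c(1, 0, 0), c(0, 0, 0)), "R1")
  expect_equal(collapse_solution(dual, c(0, 1, 0), c(0, 0, 1)),
               c("R2", "R3"))
  expect_length(collapse_solution(dual, c(0, 0, 0), c(0, 0, 0)), 0)
  expect_error(collapse_solution(dual, c(1, 0, 0), c(1, 0, 0)),
               "consistency")
})

test_that("every feasible dual support is a Farkas certificate", {
  # sign-convention-proof self-validation: any enumerated dual support
  # must make the corresponding primal LP infeasible
  for (inst in random_instances(5, base_seed = 300)) {
    res <- smallest_mcs(intervention_problem(inst$net, inst$target,
                                             max_size = 3))
    for (cs in res$cutsets) {
      chk <- check_cutset(inst$net, inst$target, cs)
      expect_true(chk$blocks)
      expect_true(chk$minimal)
    }
  }
})

test_that("the certificate scale constant does not change the family", {
  di <- make_toy("diamond")
  tgt <- parse_constraints("1 R4 >= 1")
  fams <- lapply(c(0.5, 1, 10), function(cs)
    smallest_mcs(intervention_problem(di, tgt, max_size = 3),
                 c_scale = cs)$cutsets)
  expect_same_family(fams[[1]], fams[[2]])
  expect_same_family(fams[[2]], fams[[3]])
})

test_that("reversible reactions touched by the target are split and regrouped", {
  net <- make_toy("cycle_rev")          # R2 is reversible
  tgt <- parse_constraints("1 R2 >= 1") # target touches the reversible one
  dual <- build_dual_system(net, tgt)
  expect_length(dual$vp_cols, 4)        # R2 contributes two parts
  expect_length(dual$groups[["R2"]], 4) # both parts share one group
  res <- smallest_mcs(intervention_problem(net, tgt, max_size = 2))
  for (cs in res$cutsets)
    expect_true(all(cs %in% net$reaction_ids))   # reported unsplit
  expect_true(any(vapply(res$cutsets, identical, TRUE, "R2")))
})

test_that("the dual matrix dumps in MatrixMarket coordinate format", {
  dual <- build_dual_system(make_toy("chain"), parse_constraints("1 R3 >= 1"))
  f <- withr::local_tempfile(fileext = ".mtx")
  write_dual_mtx(dual, f)
  ln <- readLines(f)
  expect_match(ln[1], "MatrixMarket")
  dims <- as.numeric(strsplit(ln[2], " ")[[1]])
  expect_equal(dims[1:2], dim(dual$A))
  expect_equal(dims[3], sum(dual$A != 0))
  expect_equal(length(ln) - 2, dims[3])
})
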