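# independent oracle: the governing equations hand-coded row by row from the
# rate vector, without the stoichiometric matrix
direct_field <- function(R, p) {
  c(Na_n = R[["1"]] - 3 * R[["3"]] + R[["40"]],
    Na_g = R[["2"]] - 3 * R[["4"]] + R[["41"]],
    GLC_n = (R[["5f"]] - R[["5b"]]) - R[["9"]],
    GLC_g = (R[["6f"]] - R[["6b"]]) + (R[["7f"]] - R[["7b"]]) - R[["10"]],
    GAP_n = 2 * R[["9"]] - R[["11"]],
    GAP_g = 2 * R[["10"]] - R[["12"]],
    PEP_n = R[["11"]] - R[["13"]],
    PEP_g = R[["12"]] - R[["14"]],
    PYR_n = R[["13"]] - (R[["15f"]] - R[["15b"]]) - R[["21"]],
    PYR_g = R[["14"]] - (R[["16f"]] - R[["16b"]]) - R[["23"]],
    LAC_n = (R[["15f"]] - R[["15b"]]) - (R[["17f"]] - R[["17b"]]),
    LAC_g = (R[["16f"]] - R[["16b"]]) - (R[["18f"]] - R[["18b"]]) -
      (R[["19f"]] - R[["19b"]]),
    NADHcyto_n = p$c1 * (R[["11"]] - (R[["15f"]] - R[["15b"]]) - R[["25"]]),
    NADHcyto_g = p$c1 * (R[["12"]] - (R[["16f"]] - R[["16b"]]) - R[["26"]]),
    NADHmito_n = p$c2 * (4 * R[["21"]] - R[["22"]] + R[["25"]]),
    NADHmito_g = p$c2 * (4 * R[["23"]] - R[["24"]] + R[["26"]]),
    ATP_n = -2 * R[["54"]] + R[["56"]] + R[["58"]] - R[["34"]] - R[["60"]] +
      3.6 * R[["62"]] + R[["64f"]] - R[["64b"]],
    ATP_g = -2 * R[["55"]] + R[["57"]] + R[["59"]] - R[["35"]] +
      0.75 * R[["36"]] - 1.75 * R[["61"]] + 3.6 * R[["63"]] +
      R[["65f"]] - R[["65b"]],
    PCr_n = -(R[["27f"]] - R[["27b"]]),
    PCr_g = -(R[["28f"]] - R[["28b"]]),
    O2_n = R[["29"]] - 0.6 * R[["22"]],
    O2_g = R[["30"]] - 0.6 * R[["24"]],
    O2_c = R[["31"]] - p$r1 * R[["29"]] - p$r2 * R[["30"]],
    GLC_c = R[["32"]] - p$r2 * (R[["7f"]] - R[["7b"]]) -
      p$r3 * (R[["8f"]] - R[["8b"]]),
    LAC_c = R[["33"]] + p$r2 * (R[["19f"]] - R[["19b"]]) +
      p$r3 * (R[["20f"]] - R[["20b"]]),
    Vv = R[["37"]],
    dHb = R[["38"]] - R[["39"]],
    GLC_e = -p$r4 * (R[["5f"]] - R[["5b"]]) - p$r5 * (R[["6f"]] - R[["6b"]]) +
      (R[["8f"]] - R[["8b"]]),
    LAC_e = p$r4 * (R[["17f"]] - R[["17b"]]) +
      p$r5 * (R[["18f"]] - R[["18b"]]) - (R[["20f"]] - R[["20b"]]))
}

test_that("matrix-times-rates reproduces every governing equation", {
  p <- fix_params()
  proto <- activation_protocol(params = p)
  S <- stoichiometric_matrix(p)
  for (seed in 1:20) {
    y <- rand_state(seed)
    R <- compute_rates(y, p, t = 100, protocol = proto)
    expect_equal(drop(S %*% R), direct_field(R, p), tolerance = 1e-12)
  }
})

test_that("phosphocreatine row is exactly the creatine-kinase net rate", {
  p <- fix_params()
  y <- rand_state(3)
  R <- compute_rates(y, p)
  g <- vector_field(y, p)
  expect_identical(unname(g["PCr_n"]), unname(-(R["27f"] - R["27b"])))
  expect_identical(unname(g["PCr_g"]), unname(-(R["28f"] - R["28b"])))
})

test_that("capillary-lactate sensitivity follows its transport couplings", {
  # LAC_c enters only the lactate transports 19b/20b and the capillary flow
  # 33, so only LAC_g, LAC_e and LAC_c respond to a LAC_c perturbation
  p <- fix_params()
  J <- jacobian_full(resting_state(), p)
  responding <- state_names()[abs(J[, "LAC_c"]) > 1e-14]
  expect_setequal(responding, c("LAC_g", "LAC_e", "LAC_c"))
  # finite-difference sensitivity scan agrees
  y <- resting_state(); h <- 1e-6
  y2 <- y; y2["LAC_c"] <- y["LAC_c"] + h
  dg <- (vector_field(y2, p) - vector_field(y, p)) / h
  expect_setequal(state_names()[abs(dg) > 1e-8], c("LAC_g", "LAC_e", "LAC_c"))
})
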