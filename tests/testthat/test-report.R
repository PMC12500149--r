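test_that("dominant-mode report applies thresholds and records normalizations", {
  fx <- scenario_fixture()
  per <- fx$periods
  p3 <- per[per$epoch == "activation" & per$M == 27, ][1, ]
  rep3 <- dominant_mode_report(p3, fx$traj, t_rep = 850)
  # threshold semantics: everything reported clears the filters, and the
  # pre-filter sums still satisfy the normalization identities
  expect_true(all(rep3$species$Po >= rep3$po_min))
  expect_true(all(abs(rep3$reactions$TPI) >= rep3$tpi_min))
  expect_equal(rep3$po_sum, 1, tolerance = 1e-8)
  expect_equal(rep3$tpi_abs_sum, 1, tolerance = 1e-8)
  expect_equal(order(-abs(rep3$reactions$TPI)),
               seq_len(nrow(rep3$reactions)))
  expect_error(dominant_mode_report(p3, fx$traj, t_rep = 1e6), "span")
})

test_that("a single-reaction mode reports all of the timescale", {
  S <- matrix(1, 1, 1, dimnames = list("y", "r1"))
  dR <- matrix(-2, 1, 1, dimnames = list("r1", "y"))
  d <- eigendecompose(S %*% dR, g = -0.6)
  tpi <- timescale_participation_index(d, S, dR, 1)
  expect_equal(as.numeric(tpi), -1)  # -100%: single dissipative contribution
})

test_that("equilibria graph classifies strong and weak reactions disjointly", {
  fx <- scenario_fixture()
  p1 <- list(label = "P1", M = 17, dominant_mode = 18, t_rep = 25,
             start = 0, end = 60)
  g1 <- equilibria_graph(p1, fx$traj)
  expect_true(all(g1$reactions$class %in% c("strong", "weak")))
  strong <- g1$reactions$label[g1$reactions$class == "strong"]
  weak <- g1$reactions$label[g1$reactions$class == "weak"]
  expect_length(intersect(strong, weak), 0)
  expect_true(all(abs(g1$reactions$API[g1$reactions$class == "strong"]) >
                  g1$strong_min))
  expect_true(all(g1$species$Po > g1$po_min))
  expect_true(all(g1$reactions$mode <= p1$M))
  # M = 0 gives an empty graph with a warning
  p0 <- list(label = "P0", M = 0, dominant_mode = 1, t_rep = 25)
  expect_warning(g0 <- equilibria_graph(p0, fx$traj), "no exhausted modes")
  expect_equal(nrow(g0$reactions), 0)
})

test_that("written outputs round-trip and are byte stable", {
  fx <- scenario_fixture()
  per <- fx$periods
  p3 <- per[per$epoch == "activation" & per$M == 27, ][1, ]
  rep3 <- dominant_mode_report(p3, fx$traj, t_rep = 850)
  p1 <- list(label = "P1", M = 17, dominant_mode = 18, t_rep = 25,
             start = 0, end = 60)
  g1 <- equilibria_graph(p1, fx$traj)
  d1 <- withr::local_tempdir()
  files <- write_outputs(list(rep3), list(g1), d1)
  expect_true(all(file.exists(files)))
  tab <- read_report_table(file.path(d1, paste0("dominant_mode_",
                                                rep3$label, ".csv")))
  expect_equal(tab$item[tab$kind == "species"], rep3$species$name)
  expect_equal(tab$value[tab$kind == "reaction"], rep3$reactions$TPI)
  d2 <- withr::local_tempdir()
  write_outputs(list(rep3), list(g1), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("empty report set writes only the manifest", {
  d <- withr::local_tempdir()
  files <- write_outputs(list(), list(), d)
  expect_equal(basename(files), "manifest.json")
})
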