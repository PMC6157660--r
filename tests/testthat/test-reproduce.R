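# The full reproduction pipeline is computed once per test run; the
# acceptance checks in test-acceptance.R assert its published values.
report <- local({
  cfg <- run_config(mc = list(n_draws = 10000, seed = 42))
  suppressMessages(reproduce_paper(cfg))
})

test_that("the report carries every pipeline product", {
  expect_s3_class(report, "csia_report")
  expect_equal(nrow(report$fish_tp), 3)
  expect_equal(nrow(report$bird_tp), 7)
  expect_equal(report$diet_table$period, c("MWP", "LIA", "all"))
  expect_s3_class(report$tef_15N, "tef_table")
  expect_null(report$tef_13C) # the packaged tables carry no per-AA d13C
  expect_lt(report$paired_test$p_value, 0.001)
  expect_output(print(report), "Discrepancies")
})

test_that("recomputation flags the one irreproducible published mean", {
  flagged <- report$discrepancies[report$discrepancies$flagged, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$quantity, "period_tp_multi")
  expect_equal(flagged$item, "LIA")
})

test_that("Monte-Carlo diet sd approximates the affine propagation", {
  mwp <- report$diet_table[report$diet_table$period == "MWP", ]
  expect_equal(mwp$mc_sd, mwp$sd_affine, tolerance = 0.05)
  expect_equal(mwp$mc_clipped, 0L)
  lia <- report$diet_table[report$diet_table$period == "LIA", ]
  expect_gt(lia$mc_clipped, 0) # f = 0.37 +/- 0.30 must truncate
})

test_that("setting the avian TDF to the plankton value collapses the models", {
  cfg <- run_config(tdf = tdf_model(tdf_bird = 7.6),
                    mc = list(n_draws = 1000, seed = 1))
  degenerate <- suppressMessages(reproduce_paper(cfg))
  expect_equal(degenerate$bird_tp$tp_multi, degenerate$bird_tp$tp_single,
               tolerance = 1e-12)
})

test_that("run configurations round-trip through YAML", {
  cfg <- run_config(tdf = tdf_model(beta = 3.2, tdf_bird = 4.1),
                    sd_convention = "population",
                    mc = list(n_draws = 5000, seed = 7))
  f <- tempfile(fileext = ".yaml")
  writeLines(config_to_yaml(cfg), f)
  back <- read_run_config(f)
  expect_equal(back$tdf, cfg$tdf)
  expect_equal(back$sd_convention, "population")
  expect_equal(back$mc$n_draws, 5000)
  expect_equal(config_hash(back), config_hash(cfg))
  expect_false(config_hash(back) == config_hash(run_config()))
})

test_that("the CLI estimates, simulates deterministically, and validates", {
  out <- tempfile(fileext = ".csv")
  status <- cli_main(c("estimate", "--input", csia_fixture("table2_birds"),
                       "--method", "multi", "--output", out))
  expect_identical(status, 0L)
  est <- read.csv(out, comment.char = "#")
  expect_equal(nrow(est), 7)
  expect_equal(round_half_up(mean(est$tp), 2), 3.47)
  expect_match(readLines(out, n = 1), "^# csiaTP config=")

  # a specimen missing Phe fails with a nonzero status naming it
  broken <- tempfile(fileext = ".csv")
  write_specimens(list(specimen("nophe",
                                profile = aa_profile(d15N = c(Glu = 19)))),
                  broken)
  expect_message(bad <- cli_main(c("estimate", "--input", broken)), "nophe")
  expect_identical(bad, 1L)

  # simulate twice with one seed: byte-identical outputs
  chain_yaml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    levels = list(list(name = "producer", tp_true = 1),
                  list(name = "fish", tp_true = 2.4, tdf_type = "plankton"),
                  list(name = "bird", tp_true = 3.4, tdf_type = "bird")),
    noise_sd_aa = 0.2, n_per_level = 2)), chain_yaml)
  s1 <- tempfile(); t1 <- tempfile(); s2 <- tempfile(); t2 <- tempfile()
  expect_message(cli_main(c("simulate", "--config", chain_yaml, "--seed", "7",
                            "--out-specimens", s1, "--out-truth", t1)), "wrote")
  suppressMessages(cli_main(c("simulate", "--config", chain_yaml, "--seed", "7",
                              "--out-specimens", s2, "--out-truth", t2)))
  expect_identical(readLines(s1), readLines(s2))
  expect_identical(readLines(t1), readLines(t2))

  # validate reports QC flags for the packaged birds
  vout <- tempfile(fileext = ".csv")
  expect_message(cli_main(c("validate", "--input",
                            csia_fixture("table2_birds"),
                            "--output", vout)), "wrote")
  qc <- read.csv(vout, comment.char = "#")
  expect_true(all(qc$usable_for_tp))
  expect_match(qc$missing_aas[3], "Met")

  # usage errors exit 2
  expect_message(unknown <- cli_main("frobnicate"), "unknown command")
  expect_identical(unknown, 2L)
  expect_message(noval <- cli_main(c("estimate", "--input")), "missing value")
  expect_identical(noval, 2L)
})

test_that("the reproduce-paper command writes the report bundle", {
  outdir <- tempfile("report")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(config_to_yaml(run_config(mc = list(n_draws = 1000, seed = 3))),
             cfg)
  expect_message(status <- cli_main(c("reproduce-paper", "--config", cfg,
                                      "--outdir", outdir)), "wrote")
  expect_identical(status, 0L)
  written <- list.files(outdir)
  expect_true(all(c("fish_tp.csv", "bird_tp.csv", "period_summary.csv",
                    "period_diet_tp.csv", "tef_15N.csv", "discrepancies.csv",
                    "summary.txt") %in% written))
  disc <- read.csv(file.path(outdir, "discrepancies.csv"), comment.char = "#")
  expect_equal(sum(disc$flagged), 1)
})
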