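test_that("single-TDF model reproduces the published flying-fish TPs", {
  expect_equal(round_half_up(tp_single_tdf(18.0, 3.0)$tp, 2), 2.53)
  expect_equal(round_half_up(tp_single_tdf(19.3, 2.5)$tp, 2), 2.76)
  # producer spacing equals beta -> TP exactly 1, for any baseline
  for (p in c(-5, 0, 3.1, 12)) {
    expect_equal(tp_single_tdf(p + 3.4, p)$tp, 1, tolerance = 1e-12)
  }
})

test_that("multi-TDF model evaluates the avian formula", {
  # numerator zero at spacing = tdf_plankton + beta -> TP exactly 2
  expect_equal(tp_multi_tdf(14.4, 3.4)$tp, 2, tolerance = 1e-12)
  expect_equal(tp_multi_tdf(19.2, 4.1)$tp, 3.1714286, tolerance = 1e-6)
  expect_equal(tp_multi_tdf(20.6, 4.6)$tp, 3.4285714, tolerance = 1e-6)
})

test_that("multi-TDF is the exact affine rescaling of single-TDF", {
  set.seed(11)
  glu <- runif(200, 10, 25)
  phe <- runif(200, -2, 8)
  m <- tdf_model()
  tp1 <- tp_single_tdf(glu, phe, m)$tp
  tp2 <- tp_multi_tdf(glu, phe, m)$tp
  expect_equal(tp2, 2 + (m$tdf_plankton / m$tdf_bird) * (tp1 - 2),
               tolerance = 1e-12)
})

test_that("both estimators are monotone in Glu and Phe", {
  set.seed(12)
  glu <- runif(50, 10, 25)
  phe <- runif(50, -2, 8)
  eps <- 0.01
  for (fn in list(tp_single_tdf, tp_multi_tdf)) {
    expect_true(all(fn(glu + eps, phe)$tp > fn(glu, phe)$tp))
    expect_true(all(fn(glu, phe + eps)$tp < fn(glu, phe)$tp))
  }
})

test_that("k plankton steps above the producer give TP 1 + k", {
  for (k in c(0, 0.38, 1, 2.5)) {
    p <- 3.1
    expect_equal(tp_single_tdf(p + 3.4 + k * 7.6, p)$tp, 1 + k,
                 tolerance = 1e-12)
  }
})

test_that("size correction shifts TP by the bulk offset over bulk_step", {
  base <- tp_estimate(2.64, method = "single_tdf")
  expect_equal(round_half_up(size_correct_tp(base, 9.2, 10.1)$tp, 2), 2.38)
  expect_equal(size_correct_tp(base, 10.1, 10.1)$tp, 2.64)
  expect_equal(size_correct_tp(base, 13.5, 10.1)$tp, 2.64 + 1,
               tolerance = 1e-12)
})

test_that("bulk-offset inference is linear in the delta15N difference", {
  fish <- tp_estimate(2.38, method = "size_corrected")
  expect_equal(round_half_up(tp_from_bulk_offset(fish, 10.2, 9.2)$tp, 2), 2.67)
  expect_equal(tp_from_bulk_offset(fish, 9.2, 9.2)$tp, 2.38)
  expect_equal(tp_from_bulk_offset(fish, 9.2 + 6.8, 9.2)$tp, 2.38 + 2,
               tolerance = 1e-12)
})

test_that("diet mass balance matches the published mixing line", {
  expect_equal(round_half_up(tp_diet(diet_model(0.88, 2.38, 2.67))$tp, 2), 3.41)
  expect_equal(round_half_up(tp_diet(diet_model(0.37, 2.38, 2.67))$tp, 2), 3.56)
  expect_equal(tp_diet(diet_model(1, 2.38, 2.67))$tp, 3.38)
  # affine in f: intercept tp_prey2 + 1, slope tp_prey1 - tp_prey2,
  # here 3.67 - 0.29 f
  f <- seq(0, 1, by = 0.25)
  tps <- vapply(f, function(x) tp_diet(diet_model(x, 2.38, 2.67))$tp,
                numeric(1))
  expect_equal(tps, 3.67 - 0.29 * f, tolerance = 1e-12)
  # bounded by prey range shifted one level
  set.seed(13)
  for (i in 1:25) {
    t1 <- runif(1, 1.5, 4); t2 <- runif(1, 1.5, 4); fr <- runif(1)
    tp <- tp_diet(diet_model(fr, t1, t2))$tp
    expect_gte(tp, min(t1, t2) + 1 - 1e-12)
    expect_lte(tp, max(t1, t2) + 1 + 1e-12)
  }
  expect_error(diet_model(1.2, 2.38, 2.67), "\\[0, 1\\]")
})

test_that("Glu-Phe spacing summarises fixtures with sample dispersion", {
  sp <- glu_phe_spacing(fish_fixture())
  expect_equal(sp$spacings, c(15.0, 15.9, 16.8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(round_half_up(sp$mean, 1), 15.9)
  expect_equal(round_half_up(sp$sd, 1), 0.9)
  one <- glu_phe_spacing(list(make_specimen("x", 18, 3)))
  expect_equal(one$mean, 15)
  expect_true(is.na(one$sd))
  same <- glu_phe_spacing(replicate(3, make_specimen("x", 18, 3),
                                    simplify = FALSE))
  expect_equal(same$sd, 0)
})

test_that("specimens missing Glu or Phe raise errors naming them", {
  s <- specimen("gone", profile = aa_profile(d15N = c(Glu = 18)))
  expect_error(estimate_tp(list(s), "single"), "'gone'.*Phe")
  expect_error(glu_phe_spacing(list(s)), "'gone'")
})

test_that("dispersion conventions differ by the n-1/n factor", {
  x <- c(2.53, 2.63, 2.76)
  expect_equal(dispersion(x, "population"),
               dispersion(x, "sample") * sqrt(2 / 3), tolerance = 1e-12)
  expect_true(is.na(dispersion(1)))
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(2.625, 2), 2.63)
  expect_equal(round_half_up(2.6447, 2), 2.64)
  expect_equal(round_half_up(-2.625, 2), -2.63)
  expect_equal(round_half_up(15.85, 1), 15.9)
})

test_that("model constants are configurable and validated", {
  m <- tdf_model(beta = 2.9, tdf_plankton = 8, tdf_bird = 4.1)
  expect_equal(tp_single_tdf(10.9, 0, m)$tp, 2)
  expect_error(tdf_model(tdf_bird = -1), "positive")
})
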