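test_that("baseline correction handles flat, clean and drifting traces", {
  pos <- seq(0, 100, length.out = 300)
  flat <- gradient_trace(pos, rep(3.7, 300))
  expect_equal(baseline_correct(flat)$absorbance, rep(0, 300))

  # a single Gaussian on a zero baseline passes through unchanged
  g <- 0.5 * exp(-(pos - 50)^2 / (2 * 3^2))
  clean <- baseline_correct(gradient_trace(pos, g))
  interior <- pos > 10 & pos < 90
  expect_lt(max(abs(clean$absorbance[interior] - g[interior])), 1e-6)

  # linear drift: recovered area within 2% of the drift-free area
  tr <- simulate_gradient_trace(
    data.frame(position = 50, area = 2, width = 3),
    drift = c(0.1, 0.003), noise_sd = 0)
  q <- quantify_profile(baseline_correct(tr),
                        peak_windows("30S" = c(10, 35), "50S" = c(35, 65)))
  expect_lt(abs(q$area[q$window == "50S"] - 2) / 2, 0.02)
})

test_that("windowed quantification recovers planted area ratios", {
  # two identical Gaussians -> ratio 1
  sym <- simulate_gradient_trace(
    data.frame(position = c(30, 54), area = c(1, 1), width = c(3, 3)),
    drift = c(0.05, 0.002), noise_sd = 0)
  expect_equal(ratio_50s_30s(quantify_profile(baseline_correct(sym))), 1,
               tolerance = 0.02)

  # planted 2:1 (50S:30S)
  two <- simulate_gradient_trace(
    data.frame(position = c(30, 54), area = c(1, 2), width = c(3, 3.5)),
    drift = c(0.05, 0.002), noise_sd = 0)
  expect_equal(ratio_50s_30s(quantify_profile(baseline_correct(two))), 2,
               tolerance = 0.04)

  # planted full-length-like ratio at 1% noise (absolute tolerance)
  tr <- planted_ratio_trace(0.34, seed = 1)
  expect_lte(abs(ratio_50s_30s(quantify_profile(baseline_correct(tr))) -
                   0.34), 0.02)

  # windows outside the trace span are rejected
  expect_error(
    quantify_profile(baseline_correct(tr),
                     peak_windows("30S" = c(-10, 5))),
    class = "ribostates_window_error")
})

test_that("area ratios in the mutant range are recovered within 5%", {
  # noise at 1% of the smaller peak's height, inside the stated regime of
  # noise sd <= 2% of peak height
  for (ratio in c(0.2, 0.34, 1.0, 1.92, 2.5)) {
    for (s in 1:5) {
      tr <- planted_ratio_trace(ratio, seed = s, ref = "min")
      got <- ratio_50s_30s(quantify_profile(baseline_correct(tr)))
      expect_lt(abs(got - ratio) / ratio, 0.05)
    }
  }
})

test_that("areas scale with absorbance and ratios are scale-invariant", {
  tr <- planted_ratio_trace(1.3, seed = 2)
  q1 <- quantify_profile(baseline_correct(tr))
  tr5 <- gradient_trace(tr$position, tr$absorbance * 5)
  q5 <- quantify_profile(baseline_correct(tr5))
  expect_equal(q5$area, q1$area * 5, tolerance = 1e-6)
  expect_equal(ratio_50s_30s(q5), ratio_50s_30s(q1), tolerance = 1e-9)
})

test_that("trapezoidal areas converge to the analytic Gaussian area", {
  errs <- vapply(c(100, 200, 400, 800), function(n) {
    tr <- simulate_gradient_trace(
      data.frame(position = 50, area = 1, width = 4),
      noise_sd = 0, n_points = n)
    q <- quantify_profile(tr, peak_windows("50S" = c(20, 80),
                                           "30S" = c(0, 20)))
    abs(q$area[q$window == "50S"] - 1)
  }, numeric(1))
  expect_true(all(diff(log(errs)) < 0 | errs[-1] < 1e-10))
})

test_that("mutant ranking orders by ratio with reference fold change", {
  q_of <- function(ratio, label) {
    tr <- planted_ratio_trace(ratio, seed = 3)
    attr(tr, "label") <- label
    quantify_profile(baseline_correct(tr))
  }
  quants <- list(q_of(0.34, "FL"), q_of(1.92, "I17N"), q_of(1.1, "D7A"))
  rk <- rank_mutants(quants, reference = "FL")
  expect_identical(rk$label, c("I17N", "D7A", "FL"))
  expect_equal(rk$fold_change[rk$label == "I17N"], 1.92 / 0.34,
               tolerance = 0.1 / (1.92 / 0.34) * 5.65)
  expect_equal(rk$fold_change[rk$label == "FL"], 1)

  expect_error(rank_mutants(quants, reference = "nope"),
               class = "ribostates_labeling_error")

  # equal-ratio ties order by label
  ties <- list(q_of(0.8, "b"), q_of(0.8, "a"), q_of(0.34, "FL"))
  expect_identical(rank_mutants(ties, "FL")$label[1:2], c("a", "b"))
})

test_that("window sets validate ordering and overlap", {
  expect_error(peak_windows("30S" = c(10, 30), "50S" = c(25, 50)),
               class = "ribostates_window_error")
  w <- peak_windows("50S" = c(42, 66), "30S" = c(18, 42))
  expect_identical(w$window, c("30S", "50S"))  # sorted by position
})
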