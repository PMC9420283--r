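test_that("preventive fraction is Pr(1 - RR) with a guarded domain", {
  expect_equal(preventive_fraction(0.15, 0.85), 0.0225)
  expect_equal(preventive_fraction(0.50, 0.68), 0.16)
  expect_equal(preventive_fraction(0.35, 1.0), 0)
  expect_error(preventive_fraction(0.15, 1.02), class = "dairyburden_domain_error")
  expect_error(preventive_fraction(0, 0.85), class = "dairyburden_domain_error")
  expect_error(preventive_fraction(1.2, 0.85), class = "dairyburden_domain_error")
})

test_that("invert_rr is the exact reciprocal", {
  expect_equal(invert_rr(1.0), 1.0)
  expect_equal(invert_rr(0.5), 2.0)
  expect_equal(invert_rr(0.85), 20 / 17) # 1.176470588..., feeds the 2.58% PARP
  expect_error(invert_rr(0), class = "dairyburden_domain_error")
  expect_error(invert_rr(-1), class = "dairyburden_domain_error")
})

test_that("parp matches its closed form and rejects protective inversions", {
  # closed form pr(1-rr)/(rr + pr(1-rr)) as the independent check
  expect_equal(parp(0.15, invert_rr(0.85)),
               0.15 * 0.15 / (0.85 + 0.15 * 0.15))
  expect_equal(round_half_up(100 * parp(0.15, invert_rr(0.85)), 2), 2.58)
  expect_equal(parp(0.50, invert_rr(0.68)), 4 / 21) # 0.190476... -> 19.05%
  expect_equal(parp(0.25, 1.0), 0)
  expect_error(parp(0.25, 0.99), class = "dairyburden_domain_error")
})

test_that("parp equals the closed form to 1e-12 relative error on a dense grid", {
  pr <- seq(0.01, 1, by = 0.01)
  rr <- seq(0.02, 1, by = 0.02)
  grid <- expand.grid(pr = pr, rr = rr)
  direct <- parp(grid$pr, 1 / grid$rr)
  closed <- grid$pr * (1 - grid$rr) / (grid$rr + grid$pr * (1 - grid$rr))
  rel <- abs(direct - closed) / pmax(abs(closed), .Machine$double.xmin)
  expect_lt(max(rel[closed > 0]), 1e-12)
  expect_equal(direct[closed == 0], closed[closed == 0])
})

test_that("sweep_fractions reproduces published rows after display rounding", {
  ev <- dairy_evidence()
  breast <- ev[ev$outcome_id == "breast_cancer" & ev$exposure_category == "total_dairy", ]
  out <- sweep_fractions(breast)
  expect_equal(round_half_up(100 * out$preventive_fraction, 2),
               c(2.25, 3.75, 5.25, 7.50))
  expect_equal(round_half_up(100 * out$parp, 2), c(2.58, 4.23, 5.82, 8.11))

  t2d <- ev[ev$outcome_id == "t2d" & ev$exposure_category == "total_dairy", ]
  at15 <- sweep_fractions(t2d, grid = 0.15)
  expect_equal(round_half_up(100 * at15$preventive_fraction, 2), 1.35)
  expect_equal(round_half_up(100 * at15$parp, 2), 1.46)

  expect_error(sweep_fractions(breast, grid = numeric(0)),
               class = "dairyburden_domain_error")
  not_sig <- make_estimate(srre = 1.06, ci_lower = 0.92, ci_upper = 1.22)
  expect_error(sweep_fractions(not_sig), class = "dairyburden_domain_error")
})

test_that("interval_fractions propagates CI bounds and clamps at the null", {
  breast <- make_estimate() # 0.85 (0.76, 0.95)
  out <- interval_fractions(breast, grid = 0.15)
  expect_equal(out$pf_conservative, 0.15 * (1 - 0.95)) # 0.0075
  expect_equal(out$pf_optimistic, 0.15 * (1 - 0.76))   # 0.0360
  expect_true(out$parp_conservative < out$parp & out$parp < out$parp_optimistic)
  expect_false(out$conservative_clamped)

  degenerate <- make_estimate(srre = 0.85, ci_lower = 0.85, ci_upper = 0.85)
  deg <- interval_fractions(degenerate, grid = 0.25)
  expect_equal(deg$pf_conservative, deg$preventive_fraction)
  expect_equal(deg$pf_optimistic, deg$preventive_fraction)

  touching <- make_estimate(srre = 0.90, ci_lower = 0.80, ci_upper = 1.00)
  tch <- interval_fractions(touching, grid = c(0.15, 0.50))
  expect_true(all(tch$conservative_clamped))
  expect_equal(tch$pf_conservative, c(0, 0))
  expect_equal(tch$parp_conservative, c(0, 0))
})

test_that("fractions are linear in pr, dominated by parp, and monotone", {
  ev <- dairy_evidence()
  set <- build_analysis_set(ev, us_dalys_2019())
  swept <- sweep_fractions(set)

  # linearity: PF at Pr 50% is (0.50/0.15) x PF at Pr 15% in every row pair
  by_est <- split(swept, paste(swept$outcome_id, swept$exposure_category))
  for (cells in by_est) {
    expect_equal(cells$preventive_fraction[cells$pr == 0.50],
                 (10 / 3) * cells$preventive_fraction[cells$pr == 0.15])
  }

  # dominance on every cell (all rr < 1, 0 < pr < 1)
  expect_true(all(swept$parp > swept$preventive_fraction))

  # monotone in pr and in (1 - rr)
  pr <- c(0.1, 0.2, 0.4, 0.8)
  for (rr in c(0.68, 0.85, 0.94)) {
    expect_true(all(diff(preventive_fraction(pr, rr)) > 0))
    expect_true(all(diff(parp(pr, 1 / rr)) > 0))
  }
  rr_seq <- seq(0.95, 0.55, by = -0.05)
  for (p in pr) {
    expect_true(all(diff(preventive_fraction(p, rr_seq)) > 0))
    expect_true(all(diff(parp(p, 1 / rr_seq)) > 0))
  }

  # null effect gives zero for any prevalence
  expect_equal(preventive_fraction(pr, 1), rep(0, 4))
  expect_equal(parp(pr, 1), rep(0, 4))
})

test_that("prevalence grid validates shape and labels scenarios", {
  g <- prevalence_grid()
  expect_equal(g$pr, c(0.15, 0.25, 0.35, 0.50))
  expect_equal(g$label[1], "Pr 15%")
  expect_error(prevalence_grid(c(0.5, 0.15)), class = "dairyburden_domain_error")
  expect_error(prevalence_grid(c(0, 0.5)), class = "dairyburden_domain_error")
  expect_error(prevalence_grid(numeric(0)), class = "dairyburden_domain_error")
})
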