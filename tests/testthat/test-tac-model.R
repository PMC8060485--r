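test_that("gamma-variate evaluation matches the closed form", {
  p <- gamma_variate_params(t0 = 10, alpha = 3, beta = 2, K = 1,
                            baseline = 40)
  # at and before bolus arrival the curve sits on the baseline
  expect_equal(eval_gamma_variate(p, 10), 40)
  expect_equal(eval_gamma_variate(p, 3), 40)
  # direct evaluation at the analytic mode t0 + alpha*beta = 16
  expect_equal(eval_gamma_variate(p, 16), 40 + 216 * exp(-3))
  expect_equal(gv_peak_time(p), 16)
  # dense-grid argmax agrees with the analytic mode
  tt <- seq(10, 40, by = 0.001)
  expect_equal(tt[which.max(eval_gamma_variate(p, tt))], 16,
               tolerance = 1e-3)
  expect_error(gamma_variate_params(10, -1, 2, 1), "alpha")
  expect_error(gamma_variate_params(10, 3, 0, 1), "beta")
  expect_error(gamma_variate_params(10, 3, 2, 0), "K")
})

test_that("the gamma-variate curve is non-negative and unimodal", {
  set.seed(1)
  tt <- seq(0.5, 60, by = 0.05)
  for (i in 1:20) {
    p <- gamma_variate_params(
      t0 = runif(1, 2, 15), alpha = runif(1, 0.5, 6),
      beta = runif(1, 0.5, 4), K = runif(1, 0.1, 50),
      baseline = runif(1, 30, 50)
    )
    enh <- eval_gamma_variate(p, tt) - p$baseline
    expect_true(all(enh >= 0))
    # unimodal: the sign of the finite difference changes at most once
    d <- diff(enh[tt > p$t0])
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)
  }
})

test_that("gv_from_peak hits the requested peak enhancement", {
  p <- gv_from_peak(t0 = 11, alpha = 3, beta = 2.5, peak_enhancement = 250,
                    baseline = 42)
  expect_equal(eval_gamma_variate(p, gv_peak_time(p)) - 42, 250)
})

test_that("sample_tac is deterministic under a seed and unbiased", {
  grid <- acquisition_grid()
  p <- gv_from_peak(11, 3, 2.5, 250)
  expect_identical(sample_tac(p, grid, 5, seed = 99),
                   sample_tac(p, grid, 5, seed = 99))
  # noiseless sampling is the plain evaluation and consumes no RNG
  expect_equal(sample_tac(p, grid, 0)$values, eval_gamma_variate(p, grid))
  # Monte-Carlo mean at one grid point within 3 standard errors
  set.seed(42)
  draws <- replicate(10000, sample_tac(p, grid[1:3], noise_sd = 5)$values[2])
  expect_lt(abs(mean(draws) - eval_gamma_variate(p, grid[2])),
            3 * 5 / sqrt(10000))
  expect_error(sample_tac(p, grid, -1), "noise_sd")
  expect_error(sample_tac(p, numeric(0)), "at least 3")
})

test_that("acquisition grid and tac constructors enforce their invariants", {
  g <- acquisition_grid()
  expect_length(g, 19)
  expect_equal(unique(diff(g)), 2)
  expect_equal(g[1], 8)
  expect_error(acquisition_grid(2), "at least 3")
  expect_error(tac(c(3, 2, 1), c(40, 50, 60)), "increasing")
  expect_error(tac(g, rep(40, 5)), "one sample per grid time")
  tc <- tac(c(1, 2, 3), c(40, 100, 60))
  expect_equal(enhancement(tc), c(0, 60, 20))  # baseline from first sample
})

test_that("phase selection takes the venous peak and the best pre-venous bilateral arterial time", {
  times <- case1_grid()
  sss <- make_tri_tac(times, 24.8, 15, amp = 400)
  mca <- make_tri_tac(times, 16.2, 10)
  ph <- select_phases(mca, mca, sss)
  expect_equal(ph$v_tac, 24.8)
  expect_equal(ph$a_tac, 16.2)
  expect_lt(ph$a_tac, ph$v_tac)

  # ties in the bilateral minimum break toward the earlier time; oracle is
  # an exhaustive scan over the pre-venous grid
  g <- acquisition_grid(10, 2, 2)
  plateau <- tac(g, 40 + c(0, 10, 80, 80, 10, 0, 0, 0, 0, 0), baseline = 40)
  sss2 <- make_tri_tac(g, 14, 6, amp = 300)
  ph2 <- select_phases(plateau, plateau, sss2)
  pre <- g[g < ph2$v_tac]
  scan <- pre[which.max(pmin(enhancement(plateau),
                             enhancement(plateau))[seq_along(pre)])]
  expect_equal(ph2$a_tac, scan)
  expect_equal(ph2$a_tac, 6)  # earlier of the two tied plateau times

  # venous peak at the very first volume leaves no arterial candidate
  sss_first <- tac(g, 40 + c(300, rep(0, 9)), baseline = 40)
  expect_error(select_phases(plateau, plateau, sss_first),
               class = "cvf_phase_selection_error")
  # mismatched grids are rejected
  other <- make_tri_tac(acquisition_grid(10, 2, 3), 14, 6)
  expect_error(select_phases(other, plateau, sss2), "share one")
})

test_that("noiseless sampling plus phase selection recovers the analytic venous peak", {
  grid <- acquisition_grid()
  sss_p <- gv_from_peak(11, 3, 2.5, 400)   # analytic peak at 18.5 s
  mca_p <- gv_from_peak(7, 3, 1.5, 300)
  ph <- select_phases(sample_tac(mca_p, grid, 0), sample_tac(mca_p, grid, 0),
                      sample_tac(sss_p, grid, 0))
  dense <- seq(min(grid), max(grid), by = 0.001)
  analytic <- dense[which.max(eval_gamma_variate(sss_p, dense))]
  expect_lte(abs(ph$v_tac - analytic), 2)  # within one grid interval
})
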