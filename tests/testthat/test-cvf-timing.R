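grid20 <- acquisition_grid(13, 2, 9)  # 9, 11, ..., 33 s

test_that("CVF1 is the earliest visibility crossing of any present vein", {
  # one vein crossing the threshold exactly at grid index 5; oracle is a
  # linear scan over the grid
  v <- make_vein_tac(grid20, onset = grid20[5], peak = 21, clear = 31)
  scan <- grid20[which(enhancement(v) >= 50)[1]]
  expect_equal(detect_cvf1(v), scan)
  expect_equal(detect_cvf1(v), grid20[5])

  # two veins: the "any vein" minimum of the onsets
  t1 <- case1_grid()
  early <- make_vein_tac(t1, 19.0, 24.8, 32.7)
  late <- make_vein_tac(t1, 20.9, 24.8, 37.7)
  expect_equal(detect_cvf1(list(early, late)), 19.0)

  # absent veins are excluded from timing
  noise <- tac(t1, rep(40, length(t1)), baseline = 40)
  expect_equal(detect_cvf1(list(noise, late), present = c(FALSE, TRUE)),
               20.9)
  expect_error(detect_cvf1(list(noise, late), present = c(FALSE, FALSE)),
               "present")

  # never reaching threshold is censoring, not absence
  dim_vein <- tac(grid20, 40 + 30 * sin(seq(0, 3, length.out = 13))^2,
                  baseline = 40)
  expect_error(detect_cvf1(dim_vein), class = "cvf_censored_onset")
})

test_that("CVF2 is the earliest time when most present veins are near their own maxima", {
  # a single vein with zero tolerance reduces to its argmax
  v <- make_vein_tac(grid20, 11, 21, 31)
  expect_equal(detect_cvf2(v, peak_tolerance = 0), 21)

  # three identical curves peak together
  expect_equal(detect_cvf2(list(v, v, v)), 21)

  # two veins peaking apart: one vein suffices for majority 0.5; exhaustive
  # scan oracle over the grid
  g <- acquisition_grid(15, 2, 7)   # contains 21 and 25
  v1 <- make_vein_tac(g, 11, 21, 33)
  v2 <- make_vein_tac(g, 11, 25, 33)
  enh <- cbind(enhancement(v1), enhancement(v2))
  near <- sweep(enh, 2, apply(enh, 2, max), `>=`)  # tolerance 0
  scan <- g[which(rowSums(near) >= 1)[1]]
  expect_equal(detect_cvf2(list(v1, v2), peak_tolerance = 0), scan)
  expect_equal(scan, 21)
  # requiring all veins pushes the time to the later peak only if some grid
  # time has both near-peak; otherwise the max-count time is used
  expect_equal(detect_cvf2(list(v1, v2), peak_tolerance = 0,
                           majority_fraction = 1), 21)
})

test_that("CVF3 is the first post-peak clearance of all present veins", {
  t1 <- case1_grid()
  veins <- lapply(1:3, function(i) make_vein_tac(t1, 19.0, 24.8, 32.7))
  cvf2 <- detect_cvf2(veins)
  # linear-scan oracle
  enh <- sapply(veins, enhancement)
  scan <- t1[which(t1 > cvf2 & rowSums(enh >= 50) == 0)[1]]
  expect_equal(detect_cvf3(veins, after = cvf2), scan)
  expect_equal(scan, 32.7)

  # a vein still opacified at the last volume censors clearance
  open_vein <- make_vein_tac(t1, 19.0, 24.8, clear = 100)
  expect_error(detect_cvf3(c(veins, list(open_vein)), after = cvf2),
               class = "cvf_censored_clearance")

  # threshold above the whole post-peak curve: first post-peak grid time
  v <- make_vein_tac(grid20, 11, 21, 31, amp = 200)
  expect_equal(detect_cvf3(v, visibility_threshold = 1000, after = 21),
               grid20[which(grid20 > 21)[1]])
})

test_that("interval derivation reproduces the printed worked examples", {
  expect_equal(derive_intervals(20.9, 24.8, 37.7),
               c(cvf21 = 3.9, cvf31 = 16.8))
  expect_equal(derive_intervals(12.6, 19.2, 25.2),
               c(cvf21 = 6.6, cvf31 = 12.6))
  expect_equal(derive_intervals(5, 5, 5), c(cvf21 = 0, cvf31 = 0))
  expect_error(derive_intervals(5, 4, 6), "ordered")
})

test_that("relative CVF is the affected-minus-contralateral difference and antisymmetric", {
  aff <- hemisphere_cvf(20.9, 24.8, 37.7)
  con <- hemisphere_cvf(19.0, 24.8, 32.7)
  r <- relative_cvf(aff, con)
  expect_equal(unclass(r),
               c(rcvf1 = 1.9, rcvf2 = 0, rcvf3 = 5.0, rcvf21 = -1.9,
                 rcvf31 = 3.1))
  expect_equal(unclass(relative_cvf(con, aff)), -unclass(r))
  expect_equal(unname(unclass(relative_cvf(aff, aff))), rep(0, 5))
  # third worked example: cvf21 8.6 vs 8.5
  expect_equal(relative_cvf(hemisphere_cvf(16.4, 25.0, 32.9),
                            hemisphere_cvf(14.5, 23.0, 28.9))[["rcvf21"]],
               0.1)
})

test_that("hemisphere scoring is equivariant under grid-interval translation", {
  g <- acquisition_grid(16, 2, 7)
  veins <- list(make_vein_tac(g, 13, 21, 29),
                make_vein_tac(g, 15, 21, 31),
                make_vein_tac(g, 13, 23, 31))
  base <- score_hemisphere(veins)
  expect_true(base$cvf1 <= base$cvf2 && base$cvf2 <= base$cvf3)
  for (k in 1:2) {
    shifted <- lapply(veins, function(v) {
      tac(v$times, c(rep(v$values[1], k), v$values[1:(length(v$values) - k)]),
          baseline = v$baseline)
    })
    sh <- score_hemisphere(shifted)
    expect_equal(sh$cvf1, base$cvf1 + 2 * k)
    expect_equal(sh$cvf2, base$cvf2 + 2 * k)
    expect_equal(sh$cvf3, base$cvf3 + 2 * k)
    expect_equal(sh$cvf21, base$cvf21)
    expect_equal(sh$cvf31, base$cvf31)
  }
})

test_that("ordering cvf1 <= cvf2 <= cvf3 holds on noiseless synthetic hemispheres", {
  set.seed(7)
  grid <- acquisition_grid()
  for (i in 1:25) {
    veins <- lapply(1:3, function(j) {
      sample_tac(gv_from_peak(runif(1, 9, 13), 3, runif(1, 2, 3),
                              runif(1, 150, 300)), grid, 0)
    })
    h <- tryCatch(score_hemisphere(veins), cvf_error = function(e) NULL)
    if (is.null(h) || is.na(h$cvf3)) next
    expect_true(h$cvf1 <= h$cvf2 && h$cvf2 <= h$cvf3)
  }
})

test_that("velocity labels split the cohort at the sample median, fast inclusive", {
  cl <- classify_velocity(c(1, 2, 3))
  expect_equal(cl$threshold, 2)
  expect_equal(cl$label, c("fast", "fast", "slow"))

  # a patient exactly at the threshold is fast (the 1.9 s rule)
  cl2 <- classify_velocity(c(0.4, 1.9, 4.5), threshold = 1.9)
  expect_equal(cl2$label[2], "fast")

  # all equal values are all fast
  expect_true(all(classify_velocity(rep(2, 6))$label == "fast"))

  # at least ceiling(n/2) labelled fast, and the labels partition the cohort
  set.seed(3)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:15, 1), 2, 2), 1)
    cl <- classify_velocity(x)
    expect_gte(sum(cl$label == "fast"), ceiling(length(x) / 2))
    expect_equal(sum(cl$label == "fast") + sum(cl$label == "slow"), length(x))
    expect_equal(cl$threshold, median(x))  # sorting oracle
  }
  expect_error(classify_velocity(numeric(0)), "at least one")
})
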