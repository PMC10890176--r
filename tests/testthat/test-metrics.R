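test_that("tally counts labels and matches the oracle tally on random traces", {
  lab <- data.frame(label = c("TP", "TN", "TN", "FP"))
  expect_equal(tally(lab), c(tp = 1L, tn = 2L, fp = 1L, fn = 0L))
  expect_equal(sum(tally(lab)), nrow(lab))
  expect_equal(tally(data.frame(label = character())),
               c(tp = 0L, tn = 0L, fp = 0L, fn = 0L))
  for (seed in 1:10) {
    rec <- random_recording(300, seed)
    lab <- forward_validate(rec, block_of(rec), 50)
    orc <- oracle_forward_validate(rec, block_of(rec), 50)
    expect_equal(tally(lab), tally(orc))
  }
})

test_that("classification metrics follow the ratio definitions", {
  # all-alert regime: sensitivity 1, specificity 0
  m <- classification_metrics(c(tp = 50, fn = 0, tn = 0, fp = 50))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  # alert-free regime: sensitivity 0, specificity 1, NPV = prevalence-free
  m <- classification_metrics(c(tp = 0, fn = 30, tn = 70, fp = 0))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(m$npv, 0.7)
  expect_true(is.na(m$ppv))  # undefined, never zero-filled
  expect_error(classification_metrics(c(tp = 0, tn = 0, fp = 0, fn = 0)),
               "all-zero")
})

test_that("Wilson interval matches the closed form and prop.test", {
  # closed-form Wilson for 9/10 evaluated independently: (0.596, 0.982)
  ci <- wilson_ci(9, 10)
  expect_equal(unname(round(ci, 3)), c(0.596, 0.982))
  m <- classification_metrics(c(tp = 9, fp = 1, tn = 90, fn = 0))
  expect_equal(m$ppv, 0.9)
  expect_equal(round(m$ppv_lo, 3), 0.596)
  expect_equal(round(m$ppv_hi, 3), 0.982)
  # prop.test without continuity correction computes the same interval
  for (x in c(0, 1, 5, 9, 10)) {
    ref <- stats::prop.test(x, 10, correct = FALSE)$conf.int
    expect_equal(unname(wilson_ci(x, 10)), as.numeric(ref),
                 tolerance = 1e-10)
  }
  # interval contains the point estimate and stays in [0, 1]
  for (n in c(1, 7, 40)) for (x in c(0, floor(n / 2), n)) {
    ci <- wilson_ci(x, n)
    expect_true(ci[1] <= x / n && x / n <= ci[2])
    expect_true(ci[1] >= 0 && ci[2] <= 1)
  }
})

test_that("TTE summary uses interpolated quantiles and handles no TPs", {
  lab <- data.frame(label = rep("TP", 3),
                    time_to_event_s = c(60, 160, 380))
  expect_equal(tte_summary(lab)$median, 160)
  lab1 <- data.frame(label = "TP", time_to_event_s = 100)
  s <- tte_summary(lab1)
  expect_equal(c(s$median, s$q25, s$q75), c(100, 100, 100))
  s0 <- tte_summary(data.frame(label = "TN", time_to_event_s = NA_real_))
  expect_true(is.na(s0$median))
  expect_equal(s0$n, 0L)
  # agrees with brute-force sorted-array interpolation on random draws
  set.seed(99)
  tte <- sort(round(runif(17, 0, 1200) / 20) * 20)
  lab <- data.frame(label = "TP", time_to_event_s = tte)
  h <- function(p) {  # type-7 quantile by hand on the sorted array
    k <- (length(tte) - 1) * p
    lo <- floor(k) + 1
    tte[lo] + (k - floor(k)) * (tte[min(lo + 1, length(tte))] - tte[lo])
  }
  s <- tte_summary(lab)
  expect_equal(s$median, h(0.5))
  expect_equal(s$q25, h(0.25))
  expect_equal(s$q75, h(0.75))
})

test_that("TWA closed forms and brute-force equivalence hold", {
  rec <- make_rec(rep(60, 30))
  expect_equal(twa_hypotension(rec, block_of(rec)), 5)
  rec <- make_rec(rep(80, 30))
  expect_equal(twa_hypotension(rec, block_of(rec)), 0)
  rec <- make_rec(c(rep(60, 15), rep(70, 15)))
  expect_equal(twa_hypotension(rec, block_of(rec)), 2.5)
  expect_error(twa_hypotension(rec, c(3L, 3L)), "empty")
  for (seed in 1:10) {
    rec <- random_recording(200, seed)
    acc <- 0  # brute-force per-sample accumulation of area / duration
    for (k in 1:200) acc <- acc + max(0, 65 - rec$map[k]) * 20
    expect_equal(twa_hypotension(rec, block_of(rec)), acc / (200 * 20))
    # translation monotonicity: lowering MAP never decreases TWA
    lower <- rec
    lower$map <- rec$map - 2.5
    expect_gte(twa_hypotension(lower, block_of(rec)),
               twa_hypotension(rec, block_of(rec)))
  }
})

test_that("ROC assembly: anchors, hand trapezoid, invariance to row order", {
  sweep <- data.frame(threshold = c(30, 60),
                      sensitivity = c(1.0, 0.8),
                      specificity = c(0.5, 0.8))
  r <- roc_from_sweep(sweep)
  # hand integration over (0,0), (0.2,0.8), (0.5,1), (1,1):
  # 0.2*0.4 + 0.3*0.9 + 0.5*1 = 0.85
  expect_equal(r$auroc, 0.85)
  expect_true(all(c(0, 1) %in% r$points$fpr))
  # row order must not matter
  r2 <- roc_from_sweep(sweep[2:1, ])
  expect_equal(r2$auroc, r$auroc)
  # perfect predictor: all interior points at (0, 1)
  perfect <- data.frame(threshold = seq(10, 90, 10),
                        sensitivity = 1, specificity = 1)
  expect_equal(roc_from_sweep(perfect)$auroc, 1.0)
  expect_error(roc_from_sweep(data.frame(threshold = 1,
                                         sensitivity = NA_real_,
                                         specificity = NA_real_)),
               "defined")
})
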