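test_that("mean translation yields exactly zero-mean series", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(c(5, 5, 5)), c(0, 0, 0))
  expect_error(mean_center(c(1, 2)), "too short")

  lj <- lj_decomposition(r_grid = seq(0.95, 2.2, length.out = 30))
  fall <- split_segments(lj)[1, ]
  idx <- fall$start:fall$end
  rep_term <- lj$terms[, "xc(a1,a2)"]
  expect_equal(mean_center(rep_term, idx), rep_term[idx] - mean(rep_term[idx]))
  expect_lt(abs(mean(mean_center(rep_term, idx))), 1e-12 * max(abs(rep_term[idx])))
})

test_that("REG slope obeys self-regression, linearity and shift rules", {
  tot <- c(1, 4, 2, 8, 5, 9)
  expect_equal(reg_value(tot, tot), 1.0)
  expect_equal(reg_value(0.7 * tot + 123, tot), 0.7)
  # scale equivariance of the term, shift invariance of either series
  expect_equal(reg_value(3 * tot, tot + 50), 3.0)
  expect_error(reg_value(tot, rep(2, 6)), "zero variance")
})

test_that("Pearson correlation hits the exact reference cases", {
  tot <- c(-1, 0, 1)
  expect_equal(reg_pearson(2 * tot, tot), 1.0)
  expect_equal(reg_pearson(-tot, tot), -1.0)
  expect_equal(reg_pearson(c(1, -2, 1), tot), 0.0)
  expect_error(reg_pearson(c(5, 5, 5), tot), "zero variance")
})

test_that("REG and Pearson match the independent lm()/cor() oracle", {
  lj <- lj_decomposition(r_grid = seq(0.95, 2.2, length.out = 30))
  segs <- split_segments(lj)
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    for (lb in colnames(lj$terms)) {
      expect_equal(reg_value(lj$terms[, lb], lj$e_total, idx),
                   oracle_slope(lj$terms[, lb], lj$e_total, idx),
                   tolerance = 1e-10)
      expect_equal(reg_pearson(lj$terms[, lb], lj$e_total, idx),
                   oracle_pearson(lj$terms[, lb], lj$e_total, idx),
                   tolerance = 1e-10)
    }
  }
})

test_that("segment analysis ranks, flags low-R terms and reports the sum rule", {
  tot <- base_curve("sigmoid", seq(0, 1, length.out = 15), height = 10)
  terms <- cbind("intra(a1)" = 0.7 * tot, "intra(a2)" = 0.3 * tot)
  ds <- reg_dataset(seq(0, 1, length.out = 15), tot, terms)
  res <- analyze_segment(ds, c(1, 15))
  expect_equal(res$entries$reg, c(0.7, 0.3))
  expect_equal(res$entries$pearson, c(1, 1))
  expect_equal(res$sum_of_reg, 1.0, tolerance = 1e-12)
  expect_equal(res$entries$rank, c(1L, 2L))

  # pure-noise term: low |R|, flagged but retained; others' ranking unchanged
  set.seed(5)
  noise <- rnorm(15, sd = 1e-3)
  noise <- noise - mean(noise)
  ds2 <- reg_dataset(ds$s, tot, cbind(terms, "intra(a3)" = noise))
  res2 <- analyze_segment(ds2, c(1, 15), r_threshold = 0.7)
  e3 <- res2$entries[res2$entries$label == "intra(a3)", ]
  expect_true(e3$discarded)
  expect_equal(abs(e3$pearson), abs(oracle_pearson(noise, tot)), tolerance = 1e-10)
  kept <- res2$entries[!res2$entries$discarded, ]
  expect_equal(kept$label, c("intra(a1)", "intra(a2)"))
  expect_equal(res2$sum_of_reg_kept, 1.0, tolerance = 1e-9)

  expect_error(analyze_segment(ds, c(1, 2)), ">= 3")
  expect_error(analyze_segment(ds, c(1, 15), r_threshold = 1), "\\[0, 1\\)")
})

test_that("whole-dataset analysis gives per-segment opposite-sign slopes", {
  s <- 0:4
  tot <- c(2, 1, 0, 1, 2)                     # V shape: falling then rising
  term <- 0.4 * tot
  ds <- reg_dataset(s, tot, list("intra(a1)" = term, "intra(a2)" = 0.6 * tot))
  out <- reg_analyze(ds)
  expect_length(out, 2)
  # same linear term: equal REG on both segments (slope vs total, not vs s)
  r1 <- out[[1]]$entries[out[[1]]$entries$label == "intra(a1)", "reg"]
  r2 <- out[[2]]$entries[out[[2]]$entries$label == "intra(a1)", "reg"]
  expect_equal(r1, 0.4); expect_equal(r2, 0.4)

  # a term rising monotonically in s flips its REG sign across the V
  riser <- as.numeric(s)
  ds2 <- reg_dataset(s, tot, list("intra(a1)" = riser))
  out2 <- reg_analyze(ds2, r_threshold = 0)
  s1 <- out2[[1]]$entries$reg
  s2 <- out2[[2]]$entries$reg
  expect_lt(s1, 0)
  expect_gt(s2, 0)
  expect_equal(s1, oracle_slope(riser, tot, 1:3), tolerance = 1e-12)
  expect_equal(s2, oracle_slope(riser, tot, 3:5), tolerance = 1e-12)
})

test_that("short segments error individually while others proceed", {
  tot <- c(0, 1, 0.5, 1.5, 2.5, 3.5)          # max at 2, min at 3, then rise
  ds <- reg_dataset(0:5, tot, list("intra(a1)" = 0.5 * tot))
  out <- reg_analyze(ds, r_threshold = 0)
  errs <- vapply(out, function(r) !is.null(r$error), logical(1))
  expect_true(any(errs))
  expect_true(any(!errs))
  ok <- out[[which(!errs)[1]]]
  expect_equal(ok$sum_of_reg, 0.5, tolerance = 1e-12)
})

test_that("REG is invariant to reparameterization and equivariant to scaling", {
  ds <- random_exact_dataset(21, m = 12, nt = 6)
  idx <- seq_len(12)
  base <- vapply(colnames(ds$terms),
                 function(lb) reg_value(ds$terms[, lb], ds$e_total, idx), numeric(1))
  # s plays no role at all
  warped <- reg_dataset(ds$s^3 + 1, ds$e_total, ds$terms)
  warped_reg <- vapply(colnames(ds$terms),
                       function(lb) reg_value(warped$terms[, lb], warped$e_total, idx),
                       numeric(1))
  expect_equal(warped_reg, base, tolerance = 1e-14)
  # scaling one term by k scales its REG by k and leaves |R| unchanged
  lb1 <- colnames(ds$terms)[1]
  expect_equal(reg_value(ds$terms[, lb1] * -2.5, ds$e_total, idx),
               -2.5 * base[[lb1]], tolerance = 1e-12)
  expect_equal(abs(reg_pearson(ds$terms[, lb1] * -2.5, ds$e_total, idx)),
               abs(reg_pearson(ds$terms[, lb1], ds$e_total, idx)),
               tolerance = 1e-12)
})

test_that("sum rule holds on every segment of exact decompositions", {
  for (seed in c(1, 2, 3)) {
    ds <- random_exact_dataset(seed)
    out <- reg_analyze(ds, r_threshold = 0)
    for (r in out) {
      if (!is.null(r$error)) next
      expect_equal(r$sum_of_reg, 1.0, tolerance = 1e-9)
    }
  }
})

test_that("recovered REG values track the generating weights under noise", {
  w <- c(0.6, 0.25, 0.15)
  reps <- 50
  rec <- matrix(NA_real_, reps, length(w))
  for (i in seq_len(reps)) {
    ds <- weighted_decomposition(w, grid = seq(0, 1, length.out = 21),
                                 sigma = 0.66, seed = 1000 + i, height = 66)
    res <- analyze_segment(ds, c(1, 21), r_threshold = 0)
    rec[i, ] <- res$entries$reg[match(sprintf("intra(a%d)", 1:3), res$entries$label)]
  }
  means <- colMeans(rec)
  ses <- apply(rec, 2, sd) / sqrt(reps)
  expect_true(all(abs(means - w) <= 3 * ses + 1e-12))
})
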