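test_that("sphere selection is a closed ball around the center atom", {
  set.seed(61)
  n <- 50
  geo <- structure(
    data.frame(label = paste0("c", 1:n), element = "C",
               x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8),
               stringsAsFactors = FALSE),
    class = c("xyz_geometry", "data.frame"))
  sel <- sphere_select(geo, "c7", 4.0)
  d <- sqrt((geo$x - geo$x[7])^2 + (geo$y - geo$y[7])^2 + (geo$z - geo$z[7])^2)
  expect_identical(sel, geo$label[d <= 4.0])
  expect_true("c7" %in% sel)

  expect_identical(sphere_select(geo, "c7", 0), "c7")
  expect_identical(sphere_select(geo, "c7", 100), geo$label)
  expect_error(sphere_select(geo, "zz9", 4), "unknown center")
  expect_error(sphere_select(geo, "c7", -1), ">= 0")
})

test_that("term filtering keeps exactly the subset-internal terms", {
  # complete 3-atom decomposition: 9 terms
  atoms <- c("a1", "b2", "c3")
  labs <- c(sprintf("intra(%s)", atoms),
            "cl(a1,b2)", "cl(a1,c3)", "cl(b2,c3)",
            "xc(a1,b2)", "xc(a1,c3)", "xc(b2,c3)")
  m <- 5
  set.seed(3)
  terms <- matrix(rnorm(m * 9), m, 9, dimnames = list(NULL, labs))
  ds <- reg_dataset(1:m, rowSums(terms), terms)

  full <- filter_terms(ds, atoms)
  expect_equal(n_terms(full), 9)

  sub <- filter_terms(ds, c("a1", "b2"))
  expect_setequal(colnames(sub$terms),
                  c("intra(a1)", "intra(b2)", "cl(a1,b2)", "xc(a1,b2)"))
  expect_equal(n_terms(sub), term_count(2)$n_total)
  expect_equal(sub$e_total, ds$e_total)   # full-system reference kept
  expect_error(filter_terms(ds, character(0)), "non-empty")

  # sum-rule deficit equals the summed REG of the excluded terms
  seg <- c(1, m)
  res_full <- analyze_segment(ds, seg, r_threshold = 0)
  res_sub <- analyze_segment(sub, seg, r_threshold = 0)
  excluded <- setdiff(colnames(ds$terms), colnames(sub$terms))
  reg_excl <- sum(res_full$entries$reg[match(excluded, res_full$entries$label)])
  expect_equal(res_full$sum_of_reg, 1, tolerance = 1e-9)
  expect_equal(1 - res_sub$sum_of_reg, reg_excl, tolerance = 1e-9)
})

test_that("truncation metrics are exact on identity and affine candidates", {
  grid <- seq(0, 1, length.out = 11)
  full <- data.frame(s = grid, e = base_curve("sigmoid", grid, height = 66))

  ident <- truncation_metrics(full, full)
  expect_equal(ident$m, 1); expect_equal(ident$r2, 1); expect_equal(ident$de_ratio, 1)

  aff <- full; aff$e <- 0.8 * full$e + 300
  met <- truncation_metrics(full, aff)
  expect_equal(met$m, 0.8, tolerance = 1e-12)
  expect_equal(met$r2, 1, tolerance = 1e-12)
  expect_equal(met$de_ratio, 0.8, tolerance = 1e-12)

  neg <- full; neg$e <- -1.5 * full$e
  metn <- truncation_metrics(full, neg)
  expect_equal(metn$m, -1.5, tolerance = 1e-12)
  expect_equal(metn$r2, 1, tolerance = 1e-12)
  expect_equal(metn$de_ratio, -1.5, tolerance = 1e-12)
})

test_that("noisy-candidate metrics match direct-formula recomputation", {
  grid <- seq(0, 1, length.out = 15)
  fe <- base_curve("sigmoid", grid, height = 66)
  set.seed(77)
  le <- fe + rnorm(15, sd = 0.05 * diff(range(fe)))
  met <- truncation_metrics(fe, le)
  f <- fe - mean(fe); l <- le - mean(le)
  expect_equal(met$m, sum(f * l) / sum(f * f), tolerance = 1e-12)
  expect_equal(met$r2, cor(fe, le)^2, tolerance = 1e-12)
  expect_equal(met$de_ratio, (le[15] - le[1]) / (fe[15] - fe[1]), tolerance = 1e-12)

  expect_error(truncation_metrics(fe, le[-1]), "same number")
  expect_error(truncation_metrics(rep(1, 5), rep(1, 5)), "zero variance")
  sym <- c(0, 1, 0.2, 1, 0)
  expect_error(truncation_metrics(sym, sym, segment = c(1, 5)))
  g1 <- data.frame(s = 1:5, e = c(0, 1, 2, 3, 4))
  g2 <- data.frame(s = 2:6, e = c(0, 1, 2, 3, 4))
  expect_error(truncation_metrics(g1, g2), "grid")
})

test_that("candidate ranking penalizes the compressed-gradient pattern", {
  grid <- seq(0, 1, length.out = 11)
  fe <- base_curve("sigmoid", grid, height = 66)

  ranked <- assess_truncations(fe, list(full = fe, scaled = 0.8 * fe))
  expect_equal(ranked$name[1], "full")
  expect_equal(ranked$max_dev[1], 0)

  # m = 1, r2 ~ 1 but dE ratio = 0.8: must never rank first against a
  # faithful candidate (systematically compressed activation energy).
  # Perturb only the endpoints, orthogonally to the centered full profile,
  # so the regression slope stays exactly 1 while dE shrinks by 20%.
  fa <- base_curve("sigmoid", grid, height = 66, center = 0.3)
  fc <- fa - mean(fa)
  de <- fa[11] - fa[1]
  # minimum-norm perturbation g with cov(fc, g) = 0 and g[11] - g[1] = -0.2 dE
  u <- rep(0, 11); u[1] <- -1; u[11] <- 1
  vf <- sum(fc^2); cc <- fc[11] - fc[1]
  beta <- -0.2 * de / (2 - cc^2 / vf)
  alpha <- -beta * cc / vf
  group_i <- fa + alpha * fc + beta * u
  met_c <- truncation_metrics(fa, group_i)
  expect_equal(met_c$m, 1, tolerance = 1e-9)
  expect_gt(met_c$r2, 0.9)
  expect_equal(met_c$de_ratio, 0.8, tolerance = 1e-9)
  set.seed(83)
  good <- fa + rnorm(11, sd = 0.005 * diff(range(fa)))
  ranked2 <- assess_truncations(fa, list(good = good, group_i = group_i))
  expect_false(ranked2$name[1] == "group_i")

  # increasing noise -> monotone ranking on a fixed seed
  set.seed(91)
  sds <- c(0.2, 1, 3, 8, 20)
  lites <- lapply(sds, function(sd) fe + rnorm(11, sd = sd))
  names(lites) <- sprintf("noise_%02d", seq_along(sds))
  ranked3 <- assess_truncations(fe, lites)
  expect_equal(ranked3$name, sprintf("noise_%02d", 1:5))

  # failing candidates are reported, not fatal
  ranked4 <- assess_truncations(fe, list(ok = fe, broken = fe[-1]))
  expect_equal(ranked4$name[1], "ok")
  expect_true(nzchar(ranked4$error[ranked4$name == "broken"]))
  expect_true(is.infinite(ranked4$max_dev[ranked4$name == "broken"]))
})
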