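test_that("dice handles identity, disjoint and counted-overlap cases", {
  g <- geometry(c(6, 6, 6), c(1, 1, 1))
  a <- array(0L, c(6, 6, 6)); a[1:2, 1:2, 1:2] <- 1L   # 8 voxels
  b <- array(0L, c(6, 6, 6)); b[1:2, 1:2, 2:3] <- 1L   # 8 voxels, 4 shared
  la <- label_map(a, g); lb <- label_map(b, g)
  expect_equal(dice(la, la, 1), 1.0)
  expect_equal(dice(la, lb, 1), 0.5)
  expect_equal(dice(la, lb, 2), 1.0)  # both empty -> agreement on absence
  c <- array(0L, c(6, 6, 6)); c[5:6, 5:6, 5:6] <- 1L
  expect_equal(dice(la, label_map(c, g), 1), 0.0)
})

test_that("rvd is the signed percent volume difference, pred minus truth", {
  a <- random_mask(8, 0.3)
  expect_equal(rvd(a, a), 0)
  t <- array(FALSE, c(5, 5, 5)); t[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  p <- array(FALSE, c(5, 5, 5)); p[1:4, 1:5, 1:5] <- TRUE
  p[5, 1:5, 1:2] <- TRUE                                   # 110 voxels
  expect_equal(rvd(p, t), 10)
  p2 <- t; p2[4, 1:5, 1:2] <- FALSE                        # 90 voxels
  expect_equal(rvd(p2, t), -10)
  expect_error(rvd(p, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("hausdorff matches simple geometry and respects spacing", {
  a <- array(FALSE, c(8, 8, 8)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5, 2, 2] <- TRUE
  expect_equal(hausdorff(a, b, spacing = c(1, 1, 1)), 3)
  expect_equal(hausdorff(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(hausdorff(a, a, spacing = c(1, 1, 1)), 0)
  expect_error(hausdorff(a, array(FALSE, c(8, 8, 8))), "non-empty")
})

test_that("dice and hausdorff equal their brute-force oracles on random masks", {
  set.seed(42)
  for (r in 1:25) {
    a <- random_mask(12, 0.15)
    b <- random_mask(12, 0.15)
    if (!any(a) || !any(b)) next
    expect_equal(dice(a, b), dice_oracle(a, b))
    sp <- c(0.94, 0.94, 1.95)
    expect_equal(hausdorff(a, b, spacing = sp), hausdorff_oracle(a, b, sp),
                 tolerance = 1e-12)
  }
})

test_that("mc_cv_plan reproduces the study layout and its invariants hold", {
  plan <- mc_cv_plan(26, 5, 8, seed = 1)
  expect_length(plan$folds, 5)
  expect_equal(sum(lengths(lapply(plan$folds, `[[`, "val"))), 40)
  for (f in plan$folds) {
    expect_length(f$train, 18)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), sprintf("S%03d", 1:26))
  }
  expect_setequal(unique(unlist(lapply(plan$folds, `[[`, "val"))),
                  sprintf("S%03d", 1:26))
  expect_error(mc_cv_plan(26, 2, 8), "infeasible")
})

test_that("mc_cv_plan invariants hold across 1000 seeds", {
  ok <- vapply(1:1000, function(seed) {
    plan <- mc_cv_plan(12, 4, 4, seed = seed)
    covered <- length(unique(unlist(lapply(plan$folds, `[[`, "val")))) == 12
    per_fold <- vapply(plan$folds, function(f) {
      length(f$val) == 4 && anyDuplicated(f$val) == 0 &&
        length(intersect(f$train, f$val)) == 0 &&
        setequal(c(f$train, f$val), sprintf("S%03d", 1:12))
    }, logical(1))
    covered && all(per_fold)
  }, logical(1))
  expect_true(all(ok))
})

test_that("bland_altman recovers known bias and limits of agreement", {
  x <- c(1, 2, 3)
  # degenerate perfect-fit cases warn in summary.lm; the values matter here
  suppressWarnings({
    expect_equal(bland_altman(x, x)$bias, 0)
    expect_equal(unname(diff(bland_altman(x, x + 2)$loa)), 0)
    expect_equal(bland_altman(x, x + 2)$bias, 2)
  })
  set.seed(99)
  x <- runif(1e4, 5, 25)
  y <- x + 0.5 + rnorm(1e4)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$bias - 0.5), 0.03)
  expect_lt(abs(unname(diff(ba$loa)) - 2 * 1.96), 0.12)
  expect_gt(ba$r_squared, 0.9)
  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("kruskal_wallis matches the hand-computed rank statistic", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  # ranks {1,2,3} vs {4,5,6}: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  h <- kruskal_wallis(list(c(1, 2, 3), c(101, 102, 103)))$H
  expect_equal(h, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-9)
  expect_equal(round(h, 3), 3.857)
  # invariant to monotone transforms of the pooled data
  g <- list(rnorm(10), rnorm(12, 1))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, exp))$H)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("partial eta squared identity reproduces published ANCOVA effect sizes", {
  expect_equal(round(partial_eta_sq(110.47, 1, 166), 3), 0.400)
  expect_equal(round(partial_eta_sq(37.31, 3, 166), 3), 0.403)
  expect_equal(round(partial_eta_sq(47.17, 1, 166), 3), 0.221)
  expect_equal(round(partial_eta_sq(64.42, 1, 166), 3), 0.280)
})

test_that("ancova_type3 agrees with car::Anova and the eta identity", {
  skip_if_not_installed("car")
  set.seed(21)
  n <- 120
  d <- data.frame(age = runif(n, 20, 70), bmi = rnorm(n, 26, 4),
                  male = rbinom(n, 1, 0.5),
                  active = sample(0:2, n, replace = TRUE))
  d$ff_pct <- 15 + 0.1 * d$age + 0.2 * d$bmi - 1.5 * d$male -
    2 * (d$active == 1) - 4 * (d$active == 2) + rnorm(n, 0, 2)
  tab <- ancova_type3(d, "ff_pct", c("age", "bmi"), c("male", "active"))
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  ref <- car::Anova(lm(ff_pct ~ age + bmi + factor(male) + factor(active), d),
                    type = 3)
  for (eff in c("age", "bmi")) {
    expect_equal(tab$F[tab$effect == eff],
                 ref[eff, "F value"], tolerance = 1e-8)
  }
  expect_equal(tab$F[tab$effect == "active"],
               ref["factor(active)", "F value"], tolerance = 1e-8)
  expect_equal(tab$df1[tab$effect == "active"], 2)
  # identity eta_p^2 = df1 F / (df1 F + df2) to 1e-9 on every row
  expect_equal(tab$partial_eta_sq,
               partial_eta_sq(tab$F, tab$df1, tab$df2), tolerance = 1e-9)
})

test_that("Type III equals sequential SS on a balanced orthogonal design", {
  d <- expand.grid(male = c(0, 1), active = c(0, 1), x = c(-1, 1), rep = 1:5)
  set.seed(5)
  d$ff_pct <- 10 + 2 * d$male - 3 * d$active + 0.5 * d$x + rnorm(nrow(d))
  tab <- ancova_type3(d, "ff_pct", "x", c("male", "active"))
  d$male_f <- factor(d$male); d$active_f <- factor(d$active)
  seq_aov <- anova(lm(ff_pct ~ x + male_f + active_f, d,
                      contrasts = list(male_f = "contr.sum",
                                       active_f = "contr.sum")))
  expect_equal(tab$sum_sq[tab$effect == "x"], seq_aov["x", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$effect == "male"],
               seq_aov["male_f", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$effect == "active"],
               seq_aov["active_f", "Sum Sq"], tolerance = 1e-8)
})

test_that("ancova_type3 rejects rank-deficient designs naming the alias", {
  d <- data.frame(age = 1:20, bmi = (1:20) * 2, male = rep(0:1, 10))
  d$ff_pct <- rnorm(20)
  expect_error(ancova_type3(d, "ff_pct", c("age", "bmi"), "male"),
               "aliased")
})

test_that("reference_table computes stratified medians and IQRs", {
  expect_equal(reference_table(
    data.frame(muscle = "P", ff_pct = c(10, 12, 14)))$median, 12)
  tab <- reference_table(data.frame(muscle = "P", ff_pct = rep(7, 5)))
  expect_equal(tab$p75 - tab$p25, 0)
  set.seed(3)
  rec <- data.frame(muscle = rep("QL", 400),
                    ff_pct = c(rnorm(200, 18, 1), rnorm(200, 14, 1)),
                    active = rep(0:1, each = 200))
  st <- reference_table(rec, strata = "activity")
  expect_equal(st$median[st$stratum == "sedentary"] -
                 st$median[st$stratum == "active"], 4, tolerance = 0.5)
})
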