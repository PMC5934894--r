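test_that("roc_curve matches pair-counting on toy sets", {
  # perfectly separated
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(rep("AR", 3), rep("IR", 3)))
  expect_equal(r$auc, 1.0)
  # all identical: pure ties
  r2 <- roc_curve(rep(5, 8), rep(c("IR", "AR"), 4))
  expect_equal(r2$auc, 0.5)
  # 6-point toy set with one tie across classes
  r3 <- roc_curve(c(5, 8, 9, 1, 2, 8),
                  c("IR", "IR", "IR", "AR", "AR", "AR"))
  expect_equal(r3$auc, (7 + 0.5) / 9)
  expect_equal(r3$auc, oracle_auc(c(5, 8, 9), c(1, 2, 8)))
  expect_error(roc_curve(1:5, rep("IR", 5)), "both classes")
})

test_that("AUC equals U/(n1 n2) for arbitrary tied data (property)", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    vals <- sample(1:6, n1 + n0, replace = TRUE)  # heavy ties
    labs <- c(rep("IR", n1), rep("AR", n0))
    r <- roc_curve(vals, labs)
    expect_equal(r$auc, oracle_auc(vals[1:n1], vals[-(1:n1)]))
    mw <- mann_whitney(vals[1:n1], vals[-(1:n1)])
    expect_equal(r$auc, mw$U / (n1 * n0))
  }
})

test_that("DeLong CI contains the AUC and is clipped to [0, 1]", {
  set.seed(8)
  vals <- c(rnorm(20, 1), rnorm(20))
  labs <- rep(c("IR", "AR"), each = 20)
  r <- roc_curve(vals, labs)
  expect_lte(r$auc_ci[1], r$auc)
  expect_gte(r$auc_ci[2], r$auc)
  rp <- roc_curve(c(1, 2, 3, 11, 12, 13), rep(c("AR", "IR"), each = 3))
  expect_lte(rp$auc_ci[2], 1)
})

test_that("optimal_cutoff minimizes d with the documented tie-breaks", {
  expect_equal(sqrt((1 - 0.94)^2 + (1 - 0.64)^2), 0.365, tolerance = 1e-3)
  # toy set: cutoff between 2 and 5 wins with sens 1, spec 2/3
  r <- roc_curve(c(5, 8, 9, 1, 2, 8), c("IR", "IR", "IR", "AR", "AR", "AR"))
  oc <- optimal_cutoff(r)
  expect_equal(oc$sens, 1)
  expect_equal(oc$spec, 2 / 3)
  expect_equal(oc$d, sqrt(0 + (1 / 3)^2))
  expect_true(oc$cutoff >= 2 && oc$cutoff < 5)
  # perfect separation: d = 0
  rp <- roc_curve(c(1, 2, 10, 11), c("AR", "AR", "IR", "IR"))
  expect_equal(optimal_cutoff(rp)$d, 0)
})

test_that("optimal cutoff is invariant under monotone transforms", {
  set.seed(17)
  vals <- runif(30, 1, 100)
  labs <- ifelse(runif(30) < plogis(scale(vals)), "IR", "AR")
  if (length(unique(labs)) < 2) labs[1:2] <- c("IR", "AR")
  r1 <- roc_curve(vals, labs)
  r2 <- roc_curve(log(vals), labs)
  oc1 <- optimal_cutoff(r1)
  oc2 <- optimal_cutoff(r2)
  expect_equal(r1$auc, r2$auc)
  expect_equal(oc1$d, oc2$d)
  expect_equal(oc2$cutoff, log(oc1$cutoff))
})

test_that("diagnostic_accuracy reproduces the printed example rows", {
  # stage I/II MTV row
  acc <- diagnostic_accuracy(diagnostic_table(tp = 15, fn = 1, fp = 4, tn = 7))
  expect_equal(acc$sensitivity$pct, 94)
  expect_equal(acc$sensitivity$ci_pct, c(70, 100))
  expect_equal(acc$specificity$pct, 64)
  expect_equal(acc$specificity$ci_pct, c(31, 89))
  expect_equal(acc$ppv$pct, 79)
  expect_equal(acc$npv$pct, 88)
  # TG/TL 1 MTV row
  acc2 <- diagnostic_accuracy(diagnostic_table(tp = 6, fn = 0, fp = 1, tn = 5))
  expect_equal(acc2$sensitivity$pct, 100)
  expect_equal(acc2$sensitivity$ci_pct, c(54, 100))
  expect_equal(acc2$specificity$pct, 83)
  expect_equal(acc2$npv$pct, 100)
  expect_equal(acc2$ppv$pct, 86)
  # zero denominator
  acc3 <- diagnostic_accuracy(diagnostic_table(tp = 0, fn = 0, fp = 2, tn = 3))
  expect_true(is.na(acc3$sensitivity$pct))
})

test_that("Clopper-Pearson intervals contain the estimate and cover", {
  set.seed(23)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(10, 30)) {
      cover <- 0
      nrep <- 400
      for (i in seq_len(nrep)) {
        x <- rbinom(1, n, p)
        ci <- clopper_pearson(x, n)
        expect_lte(ci[1], x / n + 1e-12)
        expect_gte(ci[2], x / n - 1e-12)
        cover <- cover + (ci[1] <= p && p <= ci[2])
      }
      # exact intervals are conservative: coverage >= nominal up to MC error
      expect_gte(cover / nrep, 0.95 - 2 * sqrt(0.05 * 0.95 / nrep))
    }
  }
})

test_that("mann_whitney: exact enumeration, symmetry and wilcox agreement", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)     # 2 of 20 splits are as extreme
  # identical samples: U = n^2/2, p = 1
  mw2 <- mann_whitney(1:4, 1:4)
  expect_equal(mw2$U, 8)
  expect_equal(mw2$p, 1)
  # large-sample path against the base-R implementation (no ties)
  set.seed(41)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  mw3 <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw3$U, unname(ref$statistic))
  expect_equal(mw3$p, ref$p.value, tolerance = 1e-9)
})

test_that("loglinear_association matches the closed-form Wald z", {
  tab <- matrix(c(24, 4, 5, 17), 2, 2, byrow = TRUE)   # {24,5;4,17}
  res <- loglinear_association(tab, delta = 0)
  z_wald <- log(24 * 17 / (5 * 4)) / sqrt(1 / 24 + 1 / 5 + 1 / 4 + 1 / 17)
  expect_equal(res$z[res$term == "A:B"], z_wald, tolerance = 1e-9)
  expect_equal(z_wald, 4.07, tolerance = 0.01)
  # independence: all z = 0
  flat <- array(4, c(2, 2, 2))
  res2 <- loglinear_association(flat)
  expect_true(all(abs(res2$z) < 1e-12))
  # enriching the high/IR cell raises the A:C z
  base <- array(c(10, 5, 5, 10, 5, 10, 10, 5), c(2, 2, 2))
  z0 <- loglinear_association(base)
  base2 <- base; base2[1, 1, 1] <- base2[1, 1, 1] + 5
  z1 <- loglinear_association(base2)
  expect_gt(z1$z[z1$term == "A:C"], z0$z[z0$term == "A:C"])
})

test_that("stratified analysis has the contracted shape", {
  cfg <- cohort_sim_config(seed = 3L)
  co <- simulate_cohort(cfg)
  rep_stage <- run_stratified_analysis(co, "stage_groups")
  expect_equal(nrow(rep_stage$results),
               length(unique(rep_stage$results$stratum)) * 11)
  rep_tg <- run_stratified_analysis(co, "tg_tl")
  expect_true(all(paste0("TG/TL ", 1:3) %in% rep_tg$results$stratum |
                    rep_tg$non_evaluable %in% paste0("TG/TL ", 1:3)))
  expect_equal(sort(unique(rep_tg$results$feature)), sort(feature_names()))
  # inverted polarity features report "<" cutoffs
  expect_true(all(rep_stage$results$direction[
    rep_stage$results$feature %in% c("entropy", "contrast")] == "<"))
  # every 2x2 adds up to the stratum size
  n_by_stratum <- table(ifelse(stage_number(co$stage) %in% c("I", "II"),
                               "I/II", "III/IV"))
  for (i in seq_len(nrow(rep_stage$results))) {
    row <- rep_stage$results[i, ]
    expect_equal(row$tp + row$fn + row$fp + row$tn,
                 as.integer(n_by_stratum[[row$stratum]]))
  }
})

test_that("MTV attains the top AUC in every stratum under a strong effect", {
  cfg <- cohort_sim_config(n_patients = 400L, seed = 12L)
  co <- simulate_cohort(cfg)
  rep_tg <- run_stratified_analysis(co, "tg_tl")
  res <- rep_tg$results
  for (s in unique(res$stratum)) {
    sub <- res[res$stratum == s, ]
    expect_equal(sub$feature[which.max(sub$auc)], "mtv", info = s)
  }
})
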