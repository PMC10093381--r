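test_that("confusion matrix counts reference x predicted pairs", {
  ref <- rep(c("POLE", "MSI"), each = 5)
  m <- confusion_matrix(ref, ref)
  expect_equal(sum(diag(m)), 10)
  expect_equal(sum(m) - sum(diag(m)), 0)
  # swapping the label vectors transposes the matrix
  pred <- c(rep("POLE", 3), rep("CN-low", 2), rep("MSI", 5))
  m1 <- confusion_matrix(ref, pred)
  m2 <- confusion_matrix(pred, ref)
  expect_equal(unclass(m1), t(unclass(m2)), ignore_attr = TRUE)
  expect_error(confusion_matrix(c("POLE", "odd"), c("MSI", "MSI")),
               "universe")
  expect_error(confusion_matrix("POLE", c("MSI", "MSI")), "length")
})

test_that("published 232-sample concordance table has the printed margins", {
  m <- published_concordance()
  expect_equal(unname(rowSums(m)), c(17, 65, 90, 60))
  expect_equal(unname(colSums(m)), c(17, 58, 95, 62))
  expect_equal(sum(m), 232)
})

test_that("per-class recall reproduces the printed detection rates", {
  m <- published_concordance()
  pc <- per_class_metrics(m)
  expect_equal(pc$recall[pc$class == "POLE"], 1)          # 17/17
  expect_equal(pc$recall[pc$class == "MSI"], 58 / 65)     # 89%
  expect_equal(pc$recall[pc$class == "CN-low"], 80 / 90)  # 89%
  expect_equal(pc$recall[pc$class == "CN-high"], 51 / 60) # 85%
  # empty predicted column -> precision 0 by convention
  m0 <- confusion_matrix(c("POLE", "MSI"), c("MSI", "MSI"))
  pc0 <- per_class_metrics(m0)
  expect_equal(pc0$precision[pc0$class == "POLE"], 0)
  expect_equal(pc0$f1[pc0$class == "POLE"], 0)
})

test_that("aggregate metrics match hand-computed values on the printed table", {
  m <- published_concordance()
  macro <- aggregate_metrics(m, "macro")
  weighted <- aggregate_metrics(m, "weighted")
  expect_equal(unname(macro["accuracy"]), 206 / 232)
  expect_equal(unname(macro["recall"]),
               (17 / 17 + 58 / 65 + 80 / 90 + 51 / 60) / 4)
  # diagonal matrix over its own class universe: everything 1
  d <- confusion_matrix(rep(c("POLE", "MSI"), 5), rep(c("POLE", "MSI"), 5),
                        levels = c("POLE", "MSI"))
  expect_equal(unname(aggregate_metrics(d, "macro")), c(1, 1, 1, 1),
               tolerance = 1e-12)
  expect_true(all(weighted >= 0 & weighted <= 1))
})

test_that("weighted recall equals accuracy on random complete matrices", {
  set.seed(8)
  for (i in 1:10) {
    ref <- sample(c("POLE", "MSI", "CN-low", "CN-high"), 100, replace = TRUE)
    pred <- sample(c("POLE", "MSI", "CN-low", "CN-high"), 100, replace = TRUE)
    m <- confusion_matrix(ref, pred)
    agg <- aggregate_metrics(m, "weighted")
    expect_equal(unname(agg["recall"]), unname(agg["accuracy"]),
                 tolerance = 1e-12)
  }
})

test_that("row percentages use half-up whole-percent rounding", {
  m <- published_concordance()
  rp <- row_percentages(m)
  expect_equal(unname(rp["POLE", ]), c(100, 0, 0, 0))
  expect_equal(unname(rp["MSI", ]), c(0, 89, 9, 2))
  expect_equal(unname(rp["CN-low", ]), c(0, 0, 89, 11))
  expect_equal(unname(rp["CN-high", ]), c(0, 0, 15, 85))
  # unrounded fractions sum to one per row
  fr <- row_percentages(m, digits = NULL)
  expect_equal(unname(rowSums(fr)), rep(1, 4))
  # half-up, not banker's rounding
  m2 <- confusion_matrix(rep("POLE", 200),
                         rep(c("POLE", "MSI"), c(197, 3)))
  expect_equal(unname(row_percentages(m2)["POLE", "MSI"]), 2)  # 1.5 -> 2
})

test_that("chi-square homogeneity matches the textbook Pearson formula", {
  # hand-computed 2x2: (10,20) vs (20,10) -> X2 = 60*(10*10-20*20)^2/(30*30*30*30)
  res <- chisq_homogeneity(c(10, 20), c(20, 10))
  expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 / 30^4)
  expect_equal(res$df, 1)
  # identical distributions: statistic 0, p 1
  same <- chisq_homogeneity(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # symmetry in the two vectors
  a <- c(17, 65, 90, 60); b <- c(17, 58, 95, 62)
  expect_equal(chisq_homogeneity(a, b)$statistic,
               chisq_homogeneity(b, a)$statistic)
  expect_error(chisq_homogeneity(c(0, 10), c(0, 10)), "expected")
  expect_error(chisq_homogeneity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("KM product-limit matches the hand-computed worked example", {
  # events at 1 and 2, censored at 3: S(1) = 2/3, S(2) = 1/3
  fit <- km_curve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(survival_at(fit, 1), 2 / 3)
  expect_equal(survival_at(fit, 2), 1 / 3)
  expect_equal(survival_at(fit, 2.5), 1 / 3)  # step convention
  expect_equal(survival_at(fit, 0.5), 1)      # before the first event
  # all censored: survival 1 everywhere
  fit0 <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_equal(survival_at(fit0, 100), 1)
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(12)
  t <- sort(round(rexp(40, 0.05), 1))
  fit <- km_curve(t, rep(1, 40))
  for (q in c(5, 20, 50)) {
    expect_equal(survival_at(fit, q), mean(t > q), tolerance = 1e-12)
  }
})

test_that("log-rank matches a brute-force observed-minus-expected oracle", {
  set.seed(2)
  for (rep in 1:3) {
    t <- round(rexp(20, rep(c(0.05, 0.15), each = 10)), 2)
    e <- rbinom(20, 1, 0.8)
    g <- rep(c("a", "b"), each = 10)
    if (sum(e) == 0) next
    res <- logrank_test(t, e, g)
    ut <- sort(unique(t[e == 1]))
    O1 <- E1 <- V <- 0
    for (tt in ut) {
      n <- sum(t >= tt); n1 <- sum(t >= tt & g == "a")
      d <- sum(t == tt & e == 1); d1 <- sum(t == tt & e == 1 & g == "a")
      O1 <- O1 + d1; E1 <- E1 + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    expect_equal(res$statistic, (O1 - E1)^2 / V, tolerance = 1e-10)
    expect_equal(res$df, 1)
  }
})

test_that("log-rank is null on identical groups and demands events", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(c("a", "b"), each = 4)
  res <- logrank_test(t, e, g)
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_error(logrank_test(t, rep(0, 8), g), "event")
  expect_error(logrank_test(t, e, rep("a", 8)), "2 groups")
})

test_that("four ordered-hazard synthetic groups give log-rank p < 0.01", {
  labels <- rep(c("POLE", "MSI", "CN-low", "CN-high"), c(17, 65, 90, 60))
  surv <- simulate_survival(labels, seed = 99)
  res <- logrank_test(surv$followup_months, surv$event, labels)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$df, 3)
})

test_that("evaluate_cohort assembles the full report", {
  co <- simulate_cohort(n = 80, seed = 23, n_genes = 60)
  model <- ec_classifier(co$cn, co$clinical$cn_cluster == 4, co$genes)
  calls <- predict(model, co$variants, co$clinical, co$cn)
  ev <- evaluate_cohort(calls, co$clinical)
  expect_s3_class(ev, "cohort_evaluation")
  expect_equal(sum(ev$confusion), 80)
  expect_equal(unname(ev$weighted["recall"]), unname(ev$macro["accuracy"]),
               tolerance = 1e-12)
  expect_true(all(ev$landmark_reference >= 0 & ev$landmark_reference <= 1))
  expect_equal(ev$logrank_reference$df, 3)
  expect_output(print(ev), "Chi-square")
  # reference column required
  cl2 <- co$clinical; cl2$tcga_subtype <- NULL
  expect_error(evaluate_cohort(calls, cl2), "tcga_subtype")
})
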