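test_that("confusion matrix counts actual-by-predicted", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(actual = c("A", "B"),
                                                   predicted = c("A", "B"))))
  y <- c("A", "B", "C", "A")
  cmd <- confusion_matrix(y, y, c("A", "B", "C"))
  expect_equal(sum(diag(cmd)), 4L)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0L)
  expect_error(confusion_matrix(c("A", "B"), "A"), "length")
  cm0 <- confusion_matrix(character(0), character(0), c("A", "B"))
  expect_true(all(cm0 == 0))
})

test_that("per-class accuracy is row-wise and the mean is unweighted", {
  cm <- reference_confusion("12features")
  acc <- class_accuracies(cm)
  expect_equal(acc$truncated$per_class,
               c(hunger = 0.9032, sleep = 0.8759, discomfort = 0.9569))
  expect_equal(acc$truncated$mean, 0.9120)
  # pooled accuracy differs from the unweighted mean: the reported mean is
  # the mean of the row accuracies
  expect_false(isTRUE(all.equal(truncate4(sum(diag(cm)) / sum(cm)), 0.9120)))

  cm5 <- reference_confusion("5features")
  acc5 <- class_accuracies(cm5)
  expect_equal(acc5$truncated$per_class,
               c(hunger = 0.9569, sleep = 0.9302, discomfort = 0.9677))
  expect_equal(acc5$truncated$mean, 0.9516)

  ident <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_equal(class_accuracies(ident)$per_class, c(A = 1, B = 1))
  bad <- confusion_matrix("A", "A", classes = c("A", "B"))
  expect_error(class_accuracies(bad), "B")
})

test_that("accuracies truncate (not round) to four decimals", {
  expect_equal(truncate4(113 / 129), 0.8759)   # rounds to 0.8760
  expect_equal(truncate4(0.91206), 0.9120)
  expect_equal(truncate4(1), 1)
})

test_that("the gender report reproduces its reference counts", {
  gc <- read.csv(cryclass_extdata("gender_counts.csv"))
  actual <- rep("x", sum(gc$total))
  grp <- rep(gc$group, gc$total)
  pred <- unlist(mapply(function(c0, t0) rep(c("x", "y"), c(c0, t0 - c0)),
                        gc$correct, gc$total))
  rep_ <- grouped_report(actual, pred, grp)
  rep_ <- rep_[match(gc$group, rep_$group), ]
  expect_equal(rep_$correct, gc$correct)
  expect_equal(rep_$accuracy, c(0.9378, 0.9519))
  # single group reproduces the overall accuracy
  one <- grouped_report(c("a", "a", "b"), c("a", "b", "b"), rep("g", 3))
  expect_equal(one$accuracy_full, 2 / 3)
})

test_that("stratified folds partition every row exactly once", {
  set.seed(2)
  y <- rep(c("a", "b", "c"), c(40, 30, 30))
  fold <- cryclass:::stratified_folds(y, 10)
  expect_equal(length(fold), 100L)
  expect_true(all(table(fold) == 10))
  for (cl in unique(y)) expect_true(all(table(fold[y == cl]) >= 3))
  expect_error(cryclass:::stratified_folds(rep(c("a", "b"), c(5, 50)), 10),
               "stratification")
})

test_that("cross-validation of separable clips is near-perfect", {
  cfg <- synth_config("separable")
  ds <- generate_dataset(cfg, n_per_class = 13, seed = 61)
  ft <- extract_features_all(lapply(ds$clips, `[[`, "clip"))
  red <- apply_selection(ft, "pitch")
  rep_ <- kfold_cv(red, k = 5, n_members = 10, C = 1, gamma = 0.5, seed = 62)
  expect_gte(rep_$mean_accuracy, 0.95)
  # pooled correct count equals the trace
  expect_equal(sum(rep_$predictions$actual == rep_$predictions$predicted),
               sum(diag(rep_$confusion)))
  # every row validated exactly once
  expect_equal(nrow(rep_$predictions), nrow(red))
  expect_true(all(table(rep_$predictions$fold) > 0))
})

test_that("one-vs-rest ROC has the expected extremes and complement", {
  act <- c("A", "A", "B", "B")
  perfect <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.1, 0.2, 0.9, 0.8), 4, 2,
                    dimnames = list(NULL, c("A", "B")))
  r <- roc_ovr(act, perfect)
  expect_equal(r$A$auc, 1)
  expect_equal(r$B$auc, 1)
  expect_equal(r$macro_auc, 1)
  reversed <- 1 - perfect
  colnames(reversed) <- c("A", "B")
  r2 <- roc_ovr(act, reversed)
  expect_equal(r2$A$auc, 0)

  set.seed(3)
  act3 <- sample(c("A", "B"), 1000, replace = TRUE)
  s <- runif(1000)
  sc <- cbind(A = s, B = 1 - s)
  r3 <- roc_ovr(act3, sc)
  expect_lt(abs(r3$A$auc - 0.5), 0.05)
  expect_equal(r3$A$auc + roc_ovr(act3, cbind(A = 1 - s, B = s))$A$auc, 1)
})

test_that("trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  act <- sample(c("A", "B"), 200, replace = TRUE)
  s <- runif(200) + 0.3 * (act == "A")
  ours <- roc_ovr(act, cbind(A = s, B = 1 - s))$A$auc
  ref <- as.numeric(pROC::auc(pROC::roc(act == "A", s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
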