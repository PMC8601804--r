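test_that("grid search breaks ties toward smaller C then smaller gamma", {
  set.seed(1)
  df <- make_blobs(20, list(c(0, 0), c(10, 10)))
  gs <- grid_search_svm(df, gamma_grid = c(0.1, 0.5, 1), folds = 4, seed = 2)
  expect_equal(gs$accuracy, 1)
  expect_equal(gs$C, 1)
  expect_equal(gs$gamma, 0.1)
})

test_that("grid search solves an XOR pattern with a finite gamma", {
  set.seed(3)
  n <- 30
  df <- rbind(make_blobs(n, list(c(0, 0)), sd = 0.3, labels = "a"),
              make_blobs(n, list(c(2, 2)), sd = 0.3, labels = "a"),
              make_blobs(n, list(c(0, 2)), sd = 0.3, labels = "b"),
              make_blobs(n, list(c(2, 0)), sd = 0.3, labels = "b"))
  gs <- grid_search_svm(df, gamma_grid = seq(0.1, 5, by = 0.1), folds = 5, seed = 4)
  expect_gt(gs$accuracy, 0.9)
  expect_true(is.finite(gs$gamma))
})

test_that("grid search rejects single-class and undersized-class input", {
  df <- data.frame(x1 = rnorm(20), label = "a")
  expect_error(grid_search_svm(df), "2 classes")
  df2 <- make_blobs(3, list(c(0, 0), c(5, 5)))
  expect_error(grid_search_svm(df2, folds = 5), "stratification")
})

test_that("the SAMME vote weight has its closed form and chance floor", {
  expect_equal(cryclass:::vote_weight(0.3, 3), log(0.7 / 0.3) + log(2))
  expect_equal(cryclass:::vote_weight(0.3, 3), 1.5404, tolerance = 1e-4)
  expect_equal(cryclass:::vote_weight(2 / 3, 3), 0)   # at chance for K = 3
  expect_equal(cryclass:::vote_weight(0.9, 3), 0)
  expect_equal(cryclass:::vote_weight(0, 3), log(1e6))
})

test_that("separable blobs give confident members and perfect resubstitution", {
  set.seed(5)
  df <- make_blobs(100, list(c(0, 0), c(6, 0), c(0, 6)))
  m <- train_gsvn(df, n_members = 20, C = 1, gamma = 0.5, seed = 6)
  eps_implied <- vapply(m$members, function(mm) mm$val_accuracy, numeric(1))
  expect_true(all(1 - eps_implied < 0.05))
  pr <- predict(m, df)
  expect_equal(mean(as.character(pr$labels) == df$label), 1)
})

test_that("a committee of one predicts exactly like its base SVM", {
  set.seed(7)
  df <- make_blobs(30, list(c(0, 0), c(3, 0), c(0, 3)))
  m <- train_gsvn(df, n_members = 1, C = 1, gamma = 0.5, seed = 8)
  xs <- cryclass:::apply_standardizer(as.matrix(df[, m$schema]), m$standardizer)
  base <- as.character(predict(m$members[[1]]$svm, xs))
  pr <- predict(m, df)
  expect_equal(as.character(pr$labels), base)
})

test_that("vote scores are normalized, non-negative, tie-broken by class order", {
  # hand-built committee: member 1 votes A (w 0.9), members 2-3 vote B (w 0.4)
  fake_svm <- function(lab) structure(list(lab = lab), class = "fake_svm")
  assign("predict.fake_svm", function(object, newdata, ...) {
    rep(object$lab, nrow(newdata))
  }, envir = globalenv())
  on.exit(rm("predict.fake_svm", envir = globalenv()))
  model <- structure(
    list(members = list(list(svm = fake_svm("A"), vote_weight = 0.9),
                        list(svm = fake_svm("B"), vote_weight = 0.4),
                        list(svm = fake_svm("B"), vote_weight = 0.4)),
         classes = c("A", "B"), schema = c("x1", "x2"),
         standardizer = list(center = c(x1 = 0, x2 = 0), scale = c(x1 = 1, x2 = 1)),
         unit = "clip"),
    class = "gsvn")
  pr <- predict(model, data.frame(x1 = 0, x2 = 0))
  expect_equal(as.character(pr$labels), "A")     # 0.9 beats 0.8
  expect_equal(as.numeric(pr$scores), c(0.9, 0.8) / 1.7)
  expect_equal(sum(pr$scores), 1)

  # exact tie -> first class in model order
  model$members[[1]]$vote_weight <- 0.8
  pr2 <- predict(model, data.frame(x1 = 0, x2 = 0))
  expect_equal(as.character(pr2$labels), "A")
})

test_that("prediction enforces the feature schema", {
  set.seed(9)
  df <- make_blobs(20, list(c(0, 0), c(4, 4)))
  m <- train_gsvn(df, n_members = 2, C = 1, gamma = 0.5, seed = 10)
  bad <- data.frame(x1 = rnorm(3), extra = rnorm(3))
  expect_error(predict(m, bad), "schema mismatch.*x2.*extra")
})

test_that("permuted labels leave ensemble CV accuracy near chance", {
  set.seed(11)
  df <- make_blobs(50, list(c(0, 0), c(4, 0), c(0, 4)))
  df$label <- sample(df$label)
  rep <- kfold_cv(df, k = 5, n_members = 10, C = 1, gamma = 0.5, seed = 12)
  expect_lt(abs(rep$mean_accuracy - 1 / 3), 0.1)
})

test_that("test accuracy does not degrade as class separation grows", {
  accs <- vapply(c(1, 2, 4), function(sep) {
    set.seed(13)
    df <- make_blobs(40, list(c(0, 0), c(sep, 0), c(0, sep)), sd = 1)
    kfold_cv(df, k = 4, n_members = 10, C = 1, gamma = 0.5, seed = 14)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.02))
})

test_that("training and prediction are deterministic under a fixed seed", {
  set.seed(15)
  df <- make_blobs(30, list(c(0, 0), c(3, 3)))
  m1 <- train_gsvn(df, n_members = 5, C = 1, gamma = 0.5, seed = 16)
  m2 <- train_gsvn(df, n_members = 5, C = 1, gamma = 0.5, seed = 16)
  p1 <- predict(m1, df); p2 <- predict(m2, df)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$scores, p2$scores)
  expect_identical(vapply(m1$members, `[[`, numeric(1), "vote_weight"),
                   vapply(m2$members, `[[`, numeric(1), "vote_weight"))
})

test_that("clip-level aggregation takes the margin-weighted frame plurality", {
  set.seed(17)
  df <- make_blobs(30, list(c(0, 0), c(5, 0), c(0, 5)),
                   labels = c("hunger", "sleep", "discomfort"))
  m <- train_gsvn(df, n_members = 5, C = 1, gamma = 0.5, seed = 18, unit = "frame")
  hunger_rows <- df[df$label == "hunger", 1:2]
  expect_equal(predict_clip(m, hunger_rows), "hunger")
  expect_equal(predict_clip(m, hunger_rows[1, , drop = FALSE]), "hunger")
  mixed <- rbind(df[df$label == "sleep", 1:2][1:6, ],
                 df[df$label == "hunger", 1:2][1:4, ])
  expect_equal(predict_clip(m, mixed), "sleep")
})
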