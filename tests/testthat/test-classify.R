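test_that("SMO solves symmetric and separable toy problems exactly", {
  # one feature, one point per class, symmetric about the origin
  X <- matrix(c(-1, 1), 2)
  fit <- train_linear_svm(X, c("control", "patient"),
                          svm_config(C = 100, tol = 1e-6))
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(length(fit$support), 2L)
  expect_equal(unname(predict(fit, matrix(c(0.4, -0.4), 2))),
               c("patient", "control"))
  # any separable toy set with large C: zero training errors
  set.seed(20)
  X2 <- rbind(matrix(rnorm(20, mean = 3), 10, 2),
              matrix(rnorm(20, mean = -3), 10, 2))
  y2 <- rep(c("patient", "control"), each = 10)
  fit2 <- train_linear_svm(X2, y2, svm_config(C = 100, tol = 1e-6))
  expect_equal(unname(predict(fit2, X2)), y2)
  expect_error(train_linear_svm(X2, rep("patient", 20)), "two classes")
})

test_that("SMO agrees with an interior-point QP oracle on random problems", {
  skip_if_not_installed("kernlab")
  set.seed(21)
  worst_obj <- 0; worst_dec <- 0
  for (rep_ in 1:50) {
    n <- sample(6:15, 1)
    X <- matrix(rnorm(n * 3), n)
    y01 <- c(rep(1, ceiling(n / 2)), rep(0, floor(n / 2)))
    y <- ifelse(y01 == 1, "patient", "control")
    fit <- train_linear_svm(X, y, svm_config(C = 1, tol = 1e-6,
                                             seed = rep_))
    orc <- svm_qp_oracle(X, y01, C = 1)
    scale_obj <- max(1, abs(orc$objective))
    worst_obj <- max(worst_obj, abs(fit$objective - orc$objective) /
                       scale_obj)
    dec <- predict(fit, X, type = "decision")
    scale_dec <- max(1, max(abs(orc$decision)))
    worst_dec <- max(worst_dec, max(abs(dec - orc$decision)) / scale_dec)
  }
  expect_lt(worst_obj, 1e-4)
  expect_lt(worst_dec, 1e-4)
})

test_that("SMO is deterministic and matches libsvm on a fixed problem", {
  skip_if_not_installed("e1071")
  set.seed(22)
  X <- rbind(matrix(rnorm(24, 1), 12, 2), matrix(rnorm(24, -1), 12, 2))
  y <- rep(c("patient", "control"), each = 12)
  f1 <- train_linear_svm(X, y, svm_config(tol = 1e-6, seed = 5))
  f2 <- train_linear_svm(X, y, svm_config(tol = 1e-6, seed = 5))
  expect_identical(f1$alpha, f2$alpha)
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
  w_ref <- drop(crossprod(ref$SV, ref$coefs))
  sgn <- if (ref$labels[1] == which(levels(factor(y)) == "patient")) 1 else -1
  expect_equal(f1$w, sgn * w_ref, tolerance = 1e-2, ignore_attr = TRUE)
  expect_equal(f1$b, sgn * -ref$rho, tolerance = 1e-2)
})

test_that("LOOCV excludes exactly the held-out subject per fold", {
  set.seed(23)
  n <- 12
  X <- matrix(rnorm(n * 5), n)
  y <- rep(c("patient", "control"), each = n / 2)
  cfg <- svm_config(seed = 3)
  res <- loocv(X, cfg, groups = y)
  expect_equal(nrow(res$outcomes), n)
  expect_equal(res$outcomes$fold, seq_len(n))
  # recompute a few folds by hand: train on X[-i] only, predict subject i
  for (i in c(1, 5, n)) {
    Xtr <- X[-i, ]; ytr <- y[-i]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    fit <- train_linear_svm(Xs, ytr, cfg)
    pred <- predict(fit, sweep(sweep(X[i, , drop = FALSE], 2, mu), 2,
                               sdv, `/`))
    expect_equal(unname(pred), res$outcomes$predicted[i])
  }
  # no leakage: corrupting the held-out subject's features leaves the
  # fold's trained model identical (the fold never sees that row)
  X2 <- X; X2[4, ] <- 1e3
  f_clean <- train_linear_svm(scale(X[-4, ]), y[-4], cfg)
  f_dirty <- train_linear_svm(scale(X2[-4, ]), y[-4], cfg)
  expect_identical(f_clean$alpha, f_dirty$alpha)
  expect_error(loocv(X[1:3, ], cfg, groups = y[1:3]), "at least 4")
  expect_error(loocv(X, cfg, groups = c(rep("patient", 11), "control")),
               "at least 2")
})

test_that("planted separable clouds classify perfectly; labels symmetric", {
  set.seed(24)
  n <- 36
  X <- rbind(matrix(rnorm(18 * 10, mean = 2, sd = 0.1), 18),
             matrix(rnorm(18 * 10, mean = -2, sd = 0.1), 18))
  y <- rep(c("patient", "control"), each = 18)
  res <- loocv(X, svm_config(), groups = y)
  expect_equal(res$summary$accuracy, 1.0)
  # label symmetry: swapping class names swaps sensitivity/specificity
  set.seed(25)
  Xn <- matrix(rnorm(16 * 4), 16)
  yn <- rep(c("patient", "control"), 8)
  r1 <- loocv(Xn, svm_config(seed = 1), groups = yn)
  y_sw <- ifelse(yn == "patient", "control", "patient")
  r2 <- loocv(Xn, svm_config(seed = 1), groups = y_sw)
  expect_equal(r1$summary$accuracy, r2$summary$accuracy)
  expect_equal(r1$summary$sensitivity, r2$summary$specificity)
  expect_equal(r1$summary$specificity, r2$summary$sensitivity)
})

test_that("summary arithmetic follows the confusion-matrix definitions", {
  mk <- function(correct_p, correct_c) {
    o <- data.frame(
      subject_id = sprintf("s%02d", 1:36),
      group = rep(c("patient", "control"), each = 18),
      predicted = c(ifelse(seq_len(18) <= correct_p, "patient", "control"),
                    ifelse(seq_len(18) <= correct_c, "control", "patient")),
      stringsAsFactors = FALSE)
    o$correct <- as.integer(o$predicted == o$group)
    o$fold <- 1:36
    class(o) <- c("outcome_vector", "data.frame")
    o
  }
  s <- summarize_outcomes(mk(16, 17))
  expect_equal(s$accuracy, 33 / 36)
  expect_equal(s$sensitivity, 16 / 18)
  expect_equal(s$specificity, 17 / 18)
  s_all <- summarize_outcomes(mk(18, 18))
  expect_equal(unlist(s_all[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  s_none <- summarize_outcomes(mk(0, 18))
  expect_equal(s_none$sensitivity, 0)
  expect_equal(s_none$specificity, 1)
})
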