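test_that("Gaussian weights follow the kernel formula and its limits", {
  set.seed(1)
  x <- matrix(rnorm(5 * 8), nrow = 5)
  # identical sample has weight exactly 1
  w <- gaussian_weights(x[3, ], x, sigma = 1.5)
  expect_equal(w[3], 1)
  expect_true(all(w > 0 & w <= 1))
  # closed form at distance sigma * sqrt(2)
  sigma <- 2.3
  y <- x[1, ] + c(sigma * sqrt(2), rep(0, 7))
  expect_equal(gaussian_weights(y, x, sigma)[1], exp(-1), tolerance = 1e-12)
  # huge sigma sends every weight to 1
  expect_true(all(abs(gaussian_weights(rnorm(8), x, 1e9) - 1) < 1e-9))
  # monotone decreasing in distance
  d <- sqrt(rowSums(sweep(x, 2, x[3, ])^2))
  expect_identical(order(gaussian_weights(x[3, ], x, 1.5)), order(-d))
  expect_error(gaussian_weights(rnorm(3), x), "dimension")
})

test_that("constrained solutions are feasible and match the FISTA oracle", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:10, 1); m <- sample(3:6, 1)
    x <- matrix(rnorm(n * m), nrow = n)
    y <- rnorm(m)
    w <- runif(n, 0.2, 2)
    r_ls <- sqrt(sum(stats::lm.fit(t(x), y)$residuals^2))
    eps <- r_ls + 0.4 * (sqrt(sum(y^2)) - r_ls)   # feasible by construction
    sol <- solve_weighted_l1(x, y, weights = w, epsilon = eps)
    expect_true(sol$feasible)
    expect_lte(sol$residual, eps + 1e-6)
    ora <- fista_constrained(x, y, w, eps)
    expect_equal(sol$objective, sum(w * abs(ora)), tolerance = 1e-6)
  }
})

test_that("solutions satisfy the weighted-lasso optimality conditions", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(4:12, 1); m <- sample(3:8, 1)
    x <- matrix(rnorm(n * m), nrow = n)
    y <- rnorm(m)
    w <- runif(n, 0.2, 2)
    r_ls <- sqrt(sum(stats::lm.fit(t(x), y)$residuals^2))
    eps <- r_ls + runif(1, 0.3, 0.7) * (sqrt(sum(y^2)) - r_ls)
    sol <- solve_weighted_l1(x, y, weights = w, epsilon = eps)
    corr <- as.numeric(x %*% (y - as.numeric(crossprod(x, sol$alpha))))
    lam <- sol$lambda
    # subgradient bound for every coordinate; equality and sign agreement
    # on the active ones
    expect_true(all(abs(corr) <= lam * w * (1 + 1e-5) + 1e-10))
    act <- which(sol$alpha != 0)
    if (length(act)) {
      expect_true(all(abs(abs(corr[act]) - lam * w[act]) <=
                        1e-5 * lam * w[act] + 1e-8))
      expect_true(all(sign(corr[act]) == sign(sol$alpha[act])))
    }
  }
})

test_that("solver agrees with glmnet at the stopping penalty", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  for (i in 1:10) {
    n <- 30; m <- 12
    x <- matrix(rnorm(n * m), nrow = n)   # samples in rows
    y <- rnorm(m)
    eps <- 0.4 * sqrt(sum(y^2))
    sol <- solve_weighted_l1(x, y, epsilon = eps)
    lam <- sol$lambda
    skip_if(lam <= 0)
    # glmnet solves 1/(2m) ||y - A b||^2 + lambda ||b||_1 with A = t(x)
    fit <- glmnet::glmnet(t(x), y, lambda = lam / m, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14)
    b <- as.numeric(fit$beta)
    obj <- function(a) 0.5 * sum((y - as.numeric(crossprod(x, a)))^2) +
      lam * sum(abs(a))
    expect_equal(obj(sol$alpha), obj(b), tolerance = 1e-4)
  }
})

test_that("a query equal to a training column concentrates on that column", {
  set.seed(5)
  x <- matrix(rnorm(8 * 5), nrow = 8)   # 8 samples, general position
  j <- 4
  sol <- solve_weighted_l1(x, x[j, ], epsilon = 1e-6)
  e_j <- replace(numeric(8), j, 1)
  expect_lt(sqrt(sum((sol$alpha - e_j)^2)), 1e-3)
  expect_true(sol$feasible)
})

test_that("weighted problem equals unweighted problem after change of variables", {
  set.seed(9)
  n <- 8; m <- 5
  x <- matrix(rnorm(n * m), nrow = n)
  y <- rnorm(m)
  w <- runif(n, 0.5, 2)
  eps <- 0.4 * sqrt(sum(y^2))
  # beta = W alpha on the substituted matrix with unit weights
  sol_w <- solve_weighted_l1(x, y, weights = w, epsilon = eps)
  sol_u <- solve_weighted_l1(x / w, y, epsilon = eps)
  expect_equal(sol_w$objective, sol_u$objective, tolerance = 1e-8)
  expect_equal(sol_w$alpha * w, sol_u$alpha, tolerance = 1e-6)
})

test_that("alpha = 0 is returned when y is already within epsilon", {
  x <- diag(3)
  sol <- solve_weighted_l1(x, c(1e-9, 0, 0), epsilon = 1e-6)
  expect_identical(sol$alpha, numeric(3))
  expect_identical(sol$objective, 0)
})

test_that("infeasible epsilon degrades to the minimum-residual path solution", {
  set.seed(13)
  x <- matrix(rnorm(3 * 10), nrow = 3)  # 3 samples in 10 dims: skinny span
  y <- rnorm(10)
  expect_warning(sol <- solve_weighted_l1(x, y, epsilon = 1e-8), "infeasible")
  expect_false(sol$feasible)
  expect_gt(sol$residual, 1e-8)
  expect_lte(sum(sol$alpha != 0), 3)
  # the returned residual is the least-squares optimum on the span
  r_ls <- sqrt(sum(stats::lm.fit(t(x), y)$residuals^2))
  expect_equal(sol$residual, r_ls, tolerance = 1e-6)
})

test_that("extreme locality weights do not overflow the solver", {
  set.seed(17)
  x <- matrix(rnorm(6 * 4), nrow = 6)
  y <- rnorm(4)
  w <- exp(c(-700, -500, -300, -100, -10, 0))   # underflow-floored kernel range
  sol <- suppressWarnings(solve_weighted_l1(x, y, weights = w,
                                            epsilon = 0.5 * sqrt(sum(y^2))))
  expect_true(all(is.finite(sol$alpha)))
  expect_true(is.finite(sol$objective))
})

test_that("class residuals decompose by class and respect permutations", {
  set.seed(21)
  x <- matrix(rnorm(10 * 6), nrow = 10)
  labels <- rep(c(0L, 1L), each = 5)
  y <- rnorm(6)
  alpha <- rnorm(10)
  r <- class_residuals(x, y, alpha, labels)
  expect_named(r, c("0", "1"))
  expect_true(all(r >= 0))
  # zero coefficients give ||y|| for every class
  r0 <- class_residuals(x, y, numeric(10), labels)
  expect_equal(unname(r0), rep(sqrt(sum(y^2)), 2))
  # exact reconstruction inside one class
  a1 <- ifelse(labels == 1L, alpha, 0)
  y1 <- as.numeric(crossprod(x, a1))
  r1 <- class_residuals(x, y1, a1, labels)
  expect_equal(r1[["1"]], 0, tolerance = 1e-10)
  expect_equal(r1[["0"]], sqrt(sum(y1^2)))
  # permuting columns within a class leaves residuals unchanged
  per <- c(sample(1:5), sample(6:10))
  r_p <- class_residuals(x[per, ], y, alpha[per], labels[per])
  expect_equal(r_p, r)
  # residual decomposition: sum over classes of X delta_c(alpha) = X alpha
  recon <- Reduce(`+`, lapply(c(0L, 1L), function(cl)
    as.numeric(crossprod(x, ifelse(labels == cl, alpha, 0)))))
  expect_equal(recon, as.numeric(crossprod(x, alpha)))
})

test_that("prediction recovers well-separated Gaussian clusters", {
  set.seed(404)
  m <- 10
  mk <- function(n, center) sweep(matrix(rnorm(n * m, sd = 1), nrow = n), 2,
                                  center, `+`)
  c1 <- rep(0, m); c2 <- rep(10, m)   # separation 10x the spread
  xtr <- rbind(mk(50, c1), mk(50, c2))
  ytr <- rep(c(0L, 1L), each = 50)
  xte <- rbind(mk(20, c1), mk(20, c2))
  yte <- rep(c(0L, 1L), each = 20)
  model <- wsrc_fit(xtr, ytr)
  pred <- suppressWarnings(predict(model, xte))
  expect_identical(mean(pred$class == yte), 1)
  # the residual-margin score separates the classes completely
  expect_equal(roc_auc(pred$score, yte)$auc, 1)
  # a training sample queries back to its own class
  self <- suppressWarnings(predict(model, xtr[7, ]))
  expect_identical(self$class, 0L)
})

test_that("tie-breaking and batch semantics are deterministic", {
  set.seed(6)
  x <- matrix(rnorm(6 * 4), nrow = 6)
  model <- wsrc_fit(x, rep(c(1L, 2L), each = 3))
  batch <- matrix(rnorm(3 * 4), nrow = 3)
  p_all <- suppressWarnings(predict(model, batch))
  p_one <- suppressWarnings(predict(model, batch[2, ]))
  expect_equal(p_all[2, c("r_1", "r_2", "score")],
               p_one[, c("r_1", "r_2", "score")],
               ignore_attr = TRUE)
  per <- c(3, 1, 2)
  p_per <- suppressWarnings(predict(model, batch[per, ]))
  expect_equal(p_per$score, p_all$score[per])
  expect_identical(nrow(predict(model, matrix(numeric(0), 0, 4))), 0L)
  # exact residual ties go to the lowest class label: force by symmetry
  xs <- rbind(c(1, 0), c(0, 1))
  ms <- wsrc_fit(xs, c(0L, 1L))
  pr <- suppressWarnings(predict(ms, c(1 / sqrt(2), 1 / sqrt(2))))
  expect_equal(pr$r_0, pr$r_1, tolerance = 1e-9)
  expect_identical(pr$class, 0L)
})

test_that("model validation rejects degenerate inputs", {
  x <- matrix(rnorm(12), nrow = 4)
  expect_error(wsrc_fit(x, rep(1L, 4)), "2 classes")
  expect_error(wsrc_fit(x, c(0L, 1L)), "labels length")
  expect_error(wsrc_fit(x, c(0L, 0L, 1L, 1L), sigma = -1), "sigma")
  model <- wsrc_fit(x, c(0L, 0L, 1L, 1L))
  expect_error(predict(model, rnorm(7)), "features")
})

test_that("models round-trip through the flat text archive", {
  set.seed(8)
  x <- matrix(rnorm(8 * 5), nrow = 8)
  model <- wsrc_fit(x, rep(c(0L, 1L), 4), sigma = 2, epsilon = 1e-4,
                    weight_mode = "inverse_similarity")
  d <- withr::local_tempdir()
  wsrc_save(model, d)
  back <- wsrc_load(d)
  expect_equal(back$x, model$x, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$labels, model$labels)
  expect_identical(back$sigma, model$sigma)
  expect_identical(back$weight_mode, model$weight_mode)
  y <- rnorm(5)
  expect_equal(suppressWarnings(predict(model, y))$score,
               suppressWarnings(predict(back, y))$score, tolerance = 1e-9)
})

test_that("pair symmetrization doubles rows with swapped halves", {
  x <- matrix(1:12, nrow = 2)           # 2 pairs x 6 features (halves of 3)
  aug <- symmetrize_pairs(x, labels = c(1L, 0L))
  expect_identical(dim(aug$x), c(4L, 6L))
  expect_identical(aug$labels, c(1L, 0L, 1L, 0L))
  expect_identical(unname(aug$x[3, ]), c(x[1, 4:6], x[1, 1:3]))
  expect_error(symmetrize_pairs(matrix(1:6, nrow = 2)), "%%")
})
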