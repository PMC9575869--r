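test_that("graph Laplacian: PSD, constant null vector, cluster structure", {
  set.seed(40)
  X <- matrix(rnorm(60 * 2), 60, 2)
  L <- build_laplacian(X, graph_spec(k = 5))
  expect_equal(L, t(L), tolerance = 1e-12)
  for (rep in 1:20) {
    v <- rnorm(60)
    expect_gte(drop(v %*% L %*% v), -1e-9)
  }
  expect_lt(max(abs(L %*% rep(1, 60))), 1e-12)
  # two far-separated chains with small k: exactly two zero eigenvalues
  X2 <- rbind(cbind(seq(0, 2, by = 0.1), 0),
              cbind(seq(50, 52, by = 0.1), 0))
  L2 <- build_laplacian(X2, graph_spec(k = 3))
  ev <- eigen(L2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8), 2)
  expect_error(build_laplacian(X2[1:3, ], graph_spec(k = 5)), "k \\+ 1")
})

test_that("RLS matches the dense closed-form kernel ridge solve", {
  set.seed(41)
  for (case in 1:3) {
    X <- matrix(rnorm(30 * 2), 30, 2)
    y <- sample(c("p", "q"), 30, replace = TRUE)
    mod <- fit_rls(X, y, gamma_A = 0.05)
    K <- exp(-as.matrix(dist(X))^2 / (2 * mod$sigma_k^2))
    Y <- ifelse(outer(y, sort(unique(y)), "=="), 1, -1)
    alpha <- solve(K + 0.05 * 30 * diag(30), Y)
    expect_lt(max(abs(alpha - mod$alpha)), 1e-8)
  }
  expect_error(fit_rls(matrix(rnorm(10), 5), rep("a", 5), gamma_A = 0),
               "positive")
})

test_that("huge ambient regularization collapses RLS toward zero scores", {
  set.seed(42)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- rep(c("a", "b"), each = 20)
  mod <- fit_rls(X, y, gamma_A = 1e8)
  expect_lt(max(abs(mod$alpha)), 1e-6)
  expect_lt(max(abs(predict(mod, X)$scores)), 1e-3)
})

test_that("tiny-kernel RLS interpolates one labeled point per class", {
  X <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  mod <- fit_rls(X, c("a", "b"), gamma_A = 1e-6, sigma_k = 0.3)
  expect_identical(predict(mod, X)$labels, c("a", "b"))
})

test_that("LapRLS with zero intrinsic weight reduces to RLS", {
  set.seed(43)
  Xl <- matrix(rnorm(24 * 2), 24, 2)
  yl <- rep(c("a", "b"), 12)
  Xu <- matrix(rnorm(30), 15, 2)
  rls <- fit_rls(Xl, yl, gamma_A = 0.01, sigma_k = 1)
  lap <- fit_laprls(Xl, yl, Xu, gamma_A = 0.01, gamma_I = 0, sigma_k = 1)
  probe <- matrix(rnorm(20), 10, 2)
  expect_lt(max(abs(predict(rls, probe)$scores -
                    predict(lap, probe)$scores)), 1e-6)
  expect_error(fit_laprls(Xl, yl, Xu, gamma_I = -1), "non-negative")
})

test_that("LapRLS solution minimizes the pooled-span objective", {
  set.seed(44)
  Xl <- matrix(rnorm(20 * 2), 20, 2)
  yl <- rep(c("a", "b"), 10)
  Xu <- matrix(rnorm(40), 20, 2)
  gamma_A <- 0.01; gamma_I <- 0.5
  lap <- fit_laprls(Xl, yl, Xu, gamma_A = gamma_A, gamma_I = gamma_I,
                    sigma_k = 1)
  n <- 40; l <- 20
  K <- exp(-as.matrix(dist(rbind(Xl, Xu)))^2 / 2)
  Y <- rbind(ifelse(outer(yl, c("a", "b"), "=="), 1, -1), matrix(0, 20, 2))
  L <- lap$L
  objective <- function(alpha) {
    f <- K %*% alpha
    sum((Y[1:l, ] - f[1:l, ])^2) + gamma_A * l * sum(alpha * f) +
      gamma_I * l / n^2 * sum(f * (L %*% f))
  }
  o_lap <- objective(lap$alpha)
  # embed the RLS solution in the pooled span: it cannot do better
  rls <- fit_rls(Xl, yl, gamma_A = gamma_A, sigma_k = 1)
  alpha_rls <- rbind(rls$alpha, matrix(0, 20, 2))
  expect_lte(o_lap, objective(alpha_rls) + 1e-9)
  # and random perturbations cannot do better either
  for (rep in 1:5) {
    expect_lte(o_lap, objective(lap$alpha + matrix(rnorm(80, 0, 0.01), 40)))
  }
})

test_that("two-moons: LapRLS succeeds where two-label RLS fails", {
  mm <- make_two_moons(202, noise = 0.06, seed = 7)
  Xl <- mm$X[mm$ends, , drop = FALSE]; yl <- mm$y[mm$ends]
  Xu <- mm$X[-mm$ends, , drop = FALSE]; yu <- mm$y[-mm$ends]
  rls <- fit_rls(Xl, yl, gamma_A = 1e-3, sigma_k = 0.35)
  acc_rls <- mean(predict(rls, Xu)$labels == yu)
  lap <- fit_laprls(Xl, yl, Xu, gamma_A = 1e-4, gamma_I = 100,
                    sigma_k = 0.35, spec = graph_spec(k = 7, sigma = 0.3))
  acc_lap <- mean(predict(lap, Xu)$labels == yu)
  expect_lte(acc_rls, 0.70)
  expect_gte(acc_lap, 0.95)
})

test_that("Nystrom solver: exact limit, solver contract, subsample accuracy", {
  mm <- make_two_moons(122, noise = 0.06, seed = 9)
  Xl <- mm$X[mm$ends, , drop = FALSE]; yl <- mm$y[mm$ends]
  Xu <- mm$X[-mm$ends, , drop = FALSE]; yu <- mm$y[-mm$ends]
  lap <- fit_laprls(Xl, yl, Xu, gamma_A = 1e-4, gamma_I = 100,
                    sigma_k = 0.35, spec = graph_spec(k = 7, sigma = 0.3))
  # m = n with tight tolerance reproduces the dense solution
  ny_full <- fit_nystrom_laprls(Xl, yl, Xu, gamma_A = 1e-4, gamma_I = 100,
                                sigma_k = 0.35,
                                spec = graph_spec(k = 7, sigma = 0.3),
                                m = 122, pcg_tol = 1e-12, seed = 0)
  expect_lt(max(abs(predict(ny_full, mm$X)$scores -
                    predict(lap, mm$X)$scores)), 1e-6)
  # the normal-equations solve bottoms out near sqrt(machine eps); the
  # returned residual must still be tiny
  expect_lte(ny_full$pcg$rel_residual, 1e-8)
  # quarter subsample stays within 3 accuracy points
  ny_q <- fit_nystrom_laprls(Xl, yl, Xu, gamma_A = 1e-4, gamma_I = 100,
                             sigma_k = 0.35,
                             spec = graph_spec(k = 7, sigma = 0.3),
                             m = 31, pcg_tol = 1e-6, max_pcg_iter = 3000,
                             seed = 1)
  expect_lte(ny_q$pcg$rel_residual, 1e-6)
  acc_lap <- mean(predict(lap, Xu)$labels == yu)
  acc_ny <- mean(predict(ny_q, Xu)$labels == yu)
  expect_gte(acc_ny, acc_lap - 0.03)
  expect_error(fit_nystrom_laprls(Xl, yl, Xu, m = 1000), "exceed")
})

test_that("prediction is permutation-consistent and continuous", {
  set.seed(45)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- rep(c("a", "b"), 20)
  mod <- fit_rls(X, y, gamma_A = 1e-3)
  probe <- matrix(rnorm(20), 10, 2)
  p1 <- predict(mod, probe)
  p2 <- predict(mod, probe[10:1, ])
  expect_identical(p1$labels, rev(p2$labels))
  # continuity: nearby inputs give nearby scores
  eps <- 1e-6
  p3 <- predict(mod, probe + eps)
  expect_lt(max(abs(p1$scores - p3$scores)), 1e-3)
  expect_error(predict(mod, probe[, 1, drop = FALSE]), "mismatch")
  # training labels are reproduced at small regularization on separated data
  Xs <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
              matrix(rnorm(20, 6, 0.3), 10, 2))
  ys <- rep(c("a", "b"), each = 10)
  mod2 <- fit_rls(Xs, ys, gamma_A = 1e-8)
  expect_identical(predict(mod2, Xs)$labels, ys)
})

test_that("evaluation metrics: arithmetic, invariances, flagged labels", {
  # perfect prediction
  r <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$accuracy, 1)
  expect_equal(unname(r$per_class[, "f1"]), c(1, 1))
  expect_true(all(r$confusion[upper.tri(r$confusion) |
                              lower.tri(r$confusion)] == 0))
  # hand-computed contingency: TP=8, FP=2, FN=1
  pred <- c(rep("x", 10), rep("y", 10))
  truth <- c(rep("x", 8), "y", "y", "x", rep("y", 9))
  r2 <- evaluate_predictions(pred, truth)
  expect_equal(unname(r2$per_class["x", "precision"]), 0.8)
  expect_equal(unname(r2$per_class["x", "recall"]), 8 / 9)
  # confusion rows sum to class counts
  expect_equal(as.numeric(rowSums(r2$confusion)[c("x", "y")]),
               as.numeric(table(truth)[c("x", "y")]))
  # macro F1 invariant under relabeling; accuracy invariant under permutation
  perm <- sample(20)
  r3 <- evaluate_predictions(pred[perm], truth[perm])
  expect_equal(r3$accuracy, r2$accuracy)
  ren <- c(x = "B", y = "A")
  r4 <- evaluate_predictions(unname(ren[pred]), unname(ren[truth]))
  expect_equal(r4$macro_f1, r2$macro_f1)
  # unseen predicted labels are flagged, not fatal
  r5 <- evaluate_predictions(c("a", "zz"), c("a", "b"))
  expect_identical(r5$flagged_labels, "zz")
  expect_error(evaluate_predictions("a", c("a", "b")), "mismatch")
})

test_that("score RMSE matches its definition on a designated partition", {
  scores <- matrix(c(0.5, -0.2, 0.9, -1.1), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  truth <- c("a", "b")
  r <- evaluate_predictions(c("a", "b"), truth, scores = scores)
  Tg <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(r$rmse, sqrt(mean((scores - Tg)^2)))
  r1 <- evaluate_predictions(c("a", "b"), truth, scores = scores,
                             partition = 1)
  expect_equal(r1$rmse, sqrt(mean((scores[1, ] - Tg[1, ])^2)))
})
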