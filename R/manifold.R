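#' Graph specification for the Laplacian smoothness penalty
#'
#' @param k nearest-neighbor count (>= 1; default 7).
#' @param sigma heat-kernel width; `NULL` uses the median pairwise distance
#'   of the data the graph is built on.
#' @param kind `"unnormalized"` (`L = D - W`) or `"normalized"`
#'   (`I - D^-1/2 W D^-1/2`).
#' @return A `graph_spec` list.
#' @export
graph_spec <- function(k = 7, sigma = NULL, kind = "unnormalized") {
  if (k < 1) stop("k must be >= 1")
  if (!kind %in% c("unnormalized", "normalized")) stop("unknown laplacian kind")
  structure(list(k = k, sigma = sigma, kind = kind), class = "graph_spec")
}

#' Build a graph Laplacian over feature vectors
#'
#' Symmetric k-nearest-neighbor graph (union of directed kNN, self-loops
#' excluded) with heat-kernel weights `exp(-|xi - xj|^2 / sigma^2)`;
#' `L = D - W` or its symmetric-normalized variant. `L` is symmetric
#' positive semi-definite and annihilates the constant vector in the
#' unnormalized case.
#'
#' @param X feature matrix (n x d, n >= k + 1).
#' @param spec a [graph_spec()].
#' @return The n x n Laplacian matrix.
#' @export
build_laplacian <- function(X, spec = graph_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < spec$k + 1) stop("need at least k + 1 points")
  Dm <- as.matrix(dist(X))
  sigma <- spec$sigma
  if (is.null(sigma)) sigma <- max(median(Dm[upper.tri(Dm)]), 1e-12)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(Dm[i, ])
    nb <- setdiff(ord, i)[seq_len(spec$k)]
    W[i, nb] <- exp(-Dm[i, nb]^2 / sigma^2)
  }
  W <- pmax(W, t(W))                      # union of directed kNN
  dg <- rowSums(W)
  if (spec$kind == "unnormalized") return(diag(dg) - W)
  di <- ifelse(dg > 0, 1 / sqrt(dg), 0)
  diag(1, n) - t(W * di) * di
}

rbf_kernel <- function(X, Y = X, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

median_sigma <- function(X) {
  Dm <- dist(as.matrix(X))
  max(median(Dm), 1e-12)
}

one_vs_rest_targets <- function(y, classes) {
  Y <- matrix(-1, length(y), length(classes),
              dimnames = list(NULL, classes))
  for (j in seq_along(classes)) Y[y == classes[j], j] <- 1
  Y
}

new_manifold_model <- function(algorithm, X, alpha, classes, sigma_k,
                               gamma_A, gamma_I, extra = list()) {
  structure(c(list(algorithm = algorithm, X = as.matrix(X), alpha = alpha,
                   classes = classes, sigma_k = sigma_k,
                   gamma_A = gamma_A, gamma_I = gamma_I), extra),
            class = "manifold_model")
}

#' Regularized least squares (kernel ridge) classifier
#'
#' One-vs-rest kernel ridge on labeled data only: per-class expansion
#' coefficients `alpha = (K + gamma_A * n * I)^-1 y` with `y` the +/-1
#' targets; prediction is the argmax over class scores. This is the ambient
#' term of the manifold-regularization objective with the intrinsic
#' (Laplacian) weight set to zero.
#'
#' @param X_l labeled feature matrix.
#' @param y_l labels.
#' @param gamma_A ambient regularization weight (> 0; default 1e-3).
#' @param sigma_k RBF kernel width; `NULL` uses the median pairwise
#'   distance.
#' @return A `manifold_model`.
#' @export
fit_rls <- function(X_l, y_l, gamma_A = 1e-3, sigma_k = NULL) {
  X_l <- as.matrix(X_l); y_l <- as.character(y_l)
  if (gamma_A <= 0) stop("gamma_A must be positive")
  if (is.null(sigma_k)) sigma_k <- median_sigma(X_l)
  classes <- sort(unique(y_l))
  n <- nrow(X_l)
  K <- rbf_kernel(X_l, sigma = sigma_k)
  Y <- one_vs_rest_targets(y_l, classes)
  alpha <- solve(K + gamma_A * n * diag(n), Y)
  new_manifold_model("rls", X_l, alpha, classes, sigma_k, gamma_A, 0)
}

#' Laplacian regularized least squares (semi-supervised)
#'
#' Minimizes the squared-loss manifold-regularization objective over the
#' span of kernel sections at all labeled and unlabeled points: per-class
#' `alpha = (J K + gamma_A l I + gamma_I l / (l + u)^2 L K)^-1 J y` with `J`
#' the labeled-indicator diagonal, `L` the graph Laplacian over the pooled
#' points, and `y` +/-1 targets (0 on unlabeled rows). With `gamma_I = 0`
#' the labeled-point predictions coincide with [fit_rls()].
#'
#' @param X_l,y_l labeled data; `X_u` unlabeled feature matrix (may have
#'   zero rows).
#' @param gamma_A ambient weight (> 0); `gamma_I` intrinsic weight (>= 0).
#' @param sigma_k RBF width (`NULL`: median heuristic on pooled data).
#' @param spec a [graph_spec()] for the Laplacian.
#' @return A `manifold_model` with coefficients on all `l + u` points.
#' @export
fit_laprls <- function(X_l, y_l, X_u, gamma_A = 1e-3, gamma_I = 1e-2,
                       sigma_k = NULL, spec = graph_spec()) {
  X_l <- as.matrix(X_l); y_l <- as.character(y_l)
  X_u <- if (is.null(X_u)) X_l[0, , drop = FALSE] else as.matrix(X_u)
  if (gamma_A <= 0) stop("gamma_A must be positive")
  if (gamma_I < 0) stop("gamma_I must be non-negative")
  l <- nrow(X_l); u <- nrow(X_u)
  X <- rbind(X_l, X_u)
  if (is.null(sigma_k)) sigma_k <- median_sigma(X)
  classes <- sort(unique(y_l))
  n <- l + u
  K <- rbf_kernel(X, sigma = sigma_k)
  J <- c(rep(1, l), rep(0, u))
  Y <- rbind(one_vs_rest_targets(y_l, classes),
             matrix(0, u, length(classes)))
  L <- if (gamma_I > 0) build_laplacian(X, spec) else matrix(0, n, n)
  A <- J * K + gamma_A * l * diag(n) +
    (gamma_I * l / (l + u)^2) * (L %*% K)
  alpha <- solve(A, J * Y)
  new_manifold_model("laprls", X, alpha, classes, sigma_k, gamma_A, gamma_I,
                     extra = list(n_labeled = l, spec = spec, L = L))
}

# Woodbury inverse of M = c0 I + B Ct' applied to a matrix: rank-m
# correction of a scaled identity, O(n m^2)
woodbury_solver <- function(c0, B, Ct) {
  m <- ncol(B)
  core <- diag(m) + crossprod(Ct, B) / c0
  core_inv <- solve(core)
  function(R) {
    R <- as.matrix(R)
    (R - B %*% (core_inv %*% (crossprod(Ct, R) / c0))) / c0
  }
}

#' Nystrom-preconditioned conjugate-gradient Laplacian RLS
#'
#' Solves the exact Laplacian-RLS linear system iteratively instead of by a
#' dense factorization. A uniform-random landmark set of size `m` gives the
#' Nystrom kernel approximation `K ~ K_nm K_mm^+ K_mn`; substituting it into
#' the system matrix yields a rank-m correction of a scaled identity whose
#' inverse is available in `O(n m^2)` by the Woodbury identity. That inverse
#' preconditions conjugate gradients (run on the normal equations, since the
#' system is non-symmetric), iterating until the relative residual of the
#' true system drops below `pcg_tol`. With `m = n` the preconditioner equals
#' the exact system and the solve converges immediately to the
#' [fit_laprls()] solution.
#'
#' @inheritParams fit_laprls
#' @param m landmark count (`<= l + u`).
#' @param pcg_tol relative-residual tolerance (default 1e-8).
#' @param max_pcg_iter iteration cap (default 500).
#' @param seed seed fixing the landmark subsample.
#' @return A `manifold_model`; `pcg` holds iterations, achieved residual and
#'   a convergence flag.
#' @export
fit_nystrom_laprls <- function(X_l, y_l, X_u, gamma_A = 1e-3, gamma_I = 1e-2,
                               sigma_k = NULL, spec = graph_spec(),
                               m = NULL, pcg_tol = 1e-8, max_pcg_iter = 500,
                               seed = 0) {
  X_l <- as.matrix(X_l); y_l <- as.character(y_l)
  X_u <- if (is.null(X_u)) X_l[0, , drop = FALSE] else as.matrix(X_u)
  l <- nrow(X_l); u <- nrow(X_u); n <- l + u
  if (is.null(m)) m <- max(2L, ceiling(n / 4))
  if (m > n) stop("m cannot exceed the number of points")
  X <- rbind(X_l, X_u)
  if (is.null(sigma_k)) sigma_k <- median_sigma(X)
  classes <- sort(unique(y_l))
  K <- rbf_kernel(X, sigma = sigma_k)
  J <- c(rep(1, l), rep(0, u))
  Y <- rbind(one_vs_rest_targets(y_l, classes),
             matrix(0, u, length(classes)))
  L <- if (gamma_I > 0) build_laplacian(X, spec) else matrix(0, n, n)
  cI <- gamma_I * l / (l + u)^2
  Aop <- function(V) J * (K %*% V) + gamma_A * l * V + cI * (L %*% (K %*% V))
  Atop <- function(V) K %*% (J * V) + gamma_A * l * V + cI * (K %*% (t(L) %*% V))
  b <- J * Y
  # Nystrom landmarks and Woodbury preconditioner for
  # M = gamma_A l I + (J + cI L) K_hat,  K_hat = C Kmm^+ C'
  landmarks <- with_seed(seed, sort(sample.int(n, m)))
  C <- K[, landmarks, drop = FALSE]
  Kmm <- K[landmarks, landmarks, drop = FALSE]
  Kmm_p <- tryCatch(solve(Kmm + diag(1e-8, m)), error = function(e) pinv(Kmm))
  B <- (J * C + cI * (L %*% C)) %*% Kmm_p
  Msolve <- woodbury_solver(gamma_A * l, B, C)
  Mtsolve <- woodbury_solver(gamma_A * l, C %*% Kmm_p,
                             J * C + cI * (t(L) %*% C))
  # preconditioned CGNR on A' M^-T M^-1 A x = A' M^-T M^-1 b
  op <- function(V) Msolve(Aop(V))
  opT <- function(V) Atop(Mtsolve(V))
  bt <- Msolve(b)
  x <- matrix(0, n, ncol(Y))
  r <- bt                       # residual of preconditioned system
  s <- opT(r)
  pdir <- s
  gamma_old <- sum(s * s)
  bnorm <- sqrt(sum(b * b))
  rel_res <- 1
  iters <- 0
  for (it in seq_len(max_pcg_iter)) {
    q <- op(pdir)
    denom <- sum(q * q)
    if (denom <= 0) break
    alpha_step <- gamma_old / denom
    x <- x + alpha_step * pdir
    r <- r - alpha_step * q
    true_res <- Aop(x) - b
    rel_res <- sqrt(sum(true_res^2)) / max(bnorm, 1e-300)
    iters <- it
    if (rel_res <= pcg_tol) break
    s <- opT(r)
    gamma_new <- sum(s * s)
    pdir <- s + (gamma_new / gamma_old) * pdir
    gamma_old <- gamma_new
  }
  new_manifold_model("nystrom", X, x, classes, sigma_k, gamma_A, gamma_I,
                     extra = list(n_labeled = l, spec = spec,
                                  landmarks = landmarks,
                                  pcg = list(iterations = iters,
                                             rel_residual = rel_res,
                                             converged = rel_res <= pcg_tol)))
}

#' @export
print.manifold_model <- function(x, ...) {
  cat(sprintf("<manifold_model> %s: %d expansion points, %d classes, sigma_k = %.4g\n",
              x$algorithm, nrow(x$X), length(x$classes), x$sigma_k))
  cat(sprintf("  gamma_A = %.3g, gamma_I = %.3g\n", x$gamma_A, x$gamma_I))
  if (!is.null(x$pcg))
    cat(sprintf("  pcg: %d iterations, relative residual %.3g\n",
                x$pcg$iterations, x$pcg$rel_residual))
  invisible(x)
}

#' @export
summary.manifold_model <- function(object, ...) {
  print(object)
  cat("  coefficient norms per class:\n")
  print(round(sqrt(colSums(object$alpha^2)), 6))
  invisible(object)
}

#' Predict activities with a manifold model
#'
#' Evaluates the kernel expansion at new points (natural out-of-sample
#' extension) and assigns the argmax class.
#'
#' @param object a fitted `manifold_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return List with `labels` and the real-valued `scores` matrix.
#' @export
predict.manifold_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) stop("feature dimension mismatch")
  Kx <- rbf_kernel(newdata, object$X, sigma = object$sigma_k)
  scores <- Kx %*% object$alpha
  colnames(scores) <- object$classes
  list(labels = object$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

#' Evaluate predictions against ground truth
#'
#' Confusion matrix, overall accuracy (correctly classified activities over
#' all activities), per-class precision / recall / F1 with macro means, and
#' the RMSE of the real-valued scores against +/-1 one-vs-rest targets on a
#' designated partition of the samples.
#'
#' @param pred_labels,true_labels equal-length label vectors.
#' @param scores optional n x M score matrix for the RMSE.
#' @param partition optional logical/integer index of the rows entering the
#'   RMSE (default: all).
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(pred_labels, true_labels, scores = NULL,
                                 partition = NULL) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction/truth length mismatch")
  classes <- sort(unique(true_labels))
  extra <- setdiff(unique(pred_labels), classes)   # unseen labels get columns
  lev <- c(classes, extra)
  cm <- table(truth = factor(true_labels, levels = lev),
              predicted = factor(pred_labels, levels = lev))
  acc <- sum(diag(cm)) / sum(cm)
  prf <- t(vapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3)))
  rmse <- NA_real_
  if (!is.null(scores)) {
    idx <- if (is.null(partition)) seq_along(true_labels) else partition
    sc <- scores[idx, colnames(scores) %in% classes, drop = FALSE]
    Tg <- one_vs_rest_targets(true_labels[idx], colnames(sc))
    rmse <- sqrt(mean((sc - Tg)^2))
  }
  structure(list(confusion = cm, accuracy = acc, per_class = prf,
                 macro_precision = mean(prf[, "precision"]),
                 macro_recall = mean(prf[, "recall"]),
                 macro_f1 = mean(prf[, "f1"]),
                 macro_accuracy = mean(diag(cm[classes, classes]) /
                                         pmax(rowSums(cm)[classes], 1)),
                 rmse = rmse,
                 flagged_labels = extra),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.4f (macro %.4f)\n",
              x$accuracy, x$macro_accuracy))
  cat(sprintf("  macro P/R/F1: %.3f / %.3f / %.3f", x$macro_precision,
              x$macro_recall, x$macro_f1))
  if (is.finite(x$rmse)) cat(sprintf("; RMSE %.4f", x$rmse))
  cat("\n")
  print(x$confusion)
  invisible(x)
}
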