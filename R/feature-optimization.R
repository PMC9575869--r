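#' Fit a quadratic discriminant score model
#'
#' Per-activity Gaussian models with class-specific covariances: mean
#' `mu_m`, covariance `Sigma_m` shrunk toward the pooled diagonal
#' (`(1 - lambda_s) * S_m + lambda_s * diag(pooled variances)`), and prior
#' `pi_m` equal to the class frequency. Shrinking toward the pooled rather
#' than the class diagonal keeps the precision finite along directions that
#' are constant within a class but vary between classes. The discriminant score is
#' `delta_m(x) = -1/2 log|Sigma_m| - 1/2 (x - mu_m)' Sigma_m^-1 (x - mu_m)
#' + log pi_m`. A tiny ridge (1e-8 of the mean diagonal) keeps `Sigma_m`
#' invertible when features contain structurally-constant columns (as the
#' pattern-specific zero blocks of the pipeline feature table do).
#'
#' @param X feature matrix (n x d).
#' @param y class labels (length n, >= 2 samples per class unless
#'   `shrinkage = 1`).
#' @param shrinkage diagonal shrinkage weight in `[0, 1]` (default 0.1).
#' @return A `qda_model`.
#' @export
fit_qda <- function(X, y, shrinkage = 0.1) {
  X <- as.matrix(X); y <- as.character(y)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  classes <- sort(unique(y))
  tab <- table(y)
  if (any(tab < 2) && shrinkage < 1)
    stop("every class needs >= 2 samples unless shrinkage = 1")
  d <- ncol(X)
  # shrinkage target: the pooled diagonal, so columns that are constant
  # within a class but vary between classes keep a finite precision
  pooled <- diag(cov(X))
  pooled[!is.finite(pooled) | pooled <= 0] <- mean(pooled[pooled > 0], 1)
  models <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    S <- if (nrow(Xc) > 1) cov(Xc) else matrix(0, d, d)
    S <- (1 - shrinkage) * S + shrinkage * diag(pooled, d)
    ridge <- max(mean(diag(S)), 1) * 1e-8
    S <- S + diag(ridge, d)
    ch <- chol(S)
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         prior = unname(tab[cl] / length(y)))
  })
  names(models) <- classes
  structure(list(classes = classes, models = models, d = d,
                 shrinkage = shrinkage),
            class = "qda_model")
}

#' Map features to their quadratic discriminant scores
#'
#' Each sample becomes the vector of per-class discriminant scores
#' `(delta_1(x), ..., delta_M(x))` -- the "QDA-optimized" feature set, of
#' dimension equal to the number of activities.
#'
#' @param model a [fit_qda()] model.
#' @param X feature matrix with the training dimensionality.
#' @return n x M score matrix (columns named by class).
#' @export
qda_transform <- function(model, X) {
  stopifnot(inherits(model, "qda_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("feature dimension mismatch")
  out <- vapply(model$classes, function(cl) {
    m <- model$models[[cl]]
    dx <- sweep(X, 2, m$mu)
    z <- backsolve(m$chol, t(dx), transpose = TRUE)  # R'z = dx'
    maha <- colSums(z^2)
    -0.5 * m$logdet - 0.5 * maha + log(m$prior)
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(NULL, model$classes))
  out
}

#' Classify by maximum quadratic discriminant score
#'
#' @param model a [fit_qda()] model.
#' @param X feature matrix.
#' @return Character vector of predicted classes.
#' @export
qda_classify <- function(model, X) {
  sc <- qda_transform(model, X)
  model$classes[max.col(sc, ties.method = "first")]
}

#' Fit an orthogonal fuzzy neighborhood discriminant analysis projection
#'
#' Learns a fuzzy partition of the samples over the activities and an
#' orthogonal discriminant projection. The regularized membership objective
#' is `sum_ik mu_ik^p * g_ik - lambda * sum_ik (mu_ik - 1)` with the
#' distance-growth weight `g_ik = exp((|x_k - v_i| / (eta_i / 3))^2)` and
#' per-activity radius `eta_i = max_k |x_k - v_i|`; the sum-to-one
#' constraint is enforced by its Lagrange multiplier, which yields the
#' closed-form memberships `mu_ik proportional to g_ik^(-1/(p-1))`. Centers
#' are membership-weighted means; memberships and centers alternate to
#' convergence. Supervision enters through the initialization (crisp label
#' memberships) and through the fuzzy scatter matrices: within-class
#' `S_w = sum_ik mu_ik^p (x_k - v_i)(x_k - v_i)'` and between-class
#' `S_b = sum_i (sum_k mu_ik^p)(v_i - v_bar)(v_i - v_bar)'`. The projection
#' is the sequence of leading eigenvectors of `pinv(S_w) S_b`,
#' Gram-Schmidt-orthonormalized, so `W'W = I`.
#'
#' @param X feature matrix (n x d).
#' @param y activity labels.
#' @param p fuzzifier (> 1; default 2).
#' @param d_out projected dimension (default: number of classes - 1).
#' @param max_iter,tol alternating-update controls.
#' @return An `ofnda_model` with `W` (d x d_out, orthonormal columns),
#'   `memberships` (classes x n, columns sum to 1), `centers`, `radii`,
#'   `objective` trace and `converged` flag.
#' @export
fit_ofnda <- function(X, y, p = 2, d_out = NULL, max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X); y <- as.character(y)
  if (p <= 1) stop("fuzzifier p must exceed 1")
  classes <- sort(unique(y))
  a <- length(classes); n <- nrow(X); d <- ncol(X)
  if (is.null(d_out)) d_out <- max(a - 1, 1)
  if (d_out > d) stop("d_out cannot exceed the input dimension")
  U <- t(vapply(classes, function(cl) as.numeric(y == cl), numeric(n)))
  V <- (U %*% X) / rowSums(U)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- t(vapply(seq_len(a), function(i)
      sqrt(colSums((t(X) - V[i, ])^2)), numeric(n)))    # a x n distances
    eta <- pmax(apply(D, 1, max), 1e-12)
    G <- exp(pmin((D / (eta / 3))^2, 700))
    # closed-form memberships under the sum-to-one Lagrange constraint
    Wgt <- G^(-1 / (p - 1))
    U_new <- sweep(Wgt, 2, colSums(Wgt), "/")
    fobj <- sum(U_new^p * G)
    obj <- c(obj, fobj)
    V_new <- (U_new^p %*% X) / rowSums(U_new^p)
    delta <- max(abs(U_new - U))
    U <- U_new; V <- V_new
    if (delta < tol) { converged <- TRUE; break }
  }
  Up <- U^p
  vbar <- colSums(Up %*% X) / sum(Up)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (i in seq_len(a)) {
    dx <- sweep(X, 2, V[i, ])
    Sw <- Sw + crossprod(dx * Up[i, ], dx)
    db <- V[i, ] - vbar
    Sb <- Sb + sum(Up[i, ]) * tcrossprod(db)
  }
  M <- pinv(Sw) %*% Sb
  ev <- eigen(M)
  ord <- order(-Re(ev$values))
  W_raw <- Re(ev$vectors[, ord, drop = FALSE])
  W <- gram_schmidt(W_raw, d_out)
  rownames(U) <- classes; rownames(V) <- classes
  Dfin <- t(vapply(seq_len(a), function(i)
    sqrt(colSums((t(X) - V[i, ])^2)), numeric(n)))
  structure(list(W = W, memberships = U, centers = V,
                 radii = apply(Dfin, 1, max),
                 classes = classes, p = p, d_out = d_out,
                 objective = obj, converged = converged, d = d),
            class = "ofnda_model")
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 1e-300)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# sequential Gram-Schmidt; completes with canonical basis vectors (keeping
# the result deterministic) if a candidate direction is linearly dependent
gram_schmidt <- function(V, k) {
  d <- nrow(V)
  out <- matrix(0, d, 0)
  j <- 1
  while (ncol(out) < k) {
    v <- if (j <= ncol(V)) V[, j] else {
      e <- numeric(d); e[(j - ncol(V) - 1) %% d + 1] <- 1; e
    }
    j <- j + 1
    if (ncol(out) > 0) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) out <- cbind(out, v / nv)
    if (j > ncol(V) + d + 5) stop("could not complete orthonormal basis")
  }
  out
}

#' Project features through a fitted OFNDA model
#'
#' @param model an [fit_ofnda()] model.
#' @param X feature matrix with the training dimensionality.
#' @return n x d_out projected matrix `X W`.
#' @export
ofnda_transform <- function(model, X) {
  stopifnot(inherits(model, "ofnda_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("feature dimension mismatch")
  X %*% model$W
}
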