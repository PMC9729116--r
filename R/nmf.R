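## Deterministic nonnegative matrix factorization.
##
## Initialization is the nonnegative double-SVD scheme (each singular-vector
## pair split into positive/negative parts, the larger-norm side kept), which
## is fully deterministic, followed by Lee-Seung multiplicative updates for
## the Frobenius objective. No random restarts: identical input always gives
## identical factors.

nndsvd_init <- function(A, k, eps = 1e-9) {
  sv <- svd(A, nu = k, nv = k)
  m <- nrow(A); n <- ncol(A)
  W <- matrix(eps, m, k); H <- matrix(eps, k, n)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  W[W < eps] <- eps; H[H < eps] <- eps
  list(W = W, H = H)
}

#' Nonnegative matrix factorization (deterministic)
#'
#' @param A nonnegative numeric matrix.
#' @param k factorization rank.
#' @param max_iter maximum multiplicative-update iterations.
#' @param tol relative change in reconstruction error for early stopping.
#' @return list with nonnegative `W` (nrow(A) x k) and `H` (k x ncol(A)).
#' @export
nmf_factorize <- function(A, k, max_iter = 200, tol = 1e-5) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("nmf_factorize: input must be nonnegative")
  if (k > min(dim(A))) stop("nmf_factorize: k exceeds matrix dimensions")
  if (all(A == 0)) stop("nmf_factorize: all-zero input matrix")
  eps <- 1e-9
  ini <- nndsvd_init(A, k, eps)
  W <- ini$W; H <- ini$H
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0) {
      err <- sqrt(sum((A - W %*% H)^2))
      if (is.finite(err_old) && abs(err_old - err) <= tol * err_old) break
      err_old <- err
    }
  }
  dimnames(W) <- list(rownames(A), NULL)
  dimnames(H) <- list(NULL, colnames(A))
  list(W = W, H = H)
}
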