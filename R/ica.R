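## ICA implementations used by the linear baselines (spatial FastICA) and the
## network mapping (temporal extended Infomax). Both operate on pre-whitened
## data; components are defined up to permutation and sign.

## PCA whitening: X is p x n (variables x observations), returns k x n whitened
## scores plus the (pseudo)inverse maps.
pca_whiten <- function(X, k) {
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(X)
  sv <- svd(Xc, nu = k, nv = 0)
  if (length(sv$d) < k || sv$d[k] < 1e-10 * sv$d[1])
    stop_dim("whitening: rank < k = %d", k)
  d <- sv$d[seq_len(k)]
  Kw <- t(sv$u[, seq_len(k), drop = FALSE]) / (d / sqrt(n))   # k x p
  list(Z = Kw %*% Xc, K = Kw,
       dewhiten = sv$u[, seq_len(k), drop = FALSE] * rep(d / sqrt(n), each = nrow(X)),
       mean = mu)
}

## FastICA, deflation with tanh contrast. Z: k x n whitened. Returns W (k x k,
## rows = unmixing vectors in whitened space).
fastica_deflation <- function(Z, max_iter = 500, tol = 1e-7) {
  k <- nrow(Z); n <- ncol(Z)
  W <- matrix(0, k, k)
  for (comp in seq_len(k)) {
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(crossprod(w, Z))
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- drop(Z %*% g) / n - mean(gp) * w
      if (comp > 1) {
        Wp <- W[seq_len(comp - 1), , drop = FALSE]
        w_new <- w_new - drop(crossprod(Wp, Wp %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      conv <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (conv < tol) break
    }
    W[comp, ] <- w
  }
  W
}

## Extended Infomax, natural-gradient block updates with annealing. Z: k x n
## whitened. Sign kurtosis re-estimated each sweep (super/sub-Gaussian
## switch). Converges on the rotation change between sweeps; the learned W
## carries the usual ICA scale indeterminacy.
infomax_ica <- function(Z, max_iter = 600, lr = 5e-3, tol = 1e-6,
                        block = NULL) {
  k <- nrow(Z); n <- ncol(Z)
  if (is.null(block)) block <- max(32L, min(512L, floor(sqrt(n / 3))))
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))   # random orthogonal init
  I_k <- diag(k)
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    # kurtosis sign per component (extended rule)
    kurt <- rowMeans(U^4) - 3 * rowMeans(U^2)^2
    Ksign <- diag(sign(kurt) + (kurt == 0), k)
    W_old <- W
    idx <- sample.int(n)
    for (start in seq(1, n, by = block)) {
      sel <- idx[start:min(start + block - 1, n)]
      u <- W %*% Z[, sel, drop = FALSE]
      m <- length(sel)
      grad <- (I_k - (Ksign %*% tanh(u)) %*% t(u) / m - tcrossprod(u) / m) %*% W
      W <- W + lr * grad
      if (!all(is.finite(W)) || max(abs(W)) > 1e6) {
        # diverged: restart with smaller step
        W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
        lr <- lr / 2
        break
      }
    }
    # rotation change between sweeps, scale removed (rows normalized)
    Rn <- W / sqrt(rowSums(W^2)); Ro <- W_old / sqrt(rowSums(W_old^2))
    delta <- max(abs(abs(rowSums(Rn * Ro)) - 1))
    if (it > 100) lr <- lr * 0.995
    if (delta < tol && it > 20) break
  }
  W
}
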