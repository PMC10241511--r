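## Convolution machinery for the beta-VAE.
##
## Feature maps are stored batch-major: an n x D matrix whose columns are laid
## out channel-major, row-major positions within a channel
## (col = (ch-1)*H*W + (r-1)*W + c). Convolutions are im2col gathers followed
## by one BLAS matmul; the adjoint (transposed convolution / gradient w.r.t.
## input) is a sparse scatter-add, precomputed once per layer shape.

make_conv_plan <- function(H_in, W_in, C_in, k = 4L, stride = 2L, pad = 1L) {
  H_out <- (H_in + 2L * pad - k) %/% stride + 1L
  W_out <- (W_in + 2L * pad - k) %/% stride + 1L
  P <- H_out * W_out
  kk <- k * k * C_in
  D_in <- H_in * W_in * C_in
  Pidx <- matrix(0L, P, kk)
  for (ci in seq_len(C_in)) for (dr in 0:(k - 1)) for (dc in 0:(k - 1)) {
    ke <- ((ci - 1L) * k + dr) * k + dc + 1L
    for (ro in seq_len(H_out)) {
      r <- (ro - 1L) * stride - pad + 1L + dr
      if (r < 1L || r > H_in) next
      co <- seq_len(W_out)
      cc <- (co - 1L) * stride - pad + 1L + dc
      ok <- cc >= 1L & cc <= W_in
      pos <- (ro - 1L) * W_out + co[ok]
      Pidx[pos, ke] <- (ci - 1L) * H_in * W_in + (r - 1L) * W_in + cc[ok]
    }
  }
  nz <- which(Pidx != 0L)
  S <- Matrix::sparseMatrix(
    i = (col(Pidx)[nz] - 1L) * P + row(Pidx)[nz],
    j = Pidx[nz], x = 1, dims = c(P * kk, D_in))
  list(H_in = H_in, W_in = W_in, C_in = C_in, H_out = H_out, W_out = W_out,
       P = P, k = k, kk = kk, D_in = D_in,
       gather = as.vector(Pidx) + 1L,  # into cbind(0, Z)
       S = S)
}

conv_forward <- function(Z, plan, Wt, b) {
  n <- nrow(Z)
  Xc <- cbind(0, Z)[, plan$gather, drop = FALSE]      # n x (P*kk)
  dim(Xc) <- c(n * plan$P, plan$kk)
  Y <- Xc %*% Wt                                      # (n*P) x C_out
  Y <- sweep(Y, 2, b, "+")
  dim(Y) <- c(n, plan$P * length(b))
  list(out = Y, Xc = Xc)
}

conv_backward <- function(dOut, Xc, Z_n, plan, Wt) {
  C_out <- ncol(Wt)
  dY <- dOut
  dim(dY) <- c(Z_n * plan$P, C_out)
  dW <- crossprod(Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, Wt)                           # (n*P) x kk
  dim(dXc) <- c(Z_n, plan$P * plan$kk)
  dZ <- as.matrix(dXc %*% plan$S)
  list(dZ = dZ, dW = dW, db = db)
}

## transposed convolution: small (H_out) space -> big (H_in) space, using the
## conv plan of the corresponding forward conv big -> small.
deconv_forward <- function(Z, plan, Wd, b) {
  # Z: n x (P * C), Wd: kk x C, b: length C_in (output channels, big space)
  n <- nrow(Z); C <- ncol(Wd)
  Zr <- Z
  dim(Zr) <- c(n * plan$P, C)
  Xc <- tcrossprod(Zr, Wd)                            # (n*P) x kk
  dim(Xc) <- c(n, plan$P * plan$kk)
  out <- as.matrix(Xc %*% plan$S)                     # n x D_in (big space)
  dim(Xc) <- c(n * plan$P, plan$kk)
  HW <- plan$H_in * plan$W_in
  out <- sweep(out, 2, rep(b, each = HW), "+")
  list(out = out, Zr = Zr)
}

deconv_backward <- function(dOut, Zr, plan, Wd) {
  n <- nrow(dOut); C <- ncol(Wd)
  dXc <- cbind(0, dOut)[, plan$gather, drop = FALSE]
  dim(dXc) <- c(n * plan$P, plan$kk)
  dW <- crossprod(dXc, Zr)                            # kk x C
  dZr <- dXc %*% Wd                                   # (n*P) x C
  HW <- plan$H_in * plan$W_in
  db <- colSums(matrix(colSums(dOut), HW))            # sum per channel block
  dim(dZr) <- c(n, plan$P * C)
  list(dZ = dZr, dW = dW, db = db)
}

lrelu <- function(x, a = 0.2) {
  neg <- x < 0
  x[neg] <- a * x[neg]
  x
}
lrelu_grad <- function(x, a = 0.2) 1 + (a - 1) * (x < 0)

## Adam optimizer state for a named list of parameter matrices
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
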