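# 1-D convolutional network classifier, implemented directly with matrix
# algebra (forward pass, backprop, Adam). The network treats a selected
# feature vector as a one-dimensional sequence:
#   input (1 x n_features)
#   -> conv(kernel 5, 32 filters) + ReLU + maxpool(2, stride 2)
#   -> conv(kernel 3, 64 filters) + ReLU + maxpool(2, stride 2)
#   -> flatten -> FC(flat) -> FC(256) -> FC(64) -> softmax(n_classes)

conv1d_forward <- function(X, W, b) {
  # X: array (B, L, C_in); W: (K*C_in, C_out), k-major blocks; b: C_out
  d <- dim(X); B <- d[1]; L <- d[2]; C_in <- d[3]
  K <- nrow(W) / C_in
  L_out <- L - K + 1
  C_out <- ncol(W)
  Y <- array(0, c(B, L_out, C_out))
  for (t in seq_len(L_out)) {
    patch <- matrix(X[, t:(t + K - 1), , drop = FALSE], B, K * C_in)
    Y[, t, ] <- patch %*% W + matrix(b, B, C_out, byrow = TRUE)
  }
  Y
}

conv1d_backward <- function(X, W, dY) {
  d <- dim(X); B <- d[1]; L <- d[2]; C_in <- d[3]
  K <- nrow(W) / C_in
  L_out <- dim(dY)[2]
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dX <- array(0, dim(X))
  for (t in seq_len(L_out)) {
    patch <- matrix(X[, t:(t + K - 1), , drop = FALSE], B, K * C_in)
    g <- matrix(dY[, t, ], B, ncol(W))
    dW <- dW + crossprod(patch, g)
    db <- db + colSums(g)
    dpatch <- g %*% t(W)
    dX[, t:(t + K - 1), ] <- dX[, t:(t + K - 1), , drop = FALSE] +
      array(dpatch, c(B, K, C_in))
  }
  list(dW = dW, db = db, dX = dX)
}

pool2_forward <- function(X) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  L_out <- L %/% 2L
  Y <- array(0, c(B, L_out, C))
  amax <- array(0L, c(B, L_out, C))
  for (t in seq_len(L_out)) {
    a <- X[, 2L * t - 1L, , drop = FALSE]
    bb <- X[, 2L * t, , drop = FALSE]
    take_b <- bb > a
    Y[, t, ] <- ifelse(take_b, bb, a)
    amax[, t, ] <- ifelse(take_b, 2L * t, 2L * t - 1L)
  }
  list(Y = Y, amax = amax)
}

pool2_backward <- function(X, amax, dY) {
  dX <- array(0, dim(X))
  d <- dim(dY); B <- d[1]; L_out <- d[2]; C <- d[3]
  for (t in seq_len(L_out)) for (c in seq_len(C)) for (b in seq_len(B)) {
    dX[b, amax[b, t, c], c] <- dX[b, amax[b, t, c], c] + dY[b, t, c]
  }
  dX
}

he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)

#' 1-D convolutional network classifier
#'
#' Builds the evaluation network used when feature subsets are scored by a
#' neural classifier: two convolutional blocks (kernel 5 with 32 filters,
#' then kernel 3 with 64 filters, each followed by a rectifier and a
#' max-pool of width 2 and stride 2) feeding three fully connected layers
#' (sized to the flattened output, then 256, then 64) and a softmax output
#' with one unit per class. Implemented in plain matrix code; training uses
#' Adam on the cross-entropy loss.
#'
#' @param n_features input length. Two pooling stages require
#'   `n_features >= 12`.
#' @param n_classes number of output classes (>= 2).
#' @return An object of class `cnn_classifier` (untrained).
#' @export
cnn_classifier <- function(n_features, n_classes) {
  stop_if_not(is_count(n_classes, 2L), "need at least 2 classes")
  L1 <- n_features - 4L
  P1 <- L1 %/% 2L
  L2 <- P1 - 2L
  P2 <- L2 %/% 2L
  stop_if_not(is_count(n_features, 1L) && P2 >= 1L,
              "too few features (%d) for two convolution + pooling stages; need >= 12",
              n_features)
  flat <- P2 * 64L
  params <- list(
    Wc1 = he_init(5L, 32L), bc1 = numeric(32L),
    Wc2 = he_init(3L * 32L, 64L), bc2 = numeric(64L),
    W1 = he_init(flat, flat), b1 = numeric(flat),
    W2 = he_init(flat, 256L), b2 = numeric(256L),
    W3 = he_init(256L, 64L), b3 = numeric(64L),
    Wo = he_init(64L, n_classes), bo = numeric(n_classes))
  structure(list(params = params, n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 dims = list(conv1 = L1, pool1 = P1, conv2 = L2, pool2 = P2,
                             flat = flat),
                 levels = NULL, opt = NULL),
            class = "cnn_classifier")
}

cnn_forward <- function(net, x) {
  p <- net$params
  B <- nrow(x)
  X0 <- array(x, c(B, ncol(x), 1L))
  C1 <- conv1d_forward(X0, p$Wc1, p$bc1); R1 <- pmax(C1, 0)
  P1 <- pool2_forward(R1)
  C2 <- conv1d_forward(P1$Y, p$Wc2, p$bc2); R2 <- pmax(C2, 0)
  P2 <- pool2_forward(R2)
  FL <- matrix(P2$Y, B, length(P2$Y) / B)
  Z1 <- FL %*% p$W1 + matrix(p$b1, B, length(p$b1), byrow = TRUE); A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% p$W2 + matrix(p$b2, B, length(p$b2), byrow = TRUE); A2 <- pmax(Z2, 0)
  Z3 <- A2 %*% p$W3 + matrix(p$b3, B, length(p$b3), byrow = TRUE); A3 <- pmax(Z3, 0)
  ZO <- A3 %*% p$Wo + matrix(p$bo, B, length(p$bo), byrow = TRUE)
  ZO <- ZO - apply(ZO, 1, max)
  probs <- exp(ZO) / rowSums(exp(ZO))
  list(probs = probs,
       cache = list(X0 = X0, C1 = C1, R1 = R1, P1 = P1, C2 = C2, R2 = R2,
                    P2 = P2, FL = FL, A1 = A1, A2 = A2, A3 = A3))
}

cnn_backward <- function(net, cache, probs, y_onehot) {
  p <- net$params
  B <- nrow(probs)
  dZO <- (probs - y_onehot) / B
  g <- list()
  g$Wo <- crossprod(cache$A3, dZO); g$bo <- colSums(dZO)
  dA3 <- dZO %*% t(p$Wo) * (cache$A3 > 0)
  g$W3 <- crossprod(cache$A2, dA3); g$b3 <- colSums(dA3)
  dA2 <- dA3 %*% t(p$W3) * (cache$A2 > 0)
  g$W2 <- crossprod(cache$A1, dA2); g$b2 <- colSums(dA2)
  dA1 <- dA2 %*% t(p$W2) * (cache$A1 > 0)
  g$W1 <- crossprod(cache$FL, dA1); g$b1 <- colSums(dA1)
  dFL <- dA1 %*% t(p$W1)
  dP2 <- array(dFL, dim(cache$P2$Y))
  dR2 <- pool2_backward(cache$R2, cache$P2$amax, dP2)
  dC2 <- dR2 * (cache$C2 > 0)
  bk2 <- conv1d_backward(cache$P1$Y, p$Wc2, dC2)
  g$Wc2 <- bk2$dW; g$bc2 <- bk2$db
  dP1 <- bk2$dX
  dR1 <- pool2_backward(cache$R1, cache$P1$amax, dP1)
  dC1 <- dR1 * (cache$C1 > 0)
  bk1 <- conv1d_backward(cache$X0, p$Wc1, dC1)
  g$Wc1 <- bk1$dW; g$bc1 <- bk1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, opt = opt)
}

#' Train / predict with the 1-D convnet classifier
#'
#' @param net a [cnn_classifier()].
#' @param x numeric matrix (rows = samples, columns = features).
#' @param y factor of class labels (training only).
#' @param epochs,lr,batch_size training schedule (Adam, cross-entropy).
#' @return `cnn_train()` the trained network; `cnn_predict()` a factor of
#'   predicted labels; `cnn_predict_prob()` a matrix of class probabilities
#'   whose rows sum to 1.
#' @export
cnn_train <- function(net, x, y, epochs = 60L, lr = 1e-3, batch_size = 16L) {
  y <- factor(y)
  stop_if_not(nlevels(y) == net$n_classes, "y has %d levels; network expects %d",
              nlevels(y), net$n_classes)
  net$levels <- levels(y)
  onehot <- diag(net$n_classes)[as.integer(y), , drop = FALSE]
  if (is.null(net$opt)) net$opt <- adam_init(net$params)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      fw <- cnn_forward(net, x[ix, , drop = FALSE])
      g <- cnn_backward(net, fw$cache, fw$probs, onehot[ix, , drop = FALSE])
      upd <- adam_step(net$params, g, net$opt, lr)
      net$params <- upd$params; net$opt <- upd$opt
    }
  }
  net
}

#' @rdname cnn_train
#' @export
cnn_predict_prob <- function(net, x) {
  cnn_forward(net, as.matrix(x))$probs
}

#' @rdname cnn_train
#' @export
cnn_predict <- function(net, x) {
  stop_if_not(!is.null(net$levels), "network has not been trained")
  probs <- cnn_predict_prob(net, x)
  factor(net$levels[max.col(probs, ties.method = "first")], levels = net$levels)
}
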