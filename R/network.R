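#' Training configuration for the Deep-and-Wide network
#'
#' Defaults follow common practice for this architecture: Adam with learning
#' rate 1e-3, 200 epochs, batch size 256, mean-squared-error loss on the
#' softmax output, elastic-net penalty on the fully-connected weights and a
#' max-norm (1.0) constraint on the fully-connected and output units.
#'
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (clipped to the training-set size).
#' @param l1,l2 elastic-net coefficients applied to the hidden
#'   fully-connected weights.
#' @param p_prime number of hidden units P'.
#' @param n_filters convolutional filters per branch (default 2).
#' @param finetune_epochs epochs used when fine-tuning transferred weights.
#' @param finetune_lr learning rate during fine-tuning; the default
#'   (`learning_rate * 0.3`) keeps the solution near the transferred
#'   initialization, as usual for fine-tuning.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 200,
                         batch_size = 256, l1 = 5e-4, l2 = 5e-4,
                         p_prime = 100, n_filters = 2,
                         finetune_epochs = 50, finetune_lr = NULL,
                         seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1, p_prime >= 1,
            l1 >= 0, l2 >= 0, n_filters >= 1)
  if (is.null(finetune_lr)) finetune_lr <- learning_rate * 0.3
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, l1 = l1, l2 = l2,
                 p_prime = p_prime, n_filters = n_filters,
                 finetune_epochs = finetune_epochs,
                 finetune_lr = finetune_lr, seed = seed),
            class = "train_config")
}

.bn_eps <- 1e-3
.bn_momentum <- 0.99

# 3x3 SAME-padding neighbourhood indices for an H x W image stored
# column-major; 0 marks a padded (zero) neighbour.
.nb_index <- function(H, W) {
  p <- seq_len(H * W)
  row <- (p - 1) %% H + 1
  col <- (p - 1) %/% H + 1
  nb <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- row + dr; c2 <- col + dc
    ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
    nb[ok, k] <- (c2[ok] - 1L) * H + r2[ok]
  }
  nb
}

# 2x2 stride-2 pooling groups: (H/2 * W/2) x 4 pixel indices.
.pool_index <- function(H, W) {
  Hp <- H %/% 2L; Wp <- W %/% 2L
  pi <- matrix(0L, Hp * Wp, 4L)
  q <- 0L
  for (cp in seq_len(Wp)) for (rp in seq_len(Hp)) {
    q <- q + 1L
    r <- 2L * rp - 1L; cc <- 2L * cp - 1L
    pi[q, ] <- c((cc - 1L) * H + r, (cc - 1L) * H + r + 1L,
                 cc * H + r, cc * H + r + 1L)
  }
  pi
}

# im2col over all trials of one branch: input HW x N matrix of images,
# output (HW * N) x 9 patch matrix (rows: pixel fastest, then trial).
.im2col <- function(imgs, nb) {
  HW <- nrow(imgs); N <- ncol(imgs)
  v <- as.vector(imgs)
  out <- matrix(0, HW * N, 9L)
  offs <- rep((seq_len(N) - 1L) * HW, each = HW)
  for (k in 1:9) {
    ok <- nb[, k] > 0L
    src <- rep(nb[ok, k], N) + rep((seq_len(N) - 1L) * HW, each = sum(ok))
    dst <- rep(which(ok), N) + rep((seq_len(N) - 1L) * HW, each = sum(ok))
    out[dst, k] <- v[src]
  }
  out
}

#' Build a Deep-and-Wide network
#'
#' One independent convolutional branch per topogram: 3x3 SAME convolution
#' (stride 1, `n_filters` filters, ReLU), per-channel batch normalization,
#' 2x2 max pooling to half resolution; branch outputs are concatenated and
#' flattened, batch-normalized, passed through one fully-connected ReLU
#' layer of `p_prime` units (elastic-net regularized, max-norm 1), batch
#' normalization, and a softmax output of width `n_classes` (max-norm 1).
#' Initialization is Glorot-uniform and fully determined by `seed`.
#'
#' @param Z number of topogram branches.
#' @param grid_wh `(W, H)` topogram size; both must be even (pooling).
#' @param n_classes output width Lambda (>= 2).
#' @param p_prime hidden units P'.
#' @param n_filters convolutional filters per branch.
#' @param seed RNG seed for initialization.
#' @return An object of class `dw_network`.
#' @export
build_network <- function(Z, grid_wh = c(40, 40), n_classes = 2,
                          p_prime = 100, n_filters = 2, seed = 1) {
  stopifnot(Z >= 1, n_classes >= 2)
  W <- grid_wh[1]; H <- grid_wh[2]
  if (W %% 2L != 0L || H %% 2L != 0L)
    stop("grid ", W, " x ", H, " is not divisible by the 2 x 2 pooling")
  G <- (H %/% 2L) * (W %/% 2L) * n_filters * Z
  set.seed(seed)
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  params <- list(
    conv_K = array(glorot(9 * n_filters * Z, 9, n_filters),
                   dim = c(9, n_filters, Z)),
    conv_b = matrix(0, n_filters, Z),
    bn3_gamma = matrix(1, n_filters, Z), bn3_beta = matrix(0, n_filters, Z),
    bn7_gamma = rep(1, G), bn7_beta = rep(0, G),
    A1 = matrix(glorot(G * p_prime, G, p_prime), G, p_prime),
    b1 = rep(0, p_prime),
    bn9_gamma = rep(1, p_prime), bn9_beta = rep(0, p_prime),
    A2 = matrix(glorot(p_prime * n_classes, p_prime, n_classes),
                p_prime, n_classes),
    b2 = rep(0, n_classes)
  )
  running <- list(
    bn3_mean = matrix(0, n_filters, Z), bn3_var = matrix(1, n_filters, Z),
    bn7_mean = rep(0, G), bn7_var = rep(1, G),
    bn9_mean = rep(0, p_prime), bn9_var = rep(1, p_prime)
  )
  structure(list(
    arch = list(Z = Z, W = W, H = H, n_classes = n_classes,
                p_prime = p_prime, n_filters = n_filters, G = G),
    params = params, running = running, history = NULL
  ), class = "dw_network")
}

#' @export
print.dw_network <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<dw_network> %d branches of %dx%d, %d filters; flatten %d -> FC %d -> %d classes\n",
    a$Z, a$W, a$H, a$n_filters, a$G, a$p_prime, a$n_classes))
  invisible(x)
}

# Precompute per-branch im2col matrices for a topogram stack.
.prep_inputs <- function(net, stack) {
  a <- net$arch
  d <- dim(stack$maps)
  if (d[3] != a$Z || d[1] != a$H || d[2] != a$W)
    stop("stack geometry (", d[1], "x", d[2], ", Z=", d[3],
         ") does not match the network (", a$H, "x", a$W, ", Z=", a$Z, ")")
  nb <- .nb_index(a$H, a$W)
  HW <- a$H * a$W
  N <- d[4]
  Xc <- vector("list", a$Z)
  for (z in seq_len(a$Z))
    Xc[[z]] <- .im2col(matrix(stack$maps[, , z, ], HW, N), nb)
  list(Xc = Xc, N = N)
}

# Forward pass. training=TRUE uses batch statistics and returns caches for
# backprop; training=FALSE uses running averages.
#
# Layout: branch activations live in one HW x (N * FZ) matrix V whose
# column j holds channel fz = (j-1) %% FZ + 1 of trial n = (j-1) %/% FZ + 1
# (channel fastest). With that ordering the flatten is a plain dim change
# (no aperm), and all later layers keep features on rows / trials on
# columns, so batch-norm reduces to R vector recycling.
# channel-wise scaling vector: length HW*FZ, recycled over trials by R's
# arithmetic recycling (columns are channel-fastest, so the period matches)
.chan_expand <- function(v, HW, N) rep(v, each = HW)

.dw_forward <- function(net, Xc, N, training = FALSE) {
  a <- net$arch; p <- net$params; r <- net$running
  HW <- a$H * a$W
  HWp <- HW %/% 4L
  Fz <- a$n_filters
  FZ <- Fz * a$Z
  pool_idx <- .pool_index(a$H, a$W)
  cache <- if (training) list() else NULL
  new_run <- if (training) r else NULL

  V <- matrix(0, HW, N * FZ)
  for (z in seq_len(a$Z)) {
    A <- Xc[[z]] %*% p$conv_K[, , z]                 # (HW * N) x F
    for (f in seq_len(Fz)) {
      V[, seq.int((z - 1L) * Fz + f, by = FZ, length.out = N)] <-
        A[, f] + p$conv_b[f, z]
    }
  }
  relu_mask <- V > 0
  V[!relu_mask] <- 0
  # batch norm per (branch, filter) channel over pixels x trials
  if (training) {
    mu <- rowMeans(matrix(colMeans(V), FZ, N))
    va <- rowMeans(matrix(colMeans(V^2), FZ, N)) - mu^2
    new_run$bn3_mean[] <- .bn_momentum * r$bn3_mean +
      (1 - .bn_momentum) * mu
    new_run$bn3_var[] <- .bn_momentum * r$bn3_var +
      (1 - .bn_momentum) * va
    cache$bn3_stats <- list(mu, va)
  } else {
    mu <- as.vector(r$bn3_mean); va <- as.vector(r$bn3_var)
  }
  inv_sd <- 1 / sqrt(va + .bn_eps)
  Xhat <- (V - .chan_expand(mu, HW, N)) * .chan_expand(inv_sd, HW, N)
  Vbn <- Xhat * .chan_expand(as.vector(p$bn3_gamma), HW, N) +
    .chan_expand(as.vector(p$bn3_beta), HW, N)

  v1 <- Vbn[pool_idx[, 1], , drop = FALSE]
  v2 <- Vbn[pool_idx[, 2], , drop = FALSE]
  v3 <- Vbn[pool_idx[, 3], , drop = FALSE]
  v4 <- Vbn[pool_idx[, 4], , drop = FALSE]
  mx <- pmax(v1, v2, v3, v4)
  if (training) {
    m1 <- v1 == mx
    m2 <- v2 == mx & !m1
    m3 <- v3 == mx & !m1 & !m2
    m4 <- !m1 & !m2 & !m3
  }
  # flatten: G x N (feature order: branch-major, filter, pixel fastest)
  Ut <- matrix(mx, a$G, N)

  # flatten batch norm (features on rows: plain vector recycling)
  if (training) {
    mu7 <- rowMeans(Ut); va7 <- rowMeans(Ut^2) - mu7^2
    new_run$bn7_mean <- .bn_momentum * r$bn7_mean + (1 - .bn_momentum) * mu7
    new_run$bn7_var <- .bn_momentum * r$bn7_var + (1 - .bn_momentum) * va7
    cache$bn7_stats <- list(mu7, va7)
  } else { mu7 <- r$bn7_mean; va7 <- r$bn7_var }
  inv7 <- 1 / sqrt(va7 + .bn_eps)
  X7 <- (Ut - mu7) * inv7
  U0bn <- X7 * p$bn7_gamma + p$bn7_beta

  # fully connected + ReLU (P' x N)
  Hpre <- crossprod(p$A1, U0bn) + p$b1
  relu1 <- Hpre > 0
  Hact <- Hpre; Hact[!relu1] <- 0

  if (training) {
    mu9 <- rowMeans(Hact); va9 <- rowMeans(Hact^2) - mu9^2
    new_run$bn9_mean <- .bn_momentum * r$bn9_mean + (1 - .bn_momentum) * mu9
    new_run$bn9_var <- .bn_momentum * r$bn9_var + (1 - .bn_momentum) * va9
    cache$bn9_stats <- list(mu9, va9)
  } else { mu9 <- r$bn9_mean; va9 <- r$bn9_var }
  inv9 <- 1 / sqrt(va9 + .bn_eps)
  X9 <- (Hact - mu9) * inv9
  Hbn <- X9 * p$bn9_gamma + p$bn9_beta

  logits <- crossprod(p$A2, Hbn) + p$b2               # Lambda x N
  lmx <- apply(logits, 2, max)
  el <- exp(logits - rep(lmx, each = a$n_classes))
  probs <- el * rep(1 / colSums(el), each = a$n_classes)

  if (training) {
    cache <- c(cache, list(relu_mask = relu_mask, Xhat = Xhat,
                           bn3_inv_sd = inv_sd,
                           pmasks = list(m1, m2, m3, m4),
                           X7 = X7, inv7 = inv7, U0bn = U0bn,
                           relu1 = relu1, X9 = X9,
                           inv9 = inv9, Hbn = Hbn, probs = probs))
    list(probs = t(probs), cache = cache, running = new_run, Ut = Ut)
  } else {
    list(probs = t(probs), Ut = Ut)
  }
}

# Batch-norm backward with features on rows (normalized over columns).
.bn_backward_rows <- function(dY, Xhat, inv_sd, gamma) {
  dgamma <- rowSums(dY * Xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * gamma
  dX <- (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat)) * inv_sd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Full backward pass; returns gradients shaped like net$params.
.dw_backward <- function(net, Xc, Y, fw, cfg) {
  a <- net$arch; p <- net$params
  cache <- fw$cache
  N <- nrow(Y)
  HW <- a$H * a$W; HWp <- HW %/% 4L
  Fz <- a$n_filters
  FZ <- Fz * a$Z
  pool_idx <- .pool_index(a$H, a$W)

  probs <- cache$probs                                # Lambda x N
  dP <- 2 * (probs - t(Y)) / (N * a$n_classes)        # MSE on softmax
  dLogit <- probs * (dP - rep(colSums(dP * probs), each = a$n_classes))

  g <- list()
  g$A2 <- tcrossprod(cache$Hbn, dLogit)               # P' x Lambda
  g$b2 <- rowSums(dLogit)
  dHbn <- p$A2 %*% dLogit                             # P' x N

  bn9 <- .bn_backward_rows(dHbn, cache$X9, cache$inv9, p$bn9_gamma)
  g$bn9_gamma <- bn9$dgamma; g$bn9_beta <- bn9$dbeta
  dHact <- bn9$dX
  dHact[!cache$relu1] <- 0

  g$A1 <- tcrossprod(cache$U0bn, dHact) +
    cfg$l1 * sign(p$A1) + 2 * cfg$l2 * p$A1
  g$b1 <- rowSums(dHact)
  dU0bn <- p$A1 %*% dHact                             # G x N

  bn7 <- .bn_backward_rows(dU0bn, cache$X7, cache$inv7, p$bn7_gamma)
  g$bn7_gamma <- bn7$dgamma; g$bn7_beta <- bn7$dbeta
  dUt <- bn7$dX

  # unflatten + unpool back to the HW x (N * FZ) activation matrix
  dPool <- matrix(dUt, HWp, N * FZ)
  pm <- cache$pmasks
  dVbn <- matrix(0, HW, N * FZ)
  dVbn[pool_idx[, 1], ] <- dPool * pm[[1]]
  dVbn[pool_idx[, 2], ] <- dPool * pm[[2]]
  dVbn[pool_idx[, 3], ] <- dPool * pm[[3]]
  dVbn[pool_idx[, 4], ] <- dPool * pm[[4]]

  # grouped batch-norm backward: each channel spans HW rows x N strided
  # columns
  Xhat <- cache$Xhat
  grp <- function(M) rowMeans(matrix(colMeans(M), FZ, N))
  dXhat <- dVbn * .chan_expand(as.vector(p$bn3_gamma), HW, N)
  g$bn3_gamma <- matrix(rowSums(matrix(colSums(dVbn * Xhat), FZ, N)),
                        Fz, a$Z)
  g$bn3_beta <- matrix(rowSums(matrix(colSums(dVbn), FZ, N)), Fz, a$Z)
  dV <- (dXhat - .chan_expand(grp(dXhat), HW, N) -
           Xhat * .chan_expand(grp(dXhat * Xhat), HW, N)) *
    .chan_expand(as.vector(cache$bn3_inv_sd), HW, N)
  dV[!cache$relu_mask] <- 0

  g$conv_K <- array(0, dim = dim(p$conv_K))
  g$conv_b <- matrix(0, Fz, a$Z)
  dA <- matrix(0, HW * N, Fz)
  for (z in seq_len(a$Z)) {
    for (f in seq_len(Fz))
      dA[, f] <- dV[, seq.int((z - 1L) * Fz + f, by = FZ,
                              length.out = N)]
    g$conv_K[, , z] <- crossprod(Xc[[z]], dA)
    g$conv_b[, z] <- colSums(dA)
  }
  g
}

# Project columns of FC / output weight matrices to max-norm <= 1.
.max_norm <- function(Wm, max_value = 1) {
  nrm <- sqrt(colSums(Wm^2))
  over <- nrm > max_value
  if (any(over))
    Wm[, over] <- sweep(Wm[, over, drop = FALSE], 2, nrm[over] / max_value,
                        "/")
  Wm
}

#' Predict class probabilities for a topogram stack
#'
#' Inference-mode forward pass (batch-norm running averages); deterministic
#' given the parameters and the inputs.
#'
#' @param net a trained [build_network()] object.
#' @param stack a `topogram_stack` with matching geometry and branch order.
#' @return List with `probabilities` (`N x Lambda`, rows on the simplex),
#'   `labels` (the stack's one-hot labels) and `accuracy`.
#' @export
predict_network <- function(net, stack) {
  N <- dim(stack$maps)[4]
  chunks <- split(seq_len(N), ceiling(seq_len(N) / 256))
  probs <- do.call(rbind, lapply(chunks, function(idx) {
    inp <- .prep_inputs(net, subset_stack(stack, idx))
    .dw_forward(net, inp$Xc, inp$N, training = FALSE)$probs
  }))
  list(probabilities = probs, labels = stack$labels,
       accuracy = evaluate_accuracy(probs, stack$labels))
}

#' Flatten-layer feature vectors of a topogram stack
#'
#' Runs the convolutional branches in inference mode and returns the
#' concatenated flattened feature map per trial (the network's `u0` vector,
#' before the flatten batch-norm) — the per-trial EEG representation used
#' for kernel matching across subjects.
#'
#' @param net a trained `dw_network`.
#' @param stack a `topogram_stack`.
#' @return `N x G` matrix.
#' @export
network_features <- function(net, stack) {
  N <- dim(stack$maps)[4]
  chunks <- split(seq_len(N), ceiling(seq_len(N) / 256))
  do.call(rbind, lapply(chunks, function(idx) {
    inp <- .prep_inputs(net, subset_stack(stack, idx))
    t(.dw_forward(net, inp$Xc, inp$N, training = FALSE)$Ut)
  }))
}

#' Classification accuracy of predicted probabilities
#'
#' Argmax decision rule; equals `(TP + TN) / (TP + TN + FP + FN)` for a
#' binary task.
#'
#' @param probabilities `N x Lambda` matrix (or a [predict_network()]
#'   result).
#' @param labels `N x Lambda` one-hot matrix (ignored when `probabilities`
#'   is a prediction list).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(probabilities, labels = NULL) {
  if (is.list(probabilities) && !is.null(probabilities$probabilities)) {
    labels <- probabilities$labels
    probabilities <- probabilities$probabilities
  }
  if (is.null(dim(probabilities)) || nrow(probabilities) == 0)
    stop("empty prediction set")
  mean(max.col(probabilities, ties.method = "first") ==
         max.col(labels, ties.method = "first"))
}

#' Train a Deep-and-Wide network
#'
#' Mini-batch Adam on the mean-squared error between the softmax output and
#' the one-hot labels, with an elastic-net penalty on the hidden
#' fully-connected weights and a max-norm projection of the fully-connected
#' and output unit weight vectors after every update. Fully seeded: the same
#' `cfg$seed` and data give a bit-identical loss history.
#'
#' @param stack a `topogram_stack` of training trials.
#' @param cfg a [train_config()].
#' @param init optional `dw_network` used as initialization (transfer);
#'   when supplied, the architecture must match the stack and
#'   `cfg$p_prime` is taken from it.
#' @param epochs overrides `cfg$epochs` when given.
#' @return A trained `dw_network`; `$history` holds per-epoch `loss` and
#'   `train_acc`.
#' @export
train_network <- function(stack, cfg = train_config(), init = NULL,
                          epochs = NULL) {
  Y <- stack$labels
  if (length(unique(max.col(Y))) < 2)
    stop("training set must contain at least two classes")
  Z <- dim(stack$maps)[3]
  grid_wh <- c(dim(stack$maps)[2], dim(stack$maps)[1])
  if (is.null(init)) {
    net <- build_network(Z, grid_wh, ncol(Y), cfg$p_prime, cfg$n_filters,
                         seed = cfg$seed)
  } else {
    net <- init
    a <- net$arch
    if (a$Z != Z || a$W != grid_wh[1] || a$H != grid_wh[2])
      stop("architecture mismatch between init network (Z=", a$Z, ", ",
           a$W, "x", a$H, ") and stack (Z=", Z, ", ", grid_wh[1], "x",
           grid_wh[2], ")")
    if (a$n_classes != ncol(Y))
      stop("architecture mismatch: init network has ", a$n_classes,
           " classes, labels have ", ncol(Y))
  }
  n_epochs <- if (is.null(epochs)) cfg$epochs else epochs
  if (n_epochs == 0) return(net)

  inp <- .prep_inputs(net, stack)
  N <- inp$N
  HW <- net$arch$H * net$arch$W
  bs <- min(cfg$batch_size, N)

  adam_m <- lapply(net$params, function(x) x * 0)
  adam_v <- lapply(net$params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  t_step <- 0L
  loss_hist <- numeric(n_epochs)
  acc_hist <- numeric(n_epochs)

  set.seed(cfg$seed + 1L)
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(N)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
    for (bt in batches) {
      rows <- as.vector(outer(seq_len(HW), (bt - 1L) * HW, "+"))
      Xb <- lapply(inp$Xc, function(m) m[rows, , drop = FALSE])
      Yb <- Y[bt, , drop = FALSE]
      fw <- .dw_forward(net, Xb, length(bt), training = TRUE)
      net$running <- fw$running
      loss <- mean((fw$probs - Yb)^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             "; try a smaller learning rate")
      ep_loss <- ep_loss + loss * length(bt)
      ep_n <- ep_n + length(bt)
      ep_correct <- ep_correct + sum(max.col(fw$probs) == max.col(Yb))
      g <- .dw_backward(net, Xb, Yb, fw, cfg)
      t_step <- t_step + 1L
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nm in names(g)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
        net$params[[nm]] <- net$params[[nm]] -
          cfg$learning_rate * corr * adam_m[[nm]] /
          (sqrt(adam_v[[nm]]) + eps)
      }
      net$params$A1 <- .max_norm(net$params$A1)
      net$params$A2 <- .max_norm(net$params$A2)
    }
    loss_hist[ep] <- ep_loss / ep_n
    acc_hist[ep] <- ep_correct / ep_n
  }
  # recalibrate batch-norm inference statistics on the full training set,
  # so inference does not depend on the running-average burn-in (and
  # fine-tuned networks do not keep the source subject's normalization)
  fw <- .dw_forward(net, inp$Xc, N, training = TRUE)
  st <- fw$cache
  net$running <- list(
    bn3_mean = matrix(st$bn3_stats[[1]], net$arch$n_filters, net$arch$Z),
    bn3_var = matrix(st$bn3_stats[[2]], net$arch$n_filters, net$arch$Z),
    bn7_mean = st$bn7_stats[[1]], bn7_var = st$bn7_stats[[2]],
    bn9_mean = st$bn9_stats[[1]], bn9_var = st$bn9_stats[[2]])
  net$history <- data.frame(epoch = seq_len(n_epochs), loss = loss_hist,
                            train_acc = acc_hist)
  net
}


#' Transfer pre-trained parameters to a target subject and fine-tune
#'
#' Initializes the target network from the source parameters (no layer
#' frozen) and fine-tunes on the target training trials for
#' `cfg$finetune_epochs` epochs. With zero fine-tuning epochs the result is
#' an exact parameter copy of the source.
#'
#' @param train_stack target training `topogram_stack`.
#' @param test_stack target held-out `topogram_stack`.
#' @param source_net pre-trained `dw_network` (from the source subject(s)).
#' @param cfg a [train_config()]; `p_prime` is dictated by the source.
#' @param baseline_accuracy the target's cold-start test accuracy on the
#'   identical split, used to report the gain (optional).
#' @return List with `net`, `accuracy` (fine-tuned test accuracy) and
#'   `gain` (`accuracy - baseline_accuracy`, `NA` if no baseline given).
#' @export
transfer_finetune <- function(train_stack, test_stack, source_net,
                              cfg = train_config(),
                              baseline_accuracy = NULL) {
  ft_cfg <- cfg
  if (!is.null(cfg$finetune_lr)) ft_cfg$learning_rate <- cfg$finetune_lr
  net <- train_network(train_stack, ft_cfg, init = source_net,
                       epochs = cfg$finetune_epochs)
  acc <- predict_network(net, test_stack)$accuracy
  list(net = net, accuracy = acc,
       gain = if (is.null(baseline_accuracy)) NA_real_
              else acc - baseline_accuracy)
}

#' Stratified cross-validation folds
#'
#' @param y integer class index per trial.
#' @param k number of folds.
#' @return Integer fold assignment (1..k) per trial; fold sizes differ by at
#'   most one and class ratios are preserved up to one trial.
#' @export
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  offset <- 0L
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Grid-search hyperparameter tuning by stratified K-fold cross-validation
#'
#' Evaluates every `(l1, l2, p_prime)` grid cell by stratified K-fold
#' cross-validation on the training trials and returns the configuration
#' maximizing mean validation accuracy. Ties prefer the smallest `p_prime`,
#' then the smallest `l1 + l2`.
#'
#' @param stack training `topogram_stack`.
#' @param cfg base [train_config()] (epochs, learning rate, seed).
#' @param l1_grid,l2_grid,p_grid candidate values.
#' @param k number of folds (default 10).
#' @return The winning `train_config`, with a `cv_table` attribute holding
#'   mean validation accuracy per grid cell.
#' @export
tune_hyperparameters <- function(stack, cfg = train_config(),
                                 l1_grid = c(5e-4, 1e-3, 5e-3),
                                 l2_grid = c(5e-4, 1e-3, 5e-3),
                                 p_grid = c(100, 200, 300), k = 10) {
  stopifnot(length(l1_grid) > 0, length(l2_grid) > 0, length(p_grid) > 0)
  y <- max.col(stack$labels)
  if (min(table(y)) < k)
    stop("too few trials of one class for ", k, "-fold stratification")
  set.seed(cfg$seed)
  folds <- stratified_folds(y, k)
  grid <- expand.grid(l1 = l1_grid, l2 = l2_grid, p_prime = p_grid)
  grid$val_acc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    cfg_gi <- cfg
    cfg_gi$l1 <- grid$l1[gi]; cfg_gi$l2 <- grid$l2[gi]
    cfg_gi$p_prime <- grid$p_prime[gi]
    accs <- vapply(seq_len(k), function(f) {
      tr <- which(folds != f); va <- which(folds == f)
      net <- train_network(subset_stack(stack, tr), cfg_gi)
      predict_network(net, subset_stack(stack, va))$accuracy
    }, numeric(1))
    grid$val_acc[gi] <- mean(accs)
  }
  ord <- order(-grid$val_acc, grid$p_prime, grid$l1 + grid$l2)
  best <- grid[ord[1], ]
  out <- cfg
  out$l1 <- best$l1; out$l2 <- best$l2; out$p_prime <- best$p_prime
  attr(out, "cv_table") <- grid
  out
}
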