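#' Median-heuristic kernel bandwidth
#'
#' The Gaussian length scale sigma is set to the median of the strictly
#' positive pairwise Euclidean distances between rows; zero distances
#' (replicated rows, e.g. per-trial copies of a subject's questionnaire) are
#' excluded so they cannot collapse the bandwidth.
#'
#' @param X numeric matrix (rows = observations).
#' @return Positive scalar sigma.
#' @export
median_bandwidth <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two rows")
  d <- as.vector(stats::dist(X))
  d <- d[d > 0]
  if (length(d) == 0) stop("all rows identical: no positive distances")
  stats::median(d)
}

#' Gaussian kernel matrix
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))`; symmetric with unit
#' diagonal and positive semi-definite.
#'
#' @param X numeric matrix (rows = observations).
#' @param sigma bandwidth; defaults to the median heuristic.
#' @param tag optional label describing the kernel's source space.
#' @return An object of class `kernel_matrix`: the `J x J` matrix with
#'   attributes `sigma` and `tag`.
#' @export
gaussian_kernel <- function(X, sigma = NULL, tag = "") {
  X <- as.matrix(X)
  if (is.null(sigma)) sigma <- median_bandwidth(X)
  if (sigma <= 0) stop("sigma must be > 0")
  D2 <- as.matrix(stats::dist(X))^2
  K <- exp(-D2 / (2 * sigma^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- NULL
  kernel_matrix(K, sigma = sigma, tag = tag)
}

#' Construct a kernel-matrix object
#' @param K symmetric numeric matrix.
#' @param sigma bandwidth used (or `NA`).
#' @param tag source-space label.
#' @return `K` with class `kernel_matrix` and attributes `sigma`, `tag`.
#' @export
kernel_matrix <- function(K, sigma = NA_real_, tag = "") {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  if (max(abs(K - t(K))) > 1e-8) stop("kernel matrix must be symmetric")
  structure(K, sigma = sigma, tag = tag, class = c("kernel_matrix", "matrix"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d, sigma = %s, tag = \"%s\"\n",
              nrow(x), ncol(x), format(attr(x, "sigma")), attr(x, "tag")))
  invisible(x)
}

# strip class/attrs for plain matrix algebra
.km <- function(K) {
  K <- unclass(K)
  attr(K, "sigma") <- NULL; attr(K, "tag") <- NULL
  K
}

#' Centered kernel alignment between two kernel matrices
#'
#' `CKA(K1, K2) = <HK1H, HK2H>_F / (||HK1H||_F ||HK2H||_F)` with the
#' centering matrix `H = I - J^-1 11'`. Lies in `[0, 1]` for positive
#' semi-definite inputs, is invariant to positive scaling of either kernel,
#' and equivariant under a permutation applied to both.
#'
#' @param K1,K2 square matrices of equal size (`kernel_matrix` or plain).
#' @return Scalar alignment.
#' @export
cka <- function(K1, K2) {
  K1 <- .km(K1); K2 <- .km(K2)
  J <- nrow(K1)
  if (J < 2 || any(dim(K2) != J)) stop("kernels must be equal-sized, J >= 2")
  C1 <- sweep(K1, 1, rowMeans(K1)); C1 <- sweep(C1, 2, colMeans(C1))
  C2 <- sweep(K2, 1, rowMeans(K2)); C2 <- sweep(C2, 2, colMeans(C2))
  n1 <- sqrt(sum(C1^2)); n2 <- sqrt(sum(C2^2))
  if (n1 == 0 || n2 == 0) stop("centered kernel has zero norm")
  sum(C1 * C2) / (n1 * n2)
}

#' Learn a CKA-maximizing projection of EEG features
#'
#' Finds `Upsilon` (`G x G'`) maximizing the centered kernel alignment
#' between the Gaussian kernel of the projected features `U Upsilon` and the
#' kernel `kV` of the predicted label probabilities. Initialization is the
#' top-`G'` principal directions of `U`; optimization is gradient ascent
#' with backtracking line search (so the objective trace is non-decreasing
#' up to numerical slack). The projected kernel's bandwidth is re-estimated
#' by the median heuristic at every iteration and held fixed inside each
#' gradient evaluation.
#'
#' @param U `J x G` feature matrix (flattened topogram activations pooled
#'   over subjects).
#' @param V `J x Lambda` predicted label probabilities (or a precomputed
#'   `kernel_matrix` via `kV`).
#' @param g_prime projected width `G' < G` (default 50).
#' @param max_iter maximum ascent iterations.
#' @param tol stop when the objective improves by less than `tol`.
#' @param step initial ascent step size.
#' @param kV optional precomputed label-probability kernel.
#' @return List of class `cka_projection`: `upsilon` (`G x G'`),
#'   `U_hat = U %*% upsilon`, `trace` (objective per iteration, element 1 =
#'   initial value), `sigma` (final projected-kernel bandwidth).
#' @export
learn_projection <- function(U, V = NULL, g_prime = 50, max_iter = 30,
                             tol = 1e-5, step = NULL, kV = NULL) {
  U <- as.matrix(U)
  J <- nrow(U); G <- ncol(U)
  if (g_prime >= G) stop("g_prime must be smaller than the feature width")
  if (is.null(kV)) kV <- gaussian_kernel(as.matrix(V), tag = "kV")
  KV <- .km(kV)
  C2 <- sweep(KV, 1, rowMeans(KV)); C2 <- sweep(C2, 2, colMeans(C2))
  n2 <- sqrt(sum(C2^2))
  if (n2 == 0) stop("label-probability kernel centers to zero")

  Uc <- sweep(U, 2, colMeans(U))
  sv <- svd(Uc, nu = 0, nv = g_prime)
  Ups <- sv$v[, seq_len(g_prime), drop = FALSE]

  objective <- function(Ups) {
    Uh <- U %*% Ups
    sig <- median_bandwidth(Uh)
    D2 <- as.matrix(stats::dist(Uh))^2
    K1 <- exp(-D2 / (2 * sig^2))
    C1 <- sweep(K1, 1, rowMeans(K1)); C1 <- sweep(C1, 2, colMeans(C1))
    n1 <- sqrt(sum(C1^2))
    list(value = sum(C1 * C2) / (n1 * n2), K1 = K1, C1 = C1, n1 = n1,
         sigma = sig, Uh = Uh)
  }
  gradient <- function(ob) {
    # dF/dK1 = C2/(n1 n2) - F * C1 / n1^2   (using tr(K1 H K2 H) identities)
    Fv <- ob$value
    dFdK <- C2 / (ob$n1 * n2) - Fv * ob$C1 / ob$n1^2
    M <- dFdK * ob$K1 / ob$sigma^2
    L <- diag(rowSums(M)) - M
    -2 * crossprod(U, L %*% ob$Uh)   # G x G'
  }

  ob <- objective(Ups)
  trace <- ob$value
  if (is.null(step)) step <- 0.1
  for (it in seq_len(max_iter)) {
    gr <- gradient(ob)
    if (!all(is.finite(gr)))
      stop("non-finite CKA gradient at iteration ", it)
    gn <- sqrt(sum(gr^2))
    if (gn < 1e-12) break
    st <- step
    improved <- FALSE
    for (ls in 1:12) {
      cand <- Ups + st * gr / gn
      obc <- objective(cand)
      if (is.finite(obc$value) && obc$value > ob$value) {
        improved <- TRUE
        break
      }
      st <- st / 2
    }
    if (!improved) break
    gain <- obc$value - ob$value
    Ups <- cand; ob <- obc
    trace <- c(trace, ob$value)
    step <- min(st * 2, 1)
    if (gain < tol) break
  }
  structure(list(upsilon = Ups, U_hat = ob$Uh, trace = trace,
                 sigma = ob$sigma),
            class = "cka_projection")
}

#' Tensor-product (Hadamard) fusion of two kernels
#'
#' The entrywise product of two kernels is the kernel of the tensor-product
#' feature space; by the Schur product theorem it preserves positive
#' semi-definiteness.
#'
#' @param K1,K2 `J x J` kernels with aligned row ordering.
#' @return A `kernel_matrix` tagged `"fused"`.
#' @export
fuse_kernels <- function(K1, K2) {
  A <- .km(K1); B <- .km(K2)
  if (!all(dim(A) == dim(B)))
    stop("kernels must have equal size and aligned ordering")
  kernel_matrix(A * B, sigma = NA_real_, tag = "fused")
}

#' Kernel principal component reduction and re-embedding
#'
#' Double-centers the kernel, keeps the top `n_components` eigenpairs with
#' eigenvalues above `1e-12` (truncating with a warning if fewer are
#' positive), and projects onto eigenvectors scaled by `1 / sqrt(lambda)`,
#' giving scores whose Gram matrix reproduces the centered kernel when the
#' full positive spectrum is kept. The scores are then re-embedded with a
#' median-heuristic Gaussian kernel.
#'
#' @param K a `J x J` kernel.
#' @param n_components number of components, `1 <= n < J`.
#' @return List of class `kpca_reduction`: `scores` (`J x n`), `eigenvalues`
#'   (non-increasing), `kernel` (the re-embedded `kernel_matrix`).
#' @export
kpca_reduce <- function(K, n_components) {
  K <- .km(K)
  J <- nrow(K)
  if (n_components < 1 || n_components >= J)
    stop("n_components must lie in [1, J - 1]")
  C <- sweep(K, 1, rowMeans(K)); C <- sweep(C, 2, colMeans(C))
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  pos <- which(e$values > 1e-12)
  if (length(pos) < n_components) {
    warning("only ", length(pos), " components above the numerical floor; ",
            "truncating from ", n_components)
    n_components <- length(pos)
  }
  lam <- e$values[seq_len(n_components)]
  vec <- e$vectors[, seq_len(n_components), drop = FALSE]
  scores <- C %*% sweep(vec, 2, sqrt(lam), "/")   # = vec %*% diag(sqrt(lam))
  kk <- gaussian_kernel(scores, tag = "kpca")
  structure(list(scores = scores, eigenvalues = lam, kernel = kk),
            class = "kpca_reduction")
}

#' Questionnaire kernel over pooled trials
#'
#' Encodes each subject's ordinal item scores as numbers, z-scores every
#' item across subjects (items with zero variance are dropped with a
#' warning), replicates each subject's encoded row once per trial, and
#' embeds the rows with a Gaussian kernel. Trials of the same subject have
#' pairwise similarity exactly 1.
#'
#' @param scores `M x NQ` data frame or matrix of item scores (one row per
#'   subject; a `subject_id` column is used for matching when present).
#' @param row_subject length-`J` vector of subject ids, one per pooled
#'   trial, defining the replication and row order.
#' @param sigma bandwidth; defaults to the median heuristic over the
#'   replicated rows (zero distances excluded).
#' @return A `kernel_matrix` tagged `"kS"` with attribute `items` (the
#'   retained item names).
#' @export
questionnaire_kernel <- function(scores, row_subject, sigma = NULL) {
  scores <- as.data.frame(scores)
  if ("subject_id" %in% names(scores)) {
    rownames(scores) <- as.character(scores$subject_id)
    scores$subject_id <- NULL
  }
  S <- as.matrix(scores)
  storage.mode(S) <- "double"
  sds <- apply(S, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping constant questionnaire item(s): ",
            paste(colnames(S)[drop], collapse = ", "))
    S <- S[, !drop, drop = FALSE]
  }
  if (ncol(S) == 0) stop("no informative questionnaire items left")
  S <- scale(S)
  row_subject <- as.character(row_subject)
  if (!all(row_subject %in% rownames(S)))
    stop("row_subject contains ids missing from the questionnaire: ",
         paste(setdiff(row_subject, rownames(S)), collapse = ", "))
  R <- S[row_subject, , drop = FALSE]
  k <- gaussian_kernel(R, sigma = sigma, tag = "kS")
  attr(k, "items") <- colnames(S)
  k
}
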