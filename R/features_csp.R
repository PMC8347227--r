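#' Fit common spatial patterns for one (band, segment) configuration
#'
#' CSP finds spatial filters `w` maximizing the ratio of class-1 to composite
#' variance: the generalized eigenproblem `Sigma1 w = lambda (Sigma1 +
#' Sigma2) w`. It is solved by whitening the composite covariance and
#' eigendecomposing the whitened class-1 covariance; eigenvalues are the
#' class-1 variance fractions in `[0, 1]`. Components are picked from both
#' spectrum extremes, alternating largest / smallest, up to `n_components`.
#'
#' Covariances are averaged over trials after per-segment trace
#' normalization, and regularized by shrinkage toward the identity scaled by
#' the average variance: `(1 - s) * Sigma + s * mean(diag(Sigma)) * I`.
#'
#' @param segments list over trials of `C x L` segment matrices (one segment
#'   per trial, all for the same band/segment slot).
#' @param labels integer class index per trial (values 1 and 2).
#' @param n_components number of CSP components to retain (default `3 *
#'   n_classes`, the usual choice for two-class motor imagery).
#' @param shrinkage covariance shrinkage coefficient in `[0, 1]`
#'   (default 0.1).
#' @return An object of class `csp_model`: `filters`
#'   (`n_components x C`, rows are extractors), `patterns`
#'   (`C x n_components` scalp patterns), `eigenvalues` (class-1 variance
#'   fractions of the selected components), `all_eigenvalues` (full spectrum,
#'   descending), `selection` (indices into the descending spectrum).
#' @export
fit_csp <- function(segments, labels, n_components = 6, shrinkage = 0.1) {
  labels <- as.integer(labels)
  if (!all(sort(unique(labels)) == c(1L, 2L)))
    stop("CSP requires both classes (labels 1 and 2) present")
  C <- nrow(segments[[1]])
  if (n_components > C) stop("n_components exceeds channel count")
  stopifnot(shrinkage >= 0, shrinkage <= 1)

  class_cov <- function(idx) {
    S <- matrix(0, C, C)
    for (i in idx) {
      seg <- segments[[i]]
      seg <- seg - rowMeans(seg)
      Si <- tcrossprod(seg) / ncol(seg)
      tr <- sum(diag(Si))
      if (tr > 0) S <- S + Si / tr
    }
    S <- S / length(idx)
    (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(C)
  }
  S1 <- class_cov(which(labels == 1L))
  S2 <- class_cov(which(labels == 2L))
  m <- csp_from_covariances(S1, S2, n_components)
  m$shrinkage <- shrinkage
  m
}

#' CSP from precomputed class covariance matrices
#'
#' Core solver behind [fit_csp()]: whitening of the composite covariance
#' `Sigma1 + Sigma2` followed by an eigendecomposition of the whitened
#' class-1 covariance.
#'
#' @param S1,S2 symmetric positive-definite class covariance matrices.
#' @param n_components components to keep, alternating spectrum extremes.
#' @return A `csp_model`; see [fit_csp()].
#' @export
csp_from_covariances <- function(S1, S2, n_components = 6) {
  C <- nrow(S1)
  stopifnot(ncol(S1) == C, all(dim(S2) == C), n_components <= C)
  Sc <- S1 + S2
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) < max(ec$values) * C * .Machine$double.eps)
    stop("composite covariance is singular; use shrinkage > 0")
  P <- diag(1 / sqrt(ec$values), C) %*% t(ec$vectors)  # whitener
  ew <- eigen(P %*% S1 %*% t(P), symmetric = TRUE)     # values descending
  W_full <- t(ew$vectors) %*% P                        # rows = filters
  A_full <- solve(W_full)                              # columns = patterns

  sel <- integer(n_components)
  lo <- 1L; hi <- C
  for (k in seq_len(n_components)) {
    if (k %% 2L == 1L) { sel[k] <- lo; lo <- lo + 1L }
    else { sel[k] <- hi; hi <- hi - 1L }
  }
  structure(list(
    filters = W_full[sel, , drop = FALSE],
    patterns = A_full[, sel, drop = FALSE],
    eigenvalues = ew$values[sel],
    all_eigenvalues = ew$values,
    selection = sel
  ), class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d components over %d channels; eigenvalues: %s\n",
              nrow(x$filters), ncol(x$filters),
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Back-project CSP component energies to a per-channel feature vector
#'
#' Component log-variances `f_k = log var(w_k' X)` are min-max normalized
#' over components and mapped back to channel space through the magnitude of
#' the scalp patterns: `x_c = sum_k |A[c, k]| * f_k_normalized`. When all
#' component log-variances coincide the normalized features are set to 0.5.
#'
#' @param segment `C x L` matrix.
#' @param model a fitted `csp_model`.
#' @return Nonnegative numeric vector of length `C`.
#' @export
csp_channel_features <- function(segment, model) {
  stopifnot(inherits(model, "csp_model"))
  if (ncol(model$filters) != nrow(segment))
    stop("segment channel count does not match the fitted model")
  src <- model$filters %*% (segment - rowMeans(segment))
  v <- rowSums((src - rowMeans(src))^2) / (ncol(src) - 1)
  v <- pmax(v, .Machine$double.eps)
  f <- log(v)
  rng <- max(f) - min(f)
  fn <- if (rng < .Machine$double.eps) rep(0.5, length(f))
        else (f - min(f)) / rng
  as.vector(abs(model$patterns) %*% fn)
}
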