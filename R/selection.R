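#' Subject-averaged kernel profiles
#'
#' Reshapes a pooled `J x J` kernel to `M x J`: each subject's profile is
#' the mean of that subject's trial rows.
#'
#' @param K `J x J` kernel over pooled trials.
#' @param row_subject length-`J` subject id per trial row.
#' @param subjects optional subject ordering (default: unique order of
#'   appearance).
#' @return `M x J` matrix with subject ids as row names.
#' @export
subject_profiles <- function(K, row_subject, subjects = NULL) {
  K <- .km(K)
  row_subject <- as.character(row_subject)
  if (length(row_subject) != nrow(K))
    stop("row_subject length does not match the kernel")
  if (is.null(subjects)) subjects <- unique(row_subject)
  if (!all(subjects %in% row_subject))
    stop("unknown subject id(s): ",
         paste(setdiff(subjects, row_subject), collapse = ", "))
  prof <- t(vapply(subjects, function(s)
    colMeans(K[row_subject == s, , drop = FALSE]), numeric(ncol(K))))
  rownames(prof) <- subjects
  prof
}

#' Cluster subjects into three BCI-skill groups
#'
#' Groups subjects by baseline classifier accuracy into Group I (best), II
#' and III (worst) with 1-D k-means (`k = 3`), deterministically initialized
#' at the minimum, median and maximum of the accuracies, which yields groups
#' contiguous in accuracy. Manual thresholds can be supplied instead.
#'
#' @param accuracies named numeric vector of per-subject accuracies in
#'   `[0, 1]` (names = subject ids).
#' @param thresholds optional pair `(t1, t2)` with `t1 > t2`: Group I is
#'   `accuracy >= t1`, Group III is `accuracy < t2`.
#' @return Factor of labels `"I"`, `"II"`, `"III"` named by subject.
#' @export
cluster_subjects <- function(accuracies, thresholds = NULL) {
  M <- length(accuracies)
  if (M < 3) stop("need at least 3 subjects")
  if (is.null(names(accuracies)))
    names(accuracies) <- sprintf("s%02d", seq_len(M))
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2, thresholds[1] > thresholds[2])
    lab <- ifelse(accuracies >= thresholds[1], "I",
                  ifelse(accuracies >= thresholds[2], "II", "III"))
    return(factor(stats::setNames(lab, names(accuracies)),
                  levels = c("I", "II", "III")))
  }
  if (diff(range(accuracies)) == 0)
    stop("all accuracies identical; supply manual thresholds")
  if (M == 3) {
    lab <- c("I", "II", "III")[rank(-accuracies, ties.method = "first")]
    return(factor(stats::setNames(lab, names(accuracies)),
                  levels = c("I", "II", "III")))
  }
  centers <- matrix(c(max(accuracies), stats::median(accuracies),
                      min(accuracies)))
  if (any(duplicated(centers)))
    centers <- matrix(seq(max(accuracies), min(accuracies),
                          length.out = 3))
  km <- stats::kmeans(matrix(accuracies), centers = centers)
  # relabel clusters so group means are decreasing I > II > III
  ord <- order(-km$centers[, 1])
  lab <- c("I", "II", "III")[match(km$cluster, ord)]
  factor(stats::setNames(lab, names(accuracies)),
         levels = c("I", "II", "III"))
}

#' Squared-Euclidean distance matrix between subject profiles
#'
#' @param profiles `M x J` subject profile matrix.
#' @return Symmetric `M x M` matrix with zero diagonal:
#'   `D[m, m'] = sum_j (profile[m, j] - profile[m', j])^2`.
#' @export
distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  D <- as.matrix(stats::dist(profiles))^2
  dimnames(D) <- list(rownames(profiles), rownames(profiles))
  D
}

#' Neighboring similarity matrix
#'
#' Entry `(m, m')` is the sample covariance (normalizer `1 / (M - 1)`)
#' between rows `m` and `m'` of the distance matrix, with both rows ordered
#' by one shared permutation — the subjects ranked by decreasing baseline
#' accuracy. Because the covariance pairs values column-wise, any shared
#' permutation gives the same result; the accuracy ranking fixes the
#' convention.
#'
#' @param D symmetric `M x M` distance matrix.
#' @param accuracies per-subject accuracies defining the ranking (same
#'   order as the rows of `D`); optional.
#' @return Symmetric `M x M` covariance matrix.
#' @export
neighboring_similarity <- function(D, accuracies = NULL) {
  D <- as.matrix(D)
  M <- nrow(D)
  if (M < 2) stop("need at least 2 subjects")
  ord <- if (is.null(accuracies)) seq_len(M) else order(-accuracies)
  Dr <- D[, ord, drop = FALSE]
  S <- stats::cov(t(Dr))
  dimnames(S) <- dimnames(D)
  S
}

#' Marginal domain distance per subject
#'
#' Averages the absolute neighboring similarity of each subject over the
#' whole subject set (self term included): `delta[m] = mean_m' |S[m, m']|`.
#'
#' @param S `M x M` neighboring similarity matrix.
#' @param include_self keep the diagonal term in the average
#'   (default `TRUE`).
#' @return Nonnegative numeric vector of length `M`.
#' @export
marginal_distance <- function(S, include_self = TRUE) {
  S <- as.matrix(S)
  A <- abs(S)
  if (include_self) rowMeans(A)
  else (rowSums(A) - diag(A)) / (ncol(A) - 1)
}

#' Select source subjects for transfer
#'
#' Sources come from Group I (best performers), targets from Group III.
#' Strategies: `"single"` picks the Group-I subject with the highest
#' marginal domain distance; `"multi"` the `n_sources` highest (ties broken
#' by the lower subject id); `"all"` uses the whole of Group I.
#'
#' @param delta named marginal distance vector (names = subject ids).
#' @param groups factor of group labels from [cluster_subjects()].
#' @param strategy `"single"`, `"multi"` or `"all"`.
#' @param n_sources number of sources for `"multi"` (default 4; truncated
#'   to the Group-I size when the cohort is small).
#' @return List of class `transfer_plan`: `strategy`, `sources`, `targets`.
#' @export
select_sources <- function(delta, groups, strategy = c("single", "multi",
                                                       "all"),
                           n_sources = 4) {
  strategy <- match.arg(strategy)
  ids <- names(delta)
  if (is.null(ids)) ids <- names(groups)
  if (is.null(ids)) stop("delta must be named by subject id")
  g1 <- ids[groups[ids] == "I"]
  g3 <- ids[groups[ids] == "III"]
  if (length(g1) == 0) stop("Group I is empty; no source candidates")
  d1 <- delta[g1]
  # order: decreasing delta, ties by lexicographically lower subject id
  ord <- g1[order(-d1, g1)]
  sources <- switch(strategy,
    single = ord[1],
    multi = ord[seq_len(min(n_sources, length(ord)))],
    all = ord)
  structure(list(strategy = strategy, sources = sources, targets = g3,
                 delta = delta),
            class = "transfer_plan")
}

#' @export
print.transfer_plan <- function(x, ...) {
  cat(sprintf("<transfer_plan> %s: sources {%s} -> targets {%s}\n",
              x$strategy, paste(x$sources, collapse = ", "),
              paste(x$targets, collapse = ", ")))
  invisible(x)
}
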