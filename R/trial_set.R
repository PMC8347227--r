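#' Labeled EEG trials for one subject
#'
#' A `trial_set` bundles all trials of one subject: a `C x T x N` numeric
#' array of EEG (channels x samples x trials), an `N x Lambda` one-hot label
#' matrix, the sampling rate, and the electrode montage (channel names plus
#' unit-sphere 3D coordinates).
#'
#' @param X numeric array `C x T x N` (channels x time samples x trials), or a
#'   list of `C x T` matrices sharing dimensions.
#' @param labels integer class indices (1-based, length `N`) or an
#'   `N x Lambda` one-hot matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `C`.
#' @param channel_xyz numeric `C x 3` matrix of unit-sphere electrode
#'   coordinates (x = right, y = anterior/nose, z = up).
#' @param subject_id identifier for the subject.
#' @param n_classes number of classes `Lambda`; inferred from `labels` when
#'   omitted.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(X, labels, fs, channel_names, channel_xyz,
                      subject_id = "s01", n_classes = NULL) {
  if (is.list(X)) {
    dims <- vapply(X, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all trials must share channel and sample counts")
    X <- array(unlist(X), dim = c(dims[1, 1], dims[2, 1], length(X)))
  }
  stopifnot(is.array(X), length(dim(X)) == 3L)
  if (!all(is.finite(X))) stop("non-finite samples in EEG data")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  N <- dim(X)[3]
  if (is.matrix(labels)) {
    onehot <- labels
  } else {
    labels <- as.integer(labels)
    L <- if (is.null(n_classes)) max(labels) else n_classes
    onehot <- matrix(0, N, L)
    onehot[cbind(seq_len(N), labels)] <- 1
  }
  if (nrow(onehot) != N) stop("labels length does not match trial count")
  if (ncol(onehot) < 2L) stop("at least two classes required")
  if (any(rowSums(onehot == 1) != 1L) || any(onehot != 0 & onehot != 1))
    stop("each label must be one-hot")
  channel_xyz <- as.matrix(channel_xyz)
  if (length(channel_names) != dim(X)[1] || nrow(channel_xyz) != dim(X)[1])
    stop("montage size does not match channel count")
  structure(list(
    X = X, labels = onehot, fs = as.numeric(fs),
    channel_names = as.character(channel_names),
    channel_xyz = unname(channel_xyz),
    subject_id = as.character(subject_id)
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf(
    "<trial_set> subject %s: %d trials, %d channels x %d samples @ %g Hz, %d classes\n",
    x$subject_id, d[3], d[1], d[2], x$fs, ncol(x$labels)))
  invisible(x)
}

#' Number of trials, channels, samples and classes of a trial set
#' @param ts a `trial_set`.
#' @return Named integer vector with elements `n_trials`, `n_channels`,
#'   `n_samples`, `n_classes`.
#' @export
trial_dims <- function(ts) {
  d <- dim(ts$X)
  c(n_trials = d[3], n_channels = d[1], n_samples = d[2],
    n_classes = ncol(ts$labels))
}

#' Class index vector (1-based) of a trial set
#' @param ts a `trial_set`.
#' @return Integer vector of length `N`.
#' @export
class_index <- function(ts) max.col(ts$labels, ties.method = "first")

#' Subset the trials of a trial set
#' @param ts a `trial_set`.
#' @param idx trial indices to keep.
#' @return A `trial_set` with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$X[, , idx, drop = FALSE], ts$labels[idx, , drop = FALSE],
            ts$fs, ts$channel_names, ts$channel_xyz, ts$subject_id)
}

# Idealized 10-20 positions on the unit sphere. theta = inclination from the
# vertex Cz; azim = azimuth from the nose, positive toward the right ear.
.montage1020 <- rbind(
  Fp1 = c(72, -18), Fp2 = c(72, 18),
  F7 = c(72, -54), F3 = c(46, -45), Fz = c(46, 0), F4 = c(46, 45),
  F8 = c(72, 54),
  T7 = c(72, -90), C3 = c(46, -90), Cz = c(0, 0), C4 = c(46, 90),
  T8 = c(72, 90),
  P7 = c(72, -126), P3 = c(46, -135), Pz = c(46, 180), P4 = c(46, 135),
  P8 = c(72, 126),
  O1 = c(72, -162), Oz = c(72, 180), O2 = c(72, 162)
)

#' Standard scalp montage
#'
#' Returns `n` electrode positions from a 10-20-style layout on the unit
#' sphere. Convention: x points to the right ear, y to the nose, z up.
#'
#' @param n number of channels (4 to 20).
#' @return List with `names` (character) and `xyz` (`n x 3` matrix).
#' @export
standard_montage <- function(n = 16) {
  full <- .montage1020
  if (n < 4 || n > nrow(full)) stop("montage supports 4..", nrow(full),
                                    " channels")
  # keep a spatially spread subset: drop midline extras first
  order_pref <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4", "Cz",
                  "T7", "T8", "P3", "P4", "Pz", "O1", "O2", "Fz", "P7",
                  "P8", "Oz")
  keep <- order_pref[seq_len(n)]
  ang <- full[keep, , drop = FALSE] * pi / 180
  theta <- ang[, 1]; azim <- ang[, 2]
  xyz <- cbind(x = sin(theta) * sin(azim),
               y = sin(theta) * cos(azim),
               z = cos(theta))
  list(names = keep, xyz = unname(round(xyz, 10)))
}

#' Read a montage file
#'
#' Tab-separated text, one channel per line: `name<TAB>x<TAB>y<TAB>z`.
#'
#' @param path file path.
#' @return List with `names` and `xyz` as in [standard_montage()].
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  list(names = as.character(tab$name),
       xyz = unname(as.matrix(tab[, c("x", "y", "z")])))
}

#' Write a montage file
#' @param montage list with `names` and `xyz`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(name = montage$names, montage$xyz)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
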