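#' Write a trial set to an HDF5 container
#'
#' Layout: `/X` (`N x C x T` float64), `/y` (`N` int class indices),
#' `/fs` scalar, `/channels` string array, `/xyz` (`C x 3`),
#' `/subject_id` string. Round-trips bit-exactly.
#'
#' @param ts a [trial_set()].
#' @param path output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_trial_h5 <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  d <- dim(ts$X)
  X <- aperm(ts$X, c(3, 1, 2))           # N x C x T
  rhdf5::h5write(X, path, "X")
  rhdf5::h5write(as.integer(class_index(ts)), path, "y")
  rhdf5::h5write(ts$fs, path, "fs")
  rhdf5::h5write(ts$channel_names, path, "channels")
  rhdf5::h5write(ts$channel_xyz, path, "xyz")
  rhdf5::h5write(ts$subject_id, path, "subject_id")
  rhdf5::h5write(ncol(ts$labels), path, "n_classes")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a trial set from an HDF5 container
#'
#' @param path `.h5` file written by [write_trial_h5()] (or following the
#'   same schema).
#' @return A [trial_set()].
#' @export
read_trial_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path)$name
  for (req in c("X", "y", "fs", "channels"))
    if (!req %in% have)
      stop("container ", path, " is missing dataset /", req)
  X <- rhdf5::h5read(path, "X")
  y <- as.integer(rhdf5::h5read(path, "y"))
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  channels <- as.character(rhdf5::h5read(path, "channels"))
  xyz <- if ("xyz" %in% have) rhdf5::h5read(path, "xyz")
         else standard_montage(length(channels))$xyz
  sid <- if ("subject_id" %in% have)
    as.character(rhdf5::h5read(path, "subject_id")) else "s01"
  ncl <- if ("n_classes" %in% have)
    as.integer(rhdf5::h5read(path, "n_classes")) else max(y)
  rhdf5::h5closeAll()
  trial_set(aperm(X, c(2, 3, 1)), y, fs, channels, xyz, sid,
            n_classes = ncl)
}

#' Write a cohort as per-subject HDF5 containers
#' @param cohort list of [trial_set()] objects.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(ts) {
    p <- file.path(dir, paste0(ts$subject_id, ".h5"))
    write_trial_h5(ts, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a cohort from a directory of HDF5 containers (or one file)
#'
#' Validates that channel count and order agree across subjects.
#'
#' @param path directory containing `*.h5` files, or a single file.
#' @return List of [trial_set()] objects sorted by subject id.
#' @export
read_cohort <- function(path) {
  files <- if (dir.exists(path))
    sort(list.files(path, pattern = "\\.h5$", full.names = TRUE))
  else path
  if (length(files) == 0) stop("no .h5 containers under ", path)
  cohort <- lapply(files, read_trial_h5)
  ref <- cohort[[1]]$channel_names
  for (ts in cohort)
    if (!identical(ts$channel_names, ref))
      stop("subject ", ts$subject_id,
           " has a different channel set/order than ",
           cohort[[1]]$subject_id)
  cohort[order(vapply(cohort, `[[`, character(1), "subject_id"))]
}

#' Save a Deep-and-Wide network checkpoint
#'
#' HDF5 with one group per parameter tensor (datasets `weights`; running
#' batch-norm statistics under `/running`), plus the architecture
#' descriptor as a JSON string. Round-trips bit-exactly.
#'
#' @param net a `dw_network`.
#' @param path output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "dw_network"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "params")
  rhdf5::h5createGroup(path, "running")
  for (nm in names(net$params))
    rhdf5::h5write(net$params[[nm]], path, paste0("params/", nm))
  for (nm in names(net$running))
    rhdf5::h5write(net$running[[nm]], path, paste0("running/", nm))
  rhdf5::h5write(as.character(jsonlite::toJSON(net$arch,
                                               auto_unbox = TRUE)),
                 path, "architecture")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a Deep-and-Wide network checkpoint
#' @param path `.h5` file written by [write_checkpoint()].
#' @return A `dw_network`.
#' @export
read_checkpoint <- function(path) {
  arch <- jsonlite::fromJSON(as.character(rhdf5::h5read(path,
                                                        "architecture")))
  net <- build_network(arch$Z, c(arch$W, arch$H), arch$n_classes,
                       arch$p_prime, arch$n_filters, seed = 1)
  for (nm in names(net$params)) {
    v <- rhdf5::h5read(path, paste0("params/", nm))
    d <- dim(net$params[[nm]])
    net$params[[nm]] <- if (is.null(d)) as.vector(v) else array(v, dim = d)
  }
  for (nm in names(net$running)) {
    v <- rhdf5::h5read(path, paste0("running/", nm))
    net$running[[nm]] <- if (is.null(dim(net$running[[nm]]))) as.vector(v)
                         else array(v, dim = dim(net$running[[nm]]))
  }
  rhdf5::h5closeAll()
  net
}

#' Save a kernel matrix to HDF5
#' @param K a `kernel_matrix`.
#' @param path output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_kernel_h5 <- function(K, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(.km(K), path, "kernel")
  rhdf5::h5write(as.numeric(attr(K, "sigma")), path, "sigma")
  rhdf5::h5write(as.character(attr(K, "tag")), path, "tag")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a kernel matrix from HDF5
#' @param path `.h5` file written by [write_kernel_h5()].
#' @return A `kernel_matrix`.
#' @export
read_kernel_h5 <- function(path) {
  K <- rhdf5::h5read(path, "kernel")
  sigma <- as.numeric(rhdf5::h5read(path, "sigma"))
  tag <- as.character(rhdf5::h5read(path, "tag"))
  rhdf5::h5closeAll()
  kernel_matrix(K, sigma = sigma, tag = tag)
}

#' Write a questionnaire table to CSV
#' @param q data frame with `subject_id` and item columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path) {
  utils::write.csv(q, path, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire table from CSV
#' @param path CSV with a `subject_id` column and one column per item.
#' @return Data frame.
#' @export
read_questionnaire <- function(path) {
  q <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(q))
    stop("questionnaire CSV must have a subject_id column")
  q
}
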