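#' Azimuthal-equidistant projection of electrode coordinates
#'
#' Maps unit-sphere electrode positions to the plane so that the distance
#' from the vertex (Cz, `z = 1`) is proportional to arc length; the equator
#' maps to the unit circle. Row 0 of the rendered image corresponds to the
#' nose (+y, anterior).
#'
#' @param xyz `C x 3` matrix of unit-sphere coordinates.
#' @return `C x 2` matrix of planar `(px, py)` coordinates.
#' @export
project_azimuthal <- function(xyz) {
  xyz <- as.matrix(xyz)
  nrm <- sqrt(rowSums(xyz^2))
  xyz <- xyz / nrm
  theta <- acos(pmin(pmax(xyz[, 3], -1), 1))    # inclination from vertex
  rho <- theta / (pi / 2)                        # equator -> radius 1
  horiz <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  ux <- ifelse(horiz > 0, xyz[, 1] / horiz, 0)
  uy <- ifelse(horiz > 0, xyz[, 2] / horiz, 0)
  cbind(px = rho * ux, py = rho * uy)
}

# Thin-plate spline in 2D: phi(r) = r^2 log r, plus affine part. Exact
# interpolation at the data sites.
.tps_fit <- function(pts, values) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  K <- ifelse(d > 0, d^2 * log(d), 0)
  P <- cbind(1, pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, rep(0, 3))
  coef <- solve(A, rhs)
  list(w = coef[seq_len(n)], a = coef[n + 1:3], pts = pts)
}

.tps_eval <- function(fit, grid) {
  d <- sqrt(outer(grid[, 1], fit$pts[, 1], "-")^2 +
            outer(grid[, 2], fit$pts[, 2], "-")^2)
  K <- ifelse(d > 0, d^2 * log(d), 0)
  as.vector(K %*% fit$w + cbind(1, grid) %*% fit$a)
}

#' Precompute the topographic rendering geometry for a montage
#'
#' Projects the montage, builds the evaluation grid and the head mask, and
#' factorizes the thin-plate interpolation system once, so repeated
#' [render_topogram()] calls reduce to two small matrix products.
#'
#' @param channel_xyz `C x 3` unit-sphere electrode coordinates.
#' @param grid_wh `(W, H)` image size (default `c(40, 40)`).
#' @return An object of class `topo_geometry`.
#' @export
topo_geometry <- function(channel_xyz, grid_wh = c(40, 40)) {
  W <- grid_wh[1]; H <- grid_wh[2]
  if (W < 8 || H < 8) stop("grid must be at least 8 x 8")
  pts <- project_azimuthal(channel_xyz)
  if (nrow(pts) < 4) stop("need at least 4 channels to interpolate")
  dup <- duplicated(round(pts, 10))
  if (any(dup))
    stop("duplicate projected electrode positions for channels: ",
         paste(which(dup | duplicated(round(pts, 10), fromLast = TRUE)),
               collapse = ", "))
  # image row 1 = nose (py = +1), columns left -> right (px -1 -> +1)
  gx <- seq(-1, 1, length.out = W)
  gy <- seq(1, -1, length.out = H)
  grid <- cbind(rep(gx, each = H), rep(gy, W))  # column-major H x W
  mask <- grid[, 1]^2 + grid[, 2]^2 <= 1 + 1e-12

  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  K <- ifelse(d > 0, d^2 * log(d), 0)
  P <- cbind(1, pts)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  dg <- sqrt(outer(grid[, 1], pts[, 1], "-")^2 +
             outer(grid[, 2], pts[, 2], "-")^2)
  Kg <- cbind(ifelse(dg > 0, dg^2 * log(dg), 0), 1, grid)
  # eval = Kg %*% solve(A)[, 1:n] %*% values ; fold the solve in once
  B <- Kg %*% solve(A)[, seq_len(n), drop = FALSE]
  structure(list(B = B, mask = mask, W = W, H = H, pts = pts),
            class = "topo_geometry")
}

#' Render a per-channel feature vector as a scalp topogram
#'
#' Interpolates channel values onto a `W x H` grid with a thin-plate spline
#' on the azimuthally projected plane (exact at electrode sites), zeroes
#' pixels outside the unit-circle head mask, and min-max normalizes the
#' masked image to `[0, 1]` (a constant image maps to all zeros inside the
#' mask).
#'
#' @param channel_values numeric vector of length `C`.
#' @param geometry a [topo_geometry()]; alternatively pass `channel_xyz` and
#'   `grid_wh` to build one on the fly.
#' @param channel_xyz,grid_wh used only when `geometry` is `NULL`.
#' @return `H x W` numeric matrix in `[0, 1]` (row 1 anterior).
#' @export
render_topogram <- function(channel_values, geometry = NULL,
                            channel_xyz = NULL, grid_wh = c(40, 40)) {
  if (is.null(geometry)) geometry <- topo_geometry(channel_xyz, grid_wh)
  img <- render_topograms(matrix(channel_values, ncol = 1), geometry)
  matrix(img[, 1], nrow = geometry$H, ncol = geometry$W)
}

#' Render several channel-value vectors at once
#'
#' Matrix form of [render_topogram()]: one interpolation matrix product for
#' all maps of a trial.
#'
#' @param values `C x K` matrix, one column per map.
#' @param geometry a [topo_geometry()].
#' @return `(H * W) x K` matrix of vectorized (column-major) normalized
#'   images.
#' @export
render_topograms <- function(values, geometry) {
  stopifnot(inherits(geometry, "topo_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(geometry$B))
    stop("channel value count does not match the geometry")
  imgs <- geometry$B %*% values
  msk <- geometry$mask
  imgs[!msk, ] <- 0
  lo <- apply(imgs[msk, , drop = FALSE], 2, min)
  hi <- apply(imgs[msk, , drop = FALSE], 2, max)
  span <- hi - lo
  const <- span <= 1e-9 * pmax(1, abs(lo), abs(hi))
  span[const] <- 1
  inside <- sweep(sweep(imgs[msk, , drop = FALSE], 2, lo, "-"), 2, span,
                  "/")
  inside[, const] <- 0
  imgs[msk, ] <- inside
  imgs
}
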