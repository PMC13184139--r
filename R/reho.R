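# Regional homogeneity: Kendall's coefficient of concordance over local
# voxel neighborhoods, reduced to regional means through a label atlas.

#' Kendall's coefficient of concordance (Kendall's W)
#'
#' Concordance of K time series over n time points. Each series is ranked
#' over time (midranks for ties, no tie-correction factor, matching classic
#' ReHo implementations); with \eqn{R_i} the rank sum across series at time
#' point i,
#' \deqn{W = \frac{\sum_i R_i^2 - n \bar R^2}{K^2 (n^3 - n) / 12}.}
#' Constant series are all-tied, so a set of constant series has rank-sum
#' variance 0 and W = 0: degenerate voxels do not appear synchronized.
#'
#' @param x Numeric matrix, n time points x K series.
#' @param tie_policy Only `"midrank"` is supported.
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(x, tie_policy = "midrank") {
  x <- as.matrix(x)
  K <- ncol(x); n <- nrow(x)
  if (K < 2) stop("kendalls_w needs at least 2 series (columns)")
  if (n < 2) stop("kendalls_w needs at least 2 time points (rows)")
  tie_policy <- match.arg(tie_policy, "midrank")
  ranks <- apply(x, 2, rank, ties.method = "average")
  R <- rowSums(ranks)
  Rbar <- K * (n + 1) / 2
  num <- sum(R^2) - n * Rbar^2
  den <- K^2 * (n^3 - n) / 12
  w <- num / den
  min(max(w, 0), 1)
}

# neighbor offsets for the three standard neighborhood definitions
.neighborhood_offsets <- function(neighborhood_size) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  dist <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(neighborhood_size),
    "7" = dist == 1,          # faces
    "19" = dist <= 2,         # faces + edges
    "27" = rep(TRUE, nrow(off)),  # full cube
    stop("neighborhood_size must be one of 7, 19, 27")
  )
  off[keep, , drop = FALSE]
}

#' Voxel-wise ReHo map
#'
#' For every in-mask voxel, computes [kendalls_w()] over the time series of
#' the voxel and its in-mask neighbors under the chosen adjacency (7 = faces,
#' 19 = faces + edges, 27 = full 3x3x3 cube). Voxels with fewer than 2
#' in-mask neighbors get `NA`.
#'
#' Implemented by ranking each voxel's series once and accumulating neighbor
#' rank sums with array shifts, which is algebraically identical to calling
#' [kendalls_w()] per voxel.
#'
#' @param data 4D numeric array (x, y, z, t), t >= 10.
#' @param mask 3D logical array matching the spatial extents.
#' @param neighborhood_size 7, 19 or 27 (default).
#' @return List of class `reho_map`: `values` (3D array, `NA` where absent)
#'   and `neighborhood_size`.
#' @export
reho_map <- function(data, mask = NULL, neighborhood_size = 27) {
  stopifnot(length(dim(data)) == 4)
  dims <- dim(data)[1:3]
  nt <- dim(data)[4]
  if (nt < 10) stop("need at least 10 time points")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  stopifnot(all(dim(mask) == dims))
  offs <- .neighborhood_offsets(neighborhood_size)

  # rank each voxel's time series (midranks)
  rk <- apply(data, c(1, 2, 3), rank, ties.method = "average") # t x X x Y x Z
  rk <- aperm(rk, c(2, 3, 4, 1))                               # X x Y x Z x t
  maskn <- array(as.numeric(mask), dim = dims)
  rk <- rk * as.vector(maskn)  # zero out masked voxels' ranks

  pad <- function(a, d4) {
    out <- array(0, dim = c(dims + 2L, d4))
    out[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1), ] <- a
    out
  }
  rkp <- pad(rk, nt)
  mp <- pad(array(maskn, dim = c(dims, 1)), 1L)

  Rsum <- rk                     # self contribution
  Kcnt <- maskn                  # number of contributing series
  Ncnt <- array(0, dim = dims)   # in-mask neighbors excluding self
  xi <- 2:(dims[1] + 1); yi <- 2:(dims[2] + 1); zi <- 2:(dims[3] + 1)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    Rsum <- Rsum + rkp[xi + o$dx, yi + o$dy, zi + o$dz, , drop = FALSE]
    mshift <- mp[xi + o$dx, yi + o$dy, zi + o$dz, 1]
    Kcnt <- Kcnt + mshift
    Ncnt <- Ncnt + mshift
  }

  sumR2 <- apply(Rsum^2, c(1, 2, 3), sum)
  Rbar <- Kcnt * (nt + 1) / 2
  num <- sumR2 - nt * Rbar^2
  den <- Kcnt^2 * (nt^3 - nt) / 12
  W <- num / den
  W <- pmin(pmax(W, 0), 1)
  absent <- !mask | Ncnt < 2
  W[absent] <- NA_real_
  n_absent <- sum(mask & Ncnt < 2)
  if (n_absent > 0) {
    message(sprintf("reho_map: %d in-mask voxel(s) with < 2 in-mask neighbors set absent", n_absent))
  }
  structure(list(values = W, neighborhood_size = neighborhood_size),
            class = "reho_map")
}

#' Reduce a ReHo map to 246 regional means
#'
#' @param map A `reho_map` (or bare 3D array of values).
#' @param atlas 3D integer label array, 0 = background, 1..246 = regions.
#' @return Named numeric vector of length 246; regions with no valid voxel
#'   are `NA` with a warning.
#' @export
parcellate <- function(map, atlas) {
  vals <- if (inherits(map, "reho_map")) map$values else map
  stopifnot(all(dim(vals) == dim(atlas)))
  labs <- as.integer(atlas)
  v <- as.numeric(vals)
  keep <- labs > 0L & !is.na(v)
  out <- rep(NA_real_, 246)
  names(out) <- sprintf("region_%03d", 1:246)
  if (any(keep)) {
    means <- tapply(v[keep], labs[keep], mean)
    out[as.integer(names(means))] <- means
  }
  if (anyNA(out)) {
    warning(sprintf("parcellate: %d region(s) with no valid voxels", sum(is.na(out))))
  }
  out
}

#' Write / read NIfTI images for voxel fixtures
#'
#' Thin wrappers over RNifti for the 4D data and the integer label atlas.
#'
#' @param x 3D or 4D numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path` invisibly (writer); array (reader).
#' @export
write_nifti_image <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr)[setdiff(names(attributes(arr)), "dim")] <- NULL
  arr
}
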