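#' Planar 10-20 electrode coordinates
#'
#' Approximate top-view unit-disc coordinates (x toward the right ear, y
#' toward the nasion) for the 19 + 2 electrode 10-20 montage used here.
#'
#' @param labels electrode labels to look up (default: the whole set).
#' @return data.frame with \code{channel}, \code{x}, \code{y}.
#' @export
electrodePositions <- function(labels = NULL) {
  pos <- data.frame(
    channel = c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
                "T3", "C3", "CZ", "C4", "T4",
                "T5", "P3", "PZ", "P4", "T6", "O1", "O2", "A1", "A2"),
    x = c(-0.278, 0.278, -0.728, -0.350, 0, 0.350, 0.728,
          -0.900, -0.450, 0, 0.450, 0.900,
          -0.728, -0.350, 0, 0.350, 0.728, -0.278, 0.278, -0.980, 0.980),
    y = c(0.856, 0.856, 0.529, 0.420, 0.450, 0.420, 0.529,
          0, 0, 0, 0, 0,
          -0.529, -0.420, -0.450, -0.420, -0.529, -0.856, -0.856,
          -0.100, -0.100))
  if (is.null(labels)) return(pos)
  labels <- normalizeChannelLabels(labels)
  idx <- match(labels, pos$channel)
  if (anyNA(idx))
    stop("no 10-20 coordinates for: ", paste(labels[is.na(idx)], collapse = ", "))
  out <- pos[idx, ]
  rownames(out) <- NULL
  out
}

# Thin-plate spline basis; phi(0) = 0.
tpsPhi <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Topographic scalp map by radial-basis interpolation
#'
#' Interpolates per-channel densities over the unit disc with a thin-plate
#' spline (radial basis r^2 log r plus an affine term), which reproduces the
#' channel values exactly at the electrode positions. Grid points outside the
#' disc are NA.
#'
#' @param values named numeric vector of per-channel values (names are 10-20
#'   labels); at least 4 channels.
#' @param layout data.frame of positions as from [electrodePositions()];
#'   defaults to the standard coordinates of \code{names(values)}.
#' @param gridN grid resolution per axis.
#' @return object of class \code{"ScalpMap"}: list with \code{x}, \code{y}
#'   (grid axes), \code{z} (matrix, NA outside the disc), \code{channels},
#'   \code{values}, \code{positions}.
#' @export
scalpMap <- function(values, layout = electrodePositions(names(values)),
                     gridN = 67) {
  if (length(values) < 4)
    stop("scalp map interpolation needs at least 4 channels")
  stopifnot(!is.null(names(values)), all(names(values) %in% layout$channel))
  layout <- layout[match(names(values), layout$channel), ]
  px <- layout$x; py <- layout$y; v <- as.numeric(values)
  n <- length(v)
  K <- tpsPhi(sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2))
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  w <- solve(A, c(v, 0, 0, 0))
  gx <- seq(-1, 1, length.out = gridN)
  gy <- seq(-1, 1, length.out = gridN)
  grid <- expand.grid(x = gx, y = gy)
  R <- sqrt(outer(grid$x, px, "-")^2 + outer(grid$y, py, "-")^2)
  z <- tpsPhi(R) %*% w[1:n] + cbind(1, grid$x, grid$y) %*% w[(n + 1):(n + 3)]
  z[grid$x^2 + grid$y^2 > 1] <- NA
  structure(list(x = gx, y = gy, z = matrix(z, gridN, gridN),
                 channels = names(values), values = v, positions = layout),
            class = "ScalpMap")
}

#' Evaluate a scalp map at arbitrary points
#'
#' @param map a \code{"ScalpMap"}.
#' @param x,y coordinates.
#' @return interpolated values.
#' @export
evalScalpMap <- function(map, x, y) {
  px <- map$positions$x; py <- map$positions$y; v <- map$values
  n <- length(v)
  K <- tpsPhi(sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2))
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  w <- solve(A, c(v, 0, 0, 0))
  R <- sqrt(outer(x, px, "-")^2 + outer(y, py, "-")^2)
  as.numeric(tpsPhi(R) %*% w[1:n] + cbind(1, x, y) %*% w[(n + 1):(n + 3)])
}

#' Render a scalp map to a PNG file
#'
#' @param map a \code{"ScalpMap"}.
#' @param path output PNG path.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plotScalpMap <- function(map, path, main = "") {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(map$x, map$y, map$z, asp = 1, axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(th), sin(th))
  graphics::points(map$positions$x, map$positions$y, pch = 20)
  graphics::text(map$positions$x, map$positions$y, map$channels, pos = 3,
                 cex = 0.7)
  invisible(path)
}
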