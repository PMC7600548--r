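#' Spherical head model with a hemispheric electrode montage
#'
#' Builds a single homogeneous conducting sphere together with an electrode
#' layout on its upper hemisphere.  Electrodes are arranged on rings of
#' constant polar angle (vertex ring first), with per-ring counts
#' proportional to the ring circumference, giving a 10-20-like coverage for
#' the default 64 channels.  The sphere is the forward model for all dipole
#' simulation and localization in the package: anatomy (BEM meshes, MNI
#' coordinates) is deliberately out of scope, so localization claims are
#' always relative to this self-consistent model.
#'
#' Coordinate convention: x = right, y = anterior, z = superior, origin at
#' the sphere centre, distances in millimetres.  "Front-most" channels
#' (used by the ocular-artifact heuristic) are those with the largest y.
#'
#' @param n_channels number of electrodes (default 64).
#' @param radius_mm sphere radius in mm (default 90).
#' @param conductivity homogeneous conductivity in S/m (default 0.33).
#' @return an object of class `head_model`: a list with `radius`, `sigma`,
#'   `channel_names`, `positions` (n x 3 unit vectors) and
#'   `scalp_positions` (n x 3, mm).
#' @examples
#' hm <- make_head_model(16)
#' nrow(hm$positions)
#' @export
make_head_model <- function(n_channels = 64L, radius_mm = 90,
                            conductivity = 0.33) {
  n_channels <- check_count(n_channels, "n_channels", min = 4L)
  radius_mm <- check_scalar(radius_mm, "radius_mm", lower = 1e-6)
  conductivity <- check_scalar(conductivity, "conductivity", lower = 1e-9)

  pos <- hemisphere_layout(n_channels)
  names <- sprintf("E%02d", seq_len(n_channels))
  rownames(pos) <- names
  structure(list(
    radius = radius_mm,
    sigma = conductivity,
    channel_names = names,
    positions = pos,
    scalp_positions = pos * radius_mm
  ), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> homogeneous sphere, radius %.1f mm, %d channels\n",
              x$radius, nrow(x$positions)))
  invisible(x)
}

# Ring-based layout on the upper hemisphere (unit sphere).
# Rings at equally spaced polar angles from the vertex down to 90 degrees;
# counts allocated by largest-remainder rounding of sin(theta) weights.
hemisphere_layout <- function(n) {
  n_rings <- max(2L, min(6L, ceiling(sqrt(n) / 1.4)))
  theta <- seq(0, pi / 2, length.out = n_rings + 1L)[-1L]  # exclude vertex
  n_vertex <- 1L
  w <- sin(theta)
  alloc <- (n - n_vertex) * w / sum(w)
  counts <- floor(alloc)
  rem <- alloc - counts
  short <- (n - n_vertex) - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
  }
  pos <- matrix(0, n, 3L)
  pos[1L, ] <- c(0, 0, 1)
  i <- 2L
  for (k in seq_along(theta)) {
    m <- counts[k]
    if (m == 0L) next
    # stagger alternate rings; start each ring at the front (positive y)
    phi <- pi / 2 + 2 * pi * (seq_len(m) - 1L) / m + (k %% 2L) * pi / m
    pos[i:(i + m - 1L), ] <- cbind(cos(phi) * sin(theta[k]),
                                   sin(phi) * sin(theta[k]),
                                   rep(cos(theta[k]), m))
    i <- i + m
  }
  pos
}

#' Indices of the front-most channels
#'
#' @param model a `head_model`.
#' @param n how many channels (default 4).
#' @return integer channel indices with the largest anterior (y) coordinate.
#' @keywords internal
frontal_channels <- function(model, n = 4L) {
  order(model$positions[, 2L], decreasing = TRUE)[seq_len(n)]
}
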