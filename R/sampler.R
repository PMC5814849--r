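# Conformation sampler: rigid rods and freely-jointed Kuhn links with
# uniformly random joint orientations, rejected whenever any joint (or, on
# curved walls, any long-link midpoint) penetrates the surface. Intra-chain
# excluded volume is deliberately ignored: at these contour lengths the
# dominant steric effect is the origami wall itself.

# generate m conformations of a chain with given link lengths anchored at
# `anchor`; returns joint positions as a list of m x 3 matrices (one per
# joint) so the wall test can be vectorised.
.chain_positions <- function(m, links, anchor) {
  L <- length(links)
  dirs <- matrix(stats::rnorm(3 * m * L), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs * dirs))
  pos <- vector("list", L)
  px <- rep(anchor[1], m); py <- rep(anchor[2], m); pz <- rep(anchor[3], m)
  for (j in seq_len(L)) {
    idx <- ((j - 1) * m + 1):(j * m)
    px <- px + links[j] * dirs[idx, 1]
    py <- py + links[j] * dirs[idx, 2]
    pz <- pz + links[j] * dirs[idx, 3]
    pos[[j]] <- cbind(px, py, pz)
  }
  pos
}

# logical vector: conformation entirely outside the wall
.wall_ok <- function(pos, links, anchor, track) {
  m <- nrow(pos[[1]])
  ok <- rep(TRUE, m)
  if (track$kind == "free") return(ok)
  if (track$kind == "flat") {
    for (p in pos) ok <- ok & (p[, 3] >= 0)
    return(ok)
  }
  # cylinder, walker on the convex side: radial distance from the x-axis
  # must stay >= R; long straight links can cut the curved surface between
  # joints, so their midpoints are checked as well.
  R2 <- track$radius^2 * (1 - 1e-9)
  prev <- matrix(rep(anchor, each = m), ncol = 3)
  for (j in seq_along(pos)) {
    p <- pos[[j]]
    ok <- ok & (p[, 2]^2 + p[, 3]^2 >= R2)
    if (links[j] > 2) {
      mid <- (p + prev) / 2
      ok <- ok & (mid[, 2]^2 + mid[, 3]^2 >= R2)
    }
    prev <- p
  }
  ok
}

# core rejection sampler; keep_beads = TRUE stores full conformations
# (memory-heavy, meant for small n).
.sample_arm <- function(links, track, anchor, n, seed,
                        keep_beads = FALSE, chunk = 20000L,
                        max_batches = 5000L) {
  L <- length(links)
  if (track$kind == "flat" && anchor[3] < 0) {
    stop("geometry error: anchor lies below the surface", call. = FALSE)
  }
  if (track$kind == "cylinder" &&
      anchor[2]^2 + anchor[3]^2 < track$radius^2 * (1 - 1e-6)) {
    stop("geometry error: anchor lies inside the cylinder", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ends <- matrix(NA_real_, n, 3)
  beads <- if (keep_beads) vector("list", n) else NULL
  got <- 0L; raw <- 0L; acc <- 0L; batch <- 0L
  while (got < n) {
    batch <- batch + 1L
    if (batch > max_batches) {
      stop("sampling-failure: acceptance rate too low for this geometry",
           call. = FALSE)
    }
    m <- as.integer(chunk)
    pos <- .chain_positions(m, links, anchor)
    ok <- .wall_ok(pos, links, anchor, track)
    raw <- raw + m
    idx <- which(ok)
    acc <- acc + length(idx)
    if (length(idx) == 0) next
    take <- idx[seq_len(min(length(idx), n - got))]
    ends[(got + 1):(got + length(take)), ] <- pos[[L]][take, , drop = FALSE]
    if (keep_beads) {
      for (k in seq_along(take)) {
        conf <- t(vapply(pos, function(p) p[take[k], ], numeric(3)))
        beads[[got + k]] <- rbind(anchor, conf)
      }
    }
    got <- got + length(take)
  }
  list(ends = ends, beads = beads, acceptance_rate = acc / raw,
       n = n, seed = as.integer(seed))
}

#' Sample the spatial density of an arm's reactive end
#'
#' Draws hard-wall-rejected conformations of one arm anchored at a point on
#' the track surface (free pivot: any orientation in the allowed half-space)
#' and returns the empirical 3-D cloud of the reactive (distal) end.
#'
#' @param arm List of [segment_spec()] from the anchor outward.
#' @param track A track geometry ([track_flat()], [track_cylinder()],
#'   [track_free()]).
#' @param anchor Numeric xyz anchor point (nm) on the surface. Defaults to
#'   the track's anchor A.
#' @param n Number of accepted conformations.
#' @param seed Integer RNG seed.
#' @return An object of class `end_density`: `ends` (`n x 3` matrix),
#'   `acceptance_rate`, `n`, `seed`.
#' @export
sample_end_density <- function(arm, track, anchor = NULL, n = 1e4,
                               seed = 1L) {
  .check_num(n, "n", min = 1)
  links <- arm_links(arm)
  if (is.null(anchor)) anchor <- track_frame(track)$anchor_A
  res <- .sample_arm(links, track, anchor, as.integer(n), seed)
  structure(
    list(ends = res$ends, acceptance_rate = res$acceptance_rate,
         n = res$n, seed = res$seed, anchor = anchor, links = links,
         track_kind = track$kind),
    class = "end_density"
  )
}

#' @export
print.end_density <- function(x, ...) {
  cat(sprintf(
    "<end_density> n = %d ends, %d links, acceptance %.1f%%, seed %d (%s track)\n",
    x$n, length(x$links), 100 * x$acceptance_rate, x$seed, x$track_kind
  ))
  invisible(x)
}

#' Bin an end-density cloud onto a regular grid
#'
#' Histogram of the sample cloud on a cubic voxel grid, optionally smoothed
#' with a separable Gaussian kernel.
#'
#' @param ed An `end_density` object.
#' @param voxel Voxel edge in nm.
#' @param bandwidth Gaussian kernel sd in nm; `0` disables smoothing.
#' @return List with `origin`, `voxel` and a 3-D `density` array
#'   (integrates to 1).
#' @export
density_grid <- function(ed, voxel = 1, bandwidth = 1) {
  stopifnot(inherits(ed, "end_density"))
  rng <- apply(ed$ends, 2, range)
  pad <- 4 * max(bandwidth, voxel)
  origin <- rng[1, ] - pad
  dims <- ceiling((rng[2, ] - origin + pad) / voxel) + 1L
  counts <- .bin_counts(ed$ends, origin, voxel, dims)
  if (bandwidth > 0) counts <- .smooth3d(counts, bandwidth / voxel)
  list(origin = origin, voxel = voxel,
       density = counts / (sum(counts) * voxel^3))
}

# 3-D histogram: counts array of dimension dims
.bin_counts <- function(pts, origin, voxel, dims, weights = NULL) {
  ix <- floor((pts[, 1] - origin[1]) / voxel) + 1
  iy <- floor((pts[, 2] - origin[2]) / voxel) + 1
  iz <- floor((pts[, 3] - origin[3]) / voxel) + 1
  keep <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
    iz >= 1 & iz <= dims[3]
  lin <- (ix[keep] - 1) + dims[1] * ((iy[keep] - 1) + dims[2] * (iz[keep] - 1)) + 1
  counts <- numeric(prod(dims))
  tab <- tabulate(lin, nbins = prod(dims))
  counts <- as.numeric(tab)
  array(counts, dim = dims)
}

# separable Gaussian smoothing (sigma in voxel units) via banded matrix
# multiplication along each dimension; kernel renormalised so mass inside
# the box is preserved up to edge truncation.
.smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_dim1 <- function(a) {
    d <- dim(a)
    K <- matrix(0, d[1], d[1])
    for (off in seq(-r, r)) {
      i <- seq_len(d[1])
      j <- i + off
      okj <- j >= 1 & j <= d[1]
      K[cbind(i[okj], j[okj])] <- K[cbind(i[okj], j[okj])] + k[off + r + 1]
    }
    array(K %*% matrix(a, d[1]), dim = d)
  }
  a <- smooth_dim1(a)
  a <- aperm(smooth_dim1(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  a <- aperm(smooth_dim1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
  a
}

#' Dump sampled conformations to an XYZ-style text file
#'
#' One bead per line: arm id, bead index (0 = anchor), x, y, z in nm.
#' Intended for visual inspection of a handful of conformations.
#'
#' @param arm List of [segment_spec()].
#' @param track Track geometry.
#' @param file Output path.
#' @param n Number of conformations (kept small; beads are stored).
#' @param seed Integer RNG seed.
#' @param arm_id Label written in the first column.
#' @param anchor Optional anchor override.
#' @return Invisibly, the path written.
#' @export
write_conformations_xyz <- function(arm, track, file, n = 25, seed = 1L,
                                    arm_id = "arm", anchor = NULL) {
  links <- arm_links(arm)
  if (is.null(anchor)) anchor <- track_frame(track)$anchor_A
  res <- .sample_arm(links, track, anchor, as.integer(n), seed,
                     keep_beads = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    b <- res$beads[[i]]
    for (j in seq_len(nrow(b))) {
      writeLines(sprintf("%s %d %.4f %.4f %.4f", arm_id, j - 1,
                         b[j, 1], b[j, 2], b[j, 3]), con)
    }
  }
  invisible(file)
}
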