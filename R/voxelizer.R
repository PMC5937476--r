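#' Voxelizer configuration
#'
#' Bundles the parameters of the backbone-to-grid representation.
#'
#' @param l Grid edge length in voxels; even, at least 4.  Default 32.
#' @param r_max Radius in Angstroms of the sphere around the barycenter
#'   that is mapped into the grid; structure beyond it is clipped.
#'   Default 40.
#' @param p Number of regularly spaced interpolation points inserted
#'   between consecutive backbone atoms before scaling, to close holes at
#'   fine resolutions.  `NULL` (default) selects 0, 5 or 9 for
#'   `l` = 32, 64, 96 respectively (0 otherwise).
#' @param neighbor_connectivity Neighborhood used by
#'   [remove_isolated_voxels()]: 6 (faces), 18 (faces + edges) or 26
#'   (full cube).  Default 26.
#' @param backbone_atoms Atom names retained by [parse_pdb()].
#' @param assignment How scaled coordinates map to voxel indices:
#'   `"round"` (nearest voxel center, half away from zero) or `"floor"`.
#' @return A `voxelizer_config` list.
#' @export
voxelizer_config <- function(l = 32L, r_max = 40, p = NULL,
                             neighbor_connectivity = 26L,
                             backbone_atoms = c("N", "CA", "C", "O"),
                             assignment = c("round", "floor")) {
  l <- as.integer(l)
  if (l < 4L || l %% 2L != 0L) stop("l must be an even integer >= 4")
  if (r_max <= 0) stop("r_max must be positive")
  if (is.null(p)) p <- switch(as.character(l), "32" = 0L, "64" = 5L, "96" = 9L, 0L)
  p <- as.integer(p)
  if (p < 0L) stop("p must be >= 0")
  if (!neighbor_connectivity %in% c(6L, 18L, 26L))
    stop("neighbor_connectivity must be 6, 18 or 26")
  assignment <- match.arg(assignment)
  structure(list(l = l, r_max = r_max, p = p,
                 neighbor_connectivity = as.integer(neighbor_connectivity),
                 backbone_atoms = backbone_atoms,
                 assignment = assignment),
            class = "voxelizer_config")
}

#' Flip codes
#'
#' A flip code (dx, dy, dz) in \{0,1\}^3 selects reflections through the
#' origin along each axis; (0,0,0) is the identity.  These are the only
#' rigid transformations that preserve the principal axes of an oriented
#' point cloud, and hence the only augmentations applied after PCA
#' orientation.
#'
#' @param dx,dy,dz 0 or 1.
#' @return An integer vector of class `flip_code`.
#' @export
flip_code <- function(dx = 0L, dy = 0L, dz = 0L) {
  f <- as.integer(c(dx, dy, dz))
  if (length(f) != 3L || !all(f %in% c(0L, 1L)))
    stop("flip code components must each be 0 or 1")
  structure(f, names = c("dx", "dy", "dz"), class = "flip_code")
}

#' Enumerate all flip codes
#'
#' @param include_identity Include (0,0,0)?  With the identity there are
#'   8 codes, without it the 2^3 - 1 = 7 proper flips.
#' @return List of [flip_code()] objects.
#' @export
all_flip_codes <- function(include_identity = TRUE) {
  g <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  codes <- lapply(seq_len(nrow(g)), function(i) flip_code(g$dx[i], g$dy[i], g$dz[i]))
  if (!include_identity) codes <- codes[-1L]
  codes
}

#' Interpolate consecutive backbone atoms
#'
#' Inserts `p` regularly spaced points between each consecutive pair of
#' backbone positions (A_i, A_{i+1}): the k-th inserted point is
#' ((p - k + 1) A_i + k A_{i+1}) / (p + 1) for k = 1..p.  Closes holes
#' that appear at fine grid resolutions.
#'
#' @param coords Numeric matrix of ordered positions (rows).
#' @param p Non-negative integer count of inserted points per segment.
#' @return Matrix with `n + (n - 1) * p` rows, order preserved.
#' @export
interpolate_backbone <- function(coords, p) {
  coords <- as.matrix(coords)
  if (length(p) != 1L || is.na(p) || p < 0) stop("p must be a non-negative integer")
  p <- as.integer(p)
  n <- nrow(coords)
  if (p == 0L || n < 2L) return(coords)
  out <- matrix(NA_real_, nrow = n + (n - 1L) * p, ncol = ncol(coords))
  step <- p + 1L
  out[seq(1L, by = step, length.out = n), ] <- coords
  for (k in seq_len(p)) {
    w <- k / (p + 1)
    out[seq(1L + k, by = step, length.out = n - 1L), ] <-
      (1 - w) * coords[-n, , drop = FALSE] + w * coords[-1L, , drop = FALSE]
  }
  out
}

#' Homothety ratio mapping the capture sphere into the grid
#'
#' Ratio `lambda = floor(l/2 - 1) / r_max` of the uniform scaling, centered
#' on the barycenter, that maps the sphere of radius `r_max` into the
#' voxel cube.  All structures are scaled by the same ratio so that
#' absolute size remains a feature visible to the classifier.
#'
#' @param l Grid edge length (voxels).
#' @param r_max Capture radius (Angstroms).
#' @return Scalar ratio.
#' @examples
#' homothety_ratio(32, 40)  # 0.375
#' @export
homothety_ratio <- function(l, r_max) {
  if (l < 4) stop("l must be >= 4")
  if (r_max <= 0) stop("r_max must be positive")
  floor(l / 2 - 1) / r_max
}

#' Orient a centered point cloud along its principal axes
#'
#' Rotates a centered cloud into its PCA frame: output axis 1 carries the
#' largest variance, axis 3 the smallest, and the sample covariance of the
#' output is diagonal.  Because eigenvectors are defined only up to sign,
#' a deterministic convention is applied per axis: the sign making the
#' third central moment of the projected coordinates non-negative, falling
#' back (when that moment is within `1e-9` of zero) to making the
#' largest-magnitude loading positive.  Residual ambiguity is what flip
#' augmentation addresses.
#'
#' @param coords Numeric matrix of centered positions (rows).
#' @return Matrix of the same shape in the principal-axis frame.
#' @export
pca_orient <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points for a principal-axis frame")
  cv <- stats::cov(coords)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] < 1e-12 * max(eg$values[1], 1e-300))
    warning("rank-deficient point cloud: completing the frame with an ",
            "arbitrary orthonormal axis")
  rot <- eg$vectors  # columns ordered by decreasing eigenvalue
  out <- coords %*% rot
  for (a in 1:3) {
    m3 <- mean(out[, a]^3)
    if (abs(m3) > 1e-9) {
      if (m3 < 0) out[, a] <- -out[, a]
    } else if (rot[which.max(abs(rot[, a])), a] < 0) {
      out[, a] <- -out[, a]
    }
  }
  out
}

#' Apply a flip code to centered coordinates
#'
#' Multiplies the coordinate on axis a by (-1)^(f_a): reflection through
#' the origin along the flagged axes.
#'
#' @param coords Numeric matrix of centered positions.
#' @param f A [flip_code()].
#' @return Flipped coordinate matrix.
#' @export
apply_flip <- function(coords, f) {
  stopifnot(inherits(f, "flip_code"))
  coords <- as.matrix(coords)
  s <- ifelse(unclass(f) == 1L, -1, 1)
  sweep(coords, 2L, s, `*`)
}

#' Voxel occupancy grids
#'
#' @param values An `l` x `l` x `l` array of 0/1 occupancy values.
#' @param source_id Identifier of the originating structure.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(values, source_id = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L || length(unique(dim(values))) != 1L)
    stop("values must be a cubic 3D array")
  if (!all(values %in% c(0, 1))) stop("grid values must be 0 or 1")
  storage.mode(values) <- "integer"
  structure(list(values = values, l = dim(values)[1L],
                 source_id = as.character(source_id)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s: l = %d, %d occupied voxels\n",
              x$source_id, x$l, sum(x$values)))
  invisible(x)
}

#' Map scaled, centered coordinates to a binary occupancy grid
#'
#' Shifts coordinates by +(l/2, l/2, l/2) so the barycenter sits at the
#' grid center, assigns each point to a voxel by nearest-neighbor rounding
#' (or flooring, per `assignment`), and marks those voxels occupied.
#' Voxel indices are 0-based in `[0, l-1]^3`; points assigned outside the
#' grid are silently discarded, which is how structures larger than the
#' capture sphere are clipped.
#'
#' @param coords Centered, scaled coordinate matrix.
#' @param l Grid edge length.
#' @param source_id Identifier carried into the grid.
#' @param assignment `"round"` or `"floor"`.
#' @return A [voxel_grid()].
#' @export
coords_to_grid <- function(coords, l, source_id = "",
                           assignment = c("round", "floor")) {
  assignment <- match.arg(assignment)
  coords <- as.matrix(coords)
  l <- as.integer(l)
  shifted <- coords + l / 2
  idx <- if (assignment == "round") round_half_away(shifted) else floor(shifted)
  inside <- rowSums(idx >= 0 & idx <= l - 1L) == 3L
  idx <- idx[inside, , drop = FALSE]
  vals <- array(0L, dim = c(l, l, l))
  if (nrow(idx) > 0L) {
    vals[idx + 1L] <- 1L  # matrix-index assignment, 0-based -> 1-based
  } else if (nrow(coords) > 0L) {
    warning("all points fell outside the grid for '", source_id, "'")
  }
  voxel_grid(vals, source_id)
}

#' Remove isolated voxels
#'
#' Single pass: every occupied voxel with no occupied neighbor under the
#' chosen connectivity is cleared; all other voxels are untouched.  Used
#' to drop outlier atoms from the representation.  Never adds occupancy.
#'
#' @param grid A [voxel_grid()].
#' @param connectivity 6, 18 or 26.
#' @return A [voxel_grid()] with isolated voxels cleared.
#' @export
remove_isolated_voxels <- function(grid, connectivity = 26L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  out <- .remove_isolated_cpp(as.integer(grid$values), grid$l,
                              as.integer(connectivity))
  grid$values <- array(out, dim = dim(grid$values))
  grid
}

#' Voxelize a backbone trace
#'
#' Full representation pipeline: interpolate consecutive backbone atoms
#' (`p` points per segment, in original Angstrom coordinates), center on
#' the barycenter, scale uniformly by [homothety_ratio()], clip points
#' beyond the capture sphere, orient along principal axes, apply the flip
#' code, map to the grid and remove isolated voxels.
#'
#' @param trace A [backbone_trace()].
#' @param cfg A [voxelizer_config()].
#' @param f A [flip_code()]; default identity.
#' @return A binary [voxel_grid()] of edge `cfg$l`.
#' @examples
#' tr <- generate_trace(fixture_spec("helix", seed = 1))
#' g <- voxelize(tr, voxelizer_config())
#' sum(g$values)
#' @export
voxelize <- function(trace, cfg = voxelizer_config(), f = flip_code()) {
  stopifnot(inherits(trace, "backbone_trace"), inherits(cfg, "voxelizer_config"))
  pts <- interpolate_backbone(trace$coords, cfg$p)
  pts <- sweep(pts, 2L, colMeans(trace$coords), `-`)
  pts <- pts * homothety_ratio(cfg$l, cfg$r_max)
  # clip to the scaled capture sphere of radius floor(l/2 - 1)
  pts <- pts[sqrt(rowSums(pts^2)) <= floor(cfg$l / 2 - 1), , drop = FALSE]
  if (nrow(pts) >= 2L) pts <- pca_orient(pts)
  pts <- apply_flip(pts, f)
  g <- coords_to_grid(pts, cfg$l, source_id = trace$structure_id,
                      assignment = cfg$assignment)
  remove_isolated_voxels(g, cfg$neighbor_connectivity)
}
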