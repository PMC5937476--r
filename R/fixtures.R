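#' Synthetic backbone fixture specification
#'
#' Describes one toy backbone trace from a parametric shape family.  The
#' six families -- straight, helix, ring, globule, ellipsoid, two_lobe --
#' are chosen to be separable by coarse 3D shape, which is exactly the
#' signal a volumetric occupancy classifier uses, so labeled multi-class
#' datasets built from them give the network learnable structure without
#' any real protein input.
#'
#' Atoms are laid out along the family's curve at roughly 1.5 Angstrom
#' spacing, four per residue, with isotropic Gaussian positional noise;
#' `scale` bounds the radius of the emitted cloud.  Atom names cycle
#' N, CA, C, O rather than modelling true peptide geometry: the
#' representation only uses point positions.
#'
#' @param family One of `"straight"`, `"helix"`, `"ring"`, `"globule"`,
#'   `"ellipsoid"`, `"two_lobe"`.
#' @param n_residues Number of residues (4 atoms each), at least 2.
#' @param scale Approximate radius of the trace in Angstroms; each family
#'   has its own default, sized like a small protein domain.
#' @param noise_sd Isotropic noise standard deviation (Angstroms).
#' @param seed Integer seed; traces are deterministic given the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(family = c("straight", "helix", "ring", "globule",
                                    "ellipsoid", "two_lobe"),
                         n_residues = 100L, scale = NULL, noise_sd = 0.3,
                         seed = 1L) {
  family <- match.arg(family)
  if (is.null(scale))
    scale <- c(straight = 30, helix = 18, ring = 14, globule = 12,
               ellipsoid = 20, two_lobe = 24)[[family]]
  n_residues <- as.integer(n_residues)
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (scale <= 0) stop("scale must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(family = family, n_residues = n_residues, scale = scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Parametric curves, s in [0, 1], bounded by radius `scale`.
fixture_curve <- function(family, s, scale) {
  switch(family,
    straight = cbind((2 * s - 1) * scale, 0, 0),
    helix = cbind(0.45 * scale * cos(2 * pi * 6 * s),
                  0.45 * scale * sin(2 * pi * 6 * s),
                  (2 * s - 1) * 0.8 * scale),
    ring = cbind(scale * cos(2 * pi * s), scale * sin(2 * pi * s), 0),
    ellipsoid = {
      phi <- pi * s
      th <- 2 * pi * 8 * s
      cbind(scale * sin(phi) * cos(th),
            0.5 * scale * sin(phi) * sin(th),
            0.25 * scale * cos(phi))
    },
    stop("unknown fixture family: ", family))
}

# Random walk of fixed step length confined to a ball; steps drift back
# toward the given center once the walk nears the boundary.
confined_walk <- function(n, step, radius, center = c(0, 0, 0)) {
  pts <- matrix(0, nrow = n, ncol = 3L)
  pos <- center
  pts[1L, ] <- pos
  for (i in seq_len(n - 1L)) {
    dir <- stats::rnorm(3L)
    r <- sqrt(sum((pos - center)^2))
    if (r > 0.7 * radius)  # bias inward near the boundary
      dir <- dir - 3 * (r / radius) * (pos - center) / r
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    pts[i + 1L, ] <- pos
  }
  pts
}

#' Generate a synthetic backbone trace
#'
#' @param spec A [fixture_spec()].
#' @param structure_id Identifier for the trace; defaults to
#'   `<family>_<seed>`.
#' @return A [backbone_trace()] with `4 * n_residues` atoms.
#' @examples
#' tr <- generate_trace(fixture_spec("ring", seed = 7))
#' range(sqrt(rowSums(sweep(tr$coords, 2, barycenter(tr))^2)))
#' @export
generate_trace <- function(spec, structure_id = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(structure_id))
    structure_id <- paste0(spec$family, "_", spec$seed)
  m <- 4L * spec$n_residues
  pts <- with_seed(spec$seed, {
    base <- switch(spec$family,
      globule = confined_walk(m, 1.5, spec$scale),
      two_lobe = {
        half <- m %/% 2L
        lobe_r <- 0.35 * spec$scale
        off <- c(0.6 * spec$scale, 0, 0)
        rbind(confined_walk(half, 1.5, lobe_r, -off),
              confined_walk(m - half, 1.5, lobe_r, off))
      },
      fixture_curve(spec$family, seq(0, 1, length.out = m), spec$scale))
    if (spec$noise_sd > 0)
      base <- base + matrix(stats::rnorm(3L * m, sd = spec$noise_sd), ncol = 3L)
    base
  })
  backbone_trace(structure_id,
                 residue_index = rep(seq_len(spec$n_residues), each = 4L),
                 atom_name = rep(c("N", "CA", "C", "O"), spec$n_residues),
                 coords = pts)
}

#' Write a backbone trace as a minimal PDB file
#'
#' Emits fixed-column `ATOM` records (one chain, poly-alanine residue
#' names) that round-trip through [parse_pdb()] at the format's 3-decimal
#' coordinate precision.
#'
#' @param trace A [backbone_trace()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb_trace <- function(trace, path) {
  stopifnot(inherits(trace, "backbone_trace"))
  n <- nrow(trace$coords)
  lines <- sprintf(
    "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), trace$atom_name, trace$residue_index,
    trace$coords[, 1L], trace$coords[, 2L], trace$coords[, 3L],
    substr(trace$atom_name, 1L, 1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Maps the six shape families to EC classes 1..6 (straight = EC1, helix
#' = EC2, ring = EC3, globule = EC4, ellipsoid = EC5, two_lobe = EC6),
#' writes each trace as a minimal PDB file plus a `labels.csv` table, and
#' returns the corresponding [labeled_samples()].  Per-sample seeds derive
#' from `seed`; each sample additionally jitters its scale by up to 10%
#' so classes are distributions, not a single shape.
#'
#' @param n_per_class Base number of samples per class.
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param imbalance Optional length-6 multipliers: class i receives
#'   `round(n_per_class * imbalance[i])` samples, for exercising
#'   class-weight adaptation.
#' @param n_residues Residues per trace.
#' @return A [labeled_samples()] data frame with `source` pointing at the
#'   written PDB files.
#' @export
generate_labeled_dataset <- function(n_per_class, dir = tempfile("fixtures"),
                                     seed = 1L, imbalance = rep(1, 6L),
                                     n_residues = 100L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (length(imbalance) != 6L || any(imbalance <= 0))
    stop("imbalance must be 6 positive multipliers")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2L) != 0L)
    stop("cannot write to directory: ", dir)
  families <- c("straight", "helix", "ring", "globule", "ellipsoid", "two_lobe")
  ids <- character(0); classes <- integer(0); sources <- character(0)
  for (k in seq_len(6L)) {
    n_k <- max(1L, round(n_per_class * imbalance[k]))
    for (i in seq_len(n_k)) {
      s_i <- derive_seed(seed, k * 100000 + i)
      jitter <- with_seed(s_i + 1, stats::runif(1L, 0.9, 1.1))
      spec <- fixture_spec(families[k], n_residues = n_residues,
                           seed = s_i)
      spec$scale <- spec$scale * jitter
      id <- sprintf("%s_%04d", families[k], i)
      tr <- generate_trace(spec, structure_id = id)
      p <- file.path(dir, paste0(id, ".pdb"))
      write_pdb_trace(tr, p)
      ids <- c(ids, id); classes <- c(classes, k); sources <- c(sources, p)
    }
  }
  samples <- labeled_samples(ids, classes, sources)
  utils::write.csv(
    data.frame(structure_id = samples$structure_id,
               ec_class = samples$ec_class, source = samples$source),
    file.path(dir, "labels.csv"), row.names = FALSE)
  samples
}

#' Build the synthetic benchmark split
#'
#' Generates the six-family synthetic dataset with a fixed per-class
#' train/test layout (validation optional), the configuration used to
#' exercise the full training pipeline at desk scale.
#'
#' @param n_train,n_test,n_validation Samples per class in each part.
#' @param dir Directory for the PDB files.
#' @param seed Integer master seed.
#' @param n_residues Residues per trace.
#' @return A `dataset_split`.
#' @export
synthetic_benchmark_split <- function(n_train = 60L, n_test = 30L,
                                      n_validation = 0L,
                                      dir = tempfile("bench"), seed = 1L,
                                      n_residues = 100L) {
  per_class <- n_train + n_test + n_validation
  samples <- generate_labeled_dataset(per_class, dir = dir, seed = seed,
                                      n_residues = n_residues)
  pick <- function(off, k) {
    idx <- unlist(lapply(1:6, function(cl) {
      which(samples$ec_class == cl)[off + seq_len(k)]
    }))
    d <- samples[idx, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  structure(list(train = pick(0L, n_train),
                 validation = pick(n_train, n_validation),
                 test = pick(n_train + n_validation, n_test)),
            class = "dataset_split", seed = as.integer(seed))
}
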