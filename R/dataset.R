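#' Labeled samples and label tables
#'
#' A labeled sample ties a structure ID and its PDB file to a top-level
#' EC class in 1..6.  Label tables are plain CSV with header
#' `structure_id,ec_class`.
#'
#' @param structure_id Character vector of structure IDs.
#' @param ec_class Integer vector of classes in 1..6.
#' @param source Character vector of PDB file paths (or fixture handles).
#' @return A data frame of class `labeled_samples`.
#' @export
labeled_samples <- function(structure_id, ec_class, source = NA_character_) {
  ec_class <- as.integer(ec_class)
  if (anyNA(ec_class) || !all(ec_class %in% 1:6))
    stop("ec_class must be an integer in 1..6")
  if (anyDuplicated(structure_id)) {
    dup <- unique(structure_id[duplicated(structure_id)])
    warning("rejecting multi-label structures: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    keep <- !structure_id %in% dup
    structure_id <- structure_id[keep]
    ec_class <- ec_class[keep]
    source <- if (length(source) > 1L) source[keep] else source
  }
  out <- data.frame(structure_id = as.character(structure_id),
                    ec_class = ec_class,
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_samples", "data.frame")
  out
}

#' Read a label table from CSV
#'
#' @param path CSV file with header `structure_id,ec_class` and optional
#'   `source` column.
#' @param pdb_dir Directory prepended to `<structure_id>.pdb` when the CSV
#'   has no `source` column.
#' @return A [labeled_samples()] data frame.
#' @export
read_labels <- function(path, pdb_dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("structure_id", "ec_class") %in% names(df)))
    stop("label CSV must have columns structure_id, ec_class")
  src <- if ("source" %in% names(df)) df$source
         else file.path(pdb_dir, paste0(df$structure_id, ".pdb"))
  labeled_samples(df$structure_id, df$ec_class, src)
}

#' Split samples into train / validation / test sets
#'
#' Unstratified uniform random split: 80/20 train/test, then 20% of the
#' training portion is held out for validation, giving approximately
#' 64/16/20% of the total.  Deterministic for a given seed.
#'
#' @param samples A [labeled_samples()] data frame.
#' @param seed Integer seed.
#' @param stratify Split within each class instead of overall (off by
#'   default; the unstratified split reproduces per-class proportions in
#'   expectation).
#' @return A list of class `dataset_split` with elements `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(samples, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(samples, "labeled_samples"))
  n <- nrow(samples)
  if (n < 5L) stop("need at least 5 samples to split")
  part_of <- function(idx, seed) {
    m <- length(idx)
    ord <- with_seed(seed, sample(idx))
    n_test <- round(0.2 * m)
    test <- ord[seq_len(n_test)]
    rest <- ord[-seq_len(n_test)]
    n_val <- round(0.2 * length(rest))
    list(test = test, validation = rest[seq_len(n_val)],
         train = rest[-seq_len(n_val)])
  }
  if (stratify) {
    parts <- lapply(sort(unique(samples$ec_class)), function(k)
      part_of(which(samples$ec_class == k), derive_seed(seed, k)))
    pick <- function(w) sort(unlist(lapply(parts, `[[`, w)))
  } else {
    p <- part_of(seq_len(n), seed)
    pick <- function(w) sort(p[[w]])
  }
  out <- list(train = samples[pick("train"), , drop = FALSE],
              validation = samples[pick("validation"), , drop = FALSE],
              test = samples[pick("test"), , drop = FALSE])
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  structure(out, class = "dataset_split", seed = as.integer(seed))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Write a split as plain-text ID lists
#'
#' One file per part (`train.txt`, `validation.txt`, `test.txt`) for
#' audit of which structures landed where.
#'
#' @param split A `dataset_split`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "dataset_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(split), function(w) {
    p <- file.path(dir, paste0(w, ".txt"))
    writeLines(split[[w]]$structure_id, p)
    p
  }, character(1L))
  invisible(paths)
}

#' Class weights countering class imbalance
#'
#' For training-set class counts `c_1..c_6`, the loss weight of class i is
#' `w_i = max_j(c_j) / c_i`: the largest class gets weight 1 exactly and
#' under-represented classes are up-weighted inversely to their size.
#'
#' @param train_counts Integer vector of per-class training counts, all
#'   at least 1.
#' @return Numeric vector of weights, `min(w) == 1`.
#' @examples
#' compute_class_weights(c(7096, 12081, 15290, 2875, 1703, 1632))
#' @export
compute_class_weights <- function(train_counts) {
  train_counts <- as.numeric(train_counts)
  if (length(train_counts) != 6L)
    stop("expected 6 per-class counts")
  if (anyNA(train_counts) || any(train_counts < 1))
    stop("all class counts must be >= 1")
  max(train_counts) / train_counts
}

#' Draw a random flip code
#'
#' Each axis is flipped independently with probability `p_flip`; at the
#' default `p_flip = 0.2` roughly half of samples per pass receive at
#' least one flip (1 - 0.8^3 = 0.488), and higher flip counts are rarer.
#'
#' @param p_flip Per-axis flip probability in `[0, 1]`.
#' @return A [flip_code()].
#' @export
draw_flip_code <- function(p_flip = 0.2) {
  if (p_flip < 0 || p_flip > 1) stop("p_flip must be in [0, 1]")
  f <- stats::runif(3L) < p_flip
  flip_code(f[1L], f[2L], f[3L])
}

#' Stochastic training stream of augmented voxel grids
#'
#' An iterator over the training portion of a split.  Each pass visits
#' every training sample once in a freshly shuffled order; each visit
#' draws an independent flip code (per-axis probability `p_flip`),
#' voxelizes the structure under that flip and pairs the grid with the
#' one-hot class label.  Grids are cached per (structure, flip code), so
#' repeated passes re-voxelize nothing.  Fully reproducible from `seed`;
#' per-pass shuffles and flip draws use seeds derived from it so passes
#' differ but the run is deterministic.
#'
#' @param split A `dataset_split`.
#' @param cfg A [voxelizer_config()].
#' @param p_flip Per-axis flip probability.
#' @param seed Integer master seed.
#' @return An object of class `training_stream` with `$next_item()`
#'   returning `list(grid, label, flip, structure_id)` (label is a one-hot
#'   length-6 vector), and `$pass` giving the current pass number.
#' @export
training_stream <- function(split, cfg = voxelizer_config(), p_flip = 0.2,
                            seed = 1L) {
  stopifnot(inherits(split, "dataset_split"))
  if (p_flip < 0 || p_flip > 1) stop("p_flip must be in [0, 1]")
  samples <- split$train
  n <- nrow(samples)
  if (n == 0L) stop("empty training split")
  cache <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$pass <- 0L
  state$pos <- 0L
  state$order <- integer(0)
  state$flips <- NULL

  start_pass <- function() {
    state$pass <- state$pass + 1L
    pass_seed <- derive_seed(seed, state$pass)
    with_seed(pass_seed, {
      state$order <- sample.int(n)
      state$flips <- matrix(stats::runif(3L * n) < p_flip, nrow = n)
    })
    state$pos <- 0L
  }

  traces <- new.env(parent = emptyenv())
  grid_for <- function(i, f) {
    id <- samples$structure_id[i]
    key <- paste0(id, ":", paste(unclass(f), collapse = ""))
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (is.null(traces[[id]]))
      traces[[id]] <- tryCatch(
        parse_pdb(samples$source[i], id, backbone_atoms = cfg$backbone_atoms),
        error = function(e) stop("sample '", id, "': ", conditionMessage(e)))
    g <- voxelize(traces[[id]], cfg, f)
    cache[[key]] <- g
    g
  }

  next_item <- function() {
    if (state$pos >= n || state$pass == 0L) start_pass()
    state$pos <- state$pos + 1L
    i <- state$order[state$pos]
    fr <- state$flips[state$pos, ]
    f <- flip_code(fr[1L], fr[2L], fr[3L])
    label <- numeric(6L)
    label[samples$ec_class[i]] <- 1
    list(grid = grid_for(i, f), label = label, flip = f,
         structure_id = samples$structure_id[i])
  }

  structure(list(next_item = next_item,
                 n_train = n,
                 pass = function() state$pass,
                 p_flip = p_flip),
            class = "training_stream")
}
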