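#' Decision configuration for test-time fusion
#'
#' At prediction time, the classifier can see only the unoriented volume
#' (`"none"`), or all flipped copies of it (`"flips"`), or all flipped
#' copies with each decision weighted by `1 / (dx + dy + dz + 1)`
#' (`"weighted_flips"`), favoring transformations with fewer flips.
#' Fused decisions are taken either on summed probabilities
#' (`mode = "probability"`) or by (weighted) majority vote over per-flip
#' class predictions (`mode = "class"`).
#'
#' @param strategy `"none"`, `"flips"` or `"weighted_flips"`.
#' @param mode `"probability"` or `"class"`; ignored when
#'   `strategy = "none"`.
#' @param include_identity Include the unflipped volume among the fused
#'   copies (8 codes) or use only the 2^3 - 1 proper flips (7 codes).
#' @return A `decision_config` list.
#' @export
decision_config <- function(strategy = c("none", "flips", "weighted_flips"),
                            mode = c("probability", "class"),
                            include_identity = TRUE) {
  structure(list(strategy = match.arg(strategy), mode = match.arg(mode),
                 include_identity = isTRUE(include_identity)),
            class = "decision_config")
}

#' Fusion coefficient of a flip code
#'
#' `1 / (dx + dy + dz + 1)`: 1 for the identity, decreasing with the
#' number of flipped axes, so less-transformed copies dominate the
#' weighted fusion.
#'
#' @param f A [flip_code()].
#' @return Scalar weight in (0, 1].
#' @export
flip_weight <- function(f) {
  stopifnot(inherits(f, "flip_code"))
  1 / (sum(unclass(f)) + 1)
}

#' Probability-based decision fusion
#'
#' Returns the class maximizing the coefficient-weighted sum of per-flip
#' probability vectors.  Ties break toward the lowest class index.
#'
#' @param per_flip_probs Matrix with one row per flip, one column per
#'   class.
#' @param coefficients Positive fusion coefficients, one per row
#'   (default all 1).
#' @return Integer class index.
#' @export
fuse_probability <- function(per_flip_probs,
                             coefficients = rep(1, nrow(rbind(per_flip_probs)))) {
  per_flip_probs <- rbind(per_flip_probs)
  if (nrow(per_flip_probs) == 0L) stop("no predictions to fuse")
  if (length(coefficients) != nrow(per_flip_probs) || any(coefficients <= 0))
    stop("need one positive coefficient per flip")
  totals <- as.numeric(crossprod(per_flip_probs, coefficients))
  which.max(totals)  # which.max takes the first maximum: lowest index
}

#' Class-based (majority-vote) decision fusion
#'
#' Each flip casts a vote for its predicted class, weighted by its
#' coefficient; the class with the largest summed vote wins.  Vote ties
#' break by larger coefficient-weighted summed probability (when
#' `per_flip_probs` is supplied), then by lowest class index.
#'
#' @param per_flip_classes Integer vector of per-flip predicted classes.
#' @param coefficients Positive fusion coefficients, one per flip.
#' @param per_flip_probs Optional probability matrix for tie-breaking.
#' @param n_classes Number of classes.
#' @return Integer class index.
#' @export
fuse_majority <- function(per_flip_classes,
                          coefficients = rep(1, length(per_flip_classes)),
                          per_flip_probs = NULL, n_classes = 6L) {
  n <- length(per_flip_classes)
  if (n == 0L) stop("no predictions to fuse")
  if (!all(per_flip_classes %in% seq_len(n_classes)))
    stop("class indices must be in 1..", n_classes)
  if (length(coefficients) != n || any(coefficients <= 0))
    stop("need one positive coefficient per flip")
  votes <- numeric(n_classes)
  for (j in seq_len(n))
    votes[per_flip_classes[j]] <- votes[per_flip_classes[j]] + coefficients[j]
  top <- which(votes >= max(votes) - 1e-12)
  if (length(top) > 1L && !is.null(per_flip_probs)) {
    per_flip_probs <- rbind(per_flip_probs)
    totals <- as.numeric(crossprod(per_flip_probs, coefficients))
    top <- top[totals[top] >= max(totals[top]) - 1e-12]
  }
  min(top)
}

#' Predict the final class of a structure with decision fusion
#'
#' Voxelizes the trace under each flip code of the configured strategy,
#' runs the classifier on every copy and aggregates per the decision
#' configuration.  With `strategy = "none"` a single unflipped grid is
#' classified.
#'
#' @param model A trained `enzyvox_model`.
#' @param trace A [backbone_trace()].
#' @param vox_cfg A [voxelizer_config()] with `l` equal to the model's
#'   input edge.
#' @param dec_cfg A [decision_config()].
#' @return A `prediction_result` list: `per_flip_probs` (n x 6),
#'   `flip_codes`, `coefficients`, `fused_scores` and `final_class`.
#' @export
predict_final <- function(model, trace, vox_cfg = voxelizer_config(),
                          dec_cfg = decision_config()) {
  stopifnot(inherits(model, "enzyvox_model"), inherits(trace, "backbone_trace"),
            inherits(dec_cfg, "decision_config"))
  codes <- if (dec_cfg$strategy == "none") list(flip_code())
           else all_flip_codes(include_identity = dec_cfg$include_identity)
  grids <- lapply(codes, function(f) voxelize(trace, vox_cfg, f))
  probs <- predict_probs(model, grids)
  coeff <- if (dec_cfg$strategy == "weighted_flips")
    vapply(codes, flip_weight, numeric(1L)) else rep(1, length(codes))
  final <- if (dec_cfg$strategy == "none" || dec_cfg$mode == "probability") {
    fuse_probability(probs, coeff)
  } else {
    fuse_majority(max.col(probs, ties.method = "first"), coeff,
                  per_flip_probs = probs, n_classes = ncol(probs))
  }
  fused <- as.numeric(crossprod(probs, coeff))
  structure(list(structure_id = trace$structure_id,
                 per_flip_probs = probs, flip_codes = codes,
                 coefficients = coeff, fused_scores = fused / sum(fused),
                 final_class = final),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s -> EC%d (n = %d flips)\n",
              x$structure_id, x$final_class, nrow(x$per_flip_probs)))
  invisible(x)
}
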