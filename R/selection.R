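split_label <- function(features, label_col = "label") {
  if (!label_col %in% names(features)) {
    stop(sprintf("no '%s' column in feature matrix", label_col))
  }
  schema <- attr(features, "schema")
  if (is.null(schema)) schema <- setdiff(names(features), c(label_col, "clip", "sex"))
  x <- features[, schema, drop = FALSE]
  y <- factor(features[[label_col]])
  fam <- attr(features, "families")
  if (is.null(fam)) fam <- stats::setNames(schema, schema)
  list(x = x, y = y, families = fam[schema])
}

#' Rank feature families by random-forest permutation importance
#'
#' Fits random forests on the features augmented with one row-permuted
#' "decoy" copy of every column (whose association with the label is
#' destroyed by construction), and measures mean out-of-bag permutation
#' importance, averaged over \code{n_repeats} independently seeded forests.
#' Importance is aggregated per feature family (e.g. all 12 MFCC
#' dimensions average into one \code{mfcc} score) when a family map is
#' present; the decoy importances (mean plus two standard deviations)
#' provide the elimination threshold.
#'
#' @param features Feature data.frame with a \code{label} column (see
#'   [extract_features()]).
#' @param ntree Trees per forest (default 2000).
#' @param n_repeats Number of forests averaged (default 5).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param per_family Aggregate importance per feature family (default TRUE).
#' @return List with \code{importances} (named, sorted descending),
#'   \code{ranking}, \code{threshold} (decoy mean + 2 sd),
#'   \code{threshold_kept} and the per-dimension raw importances.
#' @export
rank_importance <- function(features, ntree = 2000L, n_repeats = 5L, seed = 1L,
                            per_family = TRUE) {
  d <- split_label(features)
  if (nlevels(d$y) < 2L) stop("rank_importance: need at least 2 classes")
  if (nrow(d$x) < 10L) stop("rank_importance: need at least 10 rows")
  set.seed(seed)
  p <- ncol(d$x)
  imp_sum <- numeric(2L * p)
  for (r in seq_len(n_repeats)) {
    decoys <- as.data.frame(lapply(d$x, function(col) col[sample.int(nrow(d$x))]))
    names(decoys) <- paste0(".decoy.", names(d$x))
    aug <- cbind(d$x, decoys)
    rf <- randomForest::randomForest(x = aug, y = d$y, ntree = ntree,
                                     importance = TRUE)
    imp_sum <- imp_sum + randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  }
  imp <- imp_sum / n_repeats
  real <- imp[seq_len(p)]
  decoy <- imp[p + seq_len(p)]
  if (per_family) {
    fam <- d$families[names(d$x)]
    real <- tapply(real, fam, mean)
    real <- stats::setNames(as.numeric(real), names(real))
    decoy <- as.numeric(tapply(decoy, fam, mean))
  }
  # elimination threshold: under the null, real features and decoys are
  # exchangeable, so the decoy mean alone passes ~half of pure noise; two
  # decoy standard deviations above it gives a usable null control
  threshold <- mean(decoy) + 2 * stats::sd(decoy)
  if (is.na(threshold)) threshold <- mean(decoy)
  ranking <- names(sort(real, decreasing = TRUE))
  list(importances = sort(real, decreasing = TRUE), ranking = ranking,
       threshold = threshold,
       threshold_kept = ranking[sort(real, decreasing = TRUE)[ranking] > threshold],
       dimension_importances = imp[seq_len(p)], decoy_importances = decoy,
       ntree = ntree, n_repeats = n_repeats, seed = seed)
}

family_columns <- function(families, fams) names(families)[families %in% fams]

#' Two-step random-forest variable selection
#'
#' Step 1 (elimination): rank feature families by permutation importance
#' ([rank_importance()]) and drop those not exceeding the decoy-importance
#' threshold. Step 2 (interpretation): fit nested forests on
#' the top-1, top-2, ... surviving families and keep the smallest subset
#' whose out-of-bag error is within one standard error of the minimum.
#'
#' @inheritParams rank_importance
#' @return A \code{selection_result}: list with \code{importances},
#'   \code{ranking}, \code{threshold_kept}, \code{interpretation_set},
#'   \code{oob_errors}, \code{ntree}, \code{seed}.
#' @export
select_variables <- function(features, ntree = 2000L, n_repeats = 5L, seed = 1L,
                             per_family = TRUE) {
  rk <- rank_importance(features, ntree, n_repeats, seed, per_family)
  d <- split_label(features)
  kept <- rk$threshold_kept
  interpretation <- character(0)
  oob <- numeric(0)
  if (length(kept) > 0L) {
    set.seed(seed + 1L)
    n <- nrow(d$x)
    oob <- vapply(seq_along(kept), function(k) {
      cols <- if (per_family) family_columns(d$families, kept[seq_len(k)]) else kept[seq_len(k)]
      # OOB error averaged over several forests: a single forest's OOB
      # estimate is too noisy for the one-standard-error comparison
      mean(vapply(seq_len(max(n_repeats, 2L)), function(r) {
        rf <- randomForest::randomForest(x = d$x[, cols, drop = FALSE],
                                         y = d$y, ntree = ntree)
        mean(rf$predicted != d$y)
      }, numeric(1L)))
    }, numeric(1L))
    e_min <- min(oob)
    se <- sqrt(e_min * (1 - e_min) / n)
    k_best <- which(oob <= e_min + se)[1L]
    interpretation <- kept[seq_len(k_best)]
    names(oob) <- kept
  }
  structure(
    list(importances = rk$importances, ranking = rk$ranking,
         threshold = rk$threshold, threshold_kept = kept,
         interpretation_set = interpretation, oob_errors = oob,
         dimension_importances = rk$dimension_importances,
         ntree = ntree, n_repeats = n_repeats, seed = seed,
         per_family = per_family),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  cat("  ranking:        ", paste(x$ranking, collapse = ", "), "\n")
  cat("  threshold_kept: ", paste(x$threshold_kept, collapse = ", "), "\n")
  cat("  interpretation: ", paste(x$interpretation_set, collapse = ", "), "\n")
  invisible(x)
}

#' Reduce a feature matrix to the selected families
#'
#' @param features Feature data.frame (see [extract_features()]).
#' @param selection A \code{selection_result} (or character vector of
#'   family names).
#' @return The feature data.frame restricted to the selected columns (label
#'   and bookkeeping columns retained), with updated attributes.
#' @export
apply_selection <- function(features, selection) {
  fams <- if (inherits(selection, "selection_result")) {
    selection$interpretation_set
  } else selection
  d <- split_label(features)
  cols <- family_columns(d$families, fams)
  if (length(cols) == 0L) stop("apply_selection: empty selection")
  keep_extra <- intersect(c("label", "clip", "sex"), names(features))
  out <- features[, c(cols, keep_extra), drop = FALSE]
  attr(out, "schema") <- cols
  attr(out, "families") <- d$families[cols]
  out
}
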