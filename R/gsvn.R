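stratified_folds <- function(y, k) {
  y <- factor(y)
  if (any(table(y) < k)) {
    small <- names(which(table(y) < k))
    stop(sprintf("stratification error: class(es) %s have fewer than %d rows",
                 paste(small, collapse = ", "), k))
  }
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

standardizer <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, std) {
  scale(as.matrix(x), center = std$center, scale = std$scale)
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair of the grid by stratified k-fold
#' cross-validated accuracy of a single RBF-kernel SVM and returns the
#' maximizer. Ties are broken toward smaller C, then smaller gamma.
#' Features are z-scored with training-fold statistics inside each fold.
#'
#' @param features Feature data.frame with a \code{label} column.
#' @param C_grid Candidate regularization costs (default \code{c(1, 3, 33)}).
#' @param gamma_grid Candidate RBF bandwidths (default
#'   \code{seq(0.1, 5, by = 0.1)}).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with \code{C}, \code{gamma}, \code{accuracy}, and the full
#'   \code{results} data.frame.
#' @export
grid_search_svm <- function(features, C_grid = c(1, 3, 33),
                            gamma_grid = seq(0.1, 5, by = 0.1),
                            folds = 5L, seed = 1L) {
  d <- split_label(features)
  if (nlevels(d$y) < 2L) stop("grid_search_svm: need at least 2 classes")
  set.seed(seed)
  fold <- stratified_folds(d$y, folds)
  x <- as.matrix(d$x)
  grid <- expand.grid(gamma = gamma_grid, C = C_grid)
  acc <- numeric(nrow(grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    std <- standardizer(x[tr, , drop = FALSE])
    xtr <- apply_standardizer(x[tr, , drop = FALSE], std)
    xte <- apply_standardizer(x[!tr, , drop = FALSE], std)
    for (g in seq_len(nrow(grid))) {
      fit <- e1071::svm(x = xtr, y = d$y[tr], kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g], scale = FALSE)
      acc[g] <- acc[g] + mean(predict(fit, xte) == d$y[!tr]) / folds
    }
  }
  # ties broken by smaller C then smaller gamma: iterate in that order and
  # keep the first strict maximum
  ord <- order(grid$C, grid$gamma)
  best <- ord[1L]
  for (g in ord) if (acc[g] > acc[best] + 1e-12) best <- g
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best],
       results = cbind(grid, accuracy = acc)[ord, ])
}

vote_weight <- function(eps, n_classes, cap = log(1e6)) {
  if (eps >= (n_classes - 1) / n_classes) return(0)
  w <- log((1 - eps) / max(eps, 1e-12)) + log(n_classes - 1)
  max(0, min(w, cap))
}

#' Train a grouped-support-vector network
#'
#' Builds a committee of \code{n_members} RBF-kernel SVMs on
#' boosting-reweighted bootstrap resamples of the training set. Sample
#' weights start uniform; each round draws a weight-proportional bootstrap
#' resample, splits it 80:20 (stratified) into fit and validation parts,
#' fits an SVM with the shared (C, gamma), and earns the member a
#' SAMME-style vote weight \eqn{\ln((1-\epsilon)/\epsilon) + \ln(K-1)}
#' from its weighted validation error \eqn{\epsilon}. Training rows the
#' member misclassifies have their weights multiplied by
#' \eqn{e^{\mathrm{vote\ weight}}} before renormalization; members no
#' better than chance get vote weight 0 and reset the weights to uniform.
#' \code{mode = "bag"} disables reweighting (uniform resampling,
#' accuracy-proportional vote weights) for ablation.
#'
#' @param features Feature data.frame with a \code{label} column.
#' @param n_members Committee size (default 300).
#' @param C,gamma Shared SVM hyperparameters (see [grid_search_svm()]).
#' @param split Fit fraction of each resample (default 0.8).
#' @param seed Integer seed; training is deterministic given it.
#' @param mode \code{"boost"} (default) or \code{"bag"}.
#' @param unit Classification unit tag carried in the model
#'   (\code{"clip"} or \code{"frame"}).
#' @return A \code{gsvn} model object.
#' @export
train_gsvn <- function(features, n_members = 300L, C = 1, gamma = 0.1,
                       split = 0.8, seed = 1L, mode = c("boost", "bag"),
                       unit = "clip") {
  mode <- match.arg(mode)
  d <- split_label(features)
  if (nlevels(d$y) < 2L) stop("train_gsvn: need at least 2 classes")
  if (any(table(d$y) < 10L)) stop("train_gsvn: need at least 10 rows per class")
  set.seed(seed)
  x <- as.matrix(d$x)
  y <- d$y
  n <- nrow(x)
  K <- nlevels(y)
  std <- standardizer(x)
  xs <- apply_standardizer(x, std)
  w <- rep(1 / n, n)
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    for (try in 1:25) {
      # a degenerate weight distribution can make valid draws impossible;
      # after repeated failures reset the weights to uniform and redraw
      if (try > 20L) w <- rep(1 / n, n)
      idx <- if (mode == "boost") {
        sample.int(n, n, replace = TRUE, prob = w)
      } else {
        sample.int(n, n, replace = TRUE)
      }
      yb <- y[idx]
      fit_sel <- logical(n)
      for (cl in levels(y)) {
        pos <- which(yb == cl)
        if (length(pos) == 0L) next
        n_fit <- max(1L, floor(split * length(pos)))
        fit_sel[pos[sample.int(length(pos), n_fit)]] <- TRUE
      }
      if (length(unique(yb[fit_sel])) >= 2L && any(!fit_sel)) break
    }
    fit_idx <- idx[fit_sel]
    val_idx <- idx[!fit_sel]
    svm_fit <- e1071::svm(x = xs[fit_idx, , drop = FALSE], y = y[fit_idx],
                          kernel = "radial", cost = C, gamma = gamma,
                          scale = FALSE)
    val_pred <- predict(svm_fit, xs[val_idx, , drop = FALSE])
    val_acc <- mean(val_pred == y[val_idx])
    if (mode == "boost") {
      wv <- w[val_idx] / sum(w[val_idx])
      eps <- sum(wv * (val_pred != y[val_idx]))
      alpha <- vote_weight(eps, K)
      if (alpha == 0) {
        w <- rep(1 / n, n)
      } else {
        mis <- predict(svm_fit, xs) != y
        w <- w * exp(alpha * mis)
        w <- w / sum(w)
      }
    } else {
      alpha <- val_acc
    }
    members[[m]] <- list(svm = svm_fit, vote_weight = alpha,
                         val_accuracy = val_acc, C = C, gamma = gamma)
  }
  structure(
    list(members = members, classes = levels(y),
         schema = colnames(d$x), standardizer = std, C = C, gamma = gamma,
         split = split, mode = mode, unit = unit, seed = seed,
         families = d$families),
    class = "gsvn"
  )
}

#' @export
print.gsvn <- function(x, ...) {
  cat(sprintf("<gsvn> %d members (%s), classes: %s, C=%g gamma=%g\n",
              length(x$members), x$mode, paste(x$classes, collapse = "/"),
              x$C, x$gamma))
  invisible(x)
}

check_schema <- function(model, newdata) {
  missing <- setdiff(model$schema, names(newdata))
  extra <- setdiff(setdiff(names(newdata), c("label", "clip", "sex")),
                   model$schema)
  if (length(missing) > 0L || length(extra) > 0L) {
    stop(sprintf("schema mismatch: missing [%s], extra [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
}

#' Predict with a grouped-support-vector network
#'
#' Each committee member casts its vote weight for its predicted class; the
#' per-row class scores are the summed weights, normalized to sum to one,
#' and the label is the argmax (ties broken by class order in
#' \code{object$classes}).
#'
#' @param object A \code{gsvn} model.
#' @param newdata Feature data.frame conforming to the model schema.
#' @param ... Unused.
#' @return List with \code{labels} (factor) and \code{scores} (rows sum
#'   to 1).
#' @export
predict.gsvn <- function(object, newdata, ...) {
  check_schema(object, newdata)
  x <- apply_standardizer(as.matrix(newdata[, object$schema, drop = FALSE]),
                          object$standardizer)
  n <- nrow(x)
  K <- length(object$classes)
  scores <- matrix(0, nrow = n, ncol = K, dimnames = list(NULL, object$classes))
  for (mem in object$members) {
    if (mem$vote_weight <= 0 && length(object$members) > 1L) next
    p <- as.character(predict(mem$svm, x))
    wgt <- if (length(object$members) == 1L) max(mem$vote_weight, 1) else mem$vote_weight
    scores[cbind(seq_len(n), match(p, object$classes))] <-
      scores[cbind(seq_len(n), match(p, object$classes))] + wgt
  }
  tot <- rowSums(scores)
  zero <- tot == 0
  scores[zero, ] <- 1 / K
  scores[!zero, ] <- scores[!zero, , drop = FALSE] / tot[!zero]
  labels <- factor(object$classes[max.col(scores, ties.method = "first")],
                   levels = object$classes)
  list(labels = labels, scores = scores)
}

#' Aggregate frame predictions into a clip label
#'
#' For a frame-mode model, the clip label is the weighted plurality of the
#' frame labels, each frame vote weighted by its ensemble score margin
#' (top score minus runner-up). Ties are broken by class order.
#'
#' @param model A \code{gsvn} model with \code{unit = "frame"}.
#' @param frame_rows Feature rows of the clip's frames.
#' @return A single class label (character).
#' @export
predict_clip <- function(model, frame_rows) {
  stopifnot(model$unit == "frame")
  pr <- predict(model, frame_rows)
  sc <- pr$scores
  margin <- apply(sc, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    s[1L] - if (length(s) > 1L) s[2L] else 0
  })
  if (all(margin == 0)) margin <- rep(1, length(margin))
  votes <- tapply(margin, factor(pr$labels, levels = model$classes), sum,
                  default = 0)
  model$classes[which.max(votes)]
}
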