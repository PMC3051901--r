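# Linear soft-margin SVM built on the package's dual coordinate descent
# solver. Features are standardized (zero mean, unit variance on the training
# data) before fitting; the standardization is part of the stored model. The
# bias is realized as an augmented constant feature (B = 1).

SVM_C_GRID <- c(0.001, 0.01, 0.1, 1, 10, 100, 1000)

#' Fit a linear soft-margin SVM
#'
#' Minimizes `0.5 ||w||^2 + C sum max(0, 1 - y f(x))` with
#' `f(x) = w . x + b` by dual coordinate descent.
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y labels in \{-1, +1\}.
#' @param C soft-margin parameter.
#' @param standardize standardize columns on the training data.
#' @param max_iter,tol solver controls.
#' @return object of class `linear_svm` (weights, bias, C, standardization).
#' @export
linear_svm_fit <- function(X, y, C, standardize = TRUE, max_iter = 200,
                           tol = 1e-4) {
  X <- as.matrix(X)
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("both classes required to fit an SVM")
  if (standardize) {
    center <- colMeans(X)
    scale <- matrixStats::colSds(X)
    scale[scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  w <- svm_dcd(cbind(Xs, 1), as.numeric(y), C, max_iter, tol)
  structure(list(weights = w[seq_len(ncol(X))], bias = w[length(w)], C = C,
                 center = center, scale = scale),
            class = "linear_svm")
}

#' Decision scores of a linear SVM
#'
#' @param model `linear_svm` (or any list with weights/bias/center/scale).
#' @param X feature matrix.
#' @return numeric scores `w . x + b`.
#' @export
svm_score <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights)) {
    stop("feature dimension mismatch: model has ", length(model$weights),
         ", input has ", ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  drop(Xs %*% model$weights) + model$bias
}

# constant scorer used when a training bin contains a single class
constant_svm <- function(d, value) {
  structure(list(weights = rep(0, d), bias = value, C = NA_real_,
                 center = rep(0, d), scale = rep(1, d), constant = TRUE),
            class = "linear_svm")
}

#' Fit a monotone piecewise-linear probability calibration
#'
#' Isotonic regression of the 0/1 labels on the scores, followed by linear
#' interpolation between block centers (mean score and fitted probability of
#' each isotonic block), clipped to \[0, 1\].
#'
#' @param scores SVM decision scores.
#' @param labels 0/1 (or -1/+1) class labels.
#' @return object of class `calibration_map` (knots), or NULL with a warning
#'   when the scores are anti-correlated with the labels.
#' @export
fit_calibration <- function(scores, labels) {
  labels <- as.numeric(labels)
  labels[labels < 0] <- 0
  if (length(unique(labels)) < 2L) stop("calibration needs both classes")
  if (suppressWarnings(stats::cor(scores, labels)) < 0) {
    warning("scores anti-correlated with labels; calibration rejected")
    return(NULL)
  }
  o <- order(scores)
  iso <- stats::isoreg(scores[o], labels[o])
  fit <- iso$yf
  blocks <- cumsum(c(TRUE, diff(fit) != 0))
  knot_x <- as.vector(tapply(scores[o], blocks, mean))
  knot_y <- pmin(pmax(as.vector(tapply(fit, blocks, mean)), 0), 1)
  structure(list(knots = data.frame(score = knot_x, p = knot_y)),
            class = "calibration_map")
}

#' Apply a calibration map
#'
#' @param cal `calibration_map` (or NULL for a constant fallback).
#' @param scores decision scores.
#' @param fallback probability returned when `cal` is NULL.
#' @return calibrated probabilities in \[0, 1\].
#' @export
predict_calibrated <- function(cal, scores, fallback = 0.5) {
  if (is.null(cal)) return(rep(fallback, length(scores)))
  k <- cal$knots
  if (nrow(k) == 1L) return(rep(k$p, length(scores)))
  out <- stats::approx(k$score, k$p, xout = scores, rule = 2)$y
  pmin(pmax(out, 0), 1)
}
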