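# MDM classifier on covariance features and the SWLDA reference classifier,
# plus command-level selection for K-choice oddball paradigms.

#' Fit the minimum-distance-to-mean (MDM) classifier
#'
#' Computes the per-class geometric (Karcher) mean of the training
#' covariances, \eqn{\bar C_k = \mathfrak{G}(C_i \mid l_i = k)} for the
#' target (k = 1) and non-target (k = 2) classes.
#'
#' @param covs List of `spd` covariance matrices (super-trial features).
#' @param labels Integer class labels, 1 = target, 2 = non-target; both
#'   classes must be present.
#' @param tolerance,max_iterations Forwarded to [geometric_mean()].
#' @return An object of class `mdm_model` holding the two class means and
#'   the per-class training counts.
#' @export
mdm_fit <- function(covs, labels, tolerance = 1e-8, max_iterations = 50L) {
  stopifnot(is.list(covs), length(covs) == length(labels))
  labels <- as.integer(labels)
  for (k in c(1L, 2L)) {
    if (!any(labels == k)) {
      stop(sprintf("no training covariances for class %d", k))
    }
  }
  means <- lapply(c(1L, 2L), function(k) {
    geometric_mean(covs[labels == k], tolerance, max_iterations)
  })
  structure(
    list(means = means, counts = c(sum(labels == 1L), sum(labels == 2L)),
         dim = means[[1]]$dim),
    class = "mdm_model"
  )
}

#' Classify covariances by minimum Riemannian distance to the class means
#'
#' Implements \eqn{\hat l = \arg\min_k \delta_R(\bar C_k, C)}; an exact tie
#' is resolved to the smaller class index.
#'
#' @param model An [mdm_fit()] result.
#' @param covs A single `spd` matrix or a list of them.
#' @return Integer label(s) in `{1, 2}`.
#' @export
mdm_predict <- function(model, covs) {
  stopifnot(inherits(model, "mdm_model"))
  if (!is.list(covs) || inherits(covs, "spd")) covs <- list(covs)
  vapply(covs, function(cv) {
    d1 <- riemannian_distance(model$means[[1]], cv)
    d2 <- riemannian_distance(model$means[[2]], cv)
    if (d1 <= d2) 1L else 2L
  }, integer(1))
}

#' @export
print.mdm_model <- function(x, ...) {
  cat(sprintf(
    "<mdm_model: %d x %d class means (target J = %d, non-target J = %d)>\n",
    x$dim, x$dim, x$counts[1], x$counts[2]
  ))
  invisible(x)
}

#' Decide the attended command of one oddball selection round
#'
#' Given one feature per stimulus code 1..K, scores each code by how much
#' more target-like than non-target-like it is and picks the arg-max
#' (smallest code on an exact tie).  For the MDM model the score is
#' \eqn{\delta_R(C, \bar C_2) - \delta_R(C, \bar C_1)}; for the SWLDA model
#' it is the linear discriminant score.
#'
#' @param model An `mdm_model` or `swlda_model`.
#' @param x For MDM, a list of K `spd` covariances ordered (or named) by
#'   stimulus code; for SWLDA, a K x F feature matrix with one row per code.
#' @param ... Unused.
#' @return An object of class `command_decision` with fields `scores` and
#'   `decided_command`.
#' @export
command_select <- function(model, x, ...) UseMethod("command_select")

order_by_code <- function(x) {
  if (!is.null(names(x))) {
    codes <- suppressWarnings(as.integer(names(x)))
    if (anyNA(codes) || !setequal(codes, seq_along(x))) {
      stop("need exactly one entry per stimulus code 1..K")
    }
    x <- x[order(codes)]
  }
  x
}

new_command_decision <- function(scores) {
  structure(
    list(scores = scores, decided_command = which.max(scores)),
    class = "command_decision"
  )
}

#' @rdname command_select
#' @export
command_select.mdm_model <- function(model, x, ...) {
  x <- order_by_code(x)
  scores <- vapply(x, function(cv) {
    riemannian_distance(model$means[[2]], cv) -
      riemannian_distance(model$means[[1]], cv)
  }, numeric(1))
  new_command_decision(unname(scores))
}

#' @rdname command_select
#' @export
command_select.swlda_model <- function(model, x, ...) {
  new_command_decision(as.numeric(swlda_scores(model, x)))
}

#' @export
print.command_decision <- function(x, ...) {
  cat(sprintf("<command_decision: %d of %d (scores %s)>\n",
              x$decided_command, length(x$scores),
              paste(sprintf("%.3f", x$scores), collapse = ", ")))
  invisible(x)
}

# ---- SWLDA --------------------------------------------------------------

#' Decimated ERP amplitude features for SWLDA
#'
#' Bins each epoch channel into `n_bins` equal time bins (mean amplitude
#' within each bin; 50 bins of 20 ms for a 1000 ms epoch) and concatenates
#' the channels, giving `F = N * n_bins` features per trial — the standard
#' feature construction for P300 stepwise discriminant classifiers.
#'
#' @param epochs An [epoch_set()] or a trials x channels x samples array.
#' @param n_bins Number of time bins per channel.
#' @return Numeric matrix, trials x (channels * n_bins).
#' @export
swlda_features <- function(epochs, n_bins = 50L) {
  arr <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  d <- dim(arr)
  M <- d[3]
  if (n_bins > M) stop("more bins than samples per epoch")
  edges <- round(seq(0, M, length.out = n_bins + 1))
  bin_of <- rep(seq_len(n_bins), times = diff(edges))
  counts <- tabulate(bin_of, n_bins)
  out <- matrix(0, d[1], d[2] * n_bins)
  for (i in seq_len(d[1])) {
    e <- arr[i, , , drop = FALSE]
    dim(e) <- d[2:3]
    binned <- t(rowsum(t(e), bin_of, reorder = TRUE)) / rep(counts, each = d[2])
    out[i, ] <- as.vector(t(binned)) # channel-major: ch1 bins, ch2 bins, ...
  }
  out
}

# Entry p-values of all candidate features given an already-selected set:
# partial-F test (1 numerator df) of adding each candidate to the OLS
# regression of y on [1, x[, selected]].  Computed by residualising y and
# the candidates against the current design, so one step costs O(n * F).
swlda_entry_pvalues <- function(x, y, selected = integer(0)) {
  n <- nrow(x)
  Q <- qr.Q(qr(cbind(1, x[, selected, drop = FALSE])))
  Z <- x - Q %*% (t(Q) %*% x)
  yr <- as.numeric(y - Q %*% (t(Q) %*% y))
  z2 <- colSums(Z^2)
  yr2 <- sum(yr^2)
  df2 <- n - length(selected) - 2
  p <- rep(NA_real_, ncol(x))
  if (df2 < 1 || yr2 <= 0) return(p)
  usable <- z2 > 1e-10 * pmax(colSums(x^2), 1)
  r2 <- as.numeric(crossprod(Z, yr))^2 / (z2 * yr2)
  r2 <- pmin(r2, 1 - 1e-15)
  f <- df2 * r2 / (1 - r2)
  p[usable] <- stats::pf(f[usable], 1, df2, lower.tail = FALSE)
  p[selected] <- NA_real_
  p
}

ols_pvalues <- function(x, y, selected) {
  X <- cbind(1, x[, selected, drop = FALSE])
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  cov_diag <- diag(chol2inv(qr.R(qx))) * sigma2
  tval <- beta / sqrt(cov_diag)
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, p = p[-1], df = df)
}

#' Fit a stepwise linear discriminant (SWLDA) model
#'
#' Forward-stepwise ordinary-least-squares regression of the class labels
#' (coded +1 for targets, -1 for non-targets) on decimated amplitude
#' features: at each step the candidate with the smallest partial-F p-value
#' enters if below `p_enter`; after every addition any included feature
#' whose p-value has risen above `p_remove` is removed.  Selection stops at
#' `max_features` or when no candidate passes the entry threshold.
#' Zero-variance feature columns are skipped, not fatal.  If nothing enters
#' the model is intercept-only and prediction falls back to the majority
#' class.
#'
#' @param x Feature matrix, trials x F (see [swlda_features()]).
#' @param labels Integer class labels, 1 = target, 2 = non-target.
#' @param p_enter Entry p-value threshold (default 0.10).
#' @param p_remove Removal p-value threshold (default 0.15).
#' @param max_features Maximum number of retained features (default 60).
#' @return An object of class `swlda_model`.
#' @export
swlda_fit <- function(x, labels, p_enter = 0.10, p_remove = 0.15,
                      max_features = 60L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- as.integer(labels)
  if (!all(c(1L, 2L) %in% labels)) {
    stop("training data must contain both classes")
  }
  y <- ifelse(labels == 1L, 1, -1)
  n <- nrow(x)
  selected <- integer(0)
  steps <- 0L

  repeat {
    # guard against enter/remove cycling, a classical stepwise pathology
    steps <- steps + 1L
    if (steps > 5L * max_features) break
    if (length(selected) >= max_features) break
    p_in <- swlda_entry_pvalues(x, y, selected)
    if (all(is.na(p_in))) break
    j <- which.min(p_in)
    if (!(p_in[j] < p_enter)) break
    selected <- c(selected, j)
    # backward pass
    repeat {
      if (length(selected) < 1) break
      p_out <- ols_pvalues(x, y, selected)$p
      worst <- which.max(p_out)
      if (p_out[worst] > p_remove && length(selected) > 1) {
        selected <- selected[-worst]
      } else if (p_out[worst] > p_remove && length(selected) == 1) {
        selected <- integer(0)
        break
      } else {
        break
      }
    }
  }

  if (length(selected) > 0) {
    fit <- ols_pvalues(x, y, selected)
    weights <- unname(fit$beta[-1])
    intercept <- unname(fit$beta[1])
  } else {
    weights <- numeric(0)
    intercept <- mean(y)
  }
  structure(
    list(selected_features = selected, weights = weights,
         intercept = intercept, p_enter = p_enter, p_remove = p_remove,
         max_features = max_features, n_features = ncol(x)),
    class = "swlda_model"
  )
}

#' Linear discriminant scores of an SWLDA model
#'
#' @param model An [swlda_fit()] result.
#' @param x Feature matrix with the same number of columns as at training.
#' @return Numeric score per row; positive means target-like.
#' @export
swlda_scores <- function(model, x) {
  stopifnot(inherits(model, "swlda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) {
    stop(sprintf("feature length %d does not match training length %d",
                 ncol(x), model$n_features))
  }
  if (length(model$selected_features) == 0) {
    return(rep(model$intercept, nrow(x)))
  }
  as.numeric(x[, model$selected_features, drop = FALSE] %*% model$weights +
               model$intercept)
}

#' Predict target / non-target labels with an SWLDA model
#'
#' A strictly positive score is classified as target (label 1); a score of
#' exactly zero is non-target (label 2) by convention.
#'
#' @inheritParams swlda_scores
#' @return Integer labels in `{1, 2}`.
#' @export
swlda_predict <- function(model, x) {
  ifelse(swlda_scores(model, x) > 0, 1L, 2L)
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf(
    "<swlda_model: %d of %d features selected (p_enter %.2f, p_remove %.2f)>\n",
    length(x$selected_features), x$n_features, x$p_enter, x$p_remove
  ))
  invisible(x)
}
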