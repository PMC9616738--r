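# Gradient-boosted encoding/decoding models. Encoding predicts a unit's
# spike counts from behavioural variables (Poisson objective); decoding
# predicts a behavioural variable from the simultaneously recorded count
# matrix (squared-error objective). Data are bisected into two halves along
# time (respecting epoch boundaries); the first half trains, the second is
# the held-out evaluation set, scored by Pearson correlation.

# Row indices of the first temporal half, split at an epoch boundary when
# epoch labels are available.
#' @keywords internal
first_half_idx <- function(n, epoch = NULL) {
  if (is.null(epoch)) return(seq_len(floor(n / 2)))
  eps <- unique(epoch)
  csum <- 0L; take <- integer(0)
  for (e in eps) {
    idx <- which(epoch == e)
    take <- c(take, idx)
    csum <- csum + length(idx)
    if (csum >= n / 2) break
  }
  take
}

#' Gradient-boosted prediction of counts or behaviour
#'
#' Boosted regression trees (learning rate 0.025, 500 rounds, maximum depth
#' 3, gamma 1, subsample 1, CPU histogram method). Count targets use the
#' Poisson log-likelihood objective; continuous targets squared error.
#' The series is bisected into two equal halves (at an epoch boundary when
#' epochs are given); accuracy is the Pearson correlation between
#' prediction and target on the held-out second half.
#'
#' @param features Numeric matrix or data frame of predictors (bins x p).
#' @param target Numeric response vector.
#' @param direction `"encode"` (target = counts, Poisson loss) or
#'   `"decode"` (continuous target, squared error).
#' @param epoch Optional epoch label per bin, used for the half split.
#' @param nrounds,learning_rate,max_depth,gamma Booster hyperparameters.
#' @param seed Integer seed.
#' @return An object of class `prediction_result`: `accuracy` (held-out
#'   Pearson), `direction`, `predictors`, `n_train`, `n_test`, `predicted`,
#'   `observed`.
#' @export
fit_predictive_model <- function(features, target,
                                 direction = c("encode", "decode"),
                                 epoch = NULL, nrounds = 500L,
                                 learning_rate = 0.025, max_depth = 3L,
                                 gamma = 1, seed = 1L) {
  direction <- match.arg(direction)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(target)
  ok <- stats::complete.cases(X) & is.finite(y)
  n_rej <- sum(!ok)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  epoch <- if (is.null(epoch)) NULL else epoch[ok]
  n <- length(y)
  if (n < 4L) stop_invalid("too few usable bins")
  tr <- first_half_idx(n, epoch)
  te <- setdiff(seq_len(n), tr)
  params <- list(objective = if (direction == "encode") "count:poisson"
                 else "reg:squarederror",
                 eta = learning_rate, max_depth = max_depth, gamma = gamma,
                 subsample = 1, tree_method = "hist", nthread = 1L,
                 seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  pred <- stats::predict(booster, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
  acc <- if (stats::sd(pred) == 0 || stats::sd(y[te]) == 0) 0
         else stats::cor(pred, y[te])
  structure(list(accuracy = acc, direction = direction,
                 predictors = colnames(X), n_train = length(tr),
                 n_test = length(te), n_rejected = n_rej,
                 predicted = pred, observed = y[te]),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s from {%s}: held-out r = %.3f (train %d / test %d)\n",
              x$direction, paste(x$predictors, collapse = ", "),
              x$accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' Half-swap shift control
#'
#' Breaks the association between a feature series and the response by
#' splitting the series into two equally long halves and swapping their
#' order, preserving the temporal structure within each half. Applying it
#' twice to an even-length series restores the original.
#'
#' @param features Vector, matrix or data frame (time runs along rows).
#' @return The shifted object, same shape as the input.
#' @export
shift_control <- function(features) {
  if (is.null(dim(features))) {
    n <- length(features)
    if (n < 2L) stop_invalid("need at least 2 bins")
    k <- floor(n / 2)
    return(c(features[(k + 1L):n], features[seq_len(k)]))
  }
  n <- nrow(features)
  if (n < 2L) stop_invalid("need at least 2 bins")
  k <- floor(n / 2)
  features[c((k + 1L):n, seq_len(k)), , drop = FALSE]
}
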