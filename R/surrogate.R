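#' Fit the flavonoid-yield surrogate model
#'
#' The package's central fitting function. Given a condition-to-yield
#' table, it (1) fits per-column min-max scaling on the data, (2) scales
#' inputs and target, (3) initializes a single-hidden-layer tanh network
#' and (4) trains it by Levenberg-Marquardt (or scaled conjugate gradient)
#' backpropagation. With multiple `restarts` the fit with the lowest final
#' training MSE is kept. With 25 records and a 9-11-1 network (122 free
#' parameters) the model is heavily over-parameterized and interpolates the
#' training set; it is a surrogate for optimization, not a predictive model
#' with generalization guarantees.
#'
#' @param data Fermentation data.frame with the yield column.
#' @param hidden Hidden-layer width (default 11) or `"select"` to choose it
#'   by [select_hidden_size()] over 3:13.
#' @param control A [train_config()].
#' @param scale_range Output interval of the scaler, `c(0, 1)` or `c(-1, 1)`.
#' @param restarts Number of random initializations tried (default 1); the
#'   lowest-MSE fit is returned.
#' @param seed Integer seed; restart `i` uses `seed + i - 1`.
#' @param select_args Named list of extra arguments for
#'   [select_hidden_size()] when `hidden = "select"` (e.g. `candidates`,
#'   `folds`, `restarts`, `config`).
#' @return Object of class `flavone_surrogate` with components `network`,
#'   `scaler`, `report`, `data`, `hidden`, `seed`, `seeds_tried`, `call`.
#' @seealso [predict.flavone_surrogate()], [optimize_medium()]
#' @export
#' @examples
#' fit <- fit_surrogate(table1_fixture(), seed = 1)
#' fit
fit_surrogate <- function(data, hidden = 11L, control = train_config(),
                          scale_range = c(0, 1), restarts = 1L, seed = 1L,
                          select_args = list()) {
  cl <- match.call()
  data <- validate_dataset(data, has_target = TRUE)
  scaler <- fit_scaler(data, range = scale_range)
  sets <- .scaled_training_set(data, scaler)
  if (identical(hidden, "select")) {
    hidden <- do.call(select_hidden_size,
                      c(list(inputs = sets$x, targets = sets$y, seed = seed),
                        select_args))
  }
  hidden <- as.integer(hidden)
  best <- NULL
  seeds <- seed + seq_len(restarts) - 1L
  for (s in seeds) {
    net0 <- init_network(ncol(sets$x), hidden, seed = s)
    fit <- train_network(net0, sets$x, sets$y, control)
    if (is.null(best) || fit$report$final_mse < best$report$final_mse) {
      best <- fit
      best$seed <- s
    }
  }
  structure(list(network = best$net, scaler = scaler, report = best$report,
                 data = data, hidden = hidden, seed = best$seed,
                 seeds_tried = seeds, control = control, call = cl),
            class = "flavone_surrogate")
}

#' @export
print.flavone_surrogate <- function(x, ...) {
  cat(sprintf("Flavonoid-yield surrogate: %d-%d-1 network (tanh/linear), %d training records\n",
              x$network$n_in, x$hidden, nrow(x$data)))
  cat(sprintf("  trainer: %s, %d epochs, final scaled MSE %.6g (%s)\n",
              x$control$algorithm, x$report$epochs_run, x$report$final_mse,
              if (x$report$converged) "reached target" else "stopped at epoch limit"))
  cat(sprintf("  init seed %d; scaler range [%g, %g]\n",
              x$seed, x$scaler$range[1], x$scaler$range[2]))
  invisible(x)
}

#' Predict yields from a fitted surrogate
#'
#' @param object A `flavone_surrogate`.
#' @param newdata Data.frame with the nine component columns, a length-9
#'   vector, or an `n x 9` matrix in canonical component order. Defaults to
#'   the training data.
#' @param ... Unused.
#' @return Predicted total flavonoid yields in ug/mL.
#' @export
predict.flavone_surrogate <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.data.frame(newdata)) {
    missing <- setdiff(medium_components(), names(newdata))
    if (length(missing)) stop("newdata lacks component column(s): ",
                              paste(missing, collapse = ", "))
    newdata <- as.matrix(newdata[medium_components()])
  }
  predict_production(object$network, object$scaler, newdata)
}

#' @export
fitted.flavone_surrogate <- function(object, ...) {
  predict(object)
}

#' @export
residuals.flavone_surrogate <- function(object, ...) {
  object$data[[.target_column]] - fitted(object)
}

#' @export
coef.flavone_surrogate <- function(object, ...) {
  net <- object$network
  nm <- c(
    as.vector(outer(seq_len(net$n_hidden), seq_len(net$n_in),
                    function(j, k) sprintf("W1[%d,%d]", j, k))),
    sprintf("b1[%d]", seq_len(net$n_hidden)),
    sprintf("W2[1,%d]", seq_len(net$n_hidden)),
    "b2"
  )
  stats::setNames(.pack_params(net), nm)
}

#' @export
summary.flavone_surrogate <- function(object, ...) {
  res <- residuals(object)
  env <- rbind(min = object$scaler$x_min[medium_components()],
               max = object$scaler$x_max[medium_components()])
  out <- list(fit = object, residual_summary = summary(res),
              raw_rmse = sqrt(mean(res^2)), training_envelope = env,
              n_parameters = length(.pack_params(object$network)),
              n_records = nrow(object$data))
  class(out) <- "summary.flavone_surrogate"
  out
}

#' @export
print.summary.flavone_surrogate <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d parameters for %d records (interpolating surrogate)\n",
              x$n_parameters, x$n_records))
  cat(sprintf("  training RMSE on the raw scale: %.4g ug/mL\n", x$raw_rmse))
  cat("  residuals (ug/mL):\n")
  print(x$residual_summary)
  cat("  training envelope (per component):\n")
  print(x$training_envelope)
  invisible(x)
}

#' Diagnostic plots for a fitted surrogate
#'
#' Two panels: the accepted-step training-MSE trajectory (log scale) and
#' observed versus fitted yields on the raw scale.
#'
#' @param x A `flavone_surrogate`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.flavone_surrogate <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$report$mse_history
  graphics::plot(seq_along(h) - 1L, h, type = "l", log = "y",
                 xlab = "accepted epoch", ylab = "training MSE (scaled)",
                 main = "Training convergence", ...)
  obs <- x$data[[.target_column]]
  fit <- fitted(x)
  graphics::plot(fit, obs, xlab = "fitted yield (ug/mL)",
                 ylab = "observed yield (ug/mL)", main = "Observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
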