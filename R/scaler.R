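#' Fit per-column min-max scaling parameters
#'
#' Records, for every column of the training table (the nine components and
#' the yield), the observed minimum and maximum. These define the affine
#' map `y = (x - x_min) / (x_max - x_min)` sending the training range of
#' each column onto the unit interval; with `range = c(-1, 1)` the variant
#' `2y - 1` is used instead. Columns whose minimum equals their maximum are
#' flagged degenerate and rejected at scaling time rather than silently
#' producing NaN.
#'
#' @param data A fermentation data.frame (target column included when
#'   present).
#' @param range Output interval, `c(0, 1)` (default, the formula as
#'   printed) or `c(-1, 1)`.
#' @return An object of class `minmax_scaler`: list with `x_min`, `x_max`,
#'   `range` and logical `degenerate`, all keyed by column name.
#' @seealso [scale_value()], [inverse_scale()]
#' @export
#' @examples
#' sc <- fit_scaler(table1_fixture())
#' sc$x_min[["glucose"]]; sc$x_max[["glucose"]]
fit_scaler <- function(data, range = c(0, 1)) {
  data <- validate_dataset(data)
  if (!identical(range, c(0, 1)) && !identical(range, c(-1, 1))) {
    stop("`range` must be c(0, 1) or c(-1, 1)")
  }
  m <- as.matrix(data)
  x_min <- apply(m, 2, min)
  x_max <- apply(m, 2, max)
  structure(list(x_min = x_min, x_max = x_max, range = range,
                 degenerate = x_max == x_min),
            class = "minmax_scaler")
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat("Min-max scaler over", length(x$x_min), "columns, output range [",
      x$range[1], ",", x$range[2], "]\n")
  tab <- data.frame(x_min = x$x_min, x_max = x$x_max,
                    degenerate = x$degenerate)
  print(tab)
  invisible(x)
}

.check_scaler_column <- function(scaler, column) {
  if (!inherits(scaler, "minmax_scaler")) stop("`scaler` must be a minmax_scaler")
  if (!(column %in% names(scaler$x_min))) stop("unknown column '", column, "'")
  if (scaler$degenerate[[column]]) {
    stop("column '", column, "' is degenerate (constant in the training set); ",
         "drop or impute it before scaling")
  }
  invisible(TRUE)
}

#' Min-max scale raw values
#'
#' Applies the fitted affine map of one column to raw values. Values
#' outside the training envelope map outside the output interval:
#' extrapolation is permitted and never clamped, since the optimizer must
#' be free to query the surrogate beyond the training range.
#'
#' @param x Numeric vector of raw values.
#' @param column Column name.
#' @param scaler A [fit_scaler()] object.
#' @return Scaled values.
#' @export
#' @examples
#' sc <- fit_scaler(table1_fixture())
#' scale_value(c(20, 22.5, 25), "glucose", sc)  # 0, 0.5, 1
scale_value <- function(x, column, scaler) {
  .check_scaler_column(scaler, column)
  y <- (x - scaler$x_min[[column]]) / (scaler$x_max[[column]] - scaler$x_min[[column]])
  if (identical(scaler$range, c(-1, 1))) y <- 2 * y - 1
  y
}

#' Invert min-max scaling
#'
#' Maps scaled values back to the raw measurement scale; the exact inverse
#' of [scale_value()] up to floating-point round-off. Needed to report
#' surrogate predictions in micrograms per milliliter.
#'
#' @inheritParams scale_value
#' @param y Numeric vector of scaled values.
#' @return Raw-scale values.
#' @export
inverse_scale <- function(y, column, scaler) {
  .check_scaler_column(scaler, column)
  if (identical(scaler$range, c(-1, 1))) y <- (y + 1) / 2
  scaler$x_min[[column]] + y * (scaler$x_max[[column]] - scaler$x_min[[column]])
}

# scale a dataset into the (inputs, target) matrices the trainer consumes;
# inputs: n x 9 matrix in canonical component order, target: length-n vector
.scaled_training_set <- function(data, scaler) {
  data <- validate_dataset(data, has_target = TRUE)
  comps <- medium_components()
  x <- matrix(0, nrow(data), length(comps), dimnames = list(NULL, comps))
  for (j in comps) x[, j] <- scale_value(data[[j]], j, scaler)
  y <- scale_value(data[[.target_column]], .target_column, scaler)
  list(x = x, y = y)
}

#' Scale a chromosome matrix into network inputs
#'
#' Scales raw component concentrations (one chromosome per row, canonical
#' component order) with a fitted scaler, producing the matrix fed to the
#' surrogate network.
#'
#' @param chromosomes Numeric vector of length 9 or an n x 9 matrix.
#' @param scaler A [fit_scaler()] object.
#' @return An n x 9 matrix of scaled inputs.
#' @export
scale_chromosomes <- function(chromosomes, scaler) {
  comps <- medium_components()
  if (is.null(dim(chromosomes))) chromosomes <- matrix(chromosomes, nrow = 1)
  if (ncol(chromosomes) != length(comps)) {
    stop("chromosomes must have ", length(comps), " columns (one per component)")
  }
  if (any(!is.finite(chromosomes))) stop("chromosome values must be finite")
  out <- chromosomes
  colnames(out) <- comps
  for (j in seq_along(comps)) out[, j] <- scale_value(chromosomes[, j], comps[j], scaler)
  out
}
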