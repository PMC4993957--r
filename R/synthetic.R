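#' Specify a synthetic response surface
#'
#' Defines a known ground-truth yield surface over the nine-component
#' concentration box, used to validate the whole pipeline by parameter
#' recovery: because the true optimum is known, the hybrid method's best
#' chromosome can be compared against it. The default surface is a
#' separable negative quadratic with a unique interior maximum — the
#' simplest surface for which recovery is provable — with an optional
#' `"multimodal"` variant that superimposes a cosine ripple for stress
#' tests. Yields emulate the magnitude of real flavonoid measurements
#' (peak 2000 ug/mL, worst corner about 650 ug/mL under the defaults);
#' they do not emulate heteroscedastic assay error, batch effects, or the
#' discreteness of designed experiments.
#'
#' @param optimum Length-9 vector, the location of the true maximum
#'   (default: the box center). Must lie inside the bounds box.
#' @param peak Yield at the optimum, ug/mL (default 2000).
#' @param curvature Per-component quadratic drop (ug/mL) from the optimum
#'   to the box edge along that axis; scalar or length-9 (default 150, so
#'   the worst corner of the default box sits at 2000 - 9*150 = 650).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   yields (default 0).
#' @param n_samples Number of records to generate (>= 10, default 100).
#' @param bounds 9 x 2 bounds matrix (default [default_bounds()]).
#' @param surface `"quadratic"` or `"multimodal"`.
#' @param ripple Amplitude of the multimodal cosine term (ug/mL,
#'   default 50; ignored for the quadratic surface).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(optimum = NULL, peak = 2000, curvature = 150,
                           noise_sd = 0, n_samples = 100L,
                           bounds = default_bounds(),
                           surface = c("quadratic", "multimodal"),
                           ripple = 50, seed = 1L) {
  surface <- match.arg(surface)
  bounds <- as.matrix(bounds)
  if (is.null(optimum)) optimum <- rowMeans(bounds)
  if (length(optimum) != 9L) stop("optimum must have 9 components")
  if (any(optimum < bounds[, 1] | optimum > bounds[, 2])) {
    stop("optimum must lie inside the bounds box")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_samples < 10L) stop("n_samples must be >= 10")
  curvature <- rep_len(curvature, 9L)
  structure(list(optimum = stats::setNames(optimum, medium_components()),
                 peak = peak, curvature = curvature, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), bounds = bounds,
                 surface = surface, ripple = ripple, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ground-truth yield function of a synthetic specification
#'
#' @param spec A [synthetic_spec()].
#' @return A function mapping an `n x 9` chromosome matrix (or length-9
#'   vector) to true yields in ug/mL.
#' @export
synthetic_surface <- function(spec) {
  b <- spec$bounds
  width <- pmax(b[, 2] - b[, 1], .Machine$double.eps)
  opt <- spec$optimum
  curv <- spec$curvature
  force(spec)
  function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    u <- sweep(sweep(m, 2, opt, "-"), 2, width / 2, "/")  # normalized offset
    y <- spec$peak - drop(u^2 %*% curv)
    if (spec$surface == "multimodal") {
      y <- y + spec$ripple * rowMeans(cos(3 * pi * u))
    }
    y
  }
}

#' Generate a synthetic condition-to-yield dataset
#'
#' Samples chromosomes uniformly over the bounds box and labels them with
#' the ground-truth surface plus Gaussian noise. The true optimum, peak
#' and spec are attached as attributes so that recovery can be scored.
#'
#' @param spec A [synthetic_spec()].
#' @return A fermentation data.frame with attributes `"true_optimum"`,
#'   `"true_peak"`, `"spec"` and `"provenance"`.
#' @export
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_samples = 20, seed = 7))
#' attr(d, "true_peak")
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  set.seed(spec$seed)
  b <- spec$bounds
  m <- matrix(0, spec$n_samples, 9L, dimnames = list(NULL, medium_components()))
  for (j in seq_len(9L)) m[, j] <- stats::runif(spec$n_samples, b[j, 1], b[j, 2])
  f <- synthetic_surface(spec)
  y <- f(m) + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
  if (any(y <= 0)) {
    stop("synthetic yields include non-positive values; raise `peak`, ",
         "lower `curvature`/`ripple`, or reduce `noise_sd`")
  }
  out <- as.data.frame(m)
  out$total_flavonoids <- y
  out <- validate_dataset(out)
  attr(out, "provenance") <- sprintf(
    "synthetic %s surface, peak %g ug/mL at known interior optimum, noise sd %g, seed %d",
    spec$surface, spec$peak, spec$noise_sd, spec$seed)
  attr(out, "true_optimum") <- spec$optimum
  attr(out, "true_peak") <- spec$peak
  attr(out, "spec") <- spec
  out
}
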