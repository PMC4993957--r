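#' Training configuration for the surrogate network
#'
#' Bundles the trainer choice and its stopping/damping hyperparameters.
#' Two batch trainers are provided, selected by `algorithm`:
#' `"levenberg_marquardt"` (default), a damped Gauss-Newton least-squares
#' method, and `"scaled_conjugate_gradient"`, Moller's Hessian-free
#' conjugate-gradient method. Training stops when the training MSE (in
#' scaled units) drops to `target_mse` or after `max_epochs` accepted
#' steps, whichever comes first.
#'
#' @param algorithm `"levenberg_marquardt"` or `"scaled_conjugate_gradient"`.
#' @param target_mse Stopping threshold on the scaled-units training MSE
#'   (default 0.019, just above the published achieved error of 0.018999).
#' @param max_epochs Maximum number of accepted update steps (default 1000;
#'   0 is allowed and performs no training).
#' @param seed Optional seed applied before weight initialization when the
#'   caller asks the trainer to initialize.
#' @param lm_lambda0 Initial Levenberg-Marquardt damping (default 1e-3).
#' @param lm_factor Damping multiplier: divided out after an accepted step,
#'   multiplied in after a rejected one (default 10).
#' @return An object of class `train_config`.
#' @export
train_config <- function(algorithm = c("levenberg_marquardt", "scaled_conjugate_gradient"),
                         target_mse = 0.019, max_epochs = 1000L, seed = NULL,
                         lm_lambda0 = 1e-3, lm_factor = 10) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(target_mse) || target_mse <= 0) stop("target_mse must be > 0")
  if (max_epochs < 0) stop("max_epochs must be >= 0")
  if (lm_lambda0 <= 0 || lm_factor <= 1) stop("invalid LM damping settings")
  structure(list(algorithm = algorithm, target_mse = target_mse,
                 max_epochs = as.integer(max_epochs), seed = seed,
                 lm_lambda0 = lm_lambda0, lm_factor = lm_factor),
            class = "train_config")
}

.train_report <- function(history, target_mse) {
  final <- history[length(history)]
  list(final_mse = final, epochs_run = length(history) - 1L,
       mse_history = history, converged = final <= target_mse)
}

#' Train the surrogate network by backpropagation
#'
#' Batch training of the feedforward surrogate on scaled input/target
#' pairs. The Levenberg-Marquardt branch solves the damped normal
#' equations `(J'J + lambda I) step = -J'r` each epoch, accepting the step
#' only if the MSE decreases (damping is divided by `lm_factor` on
#' acceptance and multiplied on rejection, so ill-conditioned systems
#' escalate damping rather than crash); the accepted-step MSE sequence is
#' therefore non-increasing. The scaled-conjugate-gradient branch follows
#' Moller's algorithm with the standard constants (sigma = 5e-5, initial
#' raise factor 5e-7) and also only ever accepts error-reducing steps.
#'
#' @param net Initial network from [init_network()].
#' @param inputs `n x n_in` matrix of scaled inputs.
#' @param targets Length-`n` vector of scaled targets.
#' @param config A [train_config()].
#' @return List with elements `net` (trained network) and `report` (list:
#'   `final_mse`, `epochs_run`, `mse_history` including the initial MSE at
#'   position 1, `converged`).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(runif(10), 5, 2)
#' y <- x %*% c(1, -1)
#' fit <- train_network(init_network(2, 3, seed = 1), x, drop(y),
#'                      train_config(target_mse = 1e-10, max_epochs = 200))
#' fit$report$final_mse
train_network <- function(net, inputs, targets, config = train_config()) {
  inputs <- .as_input_matrix(net, inputs)
  if (nrow(inputs) != length(targets)) stop("inputs and targets disagree in length")
  if (length(targets) == 0L) stop("empty training data")
  if (!inherits(config, "train_config")) stop("`config` must be a train_config")
  switch(config$algorithm,
         levenberg_marquardt = .train_lm(net, inputs, targets, config),
         scaled_conjugate_gradient = .train_scg(net, inputs, targets, config))
}

.train_lm <- function(net, x, t, config) {
  theta <- .pack_params(net)
  p <- length(theta)
  mse0 <- nn_mse(.unpack_params(net, theta), x, t)
  if (!is.finite(mse0)) stop("non-finite loss at epoch 0")
  history <- mse0
  lambda <- config$lm_lambda0
  epoch <- 0L
  while (epoch < config$max_epochs && mse0 > config$target_mse) {
    rj <- .resid_jacobian(.unpack_params(net, theta), x, t)
    JtJ <- crossprod(rj$J)
    Jtr <- crossprod(rj$J, rj$r)
    improved <- FALSE
    while (!improved && lambda < 1e12) {
      step <- tryCatch(solve(JtJ + diag(lambda, p), -Jtr), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + drop(step)
        mse1 <- nn_mse(.unpack_params(net, cand), x, t)
        if (is.finite(mse1) && mse1 < mse0) {
          theta <- cand
          mse0 <- mse1
          lambda <- max(lambda / config$lm_factor, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * config$lm_factor
    }
    if (!improved) break  # no improving step exists at any damping: converged
    epoch <- epoch + 1L
    history <- c(history, mse0)
  }
  list(net = .unpack_params(net, theta),
       report = .train_report(history, config$target_mse))
}

.train_scg <- function(net, x, t, config) {
  E <- function(th) nn_mse(.unpack_params(net, th), x, t)
  dE <- function(th) nn_gradient(.unpack_params(net, th), x, t)
  sigma0 <- 5e-5
  w <- .pack_params(net)
  ew <- E(w)
  if (!is.finite(ew)) stop("non-finite loss at epoch 0")
  history <- ew
  lambda <- 5e-7; lambda_bar <- 0
  r <- -dE(w); pdir <- r
  success <- TRUE
  delta <- 0; mu <- 0
  epoch <- 0L
  n_par <- length(w)
  k <- 0L
  while (epoch < config$max_epochs && ew > config$target_mse) {
    k <- k + 1L
    p2 <- sum(pdir^2)
    if (p2 < 1e-30) break  # zero search direction: gradient vanished
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (dE(w + sigma * pdir) + r) / sigma   # +r == -(-dE(w))
      delta <- sum(pdir * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {                            # make the Hessian model positive definite
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(pdir * r)
    alpha <- mu / delta
    ew_new <- E(w + alpha * pdir)
    if (!is.finite(ew_new)) stop("non-finite loss at epoch ", epoch + 1L)
    Delta <- 2 * delta * (ew - ew_new) / mu^2
    if (Delta >= 0) {                            # accepted, error-reducing step
      w <- w + alpha * pdir
      ew <- ew_new
      r_new <- -dE(w)
      lambda_bar <- 0
      success <- TRUE
      if (k %% n_par == 0L) {
        pdir <- r_new                            # periodic restart
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        pdir <- r_new + beta * pdir
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      epoch <- epoch + 1L
      history <- c(history, ew)
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e20) break                     # damping exhausted: no reducing step
  }
  list(net = .unpack_params(net, w),
       report = .train_report(history, config$target_mse))
}

#' Choose the hidden-layer size by cross-validation
#'
#' The hidden-layer width is picked from a candidate range (3--13 by
#' convention for this problem) as the size whose predicted-vs-actual
#' discrepancy is smallest, operationalized as k-fold cross-validated MSE
#' averaged over several random restarts per fold. Ties break toward the
#' smaller network.
#'
#' @param inputs `n x n_in` matrix of scaled inputs.
#' @param targets Length-`n` vector of scaled targets.
#' @param candidates Integer vector of hidden sizes to score (default 3:13).
#' @param folds Number of cross-validation folds (default 5).
#' @param restarts Random restarts per (candidate, fold) (default 3).
#' @param seed Seed controlling fold assignment and restart initializations.
#' @param config [train_config()] used for each inner fit; the default uses
#'   a tighter `target_mse` and fewer epochs than the final fit because the
#'   inner models are scored on held-out error, not trained to a
#'   convergence story.
#' @return The selected hidden size (integer), with the per-candidate CV
#'   MSE table attached as attribute `"cv_mse"`.
#' @export
select_hidden_size <- function(inputs, targets, candidates = 3:13,
                               folds = 5L, restarts = 3L, seed = 1L,
                               config = train_config(target_mse = 1e-4,
                                                     max_epochs = 200L)) {
  if (length(candidates) == 0L) stop("candidate range is empty")
  candidates <- sort(unique(as.integer(candidates)))
  n <- length(targets)
  if (n < folds) stop("need at least as many records as folds")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv <- stats::setNames(numeric(length(candidates)), candidates)
  for (ci in seq_along(candidates)) {
    h <- candidates[ci]
    errs <- c()
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      for (r in seq_len(restarts)) {
        net0 <- init_network(ncol(inputs), h, seed = seed + 1009L * h + 31L * f + r)
        fit <- train_network(net0, inputs[tr, , drop = FALSE], targets[tr], config)
        errs <- c(errs, nn_mse(fit$net, inputs[!tr, , drop = FALSE], targets[!tr]))
      }
    }
    cv[ci] <- mean(errs)
  }
  best <- candidates[which.min(cv)]  # candidates sorted: ties go to the smaller
  attr(best, "cv_mse") <- cv
  best
}
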