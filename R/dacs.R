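# Three-stage post-hoc recalibration, fit on the validation split and applied
# to held-out logits, in fixed order:
#   raw logits -> class-conditioned temperature scaling
#              -> uncertainty-based logit shrinkage
#              -> smoothed-prior log-odds injection
#              -> softmax.

T_MIN <- 0.05
T_MAX <- 20

nll_of <- function(probs, labels) {
  mean(-log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

#' Class-conditioned temperature scaling
#'
#' Divides each class's logit by its own temperature, `z_k / T_k`, and
#' renormalizes with softmax. A scalar `T` is broadcast to all classes;
#' `T = 1` is the identity.
#'
#' @param z Logit matrix (`n x K`) or vector.
#' @param T_vec Positive temperature scalar or length-`K` vector.
#' @return List with `logits` (scaled) and `probs` (softmax of the scaled
#'   logits; rows sum to one).
#' @export
temperature_scale <- function(z, T_vec) {
  if (any(T_vec <= 0)) stop_mm("temperatures must be positive")
  vec_in <- is.null(dim(z))
  if (vec_in) z <- matrix(z, nrow = 1L)
  if (length(T_vec) == 1L) T_vec <- rep(T_vec, ncol(z))
  if (length(T_vec) != ncol(z)) stop_mm("temperature vector length mismatch")
  zs <- sweep(z, 2L, T_vec, `/`)
  p <- softmax_rows(zs)
  if (vec_in) list(logits = drop(zs), probs = drop(p))
  else list(logits = zs, probs = p)
}

#' Fit calibration temperatures by validation likelihood
#'
#' Minimizes the negative log-likelihood of `labels` under
#' `softmax(z_k / T_k)` on a validation set. `mode = "global"` fits one
#' scalar (broadcast to all classes); `mode = "per_class"` runs bounded
#' coordinate descent from `T = 1` (sweep tolerance `1e-4`, at most 50
#' sweeps) and additionally from the broadcast global optimum, keeping the
#' lower-NLL solution — so the per-class fit never does worse than the global
#' one it nests.
#'
#' @param logits Validation logit matrix (`n x K`).
#' @param labels Validation labels in `1..K`; per-class mode requires every
#'   class to be present.
#' @param mode `"global"` or `"per_class"`.
#' @return Temperature vector of length `K` in `[0.05, 20]`, with attribute
#'   `"nll"` (achieved validation NLL).
#' @export
fit_temperatures <- function(logits, labels, mode = c("global", "per_class")) {
  mode <- match.arg(mode)
  logits <- as.matrix(logits)
  K <- ncol(logits)
  nll_T <- function(T_vec) {
    nll_of(temperature_scale(logits, T_vec)$probs, labels)
  }
  g <- stats::optimize(function(lt) nll_T(rep(exp(lt), K)),
                       lower = log(T_MIN), upper = log(T_MAX), tol = 1e-6)
  T_global <- rep(exp(g$minimum), K)
  if (mode == "global") {
    return(structure(T_global, nll = g$objective))
  }
  if (!all(seq_len(K) %in% labels)) {
    stop_mm("per_class temperature fitting requires every class in the ",
            "validation labels")
  }
  descend <- function(T_start) {
    T_cur <- T_start
    for (sweep_i in seq_len(50L)) {
      T_old <- T_cur
      for (k in seq_len(K)) {
        o <- stats::optimize(function(tk) {
          T_try <- T_cur
          T_try[k] <- tk
          nll_T(T_try)
        }, lower = T_MIN, upper = T_MAX, tol = 1e-5)
        T_cur[k] <- o$minimum
      }
      if (max(abs(T_cur - T_old)) < 1e-4) break
    }
    T_cur
  }
  cands <- list(descend(rep(1, K)), descend(T_global), T_global)
  nlls <- purrr::map_dbl(cands, nll_T)
  best <- which.min(nlls)
  structure(cands[[best]], nll = nlls[best])
}

#' Uncertainty-based logit shrinkage
#'
#' Divides each sample's (temperature-scaled) logits by `1 + gamma_u * u`,
#' flattening the softmax toward uniform as the epistemic uncertainty `u`
#' grows while preserving the arg-max; the identity when `u = 0` or
#' `gamma_u = 0`.
#'
#' @param scaled_logits Logit matrix (`n x K`) or vector.
#' @param u Nonnegative per-sample uncertainty (scalar or length `n`).
#' @param gamma_u Nonnegative modulation weight.
#' @return Adjusted logits with the shape of the input.
#' @export
uncertainty_adjust <- function(scaled_logits, u, gamma_u) {
  if (any(u < 0)) stop_mm("u must be nonnegative")
  if (gamma_u < 0) stop_mm("gamma_u must be nonnegative")
  vec_in <- is.null(dim(scaled_logits))
  if (vec_in) scaled_logits <- matrix(scaled_logits, nrow = 1L)
  if (length(u) == 1L) u <- rep(u, nrow(scaled_logits))
  out <- scaled_logits / (1 + gamma_u * u)
  if (vec_in) drop(out) else out
}

#' Log-odds of prior probabilities
#'
#' `delta_k = log(pi_k / (1 - pi_k))`: converts per-class prior probabilities
#' into additive logit biases. Antisymmetric: `log_odds(1 - p) = -log_odds(p)`.
#'
#' @param p Probabilities strictly inside `(0, 1)`.
#' @return Numeric vector of log-odds.
#' @export
#' @examples
#' log_odds(c(0.5, 0.9)) # 0, log 9
log_odds <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop_mm("prior probabilities must lie strictly in (0, 1); ",
            "smooth boundary values upstream")
  }
  log(p / (1 - p))
}

#' Smooth an expert prior toward the empirical class frequencies
#'
#' Elementwise convex combination `beta * pi + (1 - beta) * pi_hat`: `beta = 1`
#' trusts the expert prior fully, `beta = 0` the data.
#'
#' @param prior Expert prior probabilities (entries in `(0, 1)`; not required
#'   to sum to one, each class is treated marginally).
#' @param empirical Empirical class frequencies.
#' @param beta Smoothing coefficient in `[0, 1]`.
#' @return Smoothed prior vector.
#' @export
smooth_prior <- function(prior, empirical, beta) {
  if (beta < 0 || beta > 1) stop_mm("beta must lie in [0, 1]")
  if (length(prior) != length(empirical)) stop_mm("prior length mismatch")
  beta * prior + (1 - beta) * empirical
}

#' Add weighted prior log-odds to logits
#'
#' `z_k + lambda_prior * delta_k`; the identity at `lambda_prior = 0`.
#'
#' @param z Logit matrix (`n x K`) or vector.
#' @param delta Length-`K` log-odds vector.
#' @param lambda_prior Nonnegative prior weight.
#' @return Adjusted logits.
#' @export
adjust_logits <- function(z, delta, lambda_prior) {
  if (lambda_prior < 0) stop_mm("lambda_prior must be nonnegative")
  vec_in <- is.null(dim(z))
  if (vec_in) z <- matrix(z, nrow = 1L)
  if (length(delta) != ncol(z)) stop_mm("delta length mismatch")
  out <- sweep(z, 2L, lambda_prior * delta, `+`)
  if (vec_in) drop(out) else out
}

#' Softmax of recalibrated logits
#'
#' @param z Adjusted logit matrix or vector.
#' @return Probabilities summing to one per row.
#' @export
calibrated_probs <- function(z) softmax_rows(z)

#' Fit the full calibration on a validation split
#'
#' Stage 1 fits the temperature vector by validation NLL
#' ([fit_temperatures()]). Stage 2 picks the uncertainty weight `gamma_u`
#' over the grid `{0, 0.1, 1, 10, 100}` by validation NLL (skipped, i.e.
#' fixed at 0, when no uncertainties are supplied). Stage 3 smooths the
#' expert prior toward add-one-smoothed empirical train frequencies
#' ([smooth_prior()]) and picks the prior weight `lambda_prior` over
#' `{0, 0.25, 0.5, 1, 2}` by validation NLL.
#'
#' @param logits Validation logit matrix (`n x K`).
#' @param labels Validation labels in `1..K`.
#' @param u Optional per-sample uncertainties (length `n`).
#' @param train_class_counts Per-class counts from the *train* split, used for
#'   the empirical prior (add-one smoothed). Defaults to the validation label
#'   tally with a warning.
#' @param prior Expert prior probabilities per class (entries in `(0,1)`);
#'   defaults to the empirical prior (making smoothing a no-op).
#' @param beta Prior smoothing coefficient in `[0, 1]` (default 0.5).
#' @param temperature_mode `"per_class"` (default) or `"global"`.
#' @param gamma_grid,lambda_grid Search grids for the two weights.
#' @return An object of class `mm_calibration` holding `T_vec`, `gamma_u`,
#'   `lambda_prior`, `beta`, `prior`, `empirical`, `smoothed`, `delta`, and
#'   the validation NLL after each stage.
#' @export
fit_calibration <- function(logits, labels, u = NULL,
                            train_class_counts = NULL,
                            prior = NULL, beta = 0.5,
                            temperature_mode = "per_class",
                            gamma_grid = c(0, 0.1, 1, 10, 100),
                            lambda_grid = c(0, 0.25, 0.5, 1, 2)) {
  logits <- as.matrix(logits)
  K <- ncol(logits)
  if (is.null(train_class_counts)) {
    warning("train_class_counts not supplied; using validation frequencies",
            call. = FALSE)
    train_class_counts <- tabulate(labels, nbins = K)
  }
  empirical <- (train_class_counts + 1) / (sum(train_class_counts) + K)
  if (is.null(prior)) prior <- empirical
  if (any(prior <= 0 | prior >= 1)) stop_mm("prior entries must be in (0, 1)")
  smoothed <- smooth_prior(prior, empirical, beta)
  delta <- log_odds(smoothed)

  T_vec <- fit_temperatures(logits, labels, mode = temperature_mode)
  nll_temp <- attr(T_vec, "nll")
  zT <- temperature_scale(logits, T_vec)$logits

  if (is.null(u)) {
    gamma_u <- 0
    nll_unc <- nll_temp
  } else {
    if (length(u) != nrow(logits)) stop_mm("u must have one entry per row")
    nlls <- purrr::map_dbl(gamma_grid, function(g) {
      nll_of(softmax_rows(uncertainty_adjust(zT, u, g)), labels)
    })
    gamma_u <- gamma_grid[which.min(nlls)]
    nll_unc <- min(nlls)
  }
  zU <- uncertainty_adjust(zT, u %||% 0, gamma_u)

  nlls <- purrr::map_dbl(lambda_grid, function(l) {
    nll_of(softmax_rows(adjust_logits(zU, delta, l)), labels)
  })
  lambda_prior <- lambda_grid[which.min(nlls)]
  nll_prior <- min(nlls)

  structure(
    list(
      T_vec = as.numeric(T_vec), gamma_u = gamma_u,
      lambda_prior = lambda_prior, beta = beta,
      prior = prior, empirical = empirical, smoothed = smoothed,
      delta = delta, temperature_mode = temperature_mode,
      val_nll = c(uncalibrated = nll_of(softmax_rows(logits), labels),
                  temperature = nll_temp, uncertainty = nll_unc,
                  prior = nll_prior)
    ),
    class = "mm_calibration"
  )
}

#' @export
print.mm_calibration <- function(x, ...) {
  cat("<mm_calibration> T =", paste(signif(x$T_vec, 4), collapse = ", "), "\n")
  cat("  gamma_u =", x$gamma_u, " lambda_prior =", x$lambda_prior,
      " beta =", x$beta, "\n")
  cat("  val NLL:", paste(names(x$val_nll), signif(x$val_nll, 5),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Calibration parameters as a tibble
#'
#' @param x An `mm_calibration`.
#' @param ... Unused.
#' @return One row per class: temperature, priors, log-odds.
#' @export
tidy.mm_calibration <- function(x, ...) {
  tibble::tibble(
    class = seq_along(x$T_vec),
    temperature = x$T_vec,
    prior = x$prior,
    empirical = x$empirical,
    smoothed = x$smoothed,
    delta = x$delta
  )
}

#' Apply the calibration pipeline to logits
#'
#' Fixed stage order: raw logits are temperature-scaled, shrunk by the
#' uncertainty modulation, shifted by the weighted prior log-odds, and passed
#' through softmax. All intermediate logits are recorded.
#'
#' @param logits Logit matrix (`n x K`) or tibble of logit columns.
#' @param params An `mm_calibration` from [fit_calibration()].
#' @param u Optional per-sample uncertainties (required to have an effect
#'   when `gamma_u > 0`; defaults to 0).
#' @return An object of class `mm_calibrated`: `probs` (tibble `p1..pK` +
#'   `.pred`) and `stages` (list of logit matrices `raw`, `temperature`,
#'   `uncertainty`, `prior`).
#' @export
calibrate_pipeline <- function(logits, params, u = NULL) {
  if (!inherits(params, "mm_calibration")) {
    stop_mm("params must come from fit_calibration()")
  }
  z <- as.matrix(logits)
  zT <- temperature_scale(z, params$T_vec)$logits
  zU <- uncertainty_adjust(zT, u %||% 0, params$gamma_u)
  zP <- adjust_logits(zU, params$delta, params$lambda_prior)
  p <- calibrated_probs(zP)
  out <- tibble::as_tibble(p, .name_repair = ~ paste0("p", seq_len(ncol(p))))
  out$.pred <- apply(p, 1L, argmax_first)
  structure(
    list(probs = out,
         stages = list(raw = z, temperature = zT, uncertainty = zU,
                       prior = zP),
         params = params),
    class = "mm_calibrated"
  )
}

#' @export
print.mm_calibrated <- function(x, ...) {
  cat("<mm_calibrated>", nrow(x$probs), "samples,",
      ncol(x$probs) - 1L, "classes\n")
  invisible(x)
}

#' Write calibration parameters to a portable JSON file
#'
#' @param params An `mm_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(params, path) {
  obj <- unclass(params)
  obj$val_nll <- as.list(obj$val_nll)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read calibration parameters written by [write_calibration()]
#'
#' @param path JSON path.
#' @return An `mm_calibration`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  obj$val_nll <- unlist(obj$val_nll)
  structure(obj, class = "mm_calibration")
}
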