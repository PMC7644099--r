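#' Fit a hierarchical GP mixed-effects model of growth curves
#'
#' The main fitting interface.  Models log optical density as a sum of
#' smooth latent functions with Gaussian-process priors: a mean curve, a
#' treatment effect per non-reference level (or a two-factor functional
#' ANOVA with interaction), and -- depending on `model` -- GP random
#' effects per batch for every fixed effect (`"batch"`), plus a per-well
#' replicate GP (`"full"`).  All latent functions are integrated out
#' analytically and the kernel hyperparameters are sampled by NUTS.
#'
#' @param formula optional one-sided formula naming the experimental
#'   factor(s), e.g. `~ stress` or `~ pH * acid`; `~ 1` fits a mean curve
#'   only.  Defaults to all factors in the data.
#' @param data a [growth_data] object, or a long data.frame passed to
#'   [growth_data()].
#' @param model hierarchy: `"null"` (fixed effects only), `"batch"`, or
#'   `"full"`.
#' @param preset lengthscale prior preset, see [default_priors()].
#' @param priors optional prior list from [default_priors()].
#' @param reference named list of reference (control) levels per factor.
#' @param dialect kernel dialect, see [rbf_kernel()].
#' @param log_transform,standardize_time preprocessing applied to raw data,
#'   see [preprocess()].
#' @param time,od,batch,replicate column names when `data` is a data.frame.
#' @inheritParams sample_posterior
#' @return an object of class `gpgrowth` with components `data`, `model`,
#'   `samples`, `validation` and `call`; see [predict.gpgrowth()],
#'   [summary.gpgrowth()], [variance_components()].
#' @examples
#' sim <- simulate_growth(sim_design(
#'   factors = list(stress = c("none", "high")),
#'   batches = 2, replicates = 2, times = seq(0, 48, length.out = 10)),
#'   model = "batch", seed = 1)
#' fit <- gpgrowth(~stress, sim$data, model = "batch", chains = 2,
#'                 iter = 50, warmup = 50, seed = 1)
#' coef(fit)
#' @export
gpgrowth <- function(formula = NULL, data, model = c("batch", "null",
                                                     "full"),
                     preset = c("halobacterium", "pseudomonas"),
                     priors = NULL, reference = NULL,
                     dialect = c("as_printed", "squared_lengthscale"),
                     log_transform = TRUE, standardize_time = TRUE,
                     time = "time", od = "od", batch = "batch",
                     replicate = "replicate",
                     chains = 4L, iter = 1000L, warmup = 1000L, seed = 1L,
                     target_accept = 0.8, max_treedepth = 10L,
                     fix = NULL, method = c("auto", "reduced", "dense"),
                     verbose = FALSE) {
  model <- match.arg(model)
  preset <- match.arg(preset)
  dialect <- match.arg(dialect)
  method <- match.arg(method)
  cl <- match.call()

  fvars <- if (!is.null(formula)) all.vars(formula) else NULL
  if (is.data.frame(data)) {
    gd <- growth_data(data, time = time, value = od, batch = batch,
                      replicate = replicate, factors = fvars)
  } else {
    stopifnot(inherits(data, "growth_data"))
    gd <- data
    if (!is.null(fvars)) {
      bad <- setdiff(fvars, gd$factors)
      if (length(bad) > 0L)
        stop("design error: unknown factor(s) in formula: ",
             paste(bad, collapse = ", "))
      gd$factors <- fvars
      gd$levels <- gd$levels[fvars]
    }
  }
  if (!gd$log_transformed && log_transform)
    gd <- preprocess(gd, log_transform = TRUE,
                     standardize_time = standardize_time)
  else if (standardize_time)
    gd <- preprocess(gd, log_transform = FALSE, standardize_time = TRUE)

  val <- validate_design(gd, model)
  if (any(val$severity == "error"))
    stop("design error: ", paste(val$message[val$severity == "error"],
                                 collapse = "; "))
  for (m in val$message[val$severity == "warning"]) warning(m)

  if (is.null(priors)) priors <- default_priors(preset)
  mdef <- build_model(model, gd, priors = priors, reference = reference,
                      dialect = dialect)
  t0 <- Sys.time()
  samples <- sample_posterior(gd, mdef, chains = chains, iter = iter,
                              warmup = warmup, seed = seed,
                              target_accept = target_accept,
                              max_treedepth = max_treedepth, fix = fix,
                              method = method, verbose = verbose)
  structure(list(call = cl, data = gd, model = mdef, samples = samples,
                 validation = val,
                 runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "gpgrowth")
}

#' @export
print.gpgrowth <- function(x, ...) {
  cat(sprintf("gpgrowth fit: M_%s, %d curves, %d observations\n",
              x$model$kind, nrow(x$data$curves), nrow(x$data$data)))
  r <- suppressWarnings(rhat(x$samples))
  cat(sprintf("  chains: %d x %d draws; max split R-hat %.3f; %d divergent\n",
              x$samples$config$chains, x$samples$config$iter,
              max(r, na.rm = TRUE), sum(x$samples$divergent)))
  cat("posterior means of hyperparameters:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object a `gpgrowth` fit.
#' @param prob central interval probability.
#' @param ... unused.
#' @return a list with the per-parameter posterior summary table, the
#'   variance-component table and the divergence count.
#' @export
summary.gpgrowth <- function(object, prob = 0.95, ...) {
  out <- list(summary = posterior_summary(object$samples, prob = prob),
              variance_components = variance_components(object,
                                                        prob = prob),
              divergent = sum(object$samples$divergent),
              model = object$model$kind)
  class(out) <- "summary.gpgrowth"
  out
}

#' @export
print.summary.gpgrowth <- function(x, ...) {
  cat(sprintf("M_%s hyperparameter posterior:\n", x$model))
  print(x$summary, digits = 3)
  bad <- x$summary$parameter[!is.na(x$summary$rhat) & x$summary$rhat >= 1.1]
  if (length(bad) > 0L)
    cat("  ** R-hat >= 1.1 for:", paste(bad, collapse = ", "), "**\n")
  cat(sprintf("divergent transitions: %d\n", x$divergent))
  cat("variance components:\n")
  print(x$variance_components, digits = 3)
  invisible(x)
}

#' @export
coef.gpgrowth <- function(object, ...) {
  s <- posterior_summary(object$samples)
  stats::setNames(s$mean, s$parameter)
}

#' Posterior of an effect function from a fit
#'
#' Convenience wrapper around [latent_function_posterior()]; see there for
#' details.
#'
#' @param object a `gpgrowth` fit.
#' @param effect,level,batch,times,derivative,ndraws,seed see
#'   [latent_function_posterior()].
#' @param ... unused.
#' @return an `effect_posterior` object.
#' @export
predict.gpgrowth <- function(object, effect = "fitted", level = NULL,
                             batch = NULL, times = NULL,
                             derivative = FALSE, ndraws = 500L, seed = 1L,
                             ...) {
  latent_function_posterior(object$data, object$model, object$samples,
                            effect = effect, level = level, batch = batch,
                            times = times, derivative = derivative,
                            ndraws = ndraws, seed = seed)
}

#' @export
plot.gpgrowth <- function(x, effect = "mean", level = NULL, batch = NULL,
                          derivative = FALSE, band = 0.95, ndraws = 200L,
                          ...) {
  fp <- predict(x, effect = effect, level = level, batch = batch,
                derivative = derivative, ndraws = ndraws)
  plot(fp, level = band, ...)
}

# plug-in fitted values at the observed time points (posterior-mean
# hyperparameters, conditional mean per (condition, batch) cell)
#' @export
fitted.gpgrowth <- function(object, ndraws = 100L, ...) {
  gd <- object$data
  cellkey <- do.call(paste, c(lapply(c(gd$factors, "batch"),
                                     function(k) gd$curves[[k]]),
                              sep = "\r"))
  fit_vals <- numeric(nrow(gd$data))
  for (k in unique(cellkey)) {
    cids <- gd$curves$curve[cellkey == k]
    i0 <- match(cids[1L], gd$curves$curve)
    lev <- vapply(gd$factors, function(f) gd$curves[[f]][i0], "")
    rows <- gd$data$curve %in% cids
    tt <- sort(unique(gd$data$time[rows]))
    fp <- predict(object,
                  effect = "fitted",
                  level = if (length(lev) > 0L) lev else NULL,
                  batch = gd$curves$batch[i0],
                  times = tt, ndraws = ndraws)
    fit_vals[rows] <- fp$mean_fun[match(gd$data$time[rows], tt)]
  }
  fit_vals
}

#' @export
residuals.gpgrowth <- function(object, ...) {
  object$data$data$value - fitted(object, ...)
}

#' Posterior-predictive replication of the fitted dataset
#'
#' Simulates new datasets on the observed design by adding fresh replicate
#' variation (a per-curve GP draw under `M_full`) and observation noise
#' around the posterior-mean fitted curve of each (condition, batch) cell.
#' Hyperparameters are plugged in at their posterior means.
#'
#' @param object a `gpgrowth` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ndraws hyperparameter draws used for the fitted curves.
#' @param ... unused.
#' @return a list of `nsim` [growth_data] objects.
#' @export
simulate.gpgrowth <- function(object, nsim = 1L, seed = 1L, ndraws = 100L,
                              ...) {
  gd <- object$data
  fv <- fitted(object, ndraws = ndraws)
  hp <- coef(object)
  if (!is.null(object$samples$fixed))
    hp[names(object$samples$fixed)] <- object$samples$fixed
  has_rep <- any(vapply(object$model$groups, function(g)
    isTRUE(g$replicate), TRUE))
  sdy <- sqrt(hp[["noise.variance"]])
  tt_all <- model_time(gd)
  set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    eps <- stats::rnorm(nrow(gd$data), sd = sdy)
    if (has_rep) {
      chol_cache <- list()
      for (id in gd$curves$curve) {
        sel <- which(gd$data$curve == id)
        key <- paste(signif(tt_all[sel], 12), collapse = ",")
        if (is.null(chol_cache[[key]])) {
          K <- rbf_kernel(tt_all[sel], tt_all[sel],
                          hp[["replicate.variance"]],
                          hp[["replicate.lengthscale"]],
                          object$model$dialect)
          chol_cache[[key]] <- t(chol(K + diag(1e-10, length(sel))))
        }
        eps[sel] <- eps[sel] +
          as.numeric(chol_cache[[key]] %*% stats::rnorm(length(sel)))
      }
    }
    gd2 <- gd
    gd2$data$value <- fv + eps
    gd2
  })
}
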