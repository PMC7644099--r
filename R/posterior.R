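# Posterior functionals: latent-effect curves conditional on hyperparameter
# draws, credible bands, significance intervals, variance components.

# covariance of the engine's (reduced) observation vector for one
# hyperparameter vector; mirrors the C++ engine exactly
engine_cov <- function(engine, hp_vec, jitter = 1e-8) {
  n <- engine$n_rows
  G <- length(engine$masks)
  Sigma <- matrix(0, n, n)
  for (g in seq_len(G)) {
    s2 <- hp_vec[2 * g - 1]; ell <- hp_vec[2 * g]
    r <- if (engine$dialect_code == 1L) 1 / ell else 1 / (2 * ell^2)
    Sigma <- Sigma + engine$masks[[g]] * (s2 * exp(-r * engine$D2))
  }
  s2y <- hp_vec[2 * G + 1]
  diag(Sigma) <- diag(Sigma) + s2y * engine$noise_w + jitter * s2y
  Sigma
}

# resolve an effect selector to a list of (group index, function index);
# function numbering follows group_assign's label enumeration on the
# dataset's own curve table
resolve_effect <- function(gd, model, engine, effect, level = NULL,
                           batch = NULL) {
  gn <- vapply(model$groups, `[[`, "", "name")
  if (!is.null(level)) {
    if (is.null(names(level)) && length(gd$factors) == 1L)
      names(level) <- gd$factors
    bad <- setdiff(names(level), gd$factors)
    if (length(bad) > 0L)
      stop("selection error: unknown factor(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(batch) && !batch %in% gd$curves$batch)
    stop("selection error: unknown batch '", batch, "'")

  # 0 = reference (zero effect), NA = no such function
  target_fun <- function(j) {
    g <- model$groups[[j]]
    if (isTRUE(g$replicate))
      stop("selection error: replicate effects are per curve; ",
           "select them through residuals instead")
    labs <- attr(group_assign(g, model, gd$curves), "labels")
    if (length(g$factors) == 0L) {
      lab <- if (isTRUE(g$batch_indexed)) as.character(batch) else "1"
    } else {
      miss <- setdiff(g$factors, names(level))
      if (length(miss) > 0L)
        stop("selection error: effect '", g$name, "' needs level(s) for ",
             paste(miss, collapse = ", "))
      lv <- as.character(level[g$factors])
      if (any(lv == vapply(g$factors, function(f)
        model$reference[[f]], "")))
        return(0L)
      for (i in seq_along(g$factors))
        if (!lv[i] %in% gd$levels[[g$factors[i]]])
          stop("selection error: unknown level '", lv[i], "' of factor '",
               g$factors[i], "'")
      lab <- paste(lv, collapse = ":")
      if (isTRUE(g$batch_indexed)) lab <- paste(lab, batch, sep = "@")
    }
    f <- match(lab, labs)
    if (is.na(f))
      stop("selection error: no latent function '", lab, "' in group '",
           g$name, "'")
    f
  }

  sel <- list()
  if (identical(effect, "fitted")) {
    if (is.null(level) && length(gd$factors) > 0L)
      stop("selection error: 'fitted' needs the factor levels via `level`")
    for (j in seq_along(model$groups)) {
      g <- model$groups[[j]]
      if (isTRUE(g$replicate)) next
      if (isTRUE(g$batch_indexed) && is.null(batch)) next
      f <- target_fun(j)
      if (f > 0L) sel[[length(sel) + 1L]] <- c(j, f)
    }
    if (length(sel) == 0L) stop("selection error: nothing to predict")
  } else {
    j <- match(effect, gn)
    if (is.na(j)) stop("selection error: unknown effect '", effect,
                       "'; available: ", paste(gn, collapse = ", "),
                       ", fitted")
    g <- model$groups[[j]]
    if (isTRUE(g$batch_indexed) && is.null(batch))
      stop("selection error: batch effect '", effect, "' needs `batch`")
    f <- target_fun(j)
    if (identical(f, 0L))
      stop("selection error: the requested level is the reference level ",
           "(zero effect by the corner constraint)")
    sel[[1L]] <- c(j, f)
  }
  sel
}

#' Posterior of a latent effect function
#'
#' For each (thinned) hyperparameter draw, draws the selected latent
#' function on a time grid from its conditional Gaussian given the data,
#' \eqn{N(K_*' \Sigma^{-1} y,\; K_{**} - K_*' \Sigma^{-1} K_*)}; the
#' returned draws therefore form a mixture over the hyperparameter
#' posterior.  With `derivative = TRUE` the analytic RBF derivative kernels
#' are substituted, giving the posterior of the instantaneous growth-rate
#' contribution d log OD / dt (per hour).
#'
#' @inheritParams marginal_loglik
#' @param samples a `gp_mcmc` object from [sample_posterior()].
#' @param effect `"fitted"` (sum of all effects applicable to a condition)
#'   or an effect-group name (`"mean"`, `"treatment"`, `"mean_batch"`, ...).
#' @param level named character vector of factor level(s) selecting the
#'   latent function (unnamed allowed with a single factor).
#' @param batch batch identifier, required for batch effects and optional
#'   for `"fitted"`.
#' @param times evaluation grid in hours (default: 100 equally spaced
#'   points over the observed range).
#' @param derivative return the time derivative of the effect.
#' @param ndraws maximum number of hyperparameter draws used (thinned
#'   evenly; default 500).
#' @param seed seed for the conditional function draws.
#' @param moments also store the per-draw conditional mean and covariance
#'   (diagnostic use).
#' @return an `effect_posterior` object: `times` (hours), `draws`
#'   (draw x grid matrix), `mean_fun` (draw-averaged conditional mean),
#'   `effect` label, `derivative` flag.
#' @export
latent_function_posterior <- function(gd, model, samples, effect = "fitted",
                                      level = NULL, batch = NULL,
                                      times = NULL, derivative = FALSE,
                                      ndraws = 500L, seed = 1L,
                                      method = c("auto", "reduced",
                                                 "dense"),
                                      moments = FALSE) {
  stopifnot(inherits(samples, "gp_mcmc"))
  engine <- build_engine(gd, model, method = match.arg(method))
  if (is.null(times))
    times <- seq(min(gd$data$time), max(gd$data$time), length.out = 100L)
  if (is.unsorted(times, strictly = TRUE))
    stop("grid times must be strictly increasing")
  sel <- resolve_effect(gd, model, engine, effect, level, batch)

  scale <- gd$time_scale[["scale"]]
  tg <- (times - gd$time_scale[["offset"]]) * scale
  d <- samples$draws
  hp_mat <- apply(d, 3, rbind)                  # (iter*chain) x param
  hp_mat <- matrix(hp_mat, ncol = dim(d)[3L],
                   dimnames = list(NULL, samples$parameters))
  total <- nrow(hp_mat)
  use <- unique(round(seq(1L, total, length.out = min(ndraws, total))))

  pn <- engine$param_names
  full_hp <- function(row) {
    hp <- numeric(length(pn)); names(hp) <- pn
    if (!is.null(samples$fixed)) hp[names(samples$fixed)] <- samples$fixed
    hp[colnames(hp_mat)] <- row
    hp
  }

  dialect <- model$dialect
  ng <- length(tg)
  cross_k <- function(j, f, hp) {
    s2 <- hp[[2 * j - 1]]; ell <- hp[[2 * j]]
    cols <- engine$cell_assign[engine$cell_id, j] == f
    K <- matrix(0, ng, engine$n_rows)
    if (any(cols)) {
      kk <- if (derivative)
        rbf_derivative_cross(tg, engine$tt[cols], s2, ell, dialect)
      else rbf_kernel(tg, engine$tt[cols], s2, ell, dialect)
      w <- if (j == engine$rep_idx) 1 else sqrt(engine$Rc[engine$cell_id])[cols]
      K[, cols] <- sweep(kk, 2L, w, `*`)
    }
    K
  }
  prior_kk <- function(j, hp) {
    s2 <- hp[[2 * j - 1]]; ell <- hp[[2 * j]]
    if (derivative) rbf_derivative_kernel(tg, s2, ell, dialect)
    else rbf_kernel(tg, tg, s2, ell, dialect)
  }

  set.seed(seed)
  draws_out <- matrix(NA_real_, nrow = length(use), ncol = ng)
  mean_acc <- numeric(ng)
  mom <- if (moments) vector("list", length(use)) else NULL
  for (i in seq_along(use)) {
    hp <- full_hp(hp_mat[use[i], ])
    Sigma <- engine_cov(engine, as.numeric(hp))
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    esc <- 1e-7
    while (is.null(L) && esc <= 1e-4) {
      L <- tryCatch(chol(Sigma + diag(esc * hp[["noise.variance"]],
                                      nrow(Sigma))),
                    error = function(e) NULL)
      esc <- esc * 10
    }
    if (is.null(L)) stop("numerical error: covariance not factorizable")
    Ks <- matrix(0, ng, engine$n_rows)
    Kss <- matrix(0, ng, ng)
    for (s in sel) {
      Ks <- Ks + cross_k(s[1L], s[2L], hp)
      Kss <- Kss + prior_kk(s[1L], hp)
    }
    A <- backsolve(L, forwardsolve(t(L), t(Ks)))   # Sigma^{-1} Ks'
    mu <- as.numeric(Ks %*% backsolve(L, forwardsolve(t(L), engine$u)))
    V <- Kss - Ks %*% A
    V <- (V + t(V)) / 2
    if (moments) mom[[i]] <- list(mean = mu, cov = V)
    ev <- eigen(V, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    draws_out[i, ] <- mu +
      as.numeric(ev$vectors %*% (sqrt(lam) * stats::rnorm(ng)))
    mean_acc <- mean_acc + mu
  }
  if (derivative) {
    draws_out <- draws_out * scale
    mean_acc <- mean_acc * scale
    if (moments)
      mom <- lapply(mom, function(m)
        list(mean = m$mean * scale, cov = m$cov * scale^2))
  }
  label <- if (identical(effect, "fitted"))
    paste0("fitted[", paste(c(level, batch), collapse = ","), "]")
  else paste0(effect, if (!is.null(level) || !is.null(batch))
    paste0("[", paste(c(level, batch), collapse = ","), "]") else "")
  structure(list(times = times, draws = draws_out,
                 mean_fun = mean_acc / length(use), effect = label,
                 derivative = derivative, moments = mom),
            class = "effect_posterior")
}

#' Pointwise credible band of an effect posterior
#'
#' @param fp an `effect_posterior` object.
#' @param level central probability of the band, in (0, 1).
#' @return a data.frame with columns `time` (hours), `lower`, `mean`,
#'   `upper`.
#' @export
credible_band <- function(fp, level = 0.95) {
  stopifnot(inherits(fp, "effect_posterior"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  a <- (1 - level) / 2
  data.frame(
    time = fp$times,
    lower = apply(fp$draws, 2, stats::quantile, probs = a, type = 7),
    mean = colMeans(fp$draws),
    upper = apply(fp$draws, 2, stats::quantile, probs = 1 - a, type = 7))
}

#' Time intervals where an effect is credibly non-zero
#'
#' Scans a pointwise credible band for maximal runs of consecutive grid
#' points whose band excludes the reference value: these are the times at
#' which the effect differs from the control with high posterior
#' confidence.  Endpoints snap to grid points.
#'
#' @param band a data.frame from [credible_band()].
#' @param reference reference value excluded from the band (default 0).
#' @return a data.frame with columns `t_start`, `t_end` (hours) and `sign`
#'   (`"+"` or `"-"`); zero rows when the band contains the reference
#'   everywhere.
#' @export
significant_intervals <- function(band, reference = 0) {
  stopifnot(is.data.frame(band),
            all(c("time", "lower", "upper") %in% names(band)))
  state <- ifelse(band$lower > reference, 1L,
                  ifelse(band$upper < reference, -1L, 0L))
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    sign = character(0), stringsAsFactors = FALSE)
  i <- 1L; n <- length(state)
  while (i <= n) {
    if (state[i] != 0L) {
      j <- i
      while (j < n && state[j + 1L] == state[i]) j <- j + 1L
      out <- rbind(out, data.frame(t_start = band$time[i],
                                   t_end = band$time[j],
                                   sign = if (state[i] > 0L) "+" else "-",
                                   stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Posterior variance components
#'
#' Summarizes the posterior of every effect group's kernel variance
#' \eqn{\sigma^2} plus the observation noise variance: the model's variance
#' components, measuring how much each source (mean curve, treatment,
#' batch, replicate/biological, instrument noise) contributes to observed
#' variability.  Batch groups are pooled into a single `"batch"` component
#' by default (draws concatenated).
#'
#' @param samples a `gp_mcmc` object or `gpgrowth` fit.
#' @param model the `gp_model` (not needed for a `gpgrowth` fit).
#' @param pool_batch pool all batch-effect groups into one component.
#' @param prob central interval probability.
#' @return a data.frame with columns `component`, `mean`, `lower`, `upper`;
#'   the underlying draws are attached as attribute `"draws"`.
#' @export
variance_components <- function(samples, model = NULL, pool_batch = TRUE,
                                prob = 0.95) {
  if (inherits(samples, "gpgrowth")) {
    model <- samples$model
    samples <- samples$samples
  }
  stopifnot(inherits(samples, "gp_mcmc"), inherits(model, "gp_model"))
  a <- (1 - prob) / 2
  get_draws <- function(par) {
    if (par %in% samples$parameters)
      as.vector(samples$draws[, , match(par, samples$parameters)])
    else if (!is.null(samples$fixed) && par %in% names(samples$fixed))
      samples$fixed[[par]]
    else NULL
  }
  comp <- list()
  for (g in model$groups) {
    d <- get_draws(paste0(g$name, ".variance"))
    if (is.null(d)) next
    nm <- if (isTRUE(g$replicate)) "biological"
    else if (isTRUE(g$batch_indexed) && pool_batch) "batch"
    else g$name
    comp[[nm]] <- c(comp[[nm]], d)
  }
  comp[["noise"]] <- get_draws("noise.variance")
  out <- data.frame(
    component = names(comp),
    mean = vapply(comp, mean, 0),
    lower = vapply(comp, stats::quantile, 0, probs = a, type = 7),
    upper = vapply(comp, stats::quantile, 0, probs = 1 - a, type = 7),
    row.names = NULL)
  attr(out, "draws") <- comp
  out
}

#' @export
print.effect_posterior <- function(x, ...) {
  cat(sprintf("effect_posterior: %s%s, %d draws on %d grid points (%g-%g h)\n",
              x$effect, if (x$derivative) " (d/dt)" else "",
              nrow(x$draws), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.effect_posterior <- function(x, level = 0.95, reference = 0, ...) {
  b <- credible_band(x, level)
  ylab <- if (x$derivative) "d log OD / dt (per h)" else "log OD effect"
  graphics::plot(b$time, b$mean, type = "n",
                 ylim = range(b$lower, b$upper, reference),
                 xlab = "time (h)", ylab = ylab, main = x$effect, ...)
  graphics::polygon(c(b$time, rev(b$time)), c(b$lower, rev(b$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(b$time, b$mean, col = "steelblue4", lwd = 2)
  graphics::abline(h = reference, lty = 2, col = "grey40")
  invisible(b)
}
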