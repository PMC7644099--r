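# Classical parametric baseline: per-curve logistic growth fits, mu_max
# extraction, kernel density estimates and group comparison.

#' Fit a logistic growth model to one curve
#'
#' Nonlinear least squares of the logistic growth form
#' \deqn{y(t) = A / (1 + \exp(4 \mu_{max} (\lambda - t)/A + 2)),}
#' parameterized so that `A` is the carrying capacity, `mu_max` directly
#' the maximum slope (maximum instantaneous growth rate) and `lambda` the
#' lag time (intercept of the tangent at the inflection with the baseline).
#' This is the parameterization popularized by classical grofit-style
#' growth analysis.  Fitting is multi-start Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) from data-derived initial guesses with a
#' Nelder-Mead fallback; the best fit by residual sum of squares is
#' returned, even for data far from sigmoid shape.
#'
#' @param times,values numeric vectors (length >= 4); or pass a list with
#'   `times`/`values` as the first argument.
#' @return a `logistic_fit` list: `A`, `mu_max`, `lambda`, `mse`,
#'   `converged`, `fitted`.
#' @export
fit_logistic <- function(times, values = NULL) {
  if (is.list(times) && is.null(values)) {
    values <- times$values; times <- times$times
  }
  stopifnot(length(times) == length(values), length(times) >= 4L)
  t <- as.numeric(times); y <- as.numeric(values)

  logi <- function(p, t) p[1L] / (1 + exp(4 * p[2L] * (p[3L] - t) / p[1L] + 2))
  sse <- function(p) {
    r <- y - logi(p, t)
    sum(r * r)
  }

  # data-derived starts: carrying capacity from the data range, slope from
  # smoothed finite differences, lag from the tangent intercept
  A0 <- max(y)
  if (A0 <= 0) A0 <- max(y) - min(y) + 1e-3
  dy <- diff(y) / diff(t)
  if (length(dy) >= 3L) dy <- stats::filter(dy, rep(1 / 3, 3L), sides = 2L)
  dy[!is.finite(dy)] <- 0
  imax <- which.max(dy)
  mu0 <- max(dy[imax], 1e-3)
  tstar <- (t[imax] + t[imax + 1L]) / 2
  lam0 <- tstar - (y[imax] - min(y)) / mu0
  starts <- list(c(A0, mu0, lam0),
                 c(A0, mu0 / 2, max(lam0, min(t))),
                 c(1.5 * A0, 2 * mu0, min(t)))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ A / (1 + exp(4 * mu * (lambda - t) / A + 2)),
        start = list(A = st[1L], mu = st[2L], lambda = st[3L]),
        control = minpack.lm::nls.lm.control(maxiter = 200L))
      p <- stats::coef(m)
      list(p = c(p[["A"]], p[["mu"]], p[["lambda"]]), conv = TRUE)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      o <- stats::optim(st, sse, method = "Nelder-Mead",
                        control = list(maxit = 500L))
      fit <- list(p = o$par, conv = FALSE)
    }
    s <- sse(fit$p)
    if (is.null(best) || s < best$sse)
      best <- list(p = fit$p, sse = s, conv = fit$conv)
  }
  if (is.null(best)) stop("fit error: logistic fit failed from all starts")
  structure(list(A = best$p[1L], mu_max = best$p[2L],
                 lambda = best$p[3L], mse = best$sse / length(y),
                 converged = best$conv, fitted = logi(best$p, t)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit: A = %.4g, mu_max = %.4g /h, lambda = %.4g h, MSE = %.3g%s\n",
    x$A, x$mu_max, x$lambda, x$mse,
    if (x$converged) "" else " (fallback optimizer)"))
  invisible(x)
}

#' Per-condition distribution of logistic-fit error
#'
#' Fits the logistic model to every curve and tabulates the mean squared
#' error by experimental condition: conditions whose growth deviates from
#' the sigmoid assumption (e.g. severe stress) show systematically larger
#' MSE.
#'
#' @param gd a [growth_data] object.
#' @return a data.frame with one row per curve (`curve`, `condition`,
#'   `batch`, `A`, `mu_max`, `lambda`, `mse`, `converged`); per-condition
#'   MSE quartiles are attached as attribute `"quartiles"`.
#' @export
fit_mse_by_condition <- function(gd) {
  stopifnot(inherits(gd, "growth_data"))
  cond <- if (length(gd$factors) > 0L)
    do.call(paste, c(gd$curves[gd$factors], sep = ":"))
  else rep("all", nrow(gd$curves))
  rows <- lapply(seq_len(nrow(gd$curves)), function(i) {
    id <- gd$curves$curve[i]
    sel <- gd$data$curve == id
    f <- fit_logistic(gd$data$time[sel], gd$data$value[sel])
    data.frame(curve = id, condition = cond[i], batch = gd$curves$batch[i],
               A = f$A, mu_max = f$mu_max, lambda = f$lambda, mse = f$mse,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  qs <- do.call(rbind, lapply(split(out$mse, out$condition), function(v)
    data.frame(q1 = stats::quantile(v, 0.25, type = 7),
               median = stats::median(v),
               q3 = stats::quantile(v, 0.75, type = 7))))
  qs$condition <- rownames(qs); rownames(qs) <- NULL
  attr(out, "quartiles") <- qs[, c("condition", "q1", "median", "q3")]
  out
}

#' Gaussian kernel density estimate with Scott's-rule bandwidth
#'
#' Direct-sum Gaussian KDE with the default bandwidth of scipy's
#' `gaussian_kde`: \eqn{h = n^{-1/5} \cdot sd(x)} (Scott's rule in one
#' dimension).  The density is evaluated exactly (no binning) on a grid
#' extending 4 bandwidths past the data range, so it integrates to 1 up to
#' grid truncation.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param grid optional evaluation grid; default 512 points.
#' @param n grid size when `grid` is `NULL`.
#' @return a list with `x` (grid), `y` (density), `bw` (bandwidth).
#' @export
kde <- function(values, grid = NULL, n = 512L) {
  x <- as.numeric(values)
  if (length(unique(x)) < 2L)
    stop("KDE error: need at least 2 distinct values")
  bw <- stats::sd(x) * length(x)^(-1 / 5)
  if (is.null(grid))
    grid <- seq(min(x) - 4 * bw, max(x) + 4 * bw, length.out = n)
  y <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)), 0)
  list(x = grid, y = y, bw = bw)
}

#' One-sided Welch comparison of maximum growth rates
#'
#' Welch (unequal-variance) one-sided t-test of `mu_max` estimates between
#' two groups of curves, the classical test for a growth-rate difference
#' between a control and a stress condition.
#'
#' @param group_a,group_b numeric vectors of mu_max estimates (length >=
#'   2).
#' @param alternative `"greater"` tests mean(group_a) > mean(group_b).
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_mu_max <- function(group_a, group_b,
                           alternative = c("greater", "less",
                                           "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("test error: each group needs at least 2 values")
  stats::t.test(group_a, group_b, alternative = alternative,
                var.equal = FALSE)
}
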