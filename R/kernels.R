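#' Radial basis function kernel
#'
#' Evaluates the RBF covariance between two time vectors.  The default
#' dialect is exactly the model's printed form,
#' \deqn{\kappa(t, t') = \sigma^2 \exp(-|t - t'|^2 / \ell),}
#' with the lengthscale un-squared in the denominator.  The field's more
#' common convention \eqn{\exp(-|t-t'|^2 / (2\ell^2))} is available as
#' `dialect = "squared_lengthscale"`.
#'
#' @param t1,t2 numeric time vectors (model scale).
#' @param variance kernel variance \eqn{\sigma^2 > 0}.
#' @param lengthscale kernel lengthscale \eqn{\ell > 0}.
#' @param dialect `"as_printed"` (default) or `"squared_lengthscale"`.
#' @return the `length(t1)` x `length(t2)` covariance matrix.
#' @export
rbf_kernel <- function(t1, t2, variance, lengthscale,
                       dialect = c("as_printed", "squared_lengthscale")) {
  dialect <- match.arg(dialect)
  check_hp(variance, lengthscale)
  d2 <- outer(t1, t2, "-")^2
  variance * exp(-d2 * kernel_rate(lengthscale, dialect))
}

kernel_rate <- function(lengthscale, dialect) {
  if (dialect == "as_printed") 1 / lengthscale else 1 / (2 * lengthscale^2)
}

check_hp <- function(variance, lengthscale) {
  if (!is.finite(variance) || variance <= 0)
    stop("parameter error: variance must be positive")
  if (!is.finite(lengthscale) || lengthscale <= 0)
    stop("parameter error: lengthscale must be positive")
  invisible(TRUE)
}

#' Derivative cross-covariance of the RBF kernel
#'
#' Analytic covariance between the time derivative of a GP at `t_deriv` and
#' the GP itself at `t_obs`:
#' \eqn{\partial\kappa/\partial t = -(2(t-t')/\ell)\,\kappa(t,t')} in the
#' default dialect.  Used to report posterior instantaneous growth rates
#' (d log OD / dt) exactly under the model, without finite differences.
#'
#' @param t_deriv times at which the derivative is taken.
#' @param t_obs times at which the function is observed.
#' @inheritParams rbf_kernel
#' @return the `length(t_deriv)` x `length(t_obs)` cross-covariance matrix.
#' @export
rbf_derivative_cross <- function(t_deriv, t_obs, variance, lengthscale,
                                 dialect = c("as_printed",
                                             "squared_lengthscale")) {
  dialect <- match.arg(dialect)
  check_hp(variance, lengthscale)
  d <- outer(t_deriv, t_obs, "-")
  r <- kernel_rate(lengthscale, dialect)
  -2 * r * d * (variance * exp(-d^2 * r))
}

#' Derivative-derivative covariance of the RBF kernel
#'
#' Covariance of the GP derivative with itself:
#' \eqn{(2/\ell - 4(t-t')^2/\ell^2)\,\kappa(t,t')} in the default dialect;
#' its diagonal is \eqn{2\sigma^2/\ell}.
#'
#' @inheritParams rbf_derivative_cross
#' @return the `length(t_deriv)` x `length(t_deriv)` covariance matrix.
#' @export
rbf_derivative_kernel <- function(t_deriv, variance, lengthscale,
                                  dialect = c("as_printed",
                                              "squared_lengthscale")) {
  dialect <- match.arg(dialect)
  check_hp(variance, lengthscale)
  d <- outer(t_deriv, t_deriv, "-")
  r <- kernel_rate(lengthscale, dialect)
  (2 * r - 4 * r^2 * d^2) * (variance * exp(-d^2 * r))
}

# ---- incidence machinery ----------------------------------------------------

# For one effect group, assign each curve to the index of the latent
# function it loads on (0 = none, e.g. reference level under the corner
# constraint).  `model` is a gp_model; `curves` the curve_info data.frame.
group_assign <- function(group, model, curves) {
  n <- nrow(curves)
  if (isTRUE(group$replicate)) return(seq_len(n))
  if (length(group$factors) == 0L) {
    fixed_part <- rep(1L, n)
    labels <- "1"
  } else {
    ref <- model$reference
    keep <- rep(TRUE, n)
    parts <- vector("list", length(group$factors))
    for (i in seq_along(group$factors)) {
      f <- group$factors[i]
      keep <- keep & (curves[[f]] != ref[[f]])
      parts[[i]] <- curves[[f]]
    }
    labels_all <- do.call(paste, c(parts, sep = ":"))
    combos <- sort(unique(labels_all[keep]))
    fixed_part <- ifelse(keep, match(labels_all, combos), 0L)
    labels <- combos
  }
  if (isTRUE(group$batch_indexed)) {
    batches <- sort(unique(curves$batch))
    bi <- match(curves$batch, batches)
    out <- ifelse(fixed_part > 0L,
                  (fixed_part - 1L) * length(batches) + bi, 0L)
    attr(out, "labels") <- as.vector(outer(batches, labels,
      function(b, l) if (identical(labels, "1")) b else paste(l, b, sep = "@")))
    out
  } else {
    attr(fixed_part, "labels") <- labels
    fixed_part
  }
}

# obs-level assignment matrix: one column per group, entries are latent
# function indices (0 = not loaded)
obs_assignments <- function(gd, model) {
  curves <- gd$curves
  idx <- match(gd$data$curve, curves$curve)
  a <- sapply(model$groups, function(g) {
    av <- group_assign(g, model, curves)
    av[idx]
  })
  colnames(a) <- vapply(model$groups, `[[`, "", "name")
  a
}

#' Marginal covariance of the observation vector
#'
#' Assembles the dense covariance of the concatenated observations after
#' integrating out every latent GP:
#' \eqn{\Sigma = \sum_g Z_g K_g Z_g' + \sigma_y^2 I}, where \eqn{Z_g} is the
#' 0/1 incidence of observations onto group g's latent functions (one
#' function per non-reference level combination for fixed effects, times
#' batch for batch effects, one per curve for the replicate effect).  Rows
#' follow the dataset's observation order.
#'
#' @param gd a [growth_data] object (times are used on the model scale).
#' @param model a model definition from [build_model()].
#' @param hp named hyperparameter vector (`"<group>.variance"`,
#'   `"<group>.lengthscale"`, `"noise.variance"`).
#' @param jitter diagonal jitter added as a fraction of the noise variance.
#' @return the n x n covariance matrix.
#' @export
assemble_covariance <- function(gd, model, hp, jitter = 1e-8) {
  hp <- check_hp_vector(hp, model)
  tt <- model_time(gd)
  n <- length(tt)
  A <- obs_assignments(gd, model)
  d2 <- outer(tt, tt, "-")^2
  Sigma <- matrix(0, n, n)
  for (j in seq_along(model$groups)) {
    g <- model$groups[[j]]
    a <- A[, j]
    mask <- (a > 0L) & outer(a, a, "==")
    r <- kernel_rate(hp[paste0(g$name, ".lengthscale")], model$dialect)
    Sigma <- Sigma +
      mask * (hp[paste0(g$name, ".variance")] * exp(-d2 * r))
  }
  s2y <- hp["noise.variance"]
  diag(Sigma) <- diag(Sigma) + s2y + jitter * s2y
  Sigma
}
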