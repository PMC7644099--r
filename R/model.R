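#' Prior specification
#'
#' Gamma priors use the shape-rate parameterization throughout (mean =
#' shape/rate); inverse-gamma priors use shape and scale.
#'
#' @param family `"gamma"` or `"inverse_gamma"`.
#' @param shape,rate positive parameters.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(family = c("gamma", "inverse_gamma"), shape, rate) {
  family <- match.arg(family)
  stopifnot(shape > 0, rate > 0)
  structure(list(family = family, shape = shape, rate = rate),
            class = "prior_spec")
}

prior_ld <- function(x, p) {
  if (!is.finite(x) || x <= 0) return(-Inf)
  if (p$family == "gamma")
    stats::dgamma(x, shape = p$shape, rate = p$rate, log = TRUE)
  else
    # inverse-gamma(shape a, scale b): b^a / Gamma(a) x^-(a+1) exp(-b/x)
    p$shape * log(p$rate) - lgamma(p$shape) -
      (p$shape + 1) * log(x) - p$rate / x
}

# d/d(log x) of [log prior + log-Jacobian of the log transform]
prior_grad_logx <- function(x, p) {
  if (p$family == "gamma") p$shape - p$rate * x
  else -p$shape + p$rate / x
}

prior_draw <- function(p) {
  if (p$family == "gamma") stats::rgamma(1L, shape = p$shape, rate = p$rate)
  else p$rate / stats::rgamma(1L, shape = p$shape, rate = 1)
}

#' Default hyperparameter priors
#'
#' Variance priors: Gamma(10, 10) for fixed-effect groups (mean 1 on the
#' log-OD\eqn{{}^2} scale) and Gamma(7, 10) for random-effect groups (mean
#' 0.7).  Lengthscale priors depend on the dataset preset, appropriate for
#' time standardized to [0, 1]: `"halobacterium"` uses inverse-Gamma(6, 1)
#' for all groups; `"pseudomonas"` uses inverse-Gamma(2, 3) for fixed and
#' inverse-Gamma(10, 1) for random effects.  The noise variance prior is
#' Gamma(1, 10) (weakly informative, mean 0.1).
#'
#' @param preset `"halobacterium"` (default) or `"pseudomonas"`.
#' @param fixed_variance,random_variance,noise length-2 numeric `(shape,
#'   rate)` overrides for the gamma variance priors.
#' @param fixed_lengthscale,random_lengthscale length-2 numeric `(shape,
#'   scale)` overrides for the inverse-gamma lengthscale priors.
#' @return a named list of `prior_spec`s.
#' @export
default_priors <- function(preset = c("halobacterium", "pseudomonas"),
                           fixed_variance = c(10, 10),
                           random_variance = c(7, 10),
                           noise = c(1, 10),
                           fixed_lengthscale = NULL,
                           random_lengthscale = NULL) {
  preset <- match.arg(preset)
  if (is.null(fixed_lengthscale))
    fixed_lengthscale <- if (preset == "halobacterium") c(6, 1) else c(2, 3)
  if (is.null(random_lengthscale))
    random_lengthscale <- if (preset == "halobacterium") c(6, 1) else c(10, 1)
  list(fixed_variance = prior_spec("gamma", fixed_variance[1], fixed_variance[2]),
       random_variance = prior_spec("gamma", random_variance[1], random_variance[2]),
       noise = prior_spec("gamma", noise[1], noise[2]),
       fixed_lengthscale = prior_spec("inverse_gamma", fixed_lengthscale[1],
                                      fixed_lengthscale[2]),
       random_lengthscale = prior_spec("inverse_gamma", random_lengthscale[1],
                                       random_lengthscale[2]))
}

new_group <- function(name, kind, factors = character(0),
                      batch_indexed = FALSE, replicate = FALSE, priors) {
  vp <- if (kind == "fixed") priors$fixed_variance else priors$random_variance
  lp <- if (kind == "fixed") priors$fixed_lengthscale else priors$random_lengthscale
  list(name = name, kind = kind, factors = factors,
       batch_indexed = batch_indexed, replicate = replicate,
       var_prior = vp, len_prior = lp)
}

#' Build a growth-model definition
#'
#' Constructs the nested model hierarchy from a dataset's design:
#' * `M_null` (`kind = "null"`): fixed effects only.  With one factor these
#'   are the mean curve m(t) plus a treatment deviation per non-reference
#'   level; with two factors a functional-ANOVA decomposition into mean,
#'   both main effects and their interaction.
#' * `M_batch`: adds a batch-indexed GP random twin of every fixed group.
#' * `M_full`: additionally adds a per-curve replicate GP, on top of the
#'   white observation noise.
#'
#' Identifiability uses corner constraints: the reference level of each
#' factor carries zero effect (default reference: the first level in sort
#' order, i.e. the designated control).
#'
#' @param kind `"null"`, `"batch"` or `"full"`.
#' @param gd a [growth_data] object.
#' @param structure `"auto"` (from the number of factors), `"mean_only"`,
#'   `"single_treatment"` or `"two_factor_interaction"`.
#' @param priors a prior list from [default_priors()].
#' @param reference named list/vector giving the reference level per factor.
#' @param dialect kernel dialect, see [rbf_kernel()].
#' @return a `gp_model` object: ordered effect groups, noise prior,
#'   reference levels, dialect.
#' @export
build_model <- function(kind = c("batch", "null", "full"), gd,
                        structure = c("auto", "mean_only",
                                      "single_treatment",
                                      "two_factor_interaction"),
                        priors = default_priors(), reference = NULL,
                        dialect = c("as_printed", "squared_lengthscale")) {
  kind <- match.arg(kind)
  structure <- match.arg(structure)
  dialect <- match.arg(dialect)
  nf <- length(gd$factors)
  if (structure == "auto")
    structure <- switch(as.character(min(nf, 2L)),
                        "0" = "mean_only",
                        "1" = "single_treatment",
                        "2" = "two_factor_interaction")
  need <- switch(structure, mean_only = 0L, single_treatment = 1L,
                 two_factor_interaction = 2L)
  if (nf != need)
    stop(sprintf("design error: structure '%s' needs %d factor(s), data has %d",
                 structure, need, nf))

  ref <- as.list(vapply(gd$levels, `[[`, "", 1L))
  if (!is.null(reference)) {
    reference <- as.list(reference)
    for (f in names(reference)) {
      if (!f %in% gd$factors) stop("design error: unknown factor ", f)
      if (!reference[[f]] %in% gd$levels[[f]])
        stop("design error: unknown reference level for ", f)
      ref[[f]] <- reference[[f]]
    }
  }

  fixed <- list(new_group("mean", "fixed", priors = priors))
  if (structure == "single_treatment") {
    fixed <- c(fixed, list(new_group("treatment", "fixed",
                                     factors = gd$factors[1], priors = priors)))
  } else if (structure == "two_factor_interaction") {
    f1 <- gd$factors[1]; f2 <- gd$factors[2]
    fixed <- c(fixed,
               list(new_group(f1, "fixed", factors = f1, priors = priors),
                    new_group(f2, "fixed", factors = f2, priors = priors),
                    new_group("interaction", "fixed", factors = c(f1, f2),
                              priors = priors)))
  }
  groups <- fixed
  if (kind %in% c("batch", "full")) {
    twins <- lapply(fixed, function(g)
      new_group(paste0(g$name, "_batch"), "random", factors = g$factors,
                batch_indexed = TRUE, priors = priors))
    groups <- c(groups, twins)
  }
  if (kind == "full")
    groups <- c(groups, list(new_group("replicate", "random",
                                       replicate = TRUE, priors = priors)))

  structure(list(kind = kind, structure = structure, groups = groups,
                 noise_prior = priors$noise, reference = ref,
                 dialect = dialect),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("gp_model M_%s (%s), %d effect groups:\n", x$kind,
              x$structure, length(x$groups)))
  for (g in x$groups)
    cat(sprintf("  %-18s %s%s\n", g$name, g$kind,
                if (g$batch_indexed) " (per batch)"
                else if (g$replicate) " (per curve)" else ""))
  invisible(x)
}

# canonical parameter names: <group>.variance, <group>.lengthscale, noise.variance
param_names <- function(model) {
  gn <- vapply(model$groups, `[[`, "", "name")
  c(rbind(paste0(gn, ".variance"), paste0(gn, ".lengthscale")),
    "noise.variance")
}

check_hp_vector <- function(hp, model) {
  pn <- param_names(model)
  miss <- setdiff(pn, names(hp))
  if (length(miss) > 0L)
    stop("structural error: missing hyperparameter(s): ",
         paste(miss, collapse = ", "))
  hp[pn]
}

#' Log prior density of the hyperparameters
#'
#' Sum of the log prior densities over every effect group's kernel variance
#' and lengthscale plus the noise variance.  Returns `-Inf` if any
#' hyperparameter is non-positive.
#'
#' @param hp named hyperparameter vector, see [assemble_covariance()].
#' @param model a `gp_model`.
#' @return a scalar log density.
#' @export
prior_logpdf <- function(hp, model) {
  hp <- check_hp_vector(hp, model)
  lp <- 0
  for (g in model$groups) {
    lp <- lp + prior_ld(hp[[paste0(g$name, ".variance")]], g$var_prior) +
      prior_ld(hp[[paste0(g$name, ".lengthscale")]], g$len_prior)
  }
  lp + prior_ld(hp[["noise.variance"]], model$noise_prior)
}

# draw a full hyperparameter vector from the priors
prior_draw_all <- function(model) {
  hp <- numeric(0)
  for (g in model$groups) {
    hp[paste0(g$name, ".variance")] <- prior_draw(g$var_prior)
    hp[paste0(g$name, ".lengthscale")] <- prior_draw(g$len_prior)
  }
  hp["noise.variance"] <- prior_draw(model$noise_prior)
  hp
}

# gradient of log prior + log-Jacobian wrt log-parameters, in param order
prior_grad_all <- function(hp, model) {
  g_out <- numeric(length(hp))
  names(g_out) <- names(hp)
  for (g in model$groups) {
    vn <- paste0(g$name, ".variance")
    ln <- paste0(g$name, ".lengthscale")
    g_out[vn] <- prior_grad_logx(hp[[vn]], g$var_prior)
    g_out[ln] <- prior_grad_logx(hp[[ln]], g$len_prior)
  }
  g_out["noise.variance"] <- prior_grad_logx(hp[["noise.variance"]],
                                             model$noise_prior)
  g_out
}
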