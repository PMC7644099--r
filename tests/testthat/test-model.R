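test_that("model construction yields the expected effect groups", {
  gd1 <- orc_dataset(n_cond = 3, n_batch = 2, n_rep = 2, n_time = 3)
  m0 <- build_model("null", gd1)
  expect_equal(vapply(m0$groups, `[[`, "", "name"), c("mean", "treatment"))
  # 3 stress levels, corner constraint: 2 treatment functions
  a <- gpgrowth:::group_assign(m0$groups[[2L]], m0, gd1$curves)
  expect_equal(length(attr(a, "labels")), 2L)
  expect_true(all(a[gd1$curves$stress == m0$reference$stress] == 0L))

  # two-factor 3 x 3: fixed {mean, f1, f2, interaction} + 4 batch twins
  df <- expand.grid(time = c(0, 12, 24), pH = c("7", "6", "5"),
                    conc = c("0", "10", "20"), batch = c("b1", "b2"),
                    replicate = "r1", stringsAsFactors = FALSE)
  df$od <- exp(rnorm(nrow(df)))
  gd2 <- preprocess(growth_data(df, factors = c("pH", "conc")))
  mb <- build_model("batch", gd2)
  expect_equal(vapply(mb$groups, `[[`, "", "name"),
               c("mean", "pH", "conc", "interaction", "mean_batch",
                 "pH_batch", "conc_batch", "interaction_batch"))
  # interaction group: one function per non-reference pair x batch
  ai <- gpgrowth:::group_assign(mb$groups[[8L]], mb, gd2$curves)
  expect_equal(length(attr(ai, "labels")), 4L * 2L)
  mf <- build_model("full", gd2)
  expect_equal(length(mf$groups), 9L)
  expect_true(mf$groups[[9L]]$replicate)
  expect_error(build_model("null", gd2, structure = "single_treatment"),
               "design error")
})

test_that("prior densities match closed forms and integrate to one", {
  p_fix <- prior_spec("gamma", 10, 10)
  p_rand <- prior_spec("gamma", 7, 10)
  expect_equal(p_fix$shape / p_fix$rate, 1.0)
  expect_equal(p_rand$shape / p_rand$rate, 0.7)
  # closed form at x = 1 (shape-rate parameterization)
  expect_equal(gpgrowth:::prior_ld(1, p_fix),
               10 * log(10) + 9 * log(1) - 10 - lgamma(10))
  expect_identical(gpgrowth:::prior_ld(-1, p_fix), -Inf)
  expect_identical(gpgrowth:::prior_ld(0, prior_spec("inverse_gamma", 6, 1)),
                   -Inf)
  # each 1-D prior integrates to 1 (quadrature)
  for (p in list(p_fix, p_rand, prior_spec("inverse_gamma", 6, 1),
                 prior_spec("inverse_gamma", 2, 3),
                 prior_spec("gamma", 1, 10))) {
    z <- stats::integrate(function(x)
      exp(vapply(x, gpgrowth:::prior_ld, 0, p = p)), 0, Inf,
      rel.tol = 1e-9)
    expect_equal(z$value, 1, tolerance = 1e-6)
  }
})

test_that("prior_logpdf sums group priors and flags non-positive values", {
  gd <- orc_dataset()
  m <- build_model("batch", gd)
  hp <- orc_hp(m)
  by_hand <- 0
  for (g in m$groups) {
    vp <- if (g$kind == "fixed") c(10, 10) else c(7, 10)
    by_hand <- by_hand +
      stats::dgamma(hp[[paste0(g$name, ".variance")]], vp[1], vp[2],
                    log = TRUE)
    x <- hp[[paste0(g$name, ".lengthscale")]]
    by_hand <- by_hand + 6 * log(1) - lgamma(6) - 7 * log(x) - 1 / x
  }
  by_hand <- by_hand + stats::dgamma(hp[["noise.variance"]], 1, 10,
                                     log = TRUE)
  expect_equal(prior_logpdf(hp, m), by_hand)
  hp_bad <- hp; hp_bad[3L] <- -1
  expect_identical(prior_logpdf(hp_bad, m), -Inf)
})

test_that("marginal likelihood has the 1-observation closed form", {
  df <- data.frame(time = c(0, 48), od = exp(c(0.3, 0.3)), batch = "b1",
                   replicate = "r1")
  gd <- preprocess(growth_data(df))
  gd$data <- gd$data[1L, ]                     # a single observation
  m <- build_model("null", gd, structure = "mean_only")
  hp <- c("mean.variance" = 2, "mean.lengthscale" = 0.5,
          "noise.variance" = 0.1)
  v <- 2 + 0.1 * (1 + 1e-8)
  expect_equal(marginal_loglik(gd, m, hp),
               stats::dnorm(0.3, 0, sqrt(v), log = TRUE), tolerance = 1e-9)
  # 1-D monotonicity: inflating noise helps iff data variance exceeds
  # model variance
  hp_small <- hp; hp_small["noise.variance"] <- 0.05
  gd_big <- gd; gd_big$data$value <- 3        # |y| >> model sd
  expect_gt(marginal_loglik(gd_big, m, hp),
            marginal_loglik(gd_big, m, hp_small))
  gd_tiny <- gd; gd_tiny$data$value <- 0.01   # |y| << model sd
  expect_lt(marginal_loglik(gd_tiny, m, hp),
            marginal_loglik(gd_tiny, m, hp_small))
})

test_that("marginal likelihood matches an independent dense MVN oracle", {
  # random tiny instances across all three hierarchies, both engine paths
  cases <- expand.grid(kind = c("null", "batch", "full"), seed = 1:7,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    kind <- cases$kind[i]; sd <- cases$seed[i]
    gd <- orc_dataset(n_cond = 2, n_batch = 2, n_rep = 1, n_time = 2 + sd %% 2,
                      shared_grid = sd %% 2 == 0, seed = sd)
    m <- build_model(kind, gd)
    hp <- orc_hp(m, seed = 100 + i)
    hp_noj <- hp
    ll_orc <- orc_dmvnorm(gd$data$value,
                          orc_covariance(gd, m, hp) +
                            diag(1e-8 * hp[["noise.variance"]],
                                 nrow(gd$data)))
    expect_equal(marginal_loglik(gd, m, hp, method = "dense"), ll_orc,
                 tolerance = 1e-9)
    expect_equal(marginal_loglik(gd, m, hp, method = "auto"), ll_orc,
                 tolerance = 1e-9)
  }
})

test_that("richer hierarchies can only improve the attainable likelihood", {
  gd <- orc_dataset(n_cond = 2, n_batch = 2, n_rep = 2, n_time = 3,
                    seed = 11)
  m0 <- build_model("null", gd)
  mb <- build_model("batch", gd)
  mf <- build_model("full", gd)
  # optimize each model, warm-starting the richer model at the simpler
  # optimum embedded with vanishing random-effect variances
  opt <- function(m, warm = NULL) {
    pn <- gpgrowth:::param_names(m)
    f <- function(z) -marginal_loglik(gd, m,
                                      stats::setNames(exp(z), pn))
    best <- NULL
    starts <- list(rep(-1, length(pn)))
    if (!is.null(warm)) {
      z <- stats::setNames(rep(-1, length(pn)), pn)
      z[grepl("\\.variance$", pn)] <- -25      # effectively absent
      z[names(warm)] <- warm
      starts <- c(starts, list(as.numeric(z)))
    }
    for (s in starts) {
      o <- stats::optim(s, f, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(val = -best$value,
         par = stats::setNames(best$par, pn))
  }
  o0 <- opt(m0); ob <- opt(mb, warm = o0$par); of <- opt(mf, warm = ob$par)
  l0 <- o0$val; lb <- ob$val; lf <- of$val
  expect_gte(lb, l0 - 1e-4)
  expect_gte(lf, lb - 1e-4)
})
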