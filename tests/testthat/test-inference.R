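mk_mcmc <- function(draws, params = dimnames(draws)[[3]]) {
  structure(list(draws = draws, parameters = params,
                 divergent = integer(dim(draws)[2]), fixed = NULL,
                 config = list(chains = dim(draws)[2], iter = dim(draws)[1],
                               warmup = 0, seed = 1)),
            class = "gp_mcmc")
}

test_that("identical seeds give bitwise-identical draws", {
  gd <- orc_dataset(n_cond = 2, n_batch = 2, n_rep = 2, n_time = 4,
                    seed = 4)
  m <- build_model("null", gd)
  s1 <- sample_posterior(gd, m, chains = 2, iter = 40, warmup = 40,
                         seed = 7)
  s2 <- sample_posterior(gd, m, chains = 2, iter = 40, warmup = 40,
                         seed = 7)
  expect_identical(s1$draws, s2$draws)
  s3 <- sample_posterior(gd, m, chains = 2, iter = 40, warmup = 40,
                         seed = 8)
  expect_false(identical(s1$draws, s3$draws))
  expect_true(all(s1$draws > 0))
})

test_that("split R-hat behaves on constructed chains", {
  # constant chains: zero within-chain variance, undefined R-hat
  d <- array(1, dim = c(100, 2, 1), dimnames = list(NULL, NULL, "a"))
  expect_warning(r <- rhat(mk_mcmc(d)), "zero within-chain variance")
  expect_true(is.nan(r[["a"]]))

  # two chains from the same normal: R-hat within (0.99, 1.01)
  set.seed(1)
  d2 <- array(rnorm(20000), dim = c(10000, 2, 1),
              dimnames = list(NULL, NULL, "a"))
  r2 <- rhat(mk_mcmc(d2))
  expect_gt(r2[["a"]], 0.99); expect_lt(r2[["a"]], 1.01)

  # chains offset by 10 sd: R-hat far above the 1.1 threshold
  d3 <- d2; d3[, 2, 1] <- d3[, 2, 1] + 10
  expect_gt(rhat(mk_mcmc(d3))[["a"]], 2)

  expect_error(rhat(mk_mcmc(d2[, 1, 1, drop = FALSE])), ">= 2 chains")
})

test_that("posterior summaries match sort-based quantile oracle", {
  set.seed(2)
  d <- array(c(rnorm(800), rep(3, 800)), dim = c(400, 2, 2),
             dimnames = list(NULL, NULL, c("sym", "const")))
  s <- posterior_summary(mk_mcmc(d))
  expect_equal(s$sd[2L], 0)
  expect_equal(s$lower[2L], s$upper[2L])
  expect_lt(abs(s$mean[1L]), 3 / sqrt(800))
  # independent type-7 quantile: h = (n-1)p + 1 on the sorted sample
  x <- sort(as.vector(d[, , 1L]))
  q_orc <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(s$lower[1L], q_orc(0.025))
  expect_equal(s$upper[1L], q_orc(0.975))
})

test_that("noise posterior matches a 1-D grid-quadrature oracle", {
  # mean-only model, mean kernel fixed wide, iid data: only sigma_y^2 free
  set.seed(5)
  df <- data.frame(time = rep(seq(0, 48, length.out = 12), 3),
                   od = exp(rnorm(36, sd = sqrt(0.3))),
                   batch = "b1",
                   replicate = rep(c("r1", "r2", "r3"), each = 12))
  gd <- preprocess(growth_data(df))
  m <- build_model("null", gd, structure = "mean_only")
  fix <- c("mean.variance" = 0.5, "mean.lengthscale" = 5)
  samp <- sample_posterior(gd, m, chains = 2, iter = 400, warmup = 400,
                           seed = 3, fix = fix)
  post_mean_mcmc <- mean(samp$draws[, , "noise.variance"])

  lg <- seq(log(1e-4), log(10), length.out = 4001)
  lp <- vapply(lg, function(z) {
    hp <- c(fix, "noise.variance" = exp(z))
    marginal_loglik(gd, m, hp) +
      gpgrowth:::prior_ld(exp(z), m$noise_prior) + z
  }, 0)
  w <- exp(lp - max(lp))
  post_mean_grid <- sum(exp(lg) * w) / sum(w)
  expect_lt(abs(post_mean_mcmc - post_mean_grid) / post_mean_grid, 0.02)
})

test_that("posterior ranks of prior-drawn truths are uniform (SBC)", {
  # mean-only model at fixed lengthscales; truth drawn from the prior,
  # rank of the true variance among thinned posterior draws
  tt <- seq(0, 48, length.out = 8)
  df0 <- data.frame(time = tt, od = 1, batch = "b1", replicate = "r1")
  gd0 <- preprocess(growth_data(df0))
  m <- build_model("null", gd0, structure = "mean_only")
  fix <- c("mean.lengthscale" = 0.2)
  K <- rbf_kernel(gpgrowth:::model_time(gd0), gpgrowth:::model_time(gd0),
                  1, 0.2)
  n_rep <- 60L; n_rank <- 9L
  ranks_m <- integer(n_rep); ranks_y <- integer(n_rep)
  set.seed(42)
  seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    s2m <- rgamma(1, 10, 10)
    s2y <- rgamma(1, 1, 10)
    S <- s2m * K + diag(s2y, 8)
    gd <- gd0
    gd$data$value <- as.numeric(t(chol(S)) %*% rnorm(8))
    samp <- sample_posterior(gd, m, chains = 1, iter = 150, warmup = 150,
                             seed = seeds[r] + 1L, fix = fix)
    thin <- round(seq(9, 150, length.out = n_rank))
    ranks_m[r] <- sum(samp$draws[thin, 1, "mean.variance"] < s2m)
    ranks_y[r] <- sum(samp$draws[thin, 1, "noise.variance"] < s2y)
  }
  for (rk in list(ranks_m, ranks_y)) {
    obs <- tabulate(rk + 1L, nbins = n_rank + 1L)
    chi2 <- sum((obs - n_rep / (n_rank + 1L))^2 / (n_rep / (n_rank + 1L)))
    expect_lt(chi2, qchisq(0.99, df = n_rank))
  }
})

test_that("posterior of the mean variance contracts with replication", {
  sds <- sapply(c(2L, 8L, 32L), function(R) {
    des <- sim_design(factors = list(), batches = 1, replicates = R,
                      times = seq(0, 48, length.out = 8))
    sim <- simulate_growth(des, truth = c("mean.variance" = 1,
                                          "mean.lengthscale" = 0.2,
                                          "noise.variance" = 0.4),
                           model = "null", seed = 99)
    samp <- sample_posterior(sim$data,
                             build_model("null", sim$data,
                                         structure = "mean_only"),
                             chains = 2, iter = 600, warmup = 400,
                             seed = 11)
    sd(samp$draws[, , "mean.variance"])
  })
  expect_lt(sds[2L], sds[1L] * 1.1)
  expect_lt(sds[3L], sds[2L] * 1.1)
  expect_lt(sds[3L], sds[1L])
})

test_that("draws serialize losslessly to long format", {
  gd <- orc_dataset(seed = 6)
  m <- build_model("null", gd)
  samp <- sample_posterior(gd, m, chains = 2, iter = 30, warmup = 30,
                           seed = 2)
  lng <- as.data.frame(samp)
  expect_equal(nrow(lng), 30 * 2 * length(samp$parameters))
  # round trip through CSV reproduces the summary exactly
  f <- tempfile(fileext = ".csv")
  utils::write.csv(lng, f, row.names = FALSE)
  lng2 <- utils::read.csv(f)
  for (p in samp$parameters) {
    v1 <- lng$value[lng$parameter == p]
    v2 <- lng2$value[lng2$parameter == p]
    expect_equal(mean(v2), mean(v1), tolerance = 1e-12)
  }
  unlink(f)
})
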