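# a gp_mcmc holding a single fixed hyperparameter vector (repeated), for
# conditioning at known hyperparameters
one_draw <- function(hp, n = 1L) {
  structure(list(
    draws = array(rep(hp, each = n), dim = c(n, 1L, length(hp)),
                  dimnames = list(NULL, NULL, names(hp))),
    parameters = names(hp), divergent = 0L, fixed = NULL,
    config = list(chains = 1L, iter = n, warmup = 0L, seed = 1L)),
    class = "gp_mcmc")
}

test_that("conditioning matches a brute-force Gaussian oracle on 4 points", {
  df <- data.frame(time = c(0, 16, 32, 48), od = exp(c(-0.2, 0.4, 1.1, 1.3)),
                   batch = "b1", replicate = "r1")
  gd <- preprocess(growth_data(df))
  m <- build_model("null", gd, structure = "mean_only")
  hp <- c("mean.variance" = 1.2, "mean.lengthscale" = 0.3,
          "noise.variance" = 0.05)
  grid <- c(5, 20, 35)
  fp <- latent_function_posterior(gd, m, one_draw(hp), effect = "mean",
                                  times = grid, moments = TRUE)
  # independent conditioning: all quantities from the naive kernel
  tt <- gd$data$time / 48; tg <- grid / 48
  S <- orc_k(outer(tt, rep(1, 4)), outer(rep(1, 4), tt), 1.2, 0.3) +
    diag(0.05 * (1 + 1e-8), 4)
  Ks <- orc_k(outer(tg, rep(1, 4)), outer(rep(1, 3), tt), 1.2, 0.3)
  Kss <- orc_k(outer(tg, rep(1, 3)), outer(rep(1, 3), tg), 1.2, 0.3)
  mu <- as.numeric(Ks %*% solve(S, gd$data$value))
  V <- Kss - Ks %*% solve(S, t(Ks))
  expect_equal(fp$moments[[1]]$mean, mu, tolerance = 1e-9)
  expect_equal(fp$moments[[1]]$cov, V, tolerance = 1e-9)

  # derivative posterior against finite differences of the mean
  fpd <- latent_function_posterior(gd, m, one_draw(hp), effect = "mean",
                                   times = grid, derivative = TRUE,
                                   moments = TRUE)
  h <- 1e-4
  mu_p <- latent_function_posterior(gd, m, one_draw(hp), effect = "mean",
                                    times = grid + h)$mean_fun
  mu_m <- latent_function_posterior(gd, m, one_draw(hp), effect = "mean",
                                    times = grid - h)$mean_fun
  expect_equal(fpd$moments[[1]]$mean, (mu_p - mu_m) / (2 * h),
               tolerance = 1e-5)
})

test_that("effect posteriors add up to the fitted-curve posterior", {
  gd <- orc_dataset(n_cond = 2, n_batch = 2, n_rep = 2, n_time = 5,
                    seed = 21)
  m <- build_model("batch", gd)
  hp <- orc_hp(m, seed = 3)
  grid <- seq(0, 48, length.out = 9)
  parts <- list(
    latent_function_posterior(gd, m, one_draw(hp), "mean", times = grid),
    latent_function_posterior(gd, m, one_draw(hp), "treatment",
                              level = "s2", times = grid),
    latent_function_posterior(gd, m, one_draw(hp), "mean_batch",
                              batch = "b1", times = grid),
    latent_function_posterior(gd, m, one_draw(hp), "treatment_batch",
                              level = "s2", batch = "b1", times = grid))
  whole <- latent_function_posterior(gd, m, one_draw(hp), "fitted",
                                     level = c(stress = "s2"),
                                     batch = "b1", times = grid)
  expect_equal(Reduce(`+`, lapply(parts, `[[`, "mean_fun")),
               whole$mean_fun, tolerance = 1e-8)
})

test_that("a latent function with no observations keeps its prior", {
  # level s2 measured only in batch b1: the (s2, b2) batch function exists
  # but loads on no observation
  rows <- list()
  for (b in c("b1", "b2")) for (s in c("s1", "s2")) {
    if (s == "s2" && b == "b2") next
    rows[[length(rows) + 1L]] <- data.frame(
      time = c(0, 24, 48), od = exp(c(0.1, 0.5, 1)), batch = b,
      replicate = "r1", stress = s)
  }
  gd <- preprocess(growth_data(do.call(rbind, rows)))
  m <- build_model("batch", gd)
  hp <- orc_hp(m, seed = 9)
  fp <- latent_function_posterior(gd, m, one_draw(hp, n = 400L),
                                  effect = "treatment_batch",
                                  level = "s2", batch = "b2",
                                  times = c(0, 24, 48), seed = 4)
  expect_equal(fp$moments, NULL)
  expect_equal(fp$mean_fun, rep(0, 3))                  # prior mean
  s2 <- hp[["treatment_batch.variance"]]
  expect_lt(abs(mean(apply(fp$draws, 2, var)) - s2) / s2, 0.35)
})

test_that("reference-level and unknown selectors are rejected", {
  gd <- orc_dataset(seed = 22)
  m <- build_model("batch", gd)
  s <- one_draw(orc_hp(m))
  expect_error(latent_function_posterior(gd, m, s, "treatment",
                                         level = "s1"),
               "reference level")
  expect_error(latent_function_posterior(gd, m, s, "nope"), "unknown effect")
  expect_error(latent_function_posterior(gd, m, s, "treatment_batch",
                                         level = "s2"), "needs `batch`")
  expect_error(latent_function_posterior(gd, m, s, "treatment",
                                         level = "zz"), "unknown level")
})

test_that("credible bands are pointwise quantile envelopes", {
  fp <- structure(list(times = 1:4, draws = matrix(2.5, 100, 4),
                       mean_fun = rep(2.5, 4), effect = "x",
                       derivative = FALSE), class = "effect_posterior")
  b <- credible_band(fp)
  expect_equal(b$lower, rep(2.5, 4))
  expect_equal(b$upper, rep(2.5, 4))
  expect_error(credible_band(fp, level = 0), "level")
  expect_error(credible_band(fp, level = 1), "level")

  set.seed(8)
  fp$times <- 1
  fp$draws <- matrix(rnorm(40000), 40000, 1)
  b2 <- credible_band(fp, 0.95)
  expect_lt(abs(b2$lower + 1.96), 0.05)
  expect_lt(abs(b2$upper - 1.96), 0.05)
  expect_lt(abs(b2$mean), 0.05)
})

test_that("significant intervals match a linear-scan oracle", {
  band <- data.frame(time = seq(0, 10, by = 2),
                     lower = c(1, 1, -1, 0.5, -2, 0.2),
                     upper = c(3, 2, -0.2, 1.5, -1, 0.9))
  si <- significant_intervals(band)
  # independent scan
  st <- ifelse(band$lower > 0, 1L, ifelse(band$upper < 0, -1L, 0L))
  runs <- rle(st)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  expect_equal(si$t_start, band$time[starts[keep]])
  expect_equal(si$t_end, band$time[ends[keep]])
  expect_equal(si$sign, ifelse(runs$values[keep] > 0, "+", "-"))

  # all-containing band: no intervals; all-excluding: one spanning run
  b0 <- data.frame(time = 1:6, lower = -1, upper = 1)
  expect_equal(nrow(significant_intervals(b0)), 0L)
  b1 <- data.frame(time = 1:6, lower = 1, mean = 2, upper = 3)
  s1 <- significant_intervals(b1)
  expect_equal(nrow(s1), 1L)
  expect_equal(c(s1$t_start, s1$t_end, s1$sign), c("1", "6", "+"))
})

test_that("intervals at 0.99 are a subset of intervals at 0.95", {
  set.seed(3)
  mu <- sin(seq(0, 3 * pi, length.out = 40))
  fp <- structure(list(times = seq_len(40), derivative = FALSE,
                       draws = t(replicate(500, mu + rnorm(40, sd = 0.6))),
                       mean_fun = mu, effect = "x"),
                  class = "effect_posterior")
  pts <- function(lv) {
    si <- significant_intervals(credible_band(fp, lv))
    unlist(lapply(seq_len(nrow(si)), function(i)
      seq(si$t_start[i], si$t_end[i])))
  }
  expect_true(all(pts(0.99) %in% pts(0.95)))
})

test_that("variance components mirror the model's group census", {
  gd <- orc_dataset(seed = 30)
  m0 <- build_model("null", gd)
  vc0 <- variance_components(one_draw(orc_hp(m0)), m0)
  expect_setequal(vc0$component, c("mean", "treatment", "noise"))
  mf <- build_model("full", gd)
  hp <- orc_hp(mf)
  vcf <- variance_components(one_draw(hp), mf)
  expect_setequal(vcf$component,
                  c("mean", "treatment", "batch", "biological", "noise"))
  # pooled batch component mixes both batch groups' draws
  expect_equal(vcf$mean[vcf$component == "batch"],
               mean(c(hp[["mean_batch.variance"]],
                      hp[["treatment_batch.variance"]])))
  vcu <- variance_components(one_draw(hp), mf, pool_batch = FALSE)
  expect_true(all(c("mean_batch", "treatment_batch") %in% vcu$component))
})

test_that("batch-vs-replicate variance ratios are recovered from data", {
  # ground truth: batch variance 5x the replicate variance; the posterior
  # mean ratio should land in [2, 10] in at least 90% of replications
  des <- sim_design(factors = list(stress = c("ctrl", "trt")), batches = 3,
                    replicates = 4, times = seq(0, 48, length.out = 10))
  truth <- c("mean.variance" = 1, "mean.lengthscale" = 0.15,
             "treatment.variance" = 0.4, "treatment.lengthscale" = 0.2,
             "mean_batch.variance" = 0.3, "mean_batch.lengthscale" = 0.25,
             "treatment_batch.variance" = 0.3,
             "treatment_batch.lengthscale" = 0.25,
             "replicate.variance" = 0.06, "replicate.lengthscale" = 0.15,
             "noise.variance" = 0.01)
  ok <- logical(20)
  set.seed(77)
  seeds <- sample.int(1e6, 20)
  for (r in seq_along(ok)) {
    sim <- simulate_growth(des, truth = truth, model = "full",
                           seed = seeds[r])
    samp <- sample_posterior(sim$data, sim$model, chains = 2, iter = 150,
                             warmup = 200, seed = seeds[r] + 1L)
    vc <- variance_components(samp, sim$model)
    ratio <- vc$mean[vc$component == "batch"] /
      vc$mean[vc$component == "biological"]
    ok[r] <- ratio >= 2 && ratio <= 10
  }
  expect_gte(sum(ok), 18L)
})

test_that("with noise pinned near zero the fit interpolates the data", {
  df <- data.frame(time = seq(0, 48, length.out = 6),
                   od = exp(c(0, 0.3, 0.9, 1.4, 1.6, 1.7)),
                   batch = "b1", replicate = "r1")
  gd <- preprocess(growth_data(df))
  m <- build_model("null", gd, structure = "mean_only")
  hp <- c("mean.variance" = 2, "mean.lengthscale" = 0.2,
          "noise.variance" = 1e-8)
  fp <- latent_function_posterior(gd, m, one_draw(hp), effect = "mean",
                                  times = df$time)
  expect_lt(max(abs(fp$mean_fun - gd$data$value)), 1e-4)
})
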