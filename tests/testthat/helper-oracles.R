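# Independent oracles used across the suite.  These are deliberately
# written as naive loops/closed forms, sharing no code path with the
# package internals they check.

# naive RBF kernel value, as-printed dialect
orc_k <- function(t1, t2, s2, ell) s2 * exp(-(t1 - t2)^2 / ell)

# Build the marginal covariance of a dataset by explicit enumeration of
# the latent functions: for every pair of observations, sum kernel terms
# for each effect group whose latent function both observations load on.
# Groups are described independently of the package's model objects.
orc_covariance <- function(gd, model, hp) {
  info <- gd$curves[match(gd$data$curve, gd$curves$curve), , drop = FALSE]
  tt <- (gd$data$time - gd$time_scale[["offset"]]) * gd$time_scale[["scale"]]
  n <- length(tt)
  ref <- model$reference

  # latent-function identity of observation i under group g, "" = none
  fun_id <- function(g, i) {
    lev <- vapply(g$factors, function(f) info[[f]][i], "")
    if (any(lev == vapply(g$factors, function(f) ref[[f]], "")))
      return("")
    id <- paste(c(g$name, lev), collapse = "|")
    if (isTRUE(g$batch_indexed)) id <- paste(id, info$batch[i], sep = "|")
    if (isTRUE(g$replicate))
      id <- paste(id, info$batch[i], info$replicate[i],
                  vapply(gd$factors, function(f) info[[f]][i], ""),
                  sep = "|")
    id
  }

  S <- matrix(0, n, n)
  for (g in model$groups) {
    s2 <- hp[[paste0(g$name, ".variance")]]
    ell <- hp[[paste0(g$name, ".lengthscale")]]
    ids <- vapply(seq_len(n), function(i) fun_id(g, i), "")
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (ids[i] != "" && ids[i] == ids[j])
        S[i, j] <- S[i, j] + orc_k(tt[i], tt[j], s2, ell)
    }
  }
  diag(S) <- diag(S) + hp[["noise.variance"]]
  S
}

# dense multivariate normal log density via eigendecomposition
orc_dmvnorm <- function(y, S) {
  e <- eigen(S, symmetric = TRUE)
  stopifnot(all(e$values > 0))
  z <- crossprod(e$vectors, y)
  -0.5 * (length(y) * log(2 * pi) + sum(log(e$values)) +
            sum(z^2 / e$values))
}

# small random dataset builder (shared grids optional)
orc_dataset <- function(n_cond = 2L, n_batch = 2L, n_rep = 2L, n_time = 3L,
                        shared_grid = TRUE, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (cc in seq_len(n_cond)) for (b in seq_len(n_batch))
    for (r in seq_len(n_rep)) {
      tt <- if (shared_grid) seq(0, 48, length.out = n_time)
      else sort(stats::runif(n_time, 0, 48))
      rows[[length(rows) + 1L]] <- data.frame(
        time = tt, od = exp(stats::rnorm(n_time)),
        batch = paste0("b", b), replicate = paste0("r", r),
        stress = paste0("s", cc))
    }
  gd <- growth_data(do.call(rbind, rows))
  preprocess(gd)
}

# random positive hyperparameters for a model
orc_hp <- function(model, seed = 1L) {
  set.seed(seed)
  pn <- gpgrowth:::param_names(model)
  hp <- stats::setNames(exp(stats::rnorm(length(pn), -1, 0.4)), pn)
  hp
}

# Empirical covariance of N forward simulations built directly from the
# latent-variable representation (each latent function drawn from its GP
# through a precomputed Cholesky, then summed through the incidence).
orc_forward_cov <- function(gd, model, hp, N = 2000L, seed = 99L) {
  A <- gpgrowth:::obs_assignments(gd, model)
  tt <- gpgrowth:::model_time(gd)
  n <- length(tt)
  pieces <- list()
  for (j in seq_along(model$groups)) {
    g <- model$groups[[j]]
    a <- A[, j]
    for (f in sort(unique(a[a > 0L]))) {
      sel <- which(a == f)
      K <- orc_k(outer(tt[sel], rep(1, length(sel))),
                 outer(rep(1, length(sel)), tt[sel]),
                 hp[[paste0(g$name, ".variance")]],
                 hp[[paste0(g$name, ".lengthscale")]])
      pieces[[length(pieces) + 1L]] <-
        list(sel = sel, Lt = t(chol(K + diag(1e-10, length(sel)))))
    }
  }
  set.seed(seed)
  Y <- matrix(stats::rnorm(N * n, sd = sqrt(hp[["noise.variance"]])), N, n)
  for (p in pieces) {
    Z <- matrix(stats::rnorm(N * length(p$sel)), length(p$sel), N)
    Y[, p$sel] <- Y[, p$sel] + t(p$Lt %*% Z)
  }
  crossprod(Y) / N
}
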