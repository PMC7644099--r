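# No-U-Turn sampler (slice variant, dual-averaging step-size adaptation,
# diagonal mass matrix estimated during warmup).  All randomness flows
# through R's RNG so identical seeds give identical draws.

nuts_chain <- function(lp_grad, z0, iter, warmup, target_accept = 0.8,
                       max_treedepth = 10L, seed = 1L) {
  set.seed(seed)
  D <- length(z0)
  minv <- rep(1, D)                    # inverse mass (posterior variances)
  Dmax <- 1000                         # divergence threshold

  cur <- lp_grad(z0)
  if (!is.finite(cur$lp)) stop("initialization error: non-finite target")
  z <- z0

  leapfrog <- function(z, p, g, eps) {
    p <- p + 0.5 * eps * g
    z <- z + eps * (minv * p)
    st <- lp_grad(z)
    p <- p + 0.5 * eps * st$grad
    list(z = z, p = p, lp = st$lp, grad = st$grad)
  }
  hamil <- function(lp, p) lp - 0.5 * sum(p^2 * minv)

  # reasonable initial step size: double/halve until acceptance crosses 1/2
  find_eps <- function(z, cur) {
    eps <- 0.1
    p <- stats::rnorm(D) / sqrt(minv)
    H0 <- hamil(cur$lp, p)
    st <- leapfrog(z, p, cur$grad, eps)
    H1 <- hamil(st$lp, st$p)
    if (!is.finite(H1)) {
      while (!is.finite(H1) && eps > 1e-10) {
        eps <- eps / 2
        st <- leapfrog(z, p, cur$grad, eps)
        H1 <- hamil(st$lp, st$p)
      }
      return(eps)
    }
    a <- if (H1 - H0 > log(0.5)) 1 else -1
    while (a * (hamil(st$lp, st$p) - H0) > -a * log(2)) {
      eps <- eps * 2^a
      if (eps > 1e3 || eps < 1e-10) break
      st <- leapfrog(z, p, cur$grad, eps)
      if (!is.finite(st$lp)) { eps <- eps / 2; break }
    }
    eps
  }

  eps <- find_eps(z, cur)
  mu <- log(10 * eps)
  log_eps_bar <- 0; Hbar <- 0
  gam <- 0.05; t0 <- 10; kap <- 0.75
  adapt_iter <- 0L

  # diagonal-mass adaptation windows
  mass_pts <- if (warmup >= 100L)
    unique(floor(warmup * c(0.35, 0.6, 0.85))) else integer(0)
  window <- matrix(0, nrow = 0, ncol = D)

  n_keep <- iter
  draws <- matrix(NA_real_, nrow = n_keep, ncol = D)
  divergent <- 0L
  treedepths <- integer(iter + warmup)

  divergence_flag <- FALSE
  build_tree <- function(z, p, st, logu, v, j, eps, H0) {
    if (j == 0L) {
      st1 <- leapfrog(z, p, st$grad, v * eps)
      H <- hamil(st1$lp, st1$p)
      if (!is.finite(H)) H <- -Inf
      n1 <- as.integer(logu <= H)
      s1 <- logu < H + Dmax
      if (!s1) divergence_flag <<- TRUE
      a <- min(1, exp(H - H0))
      if (!is.finite(a)) a <- 0
      list(zm = st1$z, pm = st1$p, stm = st1, zp = st1$z, pp = st1$p,
           stp = st1, zprime = st1$z, stprime = st1, n = n1, s = s1,
           alpha = a, nalpha = 1)
    } else {
      t1 <- build_tree(z, p, st, logu, v, j - 1L, eps, H0)
      if (!t1$s)
        return(t1)
      if (v == -1) {
        t2 <- build_tree(t1$zm, t1$pm, t1$stm, logu, v, j - 1L, eps, H0)
        t1$zm <- t2$zm; t1$pm <- t2$pm; t1$stm <- t2$stm
      } else {
        t2 <- build_tree(t1$zp, t1$pp, t1$stp, logu, v, j - 1L, eps, H0)
        t1$zp <- t2$zp; t1$pp <- t2$pp; t1$stp <- t2$stp
      }
      ntot <- t1$n + t2$n
      if (t2$n > 0L && stats::runif(1) < t2$n / ntot) {
        t1$zprime <- t2$zprime; t1$stprime <- t2$stprime
      }
      dz <- t1$zp - t1$zm
      t1$s <- t1$s && t2$s && (sum(dz * (minv * t1$pm)) >= 0) &&
        (sum(dz * (minv * t1$pp)) >= 0)
      t1$n <- ntot
      t1$alpha <- t1$alpha + t2$alpha
      t1$nalpha <- t1$nalpha + t2$nalpha
      t1
    }
  }

  total <- warmup + iter
  for (it in seq_len(total)) {
    p0 <- stats::rnorm(D) / sqrt(minv)
    H0 <- hamil(cur$lp, p0)
    logu <- H0 + log(stats::runif(1))
    zm <- z; zp <- z; pm <- p0; pp <- p0; stm <- cur; stp <- cur
    zc <- z; stc <- cur
    n <- 1L; s <- TRUE; j <- 0L
    divergence_flag <- FALSE
    alpha <- 0; nalpha <- 1
    while (s && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tr <- build_tree(zm, pm, stm, logu, v, j, eps, H0)
        zm <- tr$zm; pm <- tr$pm; stm <- tr$stm
      } else {
        tr <- build_tree(zp, pp, stp, logu, v, j, eps, H0)
        zp <- tr$zp; pp <- tr$pp; stp <- tr$stp
      }
      if (tr$s && tr$n > 0L && stats::runif(1) < min(1, tr$n / n)) {
        zc <- tr$zprime; stc <- tr$stprime
      }
      n <- n + tr$n
      dz <- zp - zm
      s <- tr$s && (sum(dz * (minv * pm)) >= 0) &&
        (sum(dz * (minv * pp)) >= 0)
      alpha <- tr$alpha; nalpha <- tr$nalpha
      j <- j + 1L
    }
    z <- zc; cur <- stc
    treedepths[it] <- j
    if (it > warmup && divergence_flag) divergent <- divergent + 1L

    if (it <= warmup) {
      # dual averaging
      adapt_iter <- adapt_iter + 1L
      Hbar <- (1 - 1 / (adapt_iter + t0)) * Hbar +
        (target_accept - alpha / nalpha) / (adapt_iter + t0)
      log_eps <- mu - sqrt(adapt_iter) / gam * Hbar
      w <- adapt_iter^(-kap)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      # mass adaptation
      window <- rbind(window, z)
      if (it %in% mass_pts) {
        nw <- nrow(window)
        if (nw > 4L) {
          v_est <- apply(window, 2, stats::var)
          minv <- (nw / (nw + 5)) * v_est + 1e-3 * (5 / (nw + 5))
          window <- matrix(0, nrow = 0, ncol = D)
          eps <- find_eps(z, cur)
          mu <- log(10 * eps)
          log_eps_bar <- 0; Hbar <- 0; adapt_iter <- 0L
        }
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- z
    }
  }
  list(draws = draws, divergent = divergent, eps = eps, minv = minv,
       treedepth = treedepths)
}

#' Sample the hyperparameter posterior by NUTS
#'
#' Draws from the posterior of all kernel hyperparameters and the noise
#' variance, proportional to `prior_logpdf + marginal_loglik`.  Sampling is
#' on the log scale (positivity by construction, Jacobian included); all
#' latent functions are marginalized analytically, so the sampler explores
#' only the low-dimensional hyperparameter space.  Identical seeds and
#' configuration give identical draws.
#'
#' @inheritParams marginal_loglik
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iter post-warmup draws per chain.
#' @param warmup adaptation iterations per chain (discarded).
#' @param seed integer master seed.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_treedepth maximum NUTS doubling depth.
#' @param fix optional named vector of hyperparameters to hold fixed (they
#'   are excluded from sampling).
#' @param verbose print per-chain progress.
#' @return a `gp_mcmc` object: `draws` (iter x chain x parameter array on
#'   the natural scale), `divergent` per chain, and the configuration.
#' @export
sample_posterior <- function(gd, model, chains = 4L, iter = 1000L,
                             warmup = 1000L, seed = 1L,
                             target_accept = 0.8, max_treedepth = 10L,
                             fix = NULL, method = c("auto", "reduced",
                                                    "dense"),
                             verbose = FALSE) {
  stopifnot(iter >= 1L, warmup >= 0L, chains >= 1L)
  method <- match.arg(method)
  engine <- build_engine(gd, model, method = method)
  pn <- engine$param_names
  if (!is.null(fix)) {
    bad <- setdiff(names(fix), pn)
    if (length(bad) > 0L) stop("unknown fixed parameter(s): ",
                               paste(bad, collapse = ", "))
  }
  free <- setdiff(pn, names(fix))
  if (length(free) == 0L) stop("no free parameters to sample")
  ifree <- match(free, pn)

  hp_full <- function(zfree) {
    hp <- numeric(length(pn)); names(hp) <- pn
    if (!is.null(fix)) hp[names(fix)] <- fix
    hp[ifree] <- exp(zfree)
    hp
  }
  lp_grad <- function(zfree) {
    hp <- hp_full(zfree)
    res <- tryCatch(engine_eval(engine, as.numeric(hp), want_grad = TRUE),
                    error = function(e) list(ok = FALSE))
    if (!res$ok || !is.finite(res$ll))
      return(list(lp = -Inf, grad = rep(0, length(zfree))))
    pr <- prior_logpdf(hp, model)
    lp <- res$ll + pr + sum(zfree)       # Jacobian of the log transform
    if (!is.finite(lp))
      return(list(lp = -Inf, grad = rep(0, length(zfree))))
    g <- res$grad[ifree] + prior_grad_all(hp, model)[ifree]
    list(lp = lp, grad = g)
  }

  set.seed(seed)
  chain_seeds <- sample.int(2^30, chains)
  draws <- array(NA_real_, dim = c(iter, chains, length(free)),
                 dimnames = list(NULL, NULL, free))
  divergent <- integer(chains)
  depths <- vector("list", chains)
  for (ch in seq_len(chains)) {
    # initialize from the priors, seed-controlled, retry on non-finite target
    set.seed(chain_seeds[ch])
    z0 <- NULL
    for (try in seq_len(100L)) {
      hp0 <- prior_draw_all(model)
      if (!is.null(fix)) hp0[names(fix)] <- fix
      z <- log(hp0[free])
      if (is.finite(lp_grad(z)$lp)) { z0 <- z; break }
    }
    if (is.null(z0))
      stop("initialization error: no finite starting point in 100 draws")
    res <- nuts_chain(lp_grad, z0, iter = iter, warmup = warmup,
                      target_accept = target_accept,
                      max_treedepth = max_treedepth,
                      seed = chain_seeds[ch] + 1L)
    draws[, ch, ] <- exp(res$draws)
    divergent[ch] <- res$divergent
    depths[[ch]] <- res$treedepth
    if (verbose)
      message(sprintf("chain %d: %d divergent, step size %.3g", ch,
                      res$divergent, res$eps))
  }
  ndiv <- sum(divergent)
  if (ndiv > 0.01 * chains * iter)
    warning(sprintf("%d divergent transitions (> 1%% of draws); ",
                    ndiv), "posterior geometry may be poorly explored")
  structure(list(draws = draws, parameters = free, divergent = divergent,
                 fixed = fix,
                 config = list(chains = chains, iter = iter,
                               warmup = warmup, seed = seed,
                               target_accept = target_accept,
                               max_treedepth = max_treedepth,
                               method = method)),
            class = "gp_mcmc")
}

#' Split potential scale reduction factor
#'
#' Split-\eqn{\hat R}: each chain is halved, and the classical
#' between/within variance ratio is computed over the resulting 2m
#' sequences.  Values near 1 indicate convergence; the conventional
#' threshold is \eqn{\hat R < 1.1}.  Constant chains (zero within-chain
#' variance) give `NaN` with a warning.
#'
#' @param samples a `gp_mcmc` object (>= 2 chains, >= 4 iterations).
#' @return named vector of \eqn{\hat R} per parameter.
#' @export
rhat <- function(samples) {
  stopifnot(inherits(samples, "gp_mcmc"))
  d <- samples$draws
  if (dim(d)[2L] < 2L) stop("diagnostic error: R-hat needs >= 2 chains")
  if (dim(d)[1L] < 4L) stop("diagnostic error: R-hat needs >= 4 iterations")
  vapply(seq_len(dim(d)[3L]), function(j) split_rhat(d[, , j, drop = FALSE]),
         0) -> r
  names(r) <- samples$parameters
  r
}

split_rhat <- function(x) {
  x <- matrix(x, nrow = dim(x)[1L])
  n2 <- floor(nrow(x) / 2L)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(c)
    cbind(x[seq_len(n2), c], x[n2 + seq_len(n2), c])))
  m <- ncol(halves); n <- nrow(halves)
  mns <- colMeans(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(mns)
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size (classical, non-rank-normalized; Geyer initial
# monotone truncation of the autocorrelation sum)
ess_basic <- function(x) {
  x <- matrix(x, nrow = dim(x)[1L])
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- sapply(seq_len(m), function(c) {
    a <- stats::acf(x[, c], lag.max = n - 1L, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- matrix(acov, nrow = n)
  chain_var <- acov[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  varp <- (n - 1) / n * W + (if (m > 1L) stats::var(colMeans(x)) else 0)
  if (varp <= 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / varp
  rho[1L] <- 1
  # Geyer: sum over initial positive pairs
  tau <- 0; t <- 1L
  maxt <- 2L * floor((n - 2L) / 2L)
  while (t < maxt) {
    pair <- rho[t + 1L] + if (t + 2L <= length(rho)) rho[t + 2L] else 0
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, standard deviation, central 95% interval
#' (quantiles by linear interpolation of order statistics), split-\eqn{\hat
#' R} and effective sample size.
#'
#' @param samples a `gp_mcmc` object.
#' @param prob central interval probability (default 0.95).
#' @return a data.frame, one row per parameter.
#' @export
posterior_summary <- function(samples, prob = 0.95) {
  stopifnot(inherits(samples, "gp_mcmc"))
  d <- samples$draws
  a <- (1 - prob) / 2
  r <- if (dim(d)[2L] >= 2L && dim(d)[1L] >= 4L)
    suppressWarnings(rhat(samples)) else rep(NA_real_, dim(d)[3L])
  out <- data.frame(
    parameter = samples$parameters,
    mean = apply(d, 3, mean),
    sd = apply(d, 3, stats::sd),
    lower = apply(d, 3, stats::quantile, probs = a, type = 7),
    upper = apply(d, 3, stats::quantile, probs = 1 - a, type = 7),
    rhat = as.numeric(r),
    ess = apply(d, 3, function(x) ess_basic(array(x, dim = dim(d)[1:2]))),
    row.names = NULL)
  out
}

#' @export
print.gp_mcmc <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("gp_mcmc: %d chains x %d draws (%d warmup), %d parameters\n",
              cfg$chains, cfg$iter, cfg$warmup, length(x$parameters)))
  cat(sprintf("  divergent transitions: %d\n", sum(x$divergent)))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

# long-format draws for serialization
#' @export
as.data.frame.gp_mcmc <- function(x, ...) {
  d <- x$draws
  di <- dim(d)
  data.frame(
    chain = rep(rep(seq_len(di[2L]), each = di[1L]), times = di[3L]),
    iteration = rep(seq_len(di[1L]), times = di[2L] * di[3L]),
    parameter = rep(x$parameters, each = di[1L] * di[2L]),
    value = as.vector(d))
}
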