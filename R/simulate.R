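# Forward simulator of the full generative model: latent functions drawn
# from their GPs on the simulation grid, summed through the design
# incidence, plus replicate GPs and iid observation noise.

#' Describe a simulated experimental design
#'
#' @param factors named list of factor level vectors (possibly empty).
#' @param batches number of batches (or a vector of batch labels).
#' @param replicates replicate curves per (condition, batch) cell.
#' @param times observation grid in hours.
#' @return a `sim_design` list.
#' @export
sim_design <- function(factors = list(), batches = 2L, replicates = 3L,
                       times = seq(0, 48, length.out = 25L)) {
  if (length(batches) == 1L && is.numeric(batches))
    batches <- sprintf("B%02d", seq_len(batches))
  stopifnot(replicates >= 1L, length(times) >= 2L,
            !is.unsorted(times, strictly = TRUE))
  structure(list(factors = factors, batches = as.character(batches),
                 replicates = as.integer(replicates), times = times),
            class = "sim_design")
}

#' Study-design presets for simulation
#'
#' `"halo_like"`: one treatment factor at 3 levels, 9 batches, 12
#' replicates per cell, 48 h at 30-min intervals (the balanced idealization
#' of a large archaeal oxidative-stress screen).  `"halo_reduced"`: 2
#' conditions x 3 batches x 3 replicates x 25 time points over 48 h, a
#' desk-scale version of the same design.  `"pa_like"`: full-factorial
#' 3 pH x 3 acid concentrations, 2 batches, 3 replicates, 24 h at 15-min
#' intervals.
#'
#' @param name preset name.
#' @return a [sim_design] object.
#' @export
sim_preset <- function(name = c("halo_reduced", "halo_like", "pa_like")) {
  name <- match.arg(name)
  switch(name,
    halo_like = sim_design(
      factors = list(condition = c("standard", "low", "high")),
      batches = 9L, replicates = 12L, times = seq(0, 48, by = 0.5)),
    halo_reduced = sim_design(
      factors = list(condition = c("standard", "stress")),
      batches = 3L, replicates = 3L,
      times = seq(0, 48, length.out = 25L)),
    pa_like = sim_design(
      factors = list(pH = c("pH7", "pH6", "pH5"),
                     acid = c("00mM", "10mM", "20mM")),
      batches = 2L, replicates = 3L, times = seq(0, 24, by = 0.25)))
}

# default ground-truth hyperparameters: batch variance comparable to the
# treatment variance (the regime where hierarchical modelling matters),
# batch effects several-fold above replicate and instrument noise
default_truth <- function(model) {
  hp <- numeric(0)
  for (g in model$groups) {
    v <- if (isTRUE(g$replicate)) c(0.06, 0.15)
    else if (isTRUE(g$batch_indexed)) c(0.3, 0.25)
    else if (g$name == "mean") c(1.0, 0.15)
    else c(0.4, 0.2)
    hp[paste0(g$name, ".variance")] <- v[1L]
    hp[paste0(g$name, ".lengthscale")] <- v[2L]
  }
  hp["noise.variance"] <- 0.01
  hp
}

#' Simulate a growth dataset from the generative model
#'
#' Draws every latent function of the requested hierarchy from its GP prior
#' on the design grid (Cholesky of the kernel), sums them through the
#' design incidence, and adds iid Gaussian observation noise (plus
#' per-curve replicate GPs when `model = "full"`).  Values are on the
#' log-OD scale; the returned dataset is ready for [gpgrowth()].
#'
#' @param design a [sim_design] (or preset name, see [sim_preset()]).
#' @param truth `"default"`, `"prior"` (hyperparameters drawn from the
#'   model priors), or a named hyperparameter vector.
#' @param model generative hierarchy: `"null"`, `"batch"` or `"full"`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param preset prior preset used when `truth = "prior"`.
#' @param reference optional reference levels (see [build_model()]).
#' @param dialect kernel dialect.
#' @return a list with `data` (a [growth_data], log scale, time
#'   standardized), `truth` (hyperparameters used plus the realized latent
#'   functions per effect on the grid) and `model` (the `gp_model` used to
#'   generate).
#' @export
simulate_growth <- function(design, truth = "default",
                            model = c("full", "batch", "null"), seed = 1L,
                            preset = c("halobacterium", "pseudomonas"),
                            reference = NULL,
                            dialect = c("as_printed",
                                        "squared_lengthscale")) {
  if (is.character(design) && length(design) == 1L)
    design <- sim_preset(design)
  stopifnot(inherits(design, "sim_design"))
  model <- match.arg(model)
  preset <- match.arg(preset)
  dialect <- match.arg(dialect)

  grid_h <- design$times
  if (anyDuplicated(grid_h) > 0L)
    stop("config error: duplicated grid times")

  # curve table: full factorial of conditions x batches x replicates
  conds <- if (length(design$factors) > 0L)
    expand.grid(design$factors, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1L)
  ncond <- max(nrow(conds), 1L)
  curves <- expand.grid(replicate = sprintf("r%02d",
                                            seq_len(design$replicates)),
                        batch = design$batches,
                        cond = seq_len(ncond),
                        stringsAsFactors = FALSE)
  for (f in names(design$factors))
    curves[[f]] <- conds[[f]][curves$cond]
  curves$cond <- NULL
  ncurve <- nrow(curves)

  # skeleton dataset (defines model time and incidence)
  df <- data.frame(
    time = rep(grid_h, ncurve),
    od = 1,
    batch = rep(curves$batch, each = length(grid_h)),
    replicate = rep(curves$replicate, each = length(grid_h)))
  for (f in names(design$factors))
    df[[f]] <- rep(curves[[f]], each = length(grid_h))
  gd <- growth_data(df, factors = names(design$factors))
  gd$log_transformed <- TRUE
  gd <- preprocess(gd, log_transform = FALSE, standardize_time = TRUE)

  priors <- default_priors(preset)
  mdef <- build_model(model, gd, priors = priors, reference = reference,
                      dialect = dialect)

  set.seed(seed)
  hp <- if (identical(truth, "default")) default_truth(mdef)
  else if (identical(truth, "prior")) prior_draw_all(mdef)
  else check_hp_vector(truth, mdef)
  if (any(hp <= 0)) stop("config error: ground-truth values must be positive")

  tg <- model_time(gd, grid_h)
  nt <- length(tg)
  latents <- list()
  for (g in mdef$groups) {
    K <- rbf_kernel(tg, tg, hp[[paste0(g$name, ".variance")]],
                    hp[[paste0(g$name, ".lengthscale")]], dialect)
    L <- chol(K + diag(1e-10, nt))
    a <- group_assign(g, mdef, gd$curves)
    nfun <- max(a, 0L)
    F <- t(L) %*% matrix(stats::rnorm(nt * nfun), nt, nfun)
    colnames(F) <- attr(a, "labels")
    latents[[g$name]] <- list(values = F, assign = as.integer(a))
  }

  sdy <- sqrt(hp[["noise.variance"]])
  vals <- matrix(stats::rnorm(nt * ncurve, sd = sdy), nt, ncurve)
  for (g in mdef$groups) {
    la <- latents[[g$name]]
    on <- la$assign > 0L
    if (any(on))
      vals[, on] <- vals[, on] + la$values[, la$assign[on], drop = FALSE]
  }

  # gd$data rows are sorted by (curve, time); curve ids follow the order of
  # first appearance in df, which is the curves-table order, and the grid is
  # ascending, so columns of `vals` line up directly
  gd$data$value <- as.vector(vals)
  truth_out <- list(
    hyperparams = hp,
    times = grid_h,
    latents = lapply(latents, function(l) l$values))
  list(data = gd, truth = truth_out, model = mdef)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates datasets, fits the model by MCMC, and reports per
#' variance component the bias and RMSE of the posterior mean and the
#' coverage of the central 95% credible interval, plus the split-R-hat
#' convergence status of each run.  With `truth = "prior"` each
#' replication's ground truth is drawn from the model priors, making
#' nominal coverage the self-consistency benchmark.
#'
#' @param design a [sim_design].
#' @param n_reps number of replications (>= 1).
#' @param model hierarchy to simulate from and fit.
#' @param truth as in [simulate_growth()].
#' @param chains,iter,warmup MCMC settings per replication.
#' @param seed master seed; the whole report is reproducible bit for bit.
#' @param preset prior preset.
#' @return a list with `per_rep` (one row per replication and parameter),
#'   `summary` (per variance component: bias, relative bias, RMSE,
#'   coverage) and `config`.
#' @export
recovery_experiment <- function(design, n_reps = 10L,
                                model = c("full", "batch", "null"),
                                truth = "prior", chains = 2L, iter = 250L,
                                warmup = 250L, seed = 1L,
                                preset = c("halobacterium",
                                           "pseudomonas")) {
  stopifnot(n_reps >= 1L)
  model <- match.arg(model)
  preset <- match.arg(preset)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_growth(design, truth = truth, model = model,
                           seed = rep_seeds[r], preset = preset)
    samp <- sample_posterior(sim$data, sim$model, chains = chains,
                             iter = iter, warmup = warmup,
                             seed = rep_seeds[r] + 1L)
    ps <- posterior_summary(samp)
    maxr <- suppressWarnings(max(ps$rhat, na.rm = TRUE))
    tr <- sim$truth$hyperparams[ps$parameter]
    rows[[r]] <- data.frame(
      rep = r, parameter = ps$parameter, truth = as.numeric(tr),
      post_mean = ps$mean, lower = ps$lower, upper = ps$upper,
      covered = tr >= ps$lower & tr <= ps$upper,
      max_rhat = maxr, rhat_ok = is.finite(maxr) && maxr < 1.1)
  }
  per_rep <- do.call(rbind, rows)
  vc <- grepl("\\.variance$", per_rep$parameter)
  agg <- split(per_rep[vc, ], per_rep$parameter[vc])
  summ <- do.call(rbind, lapply(agg, function(d) data.frame(
    parameter = d$parameter[1L],
    bias = mean(d$post_mean - d$truth),
    rel_bias = mean(d$post_mean - d$truth) / mean(d$truth),
    rmse = sqrt(mean((d$post_mean - d$truth)^2)),
    coverage = mean(d$covered))))
  rownames(summ) <- NULL
  list(per_rep = per_rep, summary = summ,
       config = list(n_reps = n_reps, model = model, chains = chains,
                     iter = iter, warmup = warmup, seed = seed))
}
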