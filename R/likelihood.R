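# Likelihood engine: precomputes the structures needed to evaluate the
# marginal log-likelihood (and its gradient in the log-hyperparameters)
# repeatedly during sampling.
#
# Replicate curves that share a (condition, batch) cell and an identical
# time grid are exchangeable under the model, so the observation vector is
# rotated (orthonormal Helmert transform per cell) into
#   * the scaled cell mean sqrt(R_c) * ybar_c, whose covariance keeps the
#     full cross-cell structure (fixed + batch effects scaled by
#     sqrt(R_i R_j)) plus one replicate-GP/noise block per cell, and
#   * R_c - 1 iid contrast vectors ~ N(0, K_rep + sigma_y^2 I), entering the
#     likelihood only through their scatter matrix.
# The rotation is orthonormal, so the density is unchanged; cells whose
# curves have unequal grids simply stay as singleton cells, which recovers
# the dense computation.  This is exact, not an approximation.

build_engine <- function(gd, model, method = c("auto", "reduced", "dense")) {
  method <- match.arg(method)
  curves <- gd$curves
  key <- do.call(paste, c(lapply(c(gd$factors, "batch"),
                                 function(k) curves[[k]]), sep = "\r"))
  if (method == "dense") key <- as.character(curves$curve)

  cell_of <- match(key, unique(key))
  ncell0 <- max(cell_of)

  # split cells whose member curves do not share a time grid
  split_curves <- split(curves$curve, cell_of)
  times_of <- split(gd$data$time, gd$data$curve)
  vals_of <- split(gd$data$value, gd$data$curve)
  cells <- list()
  for (cc in split_curves) {
    grids <- times_of[as.character(cc)]
    same <- length(cc) > 1L &&
      all(vapply(grids[-1L], function(g)
        length(g) == length(grids[[1L]]) && all(g == grids[[1L]]), TRUE))
    if (same && method != "dense") {
      cells[[length(cells) + 1L]] <- cc
    } else {
      for (one in cc) cells[[length(cells) + 1L]] <- one
    }
  }

  rep_idx <- 0L
  for (j in seq_along(model$groups))
    if (isTRUE(model$groups[[j]]$replicate)) rep_idx <- j

  # per-group curve-level assignments
  assign_c <- lapply(model$groups, group_assign, model = model,
                     curves = curves)

  u <- numeric(0); tt_h <- numeric(0); cell_id <- integer(0)
  Rc_all <- numeric(0)
  cell_assign <- matrix(0L, nrow = length(cells),
                        ncol = length(model$groups))
  contrasts_raw <- list()
  for (ci in seq_along(cells)) {
    cc <- cells[[ci]]
    Rc <- length(cc)
    grid <- times_of[[as.character(cc[1L])]]
    Y <- vapply(as.character(cc), function(k) vals_of[[k]],
                numeric(length(grid)))
    Y <- matrix(Y, nrow = length(grid))
    ybar <- rowMeans(Y)
    u <- c(u, sqrt(Rc) * ybar)
    tt_h <- c(tt_h, grid)
    cell_id <- c(cell_id, rep(ci, length(grid)))
    Rc_all[ci] <- Rc
    i0 <- match(cc[1L], curves$curve)
    for (j in seq_along(model$groups)) {
      cell_assign[ci, j] <- if (j == rep_idx) ci else assign_c[[j]][i0]
    }
    if (Rc >= 2L) {
      S <- tcrossprod(Y) - Rc * tcrossprod(ybar)
      contrasts_raw[[length(contrasts_raw) + 1L]] <-
        list(S = S, m = Rc - 1, grid = grid)
    }
  }

  tt <- (tt_h - gd$time_scale[["offset"]]) * gd$time_scale[["scale"]]
  D2 <- outer(tt, tt, "-")^2
  sr <- sqrt(Rc_all)[cell_id]
  masks <- vector("list", length(model$groups))
  for (j in seq_along(model$groups)) {
    a <- cell_assign[cell_id, j]
    if (j == rep_idx) {
      masks[[j]] <- (outer(a, a, "==")) * 1
    } else {
      masks[[j]] <- ((a > 0L) & outer(a, a, "==")) * outer(sr, sr)
    }
  }

  # pool contrast scatter over cells sharing a model-time grid
  contrasts <- list()
  if (length(contrasts_raw) > 0L) {
    sig <- vapply(contrasts_raw, function(cb)
      paste(signif(cb$grid, 12), collapse = ","), "")
    for (s in unique(sig)) {
      sel <- contrasts_raw[sig == s]
      S <- Reduce(`+`, lapply(sel, `[[`, "S"))
      m <- sum(vapply(sel, `[[`, 0, "m"))
      g <- sel[[1L]]$grid
      gm <- (g - gd$time_scale[["offset"]]) * gd$time_scale[["scale"]]
      contrasts[[length(contrasts) + 1L]] <-
        list(S = S, m = m, D2 = outer(gm, gm, "-")^2)
    }
  }

  list(u = u, D2 = D2, masks = masks, noise_w = rep(1, length(u)),
       contrasts = contrasts, rep_idx = rep_idx,
       dialect_code = if (model$dialect == "as_printed") 1L else 2L,
       n_obs = nrow(gd$data), n_rows = length(u),
       tt = tt, tt_h = tt_h, cell_id = cell_id, Rc = Rc_all,
       cell_assign = cell_assign,
       labels = lapply(assign_c, attr, "labels"),
       param_names = param_names(model))
}

engine_eval <- function(engine, hp_vec, want_grad = TRUE) {
  .eng_eval(engine$u, engine$D2, engine$masks, engine$noise_w,
            engine$contrasts, engine$rep_idx, hp_vec,
            engine$dialect_code, want_grad)
}

#' Marginal log-likelihood of a growth dataset
#'
#' Multivariate-normal log density of the concatenated observations with
#' mean zero and covariance [assemble_covariance()] (all latent GPs
#' integrated out analytically).
#'
#' @inheritParams assemble_covariance
#' @param method `"auto"` exploits exchangeable replicate curves exactly;
#'   `"dense"` forces the full observation-level computation.  Both give the
#'   same value.
#' @return a scalar log-likelihood.
#' @export
marginal_loglik <- function(gd, model, hp,
                            method = c("auto", "reduced", "dense")) {
  hp <- check_hp_vector(hp, model)
  engine <- build_engine(gd, model, method = match.arg(method))
  res <- engine_eval(engine, as.numeric(hp), want_grad = FALSE)
  if (!res$ok) stop("numerical error: covariance not factorizable ",
                    "after jitter escalation")
  res$ll
}
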