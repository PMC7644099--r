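#' Growth-curve datasets
#'
#' A `growth_data` object holds a collection of plate-reader optical-density
#' time series in long format, annotated with experimental factor levels, a
#' batch identifier (one run of the plate reader) and a replicate identifier
#' (one well; unique within its batch).  Curves may have unequal time grids;
#' missing observations are simply absent rows.
#'
#' @param df a data.frame in long format.
#' @param time,value,batch,replicate names of the columns holding time
#'   (hours), optical density, batch id and replicate id.
#' @param factors character vector naming the experimental factor columns
#'   (e.g. stress level, pH).  Defaults to every remaining column.
#' @return an object of class `growth_data` with components `data` (long
#'   data.frame: `curve`, `time`, `value`), `curves` (one row per curve:
#'   `curve`, `batch`, `replicate` and one column per factor), `factors`,
#'   `levels`, `log_transformed` and `time_scale` (affine map from hours to
#'   model time: `model_time = (hours - offset) * scale`).
#' @export
growth_data <- function(df, time = "time", value = "od", batch = "batch",
                        replicate = "replicate", factors = NULL) {
  stopifnot(is.data.frame(df))
  need <- c(time, value, batch, replicate)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(factors))
    factors <- setdiff(names(df), need)
  miss <- setdiff(factors, names(df))
  if (length(miss) > 0L)
    stop("schema error: missing factor column(s): ", paste(miss, collapse = ", "))

  tvals <- df[[time]]
  yvals <- df[[value]]
  if (is.character(tvals)) tvals <- suppressWarnings(as.numeric(tvals))
  if (is.character(yvals)) yvals <- suppressWarnings(as.numeric(yvals))
  bad <- which(!is.finite(tvals) | !is.finite(yvals))
  if (length(bad) > 0L)
    stop("parse error: non-numeric or missing time/value in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))

  key_cols <- c(factors, batch, replicate)
  key <- do.call(paste, c(lapply(key_cols, function(k) as.character(df[[k]])),
                          sep = "\r"))
  curve_id <- match(key, unique(key))

  dup <- duplicated(data.frame(curve_id, tvals))
  if (any(dup))
    stop("data error: duplicate (curve, time) rows, e.g. row ",
         which(dup)[1L])

  ord <- order(curve_id, tvals)
  dat <- data.frame(curve = curve_id[ord], time = tvals[ord],
                    value = yvals[ord])

  first <- !duplicated(curve_id)
  curves <- data.frame(curve = curve_id[first],
                       batch = as.character(df[[batch]])[first],
                       replicate = as.character(df[[replicate]])[first],
                       stringsAsFactors = FALSE)
  for (f in factors)
    curves[[f]] <- as.character(df[[f]])[first]
  curves <- curves[order(curves$curve), , drop = FALSE]
  rownames(curves) <- NULL
  if (any(!nzchar(curves$batch)) || any(!nzchar(curves$replicate)))
    stop("data error: empty batch or replicate identifier")

  lev <- lapply(curves[factors], function(x) sort(unique(x)))
  names(lev) <- factors

  structure(list(data = dat, curves = curves, factors = factors,
                 levels = lev, log_transformed = FALSE,
                 time_scale = c(offset = 0, scale = 1)),
            class = "growth_data")
}

#' Read a long-format growth table
#'
#' Reads a delimited table of plate-reader measurements (header required;
#' delimiter inferred from the file extension, comma for `.csv` and tab
#' otherwise, overridable) and groups rows into growth curves, one per
#' distinct (factor levels, batch, replicate) combination.  Values are left
#' untransformed; see [preprocess()].
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @inheritParams growth_data
#' @return a [growth_data] object.
#' @export
read_growth_table <- function(path, time = "time", value = "od",
                              batch = "batch", replicate = "replicate",
                              factors = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  growth_data(df, time = time, value = value, batch = batch,
              replicate = replicate, factors = factors)
}

#' Write a growth dataset back to a delimited table
#'
#' Serializes a [growth_data] object to the same long CSV/TSV dialect read
#' by [read_growth_table()].  Values are written on the dataset's current
#' scale (raw OD, or log OD after [preprocess()]); times are always written
#' in hours.
#'
#' @param gd a [growth_data] object.
#' @param path output file path.
#' @param sep delimiter; `NULL` to infer from the extension.
#' @export
write_growth_table <- function(gd, path, sep = NULL) {
  stopifnot(inherits(gd, "growth_data"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  info <- gd$curves[match(gd$data$curve, gd$curves$curve), , drop = FALSE]
  # 17 significant digits: doubles survive the round trip exactly
  num <- function(x) sub("^\\s+", "", formatC(x, digits = 17, format = "g"))
  out <- data.frame(time = num(gd$data$time), od = num(gd$data$value),
                    batch = info$batch, replicate = info$replicate)
  for (f in gd$factors) out[[f]] <- info[[f]]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Preprocess a growth dataset for modelling
#'
#' Applies the natural-log transform to OD values and (by default) maps
#' observed times affinely onto the unit interval; the map is stored in
#' `time_scale` and all user-facing output is converted back to hours.
#' Modelling log OD means time-zero inoculation offsets are absorbed by the
#' batch effects rather than subtracted; an optional blank value can be
#' subtracted before the log for instruments that report a media baseline.
#' Time standardization is idempotent: it always recomputes the map from the
#' raw times in hours.
#'
#' @param gd a [growth_data] object.
#' @param log_transform take the natural log of the values (error if values
#'   are not all positive; a second call is a no-op).
#' @param standardize_time map times onto [0, 1].
#' @param blank blank OD subtracted before the log transform (default 0).
#' @return the transformed [growth_data] object.
#' @export
preprocess <- function(gd, log_transform = TRUE, standardize_time = TRUE,
                       blank = 0) {
  stopifnot(inherits(gd, "growth_data"))
  if (log_transform && !gd$log_transformed) {
    v <- gd$data$value - blank
    bad <- which(v <= 0)
    if (length(bad) > 0L) {
      i <- bad[1L]
      stop(sprintf(
        "transform error: non-positive OD (curve %d at time %g h)",
        gd$data$curve[i], gd$data$time[i]))
    }
    gd$data$value <- log(v)
    gd$log_transformed <- TRUE
  }
  if (standardize_time) {
    rng <- range(gd$data$time)
    span <- rng[2L] - rng[1L]
    if (span <= 0) stop("transform error: degenerate time range")
    gd$time_scale <- c(offset = rng[1L], scale = 1 / span)
  }
  gd
}

# model-scale times for the observation rows
model_time <- function(gd, hours = gd$data$time) {
  (hours - gd$time_scale[["offset"]]) * gd$time_scale[["scale"]]
}

#' Validate an experimental design for a given model
#'
#' Checks identifiability of the requested hierarchy against the observed
#' design: batch (and replicate) random effects need more than one batch;
#' factor levels observed in a single batch give confounded batch effects.
#'
#' @param gd a [growth_data] object.
#' @param model one of `"null"`, `"batch"`, `"full"`.
#' @return a data.frame report with columns `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows when the design is clean.  The
#'   replicate count per (condition, batch) cell is attached as attribute
#'   `"cells"`.
#' @export
validate_design <- function(gd, model = c("batch", "null", "full")) {
  stopifnot(inherits(gd, "growth_data"))
  model <- match.arg(model)
  sev <- character(0); msg <- character(0)
  nb <- length(unique(gd$curves$batch))
  if (model %in% c("batch", "full") && nb < 2L) {
    sev <- c(sev, "error")
    msg <- c(msg, "batch effects unidentifiable: design has a single batch")
  }
  for (f in gd$factors) {
    for (l in gd$levels[[f]]) {
      bl <- unique(gd$curves$batch[gd$curves[[f]] == l])
      if (model %in% c("batch", "full") && nb > 1L && length(bl) == 1L) {
        sev <- c(sev, "warning")
        msg <- c(msg, sprintf(
          "level '%s' of factor '%s' observed in only one batch", l, f))
      }
    }
  }
  cond <- if (length(gd$factors) > 0L)
    interaction(gd$curves[gd$factors], drop = TRUE, sep = ":")
  else factor(rep("all", nrow(gd$curves)))
  cells <- as.data.frame(table(condition = cond, batch = gd$curves$batch),
                         responseName = "replicates")
  rep <- data.frame(severity = sev, message = msg,
                    stringsAsFactors = FALSE)
  attr(rep, "cells") <- cells
  class(rep) <- c("design_report", class(rep))
  rep
}

#' @export
print.design_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("design OK: no errors or warnings\n")
  } else {
    for (i in seq_len(nrow(x)))
      cat(sprintf("[%s] %s\n", x$severity[i], x$message[i]))
  }
  cells <- attr(x, "cells")
  cat("replicates per (condition, batch):\n")
  print(utils::head(cells[cells$replicates > 0, ], 20L), row.names = FALSE)
  invisible(x)
}

#' Subset a growth dataset by batch or factor level
#'
#' @param x a [growth_data] object.
#' @param batches batches to keep (default all).
#' @param levels named list of factor levels to keep.
#' @param ... unused.
#' @return the filtered [growth_data] (factor level tables recomputed;
#'   preprocessing state preserved).
#' @export
subset.growth_data <- function(x, batches = NULL, levels = NULL, ...) {
  keep <- rep(TRUE, nrow(x$curves))
  if (!is.null(batches)) keep <- keep & x$curves$batch %in% batches
  if (!is.null(levels))
    for (f in names(levels))
      keep <- keep & x$curves[[f]] %in% levels[[f]]
  ids <- x$curves$curve[keep]
  if (length(ids) == 0L) stop("empty subset")
  x$curves <- x$curves[keep, , drop = FALSE]
  rownames(x$curves) <- NULL
  x$data <- x$data[x$data$curve %in% ids, , drop = FALSE]
  rownames(x$data) <- NULL
  x$levels <- lapply(x$curves[x$factors], function(v) sort(unique(v)))
  names(x$levels) <- x$factors
  x
}

#' @export
print.growth_data <- function(x, ...) {
  cat(sprintf("growth_data: %d curves, %d observations\n",
              nrow(x$curves), nrow(x$data)))
  cat(sprintf("  factors: %s\n", if (length(x$factors) > 0L)
    paste(sprintf("%s (%d levels)", x$factors,
                  lengths(x$levels)), collapse = ", ") else "none"))
  cat(sprintf("  batches: %d; time range %g-%g h; %s scale\n",
              length(unique(x$curves$batch)),
              min(x$data$time), max(x$data$time),
              if (x$log_transformed) "log-OD" else "raw OD"))
  invisible(x)
}
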