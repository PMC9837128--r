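#' A FRET time series of G-protein subunit dissociation
#'
#' Container for one measured (or synthetic) FRET series: signal as percent
#' of initial intensity against time, for one ligand/pH combination, with the
#' ligand-addition time annotated. Before the addition time the signal sits
#' at a flat ~100% baseline; afterwards it decays as G-proteins dissociate
#' (the model maps the count of undissociated G-proteins affinely onto the
#' signal).
#'
#' @param time_s Times in seconds, strictly increasing.
#' @param signal_pct FRET signal, percent of initial intensity.
#' @param ligand `"fentanyl"` or `"NFEPP"`.
#' @param pH `6.5` or `7.4`.
#' @param addition_time Annotated ligand-addition time (s); `NA` if unknown
#'   (use [preprocess_fret()] with `detect_offset = TRUE`).
#' @return Object of class `"fret_series"`.
#' @export
fret_series <- function(time_s, signal_pct, ligand = c("fentanyl", "NFEPP"),
                        pH = 7.4, addition_time = 20) {
  ligand <- match.arg(ligand)
  if (length(time_s) != length(signal_pct))
    stop("time and signal lengths differ")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (!pH %in% c(6.5, 7.4)) stop("pH must be 6.5 or 7.4")
  structure(list(time_s = as.numeric(time_s),
                 signal_pct = as.numeric(signal_pct),
                 ligand = ligand, pH = pH,
                 addition_time = addition_time),
            class = "fret_series")
}

#' @export
print.fret_series <- function(x, ...) {
  cat(sprintf("FRET series: %s / pH %.1f, %d points over [%g, %g] s, ligand added at %s s\n",
              x$ligand, x$pH, length(x$time_s), min(x$time_s), max(x$time_s),
              format(x$addition_time)))
  invisible(x)
}

#' @export
as.data.frame.fret_series <- function(x, ...) {
  data.frame(ligand = x$ligand, pH = x$pH, time_s = x$time_s,
             signal_pct = x$signal_pct)
}

#' Align a FRET series to the ligand-addition time
#'
#' Shifts the time axis so that model time 0 coincides with ligand addition;
#' pre-addition samples get negative times and are retained as the baseline
#' for the scaling transform. The offset is taken from the annotation, or
#' detected from the data (`detect_offset = TRUE`) by least-squares
#' change-point fitting of a flat-baseline-plus-smooth-onset model (constant
#' before the change point, linear + quadratic hinge after it).
#'
#' @param series A [fret_series()].
#' @param detect_offset Detect the change point instead of using the
#'   annotation.
#' @return The aligned `fret_series` (addition time 0); the offset applied is
#'   stored in attribute `"offset"`.
#' @export
preprocess_fret <- function(series, detect_offset = FALSE) {
  off <- series$addition_time
  if (detect_offset || is.na(off)) {
    off <- .detect_offset(series$time_s, series$signal_pct)
  } else if (sum(series$time_s < off) < 3 && off != 0) {
    stop("need at least 3 pre-addition baseline points")
  }
  out <- series
  out$time_s <- series$time_s - off
  out$addition_time <- 0
  attr(out, "offset") <- off
  out
}

# Change-point detection: for each candidate time tau, fit a flat baseline
# plus a smooth polynomial onset (hinge powers 1..4 of (t - tau)_+) over the
# whole series and keep the tau with least mean squared residual. The onset
# has zero jump and zero initial slope, matching the gradual start of
# G-protein dissociation; accuracy is typically within two samples.
.detect_offset <- function(t, y) {
  n <- length(t)
  if (n < 10) stop("too few points to detect the ligand-addition offset")
  cand <- t[seq(4, n - 5)]
  msr <- vapply(cand, function(tau) {
    h <- pmax(t - tau, 0)
    mean(stats::lm.fit(cbind(1, h, h^2, h^3, h^4), y)$residuals^2)
  }, numeric(1))
  if (!(diff(range(msr)) > 1e-10 * (max(msr) + 1e-12)))
    stop("no baseline plateau detectable; annotate the addition time")
  cand[which.min(msr)]
}

# Model curve of undissociated G-proteins for one aligned series:
# constant 40 before addition, RRE solution afterwards.
.model_gprotein <- function(times_aligned, rates) {
  tpos <- pmax(times_aligned, 0)
  grid <- sort(unique(c(0, tpos)))
  net <- mor_network(rates)
  sol <- integrate_rre(net, initial_state(a = 0), grid)
  sol$conc[match(tpos, grid), "aGDPbg"]
}

# Closed-form per-series scaling transform: least squares of the data on the
# model curve. Returns list(slope, intercept, fitted, mse).
.fit_transform <- function(signal, m) {
  X <- cbind(1, m)
  fit <- stats::lm.fit(X, signal)
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       fitted = as.vector(X %*% fit$coefficients),
       mse = mean(fit$residuals^2))
}

#' Residual between the model and FRET data
#'
#' For each series, integrates the reaction-rate equation with the shared
#' rates and that series' binding rate `k1` (with `k11 = 0`), maps the
#' undissociated-G-protein curve through an affine scaling transform onto
#' the percent-FRET scale, and takes the mean squared difference from the
#' data; the residual is the sum of these per-series means. The transform is
#' solved in closed form (linear least squares) per series unless supplied.
#'
#' @param rates Shared rates, a [mor_rates()] vector or a named vector
#'   containing `k2..k10` (the `k1` slot is ignored; `k11` forced to 0).
#' @param k1 Numeric vector of per-series binding rates, recycled to the
#'   number of series.
#' @param datasets List of aligned [fret_series()] (see
#'   [preprocess_fret()]).
#' @param transforms Optional list of per-series `list(slope, intercept)`;
#'   if `NULL` each transform is profiled out by least squares.
#' @return The nonnegative residual, with per-series details in attribute
#'   `"details"`. If the ODE solver fails at the proposed rates, a large
#'   penalty value (`1e8`) is returned with a warning.
#' @export
fret_residual <- function(rates, k1, datasets, transforms = NULL) {
  k <- unclass(if (inherits(rates, "mor_rates")) rates else
    do.call(mor_rates, as.list(rates)))
  k1 <- rep_len(k1, length(datasets))
  total <- 0
  details <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    s <- datasets[[i]]
    ki <- k
    ki[["k1"]] <- k1[i]
    ki[["k11"]] <- 0
    m <- tryCatch(
      .model_gprotein(s$time_s, do.call(mor_rates, as.list(ki))),
      error = function(e) NULL)
    if (is.null(m)) {
      warning("ODE solver failed at the proposed rates; penalty applied")
      return(structure(1e8, details = NULL))
    }
    if (is.null(transforms)) {
      tr <- .fit_transform(s$signal_pct, m)
    } else {
      tr <- transforms[[i]]
      tr$fitted <- tr$intercept + tr$slope * m
      tr$mse <- mean((s$signal_pct - tr$fitted)^2)
    }
    total <- total + tr$mse
    details[[i]] <- tr
  }
  structure(total, details = details)
}

#' Literature-preselected binding rates
#'
#' The rough `k1` values chosen from relative binding-affinity changes in
#' molecular-dynamics work, used as starting values for the fit.
#'
#' @param ligand `"fentanyl"` or `"NFEPP"`.
#' @param pH `6.5` or `7.4`.
#' @return Binding rate in s^-1.
#' @export
k1_preselected <- function(ligand = c("fentanyl", "NFEPP"), pH = 7.4) {
  ligand <- match.arg(ligand)
  if (!pH %in% c(6.5, 7.4)) stop("pH must be 6.5 or 7.4")
  if (ligand == "fentanyl") {
    if (pH == 6.5) 1.25e-2 else 2.5e-2
  } else {
    if (pH == 6.5) 2.5e-3 else 5e-4
  }
}

#' Fit the MOR signalling model to FRET time series
#'
#' Two-stage estimation of the reaction rate constants from FRET series of
#' G-protein dissociation. Stage one minimises the summed per-series
#' mean-squared residual between the affinely rescaled
#' undissociated-G-protein curve of the reaction-rate equation and the data,
#' over the shared intracellular rates `k2..k10` in log10 space
#' (bound-constrained to a trust region around the starting values,
#' multi-started); by default the per-series binding rates `k1` are adapted
#' jointly in this stage (`joint = TRUE`), which is markedly more robust
#' when the starting `k1` are far off; `joint = FALSE` holds them at their
#' starting values as in a strict shared-only first stage. Stage two
#' fine-tunes `k1` per series with the shared rates fixed. The per-series
#' affine scaling transform is profiled out in closed form throughout, and
#' `k11` is fixed at 0 (the data come from radical-free conditions). `k7`
#' and `k8` (slow receptor recycling and degradation) are frozen by
#' default; the data span is too short to inform them.
#'
#' Identifiability caveat: FRET data observe the G-protein pool only, so
#' the calcium-channel cycle rates `k5`/`k6` move the fitted curves by less
#' than typical measurement noise across decade-scale changes and are not
#' reliably recoverable; see the package vignette.
#'
#' @param data List of [fret_series()] (typically the four ligand/pH
#'   combinations). Unaligned series are passed through
#'   [preprocess_fret()].
#' @param start_rates Starting shared rates (default: the preselected
#'   values).
#' @param start_k1 Starting per-series `k1`; defaults to the preselected
#'   value for each series' ligand/pH.
#' @param frozen Character vector of rate names among `k2..k10` to hold at
#'   their starting values.
#' @param joint Adapt per-series `k1` together with the shared rates in
#'   stage one.
#' @param span Half-width (decades) of the stage-one trust region around
#'   the starting values.
#' @param n_cycles Number of stage-one/stage-two sweeps.
#' @param n_starts Number of optimiser starts for stage one (the first from
#'   `start_rates`, the rest jittered in log10 space).
#' @param maxit Iteration cap per optimiser start.
#' @param seed Seed for the start jitter.
#' @param detect_offset Passed to [preprocess_fret()].
#' @return Object of class `"mor_fit"` with components `rates` (fitted
#'   shared rates as [mor_rates()], `k1` slot set to the first series'),
#'   `k1` (named per-series vector), `transforms`, `residual`,
#'   `residual_start`, `convergence`, `start` (starting values), and the
#'   aligned `data`. Supports `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' spec <- synth_spec(noise_sd = 0.5, seed = 7)
#' fit <- mor_fit(generate_fret_dataset(spec))
#' coef(fit)
#' }
#' @export
mor_fit <- function(data, start_rates = mor_rates(preselected = TRUE),
                    start_k1 = NULL, frozen = c("k7", "k8"),
                    joint = TRUE, span = 2, n_cycles = 1, n_starts = 3,
                    maxit = 600, seed = 1, detect_offset = FALSE) {
  if (inherits(data, "fret_series")) data <- list(data)
  data <- lapply(data, function(s)
    if (s$addition_time == 0 && !detect_offset) s
    else preprocess_fret(s, detect_offset = detect_offset))
  ns <- length(data)
  if (is.null(start_k1))
    start_k1 <- vapply(data, function(s) k1_preselected(s$ligand, s$pH),
                       numeric(1))
  start_k1 <- rep_len(start_k1, ns)
  names(start_k1) <- vapply(data, function(s)
    sprintf("%s_pH%.1f", s$ligand, s$pH), character(1))

  shared_names <- paste0("k", 2:10)
  bad <- setdiff(frozen, shared_names)
  if (length(bad)) stop("cannot freeze unknown rates: ",
                        paste(bad, collapse = ", "))
  free <- setdiff(shared_names, frozen)
  k <- unclass(start_rates)
  k1_cur <- start_k1
  res0 <- as.numeric(fret_residual(do.call(mor_rates, as.list(k)), k1_cur,
                                   data))

  nf <- length(free)
  obj <- function(p) {
    kk <- k
    kk[free] <- 10^p[seq_len(nf)]
    k1p <- if (joint) 10^p[nf + seq_len(ns)] else k1_cur
    as.numeric(fret_residual(do.call(mor_rates, as.list(kk)), k1p, data))
  }

  set.seed(seed)
  convergence <- 0L
  for (cycle in seq_len(n_cycles)) {
    if (nf > 0 || joint) {
      p0 <- c(log10(k[free]), if (joint) log10(k1_cur))
      starts <- list(p0)
      if (cycle == 1 && n_starts > 1)
        for (m in seq_len(n_starts - 1))
          starts[[m + 1]] <- p0 + stats::runif(length(p0), -0.3, 0.3)
      best <- NULL
      for (st in starts) {
        o <- stats::optim(st, obj, method = "L-BFGS-B",
                          lower = p0 - span, upper = p0 + span,
                          control = list(maxit = maxit))
        if (is.null(best) || o$value < best$value) best <- o
      }
      k[free] <- 10^best$par[seq_len(nf)]
      if (joint) k1_cur[] <- 10^best$par[nf + seq_len(ns)]
      convergence <- best$convergence
    }
    rates_fix <- do.call(mor_rates, as.list(k))
    for (i in seq_len(ns))
      k1_cur[i] <- fit_k1_per_series(data[[i]], rates_fix,
                                     k1_start = k1_cur[i])
  }

  rates_fit <- do.call(mor_rates, as.list(`[<-`(k, "k1", k1_cur[1])))
  final <- fret_residual(rates_fit, k1_cur, data)
  structure(list(rates = rates_fit, k1 = k1_cur,
                 transforms = lapply(attr(final, "details"), function(d)
                   d[c("slope", "intercept")]),
                 residual = as.numeric(final), residual_start = res0,
                 convergence = convergence, frozen = frozen,
                 start = list(rates = start_rates, k1 = start_k1),
                 data = data),
            class = "mor_fit")
}

#' Fine-tune the binding rate for a single FRET series
#'
#' One-dimensional minimisation (in log10 space) of the single-series
#' residual over `k1 > 0`, with all other rates fixed.
#'
#' @param series An aligned [fret_series()].
#' @param rates Fixed shared rates ([mor_rates()]).
#' @param k1_start Centre of the search bracket.
#' @param span Half-width of the log10 search bracket.
#' @return The fitted `k1` (s^-1). If the residual is essentially flat in
#'   `k1` (uninformative data) the result carries attribute
#'   `"flat" = TRUE` and a warning is issued.
#' @export
fit_k1_per_series <- function(series, rates, k1_start = 2.5e-2, span = 2.5) {
  if (series$addition_time != 0) series <- preprocess_fret(series)
  f <- function(lk) as.numeric(fret_residual(rates, 10^lk, list(series)))
  lo <- log10(k1_start) - span
  hi <- log10(k1_start) + span
  probe <- vapply(seq(lo, hi, length.out = 7), f, numeric(1))
  flat <- diff(range(probe)) < 1e-9 * (1 + max(probe))
  if (flat) warning("residual is flat in k1; data uninformative")
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-5)
  structure(10^opt$minimum, flat = if (flat) TRUE else NULL)
}

#' @export
print.mor_fit <- function(x, ...) {
  cat("MOR signalling model fit (shared rates + per-series k1)\n")
  cat(sprintf("  residual: %.4g (started at %.4g)\n", x$residual,
              x$residual_start))
  cat("  shared rates (s^-1):\n")
  k <- unclass(x$rates)[paste0("k", 2:10)]
  cat(sprintf("    %s\n", paste(names(k), signif(k, 3), sep = " = ",
                                collapse = ", ")))
  cat("  per-series k1 (s^-1):\n")
  for (i in seq_along(x$k1))
    cat(sprintf("    %-18s %.3g\n", names(x$k1)[i], x$k1[i]))
  invisible(x)
}

#' @export
coef.mor_fit <- function(object, ...) {
  c(unclass(object$rates)[paste0("k", 2:10)],
    stats::setNames(object$k1, paste0("k1_", names(object$k1))))
}

#' @export
summary.mor_fit <- function(object, ...) {
  per_series <- data.frame(
    series = names(object$k1),
    k1 = as.numeric(object$k1),
    slope = vapply(object$transforms, `[[`, numeric(1), "slope"),
    intercept = vapply(object$transforms, `[[`, numeric(1), "intercept"))
  out <- list(shared = unclass(object$rates)[paste0("k", 2:10)],
              per_series = per_series, residual = object$residual,
              residual_start = object$residual_start,
              frozen = object$frozen, convergence = object$convergence)
  class(out) <- "summary.mor_fit"
  out
}

#' @export
print.summary.mor_fit <- function(x, ...) {
  cat("Shared intracellular rates (s^-1):\n")
  print(signif(x$shared, 3))
  cat(sprintf("(frozen: %s)\n", paste(x$frozen, collapse = ", ")))
  cat("\nPer-series binding rate and scaling transform:\n")
  print(x$per_series, row.names = FALSE)
  cat(sprintf("\nResidual: %.4g (initial %.4g); optimiser convergence code %d\n",
              x$residual, x$residual_start, x$convergence))
  invisible(x)
}

#' Predicted FRET curves from a fitted model
#'
#' @param object A [mor_fit()].
#' @param newtimes Optional vector of aligned times (s) at which to predict;
#'   defaults to each series' own times.
#' @param ... Ignored.
#' @return List (one element per series) of data frames with `time_s` and
#'   `fitted` percent signal.
#' @export
predict.mor_fit <- function(object, newtimes = NULL, ...) {
  k <- unclass(object$rates)
  lapply(seq_along(object$data), function(i) {
    tt <- if (is.null(newtimes)) object$data[[i]]$time_s else newtimes
    ki <- `[<-`(k, "k1", object$k1[i])
    m <- .model_gprotein(tt, do.call(mor_rates, as.list(`[<-`(ki, "k11", 0))))
    tr <- object$transforms[[i]]
    data.frame(time_s = tt, fitted = tr$intercept + tr$slope * m)
  })
}

#' @export
residuals.mor_fit <- function(object, ...) {
  pred <- predict(object)
  lapply(seq_along(pred), function(i)
    object$data[[i]]$signal_pct - pred[[i]]$fitted)
}

#' Plot FRET data with fitted model curves
#'
#' @param x A [mor_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mor_fit <- function(x, ...) {
  pred <- predict(x)
  cols <- grDevices::hcl.colors(length(x$data), "Dark 3")
  rng_t <- range(unlist(lapply(x$data, `[[`, "time_s")))
  rng_y <- range(unlist(lapply(x$data, `[[`, "signal_pct")))
  graphics::plot(NA, xlim = rng_t, ylim = rng_y, xlab = "time from ligand addition (s)",
                 ylab = "FRET signal (% of initial)", ...)
  for (i in seq_along(x$data)) {
    graphics::points(x$data[[i]]$time_s, x$data[[i]]$signal_pct,
                     col = grDevices::adjustcolor(cols[i], 0.4), pch = 16,
                     cex = 0.4)
    graphics::lines(pred[[i]]$time_s, pred[[i]]$fitted, col = cols[i],
                    lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(x$k1), col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate FRET datasets from a fitted model
#'
#' Draws new synthetic FRET datasets from the fitted rates, per-series `k1`
#' and scaling transforms, with Gaussian noise at the residual standard
#' deviation of the fit.
#'
#' @param object A [mor_fit()].
#' @param nsim Number of datasets.
#' @param seed Base seed.
#' @param ... Ignored.
#' @return A list of datasets (each a list of [fret_series()]); a single
#'   dataset if `nsim = 1`.
#' @export
simulate.mor_fit <- function(object, nsim = 1, seed = 1, ...) {
  sd_hat <- sqrt(object$residual / length(object$data))
  s1 <- object$data[[1]]
  dt <- min(diff(s1$time_s))
  out <- lapply(seq_len(nsim), function(i) {
    spec <- synth_spec(
      rates = object$rates,
      k1 = as.numeric(object$k1),
      ligand = vapply(object$data, `[[`, character(1), "ligand"),
      pH = vapply(object$data, `[[`, numeric(1), "pH"),
      transforms = object$transforms,
      noise_sd = sd_hat, dt = dt,
      duration = max(s1$time_s) + attr(object$data[[1]], "offset") %||% 20,
      addition_time = attr(object$data[[1]], "offset") %||% 20,
      seed = seed + i - 1)
    generate_fret_dataset(spec)
  })
  if (nsim == 1) out[[1]] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read FRET datasets as CSV
#'
#' Long CSV with columns `series_id, ligand, pH, time_s, signal_pct`, plus a
#' JSON side-car recording each series' ligand-addition offset (and, for
#' synthetic data, the generating truth).
#'
#' @param datasets List of [fret_series()].
#' @param path CSV path.
#' @param sidecar_path JSON side-car path (default `path` with
#'   `.offsets.json`).
#' @param truth Optional list recorded verbatim in the side-car (generating
#'   parameters of synthetic data).
#' @return `path` invisibly (write); list of `fret_series` (read).
#' @export
write_fret_csv <- function(datasets, path, sidecar_path = NULL,
                           truth = NULL) {
  if (inherits(datasets, "fret_series")) datasets <- list(datasets)
  ids <- vapply(seq_along(datasets), function(i)
    sprintf("S%d_%s_pH%.1f", i, datasets[[i]]$ligand, datasets[[i]]$pH),
    character(1))
  df <- do.call(rbind, lapply(seq_along(datasets), function(i)
    cbind(series_id = ids[i], as.data.frame(datasets[[i]]))))
  utils::write.csv(df, path, row.names = FALSE)
  if (is.null(sidecar_path))
    sidecar_path <- sub("\\.csv$", ".offsets.json", path)
  side <- list(offsets = as.list(stats::setNames(
    vapply(datasets, `[[`, numeric(1), "addition_time"), ids)))
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fret_csv
#' @export
read_fret_csv <- function(path, sidecar_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(sidecar_path))
    sidecar_path <- sub("\\.csv$", ".offsets.json", path)
  offsets <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path)$offsets else list()
  lapply(split(df, factor(df$series_id, levels = unique(df$series_id))),
         function(d) {
           off <- offsets[[d$series_id[1]]] %||% NA_real_
           fret_series(d$time_s, d$signal_pct, ligand = d$ligand[1],
                       pH = d$pH[1], addition_time = as.numeric(off))
         })
}
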