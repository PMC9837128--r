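#' Reference receptor-ligand binding rates
#'
#' The fitted binding rate `k1` for each ligand/pH combination. Without
#' radicals these are the per-series estimates from the FRET fit (pH 7.4:
#' fentanyl 2.81e-3, NFEPP 1.79e-4 s^-1; pH 6.5: fentanyl 2.1625e-3, NFEPP
#' 7.5e-3 s^-1). With radicals present, disulfide-bond disruption lowers
#' ligand binding: the pH 6.5 values are reduced to 80% (fentanyl 1.73e-3,
#' NFEPP 6e-3 s^-1) while pH 7.4 values are unchanged.
#'
#' @param ligand `"fentanyl"` or `"NFEPP"`.
#' @param pH `6.5` or `7.4`.
#' @param radicals Reactive oxygen species present?
#' @return Binding rate in s^-1.
#' @export
k1_reference <- function(ligand = c("fentanyl", "NFEPP"), pH = 7.4,
                         radicals = FALSE) {
  ligand <- match.arg(ligand)
  if (!pH %in% c(6.5, 7.4)) stop("pH must be 6.5 or 7.4")
  base <- if (ligand == "fentanyl") {
    if (pH == 6.5) 2.1625e-3 else 2.81e-3
  } else {
    if (pH == 6.5) 7.5e-3 else 1.79e-4
  }
  if (radicals && pH == 6.5) 0.8 * base else base
}

#' Resolve a simulation scenario
#'
#' Maps a (ligand, pH, radicals) condition onto the model parameters it
#' implies: the binding rate `k1` from [k1_reference()], the constitutive
#' activation rate `k11` (5e-5 s^-1 with radicals, else 0), and the closed-
#' channel base level `a` of the initial state (5 with radicals, else 0).
#'
#' @inheritParams k1_reference
#' @param base_rates Shared rates for `k2..k10`.
#' @return Object of class `"mor_scenario"`: list with `ligand`, `pH`,
#'   `radicals`, `k1`, `k11`, `a`, `rates` (full [mor_rates()]) and `init`.
#' @examples
#' resolve_scenario("fentanyl", 7.4)[c("k1", "k11", "a")]
#' resolve_scenario("NFEPP", 6.5, radicals = TRUE)[c("k1", "k11", "a")]
#' @export
resolve_scenario <- function(ligand = c("fentanyl", "NFEPP"), pH = 7.4,
                             radicals = FALSE, base_rates = mor_rates()) {
  ligand <- match.arg(ligand)
  k1 <- k1_reference(ligand, pH, radicals)
  k11 <- if (radicals) 5e-5 else 0
  a <- if (radicals) 5L else 0L
  k <- unclass(base_rates)
  k[["k1"]] <- k1
  k[["k11"]] <- k11
  structure(list(ligand = ligand, pH = pH, radicals = radicals, k1 = k1,
                 k11 = k11, a = a, rates = do.call(mor_rates, as.list(k)),
                 init = initial_state(a = a)),
            class = "mor_scenario")
}

#' @export
print.mor_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s, pH %.1f, %s radicals -> k1 = %g, k11 = %g, a = %d\n",
              x$ligand, x$pH, if (x$radicals) "with" else "no", x$k1, x$k11,
              x$a))
  invisible(x)
}

.scenario_label <- function(sc)
  sprintf("%s_pH%.1f%s", sc$ligand, sc$pH, if (sc$radicals) "_radicals" else "")

.run_scenario <- function(sc, n_runs, t_end, grid_dt, seed_base) {
  net <- mor_network(sc$rates)
  run_ensemble(net, sc$init, t_end = t_end, grid_dt = grid_dt,
               n_runs = n_runs, seed_base = seed_base)
}

#' Percent of closed calcium channels over time
#'
#' @param ensemble A [run_ensemble()] result.
#' @return Numeric vector: ensemble-mean `Ca_off` as percent of all
#'   channels.
#' @export
closed_channel_pct <- function(ensemble) {
  total <- sum(ensemble$mean[1, c("Ca_on", "Ca_off")])
  100 * ensemble$mean[, "Ca_off"] / total
}

#' pH study: channel inhibition across the four ligand/pH conditions
#'
#' Runs radical-free ensembles for fentanyl and NFEPP at pH 6.5 and 7.4 and
#' summarises the mean percent of closed calcium channels, its across-run
#' variance, the batch-means 95% confidence band, and the peak amplitude per
#' scenario.
#'
#' @param n_runs Runs per scenario.
#' @param t_end,grid_dt Horizon and grid (s).
#' @param seed_base Base seed; scenario `i` uses `seed_base + (i-1)*n_runs`.
#' @param batch_size Batch size for the confidence band (skipped if it does
#'   not divide `n_runs`).
#' @return Object of class `"mor_ph_study"`: per-scenario list with the
#'   scenario, ensemble, percent curve, variance curve, CI and peak; plus a
#'   `peaks` summary table.
#' @export
run_ph_study <- function(n_runs = 500, t_end = 1200, grid_dt = 1,
                         seed_base = 1, batch_size = 50) {
  grid <- list(c("fentanyl", 6.5), c("fentanyl", 7.4),
               c("NFEPP", 6.5), c("NFEPP", 7.4))
  out <- vector("list", 4)
  for (i in seq_along(grid)) {
    sc <- resolve_scenario(grid[[i]][1], as.numeric(grid[[i]][2]),
                           radicals = FALSE)
    ens <- .run_scenario(sc, n_runs, t_end, grid_dt,
                         seed_base + (i - 1) * n_runs)
    ci <- if (n_runs %% batch_size == 0)
      batch_mean_ci(ens, "Ca_off", batch_size) else NULL
    pct <- closed_channel_pct(ens)
    out[[i]] <- list(scenario = sc, ensemble = ens, pct = pct,
                     variance = ens$variance[, "Ca_off"], ci = ci,
                     peak_pct = max(pct),
                     peak_time = ens$time[which.max(pct)])
    names(out)[i] <- .scenario_label(sc)
  }
  peaks <- data.frame(
    scenario = names(out),
    k1 = vapply(out, function(o) o$scenario$k1, numeric(1)),
    peak_pct = vapply(out, `[[`, numeric(1), "peak_pct"),
    peak_time_s = vapply(out, `[[`, numeric(1), "peak_time"),
    row.names = NULL)
  structure(list(scenarios = out, peaks = peaks, n_runs = n_runs),
            class = "mor_ph_study")
}

#' @export
print.mor_ph_study <- function(x, ...) {
  cat(sprintf("pH study, %d runs per scenario; peak %% of closed channels:\n",
              x$n_runs))
  print(transform(x$peaks, peak_pct = round(peak_pct, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mor_ph_study <- function(x, ...) {
  cols <- grDevices::hcl.colors(4, "Dark 3")
  tt <- x$scenarios[[1]]$ensemble$time
  graphics::plot(NA, xlim = range(tt), ylim = c(0, 50), xlab = "time (s)",
                 ylab = "closed calcium channels (%)", ...)
  for (i in seq_along(x$scenarios))
    graphics::lines(tt, x$scenarios[[i]]$pct, col = cols[i], lwd = 2)
  graphics::legend("topright", legend = names(x$scenarios), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Peak channel inhibition as a function of the binding rate
#'
#' Sweeps `k1` over a log-spaced grid (radical-free network otherwise) and
#' records the amplitude: the maximum over time of the ensemble-mean percent
#' of closed calcium channels. The curve is non-decreasing in `k1` up to
#' Monte-Carlo error and rises steeply below about 2e-3 s^-1.
#'
#' @param k1_grid Binding-rate grid (s^-1).
#' @param n_runs Runs per grid point.
#' @param t_end,grid_dt Horizon and grid (s).
#' @param seed_base Base seed.
#' @param base_rates Shared rates.
#' @return Object of class `"mor_amplitude_curve"`: data frame `curve` with
#'   `k1`, `amplitude_pct`, `se_pct` (Monte-Carlo standard error of the mean
#'   at the peak).
#' @export
amplitude_vs_k1 <- function(k1_grid = 10^seq(-4, -1, length.out = 25),
                            n_runs = 500, t_end = 1200, grid_dt = 1,
                            seed_base = 1, base_rates = mor_rates()) {
  k <- unclass(base_rates)
  k[["k11"]] <- 0
  amp <- se <- numeric(length(k1_grid))
  for (i in seq_along(k1_grid)) {
    ki <- `[<-`(k, "k1", k1_grid[i])
    net <- mor_network(do.call(mor_rates, as.list(ki)))
    ens <- run_ensemble(net, initial_state(a = 0), t_end = t_end,
                        grid_dt = grid_dt, n_runs = n_runs,
                        seed_base = seed_base + (i - 1) * n_runs)
    pct <- closed_channel_pct(ens)
    pk <- which.max(pct)
    amp[i] <- pct[pk]
    total <- sum(ens$mean[1, c("Ca_on", "Ca_off")])
    se[i] <- 100 * sqrt(ens$variance[pk, "Ca_off"] / n_runs) / total
  }
  structure(list(curve = data.frame(k1 = k1_grid, amplitude_pct = amp,
                                    se_pct = se),
                 n_runs = n_runs),
            class = "mor_amplitude_curve")
}

#' @export
print.mor_amplitude_curve <- function(x, ...) {
  cat(sprintf("Amplitude vs k1 (%d runs per point):\n", x$n_runs))
  print(transform(x$curve, amplitude_pct = round(amplitude_pct, 1),
                  se_pct = signif(se_pct, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mor_amplitude_curve <- function(x, ...) {
  graphics::plot(x$curve$k1, x$curve$amplitude_pct, log = "x", type = "b",
                 pch = 16, xlab = expression(k[1] ~ (s^-1)),
                 ylab = "amplitude of channel inhibition (%)", ...)
  graphics::abline(v = 2e-3, lty = 3)
  invisible(x)
}

#' Distribution of receptor-ligand binding events
#'
#' Normalised histogram, over Monte-Carlo runs, of the number of binding
#' reactions (R1) fired during a whole simulation. Since only 10 ligands
#' exist and none is ever produced, the support is `{0, ..., 10}`.
#'
#' @param scenario A [resolve_scenario()] result.
#' @param n_runs,t_end,grid_dt,seed_base Ensemble controls.
#' @return Named numeric vector of probabilities for counts `0..10`
#'   (sums to 1), with the scenario label as attribute.
#' @export
binding_event_distribution <- function(scenario, n_runs = 500, t_end = 1200,
                                       grid_dt = 10, seed_base = 1) {
  ens <- .run_scenario(scenario, n_runs, t_end, grid_dt, seed_base)
  counts <- tabulate(ens$firings[, "R1"] + 1L, nbins = 11L)
  structure(stats::setNames(counts / n_runs, 0:10),
            scenario = .scenario_label(scenario))
}

#' Radical study: healthy versus inflamed tissue
#'
#' For each ligand, compares the healthy condition (pH 7.4, no radicals,
#' `k11 = 0`, base level 0) with progressive inflammation (pH 6.5, radicals,
#' `k11 = 5e-5`, base level `a = 5`, binding rate reduced to 80% of its
#' pH 6.5 value). Inflamed ensembles start from the constitutive steady
#' state, so their closed-channel baseline is 6.25% rather than 0.
#'
#' @param ligands Ligands to study.
#' @param n_runs,t_end,grid_dt,seed_base Ensemble controls.
#' @return Object of class `"mor_radical_study"`: per ligand, the healthy
#'   and inflamed scenario results (ensemble, percent curve, peak), plus a
#'   summary table of peaks and baselines.
#' @export
run_radical_study <- function(ligands = c("fentanyl", "NFEPP"), n_runs = 500,
                              t_end = 1200, grid_dt = 1, seed_base = 1) {
  out <- list()
  offset <- 0
  for (lig in ligands) {
    pair <- list(healthy = resolve_scenario(lig, 7.4, radicals = FALSE),
                 inflamed = resolve_scenario(lig, 6.5, radicals = TRUE))
    res <- lapply(pair, function(sc) {
      ens <- .run_scenario(sc, n_runs, t_end, grid_dt, seed_base + offset)
      offset <<- offset + n_runs
      pct <- closed_channel_pct(ens)
      list(scenario = sc, ensemble = ens, pct = pct, peak_pct = max(pct),
           baseline_pct = pct[1])
    })
    out[[lig]] <- res
  }
  summary <- do.call(rbind, lapply(names(out), function(lig)
    data.frame(ligand = lig, condition = names(out[[lig]]),
               k1 = vapply(out[[lig]], function(o) o$scenario$k1, numeric(1)),
               k11 = vapply(out[[lig]], function(o) o$scenario$k11,
                            numeric(1)),
               baseline_pct = vapply(out[[lig]], `[[`, numeric(1),
                                     "baseline_pct"),
               peak_pct = vapply(out[[lig]], `[[`, numeric(1), "peak_pct"))))
  structure(list(ligands = out, summary = summary, n_runs = n_runs),
            class = "mor_radical_study")
}

#' @export
print.mor_radical_study <- function(x, ...) {
  cat(sprintf("Radical study, %d runs per condition:\n", x$n_runs))
  print(transform(x$summary, baseline_pct = round(baseline_pct, 2),
                  peak_pct = round(peak_pct, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mor_radical_study <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$ligands)))
  on.exit(graphics::par(old))
  for (lig in names(x$ligands)) {
    tt <- x$ligands[[lig]]$healthy$ensemble$time
    graphics::plot(NA, xlim = range(tt), ylim = c(0, 50), main = lig,
                   xlab = "time (s)", ylab = "closed calcium channels (%)")
    graphics::lines(tt, x$ligands[[lig]]$healthy$pct, col = "black", lwd = 2)
    graphics::lines(tt, x$ligands[[lig]]$inflamed$pct, col = "darkolivegreen",
                    lwd = 2)
    graphics::legend("topright", c("healthy", "inflamed"),
                     col = c("black", "darkolivegreen"), lwd = 2, bty = "n")
  }
  invisible(x)
}
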