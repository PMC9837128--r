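#' Exact stochastic simulation of one trajectory
#'
#' Samples one path of the Markov jump process defined by the network's
#' chemical master equation with the Gillespie direct method: exponential
#' waiting times with the total propensity as rate, and reaction choice
#' proportional to the individual propensities. The path is recorded on a
#' uniform time grid by last-value carry-forward. If the total propensity
#' reaches zero the system is frozen and the remaining grid points repeat the
#' current state.
#'
#' @param net A [mor_network()].
#' @param init Initial counts, e.g. [initial_state()].
#' @param t_end Time horizon in seconds.
#' @param grid_dt Recording grid spacing in seconds.
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return An object of class `"mor_trajectory"`: list with `time` (grid),
#'   `states` (grid x 11 integer matrix), `firings` (total occurrences of
#'   each reaction), and `seed`.
#' @examples
#' net <- mor_network(mor_rates())
#' tr <- simulate_ssa(net, initial_state(), t_end = 100, seed = 1)
#' tr$firings[["R1"]] <= 10   # at most 10 ligands can ever bind
#' @export
simulate_ssa <- function(net, init, t_end = 1200, grid_dt = 1, seed = NULL) {
  stopifnot(t_end > 0, grid_dt > 0)
  .check_state(init)
  if (!is.null(seed)) set.seed(seed)
  res <- .ssa_core(net$stoich, net$reactants, as.numeric(unclass(net$rates)),
                   as.integer(init), t_end, grid_dt)
  colnames(res$states) <- net$species
  names(res$firings) <- paste0("R", 1:11)
  structure(list(time = seq(0, t_end, by = grid_dt),
                 states = res$states, firings = res$firings, seed = seed),
            class = "mor_trajectory")
}

#' @export
print.mor_trajectory <- function(x, ...) {
  cat(sprintf("MOR trajectory: %d grid points over %g s, %d reaction events\n",
              length(x$time), max(x$time), sum(x$firings)))
  invisible(x)
}

#' Monte-Carlo ensemble of stochastic trajectories
#'
#' Runs `n_runs` independent trajectories (seeds `seed_base + 0 .. n_runs-1`)
#' and summarises the per-time-point arithmetic mean and unbiased sample
#' variance of every species, keeping the per-run reaction firing counts.
#'
#' @inheritParams simulate_ssa
#' @param n_runs Number of independent runs (>= 2).
#' @param seed_base First seed; run `i` uses `seed_base + i - 1`.
#' @return Object of class `"mor_ensemble"`: `time`, `mean` and `variance`
#'   (grid x 11 matrices), `firings` (`n_runs` x 11), `n_runs`, `seed_base`.
#' @export
run_ensemble <- function(net, init, t_end = 1200, grid_dt = 1, n_runs = 500,
                         seed_base = 1) {
  if (n_runs < 2) stop("n_runs must be >= 2 for a sample variance")
  ng <- length(seq(0, t_end, by = grid_dt))
  sum1 <- matrix(0, ng, 11)
  sum2 <- matrix(0, ng, 11)
  firings <- matrix(0L, n_runs, 11, dimnames = list(NULL, paste0("R", 1:11)))
  runs_caoff <- matrix(0L, ng, n_runs)  # kept for batch-means CIs
  i_caoff <- match("Ca_off", net$species)
  for (i in seq_len(n_runs)) {
    tr <- simulate_ssa(net, init, t_end, grid_dt, seed = seed_base + i - 1)
    st <- tr$states
    sum1 <- sum1 + st
    sum2 <- sum2 + st * st
    firings[i, ] <- tr$firings
    runs_caoff[, i] <- st[, i_caoff]
  }
  mu <- sum1 / n_runs
  va <- (sum2 - n_runs * mu * mu) / (n_runs - 1)
  va[va < 0] <- 0  # guard against roundoff
  dimnames(mu) <- dimnames(va) <- list(NULL, net$species)
  structure(list(time = seq(0, t_end, by = grid_dt), mean = mu, variance = va,
                 firings = firings, runs_caoff = runs_caoff, n_runs = n_runs,
                 seed_base = seed_base),
            class = "mor_ensemble")
}

#' @export
print.mor_ensemble <- function(x, ...) {
  pk <- which.max(x$mean[, "Ca_off"])
  cat(sprintf(
    "MOR ensemble: %d runs, %d grid points over %g s\n", x$n_runs,
    length(x$time), max(x$time)))
  cat(sprintf(
    "  peak mean closed channels: %.1f of 80 (%.1f%%) at t = %g s\n",
    x$mean[pk, "Ca_off"], 100 * x$mean[pk, "Ca_off"] / 80, x$time[pk]))
  invisible(x)
}

#' Plot the mean closed-channel time course of an ensemble
#'
#' @param x A [run_ensemble()] result.
#' @param ci Optionally a [batch_mean_ci()] result to draw 95% error bars.
#' @param every Draw an error bar every `every` grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mor_ensemble <- function(x, ci = NULL, every = 60, ...) {
  pct <- 100 * x$mean[, "Ca_off"] / sum(x$mean[1, c("Ca_on", "Ca_off")])
  graphics::plot(x$time, pct, type = "l", xlab = "time (s)",
                 ylab = "closed calcium channels (%)", ...)
  if (!is.null(ci)) {
    tot <- sum(x$mean[1, c("Ca_on", "Ca_off")])
    idx <- seq(1, length(x$time), by = every)
    graphics::arrows(x$time[idx], 100 * ci$lower[idx] / tot,
                     x$time[idx], 100 * ci$upper[idx] / tot,
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

#' Batch-means confidence interval for the ensemble mean
#'
#' Splits the runs into consecutive batches, averages a species within each
#' batch per time point, tests the batch means for normality
#' (Anderson-Darling), and forms a Student-t confidence interval for the
#' ensemble mean from the batch means (`n_batches - 1` degrees of freedom).
#'
#' @param ensemble A [run_ensemble()] result.
#' @param species Species name (currently `"Ca_off"`, the channel readout
#'   retained per run).
#' @param batch_size Runs per batch; must divide `n_runs`.
#' @param level Confidence level.
#' @return Object of class `"mor_batch_ci"`: `time`, `mean`, `lower`,
#'   `upper`, per-time-point Anderson-Darling statistic `ad_stat` and
#'   `ad_p` (NA where batch means are constant), `batch_size`, `n_batches`.
#' @export
batch_mean_ci <- function(ensemble, species = "Ca_off", batch_size = 50,
                          level = 0.95) {
  n <- ensemble$n_runs
  if (n %% batch_size != 0)
    stop("batch_size must divide the number of runs")
  if (!identical(species, "Ca_off"))
    stop("per-run values are retained for 'Ca_off' only")
  nb <- n %/% batch_size
  grp <- rep(seq_len(nb), each = batch_size)
  ng <- length(ensemble$time)
  bm <- matrix(0, ng, nb)
  for (b in seq_len(nb))
    bm[, b] <- rowMeans(ensemble$runs_caoff[, grp == b, drop = FALSE])
  mu <- rowMeans(bm)
  se <- apply(bm, 1, stats::sd) / sqrt(nb)
  tq <- stats::qt(1 - (1 - level) / 2, df = nb - 1)
  ad_stat <- ad_p <- rep(NA_real_, ng)
  # Anderson-Darling needs at least 8 batch means and nonzero spread
  ok <- if (nb >= 8) apply(bm, 1, function(v) stats::sd(v) > 0) else
    rep(FALSE, ng)
  if (any(ok)) {
    ad <- apply(bm[ok, , drop = FALSE], 1, nortest::ad.test)
    ad_stat[ok] <- vapply(ad, function(a) unname(a$statistic), numeric(1))
    ad_p[ok] <- vapply(ad, function(a) a$p.value, numeric(1))
  }
  structure(list(time = ensemble$time, mean = mu, lower = mu - tq * se,
                 upper = mu + tq * se, ad_stat = ad_stat, ad_p = ad_p,
                 batch_size = batch_size, n_batches = nb, level = level),
            class = "mor_batch_ci")
}

#' Constitutive steady-state base level of closed channels
#'
#' Without ligand-induced activation (`k1 = 0`) but with constitutive
#' G-protein activation (`k11 > 0`) the network relaxes to a stationary
#' distribution with a nonzero number of closed calcium channels. This
#' estimates its long-term mean by time-and-ensemble averaging `Ca_off`
#' over the second half of a long relaxation run, rounded to the nearest
#' natural number (ties up). The result parametrises [initial_state()] for
#' radical scenarios.
#'
#' @param rates A [mor_rates()] vector; `k1` is forced to 0.
#' @param t_relax Relaxation horizon in seconds.
#' @param n_runs Number of runs averaged.
#' @param seed_base First seed.
#' @param grid_dt Recording grid (s).
#' @return Integer base level `a` (and the unrounded mean as attribute
#'   `"mean"`).
#' @examples
#' \donttest{
#' steady_state_base_level(mor_rates(k11 = 5e-5))  # ~5
#' }
#' @export
steady_state_base_level <- function(rates, t_relax = 20000, n_runs = 100,
                                    seed_base = 1, grid_dt = 10) {
  k <- unclass(rates)
  if (k[["k11"]] <= 0) return(structure(0L, mean = 0))
  k[["k1"]] <- 0
  net <- mor_network(do.call(mor_rates, as.list(k)))
  ens <- run_ensemble(net, initial_state(a = 0), t_end = t_relax,
                      grid_dt = grid_dt, n_runs = n_runs,
                      seed_base = seed_base)
  half <- ens$time >= t_relax / 2
  m <- mean(ens$mean[half, "Ca_off"])
  structure(as.integer(floor(m + 0.5)), mean = m)
}

#' Rescale the network toward the thermodynamic limit
#'
#' Multiplies all molecule counts by a volume factor `omega` and divides the
#' bimolecular rate constants by `omega`, leaving the deterministic
#' concentration dynamics unchanged. As `omega` grows, the ensemble mean of
#' the jump process converges to `omega` times the reaction-rate-equation
#' solution.
#'
#' @param net A [mor_network()].
#' @param init Initial counts at `omega = 1`.
#' @param omega Volume scaling factor (positive integer).
#' @return List with the rescaled `net` and `init`.
#' @export
rescale_network <- function(net, init, omega) {
  stopifnot(omega >= 1)
  k <- unclass(net$rates)
  bi <- net$reactants[, 2] > 0L
  k[bi] <- k[bi] / omega
  list(net = mor_network(do.call(mor_rates, as.list(k))),
       init = {
         x <- as.integer(init * omega); names(x) <- names(init); x
       })
}

#' Simulate trajectories from a MOR network
#'
#' `simulate()` method: one call of [simulate_ssa()] per replicate.
#'
#' @param object A [mor_network()].
#' @param nsim Number of trajectories.
#' @param seed Base seed (replicate `i` uses `seed + i - 1`).
#' @param init Initial counts.
#' @param t_end,grid_dt Horizon and recording grid (s).
#' @param ... Ignored.
#' @return A list of `"mor_trajectory"` objects (a single object if
#'   `nsim = 1`).
#' @export
simulate.mor_network <- function(object, nsim = 1, seed = 1,
                                 init = initial_state(), t_end = 1200,
                                 grid_dt = 1, ...) {
  out <- lapply(seq_len(nsim), function(i)
    simulate_ssa(object, init, t_end, grid_dt, seed = seed + i - 1))
  if (nsim == 1) out[[1]] else out
}

#' Write an ensemble summary to CSV
#'
#' Long-format CSV with columns `time_s, species, mean, variance` and, when a
#' [batch_mean_ci()] is supplied, `ci_lo, ci_hi` for that species. A JSON
#' side-car manifest records rates, seeds, runs and grid.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param path Output CSV path.
#' @param ci Optional [batch_mean_ci()].
#' @param net The network simulated (for the manifest); optional.
#' @param manifest_path JSON manifest path (default: `path` with
#'   `.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path, ci = NULL, net = NULL,
                               manifest_path = NULL) {
  sp <- colnames(ensemble$mean)
  df <- data.frame(
    time_s = rep(ensemble$time, times = length(sp)),
    species = rep(sp, each = length(ensemble$time)),
    mean = as.vector(ensemble$mean),
    variance = as.vector(ensemble$variance))
  df$ci_lo <- df$ci_hi <- NA_real_
  if (!is.null(ci)) {
    sel <- df$species == "Ca_off"
    df$ci_lo[sel] <- ci$lower
    df$ci_hi[sel] <- ci$upper
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (is.null(manifest_path))
    manifest_path <- sub("\\.csv$", ".manifest.json", path)
  manifest <- list(n_runs = ensemble$n_runs, seed_base = ensemble$seed_base,
                   t_end = max(ensemble$time),
                   grid_dt = diff(ensemble$time[1:2]))
  if (!is.null(net)) manifest$rates <- as.list(unclass(net$rates))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
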