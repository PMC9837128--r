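#' Specification for a synthetic FRET dataset
#'
#' Describes the generating model for FRET-like series of G-protein subunit
#' dissociation: one series per ligand/pH combination, sampled at `1/dt` Hz
#' over `duration` seconds with the ligand added at `addition_time`. Before
#' addition the signal sits at a flat 100% baseline; afterwards it follows
#' the affinely rescaled undissociated-G-protein curve of the
#' reaction-rate equation (started from the canonical initial state with no
#' base level), plus i.i.d. Gaussian noise on the percent scale.
#' Photobleaching is assumed already corrected, so no bleaching trend is
#' simulated.
#'
#' Defaults mirror the experimental setting the estimation assumes: the four
#' fentanyl/NFEPP x pH 6.5/7.4 combinations at their reference binding
#' rates, fitted intracellular rates, 1 Hz sampling for 320 s, addition at
#' 20 s, and 1.5% noise.
#'
#' @param rates Shared rates ([mor_rates()]); `k11` is forced to 0.
#' @param ligand,pH Parallel vectors defining the series.
#' @param k1 Per-series binding rates (defaults: [k1_reference()] per
#'   ligand/pH, no radicals).
#' @param transforms Per-series affine maps `list(slope, intercept)` from
#'   G-protein count to percent signal; the default maps the initial count
#'   of 40 to 100%.
#' @param noise_sd Noise standard deviation in percent units.
#' @param dt Sampling interval (s).
#' @param duration Total duration (s); must exceed `addition_time`.
#' @param addition_time Ligand-addition time (s).
#' @param seed Seed making the dataset reproducible.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(rates = mor_rates(),
                       ligand = c("fentanyl", "fentanyl", "NFEPP", "NFEPP"),
                       pH = c(6.5, 7.4, 6.5, 7.4),
                       k1 = mapply(k1_reference, ligand, pH),
                       transforms = rep(list(list(slope = 0.5,
                                                  intercept = 80)),
                                        length(ligand)),
                       noise_sd = 1.5, dt = 1, duration = 320,
                       addition_time = 20, seed = 1) {
  if (length(ligand) != length(pH) || length(k1) != length(ligand))
    stop("ligand, pH and k1 must have equal lengths")
  if (duration <= addition_time)
    stop("duration must exceed the ligand-addition time")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(rates = rates, ligand = ligand, pH = pH,
                 k1 = as.numeric(k1), transforms = transforms,
                 noise_sd = noise_sd, dt = dt, duration = duration,
                 addition_time = addition_time, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic FRET dataset
#'
#' Produces one [fret_series()] per ligand/pH combination in the spec, fully
#' determined by the spec's seed. The generating truth (rates, per-series
#' `k1`, transforms, noise) is attached as attribute `"truth"` for
#' parameter-recovery experiments.
#'
#' @param spec A [synth_spec()].
#' @return List of [fret_series()] with attribute `"truth"`.
#' @examples
#' ds <- generate_fret_dataset(synth_spec(noise_sd = 0, seed = 1))
#' sapply(ds, function(s) min(s$signal_pct))  # NFEPP/pH 7.4 drops least
#' @export
generate_fret_dataset <- function(spec) {
  set.seed(spec$seed)
  times <- seq(0, spec$duration, by = spec$dt)
  k <- unclass(spec$rates)
  k[["k11"]] <- 0
  out <- lapply(seq_along(spec$ligand), function(i) {
    ki <- `[<-`(k, "k1", spec$k1[i])
    m <- .model_gprotein(times - spec$addition_time,
                         do.call(mor_rates, as.list(ki)))
    tr <- spec$transforms[[i]]
    sig <- tr$intercept + tr$slope * m +
      stats::rnorm(length(times), 0, spec$noise_sd)
    fret_series(times, sig, ligand = spec$ligand[i], pH = spec$pH[i],
                addition_time = spec$addition_time)
  })
  attr(out, "truth") <- list(rates = unclass(spec$rates), k1 = spec$k1,
                             transforms = spec$transforms,
                             noise_sd = spec$noise_sd)
  out
}

#' Small canned SSA ensemble for fast downstream tests
#'
#' Runs a reduced Monte-Carlo ensemble (default 20 runs) and optionally
#' writes it through [write_ensemble_csv()]; regenerating with the same seed
#' gives a byte-identical file.
#'
#' @param net A [mor_network()].
#' @param init Initial counts.
#' @param t_end,grid_dt Horizon and grid (s).
#' @param n_runs Number of runs.
#' @param seed Base seed.
#' @param path Optional CSV path to write.
#' @return The [run_ensemble()] summary (invisibly if written).
#' @export
generate_ssa_fixture <- function(net, init = initial_state(), t_end = 200,
                                 grid_dt = 1, n_runs = 20, seed = 1,
                                 path = NULL) {
  ens <- run_ensemble(net, init, t_end = t_end, grid_dt = grid_dt,
                      n_runs = n_runs, seed_base = seed)
  if (!is.null(path)) {
    write_ensemble_csv(ens, path, net = net)
    return(invisible(ens))
  }
  ens
}
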