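test_that("preprocessing aligns series to the ligand-addition time", {
  ds <- generate_fret_dataset(synth_spec(noise_sd = 0.5, seed = 1))
  al <- preprocess_fret(ds[[1]])
  expect_equal(attr(al, "offset"), 20)
  expect_equal(al$time_s, ds[[1]]$time_s - 20)
  expect_equal(al$addition_time, 0)
  # already aligned: identity
  expect_equal(preprocess_fret(al)$time_s, al$time_s)
  # too short a baseline with a nonzero annotated offset
  short <- fret_series(0:50, rep(100, 51), "fentanyl", 7.4,
                       addition_time = 1)
  expect_error(preprocess_fret(short), "baseline")
})

test_that("the ligand-addition change point is detected from the data", {
  ds <- generate_fret_dataset(synth_spec(
    ligand = "fentanyl", pH = 7.4, k1 = 2.81e-3, noise_sd = 0.5, seed = 3))
  s <- ds[[1]]
  s$addition_time <- NA
  al <- preprocess_fret(s, detect_offset = TRUE)
  expect_lte(abs(attr(al, "offset") - 20), 2)
  # an exactly flat series has no detectable change point
  flat <- fret_series(0:100, rep(100, 101), "fentanyl", 7.4,
                      addition_time = NA)
  expect_error(preprocess_fret(flat, detect_offset = TRUE), "plateau")
})

test_that("the residual is a calibrated discrepancy measure", {
  spec0 <- synth_spec(noise_sd = 0, seed = 1)
  ds0 <- lapply(generate_fret_dataset(spec0), preprocess_fret)
  truth <- attr(generate_fret_dataset(spec0), "truth")
  # self-consistency: zero at the generating parameters
  r0 <- fret_residual(mor_rates(), truth$k1, ds0)
  expect_lt(as.numeric(r0), 1e-10)
  # perturbing one series' binding rate strictly increases it
  r1 <- fret_residual(mor_rates(), truth$k1 * c(10, 1, 1, 1), ds0)
  expect_gt(as.numeric(r1), as.numeric(r0) + 0.1)
  # supplied transforms are honoured
  rfix <- fret_residual(mor_rates(), truth$k1, ds0,
                        transforms = truth$transforms)
  expect_lt(as.numeric(rfix), 1e-10)
  # additive noise of variance s^2 puts the floor near 4 s^2
  sds <- 1.5
  dsn <- lapply(generate_fret_dataset(synth_spec(noise_sd = sds, seed = 2)),
                preprocess_fret)
  rn <- as.numeric(fret_residual(mor_rates(), truth$k1, dsn))
  expect_equal(rn, 4 * sds^2, tolerance = 0.12)
})

test_that("solver failure at absurd rates yields a penalty, not a crash", {
  ds <- lapply(generate_fret_dataset(synth_spec(noise_sd = 0, seed = 1)),
               preprocess_fret)
  r <- suppressWarnings(fret_residual(mor_rates(k2 = 1e30), 1e-3, ds[1]))
  expect_equal(as.numeric(r), 1e8)
})

test_that("single-series binding-rate fits recover the truth", {
  truth_k1 <- 2.81e-3
  ds <- generate_fret_dataset(synth_spec(
    ligand = "fentanyl", pH = 7.4, k1 = truth_k1,
    transforms = list(list(slope = 0.5, intercept = 80)),
    noise_sd = 0.2, seed = 9))
  s <- preprocess_fret(ds[[1]])
  k1_hat <- fit_k1_per_series(s, mor_rates(), k1_start = 2.5e-2)
  expect_equal(as.numeric(k1_hat), truth_k1, tolerance = 0.1)
  # determinism: identical input gives the identical fit
  expect_identical(as.numeric(k1_hat),
                   as.numeric(fit_k1_per_series(s, mor_rates(),
                                                k1_start = 2.5e-2)))
  # noiseless input: residual at the optimum is essentially zero
  ds0 <- generate_fret_dataset(synth_spec(
    ligand = "fentanyl", pH = 7.4, k1 = truth_k1,
    transforms = list(list(slope = 0.5, intercept = 80)),
    noise_sd = 0, seed = 1))
  s0 <- preprocess_fret(ds0[[1]])
  k1_hat0 <- fit_k1_per_series(s0, mor_rates(), k1_start = 2.5e-2)
  expect_lt(as.numeric(fret_residual(mor_rates(), k1_hat0, list(s0))), 1e-6)
  # uninformative data: flagged as flat
  flat <- fret_series(seq(0, 320), rep(100, 321), "fentanyl", 7.4, 20)
  expect_warning(k1_flat <- fit_k1_per_series(preprocess_fret(flat),
                                              mor_rates()), "flat")
  expect_true(isTRUE(attr(k1_flat, "flat")))
})

test_that("the two-stage fit improves the residual and honours frozen rates", {
  ds <- generate_fret_dataset(synth_spec(noise_sd = 1, seed = 13))
  fit <- mor_fit(ds, n_starts = 1, maxit = 40)
  expect_s3_class(fit, "mor_fit")
  expect_lte(fit$residual, fit$residual_start)
  k <- unclass(fit$rates)
  expect_equal(unname(k["k7"]), 5e-4)   # frozen at the preselected value
  expect_equal(unname(k["k8"]), 5e-5)
  expect_equal(unname(k["k11"]), 0)
  expect_length(fit$k1, 4)
  expect_true(all(fit$k1 > 0))
  expect_named(coef(fit), c(paste0("k", 2:10),
                            paste0("k1_", names(fit$k1))))
  # transforms map the baseline G-protein count near 100%
  base <- vapply(fit$transforms,
                 function(tr) tr$intercept + tr$slope * 40, numeric(1))
  expect_equal(base, rep(100, 4), tolerance = 0.02)
  expect_error(mor_fit(ds, frozen = "k1"), "unknown")
})

test_that("degenerate flat data does not break the fit", {
  set.seed(4)
  flat <- lapply(1:2, function(i)
    fret_series(seq(0, 320, 2), 100 + rnorm(161, 0, 1),
                c("fentanyl", "NFEPP")[i], 7.4, 20))
  fit <- suppressWarnings(mor_fit(flat, n_starts = 1, maxit = 20))
  expect_true(is.finite(fit$residual))
  # residual settles at the baseline noise variance (one per series)
  expect_equal(fit$residual, 2 * 1^2, tolerance = 0.25)
})

test_that("fit methods are mutually consistent", {
  ds <- generate_fret_dataset(synth_spec(noise_sd = 1, seed = 13))
  fit <- mor_fit(ds, n_starts = 1, maxit = 40)
  pred <- predict(fit)
  res <- residuals(fit)
  expect_length(pred, 4)
  for (i in 1:4) {
    expect_equal(fit$data[[i]]$signal_pct - pred[[i]]$fitted, res[[i]])
  }
  # the residual value equals the summed per-series mean squares
  expect_equal(sum(vapply(res, function(r) mean(r^2), numeric(1))),
               fit$residual, tolerance = 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.mor_fit")
  expect_equal(nrow(s$per_series), 4)
  expect_output(print(fit), "per-series k1")
  # simulate() from the fit yields plausible new datasets
  sim <- simulate(fit, seed = 2)
  expect_length(sim, 4)
  expect_s3_class(sim[[1]], "fret_series")
})

test_that("FRET datasets round-trip through CSV with offsets", {
  ds <- generate_fret_dataset(synth_spec(noise_sd = 1, seed = 6))
  path <- tempfile(fileext = ".csv")
  write_fret_csv(ds, path, truth = list(note = "synthetic"))
  back <- read_fret_csv(path)
  expect_length(back, 4)
  i <- which(vapply(back, function(s)
    s$ligand == "NFEPP" && s$pH == 7.4, logical(1)))
  orig <- ds[[4]]
  expect_equal(back[[i]]$signal_pct, orig$signal_pct)
  expect_equal(back[[i]]$addition_time, 20)
  side <- jsonlite::read_json(sub("\\.csv$", ".offsets.json", path))
  expect_equal(side$truth$note, "synthetic")
})
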