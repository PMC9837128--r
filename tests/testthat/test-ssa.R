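test_that("a network with no active reactions stays frozen", {
  net <- mor_network(mor_rates(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0,
                               k6 = 0, k7 = 0, k8 = 0, k9 = 0, k10 = 0,
                               k11 = 0))
  tr <- simulate_ssa(net, initial_state(), t_end = 50, grid_dt = 1, seed = 1)
  expect_true(all(tr$states == rep(initial_state(), each = 51)))
  expect_equal(unname(tr$firings), rep(0L, 11))
  ens <- run_ensemble(net, initial_state(), t_end = 20, n_runs = 5,
                      seed_base = 1)
  expect_equal(ens$mean[3, ], initial_state() + 0)
  expect_true(all(ens$variance == 0))
})

test_that("pure ligand decay matches the closed-form death process", {
  k10 <- 0.02
  net <- mor_network(mor_rates(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0,
                               k6 = 0, k7 = 0, k8 = 0, k9 = 0, k10 = k10,
                               k11 = 0))
  ens <- run_ensemble(net, initial_state(), t_end = 150, grid_dt = 5,
                      n_runs = 300, seed_base = 7)
  expected <- 10 * exp(-k10 * ens$time)       # binomial survival mean
  se <- sqrt(10 * exp(-k10 * ens$time) * (1 - exp(-k10 * ens$time)) / 300)
  expect_true(all(abs(ens$mean[, "L"] - expected) <= 3 * se + 1e-9))
  # with a long horizon every ligand decays
  tr <- simulate_ssa(net, initial_state(), t_end = 2000, grid_dt = 100,
                     seed = 3)
  expect_equal(unname(tr$states[21, "L"]), 0L)
  expect_equal(unname(tr$firings["R10"]), 10L)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  net <- fentanyl_net()
  a <- simulate_ssa(net, initial_state(), t_end = 300, seed = 11)
  b <- simulate_ssa(net, initial_state(), t_end = 300, seed = 11)
  expect_identical(a$states, b$states)
  expect_identical(a$firings, b$firings)
  c <- simulate_ssa(net, initial_state(), t_end = 300, seed = 12)
  expect_false(identical(a$states, c$states))
})

test_that("trajectories respect conservation and the binding bound", {
  net <- mor_network(mor_rates(k1 = 2.81e-3, k11 = 5e-5))
  cv <- cons_vectors()
  for (seed in 1:3) {
    tr <- simulate_ssa(net, initial_state(5), t_end = 1200, grid_dt = 10,
                       seed = seed)
    expect_true(all(tr$states %*% cv$alpha == 40))
    expect_true(all(tr$states %*% cv$betagamma == 40))
    expect_true(all(tr$states %*% cv$channel == 80))
    expect_true(all(tr$states >= 0))
    expect_lte(tr$firings[["R1"]], 10L)
  }
})

test_that("ensemble summaries have exact channel-count complementarity", {
  net <- nfepp_net()
  ens <- run_ensemble(net, initial_state(), t_end = 400, grid_dt = 4,
                      n_runs = 40, seed_base = 2)
  expect_equal(ens$mean[, "Ca_on"] + ens$mean[, "Ca_off"], rep(80, 101))
  expect_true(all(ens$variance >= 0))
  expect_true(all(ens$firings[, "R1"] <= 10))
  expect_error(run_ensemble(net, initial_state(), n_runs = 1), "n_runs")
})

test_that("batch-means intervals use the right construction", {
  net <- fentanyl_net()
  ens <- run_ensemble(net, initial_state(), t_end = 200, grid_dt = 10,
                      n_runs = 100, seed_base = 5)
  ci <- batch_mean_ci(ens, "Ca_off", batch_size = 10)
  expect_equal(ci$n_batches, 10)
  expect_true(all(ci$lower <= ci$mean & ci$mean <= ci$upper))
  expect_equal(ci$mean, unname(ens$mean[, "Ca_off"]))
  # interval reproduces the t construction from the batch means
  grp <- rep(1:10, each = 10)
  bm <- tapply(ens$runs_caoff[15, ], grp, mean)
  hw <- qt(0.975, 9) * sd(bm) / sqrt(10)
  expect_equal(ci$upper[15] - ci$lower[15], 2 * hw)
  expect_error(batch_mean_ci(ens, batch_size = 30), "divide")
  # degenerate ensemble: zero-width intervals, no normality test possible
  net0 <- mor_network(mor_rates(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0,
                                k6 = 0, k7 = 0, k8 = 0, k9 = 0, k10 = 0))
  ens0 <- run_ensemble(net0, initial_state(), t_end = 20, grid_dt = 10,
                       n_runs = 20, seed_base = 1)
  ci0 <- batch_mean_ci(ens0, batch_size = 5)
  expect_true(all(ci0$upper - ci0$lower == 0))
  expect_true(all(is.na(ci0$ad_p)))
})

test_that("batch-means intervals achieve nominal coverage on iid runs", {
  set.seed(99)
  n_exp <- 200
  covered <- logical(n_exp)
  for (e in seq_len(n_exp)) {
    fake <- structure(list(
      time = 0, n_runs = 50,
      runs_caoff = matrix(rnorm(50, mean = 3, sd = 1), nrow = 1)),
      class = "mor_ensemble")
    ci <- batch_mean_ci(fake, "Ca_off", batch_size = 5)
    covered[e] <- ci$lower[1] <= 3 && 3 <= ci$upper[1]
  }
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("constitutive steady state behaves across k11 regimes", {
  expect_identical(steady_state_base_level(mor_rates(k11 = 0)),
                   structure(0L, mean = 0))
  # saturating constitutive drive sequesters every G-protein
  a_big <- steady_state_base_level(mor_rates(k11 = 1), t_relax = 400,
                                   n_runs = 10, seed_base = 1, grid_dt = 5)
  expect_gte(a_big, 38L)
  expect_lte(a_big, 40L)
})

test_that("volume rescaling divides bimolecular constants only", {
  net <- mor_network(mor_rates(k1 = 2.81e-3, k11 = 5e-5))
  rs <- rescale_network(net, initial_state(), omega = 10)
  k0 <- unclass(net$rates)
  k1 <- unclass(rs$net$rates)
  bi <- c("k1", "k2", "k4", "k5", "k6", "k11")
  uni <- setdiff(names(k0), bi)
  expect_equal(k1[bi], k0[bi] / 10)
  expect_equal(k1[uni], k0[uni])
  expect_equal(unname(rs$init["Ca_on"]), 800L)
})

test_that("the simulate method returns reproducible trajectory sets", {
  net <- fentanyl_net()
  trs <- simulate(net, nsim = 2, seed = 4, t_end = 100)
  expect_length(trs, 2)
  expect_false(identical(trs[[1]]$states, trs[[2]]$states))
  again <- simulate(net, nsim = 2, seed = 4, t_end = 100)
  expect_identical(trs[[1]]$states, again[[1]]$states)
})

test_that("ensemble CSV export round-trips the summary", {
  net <- fentanyl_net()
  ens <- generate_ssa_fixture(net, t_end = 60, n_runs = 10, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_ensemble_csv(ens, path, net = net)
  df <- read.csv(path)
  expect_setequal(unique(df$species), mor_species())
  sub <- df[df$species == "Ca_off", ]
  expect_equal(sub$mean, unname(ens$mean[, "Ca_off"]))
  expect_equal(sub$variance, unname(ens$variance[, "Ca_off"]))
  man <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", path))
  expect_equal(man$n_runs, 10)
  expect_equal(man$rates$k1, 2.81e-3)
})
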