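test_that("the pulse task reports four cases with sensible structure", {
  rep <- run_pulse_task(fitted_tree, pulse_task_spec(genome = fitted_genome))
  expect_named(rep, c("A", "B", "C", "D"))
  expect_true(all(vapply(rep, function(x) x$peak_deflection >= 0, logical(1))))
  # case counts are invariant to halving the time step
  rep2 <- run_pulse_task(fitted_tree, pulse_task_spec(genome = fitted_genome),
                         solver_config(h = 0.05, T = 200))
  for (cs in c("A", "B", "C", "D"))
    expect_equal(rep2[[cs]]$n_spikes, rep[[cs]]$n_spikes)
})

test_that("calcium-activation detection needs recordings and is off at rest", {
  r <- simulate(fitted_tree, stim_program(), solver_config(h = 0.1, T = 200))
  expect_false(detect_ca_activation(r))
  # strong sustained distal drive activates under both criteria
  r2 <- simulate(fitted_tree, stim_program(stim_step(2, 800, 0, 500)),
                 solver_config(h = 0.1, T = 500))
  expect_true(detect_ca_activation(r2, "gating"))
  expect_true(detect_ca_activation(r2, "calcium", tree = fitted_tree))
  # a tree without a calcium compartment has no recordings to inspect
  tr <- build_tree(list(compartment(1, NA, C_m = 100, g_L = 5, E_L = -70)))
  r3 <- simulate(tr, stim_program(), solver_config(h = 0.1, T = 10))
  expect_error(detect_ca_activation(r3), "configuration error")
})

test_that("the prolonged scan produces a consistent transfer surface", {
  surf <- run_prolonged_scan(fitted_tree, c(0, 300, 600), c(0, 400, 800),
                             solver_config(h = 0.1, T = 500),
                             stim_duration = 500)
  expect_equal(dim(surf$rate), c(3L, 3L))
  expect_equal(surf$rate[1, 1], 0)          # rest is subthreshold
  expect_true(all(surf$rate >= 0))
  expect_false(surf$ca_active[1, 1])
  expect_error(run_prolonged_scan(fitted_tree, c(300, 0), c(0, 400)),
               "strictly increasing")
})

test_that("spike statistics handle empty, periodic and Poisson trains", {
  expect_equal(spike_stats(numeric(), 2000),
               list(rate = 0, mean_isi = NA_real_, cv_isi = NA_real_))
  per <- seq(100, 2000, by = 100)
  st <- spike_stats(per, 2000)
  expect_equal(st$rate, 10)
  expect_equal(st$cv_isi, 0)
  expect_true(is.na(spike_stats(c(1, 2), 100)$cv_isi))
  set.seed(11)
  tr <- poisson_train(20, 0, 1e5)
  expect_equal(spike_stats(tr, 1e5)$cv_isi, 1, tolerance = 0.1)
})

test_that("the Poisson-input scan is silent without input and shaped by the grids", {
  tr <- build_tree(list(
    compartment(1, NA, C_m = fitted_genome[["C_m_s"]],
                g_L = fitted_genome[["g_L_s"]], E_L = -70,
                channels = list(adex_mechanism(2, -50, -30, -55, t_ref = 2))),
    compartment(2, 1, C_m = 60, g_L = 4, E_L = -70, g_C = 10),
    compartment(3, 1, C_m = 60, g_L = 4, E_L = -70, g_C = 10)))
  out <- run_poisson_scan(tr, apical_rates = c(0, 150), basal_rates = c(0, 100),
                          apical_comps = 2, basal_comps = 3, episodes = 2,
                          episode_T = 500,
                          config = solver_config(h = 0.1, T = 500), seed = 3)
  expect_equal(dim(out$rate), c(2L, 2L))
  expect_equal(out$rate[1, 1], 0)
  # mean apical voltage rises with apical input rate at fixed basal rate
  expect_gt(out$mean_V_apical[2, 1], out$mean_V_apical[1, 1])
  expect_gt(out$mean_V_apical[2, 2], out$mean_V_apical[1, 2])
})
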