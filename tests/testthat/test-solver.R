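test_that("the Hines solve matches a dense direct solve on random trees", {
  for (seed in 1:5) {
    s <- random_tree_system(10, seed)
    x <- hines_solve(s$parent, s$diag, s$off, s$rhs)
    expect_equal(x, solve(s$A, s$rhs), tolerance = 1e-12)
  }
  # single compartment: scalar division
  expect_equal(hines_solve(NA, 4, 0, 2), 0.5)
  # zero couplings: independent scalar solves
  x <- hines_solve(c(NA, 1, 2), c(2, 4, 8), c(0, 0, 0), c(2, 2, 2))
  expect_equal(x, c(1, 0.5, 0.25))
  expect_error(hines_solve(c(NA, 1), c(1, 0), c(0, 0), c(1, 1)), "singular")
})

test_that("passive trees follow their closed-form responses at second order", {
  tr1 <- build_tree(list(compartment(1, NA, C_m = 200, g_L = 10, E_L = -70)))
  r <- simulate(tr1, stim_program(stim_step(1, 100, 0, 100)),
                solver_config(h = 0.1, T = 100))
  exact <- -70 + (100 / 10) * (1 - exp(-r$times * 10 / 200))
  expect_lt(max(abs(r$V[, 1] - exact)), 1e-4)

  tr2 <- passive_two_comp()
  hs <- c(0.4, 0.2, 0.1, 0.05)
  errs <- vapply(hs, function(h) {
    r <- simulate(tr2, stim_program(stim_step(1, 100, 0, 50)),
                  solver_config(h = h, T = 50))
    max(abs(r$V - passive_response(tr2, c(100, 0), r$times)))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(hs)))[[2]]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
  # halving h reduces the error ~4x
  expect_gt(errs[3] / errs[4], 3.5)
})

test_that("equilibrium is preserved and deviations decay monotonically", {
  tr <- passive_two_comp()
  r <- simulate(tr, stim_program(), solver_config(h = 0.1, T = 50))
  expect_equal(max(abs(r$V + 70)), 0)
  r2 <- simulate(tr, stim_program(), solver_config(h = 0.1, T = 100),
                 v_init = c(-50, -80))
  # capacitance-weighted energy of the deviation decays monotonically
  energy <- (r2$V + 70)^2 %*% tr$C_m
  expect_true(all(diff(energy) <= 1e-12))
  expect_lt(max(abs(r2$V[nrow(r2$V), ] + 70)), 1)
})

test_that("runs are bit-identical for a fixed seed", {
  prog <- stim_program(stim_poisson(2, receptor_spec("AMPA", w = 2), 200, 0, 200),
                       stim_step(1, 150, 0, 200))
  cfg <- solver_config(h = 0.1, T = 200)
  r1 <- simulate(fitted_tree, prog, cfg, seed = 7)
  r2 <- simulate(fitted_tree, prog, cfg, seed = 7)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$spike_times, r2$spike_times)
})

test_that("refractory spikes are separated and the soma holds at V_reset", {
  g <- fitted_genome
  tr <- build_two_compartment(g)
  r <- simulate(tr, stim_program(stim_step(1, 600, 0, 1000)),
                solver_config(h = 0.1, T = 1000))
  st <- r$spike_times
  expect_gt(length(st), 3)
  expect_true(all(diff(st) >= g[["t_ref"]] - 1e-9))
  # V_s equals V_reset throughout each refractory window
  for (k in seq_along(st)) {
    idx <- which(r$times > st[k] & r$times <= st[k] + g[["t_ref"]] + 1e-9)
    expect_true(all(abs(r$V[idx, 1] - g[["V_reset"]]) < 1e-12))
  }
})

test_that("every spike delivers exactly one BAP charge w_BAP at t_k + d_BAP", {
  g <- fitted_genome
  for (h in c(0.1, 0.05)) {
    tr <- build_tree(list(
      compartment(1, NA, C_m = g[["C_m_s"]], g_L = g[["g_L_s"]], E_L = -70,
                  channels = list(adex_mechanism(2, -50, -30, -55, t_ref = 2,
                                                 w_BAP = 1500, d_BAP = 1.5))),
      compartment(2, 1, C_m = 100, g_L = 5, E_L = -70, g_C = 10)))
    tr$bap_targets[[1]] <- 2L
    r <- simulate(tr, stim_program(stim_step(1, 2000, 10, 5)),
                  solver_config(h = h, T = 60))
    st <- r$spike_times
    ev <- r$bap_events[[1]]
    expect_equal(length(ev), length(st))
    expect_equal(ev, st + round(1.5 / h) * h, tolerance = 1e-9)
    # delivered charge equals w_BAP regardless of h: the one-step voltage
    # jump in the passive distal compartment is w_BAP / C_m_d + O(h)
    i <- which.min(abs(r$times - ev[1]))
    jump <- r$V[i + 1, 2] - r$V[i, 2]
    expect_equal(jump, 1500 / 100, tolerance = 0.15 * 1500 / 100)
  }
})

test_that("the stepper tracks a fine-step explicit reference between spikes", {
  # subthreshold distal DC on the full Ca-AdEx model; explicit Euler at h/100
  g <- fitted_genome
  h <- 0.1; T <- 150; I_d <- 300
  r <- simulate(fitted_tree, stim_program(stim_step(2, I_d, 0, T)),
                solver_config(h = h, T = T))
  expect_length(r$spike_times, 0)
  hf <- h / 100
  Vs <- -70; Vd <- -70; w <- 0
  m <- gate_inf(Vd, g[["m_slope"]], g[["m_half"]])
  hh <- gate_inf(Vd, g[["h_slope"]], g[["h_half"]])
  Ca <- g[["Ca_0"]]
  mk <- kca_m_inf(Ca, g[["Ca_th"]], g[["const_KCa"]])
  ref <- matrix(0, T / h + 1, 2); ref[1, ] <- c(Vs, Vd)
  for (n in seq_len(T / hf)) {
    ICa <- ca_hva_current(Vd, m, hh, g[["g_Ca"]], g[["E_Ca"]])
    IK <- kca_current(Vd, mk, g[["g_K"]], g[["E_K"]])
    Fs <- g[["g_L_s"]] * (-70 - Vs) +
      adex_terms(Vs, w, g[["g_L_s"]], g[["Delta_T"]], g[["V_th_s"]]) +
      g[["g_C"]] * (Vd - Vs)
    Fd <- g[["g_L_d"]] * (-70 - Vd) + ICa + IK + I_d + g[["g_C"]] * (Vs - Vd)
    Vs <- Vs + hf * Fs / g[["C_m_s"]]
    Vd <- Vd + hf * Fd / g[["C_m_d"]]
    w <- w + hf * (g[["a"]] * (Vs + 70) - w) / g[["tau_w"]]
    m <- m + hf * (gate_inf(Vd, g[["m_slope"]], g[["m_half"]]) - m) / g[["tau_m_Ca"]]
    hh <- hh + hf * (gate_inf(Vd, g[["h_slope"]], g[["h_half"]]) - hh) / g[["tau_h_Ca"]]
    Ca <- Ca + hf * (g[["phi_Ca"]] * ICa - (Ca - g[["Ca_0"]]) / g[["tau_Ca"]])
    mk <- mk + hf * (kca_m_inf(Ca, g[["Ca_th"]], g[["const_KCa"]]) - mk) / g[["tau_m_KCa"]]
    if (n %% 100 == 0) ref[n / 100 + 1, ] <- c(Vs, Vd)
  }
  expect_lt(max(abs(r$V - ref)), 0.1)
})

test_that("with g_C = 0 the somatic spike train reduces to the pure AdEx", {
  g0 <- fitted_genome; g0[["g_C"]] <- 0
  two <- build_two_compartment(g0)
  one <- build_single_adex(g0)
  cfg <- solver_config(h = 0.1, T = 2000)
  for (I_d in c(400, 800)) {
    r2 <- simulate(two, stim_program(stim_step(1, 450, 0, 2000),
                                     stim_step(2, I_d, 0, 2000)), cfg)
    r1 <- simulate(one, stim_program(stim_step(1, 450, 0, 2000)), cfg)
    expect_identical(r2$spikes[["1"]], r1$spike_times)
    expect_identical(r2$V[, 1], r1$V[, 1])
  }
})
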