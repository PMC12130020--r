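test_that("calcium-channel steady states and currents follow the gating laws", {
  expect_equal(gate_inf(-30, -0.4, -30), 0.5) # half-activation by symmetry
  expect_equal(ca_hva_current(V = 40, m = 1, h = 1, g_Ca = 2, E_Ca = 50), 20)
  expect_equal(ca_hva_current(V = 0, m = 0, h = 1, g_Ca = 10, E_Ca = 50), 0)
  expect_equal(ca_hva_current(V = 0, m = 1, h = 0, g_Ca = 10, E_Ca = 50), 0)
})

test_that("K_Ca activation is a Hill function of calcium with a continuous zero limit", {
  expect_equal(kca_m_inf(4e-4, Ca_th = 4e-4, const_KCa = 3), 0.5)
  expect_equal(kca_m_inf(1e3, Ca_th = 4e-4, const_KCa = 3), 1, tolerance = 1e-9)
  # Ca = Ca_th/2 with exponent 2: 1 / (1 + 2^2)
  expect_equal(kca_m_inf(2e-4, Ca_th = 4e-4, const_KCa = 2), 0.2)
  expect_equal(kca_m_inf(0, Ca_th = 4e-4, const_KCa = 3), 0)
  expect_equal(kca_current(V = -85, m = 0.5, g_K = 10, E_K = -85), 0)
})

test_that("the calcium pool relaxes exponentially toward its closed-form steady state", {
  p <- list(phi = 2e-6, Ca0 = 1e-4, tau = 100)
  expect_equal(update_calcium(1e-4, 0, 1, p$phi, p$Ca0, p$tau), 1e-4)
  ca <- 5e-4
  for (k in 1:50) ca <- update_calcium(ca, 0, 10, p$phi, p$Ca0, p$tau)
  expect_equal(ca, p$Ca0 + (5e-4 - p$Ca0) * exp(-500 / p$tau), tolerance = 1e-12)
  # constant current: steady state Ca_0 + phi * I * tau
  ca <- p$Ca0
  for (k in 1:500) ca <- update_calcium(ca, 200, 10, p$phi, p$Ca0, p$tau)
  expect_equal(ca, p$Ca0 + p$phi * 200 * p$tau, tolerance = 1e-8)
  expect_true(ca >= p$Ca0) # never below baseline under non-negative drive
})

test_that("the exponential gating propagator matches a fine-step ODE solution", {
  expect_equal(gating_step(0.3, 0, 0.9, 5), 0.3)     # h = 0 identity
  expect_equal(gating_step(0.3, 1e4, 0.9, 5), 0.9)   # saturation
  # sinusoidal voltage drive, stepwise-constant V per step as in the solver
  skip_if_not_installed("deSolve")
  tau <- function(V) 8 + 2 * sin(V / 10)
  yinf <- function(V) 1 / (1 + exp(-0.2 * (V + 45)))
  h <- 0.1; T <- 50
  Vt <- function(t) -50 + 15 * sin(2 * pi * t / 23)
  y <- yinf(Vt(0)); ys <- y
  for (n in seq_len(T / h)) {
    Vn <- Vt(n * h)
    y <- gating_step(y, h, yinf(Vn), tau(Vn))
    ys <- c(ys, y)
  }
  ref <- deSolve::lsoda(c(y = yinf(Vt(0))), seq(0, T, by = h),
                        function(t, y, p) list((yinf(Vt(t)) - y) / tau(Vt(t))),
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ys - ref[, "y"])), 5e-3)
  # gating stays within [0, 1] for arbitrary drive
  set.seed(1)
  y <- runif(1)
  for (k in 1:200) {
    y <- gating_step(y, runif(1, 0, 50), runif(1), runif(1, 0.1, 100))
    expect_true(y >= 0 && y <= 1)
  }
})

test_that("AdEx spike-initiation term is exact at threshold and clamped above", {
  expect_equal(adex_terms(-50, 0, g_L_s = 10, Delta_T = 2, V_th_s = -50), 20)
  expect_lt(adex_terms(-90, 0, 10, 2, -50), 1e-7)
  clamped <- adex_terms(-50 + 100 * 2, 0, 10, 2, -50)
  expect_equal(clamped, 10 * 2 * exp(10))
  expect_true(is.finite(clamped))
})

test_that("receptor windows are causal, normalized to peak w, and reject tau_r >= tau_d", {
  sp <- receptor_spec("AMPA", w = 2.5)
  tp <- double_exp_peak_time(sp$tau_r, sp$tau_d)
  expect_equal(receptor_conductance(sp, 10, 10 + tp), 2.5, tolerance = 1e-9)
  expect_equal(receptor_conductance(sp, 10, 9.99), 0)
  expect_equal(receptor_conductance(sp, 10, 10), 0) # zero at onset
  # AMPA normalization constant for 0.2/3 ms
  expect_equal(double_exp_norm(0.2, 3), 1.30008, tolerance = 1e-4)
  # numeric maximization confirms a single interior maximum equal to w
  tt <- seq(10, 30, by = 1e-4)
  gg <- receptor_conductance(sp, 10, tt)
  expect_equal(max(gg), 2.5, tolerance = 1e-7)
  expect_error(receptor_spec("AMPA", tau_r = 3, tau_d = 3), "tau_d > tau_r")
  expect_error(receptor_spec("AMPA", tau_r = 5, tau_d = 3), "tau_d > tau_r")
})

test_that("the NMDA magnesium block is sigmoid, bounded and correct at anchors", {
  expect_equal(nmda_block(0), 1 / 1.3)
  expect_equal(nmda_block(-10), 0.5508, tolerance = 1e-4)
  expect_gt(nmda_block(200), 0.999)
  v <- seq(-120, 60, by = 1)
  s <- nmda_block(v)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
})
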