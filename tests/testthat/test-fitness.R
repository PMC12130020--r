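# independent transport oracle: expand mass-normalized histograms into unit
# masses via quantiles and pair sorted positions (optimal 1-D coupling)
emd_oracle <- function(u, v, spacing = 1, grain = 2000) {
  qs <- (seq_len(grain) - 0.5) / grain
  pos <- function(w) {
    cw <- cumsum(w) / sum(w)
    vapply(qs, function(q) which(cw >= q - 1e-12)[1], numeric(1))
  }
  mean(abs(pos(u) - pos(v))) * spacing
}

test_that("the 1-D earth mover's distance matches brute-force transport", {
  expect_equal(emd_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  # unit masses at positions i and j move a distance |i - j| * spacing
  u <- c(1, 0, 0, 0); v <- c(0, 0, 0, 1)
  expect_equal(emd_1d(u, v, spacing = 2), 3 * 2)
  expect_equal(emd_1d(rep(0, 5), c(1, 2, 0, 0, 1)), 0) # no mass: defined 0
  set.seed(5)
  for (k in 1:10) {
    a <- rpois(10, 3); b <- rpois(10, 3)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(emd_1d(a, b, spacing = 1.5),
                 emd_oracle(a, b, spacing = 1.5), tolerance = 0.02)
  }
})

test_that("pulse fitness is maximal at the target counts and decays symmetrically", {
  mk <- function(nA, nB, nC, burst) list(
    A = list(n_spikes = nA), B = list(n_spikes = nB),
    C = list(n_spikes = nC), D = list(n_spikes = 2, burst = burst))
  top <- pulse_fitness(mk(0, 1, 3, TRUE))
  expect_equal(unname(top), rep(1, 4))
  low <- pulse_fitness(mk(0, 1, 1, TRUE))
  expect_lt(low[["pulse_caseC"]], 1)
  expect_equal(pulse_fitness(mk(0, 1, 1, TRUE))[["pulse_caseC"]],
               pulse_fitness(mk(0, 1, 5, TRUE))[["pulse_caseC"]])
  expect_lt(pulse_fitness(mk(0, 1, 3, FALSE))[["pulse_caseD"]], 1)
})

test_that("AdEx matching scores are exact for identical curves and reject grid mismatch", {
  Is <- seq(0, 600, 100)
  ref <- list(Is_grid = Is, rate = c(0, 0, 5, 12, 20, 27, 33), cv_isi = 0.2,
              C_m = 380)
  sc <- adex_matching_fitness(Is, ref$rate, 0.2, 380, ref)
  expect_equal(unname(sc), rep(1, 5))
  expect_error(adex_matching_fitness(seq(0, 500, 100), ref$rate[-1], 0.2, 380,
                                     ref), "grid mismatch")
  # a shifted curve scores strictly below 1 on the EMD component
  sc2 <- adex_matching_fitness(Is, ref$rate + 5, 0.2, 380, ref)
  expect_lt(sc2[["adex_emd"]], 1)
})

test_that("gain/linearity scoring sees planar surfaces as perfect and counts violations", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 50))
  surf$min_Vs <- -70
  sc <- gain_linearity_fitness(surf)
  expect_equal(attr(sc, "violations"), 0L)
  expect_gt(sc[["gain_linearity"]], 0.999)
  expect_equal(sc[["gain_presence"]], 1)
  # one non-monotone cell -> exactly one violation
  surf2 <- surf
  surf2$rate[5, 8] <- surf2$rate[4, 8] - 10
  expect_equal(attr(gain_linearity_fitness(surf2), "violations"), 1L)
})

test_that("guard scores flag pathological configurations", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 50))
  surf$min_Vs <- -70
  ok <- guard_fitness(surf, rheobase_window = c(300, 800))
  expect_equal(ok[["no_ca_somatic_only"]], 1)
  expect_equal(ok[["ca_opens"]], 1)
  # calcium active in the I_d = 0 column triggers the somatic-only penalty
  bad <- surf; bad$ca_active[13, 1] <- TRUE
  expect_lt(guard_fitness(bad)[["no_ca_somatic_only"]], 1)
  # rates above the cap trigger the pathological penalty
  hot <- surf; hot$rate[10, 10] <- 400
  expect_lt(guard_fitness(hot, rate_cap = 200)[["pathological_rate"]], 1)
  # never-active calcium is penalized
  off <- surf; off$ca_active[] <- FALSE
  expect_lt(guard_fitness(off)[["ca_opens"]], 1)
})

test_that("the full fitness is the exact sum of finite components", {
  rep <- ca_adex_fitness(fitted_genome, Is_grid = seq(0, 600, 300),
                         Id_grid = seq(0, 800, 400), stim_duration = 400)
  expect_true(all(is.finite(rep$components)))
  expect_identical(rep$global, sum(rep$components))
  # a genome that breaks the simulation scores zero on every component
  broken <- fitted_genome
  broken[["C_m_d"]] <- -1
  bad <- ca_adex_fitness(broken, Is_grid = seq(0, 600, 300),
                         Id_grid = seq(0, 800, 400), stim_duration = 400)
  expect_equal(unname(bad$components), rep(0, length(bad$components)))
  expect_equal(bad$global, 0)
})
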