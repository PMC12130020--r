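test_that("the two-compartment builder attaches the right mechanisms", {
  tr <- build_two_compartment(fitted_genome)
  expect_s3_class(tr, "compartment_tree")
  expect_equal(tr$n, 2L)
  expect_s3_class(tr$adex[[1]], "adex_mechanism")
  expect_null(tr$adex[[2]])
  expect_s3_class(tr$ca[[2]], "ca_hotzone_mechanism")
  expect_equal(tr$bap_targets[[1]], 2L)
  # zero coupling is a valid (apical-isolation) configuration
  g0 <- fitted_genome; g0[["g_C"]] <- 0
  expect_equal(build_two_compartment(g0)$g_C[2], 0)
})

test_that("incomplete or out-of-bounds genomes are rejected with names", {
  g <- fitted_genome
  g <- g[setdiff(names(g), "tau_Ca")]
  expect_error(build_two_compartment(g), "tau_Ca")
  g2 <- fitted_genome; g2[["g_Ca"]] <- 1e6
  expect_error(build_two_compartment(g2), "g_Ca")
})

test_that("validate_genome reports violations and accepts closed bounds", {
  expect_equal(nrow(validate_genome(fitted_genome)), 0L)
  b <- default_genome_bounds()
  g <- fitted_genome
  g[["g_Ca"]] <- b$g_Ca[1] # exactly at the lower bound: valid
  expect_equal(nrow(validate_genome(g, b)), 0L)
  g[["tau_w"]] <- b$tau_w[2] + 1
  rep <- validate_genome(g, b)
  expect_equal(rep$parameter, "tau_w")
})

test_that("build_tree enforces the tree structure", {
  one <- build_tree(list(compartment(1, NA, C_m = 100, g_L = 5, E_L = -65)))
  expect_equal(one$n, 1L)
  expect_error(build_tree(list(
    compartment(1, NA, C_m = 100, g_L = 5, E_L = -65),
    compartment(2, 2, C_m = 100, g_L = 5, E_L = -65, g_C = 1))),
    "structure error")
  expect_error(build_tree(list(
    compartment(1, NA, C_m = 100, g_L = 5, E_L = -65),
    compartment(2, NA, C_m = 100, g_L = 5, E_L = -65))),
    "structure error")
  # edges = nodes - 1 on a random accepted layout
  set.seed(42)
  n <- 12
  comps <- list(compartment(1, NA, C_m = 100, g_L = 5, E_L = -65))
  for (i in 2:n)
    comps[[i]] <- compartment(i, sample.int(i - 1, 1), C_m = 100, g_L = 5,
                              E_L = -65, g_C = runif(1, 1, 10))
  tr <- build_tree(comps)
  expect_equal(sum(!is.na(tr$parent)), n - 1L)
})

test_that("a 16-site reduced pyramidal layout builds and runs", {
  g <- fitted_genome
  mk <- function(i, p) compartment(i, p, C_m = 40, g_L = 3, E_L = -70, g_C = 8,
                                   receptors = list(receptor_spec("AMPA_NMDA")))
  soma <- compartment(1, NA, C_m = g[["C_m_s"]], g_L = g[["g_L_s"]],
                      E_L = g[["E_L_s"]],
                      channels = list(adex_mechanism(
                        g[["Delta_T"]], g[["V_th_s"]], g[["V_th"]],
                        g[["V_reset"]], g[["t_ref"]], g[["a"]], g[["b"]],
                        g[["tau_w"]], g[["g_w"]], g[["w_BAP"]], g[["d_BAP"]])))
  hz <- compartment(2, 1, C_m = g[["C_m_d"]], g_L = g[["g_L_d"]],
                    E_L = g[["E_L_d"]], g_C = g[["g_C"]],
                    channels = list(do.call(ca_hotzone_mechanism,
                      as.list(fitted_genome[c("g_Ca", "E_Ca", "m_slope", "m_half",
                        "h_slope", "h_half", "tau_m_Ca", "tau_h_Ca", "g_K",
                        "E_K", "tau_m_KCa", "Ca_th", "const_KCa", "phi_Ca",
                        "Ca_0", "tau_Ca")]))))
  comps <- c(list(soma, hz),
             lapply(3:8, function(i) mk(i, 2L)),    # apical tuft sites
             lapply(9:16, function(i) mk(i, 1L)))   # basal sites
  tr <- build_tree(comps)
  tr$bap_targets[[1]] <- 2L
  expect_equal(tr$n, 16L)
  r <- simulate(tr, stim_program(stim_step(1, 200, 0, 50)),
                solver_config(h = 0.1, T = 50))
  expect_true(all(is.finite(r$V)))
})

test_that("trees and genomes round-trip through serialization", {
  tmp <- tempfile(fileext = ".json")
  write_tree(fitted_tree, tmp)
  tr2 <- read_tree(tmp)
  expect_equal(tr2, fitted_tree)
  tmp2 <- tempfile(fileext = ".yaml")
  write_tree(fitted_tree, tmp2)
  expect_equal(read_tree(tmp2), fitted_tree)
  gj <- tempfile(fileext = ".json")
  write_genome(fitted_genome, gj)
  expect_equal(read_genome(gj), fitted_genome)
  gy <- tempfile(fileext = ".yml")
  write_genome(fitted_genome, gy)
  expect_equal(read_genome(gy), fitted_genome, tolerance = 1e-12)
})
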