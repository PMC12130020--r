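# shared fixtures, built in code
fitted_genome <- ca_adex_genome()
fitted_tree <- build_two_compartment(fitted_genome)

passive_two_comp <- function() {
  build_tree(list(
    compartment(1, NA, C_m = 200, g_L = 10, E_L = -70),
    compartment(2, 1, C_m = 100, g_L = 5, E_L = -70, g_C = 15)))
}

# random symmetric diagonally dominant tree system for solver tests
random_tree_system <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  off <- c(0, -runif(n - 1, 0.1, 2))
  diag <- runif(n, 0.5, 2)
  for (i in 2:n) {
    diag[i] <- diag[i] + abs(off[i])
    diag[parent[i]] <- diag[parent[i]] + abs(off[i])
  }
  A <- matrix(0, n, n)
  for (i in 1:n) A[i, i] <- diag[i]
  for (i in 2:n) { A[i, parent[i]] <- off[i]; A[parent[i], i] <- off[i] }
  list(parent = parent, diag = diag, off = off, A = A,
       rhs = rnorm(n))
}

# reference ThetaPlanes model used for round-trip tests
reference_thetaplanes <- function() {
  m <- list(a_plus = 0.05, b_plus = 0.08, d_plus = 3,
            a_minus = 0.03, b_minus = 0.01, d_minus = -5,
            theta_m_H = -0.5, theta_q_H = 600,
            theta_m_rho = NA, theta_q_rho = NA, nu_low = 10, I_th = Inf)
  m$theta_m_rho <- -m$a_minus / m$b_minus
  m$theta_q_rho <- -m$d_minus / m$b_minus
  structure(m, class = "thetaplanes_model")
}
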