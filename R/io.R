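#' Read / write transfer surfaces as long-format CSV
#'
#' Columns `I_s`, `I_d`, `rate`, `ca_active`.  Row order is irrelevant on
#' read: the grid is reconstructed from the unique current values and the
#' file must cover the full grid exactly once; anything else is rejected.
#'
#' @param surface A `transfer_surface`.
#' @param path CSV path.
#' @export
write_surface <- function(surface, path) {
  grid <- expand.grid(i = seq_along(surface$Is_grid),
                      j = seq_along(surface$Id_grid))
  df <- data.frame(I_s = surface$Is_grid[grid$i], I_d = surface$Id_grid[grid$j],
                   rate = surface$rate[cbind(grid$i, grid$j)],
                   ca_active = surface$ca_active[cbind(grid$i, grid$j)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path)
  need <- c("I_s", "I_d", "rate", "ca_active")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  Is <- sort(unique(df$I_s)); Id <- sort(unique(df$I_d))
  if (nrow(df) != length(Is) * length(Id))
    stop("parse error in ", path, ": rows do not form a full I_s x I_d grid")
  rate <- matrix(NA_real_, length(Is), length(Id))
  ca <- matrix(NA, length(Is), length(Id))
  i <- match(df$I_s, Is); j <- match(df$I_d, Id)
  if (anyDuplicated(cbind(i, j)))
    stop("parse error in ", path, ": duplicated grid point")
  rate[cbind(i, j)] <- df$rate
  ca[cbind(i, j)] <- as.logical(df$ca_active)
  structure(list(Is_grid = Is, Id_grid = Id, rate = rate, ca_active = ca,
                 min_Vs = NA_real_, meta = list(source = path)),
            class = "transfer_surface")
}

#' Read / write spike files (GDF-like two-column text)
#'
#' Whitespace-separated `t_ms unit_id` rows with a header line.  Times must
#' be non-decreasing; violations are rejected with the offending line
#' number.
#'
#' @param times Spike times (ms).
#' @param ids Unit ids (integer), recycled.
#' @param path Output path.
#' @export
write_spikes <- function(times, ids, path) {
  ids <- rep_len(as.integer(ids), length(times))
  utils::write.table(data.frame(t_ms = times, unit_id = ids), path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("t_ms", "unit_id") %in% names(df)))
    stop("parse error in ", path, ": expected columns t_ms, unit_id")
  bad <- which(diff(df$t_ms) < 0)
  if (length(bad))
    stop("parse error in ", path, ": non-monotone spike time at line ",
         bad[1] + 2)
  df
}

#' Construct an exactly piecewise-planar synthetic transfer surface
#'
#' Evaluates a ThetaPlanes model on a grid and marks calcium activation by
#' the model's own Heaviside boundary; refitting such a surface recovers the
#' model (used by the round-trip tests and fixtures).
#'
#' @param model A `thetaplanes_model`.
#' @param Is_grid,Id_grid Current grids (pA).
#' @param noise_sd Optional Gaussian rate noise (Hz, default 0).
#' @return A `transfer_surface`.
#' @export
synthetic_surface <- function(model, Is_grid, Id_grid, noise_sd = 0) {
  ni <- length(Is_grid); nj <- length(Id_grid)
  grid <- expand.grid(i = seq_len(ni), j = seq_len(nj))
  Is <- Is_grid[grid$i]; Id <- Id_grid[grid$j]
  rate <- matrix(evaluate_thetaplanes(model, Is, Id), ni, nj)
  if (noise_sd > 0) rate <- rate + matrix(stats::rnorm(ni * nj, 0, noise_sd), ni, nj)
  ca <- matrix(Id - (model$theta_m_H * Is + model$theta_q_H) >= 0, ni, nj)
  structure(list(Is_grid = Is_grid, Id_grid = Id_grid, rate = rate,
                 ca_active = ca, min_Vs = NA_real_,
                 meta = list(source = "synthetic_thetaplanes")),
            class = "transfer_surface")
}

#' Closed-form response of a passive tree to constant current
#'
#' Independent linear-systems reference: solves `C dV/dt = A V + b` by eigen
#' decomposition for a passive tree (no channels) under constant injected
#' currents, evaluated on a time grid.
#'
#' @param tree A passive `compartment_tree`.
#' @param I Constant current per compartment (pA).
#' @param times Evaluation times (ms).
#' @param v0 Initial voltages (default `E_L`).
#' @return Matrix `length(times)` x n of voltages.
#' @export
passive_response <- function(tree, I, times, v0 = NULL) {
  n <- tree$n
  A <- matrix(0, n, n)
  b <- tree$g_L * tree$E_L + rep_len(I, n)
  for (i in seq_len(n)) A[i, i] <- -tree$g_L[i]
  for (i in seq_len(n)[-1]) {
    p <- tree$parent[i]
    A[i, i] <- A[i, i] - tree$g_C[i]
    A[p, p] <- A[p, p] - tree$g_C[i]
    A[i, p] <- A[i, p] + tree$g_C[i]
    A[p, i] <- A[p, i] + tree$g_C[i]
  }
  A <- A / tree$C_m
  b <- b / tree$C_m
  vinf <- solve(A, -b)
  ev <- eigen(A)
  if (is.null(v0)) v0 <- tree$E_L
  coef <- solve(ev$vectors, v0 - vinf)
  out <- matrix(0, length(times), n)
  for (k in seq_along(times)) {
    out[k, ] <- Re(vinf + ev$vectors %*% (coef * exp(ev$values * times[k])))
  }
  out
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text fixture files: `passive_tree` (a two-compartment
#' passive tree plus its closed-form step response), `planar_surface` (an
#' exactly piecewise-planar surface with its generating model),
#' `poisson_trains` (a seeded spike file) or `toy_network` (a scaled-down
#' network spec).  Byte-identical for a fixed seed.
#'
#' @param kind One of `"passive_tree"`, `"planar_surface"`,
#'   `"poisson_trains"`, `"toy_network"`.
#' @param dir Output directory (created if needed).
#' @param seed Seed.
#' @param params Optional overrides (list).
#' @return Character vector of written paths.
#' @export
generate_fixture <- function(kind = c("passive_tree", "planar_surface",
                                      "poisson_trains", "toy_network"),
                             dir, seed = 1, params = list()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (kind == "passive_tree") {
    tr <- build_tree(list(
      compartment(1, NA, C_m = 200, g_L = 10, E_L = -70),
      compartment(2, 1, C_m = 100, g_L = 5, E_L = -70, g_C = 15)))
    p1 <- file.path(dir, "passive_tree.json")
    write_tree(tr, p1)
    times <- seq(0, 100, by = 1)
    V <- passive_response(tr, c(params$I %||% 100, 0), times)
    p2 <- file.path(dir, "passive_tree_step_response.csv")
    utils::write.csv(data.frame(t_ms = times, V1_mV = V[, 1], V2_mV = V[, 2]),
                     p2, row.names = FALSE)
    return(c(p1, p2))
  }
  if (kind == "planar_surface") {
    model <- structure(list(
      a_plus = params$a_plus %||% 0.05, b_plus = params$b_plus %||% 0.08,
      d_plus = params$d_plus %||% 3,
      a_minus = params$a_minus %||% 0.03, b_minus = params$b_minus %||% 0.01,
      d_minus = params$d_minus %||% -5,
      theta_m_H = params$theta_m_H %||% -0.5,
      theta_q_H = params$theta_q_H %||% 600,
      theta_m_rho = -3, theta_q_rho = 500, nu_low = 10, I_th = Inf),
      class = "thetaplanes_model")
    model$theta_m_rho <- -model$a_minus / model$b_minus
    model$theta_q_rho <- -model$d_minus / model$b_minus
    surf <- synthetic_surface(model, seq(0, 600, by = 25), seq(0, 900, by = 25))
    p1 <- file.path(dir, "planar_surface.csv")
    p2 <- file.path(dir, "planar_surface_model.json")
    write_surface(surf, p1); write_thetaplanes(model, p2)
    return(c(p1, p2))
  }
  if (kind == "poisson_trains") {
    tt <- poisson_train(params$rate %||% 20, 0, params$T %||% 10000)
    p1 <- file.path(dir, "poisson_train.gdf")
    write_spikes(tt, 1L, p1)
    return(p1)
  }
  p1 <- file.path(dir, "toy_network.yaml")
  write_network_spec(network_spec(N_exc = params$N_exc %||% 40,
                                  N_inh = params$N_inh %||% 10,
                                  K = params$K %||% 25, J_exc = 1,
                                  ext_rate = 1000, duration = 500), p1)
  p1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
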