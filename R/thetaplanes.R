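#' Boolean masks for the two planar regions of the transfer surface
#'
#' `M_plus` marks the calcium-active (high-rate) points; `M_minus` marks the
#' points that are not calcium-active but fire above `nu_low`.  Both masks
#' exclude the band `I_s > I_th`, where boundary non-linearities would bias
#' the planar fits.
#'
#' @param surface A `transfer_surface`.
#' @param nu_low Low-rate threshold (Hz), default 10.
#' @param I_th Somatic-current exclusion edge (pA), default `Inf` (no band).
#' @return List of logical matrices `M_plus`, `M_minus`.
#' @export
compute_masks <- function(surface, nu_low = 10, I_th = Inf) {
  keep <- outer(surface$Is_grid <= I_th, rep(TRUE, length(surface$Id_grid)))
  M_plus <- surface$ca_active & keep
  M_minus <- (!surface$ca_active) & (surface$rate > nu_low) & keep
  list(M_plus = M_plus, M_minus = M_minus)
}

#' Ordinary least-squares plane fit over a masked region
#'
#' Fits `nu(I_s, I_d) = a*I_s + b*I_d + d` to the surface points selected by
#' the mask.
#'
#' @param surface A `transfer_surface`.
#' @param mask Logical matrix of the same shape as `surface$rate` with at
#'   least 3 non-collinear points.
#' @return List `a`, `b`, `d` (Hz/pA, Hz/pA, Hz) plus a residual report
#'   (`max_resid`, `rms_resid` in Hz, `n_points`).
#' @export
fit_planes <- function(surface, mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("fit error: mask has fewer than 3 points")
  Is <- surface$Is_grid[idx[, 1]]
  Id <- surface$Id_grid[idx[, 2]]
  nu <- surface$rate[mask]
  X <- cbind(Is, Id)
  if (qr(cbind(1, X))$rank < 3) stop("fit error: masked points are collinear")
  fit <- stats::lm.fit(cbind(1, X), nu)
  co <- fit$coefficients
  resid <- fit$residuals
  list(a = unname(co[2]), b = unname(co[3]), d = unname(co[1]),
       max_resid = max(abs(resid)), rms_resid = sqrt(mean(resid^2)),
       n_points = length(nu))
}

#' Boundary and rheobase lines of the piecewise-planar model
#'
#' The boundary line `Id = theta_m_H * Is + theta_q_H` is the least-squares
#' fit through the lowest calcium-active distal current of every somatic
#' current column (columns without active points are skipped, not imputed).
#' The rheobase line is the zero locus of the fitted low-rate plane,
#' `theta_m_rho = -a_minus/b_minus`, `theta_q_rho = -d_minus/b_minus`.
#'
#' @param surface A `transfer_surface`.
#' @param masks Output of [compute_masks()].
#' @param plane_minus Fitted low-rate plane from [fit_planes()].
#' @return List `theta_m_H`, `theta_q_H`, `theta_m_rho`, `theta_q_rho`.
#' @export
fit_boundary_and_rheobase <- function(surface, masks, plane_minus) {
  bx <- c(); by <- c()
  for (i in seq_along(surface$Is_grid)) {
    j <- which(masks$M_plus[i, ])
    if (length(j)) { bx <- c(bx, surface$Is_grid[i]); by <- c(by, surface$Id_grid[min(j)]) }
  }
  if (length(bx) < 2) stop("fit error: fewer than 2 boundary points")
  bf <- stats::lm.fit(cbind(1, bx), by)$coefficients
  if (abs(plane_minus$b) <= 0)
    stop("rheobase undefined: low-rate plane has zero distal-current slope")
  list(theta_m_H = unname(bf[2]), theta_q_H = unname(bf[1]),
       theta_m_rho = -plane_minus$a / plane_minus$b,
       theta_q_rho = -plane_minus$d / plane_minus$b)
}

#' Fit the full ThetaPlanes model from a transfer surface
#'
#' Pipeline: masks, the two plane fits, the boundary line and the rheobase
#' line, assembled into the 10-parameter piecewise-planar transfer function
#' (see [evaluate_thetaplanes()]).
#'
#' @inheritParams compute_masks
#' @return A `thetaplanes_model`.
#' @export
fit_thetaplanes <- function(surface, nu_low = 10, I_th = Inf) {
  masks <- compute_masks(surface, nu_low, I_th)
  pp <- fit_planes(surface, masks$M_plus)
  pm <- fit_planes(surface, masks$M_minus)
  th <- fit_boundary_and_rheobase(surface, masks, pm)
  structure(list(a_plus = pp$a, b_plus = pp$b, d_plus = pp$d,
                 a_minus = pm$a, b_minus = pm$b, d_minus = pm$d,
                 theta_m_H = th$theta_m_H, theta_q_H = th$theta_q_H,
                 theta_m_rho = th$theta_m_rho, theta_q_rho = th$theta_q_rho,
                 nu_low = nu_low, I_th = I_th),
            class = "thetaplanes_model")
}

#' Evaluate a ThetaPlanes transfer function
#'
#' `nu_F = Theta_rho * (1 - Theta_H) * nu_minus + Theta_H * nu_plus`, where
#' `Theta_H = Theta(I_d - boundary_line(I_s))` and
#' `Theta_rho = Theta(I_d - rheobase_line(I_s))`, with the Heaviside
#' convention `Theta(0) = 1` (closed on the active side).  Pure and total:
#' defined for every `(I_s, I_d)`, vectorized.
#'
#' @param model A `thetaplanes_model`.
#' @param I_s,I_d Currents (pA), recycled to a common length.
#' @return Firing rate(s) in Hz.
#' @export
evaluate_thetaplanes <- function(model, I_s, I_d) {
  n <- max(length(I_s), length(I_d))
  I_s <- rep_len(I_s, n); I_d <- rep_len(I_d, n)
  # Theta(0) = 1, decided up to a small numerical tolerance (1e-6 pA) so
  # that points lying exactly on a fitted line land on the active side
  H <- as.numeric(I_d - (model$theta_m_H * I_s + model$theta_q_H) >= -1e-6)
  R <- as.numeric(I_d - (model$theta_m_rho * I_s + model$theta_q_rho) >= -1e-6)
  nu_m <- model$a_minus * I_s + model$b_minus * I_d + model$d_minus
  nu_p <- model$a_plus * I_s + model$b_plus * I_d + model$d_plus
  R * (1 - H) * nu_m + H * nu_p
}

#' Error report of a ThetaPlanes fit
#'
#' Max and RMS errors (Hz) between the model and the simulated surface over
#' the `M_plus` region, the `M_minus` region, and their union (the exclusion
#' band `I_s > I_th` is omitted throughout).
#'
#' @param surface A `transfer_surface`.
#' @param model A `thetaplanes_model`.
#' @return Data frame with columns `region`, `max_err`, `rms_err`, `n`.
#' @export
thetaplanes_report <- function(surface, model) {
  masks <- compute_masks(surface, model$nu_low, model$I_th)
  grid <- expand.grid(i = seq_along(surface$Is_grid), j = seq_along(surface$Id_grid))
  pred <- matrix(evaluate_thetaplanes(model, surface$Is_grid[grid$i],
                                      surface$Id_grid[grid$j]),
                 length(surface$Is_grid), length(surface$Id_grid))
  err <- pred - surface$rate
  one <- function(region, m) {
    if (!any(m)) return(data.frame(region = region, max_err = NA_real_,
                                   rms_err = NA_real_, n = 0L))
    data.frame(region = region, max_err = max(abs(err[m])),
               rms_err = sqrt(mean(err[m]^2)), n = sum(m))
  }
  rbind(one("M_plus", masks$M_plus), one("M_minus", masks$M_minus),
        one("overall", masks$M_plus | masks$M_minus))
}

#' Read / write ThetaPlanes models as flat JSON
#'
#' @param model A `thetaplanes_model`.
#' @param path JSON file path.
#' @export
write_thetaplanes <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_thetaplanes
#' @export
read_thetaplanes <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a_plus", "b_plus", "d_plus", "a_minus", "b_minus", "d_minus",
            "theta_m_H", "theta_q_H", "theta_m_rho", "theta_q_rho")
  miss <- setdiff(need, names(j))
  if (length(miss)) stop("malformed thetaplanes file, missing: ",
                         paste(miss, collapse = ", "))
  structure(j[c(need, intersect(c("nu_low", "I_th"), names(j)))],
            class = "thetaplanes_model")
}
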