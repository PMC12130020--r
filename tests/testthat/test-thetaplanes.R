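test_that("masks partition the surface and honor the exclusion band", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25))
  masks <- compute_masks(surf, nu_low = 10, I_th = Inf)
  expect_false(any(masks$M_plus & masks$M_minus))
  # a silent surface yields empty masks
  silent <- surf
  silent$rate[] <- 0
  silent$ca_active[] <- FALSE
  m0 <- compute_masks(silent, 10, Inf)
  expect_false(any(m0$M_plus) || any(m0$M_minus))
  # points beyond I_th are excluded even when active and fast-firing
  m2 <- compute_masks(surf, 10, I_th = 300)
  hot <- which(surf$Is_grid > 300)
  expect_false(any(m2$M_plus[hot, ]) || any(m2$M_minus[hot, ]))
})

test_that("plane fits recover exact and noisy planar data", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25))
  masks <- compute_masks(surf, 10, Inf)
  fit <- fit_planes(surf, masks$M_plus)
  expect_equal(fit$a, 0.05, tolerance = 1e-10)
  expect_equal(fit$b, 0.08, tolerance = 1e-10)
  expect_equal(fit$d, 3, tolerance = 1e-8)
  expect_lt(fit$max_resid, 1e-9)
  # constant surface: zero slopes, intercept equals the constant
  flat <- surf; flat$rate[] <- 42
  ffit <- fit_planes(flat, masks$M_plus)
  expect_equal(c(ffit$a, ffit$b, ffit$d), c(0, 0, 42), tolerance = 1e-10)
  expect_error(fit_planes(surf, matrix(FALSE, length(surf$Is_grid),
                                       length(surf$Id_grid))), "fit error")
  # Gaussian noise: recovered coefficients stay within 3 standard errors
  cover <- 0
  for (seed in 1:20) {
    set.seed(seed)
    noisy <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25),
                               noise_sd = 0.5)
    idx <- which(masks$M_plus, arr.ind = TRUE)
    df <- data.frame(y = noisy$rate[masks$M_plus],
                     Is = noisy$Is_grid[idx[, 1]], Id = noisy$Id_grid[idx[, 2]])
    lmfit <- lm(y ~ Is + Id, df)
    se <- coef(summary(lmfit))[, "Std. Error"]
    nf <- fit_planes(noisy, masks$M_plus)
    ok <- abs(nf$a - 0.05) < 3 * se["Is"] && abs(nf$b - 0.08) < 3 * se["Id"]
    cover <- cover + ok
  }
  expect_gte(cover, 18)
})

test_that("boundary and rheobase lines follow their defining algebra", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25))
  masks <- compute_masks(surf, 10, Inf)
  pm <- fit_planes(surf, masks$M_minus)
  th <- fit_boundary_and_rheobase(surf, masks, pm)
  expect_equal(th$theta_m_H, -0.5, tolerance = 0.06)
  expect_equal(th$theta_q_H, 600, tolerance = 26) # within one grid step
  # rheobase line of a given low plane: a=0, b=0.1, d=-10 -> flat Id = 100
  th2 <- fit_boundary_and_rheobase(surf, masks, list(a = 0, b = 0.1, d = -10))
  expect_equal(th2$theta_m_rho, 0)
  expect_equal(th2$theta_q_rho, 100)
  expect_error(fit_boundary_and_rheobase(surf, masks, list(a = 1, b = 0, d = 1)),
               "rheobase undefined")
})

test_that("evaluation is piecewise-planar with a closed active side", {
  model <- reference_thetaplanes()
  # below the rheobase line: exactly zero
  expect_equal(evaluate_thetaplanes(model, 0, 0), 0)
  # above the boundary line: exactly the high plane
  expect_equal(evaluate_thetaplanes(model, 100, 800),
               0.05 * 100 + 0.08 * 800 + 3)
  # Theta(0) = 1: a point exactly on the boundary belongs to the active side
  Is <- 200; Id <- model$theta_m_H * Is + model$theta_q_H
  expect_equal(evaluate_thetaplanes(model, Is, Id),
               0.05 * Is + 0.08 * Id + 3)
  # the discontinuity across the boundary equals nu_plus - nu_minus there
  eps <- 1e-3
  lo <- evaluate_thetaplanes(model, Is, Id - eps)
  hi <- evaluate_thetaplanes(model, Is, Id)
  expect_equal(hi - lo,
               (0.05 * Is + 0.08 * Id + 3) - (0.03 * Is + 0.01 * Id - 5),
               tolerance = 1e-6)
})

test_that("the full fit round-trips a known 10-parameter model", {
  model <- reference_thetaplanes()
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25))
  fit <- fit_thetaplanes(surf, nu_low = 10, I_th = Inf)
  expect_equal(fit$a_plus, model$a_plus, tolerance = 1e-6)
  expect_equal(fit$b_plus, model$b_plus, tolerance = 1e-6)
  expect_equal(fit$d_plus, model$d_plus, tolerance = 1e-4)
  expect_equal(fit$a_minus, model$a_minus, tolerance = 1e-6)
  expect_equal(fit$b_minus, model$b_minus, tolerance = 1e-6)
  expect_equal(fit$d_minus, model$d_minus, tolerance = 1e-4)
  expect_equal(fit$theta_m_H, model$theta_m_H, tolerance = 0.06)
  expect_equal(fit$theta_q_H, model$theta_q_H, tolerance = 26)
  expect_equal(fit$theta_m_rho, model$theta_m_rho, tolerance = 1e-6)
  expect_equal(fit$theta_q_rho, model$theta_q_rho, tolerance = 1e-3)
  rp <- thetaplanes_report(surf, fit)
  expect_lt(rp$rms_err[rp$region == "M_plus"], 1e-9)
  # the fitted function is non-negative over the fitted masks
  masks <- compute_masks(surf, 10, Inf)
  idx <- which(masks$M_plus | masks$M_minus, arr.ind = TRUE)
  vals <- evaluate_thetaplanes(fit, surf$Is_grid[idx[, 1]], surf$Id_grid[idx[, 2]])
  expect_true(all(vals >= 0))
  # JSON round trip
  tmp <- tempfile(fileext = ".json")
  write_thetaplanes(fit, tmp)
  back <- read_thetaplanes(tmp)
  expect_equal(back$a_plus, fit$a_plus)
  expect_equal(back$theta_q_rho, fit$theta_q_rho)
})

test_that("the error report omits the exclusion band", {
  model <- reference_thetaplanes()
  model$I_th <- 300
  surf <- synthetic_surface(model, seq(0, 600, 50), seq(0, 900, 25))
  # corrupt rates beyond I_th: the report must not see them
  surf$rate[surf$Is_grid > 300, ] <- 1e6
  rp <- thetaplanes_report(surf, model)
  expect_lt(rp$max_err[rp$region == "overall"], 1e-6)
})
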