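# Four-flux Kubelka-Munk solution of the spongy layer: coefficient
# mapping, eigenvalues, boundary matching, and equivalence with an
# independent ODE integration.

test_that("coefficient matrix maps parameters as the four-flux system prescribes", {
  sp <- spongy_params(l = um_to_cm(58.6), a_Sp = 20, s_Sp = 600, f = 0.5)
  m <- build_km_matrix(sp, 0, 0)
  expect_equal(m$L33, -640)
  expect_equal(m$L34, 600)
  expect_equal(m$L43, -600)
  expect_equal(m$L44, 640)
  expect_equal(m$L11, -620)
  expect_equal(m$L22, 620)
  # zero scattering decouples everything
  m0 <- build_km_matrix(spongy_params(um_to_cm(50), 30, s_Sp = 0), 0.3, 0.2)
  expect_equal(m0$L31, 0); expect_equal(m0$L34, 0)
  expect_equal(m0$L33, -60)
  expect_error(build_km_matrix(sp, pi / 2, 0), "grazing")
})

test_that("scattering redistributes exactly what the collimated flows lose", {
  # flux-balance identities of the coefficient mapping: summed scattered
  # gains equal the collimated scattering loss; diffuse columns lose 2 a_Sp
  set.seed(7)
  for (k in 1:20) {
    sp <- spongy_params(um_to_cm(runif(1, 10, 150)), runif(1, 1, 500),
                        runif(1, 0, 1500), runif(1, 0, 1))
    b1 <- runif(1, 0, 40) * pi / 180; b2 <- runif(1, 0, 40) * pi / 180
    m <- build_km_matrix(sp, b1, b2)
    expect_equal(m$L11 + m$L31 - m$L41, -sp$a_Sp / cos(b1), tolerance = 1e-10)
    expect_equal(-m$L22 + m$L32 - m$L42, -sp$a_Sp / cos(b2), tolerance = 1e-10)
    expect_equal(m$L33 - m$L43, -2 * sp$a_Sp, tolerance = 1e-10)
    expect_equal(m$L34 - m$L44, -2 * sp$a_Sp, tolerance = 1e-10)
  }
})

test_that("eigenvalues reduce to the classical Kubelka-Munk exponent", {
  sp <- spongy_params(um_to_cm(58.6), a_Sp = 20, s_Sp = 600, f = 0.5)
  m <- build_km_matrix(sp, 0, 0)
  ev <- km_eigenvalues(m)
  expect_equal(ev$lambda1, m$L11)
  expect_equal(ev$lambda2, m$L22)
  expect_equal(ev$lambda3, 2 * sqrt(20 * 620), tolerance = 1e-12)  # 222.71
  expect_equal(ev$lambda4, -ev$lambda3, tolerance = 1e-12)
  # zero scattering: the block is diagonal with roots {-2a, +2a}
  m0 <- build_km_matrix(spongy_params(um_to_cm(50), 30, s_Sp = 0), 0, 0)
  ev0 <- km_eigenvalues(m0)
  expect_equal(sort(c(ev0$lambda3, ev0$lambda4)), c(-60, 60))
})

test_that("eigenvalues satisfy the characteristic equation and match a generic eigensolver", {
  set.seed(11)
  for (k in 1:20) {
    sp <- spongy_params(um_to_cm(runif(1, 10, 150)), runif(1, 1, 500),
                        runif(1, 0, 1500), runif(1, 0.05, 0.95))
    b1 <- runif(1, 0, 40) * pi / 180; b2 <- runif(1, 0, 40) * pi / 180
    m <- build_km_matrix(sp, b1, b2)
    ev <- km_eigenvalues(m)
    for (lam in c(ev$lambda3, ev$lambda4)) {
      resid <- (m$L33 - lam) * (m$L44 - lam) - m$L34 * m$L43
      expect_lt(abs(resid), 1e-9 * max(lam^2, 1))
    }
    block <- matrix(c(m$L33, m$L34, m$L43, m$L44), 2, 2, byrow = TRUE)
    expect_equal(sort(c(ev$lambda3, ev$lambda4)),
                 sort(Re(eigen(block)$values)), tolerance = 1e-10)
  }
})

test_that("solution satisfies all four boundary conditions", {
  sp <- spongy_params(um_to_cm(58.6), a_Sp = 20, s_Sp = 600, f = 0.5)
  m <- build_km_matrix(sp, refract(35 * pi / 180), refract(35 * pi / 180))
  sol <- km_solve(1000, 200, 150, 80, sp, m)
  top <- km_evaluate(sol, 0)
  bot <- km_evaluate(sol, sp$l)
  expect_equal(top$I_C, 1000, tolerance = 1e-9)
  expect_equal(top$I_S, 200, tolerance = 1e-9)
  expect_equal(bot$J_C, 150, tolerance = 1e-9)
  expect_equal(bot$J_S, 80, tolerance = 1e-9)
  # all-zero boundary fluxes give the zero solution
  z <- km_solve(0, 0, 0, 0, sp, m)
  zt <- km_evaluate(z, sp$l / 2)
  expect_true(all(abs(unlist(zt)) < 1e-12))
  expect_error(km_solve(-1, 0, 0, 0, sp, m), ">= 0")
})

test_that("analytic flows match the ODE integration oracle across random parameters", {
  set.seed(101)
  worst <- 0
  for (k in 1:50) {
    a <- runif(1, 1, 500); s <- runif(1, 0, 1500)
    l <- um_to_cm(runif(1, 10, 150)); f <- 0.5
    b1 <- runif(1, 0, 40) * pi / 180; b2 <- runif(1, 0, 40) * pi / 180
    bc <- runif(4, 0, 1000)
    sp <- spongy_params(l, a, s, f)
    m <- build_km_matrix(sp, b1, b2)
    sol <- km_solve(bc[1], bc[2], bc[3], bc[4], sp, m)
    x1 <- seq(0, l, length.out = 7)
    orc <- km_ode_oracle(bc[1], bc[2], bc[3], bc[4], l, a, s, f, b1, b2,
                         x1_out = x1[2:6])
    scale <- max(abs(orc$flows), 1)
    for (i in seq_along(x1)) {
      ana <- km_evaluate(sol, x1[i])
      num <- orc$flows[match(TRUE, abs(orc$x1 - x1[i]) < 1e-12), ]
      worst <- max(worst, abs(unlist(ana)[c("I_C", "J_C", "I_S", "J_S")] -
                                num) / scale)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("scattered output grows with scattering and thickness at fixed absorption", {
  b <- refract(35 * pi / 180)
  js_top <- function(s_Sp, l_um) {
    sp <- spongy_params(um_to_cm(l_um), a_Sp = 20, s_Sp = s_Sp, f = 0.5)
    km_evaluate(km_solve(1000, 0, 0, 0, sp, build_km_matrix(sp, b, b)), 0)$J_S
  }
  js_s <- vapply(c(200, 400, 600, 800, 1000), js_top, numeric(1), l_um = 58.6)
  expect_true(all(diff(js_s) > 0))
  js_l <- vapply(c(20, 40, 60, 80, 120), function(l) js_top(600, l), numeric(1))
  expect_true(all(diff(js_l) > 0))
})

test_that("outputs stay finite for optically thick layers and continuous at the absorption floor", {
  sp <- spongy_params(um_to_cm(150), a_Sp = 5000, s_Sp = 1500, f = 0.5)
  m <- build_km_matrix(sp, 0.3, 0.3)
  sol <- km_solve(1000, 500, 200, 100, sp, m)
  for (x in c(0, sp$l / 2, sp$l)) {
    v <- unlist(km_evaluate(sol, x))
    expect_true(all(is.finite(v)))
    expect_true(all(v >= -1e-9))
  }
  # continuity across the a_Sp floor: 0 is clamped to 1e-6, and nearby
  # positive values give indistinguishable flows
  out_at <- function(a) {
    spx <- spongy_params(um_to_cm(58.6), a, 600, 0.5)
    mx <- build_km_matrix(spx, 0.3, 0.3)
    unlist(km_evaluate(km_solve(1000, 100, 50, 20, spx, mx), spx$l / 2))
  }
  expect_equal(out_at(0), out_at(1e-5), tolerance = 1e-4)
})

test_that("near-resonant absorption values evaluate smoothly", {
  # (a_Sp + s_Sp)/cos(beta) crossing the scattered-block eigenvalue is a
  # removable singularity; the solver must bridge it without spikes
  b <- refract(35 * pi / 180)
  a_res <- 256  # near lambda1 = lambda4 for s_Sp = 600, f = 0.5, this angle
  a_grid <- seq(a_res - 2, a_res + 2, length.out = 41)
  sp <- spongy_params(um_to_cm(58.6), a_grid, 600, 0.5)
  m <- build_km_matrix(sp, b, b)
  sol <- km_solve(rep(1000, 41), rep(100, 41), rep(50, 41), rep(0, 41), sp, m)
  js <- km_evaluate(sol, 0)$J_S
  expect_true(all(is.finite(js)))
  expect_true(all(js >= 0))
  # smooth: second differences small relative to the level
  expect_lt(max(abs(diff(js, differences = 2))), 1e-3 * max(js))
})
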