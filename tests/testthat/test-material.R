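test_that("continuity constants join the toe and linear branches smoothly", {
  for (ls in c(1.06, 1.1)) {
    cc <- continuity_constants(13, 1390, ls)
    toe <- function(l) cc["c3"] * (exp(13 * (l - 1)) - 1)
    lin <- function(l) 1390 * l + cc["c6"]
    expect_equal(unname(toe(ls)), unname(lin(ls)), tolerance = 1e-10)
    h <- 1e-7
    expect_equal(unname((toe(ls) - toe(ls - h)) / h),
                 unname((lin(ls + h) - lin(ls)) / h), tolerance = 1e-5)
  }
  # limit: lambda* -> 1+ gives c3 -> c5 / c4
  cc <- continuity_constants(13, 1390, 1 + 1e-10)
  expect_equal(unname(cc["c3"]), 1390 / 13, tolerance = 1e-6)
})

test_that("the fiber force law is zero in compression and non-decreasing", {
  mat <- material_params()
  expect_identical(fiber_response(1, mat), 0)
  expect_identical(fiber_response(0.9, mat), 0)
  l <- mat$lambda_star + 0.05
  expect_equal(fiber_response(l, mat), mat$c5 * l + mat$c6)
  grid <- seq(1, 1.5, by = 1e-3)
  expect_true(all(diff(fiber_response(grid, mat)) >= 0))
  # positive tangent stiffness beyond lambda = 1
  f <- fiber_response(grid, mat)
  expect_true(all(diff(f)[grid[-1] > 1 + 1e-3] > 0))
})

test_that("simple stress states match their textbook values", {
  mat <- material_params()
  a0 <- c(0, 0, 1)
  expect_equal(cauchy_stress(diag(3), a0, mat), matrix(0, 3, 3),
               tolerance = 1e-12)
  # rigid rotation produces no stress; superposed rotation leaves the von
  # Mises value unchanged (objectivity)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(max(abs(cauchy_stress(R, a0, mat))), 0, tolerance = 1e-10)
  F <- diag(c(0.98, 0.99, 1.05)) + matrix(c(0, 0.01, 0, 0, 0, 0.02, 0, 0, 0),
                                          3, 3)
  s1 <- cauchy_stress(F, a0, mat)
  s2 <- cauchy_stress(R %*% F, a0, mat)
  expect_equal(s2, R %*% s1 %*% t(R), tolerance = 1e-9)
  expect_equal(von_mises(s2), von_mises(s1), tolerance = 1e-9)

  expect_equal(von_mises(diag(5, 3)), 0, tolerance = 1e-12)
  expect_equal(von_mises(diag(c(7, 0, 0))), 7)
  tau <- 2.5
  sh <- matrix(c(0, tau, 0, tau, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(von_mises(sh), sqrt(3) * tau)
  expect_error(von_mises(matrix(1:9, 3, 3)), "symmetric")
  expect_error(cauchy_stress(diag(c(1, 1, -1)), a0, mat), "inverted")
})

# independent oracle: Cauchy stress from central finite differences of the
# scalar strain-energy density, sigma = (dW/dF) F^T / J
fd_cauchy <- function(F, a0, mat, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy(Fp, a0, mat) -
                  strain_energy(Fm, a0, mat)) / (2 * h)
  }
  s <- P %*% t(F) / det(F)
  (s + t(s)) / 2
}

test_that("analytic stress agrees with the strain-energy derivative", {
  mat <- material_params()
  # uniaxial stretch along the fiber
  lam <- 1.05
  F <- diag(c(1 / sqrt(lam), 1 / sqrt(lam), lam))
  s <- cauchy_stress(F, c(0, 0, 1), mat)
  expect_equal(s, fd_cauchy(F, c(0, 0, 1), mat), tolerance = 1e-5)
  # fiber contribution present and axial
  expect_gt(s[3, 3], fiber_response(lam, mat) * 0.5)

  set.seed(3)
  worst <- 0
  for (k in 1:100) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
    if (det(F) <= 0.2) next
    a0 <- rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    s <- cauchy_stress(F, a0, mat)
    sfd <- fd_cauchy(F, a0, mat)
    worst <- max(worst, max(abs(s - sfd)) / max(1, max(abs(sfd))))
  }
  expect_lt(worst, 1e-5)
})

test_that("material parameters are recoverable from noiseless uniaxial data", {
  truth <- material_params()
  # closed-form incompressible uniaxial response along the fiber
  uniax <- function(lam, c1, c4, c5) {
    cc <- continuity_constants(c4, c5, truth$lambda_star)
    f <- ifelse(lam <= 1, 0,
                ifelse(lam < truth$lambda_star,
                       cc["c3"] * (exp(c4 * (lam - 1)) - 1),
                       c5 * lam + cc["c6"]))
    c1 * (lam^2 - 1 / lam) + lam * f
  }
  lam <- seq(1.005, 1.12, length.out = 40)
  y <- uniax(lam, truth$c1, truth$c4, truth$c5)
  obj <- function(p) sum((uniax(lam, p[1], p[2], p[3]) - y)^2)
  # bounded quasi-Newton keeps the search in the admissible region
  fit <- optim(c(30, 10, 1100), obj, method = "L-BFGS-B",
               lower = c(0.1, 0.1, 1),
               control = list(factr = 10, maxit = 5000))
  est <- fit$par
  expect_lt(abs(est[1] / truth$c1 - 1), 1e-3)
  expect_lt(abs(est[2] / truth$c4 - 1), 1e-3)
  expect_lt(abs(est[3] / truth$c5 - 1), 1e-3)
})
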