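#' Continuity constants of the piecewise collagen fiber law
#'
#' The collagen fiber force term is exponential in the toe (uncrimping)
#' region and linear once fibers are straight:
#' \deqn{f(\lambda) = c_3 (e^{c_4 (\lambda - 1)} - 1), \quad 1 \le \lambda < \lambda^*}
#' \deqn{f(\lambda) = c_5 \lambda + c_6, \quad \lambda \ge \lambda^*}
#' `c3` and `c6` are not free parameters: they are fixed by requiring that
#' both the force and its slope be continuous at the transition stretch
#' \eqn{\lambda^*}:
#' \deqn{c_3 = c_5 / (c_4 e^{c_4(\lambda^*-1)}), \qquad
#'       c_6 = c_3 (e^{c_4(\lambda^*-1)} - 1) - c_5 \lambda^*.}
#'
#' @param c4 fiber uncrimping rate (dimensionless exponent), > 0.
#' @param c5 modulus of the straightened fiber, MPa, > 0.
#' @param lambda_star toe-to-linear transition stretch, > 1.
#' @return named numeric vector with components `c3` and `c6` (MPa).
#' @examples
#' continuity_constants(13, 1390, 1.06)
#' @export
continuity_constants <- function(c4, c5, lambda_star) {
  stopifnot(c4 > 0, c5 > 0, lambda_star > 1)
  e <- exp(c4 * (lambda_star - 1))
  c3 <- c5 / (c4 * e)
  c6 <- c3 * (e - 1) - c5 * lambda_star
  c(c3 = c3, c6 = c6)
}

#' Tendon material parameters
#'
#' Transversely isotropic hyperelastic tendon material: isotropic
#' nearly-incompressible neo-Hookean ground substance with shear modulus
#' `c1`, plus a one-dimensional collagen fiber family with the piecewise
#' exponential/linear force law of [continuity_constants()], plus a
#' volumetric penalty with modulus `kappa`. Defaults are the in vivo
#' estimates used throughout the package's experiments: ground substance
#' stiffness 40 MPa, fiber uncrimping rate 13, straightened-fiber modulus
#' 1390 MPa. The transition stretch `lambda_star` is not reported alongside
#' those values; 1.06 (6% uncrimping stretch, a typical tendon toe length)
#' is the package default.
#'
#' @param c1 ground substance stiffness (neo-Hookean shear modulus), MPa.
#' @param c4 collagen fiber uncrimping rate, dimensionless.
#' @param c5 modulus of the straightened fiber, MPa.
#' @param lambda_star toe-to-linear transition stretch.
#' @param kappa volumetric penalty modulus, MPa; default `100 * c1`
#'   enforces near-incompressibility (effective Poisson ratio ~ 0.495)
#'   while keeping the penalty's geometric stiffness from destabilizing
#'   the quasi-static solve.
#' @return object of class `tendon_material`: a list with the five inputs
#'   plus the derived continuity constants `c3` and `c6`.
#' @examples
#' mat <- material_params()
#' mat$c3
#' @export
material_params <- function(c1 = 40, c4 = 13, c5 = 1390, lambda_star = 1.06,
                            kappa = 100 * c1) {
  stopifnot(c1 > 0, c4 > 0, c5 > 0, kappa > 0, lambda_star > 1)
  cc <- continuity_constants(c4, c5, lambda_star)
  structure(list(c1 = c1, c4 = c4, c5 = c5, lambda_star = lambda_star,
                 kappa = kappa, c3 = unname(cc["c3"]), c6 = unname(cc["c6"])),
            class = "tendon_material")
}

#' @export
print.tendon_material <- function(x, ...) {
  cat("Transversely isotropic hyperelastic tendon material\n")
  cat(sprintf("  ground substance shear modulus c1: %g MPa\n", x$c1))
  cat(sprintf("  fiber uncrimping rate c4:          %g\n", x$c4))
  cat(sprintf("  straightened fiber modulus c5:     %g MPa\n", x$c5))
  cat(sprintf("  transition stretch lambda*:        %g\n", x$lambda_star))
  cat(sprintf("  volumetric penalty kappa:          %g MPa\n", x$kappa))
  cat(sprintf("  derived continuity constants:      c3 = %.6g, c6 = %.6g MPa\n",
              x$c3, x$c6))
  invisible(x)
}

# flat numeric vector handed to the C++ kernels
material_vector <- function(mat) {
  c(mat$c1, mat$c4, mat$c5, mat$lambda_star, mat$c3, mat$c6, mat$kappa)
}

#' Collagen fiber force term
#'
#' Scalar fiber force `f(lambda)` (MPa): zero for `lambda <= 1` (fibers
#' carry no compression), exponential toe region on `[1, lambda_star)`,
#' linear beyond. Continuous with continuous slope at the transition.
#'
#' @param lambda fiber stretch(es), > 0; vectorized.
#' @param params a [material_params()] object.
#' @return numeric vector of fiber force values, MPa.
#' @export
fiber_response <- function(lambda, params) {
  stopifnot(all(lambda > 0))
  out <- numeric(length(lambda))
  toe <- lambda > 1 & lambda < params$lambda_star
  lin <- lambda >= params$lambda_star
  out[toe] <- params$c3 * (exp(params$c4 * (lambda[toe] - 1)) - 1)
  out[lin] <- params$c5 * lambda[lin] + params$c6
  out
}

# Fiber strain energy W_f(lambda): integral of fiber_response from 1.
fiber_energy <- function(lambda, params) {
  c3 <- params$c3; c4 <- params$c4; c5 <- params$c5; c6 <- params$c6
  ls <- params$lambda_star
  toe_part <- function(l) c3 * ((exp(c4 * (l - 1)) - 1) / c4 - (l - 1))
  out <- numeric(length(lambda))
  toe <- lambda > 1 & lambda < ls
  lin <- lambda >= ls
  out[toe] <- toe_part(lambda[toe])
  out[lin] <- toe_part(ls) +
    c5 / 2 * (lambda[lin]^2 - ls^2) + c6 * (lambda[lin] - ls)
  out
}

#' Strain energy density
#'
#' \deqn{W(F) = \frac{c_1}{2}(J^{-2/3} I_1 - 3) + W_f(\lambda) +
#'       \frac{\kappa}{2}(J-1)^2}
#' with \eqn{I_1 = F:F}, \eqn{J = \det F} and fiber stretch
#' \eqn{\lambda = |F a_0|}.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param a0 unit reference fiber direction.
#' @param params a [material_params()] object.
#' @return scalar energy density, MPa.
#' @export
strain_energy <- function(F, a0, params) {
  J <- det(F)
  if (J <= 0) stop("inverted deformation state: det(F) = ", J)
  I1 <- sum(F^2)
  lam <- sqrt(sum((F %*% a0)^2))
  params$c1 / 2 * (J^(-2 / 3) * I1 - 3) +
    fiber_energy(lam, params) +
    params$kappa / 2 * (J - 1)^2
}

#' Cauchy stress of the tendon material
#'
#' Analytic Cauchy stress obtained by differentiating [strain_energy()]
#' with respect to the deformation gradient: the sum of (i) an isochoric
#' neo-Hookean ground substance term, (ii) a rank-one fiber term
#' \eqn{\lambda f(\lambda)/J \; a \otimes a} along the deformed fiber
#' direction \eqn{a = F a_0 / \lambda}, and (iii) a spherical volumetric
#' penalty \eqn{\kappa (J-1) I}.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param a0 unit reference fiber direction.
#' @param params a [material_params()] object.
#' @return symmetric 3x3 Cauchy stress tensor, MPa.
#' @export
cauchy_stress <- function(F, a0, params) {
  J <- det(F)
  if (J <= 0) stop("inverted deformation state: det(F) = ", J)
  FinvT <- t(solve(F))
  I1 <- sum(F^2)
  P <- params$c1 * J^(-2 / 3) * (F - I1 / 3 * FinvT)
  m <- drop(F %*% a0)
  lam <- sqrt(sum(m^2))
  if (lam > 1) {
    P <- P + (fiber_response(lam, params) / lam) * (m %o% a0)
  }
  P <- P + params$kappa * (J - 1) * J * FinvT
  sig <- P %*% t(F) / J
  (sig + t(sig)) / 2
}

#' Von Mises equivalent stress
#'
#' \eqn{\sqrt{3/2 \; \mathrm{dev}(\sigma) : \mathrm{dev}(\sigma)}};
#' invariant to rotations and to added hydrostatic pressure.
#'
#' @param sigma symmetric 3x3 stress tensor, MPa.
#' @return scalar, MPa.
#' @export
von_mises <- function(sigma) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == 3))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("stress tensor is not symmetric")
  dev <- sigma - diag(mean(diag(sigma)), 3)
  sqrt(3 / 2 * sum(dev^2))
}
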