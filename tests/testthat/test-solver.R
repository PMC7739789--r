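test_that("zero load produces zero displacement and zero reaction", {
  mesh <- box_mesh(c(2, 2, 4), c(1, 1, 2))
  res <- solve_fe(mesh, axial_fibers(mesh), material_params(),
                  boundary_conditions(fixed = list(distal_fixed = 1:3),
                                      n_increments = 1))
  expect_equal(max(abs(res$u)), 0)
  expect_equal(res$reaction_fixed, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(max(res$von_mises), 0, tolerance = 1e-10)
})

test_that("single-element patch test reproduces the homogeneous stress state", {
  mesh <- box_mesh(c(1, 1, 1), c(1, 1, 1))
  mat <- material_params()
  lam <- 1.04
  # bottom held axially, top displaced axially, rigid modes pinned; lateral
  # contraction left free so the state is homogeneous uniaxial stretch
  bcs <- boundary_conditions(
    fixed = list(distal_fixed = 3),
    prescribed = list(set = "proximal", comp = 3, value = -(lam - 1)),
    extra_fixed = cbind(c(7, 7, 8, 5), c(1, 2, 2, 1)),
    n_increments = 4)
  res <- solve_fe(mesh, axial_fibers(mesh), mat, bcs)
  # strain field is homogeneous: recover F from the Green-Lagrange tensor
  E <- res$strain[1, ]
  expect_equal(unname(E[4:6]), c(0, 0, 0), tolerance = 1e-10)
  F <- diag(sqrt(2 * E[1:3] + 1))
  expect_equal(unname(F[3, 3]), lam, tolerance = 1e-10)
  sig <- cauchy_stress(F, c(0, 0, 1), mat)
  got <- res$cauchy[1, ]
  expect_equal(got[1:3], diag(sig), tolerance = 1e-8)
  expect_equal(got[4:6], c(0, 0, 0), tolerance = 1e-8)
  expect_equal(res$von_mises[1], von_mises(sig), tolerance = 1e-8)
  # lateral stress relieved by the free faces
  expect_lt(abs(sig[1, 1]), 1e-6 * abs(sig[3, 3]))
})

test_that("Newton iterations contract superlinearly near the solution", {
  mesh <- box_mesh(c(1, 1, 1), c(1, 1, 1))
  bcs <- boundary_conditions(
    fixed = list(distal_fixed = 3),
    prescribed = list(set = "proximal", comp = 3, value = -0.04),
    extra_fixed = cbind(c(7, 7, 8, 5), c(1, 2, 2, 1)),
    n_increments = 2)
  res <- solve_fe(mesh, axial_fibers(mesh), material_params(), bcs,
                  solve_settings(tol = 1e-10))
  rn <- res$resnorm_history[[2]]
  expect_gte(length(rn), 3)
  # each late-stage step at least squares-then-some the residual scale
  tail_rn <- rn[rn > 0]
  ratios <- tail_rn[-1] / tail_rn[-length(tail_rn)]
  expect_lt(min(ratios), 1e-3)
  expect_lt(tail_rn[length(tail_rn)], 1e-8 * tail_rn[1])
})

test_that("distributed tractions are balanced exactly by the fixed-set reaction", {
  mesh <- coarse_mesh()
  fib <- build_fiber_field(mesh, 30)
  bcs <- boundary_conditions(fixed = list(distal_fixed = 1:3),
                             tractions = c(proximal = 100),
                             n_increments = 4)
  res <- solve_fe(mesh, fib, material_params(), bcs)
  expect_equal(res$applied_force[3], -100, tolerance = 1e-9)
  expect_equal(abs(res$reaction_fixed[3]), 100, tolerance = 1e-3 * 100)
  expect_equal(sqrt(sum(res$reaction_fixed[1:2]^2)), 0,
               tolerance = 1e-3 * 100)
})

test_that("solutions are objective under a rigid rotation of the problem", {
  mesh <- coarse_mesh()
  fib <- build_fiber_field(mesh, 30)
  mat <- material_params()
  bcs <- boundary_conditions(fixed = list(distal_fixed = 1:3),
                             tractions = c(proximal = 60),
                             n_increments = 4)
  res <- solve_fe(mesh, fib, mat, bcs)

  th <- pi / 2                       # rotate everything 90 deg about x
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  fib_r <- fib
  fib_r$directions <- fib$directions %*% t(R)
  bcs_r <- boundary_conditions(fixed = list(distal_fixed = 1:3),
                               tractions = c(proximal = 60),
                               traction_direction = drop(R %*% c(0, 0, -1)),
                               n_increments = 4)
  res_r <- solve_fe(mesh_r, fib_r, mat, bcs_r)
  expect_equal(res_r$u, res$u %*% t(R), tolerance = 1e-7)
  expect_equal(res_r$von_mises, res$von_mises, tolerance = 1e-7)
})

test_that("tip displacement of a soft cantilever converges under refinement", {
  mat <- material_params(c1 = 10, c5 = 50, kappa = 200)
  tip <- vapply(list(c(1, 1, 4), c(2, 2, 8), c(3, 3, 12)), function(n) {
    mesh <- box_mesh(c(4, 4, 24), n)
    bcs <- boundary_conditions(fixed = list(distal_fixed = 1:3),
                               tractions = c(proximal = 2),
                               traction_direction = c(1, 0, 0),
                               n_increments = 4)
    res <- solve_fe(mesh, axial_fibers(mesh), mat, bcs)
    max(res$u[, 1])
  }, numeric(1))
  # trilinear elements soften monotonically toward the converged deflection
  expect_true(all(diff(tip) > 0))
  expect_lt(tip[3] - tip[2], tip[2] - tip[1])
})

test_that("tied contact moves paired nodes together; frictionless allows slip", {
  mesh <- build_sliding_mesh(geometry_params(), c(4, 6))
  fib <- build_fiber_field(mesh, 30)
  mat <- material_params()
  act <- list(activity = "toy", soleus_N = 400, gastroc_N = 100)

  tied <- run_activity(mesh, fib, mat, act, "tied", n_increments = 5)
  pr <- mesh$interface$pairs
  rel <- tied$result$u[pr[, 1], ] - tied$result$u[pr[, 2], ]
  expect_equal(max(abs(rel)), 0, tolerance = 1e-12)

  fr <- run_activity(mesh, fib, mat, act, "frictionless", n_increments = 5)
  expect_gt(fr$sliding_mm, 0.05)
  # penalty keeps the normal gap far smaller than the tangential slip
  expect_lt(fr$max_normal_gap_mm, 0.2 * fr$sliding_mm)
})

test_that("a mirror-symmetric two-subtendon model under equal loads barely slides", {
  p <- geometry_params(centerline_ml_offset = 0, partition_twist_total = 0,
                       partition_fractions = c(SOL = 0.5, MG = 0.25,
                                               LG = 0.25))
  mesh <- build_sliding_mesh(p, c(4, 6))
  fib <- build_fiber_field(mesh, 0)
  act <- list(activity = "sym", soleus_N = 300, gastroc_N = 300)
  m <- run_activity(mesh, fib, material_params(), act, "frictionless",
                    n_increments = 5)
  expect_lt(m$sliding_mm, 0.02)
  expect_lt(m$differential_lengthening_mm, 0.02)
})

test_that("interface conditions validate their inputs", {
  mesh <- coarse_mesh()
  expect_error(apply_interface_condition(mesh, "tied"), "split_interface")
  sm <- build_sliding_mesh(geometry_params(), c(4, 6))
  ic <- apply_interface_condition(sm, "tied")
  expect_identical(ic$condition, "tied")
  expect_identical(sum(ic$fold != seq_along(ic$fold)),
                   3L * nrow(sm$interface$pairs))
})
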