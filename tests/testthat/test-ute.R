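test_that("echo simulation follows the mono-exponential decay law exactly", {
  ph <- tissue_phantom(n = 48)
  e0 <- simulate_echo(ph, 0)
  S0 <- setNames(ph$tissues$S0, ph$tissues$tissue)
  expect_equal(e0$signal, matrix(S0[ph$labels], 48, 48), tolerance = 1e-15)

  # closed-form voxel values (scalar exponential oracle)
  e <- simulate_echo(ph, 2.54)
  tendon <- ph$labels == "tendon"
  muscle <- ph$labels == "muscle"
  expect_equal(unique(e$signal[tendon]), 1 * exp(-2.54 / 1),
               tolerance = 1e-12)
  expect_equal(unique(e$signal[muscle]), 1 * exp(-2.54 / 30),
               tolerance = 1e-12)
  expect_true(all(e$signal[ph$labels == "background"] == 0))

  # enormous T2*: signal ~ S0 at any TE
  ph2 <- tissue_phantom(matrix("muscle", 2, 2),
                        tissues = data.frame(tissue = "muscle", S0 = 3,
                                             T2star_ms = 1e12))
  expect_equal(simulate_echo(ph2, 50)$signal, matrix(3, 2, 2),
               tolerance = 1e-9)

  # strictly decreasing in TE for finite T2*
  tes <- seq(0, 5, by = 0.25)
  sig <- vapply(tes, function(te) simulate_echo(ph, te)$signal[tendon][1],
                numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("dual-echo subtraction matches its closed forms and boosts tendon contrast", {
  ph <- tissue_phantom(n = 48)
  sp <- sequence_params()
  e1 <- simulate_echo(ph, sp$TE1)
  e2 <- simulate_echo(ph, sp$TE2)
  d <- subtract_echoes(e1, e2)
  tendon <- ph$labels == "tendon"; muscle <- ph$labels == "muscle"
  expect_equal(unique(d$signal[tendon]),
               exp(-0.08 / 1) - exp(-2.54 / 1), tolerance = 1e-12)
  expect_equal(unique(d$signal[muscle]),
               exp(-0.08 / 30) - exp(-2.54 / 30), tolerance = 1e-12)
  expect_lt(unique(d$signal[muscle]), 0.1)

  expect_equal(subtract_echoes(e1, simulate_echo(ph, sp$TE1 + 1e-9))$signal,
               matrix(0, 48, 48), tolerance = 1e-8)
  expect_error(subtract_echoes(e2, e1), "longer echo time")
  small <- simulate_echo(tissue_phantom(n = 24), sp$TE2)
  expect_error(subtract_echoes(e1, small), "different grids")

  # subtraction inverts the tendon-muscle contrast from strongly negative
  # (tendon dark at the long echo is not even needed: at TE1 muscle ~ S0)
  c_ute <- echo_contrast(e1, ph)
  c_sub <- echo_contrast(d, ph)
  expect_gt(c_sub, c_ute)
  expect_gt(c_sub, 0.5)

  # linearity: subtract(aX, aY) = a subtract(X, Y)
  ea <- e1; ea$signal <- 3 * e1$signal
  eb <- e2; eb$signal <- 3 * e2$signal
  expect_equal(subtract_echoes(ea, eb)$signal, 3 * d$signal,
               tolerance = 1e-12)
})

test_that("region contrast matches hand arithmetic on a toy grid", {
  lab <- matrix(c("a", "a", "b"), 1, 3)
  ph <- tissue_phantom(lab, tissues = data.frame(tissue = c("a", "b"),
                                                 S0 = c(2, 1),
                                                 T2star_ms = c(10, 10)))
  img <- simulate_echo(ph, 0)
  expect_equal(echo_contrast(img, ph, "a", "b"), (2 - 1) / (2 + 1))
  expect_equal(echo_contrast(img, ph, "a", "a"), 0)
  expect_error(echo_contrast(img, ph, "a", "missing"), "empty region|missing")
})

test_that("noise is reproducible under a fixed seed", {
  ph <- tissue_phantom(n = 32)
  a <- simulate_echo(ph, 1, noise_sd = 0.05, seed = 99)
  b <- simulate_echo(ph, 1, noise_sd = 0.05, seed = 99)
  expect_identical(a$signal, b$signal)
  c <- simulate_echo(ph, 1, noise_sd = 0.05, seed = 100)
  expect_false(identical(a$signal, c$signal))
})

test_that("the TE2 sweep peaks and then loses tendon-muscle contrast", {
  ph <- tissue_phantom(n = 48)
  grid <- c(0.5, 1, 2, 2.54, 4, 8, 16, 40, 120)
  sw <- te2_sweep(ph, grid)
  expect_identical(sw$TE2_ms, grid)
  k <- which.max(sw$contrast)
  expect_lt(k, nrow(sw))
  # eventually decreasing beyond the maximum
  expect_true(all(diff(sw$contrast[k:nrow(sw)]) <= 0))
  # very long TE2 approaches the UTE-vs-proton-density limit, below optimum
  expect_lt(sw$contrast[nrow(sw)], sw$contrast[k])

  # the location of the maximum is stable under grid refinement
  dense <- te2_sweep(ph, seq(0.3, 20, by = 0.1))
  coarse <- te2_sweep(ph, seq(0.3, 20, by = 0.4))
  expect_lt(abs(dense$TE2_ms[which.max(dense$contrast)] -
                  coarse$TE2_ms[which.max(coarse$contrast)]), 0.5)
})

test_that("sequence parameter validation enforces TE ordering", {
  expect_error(sequence_params(TE1 = 2, TE2 = 1))
  sp <- sequence_params()
  expect_equal(c(sp$TE1, sp$TE2, sp$TR, sp$flip, sp$resolution),
               c(0.08, 2.54, 6, 10, 0.8))
})
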