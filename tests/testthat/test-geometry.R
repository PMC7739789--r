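test_that("partition twist is linear over the free tendon and frozen in the insertion", {
  p <- geometry_params()
  expect_identical(partition_twist_angle(0, p), 0)
  expect_identical(partition_twist_angle(1, p), 90)
  expect_equal(partition_twist_angle(0.5, p), 45)
  expect_equal(partition_twist_angle(1.3, p), 90)
  expect_error(partition_twist_angle(-0.1, p), "non-negative")
  # monotone non-decreasing
  s <- seq(0, 2, by = 0.01)
  expect_true(all(diff(partition_twist_angle(s, p)) >= 0))
  # scales with the configured total
  p2 <- geometry_params(partition_twist_total = 60)
  expect_equal(partition_twist_angle(0.5, p2), 30)
})

test_that("geometry parameter validation enforces the documented invariants", {
  expect_error(geometry_params(partition_fractions =
                                 c(SOL = 0.5, MG = 0.3, LG = 0.3)),
               "sum to 1")
  expect_error(geometry_params(partition_fractions =
                                 c(SOL = 0.2, MG = 0.6, LG = 0.2)),
               "largest")
  expect_error(geometry_params(mean_csa = -1))
})

test_that("generated meshes are valid and match the requested cross-section area", {
  mesh <- coarse_mesh()
  jac <- subtendon:::hex_corner_jacobians_cpp(mesh$nodes, mesh$elems)
  expect_true(all(jac > 0))
  expect_setequal(names(mesh$face_sets), c("proximal", "distal_fixed"))
  # integrated mid-tendon section area within 2% of the requested CSA
  mid <- floor(mesh$nz / 2) + 1L
  expect_equal(layer_area_oracle(mesh, mid), 70, tolerance = 0.02)
  # custom CSA honored too
  m2 <- generate_mesh(geometry_params(mean_csa = 55), c(6, 6))
  expect_equal(layer_area_oracle(m2, 3), 55, tolerance = 0.02)
  # centerline bowed medially by the configured offset at mid-length
  L <- mesh$params$free_tendon_length + mesh$params$insertion_length
  expect_equal(subtendon:::centerline_offset(L / 2, mesh$params), 4)
  expect_error(generate_mesh(geometry_params(), c(1, 4)), "at least 2")
})

test_that("doubling resolution in all dimensions multiplies element count by 8", {
  n1 <- nrow(generate_mesh(geometry_params(), c(4, 6))$elems)
  n2 <- nrow(generate_mesh(geometry_params(), c(8, 12))$elems)
  expect_identical(n2, 8L * n1)
})

test_that("subtendon labels follow the anatomical sectors and the twist", {
  p <- geometry_params()
  mesh <- assign_subtendons(generate_mesh(p, c(6, 12)), p, 3)
  expect_true(all(mesh$element_labels %in% c("SOL", "MG", "LG")))
  cent <- subtendon:::element_centroids(mesh)
  first <- cent[, 3] < mesh$z_layers[2]          # proximal slice
  # LG postero-lateral, MG postero-medial, SOL anterior at the proximal end
  lg <- first & mesh$element_labels == "LG"
  mg <- first & mesh$element_labels == "MG"
  sol <- first & mesh$element_labels == "SOL"
  expect_true(mean(cent[lg, 1]) < 0 && mean(cent[lg, 2]) < 0)
  expect_true(mean(cent[mg, 1]) > 0 && mean(cent[mg, 2]) < 0)
  expect_true(mean(cent[sol, 2]) > 0)
  # at the distal free tendon the MG sector has rotated toward lateral
  distal <- cent[, 3] > p$free_tendon_length - 6 &
    cent[, 3] < p$free_tendon_length
  mg_d <- distal & mesh$element_labels == "MG"
  expect_true(mean(cent[mg_d, 1]) < mean(cent[mg, 1]))

  # partition is exhaustive and exclusive; per-slice label areas track the
  # fractions to within about the largest element's section area
  expect_false(anyNA(mesh$element_labels))
  el_area <- vapply(seq_len(nrow(mesh$elems)), function(e) {
    q <- mesh$nodes[mesh$elems[e, 1:4], 1:2]
    0.5 * abs(sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2]))
  }, numeric(1))
  for (k in c(1, 4, 8)) {
    slice <- cent[, 3] > mesh$z_layers[k] & cent[, 3] < mesh$z_layers[k + 1]
    areas <- vapply(c("SOL", "MG", "LG"), function(lv)
      sum(el_area[slice & mesh$element_labels == lv]), numeric(1))
    expect_equal(sum(areas), 70, tolerance = 1e-10)  # exhaustive partition
    expect_true(all(abs(areas - 70 * p$partition_fractions) <
                      1.5 * max(el_area[slice])))
  }
})

test_that("two-subtendon partition merges both gastrocnemius sectors", {
  p <- geometry_params()
  mesh3 <- assign_subtendons(generate_mesh(p, c(4, 6)), p, 3)
  mesh2 <- assign_subtendons(generate_mesh(p, c(4, 6)), p, 2)
  expect_setequal(unique(mesh2$element_labels), c("SOL", "GAS"))
  expect_identical(mesh2$element_labels == "SOL",
                   mesh3$element_labels == "SOL")
})

test_that("interface splitting produces coincident pairs with sane normals", {
  mesh <- build_sliding_mesh(geometry_params(), c(4, 8))
  pr <- mesh$interface$pairs
  expect_gt(nrow(pr), 10)
  gap <- mesh$nodes[pr[, 1], ] - mesh$nodes[pr[, 2], ]
  expect_lt(max(abs(gap)), 1e-9)
  # unit normals, mostly in-plane (the partition surface is near-radial)
  nn <- mesh$interface$normals
  expect_equal(sqrt(rowSums(nn^2)), rep(1, nrow(nn)), tolerance = 1e-12)
  expect_gt(mean(sqrt(nn[, 1]^2 + nn[, 2]^2)), 0.9)
  expect_true(all(mesh$interface$areas >= 0))
  # the two bodies share no nodes after the split
  sol_n <- unique(as.vector(mesh$elems[mesh$element_labels == "SOL", ]))
  gas_n <- unique(as.vector(mesh$elems[mesh$element_labels == "GAS", ]))
  expect_length(intersect(sol_n, gas_n), 0)
})

test_that("population sampling is reproducible and statistically sound", {
  p <- geometry_params()
  same <- sample_population(p, c(mean_csa = 0), 3, seed = 7)
  expect_identical(same[[1]], p)
  expect_identical(same[[3]], p)

  a <- sample_population(p, c(mean_csa = 10, free_tendon_length = 5), 5,
                         seed = 42)
  b <- sample_population(p, c(mean_csa = 10, free_tendon_length = 5), 5,
                         seed = 42)
  expect_identical(a, b)
  expect_error(sample_population(p, c(nope = 1), 2, 1), "unknown fields")

  # law of large numbers: sample mean of CSA within 2% of the mean
  big <- sample_population(p, c(mean_csa = 10), 10000, seed = 1)
  csa <- vapply(big, `[[`, numeric(1), "mean_csa")
  expect_equal(mean(csa), 70, tolerance = 0.02)
  expect_true(all(csa > 0 & abs(csa - 70) <= 30))
})

test_that("geometry config files round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("free_tendon_length: 55", "mean_csa: 62",
               "partition_fractions:", "  SOL: 0.5", "  MG: 0.3",
               "  LG: 0.2", "side: left"), f)
  p <- read_geometry_config(f)
  expect_s3_class(p, "geometry_params")
  expect_equal(p$free_tendon_length, 55)
  expect_equal(p$mean_csa, 62)
  expect_identical(p$side, "left")
})

test_that("VTK export writes a readable unstructured grid", {
  p <- geometry_params()
  mesh <- assign_subtendons(generate_mesh(p, c(4, 6)), p, 3)
  fib <- build_fiber_field(mesh, 30)
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, f, cell_data = list(fiber = fib$directions))
  txt <- readLines(f)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", txt)))
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(mesh$nodes)), txt)))
  expect_true(any(grepl("VECTORS fiber double", txt)))
  expect_true(any(grepl("SCALARS subtendon double", txt)))
})
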