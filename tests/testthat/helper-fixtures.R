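# Shared fixtures, built once per test run.

# small production-style tendon mesh
coarse_mesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- generate_mesh(geometry_params(), c(4, 8))
    m
  }
})

# straight (unbowed) tendon for symmetry checks
straight_params <- function(...) {
  geometry_params(centerline_ml_offset = 0, ...)
}

# axis-aligned box mesh (single body) for patch and beam tests:
# lx x ly x lz mm, n = c(nx, ny, nz) elements; face sets proximal (z = 0)
# and distal_fixed (z = lz) as in generate_mesh().
box_mesh <- function(l = c(1, 1, 1), n = c(1, 1, 1)) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(0, l[1], length.out = nx + 1)
  ys <- seq(0, l[2], length.out = ny + 1)
  zs <- seq(0, l[3], length.out = nz + 1)
  g <- expand.grid(x = xs, y = ys, z = zs)
  nodes <- as.matrix(g)
  dimnames(nodes) <- NULL
  nid <- function(i, j, k)
    (k - 1) * (nx + 1) * (ny + 1) + (j - 1) * (nx + 1) + i
  elems <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                    nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  quad_layer <- function(k) {
    q <- matrix(0L, nx * ny, 4)
    e <- 0L
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      e <- e + 1L
      q[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                  nid(i, j + 1, k))
    }
    q
  }
  structure(list(nodes = nodes, elems = elems,
                 face_sets = list(proximal = quad_layer(1L),
                                  distal_fixed = quad_layer(nz + 1L)),
                 s = nodes[, 3] / l[3],
                 params = geometry_params(free_tendon_length = l[3],
                                          insertion_length = 1e-6,
                                          centerline_ml_offset = 0),
                 nxy = nx, nz = nz, z_layers = zs,
                 element_labels = NULL, interface = NULL),
            class = "tendon_mesh")
}

# axial fiber field for a box mesh
axial_fibers <- function(mesh) {
  structure(list(alpha = 0,
                 directions = matrix(rep(c(0, 0, 1), each = nrow(mesh$elems)),
                                     ncol = 3),
                 side = "right"),
            class = "fiber_field")
}

# independent polygon-area oracle (shoelace) for one node layer of a mesh
layer_area_oracle <- function(mesh, layer = 1L) {
  nxy <- mesh$nxy
  npl <- (nxy + 1)^2
  xy <- mesh$nodes[(layer - 1) * npl + seq_len(npl), 1:2]
  nid <- function(i, j) (j - 1) * (nxy + 1) + i
  shoelace <- function(p) 0.5 * abs(sum(p[, 1] * p[c(2:4, 1), 2] -
                                          p[c(2:4, 1), 1] * p[, 2]))
  a <- 0
  for (j in seq_len(nxy)) for (i in seq_len(nxy))
    a <- a + shoelace(xy[c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1),
                           nid(i, j + 1)), ])
  a
}
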