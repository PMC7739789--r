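#' Idealized tendon geometry parameters
#'
#' Parametric description of an idealized human Achilles tendon: an
#' elliptical-section free tendon plus calcaneal insertion segment, with a
#' configurable mediolateral bow of the centerline (the medial/lateral
#' asymmetry that makes fascicle twist mechanically relevant) and a
#' subtendon partition that twists 90 degrees across the free tendon and
#' runs straight through the insertion.
#'
#' Coordinate convention: `+z` proximal to distal, `+x` lateral to medial
#' (for a right tendon), `+y` posterior to anterior. The ellipse aspect
#' ratio follows `ap_diameter`/`ml_diameter`, and the semi-axes are scaled
#' so the cross-sectional area equals `mean_csa` exactly.
#'
#' @param free_tendon_length length of the free tendon, mm.
#' @param insertion_length length of the calcaneal insertion segment, mm.
#' @param mean_csa cross-sectional area, mm^2.
#' @param ap_diameter anterior-posterior diameter, mm (sets aspect ratio).
#' @param ml_diameter medial-lateral diameter, mm (sets aspect ratio).
#' @param centerline_ml_offset medial bow of the centerline at mid-length,
#'   mm. Zero gives a straight, mirror-symmetric tendon.
#' @param partition_fractions named fractions of the cross-section occupied
#'   by the soleus (SOL), medial (MG) and lateral (LG) gastrocnemius
#'   subtendons; must sum to 1 with SOL largest.
#' @param partition_twist_total total internal rotation of the subtendon
#'   partition across the free tendon, degrees.
#' @param side `"right"` or `"left"`; sets the chirality of the internal
#'   rotation.
#' @return object of class `geometry_params`.
#' @examples
#' geometry_params()
#' @export
geometry_params <- function(free_tendon_length = 60,
                            insertion_length = 20,
                            mean_csa = 70,
                            ap_diameter = 6,
                            ml_diameter = 15,
                            centerline_ml_offset = 4,
                            partition_fractions = c(SOL = 0.52, MG = 0.28,
                                                    LG = 0.20),
                            partition_twist_total = 90,
                            side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(free_tendon_length > 0, insertion_length > 0, mean_csa > 0,
            ap_diameter > 0, ml_diameter > 0, partition_twist_total >= 0)
  f <- partition_fractions
  if (!setequal(names(f), c("SOL", "MG", "LG")))
    stop("partition_fractions must be named SOL, MG, LG")
  f <- f[c("SOL", "MG", "LG")]
  if (any(f <= 0) || any(f >= 1) || abs(sum(f) - 1) > 1e-12)
    stop("partition fractions must lie in (0,1) and sum to 1")
  if (f["SOL"] < max(f))
    stop("the soleus subtendon must be the largest of the three")
  structure(list(free_tendon_length = free_tendon_length,
                 insertion_length = insertion_length,
                 mean_csa = mean_csa,
                 ap_diameter = ap_diameter,
                 ml_diameter = ml_diameter,
                 centerline_ml_offset = centerline_ml_offset,
                 partition_fractions = f,
                 partition_twist_total = partition_twist_total,
                 side = side),
            class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Idealized Achilles tendon geometry (", x$side, ")\n", sep = "")
  cat(sprintf("  free tendon %g mm + insertion %g mm, CSA %g mm^2 (AP %g / ML %g mm)\n",
              x$free_tendon_length, x$insertion_length, x$mean_csa,
              x$ap_diameter, x$ml_diameter))
  cat(sprintf("  medial centerline bow %g mm; partition twist %g deg\n",
              x$centerline_ml_offset, x$partition_twist_total))
  cat(sprintf("  partition fractions SOL/MG/LG: %.2f/%.2f/%.2f\n",
              x$partition_fractions["SOL"], x$partition_fractions["MG"],
              x$partition_fractions["LG"]))
  invisible(x)
}

#' Read geometry parameters from a YAML configuration file
#'
#' Keys mirror the arguments of [geometry_params()];
#' `partition_fractions` may be given as a named map.
#'
#' @param file path to a YAML file.
#' @return a `geometry_params` object.
#' @export
read_geometry_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$partition_fractions))
    cfg$partition_fractions <- unlist(cfg$partition_fractions)
  do.call(geometry_params, cfg)
}

#' Subtendon partition twist angle
#'
#' Rotation of the subtendon cutting planes at normalized axial coordinate
#' `s` (0 at the proximal free tendon, 1 at the distal free tendon, > 1 in
#' the calcaneal insertion). Linear across the free tendon, reaching the
#' total twist (default 90 degrees) at `s = 1`, and constant through the
#' insertion where subtendons fuse with the calcaneus.
#'
#' @param s normalized axial coordinate(s), >= 0; vectorized.
#' @param params a [geometry_params()] object.
#' @return twist angle(s), degrees.
#' @examples
#' partition_twist_angle(c(0, 0.5, 1, 1.3), geometry_params())
#' @export
partition_twist_angle <- function(s, params) {
  if (any(s < 0)) stop("axial coordinate s must be non-negative")
  params$partition_twist_total * pmin(s, 1)
}

# mediolateral centerline offset at axial position z (mm)
centerline_offset <- function(z, params) {
  L <- params$free_tendon_length + params$insertion_length
  zeta <- z / L
  params$centerline_ml_offset * 4 * zeta * (1 - zeta)
}

centerline_slope <- function(z, params) {
  L <- params$free_tendon_length + params$insertion_length
  params$centerline_ml_offset * 4 * (1 - 2 * z / L) / L
}

#' Generate an idealized hexahedral tendon mesh
#'
#' Builds a structured all-hexahedral mesh of an elliptical-section tendon:
#' the unit square is mapped smoothly onto the ellipse (elliptical grid
#' mapping), extruded along `z` over the free tendon and insertion, with
#' the section centroid following the bowed centerline. Face sets
#' `proximal` (z = 0) and `distal_fixed` (z = max) are created; label- and
#' interface-dependent sets are added by [assign_subtendons()] and
#' [split_interface()].
#'
#' @param params a [geometry_params()] object.
#' @param resolution either a single integer (elements per section
#'   dimension, with a proportional axial count) or `c(nxy, nz)`:
#'   `nxy` x `nxy` elements per cross-section and `nz` axial layers.
#'   Both must be >= 2.
#' @return object of class `tendon_mesh`: list with `nodes` (N x 3, mm),
#'   `elems` (E x 8 node indices, VTK hexahedron ordering), `face_sets`
#'   (lists of 4-column node-quad matrices), `s` (normalized axial
#'   coordinate per node), `params`, and bookkeeping fields.
#' @examples
#' mesh <- generate_mesh(geometry_params(), resolution = c(4, 8))
#' mesh
#' @export
generate_mesh <- function(params, resolution = c(6, 14)) {
  if (length(resolution) == 1) {
    L <- params$free_tendon_length + params$insertion_length
    d <- sqrt(4 * params$mean_csa / pi)
    resolution <- c(resolution, max(2L, round(resolution * L / d)))
  }
  nxy <- as.integer(resolution[1]); nz <- as.integer(resolution[2])
  if (nxy < 2 || nz < 2) stop("resolution must be at least 2 per dimension")
  Lf <- params$free_tendon_length; Li <- params$insertion_length
  # axial layers: split proportionally, with a layer boundary exactly at the
  # free-tendon / insertion junction
  nz_free <- max(1L, round(nz * Lf / (Lf + Li)))
  nz_free <- min(nz_free, nz - 1L)
  nz_ins <- nz - nz_free
  z_layers <- c(seq(0, Lf, length.out = nz_free + 1),
                Lf + seq(0, Li, length.out = nz_ins + 1)[-1])

  # elliptical grid mapping of [-1,1]^2 onto the unit disc
  uv <- seq(-1, 1, length.out = nxy + 1)
  g <- expand.grid(u = uv, v = uv)
  x0 <- g$u * sqrt(pmax(0, 1 - g$v^2 / 2))
  y0 <- g$v * sqrt(pmax(0, 1 - g$u^2 / 2))
  # semi-axes: aspect ratio from AP/ML diameters, area scaled to mean_csa
  ax <- sqrt(params$mean_csa * params$ml_diameter /
               (pi * params$ap_diameter))
  ay <- sqrt(params$mean_csa * params$ap_diameter /
               (pi * params$ml_diameter))
  # rescale so the discretized (polygonal) section area equals mean_csa
  # exactly at this resolution, not just in the continuum limit
  nid2 <- function(i, j) (j - 1) * (nxy + 1) + i
  a_unit <- 0
  for (j in seq_len(nxy)) for (i in seq_len(nxy)) {
    q <- cbind(x0, y0)[c(nid2(i, j), nid2(i + 1, j), nid2(i + 1, j + 1),
                         nid2(i, j + 1)), ]
    a_unit <- a_unit + 0.5 * abs(sum(q[, 1] * q[c(2:4, 1), 2] -
                                       q[c(2:4, 1), 1] * q[, 2]))
  }
  scl <- sqrt(params$mean_csa / (ax * ay * a_unit))
  ax <- ax * scl
  ay <- ay * scl

  npl <- (nxy + 1)^2  # nodes per layer
  nodes <- matrix(0, npl * (nz + 1), 3)
  for (k in seq_len(nz + 1)) {
    z <- z_layers[k]
    idx <- (k - 1) * npl + seq_len(npl)
    nodes[idx, 1] <- ax * x0 + centerline_offset(z, params)
    nodes[idx, 2] <- ay * y0
    nodes[idx, 3] <- z
  }

  nid <- function(i, j, k) (k - 1) * npl + (j - 1) * (nxy + 1) + i
  elems <- matrix(0L, nxy * nxy * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(nxy)) for (i in seq_len(nxy)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1, j, k),
                    nid(i + 1, j + 1, k), nid(i, j + 1, k),
                    nid(i, j, k + 1), nid(i + 1, j, k + 1),
                    nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }

  # boundary face sets as node quads (outward ordering not needed; faces are
  # used for consistent load integration and fixation)
  quad_layer <- function(k) {
    q <- matrix(0L, nxy * nxy, 4)
    e <- 0L
    for (j in seq_len(nxy)) for (i in seq_len(nxy)) {
      e <- e + 1L
      q[e, ] <- c(nid(i, j, k), nid(i + 1, j, k),
                  nid(i + 1, j + 1, k), nid(i, j + 1, k))
    }
    q
  }
  face_sets <- list(proximal = quad_layer(1L),
                    distal_fixed = quad_layer(nz + 1L))

  mesh <- structure(list(nodes = nodes, elems = elems,
                         face_sets = face_sets,
                         s = nodes[, 3] / Lf,
                         params = params,
                         nxy = nxy, nz = nz, z_layers = z_layers,
                         element_labels = NULL, interface = NULL),
                    class = "tendon_mesh")
  jac <- hex_corner_jacobians_cpp(mesh$nodes, mesh$elems)
  if (any(jac <= 0))
    stop(sprintf("mesh generation produced %d element(s) with non-positive corner Jacobian (min %.3g); increase resolution or check parameters",
                 sum(apply(jac <= 0, 1, any)), min(jac)))
  mesh
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf("Tendon hexahedral mesh: %d nodes, %d elements (%dx%d section, %d layers)\n",
              nrow(x$nodes), nrow(x$elems), x$nxy, x$nxy, x$nz))
  if (!is.null(x$element_labels))
    cat("  subtendon labels:",
        paste(sprintf("%s=%d", names(table(x$element_labels)),
                      table(x$element_labels)), collapse = ", "), "\n")
  if (!is.null(x$interface))
    cat(sprintf("  split interface with %d coincident node pairs\n",
                nrow(x$interface$pairs)))
  cat("  face sets:", paste(names(x$face_sets), collapse = ", "), "\n")
  invisible(x)
}

# element centroids (E x 3)
element_centroids <- function(mesh) {
  E <- nrow(mesh$elems)
  out <- matrix(0, E, 3)
  for (i in 1:8) out <- out + mesh$nodes[mesh$elems[, i], , drop = FALSE]
  out / 8
}

# numerically integrated cross-section area of a node layer (shoelace over
# the section's quadrilaterals)
section_area <- function(mesh, layer = 1L) {
  nxy <- mesh$nxy; npl <- (nxy + 1)^2
  idx <- (layer - 1) * npl + seq_len(npl)
  xy <- mesh$nodes[idx, 1:2]
  nid <- function(i, j) (j - 1) * (nxy + 1) + i
  area <- 0
  for (j in seq_len(nxy)) for (i in seq_len(nxy)) {
    q <- xy[c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1), nid(i, j + 1)), ]
    area <- area + 0.5 * abs(sum(q[, 1] * q[c(2:4, 1), 2] -
                                   q[c(2:4, 1), 1] * q[, 2]))
  }
  area
}

# base angular sector boundaries (degrees, CCW from +x = medial):
# SOL centered anteriorly (+y), then LG (postero-lateral) and MG
# (postero-medial) filling the posterior arc.
sector_boundaries <- function(fractions) {
  fS <- fractions["SOL"]; fLG <- fractions["LG"]
  b0 <- 90 - 180 * fS                       # SOL start
  c(SOL_start = unname(b0),
    LG_start = unname(b0 + 360 * fS),
    MG_start = unname(b0 + 360 * (fS + fLG)),
    MG_end = unname(b0 + 360))
}

# chirality sign: internal rotation; right tendon boundaries rotate from
# postero-medial toward lateral moving distally
twist_sign <- function(params) if (params$side == "right") 1 else -1

#' Assign subtendon labels by twisted angular sectors
#'
#' Each element is labeled by the angular sector (about the bowed
#' centerline) containing its centroid. Sector widths follow the partition
#' fractions; sector boundaries rotate with [partition_twist_angle()], so
#' the partition twists 90 degrees across the free tendon and is constant
#' through the insertion. At the proximal end the soleus occupies the
#' anterior aspect, the medial gastrocnemius the postero-medial aspect and
#' the lateral gastrocnemius the postero-lateral aspect. With
#' `n_subtendons = 2` the two gastrocnemius sectors are merged into a
#' single gastrocnemius (GAS) subtendon.
#'
#' @param mesh a [generate_mesh()] mesh.
#' @param params a [geometry_params()] object (defaults to the mesh's own).
#' @param n_subtendons 3 (SOL/MG/LG) or 2 (SOL/GAS).
#' @return the mesh with `element_labels` set and per-label proximal face
#'   sets (`proximal_SOL`, ...) added.
#' @export
assign_subtendons <- function(mesh, params = mesh$params, n_subtendons = 3) {
  stopifnot(n_subtendons %in% c(2, 3))
  cent <- element_centroids(mesh)
  lab <- element_angular_label(cent, params)
  if (n_subtendons == 2) lab[lab != "SOL"] <- "GAS"
  mesh$element_labels <- lab

  # proximal face sets per label (faces of layer-1 elements)
  first_layer <- seq_len(mesh$nxy^2)
  prox <- mesh$face_sets$proximal
  for (lv in unique(lab)) {
    mesh$face_sets[[paste0("proximal_", lv)]] <-
      prox[lab[first_layer] == lv, , drop = FALSE]
  }
  mesh$face_sets$proximal <- NULL
  mesh
}

# Label of points by rotated angular sector. Angles are measured in the
# aspect-normalized (parametric) frame of the ellipse, so that a sector of
# angular width w covers the fraction w/360 of the section AREA — physical
# angles on an ellipse would systematically over/under-size the sectors.
element_angular_label <- function(pts, params) {
  b <- sector_boundaries(params$partition_fractions)
  s <- pts[, 3] / params$free_tendon_length
  tw <- partition_twist_angle(s, params) * twist_sign(params)
  aspect <- params$ml_diameter / params$ap_diameter
  phi <- atan2(pts[, 2] * aspect,
               pts[, 1] - centerline_offset(pts[, 3], params)) * 180 / pi
  rel <- (phi + tw - b["SOL_start"]) %% 360
  f <- params$partition_fractions
  ifelse(rel < 360 * f["SOL"], "SOL",
         ifelse(rel < 360 * (f["SOL"] + f["LG"]), "LG", "MG"))
}

#' Split a two-subtendon mesh along the inter-subtendon interface
#'
#' Duplicates the nodes shared between the soleus and gastrocnemius element
#' sets so the two subtendons become separate bodies joined only by
#' coincident node pairs, the substrate for tied or frictionless
#' (penalty) interface conditions. Each pair carries a tributary reference
#' area and a normal taken from the analytic twisted partition surface (not
#' from the stair-stepped element faces, whose facet normals would spuriously
#' block axial sliding where the rotating sector boundary crosses an element
#' column).
#'
#' @param mesh a mesh labeled by [assign_subtendons()] with two labels.
#' @return the mesh with duplicated interface nodes and an `interface`
#'   component: `pairs` (node index pairs, SOL side first), `normals`,
#'   `areas` (mm^2) and the interface face quads.
#' @export
split_interface <- function(mesh) {
  lab <- mesh$element_labels
  if (is.null(lab) || length(unique(lab)) != 2)
    stop("split_interface needs a mesh with exactly two subtendon labels")
  labs <- c("SOL", setdiff(unique(lab), "SOL"))
  elsA <- which(lab == labs[1]); elsB <- which(lab == labs[2])
  nodesA <- unique(as.vector(mesh$elems[elsA, ]))
  nodesB <- unique(as.vector(mesh$elems[elsB, ]))
  shared <- intersect(nodesA, nodesB)
  if (length(shared) == 0) stop("subtendons share no nodes; nothing to split")

  # interface faces: faces shared by elements of different labels
  faces <- interface_faces(mesh)

  N0 <- nrow(mesh$nodes)
  new_ids <- N0 + seq_along(shared)
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[shared, , drop = FALSE])
  mesh$s <- c(mesh$s, mesh$s[shared])
  remap <- seq_len(N0)
  remap[shared] <- new_ids
  elB <- mesh$elems[elsB, , drop = FALSE]
  elB[] <- remap[elB]
  mesh$elems[elsB, ] <- elB
  # remap node-quad face sets belonging to the B side
  for (nm in names(mesh$face_sets)) {
    fs <- mesh$face_sets[[nm]]
    if (nm == paste0("proximal_", labs[2])) {
      fs[] <- remap[fs]
    } else if (nm == "distal_fixed") {
      # keep both copies fixed: append remapped quads of B-side elements
      fsB <- fs
      fsB[] <- remap[fsB]
      extra <- fsB[apply(fsB != fs, 1, any), , drop = FALSE]
      fs <- rbind(fs, extra)
    }
    mesh$face_sets[[nm]] <- fs
  }

  # tributary areas: quarter of each adjacent interface face's area
  area <- numeric(N0)
  for (r in seq_len(nrow(faces))) {
    q <- faces[r, ]
    a <- quad_area(mesh$nodes[q, , drop = FALSE])
    area[q] <- area[q] + a / 4
  }
  normals <- t(vapply(shared, function(n)
    partition_surface_normal(mesh$nodes[n, ], mesh$params),
    numeric(3)))
  mesh$interface <- list(pairs = cbind(SOL = shared, OTHER = new_ids),
                         normals = normals,
                         areas = area[shared],
                         faces = faces)
  mesh
}

# faces (sorted node 4-tuples) shared between elements of different labels
interface_faces <- function(mesh) {
  lf <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
              c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  E <- nrow(mesh$elems)
  keys <- character(E * 6); labs <- character(E * 6)
  quads <- matrix(0L, E * 6, 4)
  r <- 0L
  for (e in seq_len(E)) for (fc in seq_len(6)) {
    r <- r + 1L
    q <- mesh$elems[e, lf[fc, ]]
    quads[r, ] <- q
    keys[r] <- paste(sort(q), collapse = "-")
    labs[r] <- mesh$element_labels[e]
  }
  dup <- split(seq_along(keys), keys)
  dup <- dup[lengths(dup) == 2]
  sel <- vapply(dup, function(ix) labs[ix[1]] != labs[ix[2]], logical(1))
  idx <- vapply(dup[sel], `[`, integer(1), 1L)
  quads[idx, , drop = FALSE]
}

quad_area <- function(p) {
  # split into two triangles
  a1 <- 0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
  a2 <- 0.5 * sqrt(sum(cross3(p[3, ] - p[1, ], p[4, ] - p[1, ])^2))
  a1 + a2
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Unit normal of the analytic twisted partition surface at a point on the
# SOL/GAS boundary. A boundary at normalized angle theta(z) is the physical
# ray t -> centerline(z) + t (cos theta, sin(theta)/aspect); the normal is
# the cross product of the radial and axial surface tangents.
partition_surface_normal <- function(p, params) {
  z <- p[3]
  s <- z / params$free_tendon_length
  chi <- twist_sign(params)
  b <- sector_boundaries(params$partition_fractions)
  aspect <- params$ml_diameter / params$ap_diameter
  # the two SOL boundaries, rotated (sectors are tested on phi + chi*twist,
  # so boundaries sit at base - chi*twist in normalized angle)
  tw <- partition_twist_angle(s, params)
  th_bounds <- (c(b["SOL_start"], b["LG_start"]) - chi * tw) * pi / 180
  dx <- p[1] - centerline_offset(z, params); dy <- p[2]
  phi <- atan2(dy * aspect, dx)
  dang <- function(a, b) atan2(sin(a - b), cos(a - b))
  k <- which.min(abs(vapply(th_bounds, dang, numeric(1), b = phi)))
  th <- th_bounds[k]
  t_rad <- sqrt(dx^2 + (dy * aspect)^2)
  dth_dz <- if (s < 1) {
    -chi * params$partition_twist_total * pi / 180 / params$free_tendon_length
  } else 0
  cx1 <- centerline_slope(z, params)
  # surface tangents: X_t = (cos th, sin(th)/aspect, 0),
  # X_z = (cx' - t sin th th', t cos th th' / aspect, 1)
  A <- cos(th); B <- sin(th) / aspect
  C <- cx1 - t_rad * sin(th) * dth_dz
  D <- t_rad * cos(th) * dth_dz / aspect
  n <- c(B, -A, A * D - B * C)
  n / sqrt(sum(n^2))
}

#' Sample a population of tendon geometries
#'
#' Draws `n` parameter sets around a mean geometry with per-field standard
#' deviations, standing in for a population of subject-specific tendon
#' models. Fields are drawn independently from normal distributions
#' truncated at three standard deviations and at positivity.
#'
#' @param mean_params a [geometry_params()] object.
#' @param sd_table named numeric vector of standard deviations for a subset
#'   of the scalar fields (e.g. `c(mean_csa = 10, free_tendon_length = 5)`).
#' @param n number of geometries, >= 1.
#' @param seed integer seed; results are reproducible given the seed.
#' @return list of `n` `geometry_params` objects.
#' @export
sample_population <- function(mean_params, sd_table, n, seed) {
  stopifnot(n >= 1, all(sd_table >= 0))
  bad <- setdiff(names(sd_table),
                 c("free_tendon_length", "insertion_length", "mean_csa",
                   "ap_diameter", "ml_diameter", "centerline_ml_offset",
                   "partition_twist_total"))
  if (length(bad)) stop("unknown fields in sd_table: ",
                        paste(bad, collapse = ", "))
  must_be_positive <- c("free_tendon_length", "insertion_length", "mean_csa",
                        "ap_diameter", "ml_diameter")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- unclass(mean_params)
    for (f in names(sd_table)) {
      sd <- sd_table[[f]]
      if (sd == 0) next
      mu <- p[[f]]
      repeat {
        v <- rnorm(1, mu, sd)
        if (abs(v - mu) <= 3 * sd && (v > 0 || !(f %in% must_be_positive)))
          break
      }
      p[[f]] <- v
    }
    do.call(geometry_params, p)
  })
}
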