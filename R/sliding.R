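#' Activity muscle forces for the subtendon sliding experiment
#'
#' Peak soleus muscle force and the gastrocnemius force at the same
#' instant for five rehabilitation activities (Alfredson-protocol style
#' heel drops, toe walking and hopping), packaged with the package. The
#' forces are applied as distributed dead loads on the proximal faces of
#' the soleus and (merged) gastrocnemius subtendons.
#'
#' @return data frame with columns `activity`, `soleus_N`, `gastroc_N`
#'   (five rows).
#' @examples
#' load_activity_table()
#' @export
load_activity_table <- function() {
  f <- system.file("extdata", "activity_forces.csv", package = "subtendon",
                   mustWork = TRUE)
  read.csv(f, check.names = TRUE, stringsAsFactors = FALSE)
}

#' Build the two-subtendon sliding model
#'
#' Convenience constructor: generates the mesh, assigns the two-subtendon
#' (soleus / merged gastrocnemius) partition, and splits the interface
#' into coincident node pairs.
#'
#' @param params a [geometry_params()] object.
#' @param resolution mesh resolution for [generate_mesh()].
#' @return a split, labeled `tendon_mesh`.
#' @export
build_sliding_mesh <- function(params = geometry_params(),
                               resolution = c(6, 14)) {
  mesh <- generate_mesh(params, resolution)
  mesh <- assign_subtendons(mesh, params, n_subtendons = 2)
  split_interface(mesh)
}

sliding_metrics <- function(mesh, result) {
  pairs <- mesh$interface$pairs
  u <- result$u
  rel <- u[pairs[, 1], , drop = FALSE] - u[pairs[, 2], , drop = FALSE]
  nrm <- mesh$interface$normals
  gap <- rowSums(rel * nrm)
  tang <- rel - gap * nrm
  # subtendon sliding is the relative longitudinal (axial) displacement of
  # paired interface points; the full tangential magnitude (which also
  # carries circumferential untwisting that scales with total load) is
  # reported alongside
  sliding <- max(abs(tang[, 3]))
  tangential <- max(sqrt(rowSums(tang^2)))

  lab_of_node <- node_labels(mesh)
  sol_nodes <- which(lab_of_node == "SOL")
  gas_nodes <- which(lab_of_node == "GAS")
  # lengthening of a subtendon = mean axial displacement of its loaded
  # proximal face (the distal face is fixed); the mean is robust to the
  # axial displacement gradients that whole-body bending superimposes
  sol_len <- abs(mean(u[nodes_of_set(mesh, "proximal_SOL"), 3]))
  gas_len <- abs(mean(u[nodes_of_set(mesh, "proximal_GAS"), 3]))

  iface_nodes <- unique(as.vector(pairs))
  touches <- apply(matrix(mesh$elems %in% iface_nodes,
                          nrow = nrow(mesh$elems)), 1, any)
  e1 <- apply(result$strain[touches, , drop = FALSE], 1, function(E) {
    M <- matrix(c(E[1], E[4], E[5],
                  E[4], E[2], E[6],
                  E[5], E[6], E[3]), 3, 3)
    max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  })
  list(sliding_mm = sliding,
       tangential_slip_mm = tangential,
       differential_lengthening_mm = abs(sol_len - gas_len),
       max_interface_strain = max(e1),
       max_normal_gap_mm = max(abs(gap)),
       sol_max_disp_mm = max(sqrt(rowSums(u[sol_nodes, , drop = FALSE]^2))),
       gas_max_disp_mm = max(sqrt(rowSums(u[gas_nodes, , drop = FALSE]^2))))
}

node_labels <- function(mesh) {
  lab <- rep(NA_character_, nrow(mesh$nodes))
  for (lv in unique(mesh$element_labels)) {
    nn <- unique(as.vector(mesh$elems[mesh$element_labels == lv, ]))
    lab[nn] <- lv
  }
  lab
}

#' Run one activity on the two-subtendon model
#'
#' Fixes the distal face, applies the soleus force to the proximal soleus
#' faces and the gastrocnemius force to the proximal gastrocnemius faces
#' (distributed dead loads along the axial direction), solves under the
#' requested interface condition and summarizes sliding and interface
#' strain.
#'
#' @param mesh a [build_sliding_mesh()] mesh.
#' @param fibers a [build_fiber_field()] fiber field on that mesh.
#' @param material a [material_params()] object.
#' @param activity one row of [load_activity_table()] (or a list with
#'   `activity`, `soleus_N`, `gastroc_N`).
#' @param condition `"frictionless"` or `"tied"`.
#' @param settings a [solve_settings()] object.
#' @param n_increments load increments for the ramp.
#' @return list of class `sliding_metrics`: maximum tangential interface
#'   sliding (mm), differential lengthening distance (difference of the
#'   subtendons' maximum axial displacements, mm), maximum first-principal
#'   Green-Lagrange strain over interface-adjacent elements, the maximum
#'   interface normal gap, per-subtendon maximum displacements, and the
#'   underlying `fe_result`.
#' @export
run_activity <- function(mesh, fibers, material, activity,
                         condition = c("frictionless", "tied"),
                         settings = solve_settings(), n_increments = 20) {
  condition <- match.arg(condition)
  stopifnot(!is.null(mesh$interface))
  # the loaded proximal faces are guided axially (held in-plane): proximally
  # the free tendon continues into the aponeurosis, which transmits muscle
  # force along the tendon axis and prevents the cut faces from deflecting
  # sideways under the eccentric dead loads
  bcs <- boundary_conditions(
    fixed = list(distal_fixed = 1:3, proximal_SOL = 1:2,
                 proximal_GAS = 1:2),
    tractions = c(proximal_SOL = activity$soleus_N,
                  proximal_GAS = activity$gastroc_N),
    n_increments = n_increments)
  res <- solve_fe(mesh, fibers, material, bcs, settings,
                  interface_condition = condition)
  m <- sliding_metrics(mesh, res)
  structure(c(list(activity = activity$activity, condition = condition),
              m, list(result = res)),
            class = "sliding_metrics")
}

#' @export
print.sliding_metrics <- function(x, ...) {
  cat(sprintf("%s (%s interface)\n", x$activity, x$condition))
  cat(sprintf("  sliding %.3f mm | differential lengthening %.3f mm | max interface strain %.4f\n",
              x$sliding_mm, x$differential_lengthening_mm,
              x$max_interface_strain))
  invisible(x)
}

#' Compare frictionless and tied interface conditions across activities
#'
#' Solves every activity under both interface conditions and tabulates the
#' sliding and interface-strain metrics together with the tied-vs-
#' frictionless relative reductions. The reduction comparison uses the
#' differential lengthening distance (a whole-subtendon measure that
#' remains nonzero under tied contact, where differential motion persists
#' through tendon shearing) alongside the interface strain.
#'
#' @param mesh a [build_sliding_mesh()] mesh.
#' @param fibers fiber field on that mesh.
#' @param material a [material_params()] object.
#' @param activities data frame as from [load_activity_table()].
#' @param settings a [solve_settings()] object.
#' @param n_increments load increments per solve.
#' @return data frame with one row per activity and condition
#'   (`sliding_mm`, `differential_lengthening_mm`, `max_interface_strain`,
#'   `sol_max_disp_mm`, `gas_max_disp_mm`); the attribute `"reductions"`
#'   holds the per-activity relative reductions under tied contact.
#' @export
compare_contacts <- function(mesh, fibers, material,
                             activities = load_activity_table(),
                             settings = solve_settings(),
                             n_increments = 20) {
  rows <- list()
  for (i in seq_len(nrow(activities))) for (cond in c("frictionless",
                                                      "tied")) {
    m <- run_activity(mesh, fibers, material, activities[i, ], cond,
                      settings, n_increments)
    rows[[length(rows) + 1]] <- data.frame(
      activity = activities$activity[i], contact = cond,
      sliding_mm = m$sliding_mm,
      differential_lengthening_mm = m$differential_lengthening_mm,
      max_interface_strain = m$max_interface_strain,
      sol_max_disp_mm = m$sol_max_disp_mm,
      gas_max_disp_mm = m$gas_max_disp_mm)
  }
  out <- do.call(rbind, rows)
  fr <- out[out$contact == "frictionless", ]
  ti <- out[out$contact == "tied", ]
  red <- data.frame(
    activity = fr$activity,
    sliding_reduction = 1 - ti$sliding_mm / fr$sliding_mm,
    differential_lengthening_reduction =
      1 - ti$differential_lengthening_mm / fr$differential_lengthening_mm,
    interface_strain_reduction =
      1 - ti$max_interface_strain / fr$max_interface_strain)
  attr(out, "reductions") <- red
  out
}
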