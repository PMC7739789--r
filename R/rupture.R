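#' Settings for the uniaxial rupture experiment
#'
#' Rupture is simulated by prescribing increasing axial stretch (distal
#' face fixed, proximal face displaced) and monitoring the maximum element
#' von Mises stress; the rupture load is the axial reaction force at the
#' point where the peak von Mises stress reaches the failure criterion
#' (linearly interpolated between the bracketing increments). The critical
#' von Mises value is not tied to a specific specimen here and is exposed
#' as a configurable parameter.
#'
#' @param failure_von_mises critical von Mises stress, MPa.
#' @param twist_angles fascicle twist angles for sweep runs, degrees.
#' @param max_applied_stretch largest prescribed axial stretch.
#' @param stretch_increment stretch step per load increment.
#' @return list of class `rupture_settings`.
#' @export
rupture_settings <- function(failure_von_mises = 80,
                             twist_angles = c(0, 15, 30, 45, 60),
                             max_applied_stretch = 1.12,
                             stretch_increment = 0.004) {
  stopifnot(failure_von_mises > 0, max_applied_stretch > 1,
            all(twist_angles >= 0), all(twist_angles <= 90))
  structure(list(failure_von_mises = failure_von_mises,
                 twist_angles = twist_angles,
                 max_applied_stretch = max_applied_stretch,
                 stretch_increment = stretch_increment),
            class = "rupture_settings")
}

#' Simulate tendon rupture under uniaxial stretch
#'
#' @param mesh an unpartitioned [generate_mesh()] mesh (the twist-sweep
#'   rupture study runs on the single-body tendon).
#' @param fibers a [build_fiber_field()] fiber field.
#' @param material a [material_params()] object.
#' @param rupture a [rupture_settings()] object.
#' @param settings a [solve_settings()] object.
#' @return object of class `rupture_result`: `rupture_load` (N, `NA` when
#'   the criterion is not reached), `reached`, `stretch_at_failure`,
#'   `history` (per-increment stretch, axial reaction and peak von Mises),
#'   `peak_element`, and the stress state at the bracketing increment
#'   (`von_mises`, `u`).
#' @export
simulate_rupture <- function(mesh, fibers, material,
                             rupture = rupture_settings(),
                             settings = solve_settings()) {
  L <- mesh$params$free_tendon_length + mesh$params$insertion_length
  d_total <- -(rupture$max_applied_stretch - 1) * L
  n_inc <- ceiling((rupture$max_applied_stretch - 1) /
                     rupture$stretch_increment)
  # clamped grips: the distal face is fully fixed and the displaced proximal
  # face is held in-plane, as in a gripped uniaxial test (a free proximal
  # face would spin under the fiber torque of a twisted field)
  bcs <- boundary_conditions(fixed = list(distal_fixed = 1:3,
                                          proximal = 1:2),
                             prescribed = list(set = "proximal", comp = 3,
                                               value = d_total),
                             n_increments = n_inc)
  sys <- build_system(mesh, fibers, material, bcs, settings, "none")
  hist <- list()
  crossed <- FALSE
  on_inc <- function(u, s) {
    fld <- result_fields(sys, u, s)
    stretch <- 1 + s * (rupture$max_applied_stretch - 1)
    hist[[length(hist) + 1]] <<- list(
      fraction = s, stretch = stretch,
      axial_load = abs(fld$reaction_prescribed[3]),
      max_von_mises = max(fld$von_mises),
      peak_element = which.max(fld$von_mises),
      von_mises = fld$von_mises, u = u)
    crossed <<- max(fld$von_mises) >= rupture$failure_von_mises
    crossed
  }
  run <- run_increments(sys, seq_len(n_inc) / n_inc, on_inc)
  h <- data.frame(stretch = vapply(hist, `[[`, numeric(1), "stretch"),
                  axial_load = vapply(hist, `[[`, numeric(1), "axial_load"),
                  max_von_mises = vapply(hist, `[[`, numeric(1),
                                         "max_von_mises"))
  if (crossed) {
    k <- length(hist)
    vm1 <- if (k > 1) hist[[k - 1]]$max_von_mises else 0
    ld1 <- if (k > 1) hist[[k - 1]]$axial_load else 0
    st1 <- if (k > 1) hist[[k - 1]]$stretch else 1
    t <- (rupture$failure_von_mises - vm1) /
      (hist[[k]]$max_von_mises - vm1)
    out <- list(rupture_load = ld1 + t * (hist[[k]]$axial_load - ld1),
                stretch_at_failure = st1 + t * (hist[[k]]$stretch - st1),
                reached = TRUE,
                peak_element = hist[[k]]$peak_element,
                von_mises = hist[[k]]$von_mises,
                u = matrix(hist[[k]]$u, ncol = 3, byrow = TRUE),
                history = h, settings = rupture)
  } else {
    k <- length(hist)
    out <- list(rupture_load = NA_real_, stretch_at_failure = NA_real_,
                reached = FALSE,
                peak_element = if (k) hist[[k]]$peak_element else NA,
                von_mises = if (k) hist[[k]]$von_mises else NULL,
                u = if (k) matrix(hist[[k]]$u, ncol = 3, byrow = TRUE)
                else NULL,
                history = h, settings = rupture)
  }
  structure(out, class = "rupture_result")
}

#' @export
print.rupture_result <- function(x, ...) {
  if (x$reached)
    cat(sprintf("Rupture at %.1f N (stretch %.4f, von Mises criterion %g MPa)\n",
                x$rupture_load, x$stretch_at_failure,
                x$settings$failure_von_mises))
  else
    cat(sprintf("No rupture up to stretch %.4f (criterion %g MPa, peak %.1f MPa)\n",
                x$settings$max_applied_stretch, x$settings$failure_von_mises,
                max(x$history$max_von_mises)))
  invisible(x)
}

#' Medial/lateral stress asymmetry ratio
#'
#' Ratio of the peak element von Mises stress over the medial half of the
#' tendon to the peak over the lateral half, the halves being defined by
#' each cross-section's centroid (the bowed centerline). A ratio of 1
#' indicates evenly distributed peak stresses; values above 1 indicate a
#' medial stress concentration.
#'
#' @param result an `fe_result` or `rupture_result` carrying a per-element
#'   `von_mises` field.
#' @param mesh the mesh the result was computed on.
#' @return scalar asymmetry ratio.
#' @export
stress_asymmetry <- function(result, mesh) {
  vm <- result$von_mises
  if (is.null(vm)) stop("result carries no von Mises field")
  cent <- element_centroids(mesh)
  medial <- cent[, 1] > centerline_offset(cent[, 3], mesh$params)
  max(vm[medial]) / max(vm[!medial])
}

#' Rupture sweep over fascicle twist angles
#'
#' Runs [simulate_rupture()] for each geometry and twist angle and collects
#' rupture loads and stress-asymmetry ratios.
#'
#' @param geometries a single [geometry_params()] object or a list of them
#'   (e.g. from [sample_population()]).
#' @param angles fascicle twist angles, degrees.
#' @param material a [material_params()] object.
#' @param resolution mesh resolution passed to [generate_mesh()].
#' @param rupture a [rupture_settings()] object.
#' @param settings a [solve_settings()] object.
#' @return data frame with columns `geometry_id`, `alpha_deg`,
#'   `rupture_load_N`, `asymmetry_ratio`, `reached`.
#' @export
rupture_sweep <- function(geometries, angles = c(0, 15, 30, 45, 60),
                          material = material_params(),
                          resolution = c(6, 14),
                          rupture = rupture_settings(twist_angles = angles),
                          settings = solve_settings()) {
  if (inherits(geometries, "geometry_params")) geometries <- list(geometries)
  rows <- list()
  for (g in seq_along(geometries)) {
    mesh <- generate_mesh(geometries[[g]], resolution)
    for (a in angles) {
      fib <- build_fiber_field(mesh, a)
      res <- simulate_rupture(mesh, fib, material, rupture, settings)
      rows[[length(rows) + 1]] <- data.frame(
        geometry_id = g, alpha_deg = a,
        rupture_load_N = res$rupture_load,
        asymmetry_ratio = stress_asymmetry(res, mesh),
        reached = res$reached)
    }
  }
  do.call(rbind, rows)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA computed from sums of squares:
#' used to test for differences in rupture load between twist-angle
#' groups.
#'
#' @param groups list of numeric vectors (one per group), each with at
#'   least two values; at least two groups.
#' @return list with `F`, `p`, degrees of freedom and the sums of squares.
#' @examples
#' anova_one_way(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least two values")
  x <- unlist(groups)
  grand <- mean(x)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  if (ssb == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2,
                            ss_between = 0, ss_within = ssw))
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_between = ssb, ss_within = ssw)
}

#' Sensitivity of rupture load to structural factors
#'
#' Computes the rupture load at the mean geometry/material and at plus and
#' minus one standard deviation for each factor (cross-sectional area,
#' tendon stiffness, fascicle twist angle) holding the others at their
#' means. The per-factor effect is the relative load change per standard
#' deviation, `(load(+1SD) - load(-1SD)) / (2 * load(mean))`.
#'
#' @param base_params a [geometry_params()] object (the mean geometry).
#' @param material mean [material_params()].
#' @param base_twist mean fascicle twist angle, degrees.
#' @param sds list with `csa_frac` (relative SD of CSA), `stiffness_frac`
#'   (relative SD of the moduli c1 and c5) and `twist_sd_deg` (SD of the
#'   twist angle, degrees).
#' @param resolution mesh resolution.
#' @param rupture,settings experiment and solver settings.
#' @return data frame with one row per factor: low/mean/high rupture loads
#'   and the relative `effect_per_sd`.
#' @export
sensitivity_analysis <- function(base_params = geometry_params(),
                                 material = material_params(),
                                 base_twist = 30,
                                 sds = list(csa_frac = 0.15,
                                            stiffness_frac = 0.15,
                                            twist_sd_deg = 10),
                                 resolution = c(6, 14),
                                 rupture = rupture_settings(),
                                 settings = solve_settings()) {
  run <- function(params, mat, twist) {
    mesh <- generate_mesh(params, resolution)
    fib <- build_fiber_field(mesh, twist)
    simulate_rupture(mesh, fib, mat, rupture, settings)$rupture_load
  }
  scale_geom <- function(f) {
    p <- unclass(base_params)
    p$mean_csa <- p$mean_csa * f
    do.call(geometry_params, p)
  }
  scale_mat <- function(f)
    material_params(c1 = material$c1 * f, c4 = material$c4,
                    c5 = material$c5 * f,
                    lambda_star = material$lambda_star,
                    kappa = material$kappa * f)
  base_load <- run(base_params, material, base_twist)
  rows <- list()
  factors <- list(
    CSA = list(lo = function() run(scale_geom(1 - sds$csa_frac), material,
                                   base_twist),
               hi = function() run(scale_geom(1 + sds$csa_frac), material,
                                   base_twist),
               sd = sds$csa_frac),
    stiffness = list(lo = function() run(base_params,
                                         scale_mat(1 - sds$stiffness_frac),
                                         base_twist),
                     hi = function() run(base_params,
                                         scale_mat(1 + sds$stiffness_frac),
                                         base_twist),
                     sd = sds$stiffness_frac),
    twist = list(lo = function() run(base_params, material,
                                     max(0, base_twist - sds$twist_sd_deg)),
                 hi = function() run(base_params, material,
                                     base_twist + sds$twist_sd_deg),
                 sd = sds$twist_sd_deg))
  for (nm in names(factors)) {
    sd <- factors[[nm]]$sd
    if (sd == 0) {
      rows[[nm]] <- data.frame(factor = nm, load_low = base_load,
                               load_mean = base_load, load_high = base_load,
                               effect_per_sd = 0)
      next
    }
    lo <- factors[[nm]]$lo(); hi <- factors[[nm]]$hi()
    rows[[nm]] <- data.frame(factor = nm, load_low = lo,
                             load_mean = base_load, load_high = hi,
                             effect_per_sd = (hi - lo) / (2 * base_load))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
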