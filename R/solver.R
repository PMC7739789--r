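#' Nonlinear solver settings
#'
#' @param tol relative residual tolerance (against the larger of the applied
#'   load norm and the increment's initial residual).
#' @param atol absolute residual floor, N.
#' @param max_iter maximum Newton iterations per load increment.
#' @param penalty contact penalty stiffness for the frictionless interface,
#'   N/mm^3 (multiplied by each node pair's tributary area).
#' @param line_search use backtracking line search on the Newton update.
#' @param max_halvings maximum adaptive halvings of a load increment before
#'   giving up.
#' @param fd_step finite-difference step (mm) for the element tangent.
#' @return list of class `solve_settings`.
#' @export
solve_settings <- function(tol = 1e-6, atol = 1e-8, max_iter = 50,
                           penalty = 200, line_search = TRUE,
                           max_halvings = 4, fd_step = 1e-6) {
  stopifnot(tol > 0, penalty > 0, max_iter >= 1)
  structure(list(tol = tol, atol = atol, max_iter = max_iter,
                 penalty = penalty, line_search = line_search,
                 max_halvings = max_halvings, fd_step = fd_step),
            class = "solve_settings")
}

#' Boundary conditions for a quasi-static solve
#'
#' @param fixed named list mapping face-set names to the displacement
#'   components (1 = x, 2 = y, 3 = z) held at zero, e.g.
#'   `list(distal_fixed = 1:3)`. At least one fully fixed set (or
#'   equivalent `extra_fixed` entries) must prevent rigid-body motion.
#' @param prescribed optional list `list(set =, comp =, value =)`: a
#'   nonzero displacement (mm) ramped over the increments, e.g. the axial
#'   grip displacement of a uniaxial stretch run.
#' @param tractions optional named numeric vector mapping face-set names to
#'   total forces (N), distributed consistently over each set's reference
#'   area and applied as dead loads along `traction_direction`.
#' @param traction_direction unit reference direction of the applied
#'   tractions; default `c(0, 0, -1)` pulls the proximal end away from the
#'   fixed distal end.
#' @param n_increments number of load increments.
#' @param extra_fixed optional 2-column matrix of (node, comp) pairs fixed
#'   at zero in addition to `fixed` (useful for removing rigid-body modes
#'   in toy problems).
#' @return list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(fixed = list(distal_fixed = 1:3),
                                prescribed = NULL, tractions = NULL,
                                traction_direction = c(0, 0, -1),
                                n_increments = 10, extra_fixed = NULL) {
  fully_fixed <- names(fixed)[vapply(fixed, function(cmp)
    all(1:3 %in% cmp), logical(1))]
  if (!is.null(tractions) && length(intersect(names(tractions),
                                              fully_fixed)))
    stop("traction sets must be disjoint from fully fixed sets")
  structure(list(fixed = fixed, prescribed = prescribed,
                 tractions = tractions,
                 traction_direction = traction_direction /
                   sqrt(sum(traction_direction^2)),
                 n_increments = n_increments, extra_fixed = extra_fixed),
            class = "boundary_conditions")
}

nodes_of_set <- function(mesh, set) {
  fs <- mesh$face_sets[[set]]
  if (is.null(fs)) stop("mesh has no face set '", set, "'")
  sort(unique(as.vector(fs)))
}

# Consistent nodal load vector for a total force distributed uniformly over
# a face set's reference area (2x2 Gauss integration per bilinear quad).
face_load_vector <- function(mesh, set, total_force, direction) {
  quads <- mesh$face_sets[[set]]
  if (is.null(quads)) stop("mesh has no face set '", set, "'")
  g <- 1 / sqrt(3)
  gp <- expand.grid(xi = c(-g, g), eta = c(-g, g))
  f <- numeric(3 * nrow(mesh$nodes))
  weights <- numeric(nrow(mesh$nodes))
  total_area <- 0
  for (r in seq_len(nrow(quads))) {
    q <- quads[r, ]
    X <- mesh$nodes[q, , drop = FALSE]
    for (k in seq_len(nrow(gp))) {
      xi <- gp$xi[k]; eta <- gp$eta[k]
      N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
      dNxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
      dNeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
      tu <- drop(dNxi %*% X); tv <- drop(dNeta %*% X)
      dA <- sqrt(sum(cross3(tu, tv)^2))
      total_area <- total_area + dA
      weights[q] <- weights[q] + N * dA
    }
  }
  for (i in 1:3)
    f[3 * (seq_len(nrow(mesh$nodes)) - 1) + i] <-
      weights * direction[i] * total_force / total_area
  f
}

#' Interface condition between split subtendons
#'
#' Builds the constrained-system description for a mesh whose subtendons
#' were separated by [split_interface()]. Under `tied`, each coincident
#' node pair shares all displacement components (slave degrees of freedom
#' are folded onto their masters). Under `frictionless`, each pair is
#' coupled only along its local interface normal through a penalty spring
#' scaled by the pair's tributary area; tangential motion is free.
#'
#' @param mesh a mesh processed by [split_interface()].
#' @param condition `"frictionless"` or `"tied"`.
#' @param penalty penalty stiffness, N/mm^3 (frictionless only).
#' @return list of class `interface_condition` with the DOF fold map
#'   (`tied`) or the penalty stiffness triplets (`frictionless`).
#' @export
apply_interface_condition <- function(mesh,
                                      condition = c("frictionless", "tied"),
                                      penalty = 200) {
  condition <- match.arg(condition)
  if (is.null(mesh$interface))
    stop("mesh has no coincident interface node pairs; run split_interface() first")
  pairs <- mesh$interface$pairs
  ndof <- 3 * nrow(mesh$nodes)
  if (condition == "tied") {
    m <- seq_len(ndof)
    for (i in 1:3) m[3 * (pairs[, 2] - 1) + i] <- 3 * (pairs[, 1] - 1) + i
    out <- list(condition = "tied", fold = m, pairs = pairs)
  } else {
    np <- nrow(pairs)
    ti <- integer(np * 36); tj <- integer(np * 36); tx <- numeric(np * 36)
    pos <- 0L
    for (p in seq_len(np)) {
      n <- mesh$interface$normals[p, ]
      kA <- penalty * mesh$interface$areas[p]
      M <- kA * (n %o% n)
      dA <- 3 * (pairs[p, 1] - 1) + 1:3
      dB <- 3 * (pairs[p, 2] - 1) + 1:3
      blocks <- list(list(dA, dA, M), list(dB, dB, M),
                     list(dA, dB, -M), list(dB, dA, -M))
      for (bl in blocks) {
        idx <- pos + 1:9
        ti[idx] <- rep(bl[[1]], 3)
        tj[idx] <- rep(bl[[2]], each = 3)
        tx[idx] <- as.vector(bl[[3]])
        pos <- pos + 9L
      }
    }
    out <- list(condition = "frictionless", i = ti, j = tj, x = tx,
                pairs = pairs, penalty = penalty)
  }
  structure(out, class = "interface_condition")
}

# Assemble the immutable parts of a solve into a system description.
build_system <- function(mesh, fibers, material, bcs, settings,
                         interface_condition = "none") {
  N <- nrow(mesh$nodes); ndof <- 3L * N
  dof <- function(nodes, comp) 3L * (nodes - 1L) + comp

  fixed <- integer(0)
  for (set in names(bcs$fixed))
    for (cmp in bcs$fixed[[set]])
      fixed <- c(fixed, dof(nodes_of_set(mesh, set), cmp))
  if (!is.null(bcs$extra_fixed))
    fixed <- c(fixed, dof(bcs$extra_fixed[, 1], bcs$extra_fixed[, 2]))
  fixed <- sort(unique(fixed))
  if (length(fixed) == 0) stop("no fixed degrees of freedom: rigid-body motion")

  presc_dofs <- integer(0); presc_vals <- numeric(0)
  if (!is.null(bcs$prescribed)) {
    pn <- nodes_of_set(mesh, bcs$prescribed$set)
    presc_dofs <- dof(pn, bcs$prescribed$comp)
    presc_vals <- rep(bcs$prescribed$value, length(pn))
  }

  f_ext <- numeric(ndof)
  for (set in names(bcs$tractions))
    f_ext <- f_ext + face_load_vector(mesh, set, bcs$tractions[[set]],
                                      bcs$traction_direction)

  m <- seq_len(ndof)
  pen <- NULL
  if (!identical(interface_condition, "none")) {
    ic <- if (inherits(interface_condition, "interface_condition"))
      interface_condition
    else apply_interface_condition(mesh, interface_condition,
                                   penalty = settings$penalty)
    if (ic$condition == "tied") m <- ic$fold else pen <- ic
  }

  constrained <- union(fixed, presc_dofs)
  slaves <- which(m != seq_len(ndof))
  active <- setdiff(seq_len(ndof), union(constrained, slaves))

  pen_i <- if (is.null(pen)) integer(0) else m[pen$i]
  pen_j <- if (is.null(pen)) integer(0) else m[pen$j]
  pen_x <- if (is.null(pen)) numeric(0) else pen$x
  Kpen <- if (is.null(pen)) NULL else
    Matrix::sparseMatrix(i = pen$i, j = pen$j, x = pen$x,
                         dims = c(ndof, ndof))

  list(mesh = mesh, dirs = fibers$directions,
       matvec = material_vector(material),
       ndof = ndof, fixed = fixed, presc_dofs = presc_dofs,
       presc_vals = presc_vals, f_ext = f_ext, m = m, slaves = slaves,
       active = active, Kpen = Kpen, pen_i = pen_i, pen_j = pen_j,
       pen_x = pen_x, settings = settings)
}

fold_vector <- function(r, m, ndof) {
  if (length(unique(m)) == ndof) return(r)
  out <- numeric(ndof)
  agg <- tapply(r, m, sum)
  out[as.integer(names(agg))] <- agg
  out
}

residual_full <- function(sys, u, s) {
  f <- fe_internal_force_cpp(sys$mesh$nodes, sys$mesh$elems, u, sys$dirs,
                             sys$matvec)
  if (anyNA(f)) return(NULL)
  if (!is.null(sys$Kpen)) f <- f + as.numeric(sys$Kpen %*% u)
  f - s * sys$f_ext
}

sync_slaves <- function(sys, u) {
  if (length(sys$slaves)) u[sys$slaves] <- u[sys$m[sys$slaves]]
  u
}

# One Newton solve at load fraction s, starting from u. Returns NULL on
# failure (non-convergence or element inversion).
newton_solve <- function(sys, u, s) {
  st <- sys$settings
  u[sys$presc_dofs] <- s * sys$presc_vals
  u <- sync_slaves(sys, u)
  resnorms <- numeric(0)
  ref_load <- sqrt(sum((s * sys$f_ext)^2))
  ref <- NA_real_
  for (iter in seq_len(st$max_iter)) {
    asm <- fe_assemble_cpp(sys$mesh$nodes, sys$mesh$elems, u, sys$dirs,
                           sys$matvec, st$fd_step)
    if (!asm$ok || anyNA(asm$f)) return(NULL)
    r <- asm$f - s * sys$f_ext
    if (!is.null(sys$Kpen)) r <- r + as.numeric(sys$Kpen %*% u)
    rf <- fold_vector(r, sys$m, sys$ndof)
    rn <- sqrt(sum(rf[sys$active]^2))
    resnorms <- c(resnorms, rn)
    if (is.na(ref)) ref <- max(ref_load, rn)
    if (rn <= max(st$tol * ref, st$atol))
      return(list(u = u, iters = iter - 1L, resnorms = resnorms))
    K <- Matrix::sparseMatrix(i = c(sys$m[asm$i], sys$pen_i),
                              j = c(sys$m[asm$j], sys$pen_j),
                              x = c(asm$x, sys$pen_x),
                              dims = c(sys$ndof, sys$ndof))
    du <- tryCatch(
      as.numeric(Matrix::solve(K[sys$active, sys$active],
                               -rf[sys$active])),
      error = function(e) NULL)
    if (is.null(du) || anyNA(du)) return(NULL)
    # Step-length selection. The residual norm is a poor merit function for
    # stiff penalty problems (healthy Newton sequences pass through large
    # transient residuals), so the full step is accepted unless it inverts an
    # element; with line_search enabled, a catastrophically overshooting step
    # (>100x residual growth) is additionally compared against two shorter
    # trials and the best of the three is taken.
    trial <- function(alpha) {
      u_try <- u
      u_try[sys$active] <- u[sys$active] + alpha * du
      u_try <- sync_slaves(sys, u_try)
      r_try <- residual_full(sys, u_try, s)
      if (is.null(r_try)) return(NULL)
      list(u = u_try,
           rn = sqrt(sum(fold_vector(r_try, sys$m,
                                     sys$ndof)[sys$active]^2)))
    }
    alpha <- 1
    cand <- NULL
    repeat {
      cand <- trial(alpha)
      if (!is.null(cand)) break
      alpha <- alpha / 2
      if (alpha < 1 / 128) return(NULL)
    }
    if (st$line_search && cand$rn > 100 * max(rn, st$atol)) {
      for (a2 in c(alpha / 2, alpha / 4)) {
        c2 <- trial(a2)
        if (!is.null(c2) && c2$rn < cand$rn) cand <- c2
      }
    }
    u <- cand$u
  }
  NULL
}

fe_nonconvergence <- function(s, msg) {
  structure(class = c("fe_nonconvergence", "error", "condition"),
            list(message = sprintf(
              "solver failed to converge at load fraction %.4g: %s", s, msg),
              call = NULL, fraction = s))
}

# Run load increments with adaptive halving. `on_increment(u, s)` is called
# after each converged increment; returning TRUE stops the ramp early.
run_increments <- function(sys, fractions, on_increment = NULL) {
  u <- numeric(sys$ndof)
  log <- list()
  pending <- fractions
  s_prev <- 0
  halvings <- 0L
  while (length(pending)) {
    s <- pending[1]
    sol <- newton_solve(sys, u, s)
    if (is.null(sol)) {
      halvings <- halvings + 1L
      if (halvings > sys$settings$max_halvings)
        stop(fe_nonconvergence(s, sprintf(
          "exceeded %d increment halvings (last converged fraction %.4g)",
          sys$settings$max_halvings, s_prev)))
      pending <- c((s_prev + s) / 2, pending)
      next
    }
    u <- sol$u
    log[[length(log) + 1]] <- list(fraction = s, iterations = sol$iters,
                                   residual = sol$resnorms[length(sol$resnorms)],
                                   resnorms = sol$resnorms)
    s_prev <- s
    pending <- pending[-1]
    if (!is.null(on_increment) && isTRUE(on_increment(u, s))) break
  }
  list(u = u, log = log, last_fraction = s_prev)
}

result_fields <- function(sys, u, s) {
  str <- fe_stress_cpp(sys$mesh$nodes, sys$mesh$elems, u, sys$dirs,
                       sys$matvec)
  r_full <- residual_full(sys, u, s)
  reaction_of <- function(dofs) {
    out <- numeric(3)
    for (i in 1:3) out[i] <- sum(r_full[dofs[(dofs - 1) %% 3 + 1 == i]])
    out
  }
  fx <- reaction_of(sys$fixed)
  px <- if (length(sys$presc_dofs)) reaction_of(sys$presc_dofs) else
    c(0, 0, 0)
  list(strain = str$green, cauchy = str$cauchy, von_mises = str$von_mises,
       J = str$J, reaction_fixed = fx, reaction_prescribed = px)
}

#' Quasi-static finite element solve
#'
#' Total-Lagrangian Newton solution of a tendon mesh under the given
#' boundary conditions, with incremental loading and adaptive increment
#' halving on non-convergence.
#'
#' @param mesh a [generate_mesh()] mesh (optionally labeled / split).
#' @param fibers a [build_fiber_field()] fiber field.
#' @param material a [material_params()] object.
#' @param bcs a [boundary_conditions()] object.
#' @param settings a [solve_settings()] object.
#' @param interface_condition `"none"`, `"frictionless"`, `"tied"`, or an
#'   [apply_interface_condition()] object, for meshes processed by
#'   [split_interface()].
#' @return object of class `fe_result`: nodal displacements `u` (N x 3,
#'   mm), per-element Green-Lagrange `strain` and Cauchy stress `cauchy`
#'   (columns 11, 22, 33, 12, 13, 23), `von_mises` (MPa), `J`, reaction
#'   forces on the fixed and prescribed sets (N), and a convergence log.
#' @export
solve_fe <- function(mesh, fibers, material, bcs,
                     settings = solve_settings(),
                     interface_condition = "none") {
  sys <- build_system(mesh, fibers, material, bcs, settings,
                      interface_condition)
  fr <- seq_len(bcs$n_increments) / bcs$n_increments
  run <- run_increments(sys, fr)
  fields <- result_fields(sys, run$u, run$last_fraction)
  structure(c(list(u = matrix(run$u, ncol = 3, byrow = TRUE),
                   applied_force = run$last_fraction * c(
                     sum(sys$f_ext[seq(1, sys$ndof, 3)]),
                     sum(sys$f_ext[seq(2, sys$ndof, 3)]),
                     sum(sys$f_ext[seq(3, sys$ndof, 3)])),
                   log = do.call(rbind, lapply(run$log, function(l)
                     data.frame(fraction = l$fraction,
                                iterations = l$iterations,
                                residual = l$residual))),
                   resnorm_history = lapply(run$log, `[[`, "resnorms"),
                   converged = TRUE, mesh = mesh),
              fields),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat("Quasi-static FE solution\n")
  cat(sprintf("  %d nodes, %d elements; %d load increments\n",
              nrow(x$u), length(x$von_mises), nrow(x$log)))
  cat(sprintf("  max |u| = %.4g mm, max von Mises = %.4g MPa\n",
              max(sqrt(rowSums(x$u^2))), max(x$von_mises)))
  cat(sprintf("  reaction on fixed set: (%.4g, %.4g, %.4g) N\n",
              x$reaction_fixed[1], x$reaction_fixed[2], x$reaction_fixed[3]))
  invisible(x)
}

#' @export
summary.fe_result <- function(object, ...) {
  s <- list(n_nodes = nrow(object$u), n_elements = length(object$von_mises),
            max_displacement = max(sqrt(rowSums(object$u^2))),
            max_von_mises = max(object$von_mises),
            reaction_fixed = object$reaction_fixed,
            applied_force = object$applied_force,
            increments = nrow(object$log),
            total_iterations = sum(object$log$iterations))
  class(s) <- "summary.fe_result"
  s
}

#' @export
print.summary.fe_result <- function(x, ...) {
  cat(sprintf("FE solution summary: %d nodes / %d elements\n",
              x$n_nodes, x$n_elements))
  cat(sprintf("  increments %d (Newton iterations %d)\n",
              x$increments, x$total_iterations))
  cat(sprintf("  max displacement %.4g mm; max von Mises %.4g MPa\n",
              x$max_displacement, x$max_von_mises))
  cat(sprintf("  applied force (%.4g, %.4g, %.4g) N; fixed-set reaction (%.4g, %.4g, %.4g) N\n",
              x$applied_force[1], x$applied_force[2], x$applied_force[3],
              x$reaction_fixed[1], x$reaction_fixed[2], x$reaction_fixed[3]))
  invisible(x)
}

#' @export
plot.fe_result <- function(x, ...) {
  rn <- unlist(x$resnorm_history)
  plot(seq_along(rn), pmax(rn, .Machine$double.xmin), log = "y", type = "b",
       xlab = "cumulative Newton iteration", ylab = "residual norm (N)",
       main = "Convergence history", ...)
  invisible(x)
}
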