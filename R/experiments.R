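## In-silico experiment designs: perturbation ensembles, fiber-template
## runs, thickness/area sweeps and count-prediction fits.

#' Simulation configuration for experiment runs
#'
#' Bundles the slab, schedule, material, detection settings and solver
#' control used by the experiment drivers.  The default reproduces the base
#' model (60 x 60 mm, 1.5 mm cortex, growth to 1.8 in 100 steps); the
#' reduced "desk-scale" profile trades domain size, mesh resolution and
#' step count for runtime and is what the test suite uses.
#'
#' @param slab A \code{\link{slab_spec}}.
#' @param schedule A \code{\link{growth_schedule}}.
#' @param params A \code{\link{material_params}}.
#' @param detect A \code{\link{detect_config}}.
#' @param control A \code{\link{solve_control}}.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(slab = slab_spec(), schedule = growth_schedule(),
                       params = material_params(), detect = detect_config(),
                       control = solve_control()) {
  structure(list(slab = slab, schedule = schedule, params = params,
                 detect = detect, control = control), class = "sim_config")
}

#' Reduced-resolution configuration for desk-scale runs
#'
#' A smaller slab (default 21 x 21 mm in plane, 12 mm core), coarser growth
#' stepping and the same physics; full-scale ensembles at the base geometry
#' are an opt-in long-running job (see \code{\link{sim_config}}).  The
#' growth target 2.0 is near the edge of what the quasi-static solver
#' tracks reliably at this resolution: much past it the coarse shallow
#' slab snaps into mesh-scale creases and global modes with no nearby
#' discrete equilibrium, and step costs grow sharply.
#'
#' @param Lx,Ly,Hcore,tcortex Slab dimensions (mm).
#' @param n_steps,g_final Growth schedule.
#' @param ... Passed to \code{\link{slab_spec}}.
#' @return A \code{\link{sim_config}}.
#' @export
reduced_config <- function(Lx = 21, Ly = 21, Hcore = 12, tcortex = 1.5,
                           n_steps = 10L, g_final = 2.0, ...) {
  sim_config(
    slab = slab_spec(Lx = Lx, Ly = Ly, Hcore = Hcore, tcortex = tcortex,
                     core_layers = 5L, ...),
    schedule = growth_schedule(n_steps = n_steps, g_final = g_final))
}

# cheap structural fingerprint of a config (polynomial rolling hash over
# serialized bytes; modulus keeps exact double arithmetic)
.config_fingerprint <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 900000011
  sprintf("%08x", as.integer(h))
}

#' Simulate one model and detect its 3-hinge patterns
#'
#' Builds the slab, applies the seeded checkerboard perturbation, runs the
#' growth schedule and detects hinges on the final top surface.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Perturbation seed (selects the checkerboard frequency).
#' @param templates Optional list of \code{\link{fiber_template}}s.
#' @return List with the trajectory, the final-state hinge report, the mean
#'   cortical thickness and the member metadata.
#' @export
simulate_and_detect <- function(config, seed = 1L, templates = list()) {
  stopifnot(inherits(config, "sim_config"))
  mesh <- build_slab(config$slab)
  pert <- perturbation_spec(seed = seed)
  mesh <- apply_perturbation(mesh, pert)
  if (length(templates)) mesh <- lay_fibers(mesh, templates)
  traj <- fe_run(mesh, config$schedule, config$params, config$control,
                 record_every = max(1L, config$schedule$n_steps %/% 4L))
  ## a member whose schedule stops early (growth stepped past the reach of
  ## the quasi-static solver) is analyzed at its last converged state
  surf <- traj$surfaces[[length(traj$surfaces)]]
  report <- detect_hinges(surf, config$detect)
  th <- measure_cortical_thickness(mesh, traj$state, seed = seed)
  g_reached <- if (nrow(traj$log)) max(c(1, traj$log$g[traj$log$converged]))
  else 1
  list(trajectory = traj, report = report, thickness = th,
       omega = pert$omega, seed = seed, g_reached = g_reached,
       complete = isTRUE(traj$state$converged))
}

#' Run a perturbation ensemble
#'
#' N independent simulate-and-detect runs differing only in the
#' perturbation seed (hence the checkerboard frequency), mirroring the
#' 30-model ensemble design: all other parameters identical.  Failed
#' members are recorded and excluded from the aggregates with a warning.
#'
#' @param n Number of members (>= 2).
#' @param config A \code{\link{sim_config}}.
#' @param seeds Integer seeds, one per member (default \code{1:n}).
#' @return An object of class \code{ensemble_result}: per-member table,
#'   aggregate count statistics, a normality diagnostic and the config
#'   fingerprint.
#' @export
run_ensemble <- function(n, config = reduced_config(), seeds = seq_len(n)) {
  if (n < 2L) stop("an ensemble needs n >= 2 members", call. = FALSE)
  stopifnot(length(seeds) == n)
  members <- vector("list", n)
  ## a member counts as failed when it errors or never gets past 3/4 of the
  ## growth schedule; early-stopped members past that point are analyzed at
  ## their last converged state (mirrors dynamic runs ending at slightly
  ## different times)
  g_min <- 1 + 0.75 * (config$schedule$g_final - 1)
  for (m in seq_len(n)) {
    res <- tryCatch(simulate_and_detect(config, seed = seeds[m]),
                    error = function(e) e)
    if (inherits(res, "error") || res$g_reached < g_min) {
      warning(sprintf("ensemble member %d (seed %d) failed; excluded",
                      m, seeds[m]))
      members[[m]] <- list(seed = seeds[m], failed = TRUE)
    } else {
      members[[m]] <- list(seed = seeds[m], failed = FALSE,
                           omega = res$omega, count = res$report$count,
                           centers = hinge_centers(res$report),
                           thickness = res$thickness$mean,
                           g_reached = res$g_reached,
                           complete = res$complete)
    }
  }
  ok <- !vapply(members, `[[`, TRUE, "failed")
  counts <- vapply(members[ok], `[[`, 0, "count")
  shapiro_p <- if (sum(ok) >= 3 && stats::sd(counts) > 0)
    tryCatch(stats::shapiro.test(counts)$p.value, error = function(e) NA_real_)
  else NA_real_
  structure(list(
    members = members,
    counts = counts,
    mean = mean(counts), sd = stats::sd(counts),
    min = min(counts), max = max(counts),
    mean_thickness = mean(vapply(members[ok], `[[`, 0, "thickness")),
    shapiro_p = shapiro_p,
    area_mm2 = config$slab$Lx * config$slab$Ly,
    seeds = seeds, fingerprint = .config_fingerprint(config)),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "Ensemble: %d members, counts %d-%d (mean %.1f, sd %.2f), area %.0f mm2\n",
    length(x$counts), x$min, x$max, x$mean, x$sd, x$area_mm2))
  invisible(x)
}

#' Fiber-guided hinge placement experiment
#'
#' For each seed, runs a model with the fiber templates embedded and a
#' companion no-fiber control, and reports whether a 3-hinge is detected
#' within the capture radius of each template junction, with center offset
#' and spoke-direction angular error for captured hinges.
#'
#' @param templates List of \code{\link{fiber_template}}s.
#' @param seeds Integer perturbation seeds (>= 1 member each).
#' @param config A \code{\link{sim_config}}.
#' @param capture_radius Match radius around the template junction (mm).
#' @return Data frame, one row per (seed, template, arm) with columns
#'   \code{captured}, \code{offset_mm}, \code{angle_err_deg}.
#' @export
run_fiber_experiment <- function(templates, seeds,
                                 config = reduced_config(),
                                 capture_radius = 5) {
  stopifnot(length(templates) >= 1L, length(seeds) >= 1L)
  rows <- list()
  for (s in seeds) {
    for (arm in c("fiber", "control")) {
      res <- simulate_and_detect(config, seed = s,
                                 templates = if (arm == "fiber") templates
                                 else list())
      centers <- hinge_centers(res$report)
      for (ti in seq_along(templates)) {
        tm <- templates[[ti]]
        if (nrow(centers) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            seed = s, template = ti, arm = arm, captured = FALSE,
            offset_mm = NA_real_, angle_err_deg = NA_real_)
          next
        }
        d <- sqrt((centers[, 1] - tm$junction[1])^2 +
                    (centers[, 2] - tm$junction[2])^2)
        best <- which.min(d)
        captured <- d[best] <= capture_radius
        ang <- NA_real_
        if (captured) {
          hd <- res$report$hinges[[best]]$directions[, 1:2, drop = FALSE]
          td <- t(vapply(tm$spokes, function(sp) {
            v <- sp[nrow(sp), ] - sp[1, ]
            v / max(sqrt(sum(v^2)), 1e-12)
          }, numeric(2)))
          ## greedy spoke matching on in-plane angles
          hn <- hd / pmax(sqrt(rowSums(hd^2)), 1e-12)
          errs <- numeric(3)
          used <- logical(3)
          for (k in 1:3) {
            cosang <- hn %*% td[k, ]
            cosang[used] <- -Inf
            j <- which.max(cosang)
            used[j] <- TRUE
            errs[k] <- acos(pmin(1, pmax(-1, cosang[j]))) * 180 / pi
          }
          ang <- mean(errs)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, template = ti, arm = arm, captured = captured,
          offset_mm = if (captured) d[best] else NA_real_,
          angle_err_deg = ang)
      }
    }
  }
  do.call(rbind, rows)
}

#' Thickness/area sweep of 3-hinge counts
#'
#' For each (cortical thickness, in-plane side length) pair: simulate,
#' detect, count hinges inside a central patch (clipped to the domain, so
#' edge effects are lessened), and record hinge density and the final mean
#' cortical thickness.  A least-squares trend \eqn{count = area (a/t + b)}
#' is fitted (count linear in area, inverse-affine in thickness, matching
#' the analytic result that fold number scales with size over thickness).
#'
#' @param t_values Initial cortical thicknesses (mm), >= 2 values.
#' @param side_values In-plane side lengths (mm), square slabs.
#' @param config Base \code{\link{sim_config}} (slab t and size overridden).
#' @param patch_side Central counting patch side (mm; clipped to domain).
#' @param seed Perturbation seed shared by all runs.
#' @return An object of class \code{sweep_result} with the grid data frame
#'   and fitted trend coefficients.
#' @export
run_thickness_area_sweep <- function(t_values, side_values,
                                     config = reduced_config(),
                                     patch_side = 60, seed = 1L) {
  if (length(t_values) < 2L)
    stop("need at least 2 thickness values", call. = FALSE)
  grid <- expand.grid(t = t_values, side = side_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    t <- grid$t[r]; side <- grid$side[r]
    cfg <- config
    cfg$slab <- slab_spec(Lx = side, Ly = side, Hcore = cfg$slab$Hcore,
                          tcortex = t, dx = cfg$slab$dx * t / cfg$slab$tcortex,
                          cortex_layers = cfg$slab$cortex_layers,
                          core_layers = cfg$slab$core_layers,
                          grading = cfg$slab$grading)
    res <- simulate_and_detect(cfg, seed = seed)
    centers <- hinge_centers(res$report)
    ## clip to the central square patch; set semantics on hinge ids means
    ## each center is counted at most once
    ps <- min(patch_side, side)
    lo <- (side - ps) / 2; hi <- side - lo
    inpatch <- if (nrow(centers)) {
      centers[, 1] >= lo & centers[, 1] <= hi &
        centers[, 2] >= lo & centers[, 2] <= hi
    } else logical(0)
    rows[[r]] <- data.frame(
      t = t, side = side, area_mm2 = side^2,
      count_total = res$report$count,
      count_patch = sum(inpatch),
      patch_area_mm2 = ps^2,
      density_per_cm2 = sum(inpatch) / (ps^2 / 100),
      final_thickness = res$thickness$mean)
  }
  data <- do.call(rbind, rows)
  ## least-squares fit: count_patch = patch_area * (a / t + b)
  X <- cbind(data$patch_area_mm2 / data$t, data$patch_area_mm2)
  fit <- stats::lm.fit(X, data$count_patch)
  coefs <- stats::setNames(fit$coefficients, c("a", "b"))
  ## final thickness vs initial thickness linear trend
  tfit <- stats::lm(final_thickness ~ t, data = data)
  structure(list(data = data, coef = coefs,
                 thickness_fit = stats::coef(tfit),
                 thickness_r2 = summary(tfit)$r.squared,
                 t_range = range(t_values),
                 area_range = range(data$patch_area_mm2),
                 seed = seed,
                 fingerprint = .config_fingerprint(config)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "Thickness/area sweep: %d runs, count ~ area*(%.4g/t + %.4g), R2(thickness) = %.3f\n",
    nrow(x$data), x$coef["a"], x$coef["b"], x$thickness_r2))
  invisible(x)
}

#' Predict the 3-hinge count from initial geometry
#'
#' Evaluates the fitted trend \eqn{count = area (a/t + b)} at a query
#' cortical thickness and smooth-state surface area; only the initial
#' geometric parameters are needed, no simulation of the queried brain.
#' Queries outside the fitted hull are flagged as extrapolation (and
#' rejected beyond twice the fitted range).
#'
#' @param area_cm2 Smooth-state cortical surface area (cm^2).
#' @param tcortex Initial cortical thickness (mm).
#' @param fit A \code{\link{run_thickness_area_sweep}} result.
#' @return List with \code{count} and \code{extrapolated}.
#' @export
predict_count <- function(area_cm2, tcortex, fit) {
  if (!inherits(fit, "sweep_result")) stop("'fit' must be a sweep_result",
                                           call. = FALSE)
  area_mm2 <- area_cm2 * 100
  extrap <- tcortex < fit$t_range[1] || tcortex > fit$t_range[2] ||
    area_mm2 < fit$area_range[1] || area_mm2 > fit$area_range[2]
  if (tcortex < fit$t_range[1] / 2 || tcortex > fit$t_range[2] * 2 ||
      area_mm2 > fit$area_range[2] * 4)
    warning("query far outside the fitted range; prediction unreliable")
  count <- area_mm2 * (fit$coef["a"] / tcortex + fit$coef["b"])
  list(count = unname(count), extrapolated = extrap)
}
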