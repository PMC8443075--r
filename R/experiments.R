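# Scripted reproduction of the study design: ring variants x mechanical
# modes x corneal thicknesses, with per-run curvature summaries and the
# thickness/base sensitivity table.

#' Configure a simulation study
#'
#' The default grid runs the four [study_designs()] at the 0/80/160 deg arc
#' stations in both mechanical modes on the standard 550-um cornea, plus the
#' asymmetric design on the thin 450-um cornea in the axisymmetric mode.
#'
#' @param designs named list of [ring_design()] objects.
#' @param angles angular stations, degrees.
#' @param modes character subset of `c("axisymmetric", "plane_strain")`.
#' @param cct_standard,cct_thin central thicknesses, um; set `cct_thin = NULL`
#'   to drop the thin-cornea runs.
#' @param thin_designs design names run on the thin cornea.
#' @param density a [mesh_density()].
#' @param tunnel a [tunnel_spec()].
#' @param n_index keratometric index for post-processing.
#' @return object of class `study_config`.
#' @export
study_config <- function(designs = study_designs(),
                         angles = c(0, 80, 160),
                         modes = c("axisymmetric", "plane_strain"),
                         cct_standard = 550, cct_thin = 450,
                         thin_designs = "asymmetric",
                         density = mesh_density(),
                         tunnel = tunnel_spec(),
                         n_index = 1.3375) {
  structure(list(designs = designs, angles = angles, modes = modes,
                 cct_standard = cct_standard, cct_thin = cct_thin,
                 thin_designs = thin_designs, density = density,
                 tunnel = tunnel, n_index = n_index),
            class = "study_config")
}

#' Run the full simulation study
#'
#' Executes [simulate_implantation()] and [curvature_analysis()] for every
#' (design, angle, mode, cornea) combination of the configuration.  Pre-op
#' solves and meshes are shared across angles and designs of the same
#' (mode, cornea).  The pipeline contains no randomness, so re-running
#' reproduces the table bit for bit.  Individual run failures are recorded
#' (`ok = FALSE`) and the study continues.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, per-run curvature CSVs and
#'   the result table are written there.
#' @param quiet suppress progress messages.
#' @return tibble of class `study_result`, one row per run, with the design
#'   parameters at that station and the curvature summaries (dioptres):
#'   `central_delta`, `zone4_delta`, `peripheral_delta`, `bfs_delta`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      quiet = TRUE) {
  runs <- data.frame()
  for (mode in config$modes)
    for (nm in names(config$designs))
      runs <- rbind(runs, data.frame(design = nm, angle = config$angles,
                                     mode = mode,
                                     cct = config$cct_standard))
  if (!is.null(config$cct_thin))
    for (nm in intersect(config$thin_designs, names(config$designs)))
      runs <- rbind(runs, data.frame(design = nm, angle = config$angles,
                                     mode = "axisymmetric",
                                     cct = config$cct_thin))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cache <- new.env(parent = emptyenv())
  get_pre <- function(mode, cct) {
    key <- paste(mode, cct)
    if (is.null(cache[[key]])) {
      geo <- cornea_geometry(cct = cct)
      mesh <- generate_mesh(geo, config$tunnel, config$density, mode)
      lc <- load_case(pressure = c(posterior_surface = 15 * MMHG_TO_KPA),
                      prestrain = prestrain_field())
      cache[[key]] <- list(mesh = mesh,
                           preop = solve_static(mesh, default_materials(),
                                                lc, cornea_constraints(mesh)))
    }
    cache[[key]]
  }
  rows <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    design <- config$designs[[r$design]]
    if (!quiet)
      message(sprintf("run %d/%d: %s @ %g deg, %s, cct %g",
                      i, nrow(runs), r$design, r$angle, r$mode, r$cct))
    res <- tryCatch({
      pre <- get_pre(r$mode, r$cct)
      sim <- simulate_implantation(design = design, angle = r$angle,
                                   mode = r$mode, tunnel = config$tunnel,
                                   density = config$density,
                                   mesh = pre$mesh, preop = pre$preop)
      ca <- curvature_analysis(sim, n_index = config$n_index)
      cs <- sim$imposition$cross_section
      if (!is.null(out_dir))
        write_curvature_csv(ca$delta, file.path(out_dir, sprintf(
          "delta_%s_%gdeg_%s_cct%g.csv", r$design, r$angle, r$mode, r$cct)))
      tibble::tibble(
        design = r$design, angle = r$angle, mode = r$mode, cct = r$cct,
        thickness_um = cs$thickness, base_um = cs$base,
        central_delta = ca$summary$central_delta,
        zone4_delta = ca$summary$zone_mean_delta,
        peripheral_delta = ca$summary$peripheral_delta,
        peripheral_x = ca$summary$peripheral_x,
        bfs_delta = ca$bfs[["delta"]],
        ring_settle_mm = sim$postop$masters[[1]][["ty"]],
        residual = sim$postop$residual_rel, ok = TRUE, error = NA_character_)
    }, error = function(e)
      tibble::tibble(design = r$design, angle = r$angle, mode = r$mode,
                     cct = r$cct, thickness_um = NA_real_,
                     base_um = NA_real_, central_delta = NA_real_,
                     zone4_delta = NA_real_, peripheral_delta = NA_real_,
                     peripheral_x = NA_real_, bfs_delta = NA_real_,
                     ring_settle_mm = NA_real_, residual = NA_real_,
                     ok = FALSE, error = conditionMessage(e)))
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_result", class(out))
  if (!is.null(out_dir))
    utils::write.csv(as.data.frame(out), file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  out
}

#' Flattening sensitivity to ring thickness and base width
#'
#' Least-squares slope of the flattening magnitude against the varied
#' parameter over the thickness-only and base-only sweeps, averaged over the
#' central and peripheral summaries, in D/um.
#'
#' @param table a [run_study()] result containing `thickness_only` and
#'   `base_only` runs in the axisymmetric mode.
#' @param endpoints_only use only the two sweep ends (two-point finite
#'   difference) instead of the least-squares fit.
#' @return tibble with `dD_dthickness` and `dD_dwidth` (D/um).
#' @export
sensitivity_summary <- function(table, endpoints_only = FALSE) {
  slope <- function(x, y) {
    if (endpoints_only) {
      i <- which.min(x); j <- which.max(x)
      (y[j] - y[i]) / (x[j] - x[i])
    } else stats::coef(stats::lm(y ~ x))[["x"]]
  }
  sweep_slope <- function(design, var) {
    d <- table[table$design == design & table$mode == "axisymmetric" &
                 table$cct == max(table$cct) & table$ok, ]
    if (nrow(d) < 2) stop(sprintf("missing %s sweep", design))
    x <- d[[var]]
    mean(c(abs(slope(x, abs(d$central_delta))),
           abs(slope(x, abs(d$peripheral_delta)))))
  }
  tibble::tibble(
    dD_dthickness = sweep_slope("thickness_only", "thickness_um"),
    dD_dwidth = sweep_slope("base_only", "base_um"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a study result
#'
#' One row per successful run with the design parameters and the dioptric
#' summaries.
#'
#' @param x a `study_result`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) {
  out <- x[x$ok, c("design", "angle", "mode", "cct", "thickness_um",
                   "base_um", "central_delta", "zone4_delta",
                   "peripheral_delta", "bfs_delta")]
  class(out) <- class(tibble::tibble())
  out
}

#' Glance at a study result
#'
#' @param x a `study_result`.
#' @param ... unused.
#' @return one-row tibble with run counts and the sensitivity summary.
#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  sens <- tryCatch(sensitivity_summary(x),
                   error = function(e) tibble::tibble(
                     dD_dthickness = NA_real_, dD_dwidth = NA_real_))
  tibble::tibble(
    n_runs = nrow(x), n_failed = sum(!x$ok),
    max_flattening = min(x$peripheral_delta, na.rm = TRUE),
    dD_dthickness = sens$dD_dthickness, dD_dwidth = sens$dD_dwidth)
}
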