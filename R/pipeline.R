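# Study orchestration: synthetic concentration-series runs, reporting
# and protocol comparison.

REPORT_SCHEMA_VERSION <- "1"

fnv1a_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

study_config_defaults <- function() {
  list(
    compositions = list(c(2, 60), c(4, 40), c(6, 20)),
    sugar_kind = "sucrose",
    protocol = "not_preheated",
    cell = 4.0,
    n_frames = 4L,
    criterion = list(dist = 0.35, angle = 30),
    seed = 1L,
    analyses = c("hbond", "crossings", "tau", "free_energy"),
    tau = list(n_vectors = 60L, n_steps = 1500L, dt = 0.1,
               D_r_dilute = 0.2, D_r_dry = 0.02),
    free_energy = list(barrier = 10, minima = c(0.4, 1.2),
                       n_windows = 22L, force_constant = 45,
                       steps_per_window = 4000L, boundary = NULL,
                       temperature = 298),
    output_dir = NULL
  )
}

#' Validate a study configuration
#'
#' Fills defaults and rejects unknown keys by name. Configurations can be
#' R lists or YAML files (see [read_study_config()]).
#'
#' @param config named list of settings; see
#'   `study_config_defaults()` in the package source for the full key set
#'   (`compositions` as (n_sugar, n_water) pairs, `sugar_kind`,
#'   `protocol`, `cell`, `n_frames`, `criterion`, `seed`, `analyses`,
#'   `tau`, `free_energy`, `output_dir`).
#' @return Validated config (class `study_config`).
#' @export
study_config <- function(config = list()) {
  defaults <- study_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  for (nested in c("criterion", "tau", "free_energy")) {
    if (!is.null(config[[nested]])) {
      bad <- setdiff(names(config[[nested]]), names(defaults[[nested]]))
      if (length(bad) > 0L) {
        stop("validation error: unknown key(s) in '", nested, "': ",
             paste(bad, collapse = ", "))
      }
      defaults[[nested]][names(config[[nested]])] <- config[[nested]]
      config[[nested]] <- NULL
    }
  }
  defaults[names(config)] <- config
  defaults$protocol <- match.arg(defaults$protocol,
                                 c("not_preheated", "preheated", "n/a"))
  defaults$sugar_kind <- match.arg(defaults$sugar_kind, c("sucrose", "trehalose"))
  known_analyses <- c("hbond", "crossings", "tau", "free_energy")
  bad <- setdiff(defaults$analyses, known_analyses)
  if (length(bad) > 0L) {
    stop("validation error: unknown analysis: ", paste(bad, collapse = ", "))
  }
  structure(defaults, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose top-level keys follow [study_config()].
#' @return Validated `study_config`.
#' @export
read_study_config <- function(path) {
  study_config(yaml::read_yaml(path))
}

# Synthetic emulation of concentration-dependent OH rotational slowdown:
# rotational diffusion interpolated between a dry and a dilute
# coefficient (rad^2/ps) on the water-mass fraction.
tau_model_D_r <- function(water_mass_pct, tau_cfg) {
  f <- water_mass_pct / 100
  tau_cfg$D_r_dry + (tau_cfg$D_r_dilute - tau_cfg$D_r_dry) * f
}

#' Run the synthetic concentration-series study
#'
#' For every composition in the config, builds a synthetic mixture
#' trajectory (protocol-aware: preheated packs sugars clustered), runs
#' the enabled analyses and collects per-concentration tables:
#' hydrogen-bond categories (per total oxygen), curve crossing points,
#' OH rotational correlation times from the concentration-dependent
#' diffusion emulator, and a sandbox free-energy stage (umbrella WHAM +
#' well-tempered metadynamics on a double-well model potential, with
#' binding free energies). Deterministic under the config seed. A failing
#' stage is recorded in `$failures` and the remaining stages continue.
#'
#' @param config a [study_config()] (or plain list passed through it).
#' @return A `study_report`: list of tables plus a provenance block
#'   (config hash, seed, package version, schema version).
#' @export
run_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  seed <- config$seed
  crit <- hbond_criterion(config$criterion$dist, config$criterion$angle)
  failures <- character()
  series_list <- list()
  tau_rows <- list()

  comps <- lapply(config$compositions, function(cw) composition_spec(cw[1L], cw[2L]))
  hbond_tab <- NULL
  if ("hbond" %in% config$analyses) {
    res <- tryCatch({
      for (i in seq_along(comps)) {
        traj <- toy_mixture_trajectory(
          comps[[i]], n_frames = config$n_frames,
          spec = synthetic_spec(seed = derive_seed(seed, paste0("mix", i)),
                                cell = config$cell),
          sugar_kind = config$sugar_kind, protocol = config$protocol)
        series_list[[i]] <- count_series(traj, crit, "per_total_oxygen")
      }
      hbond_concentration_table(series_list)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste("hbond:", conditionMessage(res)))
    } else hbond_tab <- res
  }

  crossings <- NULL
  if ("crossings" %in% config$analyses && !is.null(hbond_tab)) {
    res <- tryCatch({
      wide <- split(hbond_tab, hbond_tab$category)
      grids <- lapply(wide, function(d) d[order(d$water_mass_pct), ])
      x <- grids[[1L]]$water_mass_pct
      if (length(x) >= 2L) {
        list(ww_vs_sw = crossing_points(x, grids[["water-water"]]$mean,
                                        grids[["sugar-water"]]$mean),
             ww_vs_ss = crossing_points(x, grids[["water-water"]]$mean,
                                        grids[["sugar-sugar"]]$mean))
      } else NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste("crossings:", conditionMessage(res)))
    } else crossings <- res
  }

  tau_tab <- NULL
  if ("tau" %in% config$analyses) {
    res <- tryCatch({
      slow <- if (identical(config$protocol, "preheated")) 0.7 else 1.0
      for (i in seq_along(comps)) {
        D_r <- tau_model_D_r(comps[[i]]$water_mass_pct, config$tau) * slow
        ser <- rotational_diffusion_vectors(
          config$tau$n_vectors, D_r, config$tau$dt, config$tau$n_steps,
          seed = derive_seed(seed, paste0("tau", i)))
        fit <- correlation_time(ser)
        tau_rows[[i]] <- data.frame(
          water_mass_pct = comps[[i]]$water_mass_pct,
          D_r = D_r, tau = fit$tau, converged = fit$converged)
      }
      do.call(rbind, tau_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste("tau:", conditionMessage(res)))
    } else tau_tab <- res
  }

  fe <- NULL
  if ("free_energy" %in% config$analyses) {
    res <- tryCatch({
      fcfg <- config$free_energy
      pot <- model_potential("double_well", barrier = fcfg$barrier,
                             minima = fcfg$minima)
      # bound state: the contact well; unbound: the separated well.
      # The dividing surface defaults to the barrier top between the two
      # minima (the double-well analogue of a fixed bound-state radius).
      boundary <- fcfg$boundary %||% mean(fcfg$minima)
      centers <- seq(fcfg$minima[1L] - 0.1, fcfg$minima[2L] + 0.25,
                     length.out = fcfg$n_windows)
      windows <- sample_umbrella_windows(
        pot, centers, force_constant = fcfg$force_constant,
        n_steps = fcfg$steps_per_window,
        temperature = fcfg$temperature,
        seed = derive_seed(seed, "umbrella"))
      pmf_us <- wham_pmf(windows)
      run <- langevin_1d(pot, temperature = fcfg$temperature, dt = 5e-4,
                         n_steps = 2e5,
                         seed = derive_seed(seed, "metad"),
                         bias = wtmetad_bias(grid_min = fcfg$minima[1L] - 0.3,
                                             grid_max = fcfg$minima[2L] + 0.5))
      pmf_mtd <- metad_fes(run$hills, estimator = "time_average",
                           z_grid = seq(fcfg$minima[1L] - 0.1,
                                        fcfg$minima[2L] + 0.2, by = 0.005))
      dg_us <- binding_free_energy(pmf_us, boundary, fcfg$temperature)
      dg_mtd <- binding_free_energy(pmf_mtd, boundary, fcfg$temperature)
      depth <- pmf_depth_report(list(umbrella = pmf_us, metadynamics = pmf_mtd))
      list(dG_umbrella = dg_us$dG, dG_metadynamics = dg_mtd$dG,
           depth_table = depth$table, depth_sum = depth$depth_sum)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste("free_energy:", conditionMessage(res)))
    } else fe <- res
  }

  structure(list(
    hbond = hbond_tab, crossings = crossings, tau = tau_tab,
    free_energy = fe, failures = failures,
    provenance = list(
      schema_version = REPORT_SCHEMA_VERSION,
      config_hash = fnv1a_hash(unclass(config)),
      seed = seed, protocol = config$protocol,
      sugar_kind = config$sugar_kind,
      package_version = as.character(utils::packageVersion("sugarglass")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report [%s, %s] seed %d, config %s\n",
              x$provenance$sugar_kind, x$provenance$protocol,
              x$provenance$seed, x$provenance$config_hash))
  if (!is.null(x$hbond)) {
    cat(sprintf("  hbond table: %d rows over %d concentrations\n",
                nrow(x$hbond), length(unique(x$hbond$water_mass_pct))))
  }
  if (!is.null(x$tau)) cat(sprintf("  tau table: %d rows\n", nrow(x$tau)))
  if (!is.null(x$free_energy)) {
    cat(sprintf("  sandbox dG: umbrella %.3f, metadynamics %.3f kJ/mol\n",
                x$free_energy$dG_umbrella, x$free_energy$dG_metadynamics))
  }
  if (length(x$failures) > 0L) {
    cat("  FAILED stages:\n"); for (f in x$failures) cat("   -", f, "\n")
  }
  invisible(x)
}

#' Serialise / restore a study report as JSON
#'
#' The JSON form round-trips losslessly at full double precision.
#'
#' @param report a `study_report`.
#' @param path output / input file.
#' @return `write_study_report()` returns `path` invisibly;
#'   `read_study_report()` the restored report.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_study_report
#' @export
read_study_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("hbond", "tau")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.data.frame(raw[[nm]])
  }
  if (!is.null(raw$free_energy$depth_table)) {
    raw$free_energy$depth_table <- as.data.frame(raw$free_energy$depth_table)
  }
  raw$failures <- as.character(raw$failures %||% character())
  structure(raw, class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two study reports
#'
#' Delegates to [difference_profile()] for the hydrogen-bond tables and
#' subtracts correlation times on the matched concentration grid, then
#' derives a conclusions table stating which quantity is higher under
#' which report (the shape of a protocol-comparison summary).
#'
#' @param report_a,report_b `study_report` objects on matched composition
#'   grids (conventionally A = not preheated, B = preheated).
#' @return List with `hbond_diff` (A - B), `tau_diff`, and `conclusions`.
#' @export
compare_protocols <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "study_report"), inherits(report_b, "study_report"))
  hb <- NULL
  if (!is.null(report_a$hbond) && !is.null(report_b$hbond)) {
    hb <- difference_profile(report_a$hbond, report_b$hbond)
  }
  tau <- NULL
  if (!is.null(report_a$tau) && !is.null(report_b$tau)) {
    a <- report_a$tau[order(report_a$tau$water_mass_pct), ]
    b <- report_b$tau[order(report_b$tau$water_mass_pct), ]
    if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$water_mass_pct, b$water_mass_pct))) {
      stop("alignment error: tau concentration grids differ")
    }
    tau <- data.frame(water_mass_pct = a$water_mass_pct,
                      delta_tau = a$tau - b$tau)
  }
  conclusions <- NULL
  if (!is.null(hb)) {
    agg <- stats::aggregate(delta ~ category, data = hb, FUN = mean)
    conclusions <- data.frame(
      quantity = paste("hydrogen bonds:", agg$category),
      higher_in = ifelse(agg$delta > 0, "A",
                         ifelse(agg$delta < 0, "B", "equal")),
      mean_difference = agg$delta, stringsAsFactors = FALSE)
    if (!is.null(tau)) {
      m <- mean(tau$delta_tau, na.rm = TRUE)
      conclusions <- rbind(conclusions, data.frame(
        quantity = "OH rotational correlation time",
        higher_in = ifelse(m > 0, "A", ifelse(m < 0, "B", "equal")),
        mean_difference = m))
    }
  }
  list(hbond_diff = hb, tau_diff = tau, conclusions = conclusions)
}

#' Write the study tables as TSV files
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_study_tables <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  emit <- function(tab, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(report$hbond)) emit(report$hbond, "hbond")
  if (!is.null(report$tau)) emit(report$tau, "tau")
  if (!is.null(report$free_energy$depth_table)) {
    emit(report$free_energy$depth_table, "pmf_depths")
  }
  invisible(written)
}
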