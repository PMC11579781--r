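# Synthetic systems: every analysis input with known ground truth.

# Evaluate expr with a private, reproducible RNG stream; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic child seed for a named stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(stage, ":", seed))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Specification for a synthetic system
#'
#' @param seed integer RNG seed; identical specs produce identical output.
#' @param n_molecules number of molecules (meaning depends on generator).
#' @param cell box edge lengths in nm (scalar = cubic), see [unit_cell()].
#' @param D_r rotational diffusion coefficient in rad^2/ps, used by
#'   [rotational_diffusion_vectors()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_molecules = 100L, cell = 5, D_r = NA_real_) {
  structure(list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
                 cell = unit_cell(cell), D_r = D_r),
            class = "synthetic_spec")
}

#' Analytic 1D model potential
#'
#' Supported forms: `harmonic` (0.5 k (z - z0)^2), `double_well`
#' (quartic with stated barrier height at the midpoint and zeros at the
#' two minima), `flat`, and `tabulated` (linear interpolation of supplied
#' values).
#'
#' @param form one of `"harmonic"`, `"double_well"`, `"flat"`, `"tabulated"`.
#' @param k,z0 harmonic force constant (kJ/(mol nm^2)) and center (nm).
#' @param barrier double-well barrier height (kJ/mol).
#' @param minima length-2 vector with the two minima positions (nm).
#' @param grid,values tabulated abscissae (nm) and energies (kJ/mol).
#' @return An object of class `model_potential` with `$value(z)` and
#'   `$force(z)` functions.
#' @export
model_potential <- function(form = c("harmonic", "double_well", "flat", "tabulated"),
                            k = 100, z0 = 0, barrier = 10, minima = c(0.4, 1.2),
                            grid = NULL, values = NULL) {
  form <- match.arg(form)
  obj <- switch(form,
    flat = list(value = function(z) rep(0, length(z)),
                force = function(z) rep(0, length(z)),
                params = list()),
    harmonic = list(value = function(z) 0.5 * k * (z - z0)^2,
                    force = function(z) -k * (z - z0),
                    params = list(k = k, z0 = z0)),
    double_well = {
      stopifnot(length(minima) == 2L, minima[2] > minima[1], barrier > 0)
      ctr <- mean(minima); a <- diff(minima) / 2
      list(value = function(z) {
             u <- z - ctr; barrier * (u^2 - a^2)^2 / a^4
           },
           force = function(z) {
             u <- z - ctr; -barrier * 4 * u * (u^2 - a^2) / a^4
           },
           params = list(barrier = barrier, center = ctr, half_sep = a,
                         minima = minima))
    },
    tabulated = {
      stopifnot(!is.null(grid), !is.null(values), length(grid) == length(values),
                length(grid) >= 2L, all(diff(grid) > 0))
      dz <- diff(grid)
      fmid <- -diff(values) / dz
      fgrid <- c(fmid[1L], (fmid[-1L] + fmid[-length(fmid)]) / 2, fmid[length(fmid)])
      list(value = function(z) approx(grid, values, z, rule = 2)$y,
           force = function(z) approx(grid, fgrid, z, rule = 2)$y,
           params = list(grid = grid, values = values, fgrid = fgrid))
    })
  structure(c(obj, list(form = form)), class = "model_potential")
}

#' Ideal-gas configuration
#'
#' Single-atom "molecules" placed i.i.d. uniformly in the cell: the exact
#' homogeneous reference for which g(r) = 1 at all distances.
#'
#' @param spec a [synthetic_spec()] (uses `seed`, `n_molecules`, `cell`).
#' @return List with `topology` and `frame`.
#' @export
ideal_gas_config <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_molecules >= 2L)
  n <- spec$n_molecules
  pos <- with_seed(spec$seed, {
    matrix(runif(3L * n), ncol = 3L) %*% diag(as.numeric(spec$cell))
  })
  atoms <- data.frame(name = rep("X", n), element = rep("X", n),
                      mass = rep(1, n), mol_index = seq_len(n) - 1L,
                      mol_kind = rep("model", n), stringsAsFactors = FALSE)
  list(topology = topology(atoms), frame = frame(0, pos, spec$cell))
}

# Random rotation matrix from a uniform quaternion (RNG state of caller).
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

# Unit vector orthogonal to u (caller's RNG).
random_perpendicular <- function(u) {
  repeat {
    v <- rnorm(3L)
    v <- v - sum(v * u) * u
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

#' Planted hydrogen-bond configuration
#'
#' Places `n_pairs` donor/acceptor model molecules on a lattice, each pair
#' with the prescribed O...O distance and H-D-A angle, far enough apart
#' that no cross-pair bonds can form. The expected detector count is known
#' by construction: `n_pairs` when the geometry satisfies the criterion,
#' zero otherwise. Donor oxygens are deliberately left off the acceptor
#' list so each planted pair contributes exactly one candidate bond.
#'
#' @param n_pairs number of donor-acceptor pairs.
#' @param d_OO donor-acceptor oxygen distance in nm.
#' @param angle_deg H-D-A angle in degrees (0 = perfectly linear O-H...O).
#' @param spec a [synthetic_spec()]; its cell must allow a lattice spacing
#'   of at least `min_separation` between pairs.
#' @param min_separation minimum distance between atoms of different pairs
#'   (nm); must exceed twice any detection cutoff in use.
#' @return List with `topology` and `frame`.
#' @export
planted_hbond_config <- function(n_pairs, d_OO = 0.28, angle_deg = 0,
                                 spec = synthetic_spec(), min_separation = 0.8) {
  stopifnot(n_pairs >= 1L)
  L <- as.numeric(spec$cell)
  n_side <- ceiling(n_pairs^(1 / 3))
  spacing <- min(L) / n_side
  extent <- d_OO + 0.1
  if (spacing - extent < min_separation) {
    stop("packing error: cell too small for ", n_pairs,
         " pairs at min separation ", min_separation, " nm")
  }
  oh <- 0.1 # donor O-H bond length, nm
  with_seed(spec$seed, {
    atoms <- list(); pos <- list()
    bonds <- NULL; donors <- NULL; acceptors <- integer()
    idx <- 0L
    grid_pts <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                      z = seq_len(n_side)))[seq_len(n_pairs), , drop = FALSE]
    centers <- (grid_pts - 0.5) * spacing
    for (p in seq_len(n_pairs)) {
      u <- rnorm(3L); u <- u / sqrt(sum(u^2))      # D -> A direction
      e <- random_perpendicular(u)
      w <- cos(angle_deg * pi / 180) * u + sin(angle_deg * pi / 180) * e # D -> H
      dO <- centers[p, ]
      hpos <- dO + oh * w
      aO <- dO + d_OO * u
      pos[[p]] <- rbind(dO, hpos, aO)
      atoms[[p]] <- data.frame(
        name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
        mass = c(15.999, 1.008, 15.999),
        mol_index = c(2L * (p - 1L), 2L * (p - 1L), 2L * p - 1L),
        mol_kind = "model", stringsAsFactors = FALSE)
      bonds <- rbind(bonds, c(idx, idx + 1L))
      donors <- rbind(donors, c(idx, idx + 1L))
      acceptors <- c(acceptors, idx + 2L)
      idx <- idx + 3L
    }
    top <- topology(do.call(rbind, atoms), bonds = bonds, donor_groups = donors,
                    acceptor_atoms = acceptors)
    list(topology = top, frame = frame(0, do.call(rbind, pos), spec$cell))
  })
}

#' Unit vectors under isotropic rotational diffusion
#'
#' Evolves `n_vectors` unit vectors by small random rotations with angular
#' variance `2 * D_r * dt` about each of two random transverse axes per
#' step, so the first-rank orientational autocorrelation has expectation
#' `exp(-2 * D_r * t)` and correlation time `tau = 1 / (2 * D_r)`.
#'
#' @param n_vectors number of independent vectors.
#' @param D_r rotational diffusion coefficient (rad^2/ps).
#' @param dt time step (ps); requires `D_r * dt <= 0.1` for stability.
#' @param n_steps number of steps (the series has `n_steps + 1` frames).
#' @param seed RNG seed.
#' @return An `orientation_series`: list with `time` (ps) and `vectors`,
#'   an array of dim (frames, vectors, 3).
#' @export
rotational_diffusion_vectors <- function(n_vectors, D_r, dt, n_steps, seed = 1L) {
  stopifnot(n_vectors >= 1L, D_r >= 0, dt > 0, n_steps >= 1L)
  if (D_r * dt > 0.1) {
    stop("stability error: D_r * dt = ", signif(D_r * dt, 3),
         " exceeds 0.1; reduce the time step")
  }
  out <- array(NA_real_, dim = c(n_steps + 1L, n_vectors, 3L))
  with_seed(seed, {
    u <- matrix(rnorm(3L * n_vectors), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    out[1L, , ] <- u
    if (D_r == 0) {
      for (t in seq_len(n_steps)) out[t + 1L, , ] <- u
    } else {
      s <- sqrt(2 * D_r * dt)
      for (t in seq_len(n_steps)) {
        # random transverse frame per vector
        v <- matrix(rnorm(3L * n_vectors), ncol = 3L)
        v <- v - rowSums(v * u) * u
        nv <- sqrt(rowSums(v^2))
        small <- nv < 1e-10
        if (any(small)) { # essentially colinear draw; redraw deterministically
          v[small, ] <- matrix(rnorm(3L * sum(small)), ncol = 3L)
          v[small, ] <- v[small, , drop = FALSE] -
            rowSums(v[small, , drop = FALSE] * u[small, , drop = FALSE]) *
            u[small, , drop = FALSE]
          nv[small] <- sqrt(rowSums(v[small, , drop = FALSE]^2))
        }
        e1 <- v / nv
        e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                    u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                    u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
        d1 <- rnorm(n_vectors, sd = s)
        d2 <- rnorm(n_vectors, sd = s)
        # exact rotation by theta = |(d1, d2)| in the tangent plane;
        # add-and-renormalise would bias the decay rate by O((D_r dt)^2)
        theta <- sqrt(d1^2 + d2^2)
        e <- (d1 * e1 + d2 * e2) / theta
        u <- cos(theta) * u + sin(theta) * e
        u <- u / sqrt(rowSums(u^2)) # guard against roundoff drift
        out[t + 1L, , ] <- u
      }
    }
  })
  structure(list(time = (0:n_steps) * dt, vectors = out),
            class = "orientation_series")
}

#' Overdamped 1D Langevin trajectory on a model potential
#'
#' Brownian dynamics with unit mass and per-step Gaussian noise of
#' variance `2 kT dt / friction`, integrated with the
#' Leimkuhler-Matthews (BAOAB-limit) scheme - each step adds the average
#' of two consecutive noise draws, giving second-order accurate
#' configurational sampling - optionally under a harmonic umbrella
#' restraint or well-tempered metadynamics hill deposition. Well-tempered deposits use
#' height `h0 * exp(-V_bias(z_t) / (kB * dT))` with `dT = (gamma - 1) * T`
#' and are logged as a [hills_record()].
#'
#' @param potential a [model_potential()].
#' @param friction friction coefficient in amu/ps.
#' @param temperature temperature in K.
#' @param dt time step (ps).
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param z0 starting position (nm).
#' @param bias `NULL`, `umbrella_bias(k, z0)`, or
#'   `wtmetad_bias(height, sigma, stride, bias_factor, ...)`.
#' @return List with `z` (length `n_steps + 1`), `time` (ps), and, for
#'   metadynamics, `hills` (a [hills_record()]).
#' @export
langevin_1d <- function(potential, friction = 1, temperature = 298, dt = 0.01,
                        n_steps = 10000L, seed = 1L, z0 = NULL, bias = NULL) {
  stopifnot(inherits(potential, "model_potential"))
  pot_type <- match(potential$form, c("flat", "harmonic", "double_well", "tabulated")) - 1L
  pot_params <- switch(potential$form,
    flat = 0,
    harmonic = c(potential$params$k, potential$params$z0),
    double_well = c(potential$params$barrier, potential$params$center,
                    potential$params$half_sep),
    tabulated = 0)
  tab_z <- if (potential$form == "tabulated") potential$params$grid else numeric()
  tab_F <- if (potential$form == "tabulated") potential$params$fgrid else numeric()
  if (is.null(z0)) {
    z0 <- switch(potential$form, flat = 0, harmonic = potential$params$z0,
                 double_well = potential$params$minima[1L],
                 tabulated = potential$params$grid[which.min(potential$params$values)])
  }
  bias_type <- 0L; bias_params <- 0
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "bias_spec"))
    if (bias$type == "umbrella") {
      bias_type <- 1L
      bias_params <- c(bias$k, bias$z0)
    } else {
      bias_type <- 2L
      if (bias$bias_factor <= 1) stop("bias factor must be > 1")
      bias_params <- c(bias$height, bias$sigma, bias$stride, bias$bias_factor,
                       bias$grid_min, bias$grid_max, bias$grid_dz)
    }
  }
  noise <- with_seed(seed, rnorm(n_steps + 1L,
                                 sd = sqrt(2 * kBT(temperature) * dt / friction)))
  res <- langevin_run_cpp(z0, as.integer(n_steps), dt, friction, kBT(temperature),
                          pot_type, pot_params, tab_z, tab_F,
                          bias_type, bias_params, noise)
  out <- list(z = res$z, time = (0:n_steps) * dt)
  if (bias_type == 2L) {
    out$hills <- hills_record(
      data.frame(time = res$hill_time, center = res$hill_center,
                 sigma = bias$sigma, height = res$hill_height),
      bias_factor = bias$bias_factor, temperature = temperature)
  }
  out
}

#' @rdname langevin_1d
#' @param k umbrella force constant (kJ/(mol nm^2)).
#' @export
umbrella_bias <- function(k, z0) {
  structure(list(type = "umbrella", k = k, z0 = z0), class = "bias_spec")
}

#' @rdname langevin_1d
#' @param height initial Gaussian hill height h0 (kJ/mol).
#' @param sigma hill width (nm).
#' @param stride deposit every `stride` steps.
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @param grid_min,grid_max,grid_dz bias accumulation grid (nm).
#' @export
wtmetad_bias <- function(height = 1.2, sigma = 0.05, stride = 500L,
                         bias_factor = 50, grid_min = 0, grid_max = 2,
                         grid_dz = 0.002) {
  structure(list(type = "wtmetad", height = height, sigma = sigma,
                 stride = as.integer(stride), bias_factor = bias_factor,
                 grid_min = grid_min, grid_max = grid_max, grid_dz = grid_dz),
            class = "bias_spec")
}

#' Composition of a sugar-water mixture
#'
#' Water mass percentage is derived as
#' `100 * n_water * MW_w / (n_water * MW_w + n_sugar * MW_s)`.
#'
#' @param n_sugar,n_water molecule counts (non-negative, not both zero).
#' @param mw_sugar,mw_water molar masses in g/mol (defaults: disaccharide
#'   342.30, water 18.015).
#' @return An object of class `composition_spec` with field
#'   `water_mass_pct` (exact; rounding happens only at reporting time).
#' @export
composition_spec <- function(n_sugar, n_water, mw_sugar = 342.30, mw_water = 18.015) {
  stopifnot(n_sugar >= 0, n_water >= 0)
  if (n_sugar == 0 && n_water == 0) {
    stop("undefined composition: sugar and water counts are both zero")
  }
  mw <- n_water * mw_water
  ms <- n_sugar * mw_sugar
  structure(list(n_sugar = as.integer(n_sugar), n_water = as.integer(n_water),
                 mw_sugar = mw_sugar, mw_water = mw_water,
                 water_mass_pct = 100 * mw / (mw + ms)),
            class = "composition_spec")
}

#' Build a composition series from molecule counts
#'
#' @param counts two-column matrix or data.frame of (n_sugar, n_water)
#'   pairs.
#' @inheritParams composition_spec
#' @return A data.frame with columns `n_sugar`, `n_water`,
#'   `water_mass_pct`, and a `specs` attribute holding the
#'   [composition_spec()] list.
#' @export
build_composition_series <- function(counts, mw_sugar = 342.30, mw_water = 18.015) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L, nrow(counts) >= 1L)
  specs <- lapply(seq_len(nrow(counts)), function(i) {
    composition_spec(counts[i, 1L], counts[i, 2L], mw_sugar, mw_water)
  })
  out <- data.frame(n_sugar = vapply(specs, `[[`, 0L, "n_sugar"),
                    n_water = vapply(specs, `[[`, 0L, "n_water"),
                    water_mass_pct = vapply(specs, `[[`, 0, "water_mass_pct"))
  attr(out, "specs") <- specs
  out
}

#' Molecule counts of the study's composition series
#'
#' The sixteen internally consistent (sugar, water) count pairs spanning
#' 0-99.44 wt% water. The additional published "2 sugars / 3700 waters"
#' system is available via `include_inconsistent = TRUE`; its printed
#' 99.95 wt% label does not follow from the mass-fraction formula
#' (recomputation gives about 98.98%), so it is excluded by default.
#'
#' @param include_inconsistent include the 2/3700 row.
#' @return Two-column matrix of (n_sugar, n_water) counts.
#' @export
study_composition_counts <- function(include_inconsistent = FALSE) {
  counts <- rbind(c(1, 3356), c(2, 3341), c(9, 3206), c(18, 3038), c(36, 2700),
                  c(53, 2363), c(71, 2025), c(89, 1688), c(107, 1350),
                  c(124, 1013), c(142, 675), c(151, 506), c(160, 338),
                  c(169, 169), c(176, 34), c(178, 0))
  if (include_inconsistent) counts <- rbind(c(2, 3700), counts)
  colnames(counts) <- c("n_sugar", "n_water")
  counts
}
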