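# Free-energy post-processing: WHAM over umbrella windows, well-tempered
# metadynamics reconstruction, binding free energies and depth ranking.

#' Potential of mean force profile
#'
#' @param z grid (nm).
#' @param w free energy w(z) (kJ/mol), finite on the grid.
#' @param zero_convention descriptor of the applied zero (`"min"`,
#'   `"plateau"`, `"largest_z"`, `"none"`).
#' @param source `"wham"`, `"metadynamics"` or `"analytic"`.
#' @param sd optional pointwise standard deviation (from averaging).
#' @return An object of class `pmf_profile`.
#' @export
pmf_profile <- function(z, w, zero_convention = "none",
                        source = c("analytic", "wham", "metadynamics"), sd = NULL) {
  source <- match.arg(source)
  stopifnot(length(z) == length(w), all(is.finite(z)), all(diff(z) > 0))
  if (!all(is.finite(w))) stop("w(z) must be finite on the whole grid")
  structure(list(z = as.numeric(z), w = as.numeric(w),
                 zero_convention = zero_convention, source = source, sd = sd),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile [%s]: %d points, z in [%.3f, %.3f] nm, depth %.3f kJ/mol (zero: %s)\n",
              x$source, length(x$z), min(x$z), max(x$z), min(x$w),
              x$zero_convention))
  invisible(x)
}

# Zero a profile at the mean of the last `frac` of its z grid (plateau).
zero_at_plateau <- function(z, w, frac = 0.05) {
  n <- length(z)
  tail_idx <- which(z >= max(z) - frac * (max(z) - min(z)))
  if (length(tail_idx) == 0L) tail_idx <- n
  w - mean(w[tail_idx])
}

#' WHAM reconstruction of a PMF from umbrella windows
#'
#' Standard self-consistent weighted-histogram iteration over binned
#' window samples with harmonic biases `0.5 k (z - z0)^2`:
#' unbiased probability
#' `p_j = sum_i n_ij / sum_i N_i exp(-(b_ij - f_i)/kT)` and window
#' constants `f_i = -kT log sum_j p_j exp(-b_ij/kT)`, iterated until the
#' largest change in any `f_i` drops below `tolerance`. The PMF
#' `w = -kT log p` is zeroed at its largest-z finite bin.
#'
#' @param windows list of [umbrella_window()] objects with pairwise
#'   overlapping sampled ranges.
#' @param bin_width histogram bin width (nm).
#' @param tolerance convergence threshold on the free-energy constants
#'   (kJ/mol).
#' @param max_iter iteration cap; exceeding it raises a non-convergence
#'   error reporting the last residual.
#' @param min_counts smallest pooled histogram count for a bin to be
#'   reported; sparser edge bins carry O(1/sqrt(n)) noise in `-kT log n`
#'   and are dropped from the profile.
#' @return A `pmf_profile` (source `"wham"`) with attribute `iterations`.
#' @export
wham_pmf <- function(windows, bin_width = 0.01, tolerance = 1e-8,
                     max_iter = 1e5, min_counts = 10L) {
  stopifnot(length(windows) >= 1L)
  for (wd in windows) stopifnot(inherits(wd, "umbrella_window"))
  temperature <- windows[[1L]]$temperature
  kt <- kBT(temperature)
  zr <- range(unlist(lapply(windows, function(w) range(w$z))))
  # window coverage check: sampled ranges must chain across z
  if (length(windows) > 1L) {
    ranges <- lapply(windows, function(w) range(w$z))
    ord <- order(vapply(ranges, `[`, 0, 1L))
    hi <- ranges[[ord[1L]]][2L]
    for (i in ord[-1L]) {
      if (ranges[[i]][1L] > hi + bin_width) {
        warning(sprintf("coverage gap between z = %.4f and z = %.4f nm",
                        hi, ranges[[i]][1L]))
      }
      hi <- max(hi, ranges[[i]][2L])
    }
  }
  edges <- seq(floor(zr[1L] / bin_width) * bin_width,
               ceiling(zr[2L] / bin_width) * bin_width, by = bin_width)
  mid <- (edges[-1L] + edges[-length(edges)]) / 2
  nb <- length(mid)
  nw <- length(windows)
  H <- matrix(0, nrow = nw, ncol = nb)  # counts
  N <- numeric(nw)
  B <- matrix(0, nrow = nw, ncol = nb)  # bias at bin centers
  for (i in seq_len(nw)) {
    wd <- windows[[i]]
    idx <- pmin(pmax(ceiling((wd$z - edges[1L]) / bin_width), 1L), nb)
    H[i, ] <- tabulate(idx, nbins = nb)
    N[i] <- length(wd$z)
    B[i, ] <- 0.5 * wd$force_constant * (mid - wd$center)^2
  }
  nbin_tot <- colSums(H)
  f <- numeric(nw)
  expB <- exp(-B / kt)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(N * exp(f / kt) * expB)  # sum_i N_i exp((f_i - b_ij)/kT)
    p <- ifelse(denom > 0, nbin_tot / denom, 0)
    f_new <- -kt * log(pmax(expB %*% p, .Machine$double.xmin))[, 1L]
    f_new <- f_new - f_new[1L]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tolerance) break
    if (iter >= max_iter) {
      stop("WHAM did not converge in ", max_iter,
           " iterations (last residual ", signif(resid, 3), " kJ/mol)")
    }
  }
  finite <- p > 0 & nbin_tot >= min_counts
  w <- rep(NA_real_, nb)
  w[finite] <- -kt * log(p[finite])
  keep <- which(finite)
  w_keep <- w[keep] - w[keep[length(keep)]]  # zero at largest-z finite bin
  out <- pmf_profile(mid[keep], w_keep, zero_convention = "largest_z",
                     source = "wham")
  attr(out, "iterations") <- iter
  attr(out, "temperature") <- temperature
  out
}

#' Average several PMF profiles
#'
#' Each profile is re-zeroed at the shared plateau (mean of the last 5% of
#' its z range), interpolated onto a common grid spanning the overlap of
#' all profiles, and averaged pointwise with a standard deviation.
#'
#' @param profiles list of >= 2 `pmf_profile` objects with a common z
#'   range.
#' @param n_grid number of points of the common grid.
#' @param plateau_frac fraction of the z grid used for plateau zeroing.
#' @return A `pmf_profile` with pointwise `sd`.
#' @export
average_pmf <- function(profiles, n_grid = 200L, plateau_frac = 0.05) {
  stopifnot(length(profiles) >= 2L)
  for (p in profiles) stopifnot(inherits(p, "pmf_profile"))
  lo <- max(vapply(profiles, function(p) min(p$z), 0))
  hi <- min(vapply(profiles, function(p) max(p$z), 0))
  if (lo >= hi) stop("alignment error: profiles have disjoint z ranges")
  zg <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(profiles, function(p) {
    wz <- approx(p$z, p$w, zg)$y
    zero_at_plateau(zg, wz, plateau_frac)
  }, numeric(n_grid))
  pmf_profile(zg, rowMeans(mat), zero_convention = "plateau",
              source = profiles[[1L]]$source,
              sd = apply(mat, 1L, sd))
}

#' Free-energy surface from a well-tempered metadynamics HILLS record
#'
#' Sums the deposited Gaussians `V(z) = sum_i h_i exp(-(z-z_i)^2/(2 s_i^2))`
#' and returns `F(z) = -gamma/(gamma-1) * V(z)`, shifted so `min F = 0`.
#' When the record's heights are not pre-scaled
#' (`heights_prescaled = FALSE`), each deposit is first tempered by
#' `exp(-V(z_i)/(kB dT))` with the bias accumulated before it.
#'
#' Because the instantaneous well-tempered estimate oscillates with an
#' amplitude set by the hill height, the `"time_average"` estimator
#' averages the instantaneous surfaces over the last `average_tail`
#' fraction of deposits (each aligned at its minimum) - the usual
#' converged-FES estimator; `"final"` is the plain end-of-run sum.
#'
#' @param hills a [hills_record()] with deposits sorted by time.
#' @param z_grid evaluation grid (nm); defaults to 400 points spanning the
#'   deposit centers +- 3 sigma.
#' @param estimator `"final"` or `"time_average"`.
#' @param average_tail fraction of deposits averaged over by
#'   `"time_average"`.
#' @return A `pmf_profile` (source `"metadynamics"`, zero convention
#'   `"min"`) with attribute `offset` (the shift applied; `F_raw = F -
#'   offset`; `"final"` only).
#' @export
metad_fes <- function(hills, z_grid = NULL,
                      estimator = c("final", "time_average"),
                      average_tail = 0.5) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(hills, "hills_record"))
  gamma <- hills$bias_factor
  if (gamma <= 1) stop("bias factor must be > 1")
  d <- hills$deposits
  if (is.null(z_grid)) {
    if (nrow(d) == 0L) z_grid <- seq(0, 1, length.out = 101L)
    else z_grid <- seq(min(d$center) - 3 * max(d$sigma),
                       max(d$center) + 3 * max(d$sigma), length.out = 400L)
  }
  V <- numeric(length(z_grid))
  if (nrow(d) > 0L) {
    h <- d$height
    if (!hills$heights_prescaled) {
      # apply tempering now: each deposit scaled by the bias before it
      kt_dT <- (gamma - 1) * kBT(hills$temperature)
      h <- numeric(nrow(d))
      vc <- function(z, k) sum(h[seq_len(k - 1L)] *
                                 exp(-(z - d$center[seq_len(k - 1L)])^2 /
                                       (2 * d$sigma[seq_len(k - 1L)]^2)))
      for (k in seq_len(nrow(d))) {
        h[k] <- d$height[k] * exp(-vc(d$center[k], k) / kt_dT)
      }
    }
    if (estimator == "time_average") {
      from <- max(1L, nrow(d) - floor(average_tail * nrow(d)) + 1L)
      G <- vapply(seq_len(nrow(d)), function(k) {
        h[k] * exp(-(z_grid - d$center[k])^2 / (2 * d$sigma[k]^2))
      }, numeric(length(z_grid)))
      Vcum <- t(apply(G, 1L, cumsum))  # bias after each deposit
      Fmat <- -gamma / (gamma - 1) * Vcum[, from:nrow(d), drop = FALSE]
      Fmat <- sweep(Fmat, 2L, apply(Fmat, 2L, min))  # align each at its min
      Fz <- rowMeans(Fmat)
      out <- pmf_profile(z_grid, Fz - min(Fz), zero_convention = "min",
                         source = "metadynamics")
      attr(out, "offset") <- NA_real_
      attr(out, "temperature") <- hills$temperature
      return(out)
    }
    for (k in seq_len(nrow(d))) {
      V <- V + h[k] * exp(-(z_grid - d$center[k])^2 / (2 * d$sigma[k]^2))
    }
  }
  Fz <- -gamma / (gamma - 1) * V
  offset <- -min(Fz)
  out <- pmf_profile(z_grid, Fz + offset, zero_convention = "min",
                     source = "metadynamics")
  attr(out, "offset") <- offset
  attr(out, "temperature") <- hills$temperature
  out
}

#' Binding free energy from a PMF
#'
#' Ratio of Boltzmann integrals over the bound region `B = [z_min,
#' boundary]` and unbound region `U = (boundary, z_max]`:
#' `dG = -kT log( int_B exp(-w/kT) dz / int_U exp(-w/kT) dz )`
#' by trapezoidal quadrature. The result is invariant under additive
#' shifts of w. No volume (4 pi z^2) Jacobian is applied by default; the
#' `jacobian` flag enables it for sensitivity checks.
#'
#' @param pmf a `pmf_profile` whose grid spans both sides of `boundary`.
#' @param boundary bound/unbound dividing distance (nm); 1.5 nm is the
#'   disaccharide convention used throughout.
#' @param temperature temperature in K.
#' @param jacobian multiply the integrand by `4 pi z^2`.
#' @return A `binding_result`: list with `dG` (kJ/mol), `bound_region`,
#'   `unbound_region` (nm), `temperature`.
#' @export
binding_free_energy <- function(pmf, boundary = 1.5, temperature = 298,
                                jacobian = FALSE) {
  stopifnot(inherits(pmf, "pmf_profile"))
  z <- pmf$z; w <- pmf$w
  if (boundary <= min(z) || boundary >= max(z)) {
    stop("domain error: boundary ", boundary, " nm outside PMF grid [",
         min(z), ", ", max(z), "]")
  }
  kt <- kBT(temperature)
  wref <- min(w) # subtracted for numerical stability; cancels in the ratio
  integrand <- exp(-(w - wref) / kt)
  if (jacobian) integrand <- integrand * 4 * pi * z^2
  wb <- approx(z, integrand, boundary)$y
  zb <- c(z[z < boundary], boundary)
  ib <- c(integrand[z < boundary], wb)
  zu <- c(boundary, z[z > boundary])
  iu <- c(wb, integrand[z > boundary])
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  dG <- -kt * log(trapz(zb, ib) / trapz(zu, iu))
  structure(list(dG = dG, bound_region = c(min(z), boundary),
                 unbound_region = c(boundary, max(z)),
                 temperature = temperature, jacobian = jacobian),
            class = "binding_result")
}

# First interior local minimum of w on its grid (smallest z where w is
# a strict-or-flat local minimum below the plateau zero); NA if the
# profile is monotone without one.
first_local_minimum <- function(z, w) {
  n <- length(w)
  for (i in 2:(n - 1L)) {
    if (w[i] <= w[i - 1L] && w[i] < w[i + 1L]) return(i)
  }
  NA_integer_
}

#' Depth ranking and depth sum of a labelled PMF set
#'
#' Re-zeroes every profile at its plateau (mean of the last 5% of the z
#' grid), takes the depth as w at the first interior local minimum, sorts
#' labels by depth (deepest first) and reports the sum of depths.
#' Monotone profiles without an interior minimum are flagged, listed and
#' excluded from the sum.
#'
#' @param profiles named list of `pmf_profile` objects.
#' @param plateau_frac fraction of the z grid used for plateau zeroing.
#' @return List with `table` (data.frame `label`, `z_min`, `depth`,
#'   ordered deepest first), `depth_sum` (kJ/mol) and `excluded` (labels
#'   without an interior minimum).
#' @export
pmf_depth_report <- function(profiles, plateau_frac = 0.05) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles))) names(profiles) <- paste0("profile_", seq_along(profiles))
  rows <- list(); excluded <- character()
  for (lab in names(profiles)) {
    p <- profiles[[lab]]
    stopifnot(inherits(p, "pmf_profile"))
    w0 <- zero_at_plateau(p$z, p$w, plateau_frac)
    i <- first_local_minimum(p$z, w0)
    if (is.na(i)) {
      excluded <- c(excluded, lab)
    } else {
      rows[[lab]] <- data.frame(label = lab, z_min = p$z[i], depth = w0[i],
                                stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(label = character(), z_min = numeric(), depth = numeric())
  tab <- tab[order(tab$depth), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, depth_sum = sum(tab$depth), excluded = excluded)
}

#' Umbrella-sampling windows from the Langevin sandbox
#'
#' Convenience generator: runs one overdamped Langevin simulation per
#' window center on a model potential and collects the sampled collective
#' variable into [umbrella_window()] objects — the desk-scale analogue of
#' a pulled umbrella-sampling ladder.
#'
#' @param potential a [model_potential()].
#' @param centers window centers (nm); the study convention is 22 windows
#'   along the pull coordinate.
#' @param force_constant umbrella force constant (kJ/(mol nm^2)).
#' @param n_steps,dt,friction,temperature Langevin parameters per window.
#' @param n_equil equilibration steps discarded from each window.
#' @param seed root seed (one child seed per window).
#' @return List of [umbrella_window()] objects.
#' @export
sample_umbrella_windows <- function(potential, centers, force_constant = 45,
                                    n_steps = 20000L, dt = 5e-4, friction = 1,
                                    temperature = 298, n_equil = 2000L,
                                    seed = 1L) {
  lapply(seq_along(centers), function(i) {
    run <- langevin_1d(potential, friction = friction, temperature = temperature,
                       dt = dt, n_steps = n_steps + n_equil,
                       seed = derive_seed(seed, paste0("window", i)),
                       z0 = centers[i],
                       bias = umbrella_bias(force_constant, centers[i]))
    umbrella_window(centers[i], force_constant,
                    z = run$z[-seq_len(n_equil + 1L)],
                    temperature = temperature)
  })
}
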