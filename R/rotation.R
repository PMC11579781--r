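# OH-bond-vector rotational dynamics: orientation series, first-rank
# autocorrelation and exponential correlation-time fits.

#' OH-bond orientation series from a trajectory
#'
#' Extracts the minimum-image O to H unit vector of each selected hydroxyl
#' group in every frame.
#'
#' @param traj a [trajectory()].
#' @param oh_groups two-column matrix of 0-based (O, H) index pairs;
#'   defaults to the donor pairs of all non-water molecules.
#' @return An `orientation_series` (see
#'   [rotational_diffusion_vectors()]).
#' @export
oh_orientation_series <- function(traj, oh_groups = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  if (is.null(oh_groups)) {
    dg <- top$donor_groups
    sugarish <- top$atoms$mol_kind[dg[, 1L] + 1L] != "water"
    oh_groups <- dg[sugarish, , drop = FALSE]
  }
  oh_groups <- as.matrix(oh_groups)
  stopifnot(ncol(oh_groups) == 2L, nrow(oh_groups) >= 1L)
  nf <- n_frames(traj)
  out <- array(NA_real_, dim = c(nf, nrow(oh_groups), 3L))
  for (f in seq_len(nf)) {
    frm <- traj$frames[[f]]
    v <- minimum_image_displacement(frm$positions[oh_groups[, 1L] + 1L, , drop = FALSE],
                                    frm$positions[oh_groups[, 2L] + 1L, , drop = FALSE],
                                    frm$cell)
    if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
    nv <- sqrt(rowSums(v^2))
    if (any(nv < 1e-12)) stop("geometry error: zero-length O-H bond in frame ", f)
    out[f, , ] <- v / nv
  }
  structure(list(time = frame_times(traj), vectors = out),
            class = "orientation_series")
}

#' First-rank orientational autocorrelation
#'
#' `C(t) = <u(t0) . u(t0 + t)>` averaged over all time origins and all
#' vectors (FFT-based, every frame a time origin). `C(0) = 1` by
#' construction for unit vectors.
#'
#' @param series an `orientation_series`.
#' @param max_lag_fraction largest lag as a fraction of the series length.
#' @return List with `lag` (ps) and `C`.
#' @export
autocorrelation <- function(series, max_lag_fraction = 0.5) {
  stopifnot(inherits(series, "orientation_series"))
  v <- series$vectors
  nf <- dim(v)[1L]
  if (nf < 10L) stop("need at least 10 frames for an autocorrelation")
  if (max_lag_fraction > 1) {
    warning("max_lag_fraction > 1; truncating to the series length")
    max_lag_fraction <- 1
  }
  max_lag <- max(1L, floor((nf - 1L) * max_lag_fraction))
  nv <- dim(v)[2L]
  m <- matrix(v, nrow = nf) # nf x (nv*3), components side by side
  npad <- 2L * nf
  mp <- rbind(m, matrix(0, nrow = npad - nf, ncol = ncol(m)))
  ft <- stats::mvfft(mp)
  ac <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / npad
  # sum over components and vectors; normalise by origin count
  s <- rowSums(ac[seq_len(max_lag + 1L), , drop = FALSE])
  C <- s / ((nf - 0:max_lag) * nv)
  dt <- if (nf > 1L) series$time[2L] - series$time[1L] else 1
  list(lag = (0:max_lag) * dt, C = C)
}

#' Fit an exponential correlation time
#'
#' Least-squares fit of `exp(-t / tau)` to C(t) over lags where
#' `C > threshold`: a linearised log fit weighted by C^2 seeds one
#' nonlinear refinement pass. The correlation time is the e-fold decay
#' time of the fit. When C(t) never decays below 1/e inside the lag
#' window the result is flagged non-converged and `tau` is `NA` (no
#' error is raised).
#'
#' @param acf list with `lag` (ps) and `C`, from [autocorrelation()].
#' @param threshold smallest C included in the fit window.
#' @return A `correlation_fit`: list with `tau` (ps or `NA`), `converged`,
#'   `lag`, `C`, `fit_window` (lag range used), `residual_rms`.
#' @export
fit_correlation_time <- function(acf, threshold = 0.05) {
  lag <- acf$lag; C <- acf$C
  stopifnot(length(lag) == length(C), length(lag) >= 3L)
  if (min(C) > exp(-1)) {
    return(structure(list(tau = NA_real_, converged = FALSE, lag = lag, C = C,
                          fit_window = NULL, residual_rms = NA_real_),
                     class = "correlation_fit"))
  }
  # fit window: from lag 0 up to the first dip below threshold
  below <- which(C <= threshold)
  last <- if (length(below) > 0L) max(2L, below[1L] - 1L) else length(C)
  sel <- which(C[seq_len(last)] > 0)
  t_fit <- lag[sel]; c_fit <- C[sel]
  w <- c_fit^2
  slope <- sum(w * t_fit * log(c_fit)) / sum(w * t_fit^2)
  tau0 <- -1 / slope
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t_fit[t_fit > 0]) / 2
  tau <- tryCatch({
    fit <- minpack.lm::nlsLM(c_fit ~ exp(-t_fit / tau),
                             start = list(tau = tau0),
                             lower = 1e-12,
                             control = minpack.lm::nls.lm.control(maxiter = 100))
    coef(fit)[["tau"]]
  }, error = function(e) tau0)
  res <- c_fit - exp(-t_fit / tau)
  structure(list(tau = tau, converged = TRUE, lag = lag, C = C,
                 fit_window = range(t_fit), residual_rms = sqrt(mean(res^2))),
            class = "correlation_fit")
}

#' Correlation time of an orientation series
#'
#' Convenience pipeline: [autocorrelation()] then
#' [fit_correlation_time()].
#'
#' @inheritParams autocorrelation
#' @inheritParams fit_correlation_time
#' @return A `correlation_fit`.
#' @export
correlation_time <- function(series, max_lag_fraction = 0.5, threshold = 0.05) {
  fit_correlation_time(autocorrelation(series, max_lag_fraction), threshold)
}
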