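test_that("single unbiased window reduces to -kT log(histogram)", {
  run <- langevin_1d(model_potential("harmonic", k = 80, z0 = 0.6),
                     dt = 0.002, n_steps = 50000, seed = 5)
  w <- umbrella_window(0.6, 0, z = run$z[-(1:5000)])
  pmf <- wham_pmf(list(w), bin_width = 0.02, min_counts = 1)
  # direct histogram estimate on the same bins
  edges <- seq(min(pmf$z) - 0.01, max(pmf$z) + 0.01, by = 0.02)
  h <- hist(w$z, breaks = edges, plot = FALSE)
  keep <- h$counts > 0
  direct <- -kBT(298) * log(h$counts[keep])
  direct <- direct - direct[sum(keep)]
  expect_equal(pmf$w, direct, tolerance = 1e-8)
})

test_that("WHAM recovers a harmonic potential's curvature", {
  k_true <- 60
  pot <- model_potential("harmonic", k = k_true, z0 = 0.8)
  centers <- seq(0.4, 1.2, length.out = 9)
  windows <- sample_umbrella_windows(pot, centers, force_constant = 45,
                                     n_steps = 15000, seed = 77)
  pmf <- wham_pmf(windows)
  fit <- lm(w ~ poly(z, 2, raw = TRUE),
            data = data.frame(z = pmf$z, w = pmf$w),
            weights = dnorm(pmf$z, 0.8, 0.2))
  k_fit <- 2 * coef(fit)[[3]]
  expect_equal(k_fit, k_true, tolerance = 0.05)
})

test_that("WHAM recovers the double-well sandbox potential", {
  pot <- model_potential("double_well", barrier = 10, minima = c(0.4, 1.2))
  centers <- seq(0.3, 1.7, length.out = 22)
  windows <- sample_umbrella_windows(pot, centers, force_constant = 45,
                                     n_steps = 20000, seed = 1)
  pmf <- wham_pmf(windows)
  err <- pmf$w - pot$value(pmf$z)
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)), 0.5)
  # window-order invariance
  pmf2 <- wham_pmf(rev(windows))
  expect_equal(pmf2$w, pmf$w, tolerance = 1e-6)
})

test_that("WHAM reports gaps and non-convergence", {
  w1 <- umbrella_window(0.2, 100, z = rnorm(500, 0.2, 0.03))
  w2 <- umbrella_window(1.5, 100, z = rnorm(500, 1.5, 0.03))
  expect_warning(wham_pmf(list(w1, w2)), "coverage gap")
  pot <- model_potential("double_well", barrier = 10, minima = c(0.4, 1.2))
  windows <- sample_umbrella_windows(pot, c(0.4, 0.6, 0.8), force_constant = 45,
                                     n_steps = 2000, seed = 2)
  expect_error(wham_pmf(windows, max_iter = 2), "did not converge")
})

test_that("profile averaging re-zeroes, averages pointwise and tracks spread", {
  z <- seq(0, 2, 0.01)
  base <- pmf_profile(z, (z - 1)^2)
  same <- average_pmf(list(base, base, base, base, base), n_grid = 201L)
  expect_equal(max(abs(same$sd)), 0, tolerance = 1e-12)
  expect_equal(approx(same$z, same$w, 1)$y,
               approx(base$z, base$w - mean(base$w[z >= 1.9]), 1)$y,
               tolerance = 1e-9)
  # additive constants vanish after re-zeroing
  shifted <- pmf_profile(z, (z - 1)^2 + 37)
  avg <- average_pmf(list(base, shifted))
  expect_equal(max(abs(avg$sd)), 0, tolerance = 1e-9)
  # direct pointwise mean of two distinct analytic profiles
  other <- pmf_profile(z, 2 * (z - 1)^2)
  avg2 <- average_pmf(list(base, other), n_grid = 201L)
  b0 <- base$w - mean(base$w[z >= 1.9])
  o0 <- other$w - mean(other$w[z >= 1.9])
  want <- approx(z, (b0 + o0) / 2, avg2$z)$y
  expect_equal(avg2$w, want, tolerance = 1e-9)
  expect_error(average_pmf(list(pmf_profile(0:1, c(0, 0)),
                                pmf_profile(2:3, c(0, 0)))),
               "disjoint")
})

test_that("metadynamics FES formula is exact for a single deposit", {
  h <- hills_record(data.frame(time = 1, center = 0.5, sigma = 0.05, height = 1.2),
                    bias_factor = 50)
  fes <- metad_fes(h, z_grid = seq(0, 1, 0.001))
  raw_center <- fes$w[fes$z == 0.5] - attr(fes, "offset")
  expect_equal(raw_center, -(50 / 49) * 1.2, tolerance = 1e-9)
  # minimum of the shifted profile sits at the deposit center
  expect_equal(fes$z[which.min(fes$w)], 0.5)
  # empty deposit list: flat zero
  empty <- hills_record(data.frame(time = numeric(), center = numeric(),
                                   sigma = numeric(), height = numeric()),
                        bias_factor = 50)
  expect_true(all(metad_fes(empty)$w == 0))
  expect_error(hills_record(data.frame(time = 1, center = 0, sigma = 0.05,
                                       height = 1), bias_factor = 1),
               "bias factor")
})

test_that("metadynamics bias is additive over deposit subsets", {
  set.seed(8)
  d <- data.frame(time = 1:20, center = runif(20, 0.3, 0.7),
                  sigma = 0.05, height = runif(20, 0.5, 1.2))
  zg <- seq(0, 1, 0.005)
  f_all <- metad_fes(hills_record(d, 50), zg)
  f_a <- metad_fes(hills_record(d[1:8, ], 50), zg)
  f_b <- metad_fes(hills_record(d[9:20, ], 50), zg)
  raw <- function(f) f$w - attr(f, "offset")
  expect_equal(raw(f_all), raw(f_a) + raw(f_b), tolerance = 1e-10)
})

test_that("long well-tempered runs recover the sandbox potential near its minima", {
  pot <- model_potential("double_well", barrier = 10, minima = c(0.4, 1.2))
  run <- langevin_1d(pot, dt = 5e-4, n_steps = 1e6, seed = 2,
                     bias = wtmetad_bias(height = 1.2, sigma = 0.05,
                                         stride = 500, bias_factor = 50,
                                         grid_min = 0, grid_max = 2))
  fes <- metad_fes(run$hills, z_grid = seq(0.25, 1.35, 0.005),
                   estimator = "time_average", average_tail = 0.7)
  ana <- pot$value(fes$z)
  for (m in c(0.4, 1.2)) {
    sel <- abs(fes$z - m) <= 0.06
    d <- (fes$w - ana)[sel]
    d <- d - d[which.min(abs(fes$z[sel] - m))]
    expect_lt(max(abs(d)), 1.0)
  }
})

test_that("flat-PMF binding free energy equals the closed-form length ratio", {
  z <- seq(0.2, 1.7, by = 0.005)
  flat <- pmf_profile(z, rep(0, length(z)))
  res <- binding_free_energy(flat, boundary = 1.5, temperature = 298)
  expect_equal(res$dG, -kBT(298) * log(1.3 / 0.2), tolerance = 1e-10)
  expect_equal(round(res$dG, 2), -4.64)
  # additive shifts leave dG unchanged
  shifted <- pmf_profile(z, rep(100, length(z)))
  expect_equal(binding_free_energy(shifted, 1.5, 298)$dG, res$dG,
               tolerance = 1e-10)
  # deep well against hand trapezoidal quadrature on the same grid
  kt <- kBT(298)
  w <- -20 * exp(-((z - 0.6) / 0.25)^2)
  well <- pmf_profile(z, w)
  got <- binding_free_energy(well, 1.5, 298)$dG
  integ <- exp(-w / kt)
  trap <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  inB <- z <= 1.5; inU <- z >= 1.5
  want <- -kt * log(trap(z[inB], integ[inB]) / trap(z[inU], integ[inU]))
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(binding_free_energy(flat, 2.0), "domain error")
})

test_that("binding free energy is stable under grid refinement", {
  z1 <- seq(0.2, 1.7, by = 0.01)
  z2 <- seq(0.2, 1.7, by = 0.005)
  wfun <- function(z) -8 * exp(-((z - 0.45) / 0.15)^2)
  g1 <- binding_free_energy(pmf_profile(z1, wfun(z1)), 1.5, 298)$dG
  g2 <- binding_free_energy(pmf_profile(z2, wfun(z2)), 1.5, 298)$dG
  expect_lt(abs(g1 - g2), 0.01)
})

test_that("depth report ranks minima, sums depths and flags monotone profiles", {
  z <- seq(0, 2, 0.01)
  mk <- function(depth) pmf_profile(z, depth * exp(-((z - 0.5) / 0.2)^2))
  profs <- list(a = mk(-1), b = mk(-5), c = mk(-3),
                mono = pmf_profile(z, 3 - z))
  rep <- pmf_depth_report(profs)
  expect_equal(rep$table$label, c("b", "c", "a"))
  expect_equal(rep$table$depth, c(-5, -3, -1), tolerance = 1e-6)
  expect_equal(rep$depth_sum, -9, tolerance = 1e-6)
  expect_equal(rep$excluded, "mono")
  # the first-minimum position matches the calculus oracle on an analytic curve
  dw <- model_potential("double_well", barrier = 6, minima = c(0.5, 1.3))
  prof <- pmf_profile(seq(0.2, 1.6, 0.002), dw$value(seq(0.2, 1.6, 0.002)))
  rep2 <- pmf_depth_report(list(dw = prof))
  expect_equal(rep2$table$z_min, 0.5, tolerance = 0.005)
})

test_that("WHAM and metadynamics agree on the same sandbox potential", {
  pot <- model_potential("double_well", barrier = 10, minima = c(0.4, 1.2))
  windows <- sample_umbrella_windows(pot, seq(0.3, 1.7, length.out = 22),
                                     force_constant = 45, n_steps = 20000,
                                     seed = 3)
  pmf_us <- wham_pmf(windows)
  run <- langevin_1d(pot, dt = 5e-4, n_steps = 1e6, seed = 4,
                     bias = wtmetad_bias(grid_min = 0, grid_max = 2))
  pmf_mtd <- metad_fes(run$hills, estimator = "time_average",
                       average_tail = 0.7)
  zc <- seq(0.3, 1.3, 0.01)
  d <- approx(pmf_us$z, pmf_us$w, zc)$y - approx(pmf_mtd$z, pmf_mtd$w, zc)$y
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 1.0)
})

test_that("HILLS and umbrella-series files round-trip", {
  d <- data.frame(time = c(0.5, 1, 1.5), center = c(0.4, 0.5, 0.45),
                  sigma = 0.05, height = c(1.2, 1.1, 1.05))
  h <- hills_record(d, bias_factor = 50)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hills(h, path)
  back <- read_hills(path)
  expect_equal(back$deposits, d, tolerance = 1e-8)
  expect_equal(back$bias_factor, 50)
  wpath <- withr::local_tempfile(fileext = ".dat")
  w <- umbrella_window(0.7, 45, z = c(0.69, 0.71, 0.7), time = 0:2)
  write_umbrella_series(w, wpath)
  back_w <- read_umbrella_series(wpath, 0.7, 45)
  expect_equal(back_w$z, w$z, tolerance = 1e-8)
  ppath <- withr::local_tempfile(fileext = ".xvg")
  p <- pmf_profile(seq(0, 1, 0.1), (seq(0, 1, 0.1) - 0.5)^2)
  write_pmf(p, ppath)
  tab <- read.table(ppath, comment.char = "#",
                    skip = 3)
  expect_equal(tab[[1]], p$z, tolerance = 1e-6)
  expect_equal(tab[[2]], p$w, tolerance = 1e-6)
})
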