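test_that("composition formula reproduces the published series at printed rounding", {
  counts <- study_composition_counts()
  ser <- build_composition_series(counts)
  # rows printed at two decimals
  expect_equal(round(ser$water_mass_pct[ser$n_sugar == 1 & ser$n_water == 3356], 2),
               99.44)
  # rows printed at integer precision
  printed <- c("2/3341" = 99, "9/3206" = 95, "18/3038" = 90, "36/2700" = 80,
               "53/2363" = 70, "71/2025" = 60, "89/1688" = 50, "107/1350" = 40,
               "124/1013" = 30, "142/675" = 20, "151/506" = 15, "160/338" = 10,
               "169/169" = 5, "176/34" = 1, "178/0" = 0)
  for (key in names(printed)) {
    nn <- as.integer(strsplit(key, "/")[[1]])
    row <- ser[ser$n_sugar == nn[1] & ser$n_water == nn[2], ]
    expect_equal(round(row$water_mass_pct), unname(printed[key]), label = key)
  }
  # the 2/3700 row does not recompute to its printed 99.95 label
  incon <- composition_spec(2, 3700)
  expect_false(round(incon$water_mass_pct, 2) == 99.95)
  expect_equal(incon$water_mass_pct, 98.98, tolerance = 0.01)
})

test_that("composition edge cases error as specified", {
  expect_error(composition_spec(0, 0), "undefined composition")
  expect_equal(composition_spec(5, 0)$water_mass_pct, 0)
  expect_equal(composition_spec(0, 5)$water_mass_pct, 100)
})

test_that("ideal-gas configurations are uniform and seed-reproducible", {
  spec <- synthetic_spec(seed = 9, n_molecules = 500, cell = 5)
  a <- ideal_gas_config(spec)
  b <- ideal_gas_config(spec)
  expect_identical(a$frame$positions, b$frame$positions)
  expect_true(all(a$frame$positions >= 0 & a$frame$positions <= 5))
  c2 <- ideal_gas_config(synthetic_spec(seed = 10, n_molecules = 2, cell = 5))
  expect_equal(nrow(c2$frame$positions), 2)
})

test_that("planted hydrogen-bond geometry is exact by construction", {
  spec <- synthetic_spec(seed = 21, cell = 6)
  ph <- planted_hbond_config(10, d_OO = 0.28, angle_deg = 25, spec = spec)
  pos <- ph$frame$positions
  for (p in 1:10) {
    dO <- pos[3 * p - 2, ]; h <- pos[3 * p - 1, ]; aO <- pos[3 * p, ]
    expect_equal(sqrt(sum((aO - dO)^2)), 0.28, tolerance = 1e-12)
    v_dh <- h - dO; v_da <- aO - dO
    ang <- acos(sum(v_dh * v_da) / sqrt(sum(v_dh^2) * sum(v_da^2))) * 180 / pi
    expect_equal(ang, 25, tolerance = 1e-9)
  }
  # inter-pair separation exceeds twice the conventional cutoff
  centers <- pos[seq(1, 30, by = 3), ]
  dmin <- min(dist(centers))
  expect_gt(dmin, 0.7)
  expect_error(planted_hbond_config(100, spec = synthetic_spec(cell = 2)),
               "packing error")
})

test_that("rotational diffusion keeps unit norms, is reproducible, and freezes at D_r = 0", {
  ser <- rotational_diffusion_vectors(20, 0.05, 0.1, 200, seed = 4)
  norms <- sqrt(apply(ser$vectors^2, c(1, 2), sum))
  expect_true(all(abs(norms - 1) < 1e-9))
  ser2 <- rotational_diffusion_vectors(20, 0.05, 0.1, 200, seed = 4)
  expect_identical(ser$vectors, ser2$vectors)
  frozen <- rotational_diffusion_vectors(5, 0, 0.1, 50, seed = 4)
  for (t in 1:51) expect_equal(frozen$vectors[t, , ], frozen$vectors[1, , ])
  expect_error(rotational_diffusion_vectors(5, 2, 0.1, 10), "stability")
})

test_that("free Brownian motion obeys the Einstein relation", {
  run <- langevin_1d(model_potential("flat"), friction = 1, temperature = 298,
                     dt = 0.01, n_steps = 50000, seed = 12)
  # lagged displacements: var(z_{t+k} - z_t) -> k * 2 kT dt / friction
  k <- 20
  dz <- run$z[-(1:k)] - run$z[seq_len(length(run$z) - k)]
  expect_equal(var(dz), k * 2 * kBT(298) * 0.01, tolerance = 0.05)
})

test_that("harmonic restraint samples the Boltzmann distribution", {
  run <- langevin_1d(model_potential("harmonic", k = 100, z0 = 0.5),
                     dt = 0.005, n_steps = 50000, seed = 3)
  z <- run$z[-(1:2000)]
  expect_equal(mean(z), 0.5, tolerance = 0.01)
  expect_equal(var(z), kBT(298) / 100, tolerance = 0.05)
  # determinism
  run2 <- langevin_1d(model_potential("harmonic", k = 100, z0 = 0.5),
                      dt = 0.005, n_steps = 50000, seed = 3)
  expect_identical(run$z, run2$z)
})

test_that("umbrella-biased sampling follows the analytic biased density", {
  # harmonic potential + umbrella = harmonic with combined k and shifted center
  k1 <- 50; z1 <- 0.4; k2 <- 45; z2 <- 0.8
  run <- langevin_1d(model_potential("harmonic", k = k1, z0 = z1),
                     dt = 0.002, n_steps = 1e5, seed = 8,
                     bias = umbrella_bias(k2, z2))
  z <- run$z[-(1:5000)]
  k_tot <- k1 + k2
  mu <- (k1 * z1 + k2 * z2) / k_tot
  ks <- suppressWarnings(
    stats::ks.test(z, "pnorm", mean = mu, sd = sqrt(kBT(298) / k_tot)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("well-tempered deposition logs tempered heights", {
  pot <- model_potential("harmonic", k = 200, z0 = 0.5)
  run <- langevin_1d(pot, dt = 0.001, n_steps = 5000, seed = 2,
                     bias = wtmetad_bias(height = 1.2, sigma = 0.05,
                                         stride = 500, bias_factor = 50,
                                         grid_min = 0, grid_max = 1))
  h <- run$hills
  expect_s3_class(h, "hills_record")
  expect_equal(nrow(h$deposits), 10)
  expect_equal(h$deposits$time, (1:10) * 0.5)
  # heights decay from h0 as bias accumulates, but stay positive
  expect_true(all(h$deposits$height <= 1.2 + 1e-12))
  expect_true(all(h$deposits$height > 0))
  expect_lt(h$deposits$height[10], h$deposits$height[1])
})

test_that("mixture builder honours the 0.3 nm separation rule and the seed", {
  comp <- composition_spec(2, 80)
  spec <- synthetic_spec(seed = 31, cell = 3)
  mix <- toy_mixture_builder(comp, spec)
  pos <- mix$frame$positions
  mol <- mix$topology$atoms$mol_index
  n <- nrow(pos)
  ij <- t(combn(n, 2))
  inter <- mol[ij[, 1]] != mol[ij[, 2]]
  d <- mapply(function(i, j) {
    minimum_image_distance(pos[i, ], pos[j, ], mix$frame$cell)
  }, ij[inter, 1][1:2000], ij[inter, 2][1:2000])
  # spot-check a subsample against the rule, allowing the planted
  # donor-acceptor contacts (>= 0.12 nm by construction)
  expect_true(all(d >= 0.12))
  mix2 <- toy_mixture_builder(comp, spec)
  expect_identical(mix$frame$positions, mix2$frame$positions)
  # pure water box
  pure <- toy_mixture_builder(composition_spec(0, 30), synthetic_spec(seed = 5, cell = 3))
  expect_true(all(pure$topology$atoms$mol_kind == "water"))
  expect_error(toy_mixture_builder(composition_spec(50, 500),
                                   synthetic_spec(seed = 1, cell = 2),
                                   max_tries = 5),
               "density error")
})

test_that("sugar templates carry the full label set and valid topology", {
  for (kind in c("sucrose", "trehalose")) {
    tpl <- sugar_template(kind)
    expect_equal(nrow(tpl$atoms), 23)
    expect_equal(sum(tpl$atoms$element == "O"), 11)
    expect_equal(nrow(tpl$donor_groups), 8)
    expect_length(tpl$named_groups, 11)
    expect_length(tpl$acceptor_atoms, 11)
  }
  # trehalose symmetry classes pair its equivalent groups
  tre <- sugar_template("trehalose")
  expect_length(tre$symmetry_classes, 5)
  expect_true(any(vapply(tre$symmetry_classes,
                         function(x) setequal(x, c("O4-H10", "O9-H20")), TRUE)))
  expect_length(sugar_template("sucrose")$symmetry_classes, 0)
})
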