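test_that("planted configurations give the constructed bond count", {
  spec <- synthetic_spec(seed = 17, cell = 6)
  ph <- planted_hbond_config(10, d_OO = 0.28, angle_deg = 0, spec = spec)
  expect_equal(nrow(detect_hbonds(ph$frame, ph$topology)), 10)
  # below the distance geometry
  expect_equal(nrow(detect_hbonds(ph$frame, ph$topology,
                                  hbond_criterion(0.25, 30))), 0)
  # beyond the cutoff
  far <- planted_hbond_config(10, d_OO = 0.40, angle_deg = 0, spec = spec)
  expect_equal(nrow(detect_hbonds(far$frame, far$topology)), 0)
  # angle criterion excludes bent geometry
  bent <- planted_hbond_config(10, d_OO = 0.28, angle_deg = 40, spec = spec)
  expect_equal(nrow(detect_hbonds(bent$frame, bent$topology)), 0)
  # bracketing criterion recovers them
  expect_equal(nrow(detect_hbonds(bent$frame, bent$topology,
                                  hbond_criterion(0.35, 45))), 10)
})

test_that("detection equals the O(n^2) brute-force oracle on random boxes", {
  for (seed in 1:12) {
    n_mol <- sample(20:60, 1)
    box <- random_water_box(n_mol, L = 1.6, seed = 1000 + seed)
    got <- detect_hbonds(box$frame, box$topology)
    want <- oracle_hbonds(box$frame$positions, box$topology$donor_groups,
                          box$topology$acceptor_atoms, rep(1.6, 3), 0.35, 30)
    got_keys <- sort(paste(got$donor, got$hydrogen, got$acceptor))
    want_keys <- if (is.null(want)) character() else
      sort(paste(want[, 1], want[, 2], want[, 3]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("cell-list path is identical to the all-pairs path", {
  box <- random_water_box(400, L = 3.2, seed = 99) # 1200 atoms
  fast <- detect_hbonds(box$frame, box$topology, cell_list_threshold = 1000)
  slow <- detect_hbonds(box$frame, box$topology, cell_list_threshold = 1e9)
  expect_identical(fast, slow)
  expect_gt(nrow(fast), 0)
})

test_that("category counts partition the total and normalisations divide correctly", {
  comp <- composition_spec(3, 40)
  traj <- toy_mixture_trajectory(comp, n_frames = 3,
                                 spec = synthetic_spec(seed = 8, cell = 3))
  raw <- count_series(traj, normalization = "raw")
  per_frame_total <- rowSums(raw$per_frame)
  for (f in seq_along(traj$frames)) {
    hb <- detect_hbonds(traj$frames[[f]], traj$topology)
    expect_equal(per_frame_total[f], nrow(hb))
  }
  n_oxy <- sum(traj$topology$atoms$element == "O")
  per_o <- count_series(traj, normalization = "per_total_oxygen")
  expect_equal(per_o$per_frame, raw$per_frame / n_oxy)
  expect_equal(per_o$denominator, n_oxy)
  # a pure-water box has no sugar categories
  pure <- toy_mixture_trajectory(composition_spec(0, 40), n_frames = 2,
                                 spec = synthetic_spec(seed = 3, cell = 3))
  s <- count_series(pure, normalization = "raw")
  expect_equal(unname(s$mean["sugar-sugar"]), 0)
  expect_equal(unname(s$mean["sugar-water"]), 0)
})

test_that("per-group totals add up to the sugar-water category count", {
  comp <- composition_spec(2, 50)
  traj <- toy_mixture_trajectory(comp, n_frames = 2,
                                 spec = synthetic_spec(seed = 12, cell = 3))
  tab <- group_hbond_profile(traj, symmetry_average = FALSE)
  raw <- count_series(traj, normalization = "raw")
  # groups cover all sugar oxygens, so instance-weighted sugar-water rows
  # must sum to the per-frame category mean
  expect_equal(sum(tab$sugar_water * tab$n_instances),
               unname(raw$mean["sugar-water"]))
})

test_that("symmetry averaging merges classes and is idempotent", {
  tab <- data.frame(group = c("O4-H10", "O9-H20", "O6"),
                    sugar_sugar = c(2, 0, 1), sugar_water = c(1, 3, 0),
                    n_instances = c(1L, 1L, 1L), symmetry_averaged = FALSE,
                    stringsAsFactors = FALSE)
  cls <- list(c("O4-H10", "O9-H20"))
  merged <- sugarglass:::symmetry_average_table(tab, cls)
  row <- merged[merged$group == "O4-H10/O9-H20", ]
  expect_equal(row$sugar_sugar, 1)   # (2 + 0) / 2
  expect_equal(row$sugar_water, 2)   # (1 + 3) / 2
  expect_true(row$symmetry_averaged)
  expect_identical(sugarglass:::symmetry_average_table(merged, cls), merged)
})

test_that("trehalose symmetry rows equal the mean of their class members", {
  comp <- composition_spec(2, 40)
  traj <- toy_mixture_trajectory(comp, n_frames = 2,
                                 spec = synthetic_spec(seed = 23, cell = 3),
                                 sugar_kind = "trehalose")
  full <- group_hbond_profile(traj, symmetry_average = FALSE)
  avg <- group_hbond_profile(traj, symmetry_average = TRUE)
  row <- avg[avg$group == "O4-H10/O9-H20", ]
  members <- full[full$group %in% c("O4-H10", "O9-H20"), ]
  expect_equal(row$sugar_water, mean(members$sugar_water))
  expect_equal(row$sugar_sugar, mean(members$sugar_sugar))
})

test_that("a lone aligned donor-acceptor pair yields exactly its planted bond", {
  # one water donating to one sugar hydroxyl oxygen: the group's row is 1
  tpl <- sugar_template("sucrose")
  watpl <- water_template()
  atoms <- rbind(
    data.frame(tpl$atoms, mol_index = 0L, mol_kind = "sucrose",
               stringsAsFactors = FALSE),
    data.frame(watpl$atoms, mol_index = 1L, mol_kind = "water",
               stringsAsFactors = FALSE))
  top <- topology(atoms,
                  bonds = rbind(tpl$bonds, watpl$bonds + 23L),
                  donor_groups = rbind(tpl$donor_groups, watpl$donor_groups + 23L),
                  acceptor_atoms = c(tpl$acceptor_atoms, watpl$acceptor_atoms + 23L),
                  named_groups = tpl$named_groups,
                  symmetry_classes = tpl$symmetry_classes)
  # place the water's O-H1 pointing at the O of O2-H8 from 0.29 nm,
  # approaching perpendicular to the hydroxyl's own O-H direction so the
  # sugar cannot donate back to the water
  target <- tpl$named_groups[["O2-H8"]][1] + 1L
  tO <- tpl$coords[target, ]
  u <- c(1, 0, 0)
  wO <- tO + 0.29 * u
  h1 <- wO - 0.1 * u          # points back toward the target
  h2 <- wO + c(0, 0, -0.1)    # aimed away from every other oxygen
  pos <- rbind(tpl$coords, wO, h1, h2) + 2.5
  traj <- trajectory(top, list(frame(0, pos, 6), frame(1, pos, 6)))
  tab <- group_hbond_profile(traj, symmetry_average = FALSE)
  expect_equal(tab$sugar_water[tab$group == "O2-H8"], 1)
  expect_equal(sum(tab$sugar_water), 1)
  expect_equal(sum(tab$sugar_sugar), 0)
})

test_that("difference profiles subtract pointwise and propagate errors", {
  a <- data.frame(water_mass_pct = rep(c(10, 50, 90), each = 3),
                  category = rep(c("sugar-sugar", "sugar-water", "water-water"), 3),
                  mean = 1:9, sd = rep(0.3, 9))
  expect_equal(difference_profile(a, a)$delta, rep(0, 9))
  b <- a; b$mean <- b$mean + 1
  d <- difference_profile(b, a)
  expect_equal(d$delta, rep(1, 9))
  expect_equal(d$sd, rep(sqrt(0.18), 9))
  # antisymmetry
  expect_equal(difference_profile(a, b)$delta, -d$delta)
  bad <- a; bad$water_mass_pct <- bad$water_mass_pct + 5
  expect_error(difference_profile(a, bad), "alignment error")
})

test_that("crossing points interpolate linearly and flag degeneracy", {
  out <- crossing_points(c(0, 100), c(1, 3), c(3, 1))
  expect_equal(out$crossings, 50)
  same <- crossing_points(c(0, 50, 100), c(1, 2, 3), c(1, 2, 3))
  expect_length(same$crossings, 0)
  expect_equal(same$degenerate, c(0, 50, 100))
  parallel <- crossing_points(c(0, 50, 100), c(1, 2, 3), c(2, 3, 4))
  expect_length(parallel$crossings, 0)
  expect_length(parallel$degenerate, 0)
  expect_error(crossing_points(1, 1, 1), "at least 2")
})
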