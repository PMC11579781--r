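# Independent oracles, deliberately written as plain brute-force code
# sharing nothing with the package's implementation paths.

# Minimum image by explicit search over all 27 periodic images.
oracle_min_image <- function(a, b, L) {
  best <- NULL
  best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * L) - a
    nd <- sqrt(sum(d^2))
    if (nd < best_d) { best_d <- nd; best <- d }
  }
  best
}

# Shortest periodic displacement b - a by explicit minimisation over all
# 27 images, vectorised over pair rows (independent of the package's
# round()-based arithmetic).
oracle_disp27 <- function(a, b, L) {
  n <- nrow(a)
  best <- b - a
  best_d2 <- rowSums(best^2)
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    if (ix == 0 && iy == 0 && iz == 0) next
    cand <- b + matrix(c(ix, iy, iz) * L, n, 3, byrow = TRUE) - a
    d2 <- rowSums(cand^2)
    swap <- d2 < best_d2
    best[swap, ] <- cand[swap, , drop = FALSE]
    best_d2[swap] <- d2[swap]
  }
  best
}

# O(n^2) hydrogen-bond scan: every donor O-H against every acceptor O,
# with its own 27-image periodic arithmetic.
oracle_hbonds <- function(pos, donors, acceptors, L, dist_cut, angle_cut) {
  nd <- nrow(donors); na <- length(acceptors)
  di <- rep(seq_len(nd), each = na)
  dO <- donors[di, 1L]; dH <- donors[di, 2L]
  aO <- rep(acceptors, times = nd)
  keep <- dO != aO
  dO <- dO[keep]; dH <- dH[keep]; aO <- aO[keep]
  v_da <- oracle_disp27(pos[dO + 1L, , drop = FALSE],
                        pos[aO + 1L, , drop = FALSE], L)
  dd <- sqrt(rowSums(v_da^2))
  v_dh <- oracle_disp27(pos[dO + 1L, , drop = FALSE],
                        pos[dH + 1L, , drop = FALSE], L)
  cosang <- rowSums(v_dh * v_da) / (sqrt(rowSums(v_dh^2)) * dd)
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  hit <- dd <= dist_cut & ang <= angle_cut
  if (!any(hit)) return(NULL)
  cbind(dO[hit], dH[hit], aO[hit])
}

# Dihedral via an explicit Gram-Schmidt frame: project b3 onto the plane
# frame built from b2, measure the signed angle of -b1's normal component.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  e2 <- b2 / sqrt(sum(b2^2))
  u <- -b1 - sum(-b1 * e2) * e2 # component of -b1 perpendicular to b2
  w <- b3 - sum(b3 * e2) * e2   # component of b3 perpendicular to b2
  ex <- u / sqrt(sum(u^2))
  ey <- c(e2[2] * ex[3] - e2[3] * ex[2], e2[3] * ex[1] - e2[1] * ex[3],
          e2[1] * ex[2] - e2[2] * ex[1])
  ang <- atan2(sum(w * ey), sum(w * ex)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Random water-like box: n_mol 3-site molecules (O + 2 H at 0.1 nm) at
# uniform random positions/orientations; returns topology + frame.
random_water_box <- function(n_mol, L, seed) {
  set.seed(seed)
  atoms <- NULL; pos <- NULL; bonds <- NULL; donors <- NULL
  for (m in seq_len(n_mol)) {
    o <- runif(3) * L
    hs <- lapply(1:2, function(i) {
      u <- rnorm(3); o + 0.1 * u / sqrt(sum(u^2))
    })
    base <- 3L * (m - 1L)
    pos <- rbind(pos, o, hs[[1]], hs[[2]])
    atoms <- rbind(atoms, data.frame(
      name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      mass = c(15.999, 1.008, 1.008), mol_index = m - 1L,
      mol_kind = "water", stringsAsFactors = FALSE))
    bonds <- rbind(bonds, c(base, base + 1L), c(base, base + 2L))
    donors <- rbind(donors, c(base, base + 1L), c(base, base + 2L))
  }
  rownames(pos) <- NULL
  top <- topology(atoms, bonds = bonds, donor_groups = donors,
                  acceptor_atoms = 3L * (seq_len(n_mol) - 1L))
  list(topology = top, frame = frame(0, pos, unit_cell(L)))
}

# 3-frame single-molecule trajectory from fixed coordinates.
single_molecule_trajectory <- function(tpl, kind, cell = 5, n = 3L,
                                       jitter = 0, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(tpl$atoms, mol_index = 0L, mol_kind = kind,
                      stringsAsFactors = FALSE)
  top <- topology(atoms, bonds = tpl$bonds, donor_groups = tpl$donor_groups,
                  acceptor_atoms = tpl$acceptor_atoms,
                  named_groups = tpl$named_groups,
                  symmetry_classes = tpl$symmetry_classes)
  frames <- lapply(seq_len(n), function(i) {
    p <- tpl$coords + 2.5
    if (jitter > 0) p <- p + matrix(rnorm(length(p), sd = jitter), ncol = 3L)
    frame(i - 1, p, cell)
  })
  trajectory(top, frames)
}
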