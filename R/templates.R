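# Rigid model molecule templates.
#
# The sugar templates are schematic 23-site disaccharide skeletons carrying
# the oxygen/hydroxyl label set used throughout the analyses (two rings of
# four hydroxyls each, two ring ether oxygens, one glycosidic ether), not
# force-field-accurate conformers. Trehalose additionally declares its
# symmetry classes (the C2-symmetric group pairs); sucrose groups are all
# distinct.

sugar_label_sets <- list(
  sucrose = list(
    ring_a_oh = c("O2-H8", "O3-H9", "O4-H10", "O6-H11"),
    ring_b_oh = c("O8-H19", "O9-H20", "O10-H21", "O11-H22"),
    ether_a = "O1", ether_b = "O7", ether_glyco = "O5",
    symmetry = list()),
  trehalose = list(
    ring_a_oh = c("O2-H8", "O3-H9", "O4-H10", "O5-H11"),
    ring_b_oh = c("O8-H19", "O9-H20", "O10-H21", "O11-H22"),
    ether_a = "O1", ether_b = "O7", ether_glyco = "O6",
    symmetry = list(c("O2-H8", "O11-H22"), c("O3-H9", "O10-H21"),
                    c("O4-H10", "O9-H20"), c("O5-H11", "O8-H19"),
                    c("O1", "O7")))
)

split_oh_label <- function(lab) strsplit(lab, "-", fixed = TRUE)[[1]]

#' Rigid model disaccharide template
#'
#' A 23-site schematic disaccharide: four backbone carbons, three ether
#' oxygens (two ring, one glycosidic) and eight hydroxyl groups arranged
#' radially around two ring centers, with the group label set used by the
#' per-group hydrogen-bond and free-energy analyses. O-H bonds are 0.1 nm;
#' hydroxyl oxygens sit 0.22 nm from their ring center and the ring
#' centers are 0.6 nm apart.
#'
#' @param kind `"sucrose"` or `"trehalose"` (the latter carries symmetry
#'   classes for its equivalent group pairs).
#' @return A `molecule_template`: list with `coords` (n x 3, nm, centered),
#'   `atoms` (data.frame), `bonds`, `donor_groups`, `acceptor_atoms`
#'   (0-based, local), `named_groups`, `symmetry_classes`.
#' @export
sugar_template <- function(kind = c("sucrose", "trehalose")) {
  kind <- match.arg(kind)
  lab <- sugar_label_sets[[kind]]
  cA <- c(-0.30, 0, 0); cB <- c(0.30, 0, 0)
  atoms <- data.frame(name = character(), element = character(),
                      mass = numeric(), stringsAsFactors = FALSE)
  coords <- NULL
  add_atom <- function(name, element, pos) {
    atoms <<- rbind(atoms, data.frame(name = name, element = element,
                                      mass = unname(element_masses[element]),
                                      stringsAsFactors = FALSE))
    coords <<- rbind(coords, pos)
    nrow(atoms) - 1L # local 0-based index
  }
  iC1 <- add_atom("C1", "C", cA)
  iC2 <- add_atom("C2", "C", cA + c(0.15, 0, 0))
  iC3 <- add_atom("C3", "C", cB - c(0.15, 0, 0))
  iC4 <- add_atom("C4", "C", cB)
  bonds <- rbind(c(iC1, iC2), c(iC3, iC4))
  named_groups <- list()

  iOg <- add_atom(lab$ether_glyco, "O", c(0, 0, 0.10))
  bonds <- rbind(bonds, c(iC2, iOg), c(iC3, iOg))
  named_groups[[lab$ether_glyco]] <- iOg
  iOa <- add_atom(lab$ether_a, "O", cA + c(-0.10, 0, 0.18))
  bonds <- rbind(bonds, c(iC1, iOa))
  named_groups[[lab$ether_a]] <- iOa
  iOb <- add_atom(lab$ether_b, "O", cB + c(0.10, 0, 0.18))
  bonds <- rbind(bonds, c(iC4, iOb))
  named_groups[[lab$ether_b]] <- iOb

  donor_groups <- NULL
  place_oh <- function(labels, center, carbon) {
    th <- c(45, 135, 225, 315) * pi / 180
    for (i in seq_along(labels)) {
      parts <- split_oh_label(labels[i])
      dir <- c(0, cos(th[i]), sin(th[i]))
      iO <- add_atom(parts[1L], "O", center + 0.22 * dir)
      iH <- add_atom(parts[2L], "H", center + 0.32 * dir)
      bonds <<- rbind(bonds, c(carbon, iO), c(iO, iH))
      donor_groups <<- rbind(donor_groups, c(iO, iH))
      named_groups[[labels[i]]] <<- c(iO, iH)
    }
  }
  place_oh(lab$ring_a_oh, cA, iC1)
  place_oh(lab$ring_b_oh, cB, iC4)

  acceptor_atoms <- which(atoms$element == "O") - 1L
  rownames(coords) <- NULL
  structure(list(coords = coords, atoms = atoms, bonds = bonds,
                 donor_groups = donor_groups, acceptor_atoms = acceptor_atoms,
                 named_groups = named_groups, symmetry_classes = lab$symmetry,
                 kind = kind),
            class = "molecule_template")
}

#' Rigid 3-site water template
#'
#' O-H bonds of 0.1 nm at the tetrahedral HOH angle.
#'
#' @return A `molecule_template` (see [sugar_template()]).
#' @export
water_template <- function() {
  a <- 109.47 * pi / 180 / 2
  coords <- rbind(c(0, 0, 0),
                  c(0.1 * sin(a), 0.1 * cos(a), 0),
                  c(-0.1 * sin(a), 0.1 * cos(a), 0))
  atoms <- data.frame(name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
                      mass = c(15.999, 1.008, 1.008), stringsAsFactors = FALSE)
  structure(list(coords = coords, atoms = atoms,
                 bonds = rbind(c(0L, 1L), c(0L, 2L)),
                 donor_groups = rbind(c(0L, 1L), c(0L, 2L)),
                 acceptor_atoms = 0L, named_groups = list(),
                 symmetry_classes = list(), kind = "water"),
            class = "molecule_template")
}

# Assemble a topology + frame from placed template instances.
# placements: list of list(template, coords (already rotated/translated),
# kind); labels from the first molecule of each sugar kind are exported as
# named groups (per-molecule resolution happens in the group analysis).
assemble_system <- function(placements, cell) {
  atoms <- list(); coords <- list()
  bonds <- NULL; donors <- NULL; acceptors <- integer()
  named_groups <- list(); symmetry_classes <- list()
  offset <- 0L
  for (m in seq_along(placements)) {
    pl <- placements[[m]]
    tpl <- pl$template
    n <- nrow(tpl$atoms)
    atoms[[m]] <- data.frame(tpl$atoms, mol_index = m - 1L,
                             mol_kind = pl$kind, stringsAsFactors = FALSE)
    coords[[m]] <- pl$coords
    if (!is.null(tpl$bonds)) bonds <- rbind(bonds, tpl$bonds + offset)
    if (!is.null(tpl$donor_groups)) donors <- rbind(donors, tpl$donor_groups + offset)
    acceptors <- c(acceptors, tpl$acceptor_atoms + offset)
    # labels accumulate across molecules of the same kind; the group
    # analysis normalises by the number of molecule instances per label
    for (g in names(tpl$named_groups)) {
      named_groups[[g]] <- c(named_groups[[g]], tpl$named_groups[[g]] + offset)
    }
    for (cls in tpl$symmetry_classes) {
      if (!any(vapply(symmetry_classes, function(x) setequal(x, cls), TRUE))) {
        symmetry_classes <- c(symmetry_classes, list(cls))
      }
    }
    offset <- offset + n
  }
  top <- topology(do.call(rbind, atoms), bonds = bonds, donor_groups = donors,
                  acceptor_atoms = acceptors, named_groups = named_groups,
                  symmetry_classes = symmetry_classes)
  list(topology = top, frame = frame(0, do.call(rbind, coords), cell))
}

# Rotation taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) { # antiparallel: rotate pi about any perpendicular
    p <- random_perpendicular(a)
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               nrow = 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(axis, axis) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
           nrow = 3L, byrow = TRUE) * s_
}

# One random rigid placement attempt set for a whole mixture; returns NULL
# on packing failure. Runs inside the caller's seeded RNG.
#
# Placement emulates a hydrogen-bonded liquid: with probability
# p_attach (per molecule, given an oxygen is already present) the new
# molecule is placed as an aligned donor to a randomly chosen placed
# acceptor oxygen - one of its O-H bonds pointing at the target oxygen
# at an O...O distance drawn from attach_range - so planted bonds
# satisfy any conventional geometric criterion. Other molecules (and
# failed attachment attempts) fall back to uniform random placement.
place_mixture_once <- function(composition, cell, sugar_kind, min_sep,
                               max_tries, clustered = FALSE,
                               cluster_radius = 1.2,
                               p_attach_water = 0.9, p_attach_sugar = 0.35,
                               attach_range = c(0.28, 0.32)) {
  L <- as.numeric(cell)
  tpl_sugar <- sugar_template(sugar_kind)
  tpl_water <- water_template()
  placements <- list()
  placed <- NULL       # running atom-position matrix for overlap checks
  placed_mol <- integer() # owning molecule per placed atom
  acc_rows <- integer()   # rows of `placed` that are acceptor oxygens
  cluster_center <- runif(3) * L

  check_and_commit <- function(tpl, cand, kind, exempt_rows = integer()) {
    ok <- TRUE
    if (!is.null(placed)) {
      ii <- rep(seq_len(nrow(cand)) - 1L, each = nrow(placed))
      jj <- rep(seq_len(nrow(placed)) - 1L, times = nrow(cand))
      d <- pair_distances_cpp(cand, placed, ii, jj, L)
      thr <- rep(min_sep, length(d))
      if (length(exempt_rows) > 0L) {
        # the planted donor contact is allowed closer than min_sep
        thr[(jj + 1L) %in% exempt_rows] <- 0.12
      }
      ok <- all(d >= thr)
    }
    if (ok) {
      m <- length(placements) + 1L
      acc_rows <<- c(acc_rows, (nrow(placed) %||% 0L) + tpl$acceptor_atoms + 1L)
      placed <<- rbind(placed, cand)
      placed_mol <<- c(placed_mol, rep(m, nrow(cand)))
      placements[[m]] <<- list(template = tpl, coords = cand, kind = kind)
    }
    ok
  }

  add_molecule <- function(tpl, kind, sugar, p_attach) {
    attach <- length(acc_rows) > 0L && runif(1) < p_attach
    if (attach) {
      for (try in seq_len(max_tries)) {
        target_row <- acc_rows[sample.int(length(acc_rows), 1L)]
        target <- placed[target_row, ]
        dg <- tpl$donor_groups
        don <- dg[sample.int(nrow(dg), 1L), ]
        v0 <- tpl$coords[don[2L] + 1L, ] - tpl$coords[don[1L] + 1L, ]
        v0 <- v0 / sqrt(sum(v0^2))
        u <- rnorm(3); u <- u / sqrt(sum(u^2)) # new O -> target direction
        rot <- rotation_between(v0, u) # roll about u is free
        rot <- rotation_about(u, runif(1, 0, 2 * pi)) %*% rot
        d_att <- runif(1, attach_range[1L], attach_range[2L])
        coords_rot <- tpl$coords %*% t(rot)
        shift <- (target - d_att * u) - coords_rot[don[1L] + 1L, ]
        cand <- wrap_positions(sweep(coords_rot, 2L, shift, `+`), cell)
        tgt_mol_rows <- which(placed_mol == placed_mol[target_row])
        if (check_and_commit(tpl, cand, kind, exempt_rows = tgt_mol_rows)) {
          return(TRUE)
        }
      }
      # fall through to free placement
    }
    for (try in seq_len(max_tries)) {
      rot <- random_rotation()
      shift <- if (sugar && clustered) {
        d <- rnorm(3); r <- runif(1)^(1 / 3) * cluster_radius
        (cluster_center + d / sqrt(sum(d^2)) * r) %% L
      } else runif(3) * L
      cand <- wrap_positions(sweep(tpl$coords %*% t(rot), 2L, shift, `+`), cell)
      if (check_and_commit(tpl, cand, kind)) return(TRUE)
    }
    FALSE
  }
  p_sugar <- if (clustered) min(1, 2 * p_attach_sugar) else p_attach_sugar
  for (s in seq_len(composition$n_sugar)) {
    if (!add_molecule(tpl_sugar, sugar_kind, sugar = TRUE, p_sugar)) return(NULL)
  }
  for (w in seq_len(composition$n_water)) {
    if (!add_molecule(tpl_water, "water", sugar = FALSE, p_attach_water)) return(NULL)
  }
  placements
}

#' Random non-overlapping model mixture with planted hydrogen bonds
#'
#' Places rigid model sugar templates and 3-site waters at random
#' positions and orientations with all inter-molecular atom distances of
#' at least `min_sep` (0.3 nm by default, the placement rule of the study
#' design). To emulate a hydrogen-bonded liquid, a configurable fraction
#' of molecules is placed as aligned donors to an already-placed acceptor
#' oxygen (O...O distance 0.28-0.32 nm, collinear O-H), the planted-bond
#' geometry; all other molecules are placed uniformly, and their random
#' orientations contribute essentially no additional bonds under a 30
#' degree criterion. Deterministic under the spec's seed.
#'
#' @param composition a [composition_spec()].
#' @param spec a [synthetic_spec()] providing seed and cell.
#' @param sugar_kind `"sucrose"` or `"trehalose"`.
#' @param min_sep minimum inter-molecular atom distance (nm).
#' @param max_tries placement attempts per molecule before declaring a
#'   packing failure.
#' @param clustered place sugar molecules within a compact cluster (and
#'   double their attachment probability), emulating the sugar
#'   aggregation of preheated systems.
#' @param p_attach_water,p_attach_sugar probability that a water / sugar
#'   molecule is placed as an aligned hydrogen-bond donor to a placed
#'   oxygen rather than uniformly.
#' @return List with `topology` and `frame`.
#' @export
toy_mixture_builder <- function(composition, spec = synthetic_spec(),
                                sugar_kind = c("sucrose", "trehalose"),
                                min_sep = 0.3, max_tries = 200L,
                                clustered = FALSE, p_attach_water = 0.9,
                                p_attach_sugar = 0.35) {
  stopifnot(inherits(composition, "composition_spec"))
  sugar_kind <- match.arg(sugar_kind)
  with_seed(spec$seed, {
    placements <- place_mixture_once(composition, spec$cell, sugar_kind,
                                     min_sep, max_tries, clustered,
                                     p_attach_water = p_attach_water,
                                     p_attach_sugar = p_attach_sugar)
    if (is.null(placements)) {
      stop("density error: could not place ", composition$n_sugar, " sugars + ",
           composition$n_water, " waters at min separation ", min_sep,
           " nm after ", max_tries, " tries per molecule")
    }
    assemble_system(placements, spec$cell)
  })
}

#' Synthetic mixture trajectory
#'
#' Builds an `n_frames`-frame trajectory whose frames are independent
#' random rigid packings of the same composition (an equilibrium-ensemble
#' stand-in with per-frame seeds derived from the spec seed). The
#' `"preheated"` protocol label places sugars clustered, emulating the
#' sugar aggregation that thermal annealing induces; `"not_preheated"`
#' places them uniformly.
#'
#' @inheritParams toy_mixture_builder
#' @param n_frames number of frames (1 ps spacing).
#' @param protocol `"preheated"`, `"not_preheated"` or `"n/a"`.
#' @return A [trajectory()].
#' @export
toy_mixture_trajectory <- function(composition, n_frames = 5L,
                                   spec = synthetic_spec(),
                                   sugar_kind = c("sucrose", "trehalose"),
                                   protocol = "n/a", min_sep = 0.3,
                                   max_tries = 200L, p_attach_water = 0.9,
                                   p_attach_sugar = 0.35) {
  sugar_kind <- match.arg(sugar_kind)
  clustered <- identical(protocol, "preheated") && composition$n_sugar > 1L
  frames <- vector("list", n_frames)
  top <- NULL
  for (f in seq_len(n_frames)) {
    sys <- toy_mixture_builder(
      composition,
      synthetic_spec(seed = derive_seed(spec$seed, paste0("frame", f)),
                     cell = as.numeric(spec$cell)),
      sugar_kind = sugar_kind, min_sep = min_sep, max_tries = max_tries,
      clustered = clustered, p_attach_water = p_attach_water,
      p_attach_sugar = p_attach_sugar)
    if (is.null(top)) top <- sys$topology
    frames[[f]] <- frame(f - 1, sys$frame$positions, spec$cell)
  }
  trajectory(top, frames, protocol = protocol,
             water_mass_pct = composition$water_mass_pct,
             description = sprintf("synthetic %s mixture (%d sugar, %d water)",
                                   sugar_kind, composition$n_sugar,
                                   composition$n_water))
}
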