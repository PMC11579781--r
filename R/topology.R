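#' Molecular topology
#'
#' A `topology` binds per-atom annotations (name, element, mass, molecule
#' index and kind) to the hydrogen-bonding roles and named oxygen/hydroxyl
#' groups that all downstream analyses use. Atom indexing is 0-based
#' internally; 1-based indices appear only in files (GRO convention).
#'
#' @param atoms data.frame with columns `name` (character), `element`
#'   (character), `mass` (g/mol, > 0), `mol_index` (integer, 0-based),
#'   `mol_kind` (one of `"sucrose"`, `"trehalose"`, `"water"`, `"model"`).
#' @param bonds two-column integer matrix of bonded atom pairs (0-based).
#' @param donor_groups two-column integer matrix; each row an O-H pair
#'   (donor oxygen, donor hydrogen) eligible to donate a hydrogen bond.
#' @param acceptor_atoms integer vector of acceptor oxygen indices.
#' @param named_groups named list mapping a group label (e.g. `"O10-H21"`,
#'   `"O5"`) to its 0-based atom-index set. Groups must be disjoint within
#'   a molecule.
#' @param symmetry_classes list of character vectors; each vector is a set
#'   of group labels treated as chemically equivalent (e.g. the symmetric
#'   hydroxyls of trehalose).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL, donor_groups = NULL,
                     acceptor_atoms = integer(), named_groups = list(),
                     symmetry_classes = list()) {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "element", "mass", "mol_index", "mol_kind")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  kinds <- c("sucrose", "trehalose", "water", "model")
  if (!all(atoms$mol_kind %in% kinds)) {
    stop("mol_kind must be one of: ", paste(kinds, collapse = ", "))
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be positive and finite")
  }
  n <- nrow(atoms)
  bonds <- as_index_pairs(bonds, n, "bonds")
  donor_groups <- as_index_pairs(donor_groups, n, "donor_groups")
  acceptor_atoms <- check_indices(acceptor_atoms, n, "acceptor_atoms")

  # every donor hydrogen must be bonded to its donor oxygen
  if (nrow(donor_groups) > 0L) {
    bond_keys <- c(paste(bonds[, 1L], bonds[, 2L]), paste(bonds[, 2L], bonds[, 1L]))
    dg_keys <- paste(donor_groups[, 1L], donor_groups[, 2L])
    if (!all(dg_keys %in% bond_keys)) {
      stop("every donor hydrogen must be bonded to its donor oxygen")
    }
  }

  if (length(named_groups) > 0L) {
    if (is.null(names(named_groups)) || any(names(named_groups) == "")) {
      stop("named_groups must be a named list")
    }
    named_groups <- lapply(named_groups, check_indices, n = n, what = "named_groups")
    # no atom may belong to two labels (disjointness within each molecule)
    idx <- unlist(named_groups, use.names = FALSE)
    if (anyDuplicated(idx)) stop("named_groups overlap")
  }
  if (length(symmetry_classes) > 0L) {
    for (cls in symmetry_classes) {
      if (length(cls) < 1L) stop("every symmetry class needs at least one member")
      unknown <- setdiff(cls, names(named_groups))
      if (length(unknown) > 0L) {
        stop("symmetry class refers to unknown group(s): ",
             paste(unknown, collapse = ", "))
      }
    }
  }

  structure(list(atoms = atoms, bonds = bonds, donor_groups = donor_groups,
                 acceptor_atoms = acceptor_atoms, named_groups = named_groups,
                 symmetry_classes = symmetry_classes),
            class = "topology")
}

as_index_pairs <- function(x, n, what) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, NULL)))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop(what, " must be a two-column matrix of atom indices")
  storage.mode(x) <- "integer"
  check_indices(as.vector(x), n, what)
  x
}

check_indices <- function(idx, n, what) {
  idx <- as.integer(idx)
  if (length(idx) > 0L && (any(idx < 0L) || any(idx >= n))) {
    stop(what, " contains out-of-range atom indices (0-based, n = ", n, ")")
  }
  idx
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d molecules, %d bonds\n",
              nrow(x$atoms), length(unique(x$atoms$mol_index)), nrow(x$bonds)))
  cat(sprintf("  donors: %d O-H pairs, acceptors: %d O, named groups: %d, symmetry classes: %d\n",
              nrow(x$donor_groups), length(x$acceptor_atoms),
              length(x$named_groups), length(x$symmetry_classes)))
  invisible(x)
}

#' Orthorhombic unit cell
#'
#' @param lengths numeric vector of three box edge lengths in nm (a scalar
#'   is recycled to a cubic cell). Triclinic cells are rejected.
#' @return An object of class `unit_cell` (numeric length-3 vector).
#' @export
unit_cell <- function(lengths) {
  if (length(lengths) == 1L) lengths <- rep(lengths, 3L)
  if (length(lengths) != 3L) {
    stop("only orthorhombic cells are supported: give 3 edge lengths (nm)")
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all cell edge lengths must be positive")
  }
  structure(lengths, class = "unit_cell")
}

#' Single trajectory frame
#'
#' @param time time in ps.
#' @param positions n x 3 numeric matrix of coordinates in nm.
#' @param cell a [unit_cell()].
#' @return An object of class `frame`.
#' @export
frame <- function(time, positions, cell) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix (nm)")
  if (!inherits(cell, "unit_cell")) cell <- unit_cell(cell)
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time))
  structure(list(time = as.numeric(time), positions = positions, cell = cell),
            class = "frame")
}

#' Trajectory: a topology plus an ordered list of frames
#'
#' @param topology a [topology()].
#' @param frames list of [frame()] objects with strictly increasing times
#'   and a shared atom count equal to the topology's.
#' @param protocol equilibration-protocol label: `"preheated"`,
#'   `"not_preheated"` or `"n/a"`. Carried as metadata only.
#' @param water_mass_pct water mass percentage of the system (0-100), or
#'   `NA` when not applicable.
#' @param description free-text description.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, protocol = "n/a",
                       water_mass_pct = NA_real_, description = "") {
  stopifnot(inherits(topology, "topology"), is.list(frames), length(frames) >= 1L)
  protocol <- match.arg(protocol, c("preheated", "not_preheated", "n/a"))
  n_atoms <- nrow(topology$atoms)
  times <- vapply(frames, function(f) {
    if (!inherits(f, "frame")) stop("frames must be a list of frame objects")
    if (nrow(f$positions) != n_atoms) {
      stop("frame atom count (", nrow(f$positions),
           ") does not match topology (", n_atoms, ")")
    }
    f$time
  }, 0)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, frames = frames,
                 protocol = protocol, water_mass_pct = water_mass_pct,
                 description = description),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms [%s, %s wt%% water]\n",
              length(x$frames), nrow(x$topology$atoms), x$protocol,
              ifelse(is.na(x$water_mass_pct), "?", format(x$water_mass_pct))))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) vapply(traj$frames, `[[`, 0, "time")

#' Select atoms by group label or kind/element expression
#'
#' Resolves either a named-group label declared in the topology (e.g.
#' `"O10-H21"`) or a simple filter expression of the form
#' `"<kind>"`, `"element <El>"` or `"<kind> and element <El>"`
#' (e.g. `"water and element O"`).
#'
#' @param topology a [topology()].
#' @param what group label or filter expression.
#' @return Sorted integer vector of 0-based atom indices. Deterministic and
#'   idempotent: the same input always yields the same sorted set.
#' @export
select_group <- function(topology, what) {
  stopifnot(inherits(topology, "topology"), is.character(what), length(what) == 1L)
  if (what %in% names(topology$named_groups)) {
    return(sort(unique(topology$named_groups[[what]])))
  }
  tokens <- strsplit(trimws(what), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(topology$atoms))
  kinds <- c("sucrose", "trehalose", "water", "model")
  matched <- FALSE
  for (tok in tokens) {
    tok <- trimws(tok)
    if (tok %in% kinds) {
      keep <- keep & (topology$atoms$mol_kind == tok)
      matched <- TRUE
    } else if (grepl("^element\\s+\\S+$", tok)) {
      el <- sub("^element\\s+", "", tok)
      keep <- keep & (topology$atoms$element == el)
      matched <- TRUE
    } else {
      stop("unknown group '", what, "'; available labels: ",
           paste(names(topology$named_groups), collapse = ", "))
    }
  }
  if (!matched) {
    stop("unknown group '", what, "'; available labels: ",
         paste(names(topology$named_groups), collapse = ", "))
  }
  sort(which(keep) - 1L)
}
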