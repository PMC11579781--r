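# Geometric hydrogen-bond detection and the study's counting conventions.

#' Geometric hydrogen-bond criterion
#'
#' A donor-acceptor oxygen pair is bonded when the minimum-image O(D)...O(A)
#' distance is at most `dist_cutoff` and the H-D-A angle (at the donor,
#' between the O-H bond and the O...O axis) is at most `angle_cutoff`.
#' The defaults (0.35 nm, 30 degrees) are the conventional geometric
#' criterion of GROMACS-style analyses; both are configurable because
#' different engines ship different defaults.
#'
#' @param dist_cutoff donor-acceptor distance cutoff (nm, > 0).
#' @param angle_cutoff H-D-A angle cutoff (degrees, > 0).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 0.35, angle_cutoff = 30) {
  stopifnot(dist_cutoff > 0, angle_cutoff > 0)
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

hb_category <- function(kind_d, kind_a) {
  wd <- kind_d == "water"; wa <- kind_a == "water"
  ifelse(wd & wa, "water-water",
         ifelse(wd | wa, "sugar-water", "sugar-sugar"))
}

HB_CATEGORIES <- c("sugar-sugar", "sugar-water", "water-water")

#' Detect hydrogen bonds in one frame
#'
#' Scans all declared donor O-H pairs against all acceptor oxygens under
#' the geometric criterion, with minimum-image distances. Each D-H...A
#' triple counts once (a donor oxygen with two hydrogens can form two
#' bonds). For systems above `cell_list_threshold` atoms a cell-list
#' neighbour search restricts the candidate acceptors per donor; the
#' accepted set is identical to the all-pairs scan because the criterion
#' arithmetic is unchanged and the cell list provably contains every
#' acceptor within the cutoff.
#'
#' @param frm a [frame()].
#' @param top a [topology()] declaring `donor_groups` and `acceptor_atoms`.
#' @param criterion an [hbond_criterion()].
#' @param cell_list_threshold atom count above which the cell list is used.
#' @return data.frame with columns `donor` (O index), `hydrogen`,
#'   `acceptor` (O index), `distance` (nm), `angle` (degrees), `category`
#'   (sugar-sugar / sugar-water / water-water; non-water molecule kinds
#'   count as the sugar side). Rows ordered by (donor, hydrogen, acceptor).
#' @export
detect_hbonds <- function(frm, top, criterion = hbond_criterion(),
                          cell_list_threshold = 1000L) {
  stopifnot(inherits(frm, "frame"), inherits(top, "topology"),
            inherits(criterion, "hbond_criterion"))
  if (nrow(top$donor_groups) == 0L) {
    stop("topology error: no donor O-H pairs declared")
  }
  pos <- frm$positions
  cell <- frm$cell
  donors <- top$donor_groups
  acceptors <- top$acceptor_atoms
  n_atoms <- nrow(pos)

  candidate <- if (n_atoms > cell_list_threshold) {
    cell_list_candidates(pos, cell, donors[, 1L], acceptors, criterion$dist_cutoff)
  } else {
    list(di = rep(seq_len(nrow(donors)), each = length(acceptors)),
         ai = rep(seq_along(acceptors), times = nrow(donors)))
  }
  di <- candidate$di; ai <- candidate$ai
  if (length(di) == 0L) {
    return(empty_hbond_table())
  }
  d_idx <- donors[di, 1L]; h_idx <- donors[di, 2L]; a_idx <- acceptors[ai]
  keep <- d_idx != a_idx
  di <- di[keep]
  d_idx <- d_idx[keep]; h_idx <- h_idx[keep]; a_idx <- a_idx[keep]
  if (length(d_idx) == 0L) return(empty_hbond_table())

  v_da <- minimum_image_displacement(pos[d_idx + 1L, , drop = FALSE],
                                     pos[a_idx + 1L, , drop = FALSE], cell)
  if (!is.matrix(v_da)) v_da <- matrix(v_da, ncol = 3L)
  dist_da <- sqrt(rowSums(v_da^2))
  within <- dist_da <= criterion$dist_cutoff
  if (!any(within)) return(empty_hbond_table())
  d_idx <- d_idx[within]; h_idx <- h_idx[within]; a_idx <- a_idx[within]
  v_da <- v_da[within, , drop = FALSE]; dist_da <- dist_da[within]

  v_dh <- minimum_image_displacement(pos[d_idx + 1L, , drop = FALSE],
                                     pos[h_idx + 1L, , drop = FALSE], cell)
  if (!is.matrix(v_dh)) v_dh <- matrix(v_dh, ncol = 3L)
  cosang <- rowSums(v_dh * v_da) / (sqrt(rowSums(v_dh^2)) * dist_da)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ok <- ang <= criterion$angle_cutoff
  if (!any(ok)) return(empty_hbond_table())

  kinds <- top$atoms$mol_kind
  out <- data.frame(donor = d_idx[ok], hydrogen = h_idx[ok],
                    acceptor = a_idx[ok], distance = dist_da[ok],
                    angle = ang[ok],
                    category = hb_category(kinds[d_idx[ok] + 1L],
                                           kinds[a_idx[ok] + 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hbond_table <- function() {
  data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
             distance = numeric(), angle = numeric(), category = character(),
             stringsAsFactors = FALSE)
}

# Cell-list candidate (donor-row, acceptor-position) index pairs: bins of
# edge >= cutoff, 27-neighbourhood lookup. Guaranteed superset of all
# in-range pairs.
cell_list_candidates <- function(pos, cell, donor_o, acceptors, cutoff) {
  L <- as.numeric(cell)
  nb <- pmax(1L, floor(L / cutoff))
  wrapped <- wrap_positions(pos, cell)
  bin_of <- function(idx0) {
    p <- wrapped[idx0 + 1L, , drop = FALSE]
    b <- cbind(pmin(floor(p[, 1L] / L[1L] * nb[1L]), nb[1L] - 1L),
               pmin(floor(p[, 2L] / L[2L] * nb[2L]), nb[2L] - 1L),
               pmin(floor(p[, 3L] / L[3L] * nb[3L]), nb[3L] - 1L))
    b[, 1L] + nb[1L] * (b[, 2L] + nb[2L] * b[, 3L])
  }
  acc_bin <- bin_of(acceptors)
  acc_by_bin <- split(seq_along(acceptors), acc_bin)
  don_bin3 <- {
    p <- wrapped[donor_o + 1L, , drop = FALSE]
    cbind(pmin(floor(p[, 1L] / L[1L] * nb[1L]), nb[1L] - 1L),
          pmin(floor(p[, 2L] / L[2L] * nb[2L]), nb[2L] - 1L),
          pmin(floor(p[, 3L] / L[3L] * nb[3L]), nb[3L] - 1L))
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  di_all <- integer(0); ai_all <- integer(0)
  for (d in seq_along(donor_o)) {
    nbr <- sweep(offs, 2L, don_bin3[d, ], `+`)
    nbr <- sweep(nbr, 2L, nb, `%%`)
    key <- unique(nbr[, 1L] + nb[1L] * (nbr[, 2L] + nb[2L] * nbr[, 3L]))
    cand <- unlist(acc_by_bin[as.character(key)], use.names = FALSE)
    if (length(cand) > 0L) {
      di_all <- c(di_all, rep(d, length(cand)))
      ai_all <- c(ai_all, cand)
    }
  }
  list(di = di_all, ai = ai_all)
}

#' Per-frame hydrogen-bond counts by category
#'
#' Counts sugar-sugar, sugar-water and water-water bonds in every frame
#' and summarises mean and standard deviation across frames. The
#' `per_total_oxygen` normalisation divides by the count of all oxygen
#' atoms in the system (sugar plus water), the convention used for
#' whole-system comparisons across the concentration series.
#'
#' @param traj a [trajectory()].
#' @param criterion an [hbond_criterion()].
#' @param normalization `"raw"`, `"per_total_oxygen"`, or `"per_group"`
#'   (divides by the number of declared named groups).
#' @return An `hbond_series`: list with `per_frame` (frames x categories
#'   matrix of normalised counts), `mean`, `sd` (named by category),
#'   `normalization`, `denominator`, `n_frames`, plus the trajectory's
#'   protocol and water mass percentage.
#' @export
count_series <- function(traj, criterion = hbond_criterion(),
                         normalization = c("raw", "per_total_oxygen", "per_group")) {
  stopifnot(inherits(traj, "trajectory"))
  normalization <- match.arg(normalization)
  if (n_frames(traj) < 1L) stop("input error: empty trajectory")
  denom <- switch(normalization,
    raw = 1,
    per_total_oxygen = sum(traj$topology$atoms$element == "O"),
    per_group = length(traj$topology$named_groups))
  if (denom == 0) stop("normalization denominator is zero")
  per_frame <- t(vapply(traj$frames, function(f) {
    hb <- detect_hbonds(f, traj$topology, criterion)
    counts <- table(factor(hb$category, levels = HB_CATEGORIES))
    as.numeric(counts)
  }, numeric(3L)))
  colnames(per_frame) <- HB_CATEGORIES
  per_frame <- per_frame / denom
  structure(list(per_frame = per_frame,
                 mean = colMeans(per_frame),
                 sd = apply(per_frame, 2L, sd),
                 normalization = normalization, denominator = denom,
                 n_frames = nrow(per_frame),
                 protocol = traj$protocol,
                 water_mass_pct = traj$water_mass_pct),
            class = "hbond_series")
}

# Map each atom index (0-based) to its owning group label, NA if none.
group_membership <- function(top) {
  lab <- rep(NA_character_, nrow(top$atoms))
  for (g in names(top$named_groups)) lab[top$named_groups[[g]] + 1L] <- g
  lab
}

#' Per-group hydrogen-bond profile
#'
#' For every named O/O-H group of the sugar molecules, counts hydrogen
#' bonds (donated or accepted) between the group's atoms and (a) atoms of
#' other sugar groups (`sugar_sugar` column) and (b) water
#' (`sugar_water` column), excluding bonds internal to the selected group.
#' Counts are means per frame and per group instance (label present in
#' several molecules = several instances). Members of one symmetry class
#' are averaged into a single row (class total divided by class size);
#' averaging is idempotent.
#'
#' @param traj a [trajectory()] whose topology declares named groups.
#' @param criterion an [hbond_criterion()].
#' @param symmetry_average collapse symmetry classes into single rows.
#' @return A `group_hbond_table` data.frame with columns `group`,
#'   `sugar_sugar`, `sugar_water`, `n_instances`, `symmetry_averaged`.
#' @export
group_hbond_profile <- function(traj, criterion = hbond_criterion(),
                                symmetry_average = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  if (length(top$named_groups) == 0L) {
    stop("configuration error: topology declares no named groups")
  }
  membership <- group_membership(top)
  # overlapping definitions are rejected at topology construction; the
  # membership map is therefore single-valued
  kinds <- top$atoms$mol_kind
  mols <- top$atoms$mol_index
  labels <- names(top$named_groups)
  n_inst <- vapply(labels, function(g) {
    length(unique(mols[top$named_groups[[g]] + 1L]))
  }, 0L)
  ss <- setNames(numeric(length(labels)), labels)
  sw <- setNames(numeric(length(labels)), labels)
  nf <- n_frames(traj)
  for (f in traj$frames) {
    hb <- detect_hbonds(f, top, criterion)
    if (nrow(hb) == 0L) next
    gd <- membership[hb$donor + 1L]
    ga <- membership[hb$acceptor + 1L]
    same_group_instance <- !is.na(gd) & !is.na(ga) & gd == ga &
      mols[hb$donor + 1L] == mols[hb$acceptor + 1L]
    for (r in seq_len(nrow(hb))) {
      if (same_group_instance[r]) next # internal to one group: excluded
      kd <- kinds[hb$donor + 1L][r]; ka <- kinds[hb$acceptor + 1L][r]
      if (hb$category[r] == "water-water") next
      if (hb$category[r] == "sugar-sugar") {
        # credit both endpoint groups (each group sees one bond)
        if (!is.na(gd[r])) ss[gd[r]] <- ss[gd[r]] + 1
        if (!is.na(ga[r])) ss[ga[r]] <- ss[ga[r]] + 1
      } else { # sugar-water: credit the sugar-side group
        g <- if (kd != "water") gd[r] else ga[r]
        if (!is.na(g)) sw[g] <- sw[g] + 1
      }
    }
  }
  ss <- ss / (nf * n_inst)
  sw <- sw / (nf * n_inst)
  out <- data.frame(group = labels, sugar_sugar = unname(ss),
                    sugar_water = unname(sw), n_instances = unname(n_inst),
                    symmetry_averaged = FALSE, stringsAsFactors = FALSE)
  if (symmetry_average && length(top$symmetry_classes) > 0L) {
    out <- symmetry_average_table(out, top$symmetry_classes)
  }
  class(out) <- c("group_hbond_table", class(out))
  out
}

# Collapse symmetry classes: class members averaged into one row labelled
# "a/b". Already-collapsed rows pass through (idempotence).
symmetry_average_table <- function(tab, symmetry_classes) {
  for (cls in symmetry_classes) {
    rows <- match(cls, tab$group)
    rows <- rows[!is.na(rows)]
    if (length(rows) < 2L) next
    merged <- tab[rows[1L], , drop = FALSE]
    merged$group <- paste(cls, collapse = "/")
    merged$sugar_sugar <- mean(tab$sugar_sugar[rows])
    merged$sugar_water <- mean(tab$sugar_water[rows])
    merged$n_instances <- sum(tab$n_instances[rows])
    merged$symmetry_averaged <- TRUE
    tab <- rbind(tab[-rows, , drop = FALSE], merged)
  }
  rownames(tab) <- NULL
  tab
}

#' Difference profile between two concentration series
#'
#' Pointwise `A - B` per category on a shared concentration grid, with
#' standard deviations propagated as `sqrt(sd_A^2 + sd_B^2)`. Used both
#' for protocol comparisons (not preheated minus preheated, same sugar)
#' and sugar comparisons (sucrose minus trehalose, same protocol).
#'
#' @param series_a,series_b data.frames with columns `water_mass_pct`,
#'   `category`, `mean`, `sd` and identical normalisations (as produced by
#'   [hbond_concentration_table()]).
#' @return data.frame with columns `water_mass_pct`, `category`, `delta`,
#'   `sd`.
#' @export
difference_profile <- function(series_a, series_b) {
  need <- c("water_mass_pct", "category", "mean", "sd")
  stopifnot(all(need %in% names(series_a)), all(need %in% names(series_b)))
  a <- series_a[order(series_a$category, series_a$water_mass_pct), ]
  b <- series_b[order(series_b$category, series_b$water_mass_pct), ]
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$water_mass_pct, b$water_mass_pct)) ||
      !identical(a$category, b$category)) {
    stop("alignment error: concentration grids or categories differ")
  }
  data.frame(water_mass_pct = a$water_mass_pct, category = a$category,
             delta = a$mean - b$mean, sd = sqrt(a$sd^2 + b$sd^2),
             stringsAsFactors = FALSE)
}

#' Tabulate hydrogen-bond series over a concentration grid
#'
#' @param series_list list of `hbond_series` (one per concentration, each
#'   carrying its `water_mass_pct`).
#' @return Long-format data.frame: `water_mass_pct`, `category`, `mean`,
#'   `sd`, `n_frames`, `normalization`.
#' @export
hbond_concentration_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    stopifnot(inherits(s, "hbond_series"))
    data.frame(water_mass_pct = s$water_mass_pct,
               category = HB_CATEGORIES,
               mean = unname(s$mean[HB_CATEGORIES]),
               sd = unname(s$sd[HB_CATEGORIES]),
               n_frames = s$n_frames, normalization = s$normalization,
               stringsAsFactors = FALSE)
  }))
}

#' Crossing points of two curves on a shared concentration grid
#'
#' Linear-interpolation abscissae where `curve_a - curve_b` changes sign.
#' Grid points where the curves coincide exactly are reported as
#' degenerate crossings.
#'
#' @param x shared, sorted abscissa grid (e.g. water mass %).
#' @param curve_a,curve_b ordinates on `x`.
#' @return List with `crossings` (ordered numeric vector) and `degenerate`
#'   (grid abscissae where the curves are exactly equal).
#' @export
crossing_points <- function(x, curve_a, curve_b) {
  stopifnot(length(x) == length(curve_a), length(x) == length(curve_b))
  if (length(x) < 2L) stop("input error: need at least 2 grid points")
  if (is.unsorted(x, strictly = TRUE)) stop("grid must be sorted and strictly increasing")
  d <- curve_a - curve_b
  degenerate <- x[d == 0]
  crossings <- numeric(0)
  for (i in seq_len(length(x) - 1L)) {
    if (d[i] == 0 || d[i + 1L] == 0) next # endpoint equality: degenerate
    if (sign(d[i]) != sign(d[i + 1L])) {
      t <- d[i] / (d[i] - d[i + 1L])
      crossings <- c(crossings, x[i] + t * (x[i + 1L] - x[i]))
    }
  }
  list(crossings = sort(crossings), degenerate = degenerate)
}
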