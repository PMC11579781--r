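#' @useDynLib sugarglass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd coef approx setNames aggregate
#' @importFrom utils head tail write.table read.table
NULL

# residue-name -> molecule kind; user overrides merge on top
default_kind_map <- c(SUC = "sucrose", TRE = "trehalose",
                      SOL = "water", WAT = "water", HOH = "water")

element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

guess_element <- function(atom_names) {
  el <- toupper(substr(gsub("^[0-9]+", "", atom_names), 1L, 1L))
  ifelse(el %in% names(element_masses), el, "X")
}

#' Read a GROMACS GRO coordinate file
#'
#' Parses the fixed-column GRO layout (title, atom count, atom records,
#' final box line). Coordinates and box are in nm. Molecule indices are
#' inferred from residue numbering and molecule kinds from residue names.
#'
#' @param path path to a `.gro` file.
#' @param kind_map named character vector overriding the residue-name to
#'   molecule-kind mapping (defaults cover SUC/TRE/SOL/WAT/HOH; unmatched
#'   residues become kind `"model"`).
#' @return A list with elements `topology` (a skeleton [topology()]: atoms
#'   only, no bonds or donor annotations) and `frame` (a [frame()]).
#' @export
read_gro <- function(path, kind_map = character()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO parse error: file too short (line 2 expected atom count)")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || n < 0L) stop("GRO parse error at line 2: malformed atom count '", trimws(lines[2L]), "'")
  if (length(lines) < 2L + n + 1L) {
    stop("GRO parse error: header declares ", n, " atoms but file ends at line ", length(lines))
  }
  atom_lines <- lines[3:(2L + n)]
  short <- which(nchar(atom_lines) < 44L)
  if (length(short) > 0L) {
    stop("GRO parse error at line ", 2L + short[1L], ": atom record too short")
  }
  res_num <- as.integer(substr(atom_lines, 1L, 5L))
  res_name <- trimws(substr(atom_lines, 6L, 10L))
  atom_name <- trimws(substr(atom_lines, 11L, 15L))
  x <- as.numeric(substr(atom_lines, 21L, 28L))
  y <- as.numeric(substr(atom_lines, 29L, 36L))
  z <- as.numeric(substr(atom_lines, 37L, 44L))
  bad <- which(is.na(res_num) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L) {
    stop("GRO parse error at line ", 2L + bad[1L], ": malformed atom record")
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + n + 1L]), "\\s+")[[1]]))
  if (length(box) < 3L || any(is.na(box[1:3]))) {
    stop("GRO parse error at line ", 2L + n + 1L, ": malformed box line")
  }
  if (length(box) > 3L && any(box[4:length(box)] != 0)) {
    stop("triclinic cells are not supported (non-zero off-diagonal box components)")
  }
  km <- default_kind_map
  km[names(kind_map)] <- kind_map
  kind <- unname(km[res_name])
  kind[is.na(kind)] <- "model"
  el <- guess_element(atom_name)
  mass <- unname(element_masses[el])
  mass[is.na(mass)] <- 1.0
  atoms <- data.frame(name = atom_name, element = el, mass = mass,
                      mol_index = match(res_num, unique(res_num)) - 1L,
                      mol_kind = kind, stringsAsFactors = FALSE)
  list(topology = topology(atoms),
       frame = frame(0, cbind(x, y, z), unit_cell(box[1:3])))
}

#' Write a GROMACS GRO coordinate file
#'
#' Output is bit-stable: atoms in index order, coordinates at fixed
#' 3-decimal nm precision.
#'
#' @param topology a [topology()] consistent with `frm`.
#' @param frm a [frame()].
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, frm, path, title = "sugarglass frame") {
  stopifnot(inherits(topology, "topology"), inherits(frm, "frame"))
  n <- nrow(topology$atoms)
  if (n == 0L) stop("cannot write an empty frame")
  if (nrow(frm$positions) != n) {
    stop("frame atom count (", nrow(frm$positions),
         ") does not match topology (", n, ")")
  }
  res_names <- c(sucrose = "SUC", trehalose = "TRE", water = "SOL",
                 model = "MOL")[topology$atoms$mol_kind]
  rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                 (topology$atoms$mol_index %% 100000L) + 1L, res_names,
                 substr(topology$atoms$name, 1L, 5L),
                 (seq_len(n) - 1L) %% 100000L + 1L,
                 frm$positions[, 1L], frm$positions[, 2L], frm$positions[, 3L])
  writeLines(c(title, sprintf("%5d", n), rec,
               sprintf("%10.5f%10.5f%10.5f", frm$cell[1L], frm$cell[2L], frm$cell[3L])),
             path)
  invisible(path)
}

#' Read a multi-frame XYZ-with-box trajectory
#'
#' The dialect stores repeated blocks: atom count, a comment line carrying
#' `time=<ps> box=<lx>,<ly>,<lz>`, then `name x y z` atom lines in nm.
#'
#' @param path path to the trajectory file.
#' @param topology optional full [topology()] to attach; when `NULL` a
#'   skeleton is built from the first frame's atom names.
#' @param protocol,water_mass_pct,description trajectory metadata, see
#'   [trajectory()].
#' @return A [trajectory()] with frames ordered by time.
#' @export
read_xyz_trajectory <- function(path, topology = NULL, protocol = "n/a",
                                water_mass_pct = NA_real_, description = "") {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  n_ref <- NA_integer_
  first_names <- NULL
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) stop("XYZ format error at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines)) stop("XYZ format error: truncated frame at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) < 2L) stop("XYZ format error at line ", i + 1L, ": missing time=<ps>")
    if (length(bx) < 4L) stop("XYZ format error at line ", i + 1L, ": missing box=<lx,ly,lz>")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    nm <- vapply(rows, `[`, "", 1L)
    xyz <- matrix(as.numeric(vapply(rows, function(r) r[2:4], character(3L))),
                  ncol = 3L, byrow = TRUE)
    if (any(is.na(xyz))) stop("XYZ format error: non-numeric coordinate in frame starting at line ", i)
    if (is.na(n_ref)) { n_ref <- n; first_names <- nm }
    else if (n != n_ref) stop("XYZ format error: frame atom count changed from ", n_ref, " to ", n)
    frames[[length(frames) + 1L]] <-
      frame(as.numeric(tm[2L]), xyz, unit_cell(as.numeric(bx[2:4])))
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("XYZ format error: no frames found")
  times <- vapply(frames, `[[`, 0, "time")
  if (any(diff(times) <= 0)) stop("XYZ ordering error: frame times must be strictly increasing")
  if (is.null(topology)) {
    el <- guess_element(first_names)
    mass <- unname(element_masses[el]); mass[is.na(mass)] <- 1.0
    topology <- topology(data.frame(name = first_names, element = el, mass = mass,
                                    mol_index = 0L, mol_kind = "model",
                                    stringsAsFactors = FALSE))
  }
  trajectory(topology, frames, protocol = protocol,
             water_mass_pct = water_mass_pct, description = description)
}

#' Write a trajectory in the XYZ-with-box dialect
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6L) {
  stopifnot(inherits(traj, "trajectory"))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(c(sprintf("%d", nrow(f$positions)),
                 sprintf("time=%.6f box=%.6f,%.6f,%.6f",
                         f$time, f$cell[1L], f$cell[2L], f$cell[3L]),
                 sprintf(fmt, traj$topology$atoms$name,
                         f$positions[, 1L], f$positions[, 2L], f$positions[, 3L])),
               con)
  }
  invisible(path)
}

#' Read a PLUMED-style HILLS file
#'
#' Whitespace-separated columns: time (ps), center (nm), sigma (nm),
#' height (kJ/mol), biasfactor. Comment lines starting with `#` are
#' skipped.
#'
#' @param path path to a HILLS file.
#' @param temperature temperature in K attached to the record.
#' @param heights_prescaled whether the stored heights are the deposited
#'   (already well-tempered) heights (`TRUE`, the default interpretation)
#'   or raw heights that each deposit's tempering factor must still be
#'   applied to at reconstruction time (`FALSE`). The interpretation used
#'   is recorded in the returned object.
#' @return A `hills_record` list: `deposits` data.frame (time, center,
#'   sigma, height), `bias_factor`, `temperature`, `heights_prescaled`.
#' @export
read_hills <- function(path, temperature = 298, heights_prescaled = TRUE) {
  tab <- read.table(path, comment.char = "#")
  if (ncol(tab) < 5L) stop("HILLS format error: expected >= 5 columns (time center sigma height biasfactor)")
  names(tab)[1:5] <- c("time", "center", "sigma", "height", "bias_factor")
  hills_record(tab[, c("time", "center", "sigma", "height")],
               bias_factor = tab$bias_factor[1L], temperature = temperature,
               heights_prescaled = heights_prescaled)
}

#' Construct a HILLS record
#'
#' @param deposits data.frame with columns `time` (ps), `center` (nm),
#'   `sigma` (nm), `height` (kJ/mol), sorted by time.
#' @inheritParams read_hills
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @return An object of class `hills_record`.
#' @export
hills_record <- function(deposits, bias_factor, temperature = 298,
                         heights_prescaled = TRUE) {
  stopifnot(is.data.frame(deposits))
  need <- c("time", "center", "sigma", "height")
  if (!all(need %in% names(deposits))) {
    stop("deposits needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(deposits) > 0L) {
    if (any(deposits$sigma <= 0)) stop("all hill sigmas must be > 0")
    if (any(deposits$height <= 0)) stop("all hill heights must be > 0")
    if (is.unsorted(deposits$time)) stop("deposits must be sorted by time")
  }
  if (!is.finite(bias_factor) || bias_factor <= 1) {
    stop("bias factor must be > 1")
  }
  structure(list(deposits = deposits[, need], bias_factor = bias_factor,
                 temperature = temperature,
                 heights_prescaled = isTRUE(heights_prescaled)),
            class = "hills_record")
}

#' Write a HILLS record in PLUMED-style columns
#'
#' @param hills a [hills_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "hills_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  d <- hills$deposits
  writeLines(sprintf("%14.6f %14.9f %14.9f %14.9f %8.3f",
                     d$time, d$center, d$sigma, d$height, hills$bias_factor), con)
  invisible(path)
}

#' Read an umbrella-window collective-variable time series
#'
#' Two whitespace-separated columns: time (ps) and the collective variable
#' z (nm); `#` comment lines skipped.
#'
#' @param path path to the series file.
#' @param center,force_constant window parameters: restraint center z0 (nm)
#'   and force constant k (kJ/(mol nm^2)).
#' @param temperature temperature in K.
#' @return An `umbrella_window` list: `center`, `force_constant`, `z`
#'   (numeric series), `time`, `temperature`.
#' @export
read_umbrella_series <- function(path, center, force_constant, temperature = 298) {
  tab <- read.table(path, comment.char = "#")
  if (ncol(tab) < 2L) stop("umbrella series format error: expected 2 columns (time z)")
  umbrella_window(center, force_constant, z = tab[[2L]], time = tab[[1L]],
                  temperature = temperature)
}

#' Construct an umbrella window
#'
#' @inheritParams read_umbrella_series
#' @param z sampled collective-variable series (nm), non-empty.
#' @param time optional time stamps (ps).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, z, time = NULL,
                            temperature = 298) {
  stopifnot(length(z) >= 1L, all(is.finite(z)), force_constant >= 0)
  structure(list(center = center, force_constant = force_constant,
                 z = as.numeric(z), time = time, temperature = temperature),
            class = "umbrella_window")
}

#' Write an umbrella series as two-column text
#'
#' @param window an [umbrella_window()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_umbrella_series <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  tm <- if (is.null(window$time)) seq_along(window$z) - 1 else window$time
  writeLines(c(sprintf("# center=%g k=%g T=%g", window$center,
                       window$force_constant, window$temperature),
               sprintf("%14.6f %14.9f", tm, window$z)), path)
  invisible(path)
}

#' Write a PMF profile as XVG-compatible two-column text
#'
#' @param pmf a `pmf_profile` (see [wham_pmf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  writeLines(c(sprintf("# PMF source=%s zero=%s", pmf$source, pmf$zero_convention),
               "@    xaxis  label \"z (nm)\"",
               "@    yaxis  label \"w(z) (kJ/mol)\"",
               sprintf("%12.6f %14.8f", pmf$z, pmf$w)), path)
  invisible(path)
}
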