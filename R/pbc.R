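#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Returns the shortest periodic image of `b - a`. Each component of the
#' result lies in (-L/2, L/2] for the corresponding box edge L.
#'
#' @param a,b positions in nm; either length-3 vectors or n x 3 matrices
#'   (recycled against each other row-wise).
#' @param cell a [unit_cell()] or numeric length-3 vector of edges (nm).
#' @return Displacement vector(s) in nm, same shape as the broadcast inputs.
#' @export
minimum_image_displacement <- function(a, b, cell) {
  if (!inherits(cell, "unit_cell")) cell <- unit_cell(cell)
  a <- if (is.matrix(a)) a else matrix(a, ncol = 3L)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 3L)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  d <- b - a
  for (k in 1:3) {
    L <- cell[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
    # round() maps the boundary to -L/2; fold onto (-L/2, L/2]
    at_edge <- d[, k] <= -L / 2
    d[, k][at_edge] <- d[, k][at_edge] + L
  }
  if (nrow(d) == 1L) drop(d) else d
}

#' Minimum-image distances
#'
#' Convenience wrapper around [minimum_image_displacement()] returning
#' Euclidean norms.
#'
#' @inheritParams minimum_image_displacement
#' @return Numeric vector of distances in nm.
#' @export
minimum_image_distance <- function(a, b, cell) {
  d <- minimum_image_displacement(a, b, cell)
  if (is.matrix(d)) sqrt(rowSums(d * d)) else sqrt(sum(d * d))
}

# Re-fold positions into [0, L) per axis.
wrap_positions <- function(pos, cell) {
  for (k in 1:3) pos[, k] <- pos[, k] %% cell[k]
  pos
}
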