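#' Wrap coordinates into the periodic box
#'
#' Maps coordinates into `[0, box_length)` by modular arithmetic; the right
#' edge maps to 0. Vectorised over `x` and `y`.
#'
#' @param x,y Numeric coordinate vectors (finite).
#' @param box_length Side of the periodic box.
#' @return A list with wrapped `x` and `y`.
#' @examples
#' wrap_position(1.2, -0.3, box_length = 1)
#' @export
wrap_position <- function(x, y, box_length = 1) {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite coordinates cannot be wrapped", call. = FALSE)
  }
  wx <- x %% box_length
  wy <- y %% box_length
  # numerical edge: v %% L can return L when v is a tiny negative number
  wx[wx >= box_length] <- 0
  wy[wy >= box_length] <- 0
  list(x = wx, y = wy)
}

#' Torus (minimum-image) distance
#'
#' Euclidean distance on the periodic square under the minimum-image
#' convention: along each axis the shorter of the direct and the wrapped
#' separation is used. Symmetric, and never larger than
#' `box_length * sqrt(2) / 2`. Vectorised.
#'
#' @param x1,y1,x2,y2 Wrapped coordinates.
#' @param box_length Side of the periodic box.
#' @return Numeric vector of distances.
#' @examples
#' torus_distance(0.05, 0.5, 0.95, 0.5, box_length = 1)  # 0.1, across the seam
#' @export
torus_distance <- function(x1, y1, x2, y2, box_length = 1) {
  dx <- abs(x1 - x2)
  dx <- pmin(dx, box_length - dx)
  dy <- abs(y1 - y2)
  dy <- pmin(dy, box_length - dy)
  sqrt(dx * dx + dy * dy)
}

#' Build a periodic cell grid
#'
#' Uniform cell-list index over the periodic box. `cell_size` must be at
#' least as large as any query radius, so that a radius query only needs the
#' 3x3 block of cells around the query point; the actual cell width is
#' `box_length / floor(box_length / cell_size)`, never smaller than
#' `cell_size`. Supports constant-time incremental updates
#' ([grid_insert()], [grid_remove()], [grid_move()]).
#'
#' @param x,y Wrapped coordinates of the indexed individuals; ids are their
#'   positions in these vectors.
#' @param cell_size Minimum cell width (usually
#'   `max(pred_radius, repro_radius)`).
#' @param box_length Side of the periodic box.
#' @return An object of class `cell_grid`: a list with `cells_per_side`,
#'   `cell_width`, `box_length`, per-individual coordinates and a
#'   `membership` list mapping each cell to the ids it contains.
#' @export
build_cell_grid <- function(x, y, cell_size, box_length = 1) {
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (cell_size > box_length) stop("cell_size exceeds box", call. = FALSE)
  nside <- max(1L, floor(box_length / cell_size))
  width <- box_length / nside
  grid <- structure(list(
    cells_per_side = as.integer(nside),
    cell_width = width,
    box_length = box_length,
    x = as.numeric(x),
    y = as.numeric(y),
    membership = rep(list(integer(0)), nside * nside)
  ), class = "cell_grid")
  for (i in seq_along(x)) {
    ci <- .cell_of(grid, x[i], y[i])
    grid$membership[[ci]] <- c(grid$membership[[ci]], i)
  }
  grid
}

.cell_of <- function(grid, x, y) {
  n <- grid$cells_per_side
  cx <- min(floor(x / grid$cell_width), n - 1)
  cy <- min(floor(y / grid$cell_width), n - 1)
  as.integer(cy * n + cx + 1)
}

#' Incremental cell-grid updates
#'
#' Insert, delete or move a single individual, keeping the grid membership
#' consistent with its coordinates. `id` for `grid_insert()` must not already
#' be present (use the next free integer).
#'
#' @param grid A `cell_grid`.
#' @param id Individual id.
#' @param x,y Wrapped coordinates (new position for `grid_move()`).
#' @return The updated grid.
#' @export
grid_insert <- function(grid, id, x, y) {
  grid$x[id] <- x
  grid$y[id] <- y
  ci <- .cell_of(grid, x, y)
  grid$membership[[ci]] <- c(grid$membership[[ci]], as.integer(id))
  grid
}

#' @rdname grid_insert
#' @export
grid_remove <- function(grid, id) {
  ci <- .cell_of(grid, grid$x[id], grid$y[id])
  grid$membership[[ci]] <- setdiff(grid$membership[[ci]], as.integer(id))
  grid$x[id] <- NA_real_
  grid$y[id] <- NA_real_
  grid
}

#' @rdname grid_insert
#' @export
grid_move <- function(grid, id, x, y) {
  old <- .cell_of(grid, grid$x[id], grid$y[id])
  new <- .cell_of(grid, x, y)
  grid$x[id] <- x
  grid$y[id] <- y
  if (old != new) {
    grid$membership[[old]] <- setdiff(grid$membership[[old]], as.integer(id))
    grid$membership[[new]] <- c(grid$membership[[new]], as.integer(id))
  }
  grid
}

.block_ids <- function(grid, x, y) {
  n <- grid$cells_per_side
  if (n < 3) return(seq_along(grid$x)[!is.na(grid$x)])
  cx <- min(floor(x / grid$cell_width), n - 1)
  cy <- min(floor(y / grid$cell_width), n - 1)
  xs <- (cx + c(-1, 0, 1)) %% n
  ys <- (cy + c(-1, 0, 1)) %% n
  cells <- as.vector(outer(xs, ys, function(a, b) b * n + a + 1))
  unlist(grid$membership[cells], use.names = FALSE)
}

#' Radius query on a cell grid
#'
#' Returns exactly the individuals whose torus distance to the query point is
#' at most `radius` (closed disk, so an individual at the query point itself
#' is returned at distance 0), using only the 3x3 cell block around the
#' point. Requires `radius <= cell_width`, otherwise completeness cannot be
#' guaranteed and an error is raised.
#'
#' @param grid A `cell_grid`.
#' @param x,y Query point (wrapped).
#' @param radius Query radius.
#' @return A tibble with columns `id` and `distance`, sorted by id.
#' @seealso [neighbors_brute()] for the O(N) reference scan.
#' @export
neighbors_within <- function(grid, x, y, radius) {
  if (radius > grid$cell_width + 1e-12) {
    stop("radius exceeds cell width; the 3x3 block query would be incomplete",
         call. = FALSE)
  }
  ids <- .block_ids(grid, x, y)
  if (length(ids) == 0) {
    return(tibble::tibble(id = integer(0), distance = numeric(0)))
  }
  d <- torus_distance(grid$x[ids], grid$y[ids], x, y, grid$box_length)
  keep <- d <= radius
  out <- tibble::tibble(id = as.integer(ids[keep]), distance = d[keep])
  dplyr::arrange(out, .data$id)
}

#' Brute-force radius query
#'
#' O(N) reference scan over all individuals with [torus_distance()]; the
#' oracle against which the cell-grid query is validated.
#'
#' @param x,y Coordinates of all individuals (ids are vector positions).
#' @param qx,qy Query point.
#' @param radius Query radius.
#' @param box_length Side of the periodic box.
#' @return A tibble with columns `id` and `distance`, sorted by id.
#' @export
neighbors_brute <- function(x, y, qx, qy, radius, box_length = 1) {
  d <- torus_distance(x, y, qx, qy, box_length)
  keep <- which(!is.na(d) & d <= radius)
  tibble::tibble(id = as.integer(keep), distance = d[keep])
}

#' Closest individual of a species within a radius
#'
#' Among individuals of `species_label` within `radius` of the position of
#' individual `actor_id` (the actor itself excluded by id, not by
#' coordinates), returns the id with minimal torus distance; ties are broken
#' by smallest id (exact ties have probability zero in continuous space but
#' deterministic tie-breaking keeps runs reproducible). `NA` if none.
#'
#' @param grid A `cell_grid` indexing all individuals.
#' @param actor_id Id of the focal individual.
#' @param radius Search radius.
#' @param species_label Target species, one of `"A"`, `"B"`, `"C"`.
#' @param species Character vector of species labels, parallel to the grid.
#' @return Integer id or `NA_integer_`.
#' @export
closest_of_species <- function(grid, actor_id, radius, species_label, species) {
  nb <- neighbors_within(grid, grid$x[actor_id], grid$y[actor_id], radius)
  nb <- nb[nb$id != actor_id & species[nb$id] == species_label, , drop = FALSE]
  if (nrow(nb) == 0) return(NA_integer_)
  nb$id[which.min(nb$distance)]  # ids sorted, which.min takes first => smallest id
}
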