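# Partition of the interpolation grid into contiguous regions (stand-ins
# for administrative districts) and the region adjacency graph used as the
# CAR neighborhood.

#' Construct a region map from explicit membership
#'
#' @param membership integer vector, one entry per grid cell, mapping each
#'   cell to a region id in `1..n_regions` (surjective).
#' @param grid the [grid_spec()] the membership refers to.
#' @return an object of class `region_map` with fields `region_ids`,
#'   `membership`, `adjacency` (two-column matrix of unordered region pairs,
#'   first column < second), `n_regions`, `grid`.
#' @export
region_map <- function(membership, grid) {
  stopifnot(inherits(grid, "grid_spec"),
            length(membership) == n_cells(grid))
  membership <- as.integer(membership)
  ids <- sort(unique(membership))
  n_regions <- length(ids)
  if (!identical(ids, seq_len(n_regions)))
    stop("membership must use consecutive region ids 1..n_regions", call. = FALSE)
  adj <- adjacency_from_membership(membership, grid)
  rm <- structure(list(region_ids = ids, membership = membership,
                       adjacency = adj, n_regions = n_regions, grid = grid),
                  class = "region_map")
  rm
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d regions on a %d x %d grid, %d adjacency pairs\n",
              x$n_regions, x$grid$nx, x$grid$ny, nrow(x$adjacency)))
  invisible(x)
}

# Region pairs sharing at least one grid-cell edge (rook moves; on a cell
# partition queen vs rook distinguishes only corner touches, which do not
# occur as sole contacts for grown regions and are ignored by convention).
adjacency_from_membership <- function(membership, grid) {
  m <- matrix(membership, nrow = grid$nx)  # [col, row] layout, cell = (row-1)*nx + col
  pairs <- rbind(
    if (grid$nx > 1) cbind(as.integer(m[-grid$nx, , drop = FALSE]),
                           as.integer(m[-1, , drop = FALSE])),
    if (grid$ny > 1) cbind(as.integer(m[, -grid$ny, drop = FALSE]),
                           as.integer(m[, -1, drop = FALSE])))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  diffp <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(diffp) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  lo <- pmin(diffp[, 1], diffp[, 2])
  hi <- pmax(diffp[, 1], diffp[, 2])
  u <- unique(cbind(lo, hi))
  u <- u[order(u[, 1], u[, 2]), , drop = FALSE]
  dimnames(u) <- list(NULL, c("i", "j"))
  u
}

# Connectivity of the region adjacency graph (BFS).
adjacency_connected <- function(adjacency, n_regions) {
  if (n_regions == 1) return(TRUE)
  if (nrow(adjacency) == 0) return(FALSE)
  nbr <- split(c(adjacency[, 2], adjacency[, 1]),
               c(adjacency[, 1], adjacency[, 2]))
  seen <- logical(n_regions)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in nbr[[as.character(v)]]) {
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

#' Partition a grid into contiguous regions
#'
#' `method = "grow"` (default) seeds `n_regions` random cells and grows them
#' by repeated dilation in randomized order, giving an irregular contiguous
#' partition; if the resulting adjacency graph is disconnected the partition
#' is regenerated (up to `max_retries`). `method = "blocks"` splits the grid
#' deterministically into near-equal row and column bands (requires
#' `n_regions` to factor as `kr * kc` with `kr <= ny`, `kc <= nx`); block
#' ids run row-major from the north-west, so 4 regions on a square grid are
#' the four quadrants.
#'
#' @param grid a [grid_spec()].
#' @param n_regions number of regions, at most the number of cells.
#' @param seed integer seed (ignored for `method = "blocks"`).
#' @param method `"grow"` or `"blocks"`.
#' @param max_retries regeneration attempts for a disconnected result.
#' @return a `region_map`.
#' @export
make_regions <- function(grid, n_regions, seed = 1L,
                         method = c("grow", "blocks"), max_retries = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "grid_spec"), is_count(n_regions),
            n_regions >= 1, n_regions <= n_cells(grid))
  if (method == "blocks") return(make_regions_blocks(grid, n_regions))
  for (attempt in seq_len(max_retries)) {
    set.seed(derive_seed(seed, 7000 + attempt))
    memb <- grow_partition(grid, n_regions)
    rm <- region_map(memb, grid)
    if (n_regions == 1 || adjacency_connected(rm$adjacency, n_regions))
      return(rm)
  }
  stop(sprintf("could not generate a connected region graph in %d attempts",
               max_retries), call. = FALSE)
}

grow_partition <- function(grid, n_regions) {
  nc <- n_cells(grid)
  nx <- grid$nx; ny <- grid$ny
  memb <- integer(nc)
  seeds <- sample.int(nc, n_regions)
  memb[seeds] <- seq_len(n_regions)
  frontier <- seeds
  while (any(memb == 0L)) {
    newly <- integer(0)
    for (cell in sample(frontier)) {
      col <- (cell - 1L) %% nx
      row <- (cell - 1L) %/% nx
      nbrs <- c(if (col > 0L) cell - 1L, if (col < nx - 1L) cell + 1L,
                if (row > 0L) cell - nx, if (row < ny - 1L) cell + nx)
      free <- nbrs[memb[nbrs] == 0L]
      if (length(free)) {
        memb[free] <- memb[cell]
        newly <- c(newly, free)
      }
    }
    frontier <- if (length(newly)) newly else which(memb != 0L)
  }
  memb
}

make_regions_blocks <- function(grid, n_regions) {
  facs <- which(n_regions %% seq_len(n_regions) == 0)
  best <- NULL
  for (kr in facs) {
    kc <- n_regions %/% kr
    if (kr <= grid$ny && kc <= grid$nx &&
        (is.null(best) || abs(kr - kc) < abs(best[1] - best[2])))
      best <- c(kr, kc)
  }
  if (is.null(best))
    stop(sprintf("n_regions = %d does not factor onto a %d x %d grid",
                 n_regions, grid$nx, grid$ny), call. = FALSE)
  kr <- best[1]; kc <- best[2]
  # row band 1 = north; ids row-major from the north-west
  row_band <- rev(cut(seq_len(grid$ny), kr, labels = FALSE))
  col_band <- cut(seq_len(grid$nx), kc, labels = FALSE)
  cc <- cell_centers(grid)
  memb <- (row_band[cc$row + 1L] - 1L) * kc + col_band[cc$col + 1L]
  region_map(memb, grid)
}

#' Region cell counts
#' @param regions a `region_map`.
#' @return integer vector of cells per region.
#' @export
region_sizes <- function(regions) {
  tabulate(regions$membership, nbins = regions$n_regions)
}

#' Write / read the adjacency edge list
#'
#' Plain two-column whitespace-separated text, one unordered pair per line.
#' @param regions a `region_map` (or a two-column adjacency matrix).
#' @param path file path.
#' @name adjacency_io
#' @export
write_adjacency <- function(regions, path) {
  adj <- if (inherits(regions, "region_map")) regions$adjacency else regions
  utils::write.table(adj, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname adjacency_io
#' @export
read_adjacency <- function(path) {
  adj <- as.matrix(utils::read.table(path, col.names = c("i", "j")))
  storage.mode(adj) <- "integer"
  adj
}
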