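# Cost-surface construction, anisotropic path-distance accumulation over an
# 8-connected grid, backlink/least-cost-path extraction, and multi-source
# distance summaries.

#' Construct a regular raster grid
#'
#' Values are stored as a matrix whose first row is the NORTHERN (top) row,
#' matching the ESRI ASCII grid row order. Cell centers are at
#' `xllcorner + (col - 0.5) * cellsize`, `yllcorner + (nrows - row + 0.5) *
#' cellsize`.
#'
#' @param data numeric matrix (top row first).
#' @param xllcorner,yllcorner lower-left corner of the grid.
#' @param cellsize cell edge length (same units as the corners).
#' @param nodata value representing missing cells in files; stored as `NA`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(data, xllcorner = 0, yllcorner = 0, cellsize = 1,
                        nodata = -9999) {
  data <- as.matrix(data)
  stopifnot(nrow(data) > 0, ncol(data) > 0)
  structure(list(data = data, nrows = nrow(data), ncols = ncol(data),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid:", x$nrows, "x", x$ncols, "cells, cellsize", x$cellsize,
      "\n")
  invisible(x)
}

congruent <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(c(a$xllcorner, a$yllcorner),
                     c(b$xllcorner, b$yllcorner)))
}

#' Read an ESRI ASCII grid (.asc)
#' @param path file path.
#' @return A `raster_grid`; file nodata values become `NA`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("missing ESRI ASCII header field(s): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("cell count ", length(vals), " does not match header ",
         hdr$nrows, "x", hdr$ncols)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid (.asc)
#' @param r a `raster_grid`.
#' @param path output path.
#' @export
write_asc <- function(r, path) {
  hdr <- c(paste("ncols", r$ncols), paste("nrows", r$nrows),
           paste("xllcorner", format(r$xllcorner, scientific = FALSE)),
           paste("yllcorner", format(r$yllcorner, scientific = FALSE)),
           paste("cellsize", format(r$cellsize, scientific = FALSE)),
           paste("NODATA_value", format(r$nodata, scientific = FALSE)))
  m <- r$data
  m[is.na(m)] <- r$nodata
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reclassify water-percentage cover into travel-cost classes
#'
#' Maps percent water cover to six friction classes on a 1-16 scale:
#' 0 percent to 1, (0,20] to 2, (20,40] to 4, (40,60] to 6, (60,80] to 8 and
#' (80,100] to 16. Open land is easiest to cross; high water percentages
#' (offshore, large wetlands) act as near-barriers without being fully
#' impassable. Nodata is preserved.
#'
#' @param water a `raster_grid` of percent values in `[0, 100]`.
#' @return A `raster_grid` of cost classes.
#' @export
reclassify_water <- function(water) {
  v <- water$data
  bad <- which(!is.na(v) & (v < 0 | v > 100))
  if (length(bad)) {
    stop("water percentage out of [0,100] at cell index ", bad[1L],
         " (value ", v[bad[1L]], ")")
  }
  classes <- c(1, 2, 4, 6, 8, 16)
  out <- classes[as.integer(cut(v, breaks = c(-Inf, 0, 20, 40, 60, 80, 100)))]
  out <- matrix(out, nrow = water$nrows)
  raster_grid(out, water$xllcorner, water$yllcorner, water$cellsize,
              water$nodata)
}

#' Add the ice-sheet penalty to a cost raster
#'
#' Cells under the ice mask get 999 added to their cost, making ice sheets
#' effectively avoided but not strictly impassable.
#'
#' @param cost a cost `raster_grid`.
#' @param ice an ice-mask `raster_grid` (1 = ice, 0 = free), congruent with
#'   `cost`.
#' @param penalty cost added on ice (default 999).
#' @export
add_ice <- function(cost, ice, penalty = 999) {
  if (!congruent(cost, ice)) stop("cost and ice grids are not congruent")
  out <- cost
  on_ice <- !is.na(ice$data) & ice$data == 1
  out$data[on_ice] <- out$data[on_ice] + penalty
  out
}

#' Vertical factor for a move between two cells
#'
#' Inverse-linear vertical factor: the vertical relative moving angle (VRMA)
#' is `theta = atan2(elev_to - elev_from, horizontal_distance)` in degrees
#' (positive uphill). Moves with `|theta|` above `vrma_cut` are impassable
#' (factor infinity); otherwise `VF = 1 + theta * slope_param`, so gently
#' descending moves are cheaper than flat ones, floored at `vf_floor`.
#'
#' @param elev_from,elev_to elevations in meters (`NA` = impassable).
#' @param horizontal_distance horizontal move length (> 0), same units.
#' @param vrma_cut cutoff angle in degrees (default 5).
#' @param slope_param linear coefficient per degree (default 1/45).
#' @param vf_floor minimum factor (default 0.05).
#' @return Numeric factor (possibly `Inf`); vectorized.
#' @export
vertical_factor <- function(elev_from, elev_to, horizontal_distance,
                            vrma_cut = 5, slope_param = 1 / 45,
                            vf_floor = 0.05) {
  stopifnot(all(horizontal_distance > 0))
  theta <- atan2(elev_to - elev_from, horizontal_distance) * 180 / pi
  vf <- pmax(vf_floor, 1 + theta * slope_param)
  vf[abs(theta) > vrma_cut] <- Inf
  vf[is.na(elev_from) | is.na(elev_to)] <- Inf
  vf
}

# Neighbor offsets in ArcGIS backlink order: 1=E, 2=SE, 3=S, 4=SW, 5=W,
# 6=NW, 7=N, 8=NE (row offset, col offset; row grows southward).
NEIGHBOR_OFFSETS <- matrix(c(
  0L, 1L,   1L, 1L,   1L, 0L,   1L, -1L,
  0L, -1L,  -1L, -1L,  -1L, 0L,  -1L, 1L
), ncol = 2L, byrow = TRUE)

# direction code pointing back from v to u, given code of move u -> v
OPPOSITE_DIR <- c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L)

#' Accumulated path distance over a cost surface (multi-source Dijkstra)
#'
#' Computes the minimum accumulated travel cost from a set of source cells
#' to every cell, over the 8-connected grid. The cost of moving from cell u
#' to neighbor v is `d(u,v) * (cost_u + cost_v)/2 * VF(u -> v)` with `d` the
#' center-to-center distance (cellsize, or cellsize*sqrt(2) diagonally; for
#' grids in degrees the east-west component is scaled by cos(latitude)).
#'
#' @param cost a cost `raster_grid` (values >= some positive cost; `NA` =
#'   impassable).
#' @param elev optional elevation `raster_grid` for the vertical factor;
#'   `NULL` disables it (factor 1).
#' @param sources two-column matrix/data.frame of (row, col) grid indices.
#' @param vrma_cut,slope_param,vf_floor see [vertical_factor()].
#' @param geographic treat coordinates as degrees and apply the
#'   cos(latitude) correction to east-west distances.
#' @return A list of class `path_distance_result`: `accumulated` and
#'   `backlink` `raster_grid`s plus the source list. Backlink codes are 0 at
#'   sources and 1-8 (E, SE, S, SW, W, NW, N, NE) pointing toward the
#'   predecessor cell otherwise.
#' @export
path_distance <- function(cost, elev = NULL, sources, vrma_cut = 5,
                          slope_param = 1 / 45, vf_floor = 0.05,
                          geographic = FALSE) {
  if (!is.null(elev) && !congruent(cost, elev)) {
    stop("cost and elevation grids are not congruent")
  }
  sources <- as.matrix(sources)
  storage.mode(sources) <- "integer"
  nr <- cost$nrows; nc <- cost$ncols
  if (nrow(sources) < 1L) stop("at least one source required")
  inside <- sources[, 1L] >= 1L & sources[, 1L] <= nr &
    sources[, 2L] >= 1L & sources[, 2L] <= nc
  if (!all(inside)) stop("source outside grid")
  cm <- cost$data
  src_idx <- (sources[, 2L] - 1L) * nr + sources[, 1L]
  if (any(is.na(cm[src_idx]))) stop("source on a nodata cell")
  dist <- matrix(Inf, nr, nc)
  back <- matrix(NA_integer_, nr, nc)
  dist[src_idx] <- 0
  back[src_idx] <- 0L
  visited <- matrix(FALSE, nr, nc)
  visited[is.na(cm)] <- TRUE  # impassable
  em <- if (is.null(elev)) NULL else elev$data
  cs <- cost$cellsize
  repeat {
    active <- which(!visited & is.finite(dist))
    if (length(active) == 0L) break
    u <- active[which.min(dist[active])]
    visited[u] <- TRUE
    ur <- (u - 1L) %% nr + 1L
    uc <- (u - 1L) %/% nr + 1L
    lat_u <- cost$yllcorner + (nr - ur + 0.5) * cs
    for (dir in 1:8) {
      vr <- ur + NEIGHBOR_OFFSETS[dir, 1L]
      vc <- uc + NEIGHBOR_OFFSETS[dir, 2L]
      if (vr < 1L || vr > nr || vc < 1L || vc > nc) next
      v <- (vc - 1L) * nr + vr
      if (visited[v]) next
      dx <- abs(NEIGHBOR_OFFSETS[dir, 2L]) * cs
      dy <- abs(NEIGHBOR_OFFSETS[dir, 1L]) * cs
      if (geographic) {
        lat_v <- cost$yllcorner + (nr - vr + 0.5) * cs
        dx <- dx * cos(mean(c(lat_u, lat_v)) * pi / 180)
      }
      d <- sqrt(dx^2 + dy^2)
      w <- d * (cm[u] + cm[v]) / 2
      if (!is.null(em)) {
        w <- w * vertical_factor(em[u], em[v], d, vrma_cut, slope_param,
                                 vf_floor)
      }
      nd <- dist[u] + w
      if (nd < dist[v]) {
        dist[v] <- nd
        back[v] <- OPPOSITE_DIR[dir]
      }
    }
  }
  mk <- function(m) raster_grid(m, cost$xllcorner, cost$yllcorner,
                                cost$cellsize, cost$nodata)
  structure(list(accumulated = mk(dist), backlink = mk(back),
                 sources = sources),
            class = "path_distance_result")
}

#' Extract a least-cost path by backlink tracing
#'
#' @param pdr a `path_distance_result`.
#' @param destination `(row, col)` of the destination cell.
#' @return List with `path` (matrix of row/col from destination's source to
#'   the destination) and `total_cost`.
#' @export
least_cost_path <- function(pdr, destination) {
  destination <- as.integer(destination)
  acc <- pdr$accumulated$data
  back <- pdr$backlink$data
  nr <- nrow(acc)
  r <- destination[1L]; c <- destination[2L]
  if (r < 1L || r > nr || c < 1L || c > ncol(acc)) stop("destination outside grid")
  if (!is.finite(acc[r, c])) stop("destination unreachable")
  total <- acc[r, c]
  path <- list(c(r, c))
  while (back[r, c] != 0L) {
    dir <- back[r, c]
    r2 <- r + NEIGHBOR_OFFSETS[dir, 1L]
    c2 <- c + NEIGHBOR_OFFSETS[dir, 2L]
    r <- r2; c <- c2
    path[[length(path) + 1L]] <- c(r, c)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("row", "col")
  list(path = path, total_cost = total)
}

#' Convert x/y (or lon/lat) coordinates to grid row/col indices
#' @param r a `raster_grid`.
#' @param x,y point coordinates in grid units.
#' @return Two-column integer matrix (row, col).
#' @export
cell_from_xy <- function(r, x, y) {
  col <- floor((x - r$xllcorner) / r$cellsize) + 1L
  row <- r$nrows - floor((y - r$yllcorner) / r$cellsize)
  out <- cbind(row = as.integer(row), col = as.integer(col))
  if (any(col < 1L | col > r$ncols | row < 1L | row > r$nrows)) {
    stop("point outside grid")
  }
  out
}

#' Multi-source least-cost distance summaries
#'
#' Runs one [path_distance()] per source point and reports, per destination
#' and per named source set, the minimum, median and total accumulated cost
#' across the set's sources (e.g. the minimum over five WHG points, or the
#' single-point distance from a far-eastern source).
#'
#' @param cost,elev `raster_grid`s (elev may be `NULL`).
#' @param source_sets named list of two-column (row, col) matrices.
#' @param destinations two-column (row, col) matrix, optionally with
#'   rownames used as destination labels.
#' @param ... passed to [path_distance()].
#' @return A `data.frame`: destination, set, dist_min, dist_median,
#'   dist_total.
#' @export
multi_source_summary <- function(cost, elev = NULL, source_sets,
                                 destinations, ...) {
  destinations <- as.matrix(destinations)
  dlab <- rownames(destinations)
  if (is.null(dlab)) dlab <- paste0("dest", seq_len(nrow(destinations)))
  rows <- list()
  for (set_name in names(source_sets)) {
    pts <- as.matrix(source_sets[[set_name]])
    dmat <- sapply(seq_len(nrow(pts)), function(i) {
      pdr <- path_distance(cost, elev, pts[i, , drop = FALSE], ...)
      pdr$accumulated$data[cbind(destinations[, 1L], destinations[, 2L])]
    })
    dmat <- matrix(dmat, nrow = nrow(destinations))
    rows[[set_name]] <- data.frame(
      destination = dlab, set = set_name,
      dist_min = apply(dmat, 1L, min),
      dist_median = apply(dmat, 1L, stats::median),
      dist_total = rowSums(dmat),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
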