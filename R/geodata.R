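#' Define a raster grid
#'
#' A grid definition fixes the geometry every layer, occurrence set and map in
#' an analysis shares: a top-left origin, a uniform cell size, and the number
#' of rows and columns. Cells are indexed 0-based in row-major order; cell
#' `(r, c)` covers the half-open square
#' `[origin_x + c*s, origin_x + (c+1)*s)` by `(origin_y - (r+1)*s, origin_y - r*s]`.
#'
#' @param origin_x,origin_y Coordinate of the top-left corner, in map units.
#' @param cell_size Uniform cell edge length (km for equal-area grids, degrees
#'   for geographic ones). Must be positive.
#' @param n_rows,n_cols Grid dimensions, positive integers.
#' @param crs_tag Free-text identifier of the coordinate reference; use
#'   `"geographic"` (or any tag containing "geographic"/"longlat") for
#'   lon/lat grids so distances are computed on the sphere, anything else
#'   (e.g. the default `"synthetic-equal-area"`) for planar map units.
#' @return A `grid_def` object.
#' @export
grid_def <- function(origin_x = 0, origin_y = 0, cell_size = 1,
                     n_rows = 1, n_cols = 1, crs_tag = "synthetic-equal-area") {
  assert_that(is_scalar_number(cell_size) && cell_size > 0, "cell_size must be > 0")
  assert_that(n_rows >= 1 && n_cols >= 1, "grid must have at least one row and column")
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs_tag = crs_tag),
    class = "grid_def"
  )
}

#' @export
print.grid_def <- function(x, ...) {
  cat(sprintf("<grid_def> %d x %d cells of %g units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_tag))
  invisible(x)
}

is_geographic <- function(grid) {
  grepl("geographic|longlat|epsg:4326", tolower(grid$crs_tag))
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

# 0-based row-major cell arithmetic ------------------------------------------

cell_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  list(row = cell %/% grid$n_cols, col = cell %% grid$n_cols)
}

rowcol_cell <- function(grid, row, col) as.integer(row) * grid$n_cols + as.integer(col)

#' Cell centre coordinates
#'
#' @param grid A [grid_def()].
#' @param cell Integer vector of 0-based row-major cell indices.
#' @return A tibble with columns `cell`, `x`, `y`.
#' @export
cell_center <- function(grid, cell) {
  rc <- cell_rowcol(grid, cell)
  tibble::tibble(
    cell = as.integer(cell),
    x = grid$origin_x + (rc$col + 0.5) * grid$cell_size,
    y = grid$origin_y - (rc$row + 0.5) * grid$cell_size
  )
}

#' Map coordinates to cell indices
#'
#' Points outside the grid map to `NA`. The half-open cell convention means a
#' point exactly on a shared edge belongs to the cell to its right/above.
#'
#' @inheritParams cell_center
#' @param x,y Numeric coordinate vectors.
#' @return Integer vector of 0-based cell indices (`NA` outside the grid).
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size)
  row <- floor((grid$origin_y - y) / grid$cell_size)
  ok <- is.finite(x) & is.finite(y) &
    col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- rowcol_cell(grid, row[ok], col[ok])
  out
}

grids_identical <- function(a, b, tol = 1e-9) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

# Pairwise/elementwise distances between cell centres, respecting the crs.
cell_distances <- function(grid, cells_a, cells_b) {
  ca <- cell_center(grid, cells_a)
  cb <- cell_center(grid, cells_b)
  if (is_geographic(grid)) {
    geosphere::distm(cbind(ca$x, ca$y), cbind(cb$x, cb$y),
                     fun = geosphere::distHaversine) / 1000
  } else {
    sqrt(outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2)
  }
}

point_distances <- function(grid, xy_a, xy_b) {
  if (is_geographic(grid)) {
    geosphere::distm(xy_a, xy_b, fun = geosphere::distHaversine) / 1000
  } else {
    sqrt(outer(xy_a[, 1], xy_b[, 1], "-")^2 + outer(xy_a[, 2], xy_b[, 2], "-")^2)
  }
}

# Layers and stacks ----------------------------------------------------------

#' Create an environmental layer
#'
#' Values are stored as a matrix in grid orientation (row 1 = top row);
#' `NA` marks nodata. Categorical layers hold integer or numeric label codes;
#' their label set is the sorted unique non-missing values.
#'
#' @param name Layer name (unique within a stack).
#' @param values Numeric `n_rows x n_cols` matrix; `NA` = nodata.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An `env_layer`.
#' @export
env_layer <- function(name, values, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  assert_that(is.matrix(values), "values must be a matrix")
  if (kind == "continuous" && any(is.infinite(values)))
    stop("continuous layer '", name, "' contains non-finite values outside nodata",
         call. = FALSE)
  structure(list(name = name, kind = kind, values = values), class = "env_layer")
}

layer_labels <- function(layer) sort(unique(as.vector(layer$values[!is.na(layer$values)])))

#' Assemble an environmental stack
#'
#' Bundles co-registered layers on one grid. The joint nodata mask (the union
#' of every layer's missing cells) is applied uniformly to all layers, so any
#' cell is either fully observed or fully nodata.
#'
#' @param layers List of [env_layer()] objects with unique names.
#' @param grid The shared [grid_def()].
#' @param period_tag Label for the period/scenario the stack represents,
#'   e.g. `"current"` or `"2041-2070-ssp370"`.
#' @return An `env_stack` with elements `grid`, `layers` (named list),
#'   `period_tag` and `nodata` (logical matrix, `TRUE` = nodata).
#' @export
env_stack <- function(layers, grid, period_tag = "current") {
  nms <- vapply(layers, `[[`, "", "name")
  assert_that(!anyDuplicated(nms), "layer names must be unique")
  for (ly in layers) {
    if (!identical(dim(ly$values), c(grid$n_rows, grid$n_cols)))
      stop("alignment error: layer '", ly$name, "' has shape ",
           paste(dim(ly$values), collapse = "x"), ", expected ",
           grid$n_rows, "x", grid$n_cols, call. = FALSE)
  }
  nodata <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)),
                   matrix(FALSE, grid$n_rows, grid$n_cols))
  layers <- lapply(layers, function(l) { l$values[nodata] <- NA; l })
  names(layers) <- nms
  structure(list(grid = grid, layers = layers, period_tag = period_tag,
                 nodata = nodata),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, "", "kind")
  cat(sprintf("<env_stack> '%s': %d layers (%d continuous, %d categorical) on %d x %d grid, %d nodata cells\n",
              x$period_tag, length(x$layers), sum(kinds == "continuous"),
              sum(kinds == "categorical"), x$grid$n_rows, x$grid$n_cols,
              sum(x$nodata)))
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)
continuous_names <- function(stack)
  names(stack$layers)[vapply(stack$layers, `[[`, "", "kind") == "continuous"]
categorical_names <- function(stack)
  names(stack$layers)[vapply(stack$layers, `[[`, "", "kind") == "categorical"]

#' @export
as_tibble.env_stack <- function(x, ...) {
  cells <- which(!t(x$nodata)) - 1L  # row-major order over non-nodata cells
  extract_at_cells(x, cells, labels = rep(NA_integer_, length(cells)))
}

#' Load an environmental stack from raster files
#'
#' Reads one ESRI ASCII grid per layer, checks that every file shares one
#' geometry, and returns the assembled stack with a unified nodata mask.
#'
#' @param layer_sources Named character vector of file paths; names become
#'   layer names (basenames without extension are used if unnamed).
#' @param kinds Character vector, `"continuous"` or `"categorical"` per layer
#'   (recycled if length 1).
#' @param period_tag Passed to [env_stack()].
#' @param crs_tag Coordinate reference tag for the grid.
#' @return An [env_stack()].
#' @export
load_env_stack <- function(layer_sources, kinds = "continuous",
                           period_tag = "current",
                           crs_tag = "synthetic-equal-area") {
  if (is.null(names(layer_sources)) || any(names(layer_sources) == ""))
    names(layer_sources) <- tools::file_path_sans_ext(basename(layer_sources))
  kinds <- rep_len(kinds, length(layer_sources))
  parsed <- purrr::imap(layer_sources, function(path, nm) {
    if (!file.exists(path)) stop("cannot read layer source '", path, "'", call. = FALSE)
    read_ascii_grid(path)
  })
  ref <- parsed[[1]]$grid
  for (i in seq_along(parsed)) {
    if (!grids_identical(parsed[[i]]$grid, ref))
      stop("alignment error: layer '", names(layer_sources)[i],
           "' does not share the reference geometry", call. = FALSE)
  }
  ref$crs_tag <- crs_tag
  layers <- purrr::map2(parsed, seq_along(parsed),
                        function(p, i) env_layer(names(parsed)[i], p$values, kinds[i]))
  env_stack(unname(layers), ref, period_tag)
}

#' Write a stack to a directory of ASCII grids
#'
#' One `.asc` file per layer plus a `meta.json` sidecar holding layer kinds,
#' the period tag and crs tag. Written values round-trip bit-exactly for
#' integer data and to full double precision for continuous data.
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(stack$layers, function(ly, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(ly$values, stack$grid, p)
    p
  })
  meta <- list(period_tag = stack$period_tag, crs_tag = stack$grid$crs_tag,
               layers = names(stack$layers),
               kinds = unname(vapply(stack$layers, `[[`, "", "kind")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(c(paths, file.path(dir, "meta.json")))
}

#' Read a stack written by [write_env_stack()]
#' @param dir Directory containing `.asc` layers and `meta.json`.
#' @return An [env_stack()].
#' @export
read_env_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  src <- file.path(dir, paste0(meta$layers, ".asc"))
  names(src) <- meta$layers
  load_env_stack(src, kinds = meta$kinds, period_tag = meta$period_tag,
                 crs_tag = meta$crs_tag)
}

# ESRI ASCII grid I/O. Doubles are printed with 17 significant digits so
# read(write(x)) reproduces x bit-exactly.
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", sprintf("%.17g", grid$origin_x)),
    paste("yllcorner", sprintf("%.17g", grid$origin_y - grid$n_rows * grid$cell_size)),
    paste("cellsize", sprintf("%.17g", grid$cell_size)),
    paste("NODATA_value", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  for (r in seq_len(nrow(v)))
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
}

read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1))
  vals <- as.numeric(vapply(kv, `[[`, "", 2))
  names(vals) <- keys
  n_cols <- as.integer(vals[["ncols"]]); n_rows <- as.integer(vals[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != n_rows * n_cols)
    stop("malformed ASCII grid '", path, "': expected ", n_rows * n_cols,
         " values, found ", length(body), call. = FALSE)
  m <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  grid <- grid_def(origin_x = vals[["xllcorner"]],
                   origin_y = vals[["yllcorner"]] + n_rows * vals[["cellsize"]],
                   cell_size = vals[["cellsize"]],
                   n_rows = n_rows, n_cols = n_cols)
  list(grid = grid, values = m)
}

# Resampling -----------------------------------------------------------------

#' Aggregate a stack to a coarser resolution
#'
#' Blocks of `factor x factor` source cells collapse to one target cell:
#' continuous layers by block mean (default), categorical layers by block
#' majority with ties broken by the smallest label. Blocks that are entirely
#' nodata stay nodata. Dimensions not divisible by `factor` are padded with
#' nodata on the bottom/right before aggregation.
#'
#' @param stack An [env_stack()].
#' @param factor Positive integer aggregation factor; 1 returns the stack
#'   unchanged.
#' @param continuous_rule Currently `"mean"`.
#' @param categorical_rule Currently `"majority"`.
#' @return An [env_stack()] whose grid cell size is multiplied by `factor`.
#' @export
resample_stack <- function(stack, factor, continuous_rule = "mean",
                           categorical_rule = "majority") {
  assert_that(is_scalar_number(factor) && factor >= 1 && factor == round(factor),
              "factor must be a positive integer")
  if (!continuous_rule %in% "mean")
    stop("configuration error: unknown continuous_rule '", continuous_rule, "'",
         call. = FALSE)
  if (!categorical_rule %in% "majority")
    stop("configuration error: unknown categorical_rule '", categorical_rule, "'",
         call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)

  g <- stack$grid
  out_rows <- ceiling(g$n_rows / factor)
  out_cols <- ceiling(g$n_cols / factor)
  pad <- function(m) {
    p <- matrix(NA_real_, out_rows * factor, out_cols * factor)
    p[seq_len(g$n_rows), seq_len(g$n_cols)] <- m
    p
  }
  block_apply <- function(m, f) {
    m <- pad(m)
    out <- matrix(NA_real_, out_rows, out_cols)
    for (br in seq_len(out_rows)) {
      rows <- ((br - 1) * factor + 1):(br * factor)
      for (bc in seq_len(out_cols)) {
        cols <- ((bc - 1) * factor + 1):(bc * factor)
        v <- m[rows, cols]
        v <- v[!is.na(v)]
        if (length(v)) out[br, bc] <- f(v)
      }
    }
    out
  }
  majority_smallest <- function(v) {
    tab <- table(v)
    winners <- as.numeric(names(tab)[tab == max(tab)])
    min(winners)  # deterministic tie-break: smallest label
  }
  new_layers <- lapply(stack$layers, function(ly) {
    f <- if (ly$kind == "continuous") mean else majority_smallest
    env_layer(ly$name, block_apply(ly$values, f), ly$kind)
  })
  new_grid <- grid_def(g$origin_x, g$origin_y, g$cell_size * factor,
                       out_rows, out_cols, g$crs_tag)
  env_stack(unname(new_layers), new_grid, stack$period_tag)
}

# Extraction -----------------------------------------------------------------

#' Extract environmental values at cells
#'
#' Builds the design matrix all learners consume: one row per cell with its
#' presence/pseudo-absence label and one column per layer. Rows touching
#' nodata are dropped; the drop count is attached as attribute `n_dropped`.
#' Categorical layers become factor columns over the layer's full label set.
#'
#' @param stack An [env_stack()].
#' @param cells Integer vector of 0-based cell indices.
#' @param labels Vector the same length as `cells` (1 = presence,
#'   0 = pseudo-absence; `NA` allowed for unlabeled projection rows).
#' @return A tibble with columns `label`, `cell`, then one per layer.
#' @export
extract_at_cells <- function(stack, cells, labels) {
  assert_that(length(cells) == length(labels), "cells and labels must align")
  cells <- as.integer(cells)
  if (length(cells) && (min(cells) < 0 || max(cells) >= n_cells(stack$grid)))
    stop("index error: cell index out of grid bounds", call. = FALSE)
  rc <- cell_rowcol(stack$grid, cells)
  idx <- cbind(rc$row + 1L, rc$col + 1L)
  cols <- lapply(stack$layers, function(ly) {
    v <- ly$values[idx]
    if (ly$kind == "categorical") factor(v, levels = layer_labels(ly)) else v
  })
  out <- tibble::tibble(label = labels, cell = cells, !!!cols)
  keep <- stats::complete.cases(out[, -1])
  dropped <- sum(!keep)
  out <- out[keep, ]
  attr(out, "n_dropped") <- dropped
  out
}
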