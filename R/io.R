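#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of values from the north edge down, matching the in-memory matrix layout.
#' `NA` cells are written as the no-data value and restored on read.
#'
#' @param values `n_rows x n_cols` matrix (row 1 = north).
#' @param grid The matching [grid_spec()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata No-data sentinel.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$n_rows,
            ncol(values) == grid$n_cols)
  header <- c(sprintf("ncols %d", grid$n_cols),
              sprintf("nrows %d", grid$n_rows),
              sprintf("xllcorner %.10g", grid$origin_x),
              sprintf("yllcorner %.10g", grid$origin_y),
              sprintf("cellsize %.10g", grid$resolution),
              sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `grid` ([grid_spec()]) and `values` (matrix with
#'   no-data cells as `NA`).
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(header))
  if (length(missing) > 0) {
    stop(sprintf("ESRI ASCII header lacks: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  grid <- grid_spec(header$xllcorner, header$yllcorner, header$cellsize,
                    header$ncols, header$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_cells(grid)) {
    stop(sprintf("expected %d values, found %d", n_cells(grid), length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  if (!is.null(header$nodata_value)) m[m == header$nodata_value] <- NA
  list(grid = grid, values = m)
}

#' Write and read a landscape directory
#'
#' One ESRI ASCII grid per covariate plus a `landscape.json` sidecar
#' holding the grid spec, per-covariate variogram specs and seeds.
#'
#' @param landscape A `garp_landscape`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) or a `garp_landscape` (read).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(landscape$covariates)) {
    write_raster(landscape$covariates[[nm]], landscape$grid,
                 file.path(dir, paste0(nm, ".asc")))
  }
  sidecar <- list(grid = unclass(landscape$grid),
                  covariates = names(landscape$covariates),
                  vgm = lapply(landscape$vgm, unclass),
                  seeds = as.list(landscape$seeds),
                  master_seed = landscape$master_seed)
  jsonlite::write_json(sidecar, file.path(dir, "landscape.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "landscape.json"),
                                 simplifyVector = TRUE)
  covn <- sidecar$covariates
  rasters <- lapply(covn, function(nm) read_raster(file.path(dir, paste0(nm, ".asc"))))
  grids <- lapply(rasters, `[[`, "grid")
  for (k in seq_along(grids)[-1]) {
    if (!identical(unclass(grids[[k]]), unclass(grids[[1]]))) {
      stop(sprintf("raster '%s' does not match the grid of '%s'",
                   covn[k], covn[1]), call. = FALSE)
    }
  }
  ls <- landscape(grids[[1]], setNames(lapply(rasters, `[[`, "values"), covn))
  if (!is.null(sidecar$vgm) && length(sidecar$vgm) > 0) {
    ls$vgm <- lapply(sidecar$vgm, function(v)
      variogram_spec(v$model, v$range, v$sill, v$nugget))
  }
  if (!is.null(sidecar$seeds)) ls$seeds <- unlist(sidecar$seeds)
  if (!is.null(sidecar$master_seed)) ls$master_seed <- sidecar$master_seed
  ls
}

#' Read and write point CSV files
#'
#' Two-column (`x`, `y`) CSV, with any extra columns preserved.
#'
#' @param path CSV path.
#' @param points Tibble with `x` and `y` columns.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_points_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    # tolerate longitude/latitude headers
    names(df)[match(c("longitude", "latitude"), tolower(names(df)))] <- c("x", "y")
  }
  stopifnot(all(c("x", "y") %in% names(df)))
  as_tibble(df)
}

#' @rdname read_points_csv
#' @export
write_points_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Reduce points to spatially unique cells
#'
#' One point per occupied grid cell (the cell centroid), keeping the first
#' point's order: the standard presence preprocessing when the model treats
#' any occupied pixel as present.
#'
#' @param points Tibble with `x`, `y`.
#' @param grid A [grid_spec()].
#' @return Tibble of centroids (`x`, `y`, `cell`), one per occupied cell.
#' @export
spatially_unique <- function(points, grid) {
  cells <- point_to_cell(grid, points$x, points$y)
  keep <- !duplicated(cells)
  cell_centroids(grid, cells[keep])[, c("x", "y", "cell")]
}

#' External train/test split
#'
#' Seeded, stratification-free random partition of occurrence points used
#' before modelling, with the same rounding rules as [internal_split()].
#'
#' @inheritParams internal_split
#' @return List with `train` and `test` tibbles.
#' @export
external_split <- function(points, fraction = 0.75, seed, rule = "half_up") {
  internal_split(points, fraction, seed, rule)
}

#' Experiment configuration
#'
#' One nested list of every tunable: grid, variogram families, scenario,
#' engine parameters, best-subset parameters and the UI threshold, with the
#' benchmark defaults. Serializes losslessly to JSON.
#'
#' @param ... Overrides, as `section$name = value` nested lists.
#' @return A `garp_config` list.
#' @export
garp_config <- function(...) {
  cfg <- list(
    grid = unclass(grid_spec()),
    vgm_exponential = unclass(variogram_spec("exponential", range = 10)),
    vgm_spherical = unclass(variogram_spec("spherical", range = 6)),
    n_exponential = 5, n_spherical = 5,
    scenario = unclass(species_scenario("weak")),
    params = unclass(garp_params()),
    subset = list(omission_threshold = 10, n_low_omission = 20,
                  commission_window = 0.5),
    ui = list(threshold = 0.5, cutoff = 0.90, coef_tol = 0,
              scale = "landscape"),
    seed = 1)
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  structure(cfg, class = "garp_config")
}

#' @rdname garp_config
#' @param config A `garp_config`.
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname garp_config
#' @export
load_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "garp_config")
}
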