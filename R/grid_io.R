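#' Georeferenced raster grid
#'
#' Lightweight in-memory raster: a numeric matrix with an affine north-up
#' georeference (cell-center registration, row 1 = north, 0-based grid maths
#' done internally from 1-based R indices), a CRS identifier string and a
#' free-form semantic/units tag. Nodata cells are `NA` in `values`; every
#' downstream statistic in the package excludes them.
#'
#' @param values numeric matrix (row 1 = northernmost row of cells).
#' @param xmin x coordinate of the western edge of the grid (map units).
#' @param ymax y coordinate of the northern edge of the grid (map units).
#' @param dx,dy strictly positive pixel width/height in map units. The
#'   default 1000 m matches a 1-km analysis grid, so each pixel covers
#'   `1e6` square metres.
#' @param crs coordinate reference identifier. Area aggregation assumes an
#'   equal-area projected CRS in metres.
#' @param semantic value meaning + units tag, e.g. `"NEP g C m-2 a-1"`.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * dy,
                        dx = 1000, dy = dx,
                        crs = "LOCAL:equal-area-metres", semantic = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("pixel size must be strictly positive (got dx=", dx, ", dy=", dy, ")")
  structure(
    list(values = values,
         transform = list(xmin = xmin, ymax = ymax, dx = dx, dy = dy),
         crs = crs, semantic = semantic),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  tr <- x$transform
  cat(sprintf("raster_grid %d x %d  [%s]\n", nrow(x$values), ncol(x$values),
              x$semantic))
  cat(sprintf("  origin (%g, %g), pixel %g x %g, crs: %s\n",
              tr$xmin, tr$ymax, tr$dx, tr$dy, x$crs))
  cat(sprintf("  valid cells: %d / %d\n", sum(!is.na(x$values)),
              length(x$values)))
  invisible(x)
}

#' Nodata mask of a raster grid
#' @param grid a `raster_grid`.
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

#' Cell-center coordinates of a grid
#' @param grid a `raster_grid`.
#' @return list with `x` (west to east) and `y` (north to south) center
#'   coordinate vectors.
#' @export
cell_centers <- function(grid) {
  tr <- grid$transform
  list(x = tr$xmin + (seq_len(ncol(grid$values)) - 0.5) * tr$dx,
       y = tr$ymax - (seq_len(nrow(grid$values)) - 0.5) * tr$dy)
}

#' Pixel area implied by the georeference
#' @param grid a `raster_grid` (or a transform list).
#' @return area of one pixel in squared map units.
#' @export
pixel_area <- function(grid) {
  tr <- if (inherits(grid, "raster_grid")) grid$transform else grid
  tr$dx * tr$dy
}

grid_extent <- function(grid) {
  tr <- grid$transform
  c(xmin = tr$xmin, xmax = tr$xmin + ncol(grid$values) * tr$dx,
    ymin = tr$ymax - nrow(grid$values) * tr$dy, ymax = tr$ymax)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(unlist(a$transform) - unlist(b$transform)) < tol)
}

#' Temporal stack of co-registered raster layers
#'
#' Array-backed stack (rows x cols x layers) sharing one transform and CRS,
#' with an optional `(year, month)` time index for monthly series or a
#' `year` index for annual series.
#'
#' @param values 3-D numeric array `[row, col, layer]` (a matrix is promoted
#'   to a single-layer stack).
#' @param template a `raster_grid` supplying transform/crs, or `NULL` to use
#'   the remaining arguments.
#' @param time_index `data.frame` with column `year` and optionally `month`;
#'   `NULL` for non-temporal stacks.
#' @param semantic units tag applied to all layers.
#' @inheritParams raster_grid
#' @return object of class `grid_stack`.
#' @export
grid_stack <- function(values, template = NULL, time_index = NULL,
                       semantic = "", xmin = 0, ymax = NULL, dx = 1000,
                       dy = dx, crs = "LOCAL:equal-area-metres") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  if (!is.null(template)) {
    tr <- template$transform; crs <- template$crs
  } else {
    if (is.null(ymax)) ymax <- dim(values)[1] * dy
    tr <- list(xmin = xmin, ymax = ymax, dx = dx, dy = dy)
  }
  if (!is.null(time_index)) {
    time_index <- as.data.frame(time_index)
    if (nrow(time_index) != dim(values)[3])
      stop("time_index length (", nrow(time_index),
           ") must equal layer count (", dim(values)[3], ")")
  }
  structure(list(values = values, transform = tr, crs = crs,
                 time_index = time_index, semantic = semantic),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grid_stack %d x %d x %d layers  [%s]\n", d[1], d[2], d[3],
              x$semantic))
  if (!is.null(x$time_index)) {
    rng <- range(x$time_index$year)
    cat(sprintf("  years %d-%d%s\n", rng[1], rng[2],
                if ("month" %in% names(x$time_index)) ", monthly" else ""))
  }
  invisible(x)
}

#' Extract one layer of a stack as a raster_grid
#' @param stack a `grid_stack`.
#' @param i layer index.
#' @export
stack_layer <- function(stack, i) {
  raster_grid(stack$values[, , i],
              xmin = stack$transform$xmin, ymax = stack$transform$ymax,
              dx = stack$transform$dx, dy = stack$transform$dy,
              crs = stack$crs, semantic = stack$semantic)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a raster to an Arc/Info ASCII grid
#'
#' Writes the standard text raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by north-to-south rows). Non-square
#' pixels use the `dx`/`dy` header extension. CRS and semantic tag go to a
#' JSON sidecar `<path>.aux.json` so the file round-trips completely.
#'
#' @param grid a `raster_grid`.
#' @param path output path (conventionally `.asc`).
#' @param nodata value standing for nodata cells in the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  tr <- grid$transform
  ext <- grid_extent(grid)
  hdr <- c(paste("ncols", ncol(grid$values)),
           paste("nrows", nrow(grid$values)),
           paste("xllcorner", fmt_num(ext["xmin"])),
           paste("yllcorner", fmt_num(ext["ymin"])))
  hdr <- c(hdr, if (isTRUE(all.equal(tr$dx, tr$dy)))
    paste("cellsize", fmt_num(tr$dx))
    else c(paste("dx", fmt_num(tr$dx)), paste("dy", fmt_num(tr$dy))))
  hdr <- c(hdr, paste("NODATA_value", fmt_num(nodata)))
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(vals, 1, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  jsonlite::write_json(list(crs = grid$crs, semantic = grid$semantic),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an Arc/Info ASCII grid
#'
#' @param path path to an `.asc` file written by [write_raster()] or any
#'   other producer of the format. A missing file or a file without the
#'   georeference header is an explicit error.
#' @param semantic optional units tag overriding the sidecar's.
#' @return a `raster_grid` with file-nodata cells masked (`NA`).
#' @export
read_raster <- function(path, semantic = NULL) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)) ||
      !any(c("xllcorner", "xllcenter") %in% names(hdr)))
    stop("file is not a georeferenced ASCII grid (header incomplete): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (!is.null(hdr$cellsize)) { dx <- hdr$cellsize; dy <- hdr$cellsize }
  else if (!is.null(hdr$dx) && !is.null(hdr$dy)) { dx <- hdr$dx; dy <- hdr$dy }
  else stop("file is not a georeferenced ASCII grid (no cellsize): ", path)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - dx / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - dy / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  aux_path <- paste0(path, ".aux.json")
  crs <- "LOCAL:equal-area-metres"; sem <- ""
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
    if (!is.null(aux$crs)) crs <- aux$crs
    if (!is.null(aux$semantic)) sem <- aux$semantic
  }
  if (!is.null(semantic)) sem <- semantic
  raster_grid(m, xmin = xll, ymax = yll + nr * dy, dx = dx, dy = dy,
              crs = crs, semantic = sem)
}

#' Write a temporal stack as a directory of ASCII grids
#'
#' One `.asc` per layer plus a `manifest.json` recording layer order, time
#' index, CRS and semantic tag; readable back with [read_stack()].
#'
#' @param stack a `grid_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "grid_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nl <- dim(stack$values)[3]
  names <- if (!is.null(stack$time_index) &&
               all(c("year", "month") %in% names(stack$time_index)))
    sprintf("%04d-%02d", stack$time_index$year, stack$time_index$month)
  else if (!is.null(stack$time_index) && "year" %in% names(stack$time_index))
    sprintf("%04d", stack$time_index$year)
  else sprintf("band_%03d", seq_len(nl))
  files <- paste0(names, ".asc")
  for (k in seq_len(nl)) write_raster(stack_layer(stack, k),
                                      file.path(dir, files[k]))
  jsonlite::write_json(
    list(files = files, crs = stack$crs, semantic = stack$semantic,
         time_index = stack$time_index),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a temporal stack written by [write_stack()]
#' @param dir stack directory containing `manifest.json`.
#' @return a `grid_stack`.
#' @export
read_stack <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no stack manifest in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  layers <- lapply(file.path(dir, mf$files), read_raster)
  g1 <- layers[[1]]
  vals <- array(NA_real_, c(dim(g1$values), length(layers)))
  for (k in seq_along(layers)) vals[, , k] <- layers[[k]]$values
  ti <- if (!is.null(mf$time_index)) as.data.frame(mf$time_index) else NULL
  grid_stack(vals, template = g1, time_index = ti,
             semantic = if (is.null(mf$semantic)) "" else mf$semantic)
}

#' Align a raster onto a target grid
#'
#' Resamples `src` onto the geometry of `target`: bilinear interpolation for
#' continuous fields (the convention used to bring all layers to one common
#' grid), nearest neighbour for categorical codes (bilinear would invent
#' category values). Nodata is never interpolated into valid cells: any
#' bilinear neighbourhood touching nodata yields nodata, and target cells
#' outside the source extent are nodata.
#'
#' @param src `raster_grid` to resample.
#' @param target `raster_grid` supplying the output geometry.
#' @param kind `"continuous"` (bilinear) or `"categorical"` (nearest).
#' @return `raster_grid` on `target`'s grid.
#' @export
align_to_grid <- function(src, target, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (same_geometry(src, target)) {
    out <- src
    out$transform <- target$transform
    return(out)
  }
  es <- grid_extent(src); et <- grid_extent(target)
  if (es["xmax"] <= et["xmin"] || et["xmax"] <= es["xmin"] ||
      es["ymax"] <= et["ymin"] || et["ymax"] <= es["ymin"])
    stop(sprintf(
      "extents do not overlap: src [%g,%g]x[%g,%g] vs target [%g,%g]x[%g,%g]",
      es["xmin"], es["xmax"], es["ymin"], es["ymax"],
      et["xmin"], et["xmax"], et["ymin"], et["ymax"]))
  cs <- cell_centers(src); ct <- cell_centers(target)
  xp <- rep(ct$x, each = length(ct$y))
  yp <- rep(ct$y, times = length(ct$x))
  inside <- xp >= es["xmin"] & xp <= es["xmax"] &
    yp >= es["ymin"] & yp <= es["ymax"]
  out <- rep(NA_real_, length(xp))
  if (kind == "continuous") {
    # interp2 needs ascending y; clamp in-extent points to the center lattice
    # so the half-pixel rim keeps the edge value (standard edge handling).
    xq <- pmin(pmax(xp[inside], min(cs$x)), max(cs$x))
    yq <- pmin(pmax(yp[inside], min(cs$y)), max(cs$y))
    z_asc <- src$values[rev(seq_len(nrow(src$values))), , drop = FALSE]
    out[inside] <- pracma::interp2(cs$x, rev(cs$y), z_asc, xq, yq,
                                   method = "linear")
  } else {
    j <- pmin(pmax(round((xp[inside] - src$transform$xmin) /
                           src$transform$dx + 0.5), 1), ncol(src$values))
    i <- pmin(pmax(round((src$transform$ymax - yp[inside]) /
                           src$transform$dy + 0.5), 1), nrow(src$values))
    out[inside] <- src$values[cbind(i, j)]
  }
  m <- matrix(out, nrow = length(ct$y), ncol = length(ct$x))
  raster_grid(m, xmin = target$transform$xmin, ymax = target$transform$ymax,
              dx = target$transform$dx, dy = target$transform$dy,
              crs = target$crs, semantic = src$semantic)
}
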