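# Suitability-raster file output. With no GDAL-backed R package in the
# dependency set, the raster goes out as a multiband float TIFF (via the
# tiff package, which stores samples in [0, 1]) accompanied by two
# plain-text sidecars: an ESRI world file (.tfw) with the affine
# georeferencing, and a .bands.txt listing band names and the linear
# scaling (per-band min/max) used to pack values into [0, 1]. The last
# band is a data mask (1 = land cell, 0 = no data).
# read_suitability_raster() understands the trio, so write -> read
# round-trips the layers to float32 precision.

.raster_bands <- c("ei", "class_code", "cs", "hs", "ds", "ws")

#' Write a suitability raster as a multiband TIFF
#'
#' Bands, in order: EI, class code (0-3), cold, heat, dry and wet stress,
#' plus a trailing data-mask band. Values are packed linearly into the
#' \[0, 1\] sample range of 32-bit float TIFF; the per-band ranges go in
#' the plain-text `<path>.bands.txt` sidecar and the georeferencing in an
#' ESRI world file (`.tfw`, cell-centre convention).
#'
#' @param x A `suitability_raster` from [run_grid()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_suitability_raster <- function(x, path) {
  ranges <- vapply(.raster_bands, function(b) {
    v <- x[[b]][is.finite(x[[b]])]
    if (!length(v)) return(c(0, 1))
    r <- range(v)
    if (r[1] == r[2]) r[2] <- r[1] + 1
    r
  }, numeric(2))
  layers <- lapply(.raster_bands, function(b) {
    m <- (x[[b]] - ranges[1, b]) / (ranges[2, b] - ranges[1, b])
    m[!is.finite(m)] <- 0
    matrix(pmin(pmax(as.numeric(m), 0), 1), nrow(x[[b]]), ncol(x[[b]]))
  })
  layers <- c(layers, list(matrix(as.numeric(x$mask), nrow(x$mask))))
  ok <- tryCatch({
    tiff::writeTIFF(layers, path, bits.per.sample = 32L, reduce = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write TIFF: %s", path)
  res <- x$resolution
  # world file: x-scale, rotations, negative y-scale, upper-left cell centre
  writeLines(format(c(res, 0, 0, -res, x$lon[1], x$lat[1]),
                    digits = 15, trim = TRUE, scientific = FALSE),
             paste0(tools::file_path_sans_ext(path), ".tfw"))
  writeLines(c(paste("bands:", paste(c(.raster_bands, "mask"), collapse = ",")),
               "crs: EPSG:4326",
               vapply(.raster_bands, function(b)
                 sprintf("range %s: %.10g %.10g", b, ranges[1, b],
                         ranges[2, b]), character(1))),
             paste0(path, ".bands.txt"))
  invisible(path)
}

#' Read back a suitability raster written by [write_suitability_raster()]
#'
#' @param path TIFF path (the `.tfw` and `.bands.txt` sidecars must sit
#'   next to it).
#' @return A list with `lon`, `lat`, `resolution`, `mask` and one matrix
#'   per band. Values are float32-rounded copies of what was written;
#'   masked cells are `NA`.
#' @export
read_suitability_raster <- function(path) {
  if (!file.exists(path)) stop_io("raster not found: %s", path)
  tfw <- paste0(tools::file_path_sans_ext(path), ".tfw")
  meta <- paste0(path, ".bands.txt")
  if (!file.exists(tfw)) stop_io("world file not found: %s", tfw)
  if (!file.exists(meta)) stop_io("band sidecar not found: %s", meta)
  layers <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(layers)) layers <- list(layers)
  lines <- readLines(meta)
  bands <- strsplit(sub("^bands: *", "", lines[grepl("^bands:", lines)]),
                    ",")[[1]]
  names(layers) <- bands[seq_along(layers)]
  mask <- layers$mask > 0.5
  for (b in setdiff(names(layers), "mask")) {
    rng_line <- lines[grepl(paste0("^range ", b, ":"), lines)]
    rng <- as.numeric(strsplit(sub(".*: *", "", rng_line), " +")[[1]])
    layers[[b]] <- layers[[b]] * (rng[2] - rng[1]) + rng[1]
    layers[[b]][!mask] <- NA_real_
  }
  wf <- as.numeric(readLines(tfw))
  res <- wf[1]
  nlat <- nrow(layers[[1]]); nlon <- ncol(layers[[1]])
  c(list(lon = wf[5] + (seq_len(nlon) - 1) * res,
         lat = wf[6] - (seq_len(nlat) - 1) * res,
         resolution = res, mask = mask),
    layers[setdiff(names(layers), "mask")])
}

#' Export a suitability map (TIFF + rendered PNG)
#'
#' Writes the multiband raster via [write_suitability_raster()] and a
#' rendered PNG of the four suitability classes with a legend.
#'
#' @param x A `suitability_raster`.
#' @param path Output path prefix (without extension): `<path>.tif` and
#'   `<path>.png` are written.
#' @param width,height PNG size in pixels.
#' @return Invisibly, a list with the written paths and the legend labels
#'   (always the four suitability classes).
#' @export
export_map <- function(x, path, width = 800, height = 500) {
  tif <- paste0(path, ".tif")
  png_path <- paste0(path, ".png")
  write_suitability_raster(x, tif)
  if (all(!x$mask)) warning("raster is fully masked; map will be blank")
  legend_labels <- c("unsuitable (EI = 0)", "marginal (0 < EI < 10)",
                     "suitable (10 <= EI < 20)", "very suitable (EI >= 20)")
  cols <- c("#f2f0eb", "#ffe08a", "#8fd175", "#1a9641")
  ok <- tryCatch({
    grDevices::png(png_path, width = width, height = height, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(4, 4, 2, 1))
    if (any(x$mask)) {
      z <- t(x$class_code[rev(seq_along(x$lat)), , drop = FALSE])
      graphics::image(x = x$lon, y = rev(x$lat), z = z, zlim = c(0, 3),
                      col = cols, xlab = "Longitude", ylab = "Latitude",
                      main = "Climatic suitability")
    } else {
      graphics::plot.new()
      graphics::title("Climatic suitability (no data)")
    }
    graphics::legend("bottomleft", legend = legend_labels, fill = cols,
                     bg = "white", cex = 0.8)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot render PNG map: %s", png_path)
  invisible(list(tif = tif, png = png_path, legend = legend_labels))
}
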