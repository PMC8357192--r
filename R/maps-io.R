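#' Export FLIm maps to image files and an archival CSV
#'
#' Writes one multi-page 32-bit float TIFF per quantity (`lt.tif`,
#' `intensity.tif`, `ratio.tif`, one page per channel) for viewing, plus a
#' long-format CSV (`maps.csv`: row, col, channel, lt, intensity, ratio,
#' valid) and a small `meta.json`. TIFF samples are min-max scaled to
#' `[0, 1]` per page (the scaling ranges are recorded in `meta.json`,
#' invalid pixels are written as 0); the CSV stores full double precision
#' with `NA` sentinels and is the archival format from which
#' [importMaps()] reconstructs the maps bit-identically.
#'
#' @param maps A [FLImMaps-class].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @seealso [importMaps()]
#' @export
exportMaps <- function(maps, path) {
  validObject(maps)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ranges <- list()
  writeQuantity <- function(a, name) {
    pages <- vector("list", 3L)
    rg <- matrix(NA_real_, 3, 2)
    for (k in 1:3) {
      m <- a[, , k]
      lo <- suppressWarnings(min(m, na.rm = TRUE))
      hi <- suppressWarnings(max(m, na.rm = TRUE))
      if (!is.finite(lo)) { lo <- 0; hi <- 1 }
      if (hi <= lo) hi <- lo + 1
      m <- (m - lo) / (hi - lo)
      m[is.na(m)] <- 0
      pages[[k]] <- m
      rg[k, ] <- c(lo, hi)
    }
    tiff::writeTIFF(pages, file.path(path, paste0(name, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
    ranges[[name]] <<- rg
  }
  writeQuantity(maps@lt, "lt")
  writeQuantity(maps@intensity, "intensity")
  writeQuantity(maps@ratio, "ratio")
  d <- dim(maps@lt)
  tab <- data.frame(
    row = rep(rep(seq_len(d[1]), d[2]), 3),
    col = rep(rep(seq_len(d[2]), each = d[1]), 3),
    channel = rep(1:3, each = d[1] * d[2]),
    lt = as.vector(maps@lt),
    intensity = as.vector(maps@intensity),
    ratio = as.vector(maps@ratio),
    valid = rep(as.vector(maps@valid), 3)
  )
  # full-precision text so the CSV round-trips bit-identically
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- cbind(tab[, 1:3],
               lt = fmt(tab$lt), intensity = fmt(tab$intensity),
               ratio = fmt(tab$ratio), valid = tab$valid)
  utils::write.csv(out, file.path(path, "maps.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(format = "flimcart-maps-v1", nRows = d[1], nCols = d[2],
         pixelPitch = maps@pixelPitch, tiffRanges = ranges),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import FLIm maps from an export directory
#'
#' Rebuilds a [FLImMaps-class] from the archival CSV written by
#' [exportMaps()].
#'
#' @param path Directory written by [exportMaps()].
#' @return A [FLImMaps-class].
#' @export
importMaps <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "flimcart-maps-v1"))
    stop("not a flimcart maps export: ", path)
  tab <- utils::read.csv(file.path(path, "maps.csv"))
  nr <- meta$nRows; nc <- meta$nCols
  arr <- function(v) array(as.numeric(v), c(nr, nc, 3))
  new("FLImMaps",
      lt = arr(tab$lt), intensity = arr(tab$intensity),
      ratio = arr(tab$ratio),
      valid = matrix(tab$valid[seq_len(nr * nc)], nr, nc),
      pixelPitch = meta$pixelPitch)
}

#' Export a depth profile as CSV
#'
#' @param profile A [DepthProfile-class].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
exportDepthProfile <- function(profile, file) {
  utils::write.csv(profile@table, file, row.names = FALSE)
  invisible(file)
}

#' Export a segmentation result as CSV (per-column thickness) plus a mask
#' image
#'
#' @param seg A [SegmentationResult-class].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
exportSegmentation <- function(seg, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(col = seq_along(seg@thicknessPerColumn),
               thickness_mm = seg@thicknessPerColumn),
    file.path(path, "thickness.csv"), row.names = FALSE)
  tiff::writeTIFF(seg@depletedMask + 0, file.path(path, "depleted_mask.tif"),
                  bits.per.sample = 8L)
  invisible(path)
}
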