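# internal volumetric format: gzipped little-endian float64 raster plus a
# JSON sidecar carrying geometry and axis names

.sidecarPath <- function(path) paste0(path, ".json")
.rasterPath <- function(path) paste0(path, ".raw.gz")

#' Save a volume in the internal format
#'
#' Writes `<path>.raw.gz` (gzipped little-endian float64, x fastest) and
#' `<path>.json` (kind, dim, spacing, origin, axis names).
#'
#' @param x a [DensityGrid-class] or [DoseGrid-class].
#' @param path file path prefix (no extension).
#' @return `path`, invisibly.
#' @export
saveVolume <- function(x, path) {
    meta <- list(kind = class(x)[1], dim = dim(x@voxels),
                 spacing = x@spacing, origin = x@origin,
                 axes = c("lateral", "vertical", "longitudinal"))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               .sidecarPath(path))
    con <- gzfile(.rasterPath(path), "wb")
    on.exit(close(con))
    writeBin(as.vector(x@voxels), con, size = 8, endian = "little")
    invisible(path)
}

#' Load a volume from the internal format
#'
#' Round-trip stable with [saveVolume()]; malformed or truncated files raise
#' a format error naming the problem rather than returning corrupt data.
#'
#' @param path file path prefix used at save time.
#' @return A [DensityGrid-class] or [DoseGrid-class] per the sidecar's kind.
#' @export
loadVolume <- function(path) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc) || !file.exists(.rasterPath(path)))
        stop("format error: missing sidecar or raster file for '", path, "'")
    meta <- jsonlite::fromJSON(sc)
    for (f in c("kind", "dim", "spacing", "origin"))
        if (is.null(meta[[f]]))
            stop("format error: sidecar missing field '", f, "'")
    n <- prod(meta$dim)
    con <- gzfile(.rasterPath(path), "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(vals) != n)
        stop("format error: raster truncated (", length(vals), " of ", n,
             " voxels)")
    arr <- array(vals, meta$dim)
    switch(meta$kind,
           DensityGrid = DensityGrid(arr, meta$spacing, meta$origin),
           DoseGrid = DoseGrid(arr, meta$spacing, meta$origin),
           stop("format error: unknown kind '", meta$kind, "'"))
}

#' Write an error series as CSV
#'
#' Columns: fraction, dx, dy, dz (mm), class, scenario; the seed is stored
#' in a comment-free companion column-less way via the run manifest.
#'
#' @param series an [ErrorSeries-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeErrorSeries <- function(series, path) {
    df <- data.frame(fraction = seq_len(nrow(series@shifts)),
                     dx = series@shifts[, 1], dy = series@shifts[, 2],
                     dz = series@shifts[, 3], class = series@errorClass,
                     scenario = series@scenario)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read an error series written by [writeErrorSeries()]
#'
#' @param path CSV file path.
#' @return An [ErrorSeries-class].
#' @export
readErrorSeries <- function(path) {
    df <- utils::read.csv(path)
    need <- c("fraction", "dx", "dy", "dz", "class", "scenario")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("format error: error-series CSV missing column(s) ",
             paste(miss, collapse = ", "))
    ErrorSeries(as.matrix(df[, c("dx", "dy", "dz")]), df$class[1],
                df$scenario[1])
}

#' Write a robustness report to disk
#'
#' Writes `report.csv` (one row per technique x scenario), `reference.csv`
#' and `manifest.json` under `dir`.
#'
#' @param report a [RobustnessReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report@table, file.path(dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(report@reference, file.path(dir, "reference.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(report@manifest, auto_unbox = TRUE,
                                digits = NA, force = TRUE, pretty = TRUE),
               file.path(dir, "manifest.json"))
    invisible(dir)
}
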