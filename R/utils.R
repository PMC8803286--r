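# internal voxel-grid helpers shared across modules

# world coordinates (mm) of voxel centres along one axis
.axisCoords <- function(dimLen, spacing, origin)
    origin + (seq_len(dimLen) - 1) * spacing

.gridCoords <- function(dims, spacing, origin)
    lapply(1:3, function(k) .axisCoords(dims[k], spacing[k], origin[k]))

.sameGeometry <- function(a, b, tol = 1e-9) {
    da <- if (is(a, "StructureSet")) dim(a@masks[[1]]) else dim(a@voxels)
    db <- if (is(b, "StructureSet")) dim(b@masks[[1]]) else dim(b@voxels)
    identical(as.integer(da), as.integer(db)) &&
        all(abs(a@spacing - b@spacing) < tol) &&
        all(abs(a@origin - b@origin) < tol)
}

.stopIfGeometryMismatch <- function(a, b, what = "grids") {
    if (!.sameGeometry(a, b))
        stop("geometry error: ", what,
             " are not co-registered (shape/spacing/origin differ)")
    invisible(TRUE)
}

# translate a logical mask by an integer voxel offset, zero-filling
.translateMask <- function(mask, voxShift) {
    d <- dim(mask)
    out <- array(FALSE, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
        s <- voxShift[k]
        if (abs(s) >= d[k]) return(out)
        if (s >= 0) {
            src[[k]] <- seq_len(d[k] - s)
            dst[[k]] <- seq_len(d[k] - s) + s
        } else {
            src[[k]] <- seq_len(d[k] + s) - s
            dst[[k]] <- seq_len(d[k] + s)
        }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    out
}

# translate a numeric array by an integer voxel offset, filling with `fill`
.translateArray <- function(arr, voxShift, fill) {
    d <- dim(arr)
    out <- array(fill, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
        s <- voxShift[k]
        if (abs(s) >= d[k]) return(out)
        if (s >= 0) {
            src[[k]] <- seq_len(d[k] - s)
            dst[[k]] <- seq_len(d[k] - s) + s
        } else {
            src[[k]] <- seq_len(d[k] + s) - s
            dst[[k]] <- seq_len(d[k] + s)
        }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
}

# morphological dilation by a Euclidean ball of radius mm, handled in mm
# space so anisotropic voxels dilate isotropically. The structuring element
# is inflated by a quarter voxel: the rasterized surface sits between the
# outermost voxel centres and half a voxel beyond them, and the candidate
# voxels are rasterized too, so a quarter-voxel correction debiases the
# centre-to-centre distance (validated against analytic shell volumes).
.dilateMask <- function(mask, radiusMM, spacing) {
    if (radiusMM <= 0) return(mask)
    reff <- radiusMM + mean(spacing) / 4
    r <- ceiling(reff / spacing)
    offs <- expand.grid(ox = -r[1]:r[1], oy = -r[2]:r[2], oz = -r[3]:r[3])
    keep <- sqrt((offs$ox * spacing[1])^2 + (offs$oy * spacing[2])^2 +
                 (offs$oz * spacing[3])^2) <= reff + 1e-9
    offs <- offs[keep, , drop = FALSE]
    out <- array(FALSE, dim(mask))
    for (i in seq_len(nrow(offs))) {
        sh <- .translateMask(mask, c(offs$ox[i], offs$oy[i], offs$oz[i]))
        out <- out | sh
    }
    out
}

# centroid of a mask in world coordinates (mm)
.maskCentroid <- function(mask, spacing, origin) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("structure error: mask is empty")
    unname(origin + (colMeans(idx) - 1) * spacing)
}

# md5 of a canonical JSON rendering, for run manifests
.configHash <- function(x) {
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                force = TRUE), f)
    unname(tools::md5sum(f))
}
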