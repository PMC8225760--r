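## Buried-cavity tracking on a regular grid: distance-band (d_min..d_max to
## the nearest heavy atom) plus ray-buriedness (>= min_hits of 14 lattice
## rays hit an atom within ray_length). A cross-frame frequency map
## thresholded at the isovalue gives the persistent pocket as a
## 26-connected component around a seed point; per-frame volume is the
## count of that frame's cavity points inside the component times
## spacing^3. This is a self-contained method, not an MDpocket/fpocket
## re-implementation; hydrogens are ignored by taking all atoms of the
## (heavy-atom-only) synthetic frames.

.asFrameList <- function(frames) {
    if (is(frames, "Frame")) return(list(frames))
    if (is(frames, "Trajectory"))
        return(lapply(seq_len(nFrames(frames)), function(i)
            getFrame(frames, i)))
    if (is.list(frames) && !is.null(frames$frames)) return(frames$frames)
    frames
}

.latticeDirections <- function() {
    ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
    dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
    unname(rbind(ax, dg))
}

#' Shared grid over a set of frames
#'
#' Regular grid covering the union bounding box of all atoms plus a
#' `d_max_A` margin, at the configured spacing.
#'
#' @param frames frames ([Frame-class] list, [Trajectory-class], or the
#'   result of [subsampleFrames()]).
#' @param config a [PocketConfig-class].
#' @return list with `origin`, `spacing`, `dims`, and `points`
#'   (`n x 3` matrix, x fastest).
#' @export
pocketGrid <- function(frames, config) {
    frames <- .asFrameList(frames)
    if (length(frames) == 0L) stop("no frames supplied")
    rng <- sapply(c("x", "y", "z"), function(ax)
        range(unlist(lapply(frames, function(f) f@atoms[[ax]]))))
    if (any(!is.finite(rng))) stop("degenerate grid: non-finite bounds")
    sp <- config@grid_spacing_A
    lo <- floor((rng[1L, ] - config@d_max_A) / sp) * sp
    hi <- ceiling((rng[2L, ] + config@d_max_A) / sp) * sp
    dims <- as.integer(round((hi - lo) / sp)) + 1L
    axes <- lapply(1:3, function(k) lo[k] + sp * (seq_len(dims[k]) - 1L))
    pts <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]],
                                 z = axes[[3L]]))
    list(origin = lo, spacing = sp, dims = dims, points = unname(pts))
}

## logical cavity mask over query points for one set of atom coordinates;
## the distance-band + ray-buriedness rule itself lives in compiled code
## (src/cavity.cpp) and is shared by the grid and Monte-Carlo routes
.cavityMask <- function(atoms, grid, config) {
    .cavityRuleCpp(grid$points, atoms, config@d_min_A, config@d_max_A,
                   .latticeDirections(), config@buriedness_min_hits,
                   config@ray_length_A, config@ray_hit_radius_A)
}

#' Cavity grid points of a single frame
#'
#' Points whose nearest-atom distance lies in `[d_min, d_max]` and that are
#' buried (at least `buriedness_min_hits` of 14 lattice rays hit an atom
#' within the ray length).
#'
#' @param frame a [Frame-class].
#' @param config a [PocketConfig-class].
#' @param grid optional shared grid from [pocketGrid()] (derived from the
#'   frame when NULL).
#' @return list with `mask` (logical over grid points), `n_points` and
#'   `grid`.
#' @export
cavityPoints <- function(frame, config, grid = NULL) {
    if (nrow(frame@atoms) == 0L) stop("empty frame")
    if (is.null(grid)) grid <- pocketGrid(frame, config)
    mask <- .cavityMask(coords(frame), grid, config)
    list(mask = mask, n_points = sum(mask), grid = grid)
}

#' Cross-frame cavity frequency map
#'
#' Per grid point, the count of frames in which the point is a cavity
#' point.
#'
#' @param frames frames ([Frame-class] list, [Trajectory-class], or
#'   [subsampleFrames()] output).
#' @param config a [PocketConfig-class].
#' @param grid optional shared grid (derived from all frames when NULL).
#' @return list with `counts` (integer per grid point), `masks` (list of
#'   per-frame logical masks), `n_frames` and `grid`.
#' @export
frequencyMap <- function(frames, config, grid = NULL) {
    frames <- .asFrameList(frames)
    if (length(frames) == 0L) stop("no frames supplied")
    if (is.null(grid)) grid <- pocketGrid(frames, config)
    masks <- lapply(frames, function(f)
        .cavityMask(coords(f), grid, config))
    counts <- Reduce(`+`, lapply(masks, as.integer))
    list(counts = counts, masks = masks, n_frames = length(frames),
         grid = grid)
}

## 26-connected component of `qual` (logical vector over the grid)
## containing the grid point `start` (linear index)
.floodFill26 <- function(qual, dims, start) {
    nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
    comp <- logical(length(qual))
    queue <- integer(1024L); queue[1L] <- start; qn <- 1L
    comp[start] <- TRUE
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0L, ]
    while (qn > 0L) {
        cur <- queue[qn]; qn <- qn - 1L
        k <- (cur - 1L) %/% (nx * ny)
        rem <- (cur - 1L) %% (nx * ny)
        j <- rem %/% nx
        i <- rem %% nx
        ii <- i + offs[, 1L]; jj <- j + offs[, 2L]; kk <- k + offs[, 3L]
        valid <- ii >= 0L & ii < nx & jj >= 0L & jj < ny & kk >= 0L & kk < nz
        nb <- 1L + ii[valid] + nx * (jj[valid] + ny * kk[valid])
        nb <- nb[qual[nb] & !comp[nb]]
        if (length(nb) > 0L) {
            comp[nb] <- TRUE
            if (qn + length(nb) > length(queue))
                queue <- c(queue, integer(length(queue)))
            queue[(qn + 1L):(qn + length(nb))] <- nb
            qn <- qn + length(nb)
        }
    }
    comp
}

#' Select the persistent pocket component from a frequency map
#'
#' Thresholds the frequency map at the isovalue (count >= isovalue) and
#' returns the 26-connected component containing the qualifying grid point
#' nearest to the configured seed point (which must lie within the 3
#' Angstrom rescue radius).
#'
#' @param fmap output of [frequencyMap()].
#' @param config a [PocketConfig-class].
#' @return list with `component` (logical over grid points), `n_points` and
#'   `grid`.
#' @export
selectPocket <- function(fmap, config) {
    qual <- fmap$counts >= config@isovalue
    if (!any(qual))
        stop(sprintf("no grid point reaches isovalue %d", config@isovalue))
    qi <- which(qual)
    d2 <- colSums((t(fmap$grid$points[qi, , drop = FALSE]) -
                       config@seed_point)^2)
    if (min(d2) > 3^2)
        stop("no qualifying grid point within 3 A of the seed point")
    comp <- .floodFill26(qual, fmap$grid$dims, qi[which.min(d2)])
    list(component = comp, n_points = sum(comp), grid = fmap$grid)
}

#' Per-frame pocket volume series
#'
#' Volume of frame f is the number of its cavity points inside the selected
#' component times spacing^3.
#'
#' @param frames frames (as for [frequencyMap()]), or NULL to reuse
#'   `masks`.
#' @param component output of [selectPocket()].
#' @param config a [PocketConfig-class].
#' @param masks optional precomputed per-frame masks (from
#'   [frequencyMap()]).
#' @return numeric vector of per-frame volumes in Angstrom^3.
#' @export
volumeSeries <- function(frames, component, config, masks = NULL) {
    if (is.null(masks)) {
        frames <- .asFrameList(frames)
        masks <- lapply(frames, function(f)
            .cavityMask(coords(f), component$grid, config))
    }
    sp3 <- config@grid_spacing_A^3
    vapply(masks, function(m) sum(m & component$component) * sp3,
           numeric(1L))
}

#' Track a buried pocket across frames
#'
#' Convenience wrapper running [frequencyMap()], [selectPocket()] and
#' [volumeSeries()] on a shared grid.
#'
#' @param frames frames ([Frame-class] list, [Trajectory-class], or
#'   [subsampleFrames()] output).
#' @param config a [PocketConfig-class].
#' @return A [PocketResult-class].
#' @export
trackPocket <- function(frames, config) {
    frames <- .asFrameList(frames)
    fmap <- frequencyMap(frames, config)
    sel <- selectPocket(fmap, config)
    vols <- volumeSeries(NULL, sel, config, masks = fmap$masks)
    counts <- array(fmap$counts, dim = fmap$grid$dims)
    comp <- array(sel$component, dim = fmap$grid$dims)
    new("PocketResult",
        grid = fmap$grid[c("origin", "spacing", "dims")],
        counts = counts, component = comp, volumes_A3 = vols,
        point_counts = vapply(fmap$masks, function(m)
            sum(m & sel$component), integer(1L)),
        metadata = list(connectivity = 26L, seed_rescue_radius_A = 3,
                        isovalue = config@isovalue,
                        rule = "nearest-atom distance band + 14-ray buriedness",
                        heavy_atoms_only = TRUE))
}

#' Monte-Carlo buried-void volume oracle
#'
#' Estimates the volume satisfying the same cavity rule (distance band +
#' ray buriedness) by uniform sampling over the grid bounding box;
#' independent of the grid discretisation. Used to validate the grid
#' method.
#'
#' @param frame a [Frame-class].
#' @param config a [PocketConfig-class].
#' @param n_samples number of uniform samples, default 1e6.
#' @param seed RNG seed.
#' @return list with `volume_A3`, `fraction` and `n_samples`.
#' @export
monteCarloBuriedVolume <- function(frame, config, n_samples = 1e6,
                                   seed = 1L) {
    grid <- pocketGrid(frame, config)
    lo <- grid$origin
    hi <- grid$origin + (grid$dims - 1L) * grid$spacing
    pts <- .withSeed(seed,
        cbind(stats::runif(n_samples, lo[1L], hi[1L]),
              stats::runif(n_samples, lo[2L], hi[2L]),
              stats::runif(n_samples, lo[3L], hi[3L])))
    g2 <- list(points = pts, dims = grid$dims)
    mask <- .cavityMask(coords(frame), g2, config)
    frac <- mean(mask)
    list(volume_A3 = frac * prod(hi - lo), fraction = frac,
         n_samples = n_samples)
}
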