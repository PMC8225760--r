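#' @import methods
NULL

.validAtomTable <- function(df) {
    need <- c("name", "resid", "resname", "chain", "x", "y", "z")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L)
        return(paste0("atom table lacks column(s): ", paste(miss, collapse = ", ")))
    if (nrow(df) > 0L) {
        if (any(!nzchar(df$name))) return("atom names must be non-empty")
        if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
            return("atom coordinates must be finite")
    }
    TRUE
}

#' Single structure frame
#'
#' A `Frame` holds one model of a (multi-model) PDB structure: an ordered
#' atom table (PDB author numbering, coordinates in Angstrom) and a frame
#' time in picoseconds.
#'
#' @slot atoms data.frame with columns `name`, `resid`, `resname`, `chain`,
#'   `x`, `y`, `z`.
#' @slot time_ps non-negative frame time in picoseconds.
#' @export
setClass("Frame",
    representation(atoms = "data.frame", time_ps = "numeric"),
    prototype(atoms = data.frame(name = character(), resid = integer(),
                                 resname = character(), chain = character(),
                                 x = numeric(), y = numeric(), z = numeric(),
                                 stringsAsFactors = FALSE),
              time_ps = 0))

setValidity("Frame", function(object) {
    v <- .validAtomTable(object@atoms)
    if (!isTRUE(v)) return(v)
    if (length(object@time_ps) != 1L || !is.finite(object@time_ps) ||
        object@time_ps < 0)
        return("time_ps must be a single non-negative number")
    TRUE
})

#' Construct a Frame
#'
#' @param atoms atom data.frame (see [Frame-class]).
#' @param time_ps frame time in picoseconds.
#' @return A [Frame-class] object.
#' @export
Frame <- function(atoms, time_ps = 0) {
    atoms$resid <- as.integer(atoms$resid)
    new("Frame", atoms = atoms, time_ps = as.numeric(time_ps))
}

#' Trajectory of frames sharing one atom ordering
#'
#' Frames are stored compactly as an `n_atoms x 3 x n_frames` coordinate
#' array over a shared atom template; frame times are strictly increasing
#' and consistent with `frame_interval_ps`.
#'
#' @slot atoms template data.frame (`name`, `resid`, `resname`, `chain`).
#' @slot coords numeric array, `n_atoms x 3 x n_frames`.
#' @slot times_ps strictly increasing frame times (ps).
#' @slot replica_id integer replica label.
#' @slot frame_interval_ps spacing between consecutive frames (ps).
#' @export
setClass("Trajectory",
    representation(atoms = "data.frame", coords = "array",
                   times_ps = "numeric", replica_id = "integer",
                   frame_interval_ps = "numeric"))

setValidity("Trajectory", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        return("coords must be an n_atoms x 3 x n_frames array")
    if (d[1] != nrow(object@atoms))
        return("coords first dimension must match the atom template")
    nf <- d[3]
    if (length(object@times_ps) != nf)
        return("times_ps length must equal the number of frames")
    if (nf > 1L) {
        dt <- diff(object@times_ps)
        if (any(dt <= 0)) return("frame times must be strictly increasing")
        if (any(abs(dt - object@frame_interval_ps) >
                1e-6 * max(1, object@frame_interval_ps)))
            return("frame times inconsistent with frame_interval_ps")
    }
    if (object@frame_interval_ps <= 0)
        return("frame_interval_ps must be positive")
    TRUE
})

#' Construct a Trajectory from a list of Frames
#'
#' All frames must share the same atom ordering (name/resid/resname/chain).
#'
#' @param frames list of [Frame-class] objects.
#' @param replica_id integer replica label.
#' @param frame_interval_ps frame spacing in picoseconds; defaults to the
#'   spacing of the first two frame times (100 ps for a single frame).
#' @return A [Trajectory-class].
#' @export
Trajectory <- function(frames, replica_id = 1L, frame_interval_ps = NULL) {
    if (length(frames) == 0L) stop("empty trajectory")
    tmpl <- frames[[1L]]@atoms[, c("name", "resid", "resname", "chain")]
    na <- nrow(tmpl)
    coords <- array(NA_real_, dim = c(na, 3L, length(frames)))
    times <- numeric(length(frames))
    for (i in seq_along(frames)) {
        fr <- frames[[i]]
        if (nrow(fr@atoms) != na)
            stop(sprintf("frame %d has %d atoms, expected %d",
                         i, nrow(fr@atoms), na))
        coords[, , i] <- as.matrix(fr@atoms[, c("x", "y", "z")])
        times[i] <- fr@time_ps
    }
    if (is.null(frame_interval_ps))
        frame_interval_ps <- if (length(frames) > 1L) times[2] - times[1] else 100
    new("Trajectory", atoms = tmpl, coords = coords, times_ps = times,
        replica_id = as.integer(replica_id),
        frame_interval_ps = as.numeric(frame_interval_ps))
}

#' Ballesteros-Weinstein numbering scheme
#'
#' Anchors give, per helix, the alignment column carrying the x.50
#' reference; helix ranges give the inclusive alignment-column span of each
#' helix. Offsets from the anchor are counted in ungapped sequence space.
#'
#' @slot anchors data.frame with columns `helix`, `anchor_col`.
#' @slot helix_ranges data.frame with columns `helix`, `start_col`, `end_col`.
#' @export
setClass("BWScheme",
    representation(anchors = "data.frame", helix_ranges = "data.frame"))

setValidity("BWScheme", function(object) {
    a <- object@anchors; r <- object@helix_ranges
    if (!all(c("helix", "anchor_col") %in% names(a)))
        return("anchors needs columns helix, anchor_col")
    if (!all(c("helix", "start_col", "end_col") %in% names(r)))
        return("helix_ranges needs columns helix, start_col, end_col")
    if (!all(a$helix %in% r$helix)) return("every anchor needs a helix range")
    for (i in seq_len(nrow(a))) {
        rr <- r[r$helix == a$helix[i], ]
        if (a$anchor_col[i] < rr$start_col || a$anchor_col[i] > rr$end_col)
            return(sprintf("anchor column of helix %d outside its span", a$helix[i]))
    }
    o <- order(r$start_col)
    if (nrow(r) > 1L && any(r$start_col[o][-1] <= r$end_col[o][-nrow(r)]))
        return("helix spans overlap")
    TRUE
})

#' Construct a BWScheme
#'
#' @param anchors data.frame (`helix`, `anchor_col`): alignment column of the
#'   x.50 residue of each helix.
#' @param helix_ranges data.frame (`helix`, `start_col`, `end_col`).
#' @return A [BWScheme-class].
#' @export
BWScheme <- function(anchors, helix_ranges) {
    anchors$helix <- as.integer(anchors$helix)
    anchors$anchor_col <- as.integer(anchors$anchor_col)
    helix_ranges$helix <- as.integer(helix_ranges$helix)
    helix_ranges$start_col <- as.integer(helix_ranges$start_col)
    helix_ranges$end_col <- as.integer(helix_ranges$end_col)
    new("BWScheme", anchors = anchors, helix_ranges = helix_ranges)
}

#' Residue index to Ballesteros-Weinstein code map
#'
#' Bidirectional map between (ungapped) residue indices of one sequence and
#' BW codes such as "6.43".
#'
#' @slot seq_id identifier of the mapped sequence.
#' @slot table data.frame with columns `resid`, `bw`, `helix`, `pos`.
#' @export
setClass("ResidueMap",
    representation(seq_id = "character", table = "data.frame"))

setValidity("ResidueMap", function(object) {
    t <- object@table
    if (!all(c("resid", "bw", "helix", "pos") %in% names(t)))
        return("table needs columns resid, bw, helix, pos")
    if (anyDuplicated(t$resid)) return("duplicate residue indices")
    if (anyDuplicated(t$bw)) return("duplicate BW codes")
    TRUE
})

#' Per-replica kink angle time series
#'
#' @slot replica_id integer replica label.
#' @slot times_ns frame times in nanoseconds.
#' @slot angles_deg raw per-frame vertex angles (degrees).
#' @slot smoothed_deg moving-average smoothed angles, same length.
#' @export
setClass("KinkAngleSeries",
    representation(replica_id = "integer", times_ns = "numeric",
                   angles_deg = "numeric", smoothed_deg = "numeric"))

setValidity("KinkAngleSeries", function(object) {
    n <- length(object@times_ns)
    if (length(object@angles_deg) != n)
        return("angles_deg length mismatch")
    if (length(object@smoothed_deg) != n)
        return("smoothed_deg length mismatch")
    if (any(object@angles_deg <= 0 | object@angles_deg > 180))
        return("angles must lie in (0, 180]")
    TRUE
})

#' Replica-pooled angle summary
#'
#' @slot mean_deg frame-pooled mean over raw angles.
#' @slot sd_deg frame-pooled SD (denominator n-1; 0 when n = 1).
#' @slot n_frames total pooled frame count.
#' @slot replica_means named per-replica means.
#' @export
setClass("AngleSummary",
    representation(mean_deg = "numeric", sd_deg = "numeric",
                   n_frames = "integer", replica_means = "numeric"))

#' Buried-cavity grid configuration
#'
#' Distance-band plus ray-buriedness grid method: a grid point is a cavity
#' point when its nearest-heavy-atom distance lies in `[d_min_A, d_max_A]`
#' and at least `buriedness_min_hits` of 14 lattice ray directions hit an
#' atom within `ray_length_A` (an atom within `ray_hit_radius_A` of the
#' ray). This is not an MDpocket/fpocket reimplementation.
#'
#' @slot grid_spacing_A grid spacing (Angstrom).
#' @slot d_min_A clash-exclusion distance.
#' @slot d_max_A bulk-exclusion distance.
#' @slot buriedness_min_hits minimum number of the 14 rays that must hit.
#' @slot ray_length_A ray length.
#' @slot ray_hit_radius_A perpendicular atom-to-ray distance counting a hit.
#' @slot isovalue minimum per-point frame count in the frequency pocket.
#' @slot seed_point 3D point inside the cavity of interest.
#' @export
setClass("PocketConfig",
    representation(grid_spacing_A = "numeric", d_min_A = "numeric",
                   d_max_A = "numeric", buriedness_min_hits = "integer",
                   ray_length_A = "numeric", ray_hit_radius_A = "numeric",
                   isovalue = "integer", seed_point = "numeric"))

setValidity("PocketConfig", function(object) {
    if (object@grid_spacing_A <= 0) return("grid spacing must be positive")
    if (!(0 < object@d_min_A && object@d_min_A < object@d_max_A))
        return("need 0 < d_min < d_max")
    if (object@buriedness_min_hits < 1L || object@buriedness_min_hits > 14L)
        return("buriedness_min_hits must be in 1..14")
    if (object@isovalue < 1L) return("isovalue must be >= 1")
    if (length(object@seed_point) != 3L || any(!is.finite(object@seed_point)))
        return("seed_point must be a finite 3D point")
    TRUE
})

#' Construct a PocketConfig
#'
#' @param seed_point 3D point inside the cavity of interest.
#' @param grid_spacing_A grid spacing, default 0.8 Angstrom.
#' @param d_min_A clash-exclusion distance, default 2.6.
#' @param d_max_A bulk-exclusion distance, default 5.5.
#' @param buriedness_min_hits minimum ray hits (of 14), default 9.
#' @param ray_length_A ray length, default 8.
#' @param ray_hit_radius_A ray hit radius, default 2.
#' @param isovalue frequency-map threshold, default 3.
#' @return A [PocketConfig-class].
#' @export
PocketConfig <- function(seed_point, grid_spacing_A = 0.8, d_min_A = 2.6,
                         d_max_A = 5.5, buriedness_min_hits = 9L,
                         ray_length_A = 8, ray_hit_radius_A = 2,
                         isovalue = 3L) {
    new("PocketConfig", grid_spacing_A = grid_spacing_A, d_min_A = d_min_A,
        d_max_A = d_max_A, buriedness_min_hits = as.integer(buriedness_min_hits),
        ray_length_A = ray_length_A, ray_hit_radius_A = ray_hit_radius_A,
        isovalue = as.integer(isovalue), seed_point = as.numeric(seed_point))
}

#' Pocket tracking result
#'
#' @slot grid list describing the shared grid (origin, spacing, dims).
#' @slot counts integer array of per-point frame counts.
#' @slot component logical array marking the selected 26-connected component.
#' @slot volumes_A3 per-frame pocket volumes (Angstrom^3).
#' @slot point_counts per-frame cavity-point counts inside the component.
#' @slot metadata list (connectivity, seed rescue radius, distance rule).
#' @export
setClass("PocketResult",
    representation(grid = "list", counts = "array", component = "array",
                   volumes_A3 = "numeric", point_counts = "integer",
                   metadata = "list"))

#' Nonlinear / linear model fit result
#'
#' @slot model model name (e.g. "saturation_3p", "bell", "one_phase", "linear").
#' @slot coefficients named parameter estimates.
#' @slot se named asymptotic standard errors.
#' @slot ss residual sum of squares.
#' @slot df residual degrees of freedom (n - p).
#' @slot converged logical convergence flag.
#' @slot flags character vector of data-quality flags.
#' @export
setClass("FitResult",
    representation(model = "character", coefficients = "numeric",
                   se = "numeric", ss = "numeric", df = "integer",
                   converged = "logical", flags = "character"))

setValidity("FitResult", function(object) {
    if (object@ss < 0) return("residual SS must be non-negative")
    if (object@df <= 0L) return("residual degrees of freedom must be positive")
    TRUE
})

## show methods ------------------------------------------------------------

setMethod("show", "Frame", function(object) {
    cat(sprintf("Frame: %d atoms, t = %g ps\n", nrow(object@atoms),
                object@time_ps))
})

setMethod("show", "Trajectory", function(object) {
    d <- dim(object@coords)
    cat(sprintf("Trajectory (replica %d): %d frames x %d atoms, dt = %g ps\n",
                object@replica_id, d[3], d[1], object@frame_interval_ps))
})

setMethod("show", "ResidueMap", function(object) {
    cat(sprintf("ResidueMap for '%s': %d residues mapped (%s .. %s)\n",
                object@seq_id, nrow(object@table),
                object@table$bw[1], object@table$bw[nrow(object@table)]))
})

setMethod("show", "KinkAngleSeries", function(object) {
    cat(sprintf("KinkAngleSeries (replica %d): %d frames, mean %.2f deg\n",
                object@replica_id, length(object@angles_deg),
                mean(object@angles_deg)))
})

setMethod("show", "AngleSummary", function(object) {
    cat(sprintf("AngleSummary: %.2f +/- %.2f deg over %d frames (%d replicas)\n",
                object@mean_deg, object@sd_deg, object@n_frames,
                length(object@replica_means)))
})

setMethod("show", "PocketResult", function(object) {
    cat(sprintf(
        "PocketResult: component of %d grid points, %d frames, median volume %.0f A^3\n",
        sum(object@component), length(object@volumes_A3),
        stats::median(object@volumes_A3)))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s]%s\n", object@model,
                if (object@converged) "" else " (NOT converged)"))
    est <- object@coefficients
    se <- object@se[names(est)]
    for (nm in names(est))
        cat(sprintf("  %-10s %12.5g (SE %.4g)\n", nm, est[[nm]],
                    if (is.na(se[[nm]])) NA else se[[nm]]))
    cat(sprintf("  SS = %.5g on %d df\n", object@ss, object@df))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
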