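## Per-frame TM6 kink-angle statistics: the three-point vertex angle over
## backbone N atoms, 1-ns moving-average smoothing (display only) and
## replica-pooled summaries over the raw angles.

#' Interior angle at the vertex of three points
#'
#' Angle in degrees in [0, 180] between the rays `p2 -> p1` and
#' `p2 -> p3`. Invariant under rigid transforms and under swapping p1/p3.
#'
#' @param p1,p2,p3 numeric xyz points; `p2` is the vertex.
#' @return angle in degrees.
#' @export
threePointAngle <- function(p1, p2, p3) {
    v1 <- p1 - p2; v2 <- p3 - p2
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-12 || n2 < 1e-12) stop("coincident points")
    acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Per-frame TM6 kink angle series of a trajectory
#'
#' Measures, in every frame, the angle between the backbone nitrogen atoms
#' of the residues at BW positions `vertex - 0.04`, `vertex` and
#' `vertex + 0.04` (default 6.39 / 6.43 / 6.47) and attaches a
#' moving-average smoothed copy (display only; summaries use raw angles).
#'
#' @param traj a [Trajectory-class].
#' @param resmap a [ResidueMap-class] for the trajectory's sequence.
#' @param vertex_bw vertex BW code, default "6.43".
#' @param window_ns smoothing window, default 1 ns.
#' @return A [KinkAngleSeries-class].
#' @export
tm6KinkSeries <- function(traj, resmap, vertex_bw = "6.43", window_ns = 1) {
    hx <- sub("\\..*$", "", vertex_bw)
    vpos <- as.integer(sub("^.*\\.", "", vertex_bw))
    codes <- sprintf("%s.%d", hx, vpos + c(-4L, 0L, 4L))
    resids <- bwToResid(resmap, codes)
    at <- traj@atoms
    idx <- vapply(resids, function(r) {
        i <- which(at$resid == r & at$name == "N")
        if (length(i) != 1L)
            stop(sprintf("backbone N of residue %d (BW %s) missing or ambiguous",
                         r, codes[match(r, resids)]))
        i
    }, integer(1L))
    co <- traj@coords
    v1 <- co[idx[1L], , ] - co[idx[2L], , ]      # 3 x nframes
    v2 <- co[idx[3L], , ] - co[idx[2L], , ]
    if (nFrames(traj) == 1L) { v1 <- matrix(v1, 3L); v2 <- matrix(v2, 3L) }
    dot <- colSums(v1 * v2)
    ang <- acos(pmin(1, pmax(-1, dot / (sqrt(colSums(v1^2)) *
                                            sqrt(colSums(v2^2)))))) * 180 / pi
    sm <- movingAverage(ang, window_ns = window_ns,
                        interval_ns = traj@frame_interval_ps / 1000)
    new("KinkAngleSeries", replica_id = traj@replica_id,
        times_ns = traj@times_ps / 1000, angles_deg = ang, smoothed_deg = sm)
}

#' Centred moving-average smoothing
#'
#' Box filter of `w = round(window_ns / interval_ns)` frames, forced odd by
#' adding one when even; edges use the truncated available window so the
#' series length is preserved. Commutes with adding a constant and never
#' leaves the range of the input.
#'
#' @param x numeric series.
#' @param window_ns smoothing window in ns, default 1.
#' @param interval_ns frame interval in ns.
#' @return smoothed series of the same length.
#' @export
movingAverage <- function(x, window_ns = 1, interval_ns) {
    if (window_ns < interval_ns)
        stop("smoothing window is smaller than the frame interval")
    w <- round(window_ns / interval_ns)
    if (w %% 2 == 0) w <- w + 1L
    h <- (w - 1L) %/% 2L
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(1L, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Pool kink-angle series across replicas
#'
#' Frame-weighted mean and SD (denominator n - 1) over the pooled raw
#' (unsmoothed) angles of all replicas; per-replica means are reported so a
#' replica-mean-pooled reading stays recoverable.
#'
#' @param series list of [KinkAngleSeries-class] (or a single one).
#' @return An [AngleSummary-class].
#' @export
summarizeAngles <- function(series) {
    if (is(series, "KinkAngleSeries")) series <- list(series)
    if (length(series) == 0L) stop("no angle series supplied")
    pooled <- unlist(lapply(series, function(s) s@angles_deg))
    rm <- vapply(series, function(s) mean(s@angles_deg), numeric(1L))
    names(rm) <- vapply(series, function(s) paste0("replica_", s@replica_id),
                        character(1L))
    n <- length(pooled)
    new("AngleSummary", mean_deg = mean(pooled),
        sd_deg = if (n > 1L) stats::sd(pooled) else 0,
        n_frames = n, replica_means = rm)
}
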