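## Synthetic structural inputs: ideal/kinked alpha-helices, multi-replica
## trajectory ensembles with prescribed vertex-angle statistics, and a toy
## 7-helix bundle with a central channel. All generators are pure functions
## of (spec, seed).

#' Ideal helix geometry specification
#'
#' @slot n_res number of residues (>= 9 so a mid-helix vertex has +/-4
#'   flanking residues).
#' @slot rise_per_res axial rise per residue (Angstrom).
#' @slot twist_per_res twist per residue (degrees).
#' @slot atom_offsets per backbone atom name: `r` (radius, Angstrom),
#'   `phase_deg`, `dz` (axial shift, Angstrom).
#' @export
setClass("HelixSpec",
    representation(n_res = "integer", rise_per_res = "numeric",
                   twist_per_res = "numeric", atom_offsets = "data.frame"))

setValidity("HelixSpec", function(object) {
    if (object@n_res < 9L) return("n_res must be >= 9")
    if (!all(c("name", "r", "phase_deg", "dz") %in% names(object@atom_offsets)))
        return("atom_offsets needs columns name, r, phase_deg, dz")
    TRUE
})

.defaultAtomOffsets <- function() {
    data.frame(name = c("N", "CA", "C", "O"),
               r = c(1.46, 2.29, 1.67, 2.00),
               phase_deg = c(-26, 0, 21, 32),
               dz = c(-0.60, 0, 0.55, 1.05),
               stringsAsFactors = FALSE)
}

#' Construct a HelixSpec
#' @param n_res number of residues, default 31 (a TM6-length helix).
#' @param rise_per_res Angstrom per residue, default 1.5.
#' @param twist_per_res degrees per residue, default 100.
#' @param atom_offsets backbone atom placement table (default N/CA/C/O).
#' @return A [HelixSpec-class].
#' @export
helixSpec <- function(n_res = 31L, rise_per_res = 1.5, twist_per_res = 100,
                      atom_offsets = .defaultAtomOffsets()) {
    new("HelixSpec", n_res = as.integer(n_res), rise_per_res = rise_per_res,
        twist_per_res = twist_per_res, atom_offsets = atom_offsets)
}

#' Kink statistics specification
#'
#' Presets carry the per-receptor TM6 vertex-angle statistics observed in
#' four-replica simulations: fzd6 (158.5 +/- 4.5 deg, kinked) and smo
#' (168.4 +/- 4.2 deg, straight). The point mutants swap phenotypes
#' (fzd6_P643F straight-like, smo_F643P kinked-like); no printed angle
#' exists for them, so they reuse the opposite wild-type values.
#'
#' @slot vertex_bw BW code of the kink vertex (default "6.43").
#' @slot angle_mean_deg mean vertex angle (degrees).
#' @slot angle_sd_deg SD of the vertex angle.
#' @slot ar1_phi AR(1) autocorrelation of the per-frame angle, in [0, 1).
#' @export
setClass("KinkSpec",
    representation(vertex_bw = "character", angle_mean_deg = "numeric",
                   angle_sd_deg = "numeric", ar1_phi = "numeric"))

setValidity("KinkSpec", function(object) {
    if (!(object@angle_mean_deg > 0 && object@angle_mean_deg <= 180))
        return("angle_mean_deg must be in (0, 180]")
    if (object@angle_sd_deg < 0) return("angle_sd_deg must be >= 0")
    if (object@ar1_phi < 0 || object@ar1_phi >= 1)
        return("ar1_phi must be in [0, 1)")
    TRUE
})

#' Construct a KinkSpec
#' @param angle_mean_deg,angle_sd_deg vertex-angle statistics (degrees).
#' @param vertex_bw BW code of the vertex residue, default "6.43".
#' @param ar1_phi AR(1) autocorrelation, default 0 (iid frames).
#' @return A [KinkSpec-class].
#' @export
kinkSpec <- function(angle_mean_deg, angle_sd_deg, vertex_bw = "6.43",
                     ar1_phi = 0) {
    new("KinkSpec", vertex_bw = vertex_bw, angle_mean_deg = angle_mean_deg,
        angle_sd_deg = angle_sd_deg, ar1_phi = ar1_phi)
}

#' Named kink presets
#' @param name one of "fzd6", "smo", "fzd6_P643F", "smo_F643P".
#' @param ar1_phi AR(1) autocorrelation, default 0.
#' @return A [KinkSpec-class].
#' @export
kinkPreset <- function(name = c("fzd6", "smo", "fzd6_P643F", "smo_F643P"),
                       ar1_phi = 0) {
    name <- match.arg(name)
    p <- switch(name,
        fzd6 = c(158.5, 4.5),
        smo = c(168.4, 4.2),
        fzd6_P643F = c(168.4, 4.2),   # straight-like mutant
        smo_F643P = c(158.5, 4.5))    # kinked-like mutant
    kinkSpec(p[1], p[2], ar1_phi = ar1_phi)
}

#' Trajectory ensemble specification
#'
#' Defaults mirror a four-replica layout of 500 + 250 + 250 + 250 ns (the
#' first replica starts at t = 0 inclusive, continuation replicas start one
#' frame interval in) at 100 ps per frame.
#'
#' @slot replica_lengths_ns replica lengths in ns.
#' @slot frame_interval_ps frame spacing in ps.
#' @slot seed integer RNG seed.
#' @export
setClass("EnsembleSpec",
    representation(replica_lengths_ns = "numeric",
                   frame_interval_ps = "numeric", seed = "integer"))

setValidity("EnsembleSpec", function(object) {
    if (any(object@replica_lengths_ns <= 0))
        return("replica lengths must be positive")
    if (object@frame_interval_ps <= 0)
        return("frame_interval_ps must be positive")
    TRUE
})

#' Construct an EnsembleSpec
#' @param replica_lengths_ns default `c(500, 250, 250, 250)`.
#' @param frame_interval_ps default 100.
#' @param seed integer seed, default 1.
#' @return An [EnsembleSpec-class].
#' @export
ensembleSpec <- function(replica_lengths_ns = c(500, 250, 250, 250),
                         frame_interval_ps = 100, seed = 1L) {
    new("EnsembleSpec", replica_lengths_ns = replica_lengths_ns,
        frame_interval_ps = frame_interval_ps, seed = as.integer(seed))
}

#' Build an ideal circular alpha-helix about the z axis
#'
#' Backbone atom `a` of residue `j` sits at angle
#' `twist * (j - 1) + phase_a` on a circle of radius `r_a`, at height
#' `rise * (j - 1) + dz_a`. Deterministic.
#'
#' @param spec a [HelixSpec-class].
#' @param chain chain identifier, default "A".
#' @param start_resid first residue index, default 1.
#' @param resname residue name used for all residues, default "ALA".
#' @return A [Frame-class].
#' @export
buildIdealHelix <- function(spec, chain = "A", start_resid = 1L,
                            resname = "ALA") {
    off <- spec@atom_offsets
    j <- rep(seq_len(spec@n_res), each = nrow(off))
    k <- rep(seq_len(nrow(off)), times = spec@n_res)
    theta <- (spec@twist_per_res * (j - 1) + off$phase_deg[k]) * pi / 180
    at <- data.frame(
        name = off$name[k],
        resid = as.integer(start_resid + j - 1L),
        resname = resname,
        chain = chain,
        x = off$r[k] * cos(theta),
        y = off$r[k] * sin(theta),
        z = spec@rise_per_res * (j - 1) + off$dz[k],
        stringsAsFactors = FALSE)
    Frame(at, time_ps = 0)
}

## Precompute the kink machinery for one template frame: vertex pivot, the
## rotation axis (local pre-kink helix axis x vertex-N radial vector), the
## downstream atom rows, and a cheap measured-angle(beta) function that only
## rotates the single N atom entering the three-point measurement.
.kinkSetup <- function(frame, vertex_resid) {
    at <- frame@atoms
    getN <- function(r) {
        i <- which(at$resid == r & at$name == "N")
        if (length(i) != 1L)
            stop(sprintf("vertex too close to termini: need N of residue %d", r))
        c(at$x[i], at$y[i], at$z[i])
    }
    Nm4 <- getN(vertex_resid - 4L)
    Nv <- getN(vertex_resid)
    Np4 <- getN(vertex_resid + 4L)
    ## local pre-kink helix axis: principal direction of the N atoms of
    ## residues vertex-4 .. vertex
    pre <- which(at$resid >= vertex_resid - 4L & at$resid <= vertex_resid &
                     at$name == "N")
    P <- as.matrix(at[pre, c("x", "y", "z")])
    Pc <- sweep(P, 2L, colMeans(P))
    a <- svd(Pc, nu = 0L, nv = 3L)$v[, 1L]
    if (sum(a * (Nv - Nm4)) < 0) a <- -a
    radial <- (Nv - colMeans(P))
    radial <- radial - sum(radial * a) * a
    if (sqrt(sum(radial^2)) < 1e-8) {
        radial <- .cross3(a, c(1, 0, 0))
        if (sqrt(sum(radial^2)) < 1e-8) radial <- .cross3(a, c(0, 1, 0))
    }
    u <- .cross3(a, radial / sqrt(sum(radial^2)))
    u <- u / sqrt(sum(u^2))
    down <- which(at$resid > vertex_resid)
    measured <- function(beta_deg) {
        p <- .rotate(matrix(Np4 - Nv, 1L), u, beta_deg * pi / 180)[1L, ] + Nv
        threePointAngle(Nm4, Nv, p)
    }
    ## orient the axis so that positive beta closes (decreases) the angle
    if (measured(5) > measured(0)) {
        u <- -u
        measured <- function(beta_deg) {
            p <- .rotate(matrix(Np4 - Nv, 1L), u, beta_deg * pi / 180)[1L, ] + Nv
            threePointAngle(Nm4, Nv, p)
        }
    }
    list(Nv = Nv, u = u, down = down, measured = measured,
         base = measured(0))
}

## Solve the rotation magnitude whose measured three-point angle equals
## `target` within `tol` degrees; bisection over the bracket found by a
## 1-degree outward scan from beta = 0 (bracket [-90, 90]).
.solveKinkBeta <- function(setup, target, tol = 0.01) {
    f <- function(b) setup$measured(b) - target
    f0 <- f(0)
    if (abs(f0) <= tol) return(0)
    dir <- if (target < setup$base) 1 else -1
    prev <- 0
    for (b in seq(1, 90, by = 1) * dir) {
        if (sign(f(b)) != sign(f0)) {
            lo <- min(prev, b); hi <- max(prev, b)
            r <- stats::uniroot(f, c(lo, hi), tol = 1e-7)
            if (abs(setup$measured(r$root) - target) > tol)
                stop(sprintf("kink solver failed to reach %.3f deg", target))
            return(r$root)
        }
        prev <- b
    }
    stop(sprintf(
        "target angle %.2f deg unreachable by rotation at the vertex (base %.2f deg)",
        target, setup$base))
}

#' Kink a helix to a prescribed three-point vertex angle
#'
#' Residues downstream of the vertex are rigidly rotated about an axis
#' through the vertex backbone N (axis = local pre-kink helix axis x
#' vertex-N radial vector); the rotation magnitude is solved numerically so
#' that the three-point angle over the backbone N atoms of residues
#' (vertex-4, vertex, vertex+4) equals `target_angle_deg` within 0.01
#' degrees. Atoms at or upstream of the vertex are untouched (exact
#' equality). Unreachable targets raise an error.
#'
#' @param frame a [Frame-class] (typically from [buildIdealHelix()]).
#' @param vertex_resid residue index of the kink vertex.
#' @param target_angle_deg target angle in (90, 180].
#' @return A kinked [Frame-class].
#' @export
applyKink <- function(frame, vertex_resid, target_angle_deg) {
    if (!(target_angle_deg > 90 && target_angle_deg <= 180))
        stop("target angle must lie in (90, 180]")
    setup <- .kinkSetup(frame, vertex_resid)
    beta <- .solveKinkBeta(setup, target_angle_deg)
    .applyKinkBeta(frame, setup, beta)
}

.applyKinkBeta <- function(frame, setup, beta_deg) {
    if (beta_deg == 0) return(frame)
    at <- frame@atoms
    m <- as.matrix(at[setup$down, c("x", "y", "z")])
    m <- sweep(m, 2L, setup$Nv)
    m <- .rotate(m, setup$u, beta_deg * pi / 180)
    m <- sweep(m, 2L, setup$Nv, "+")
    at[setup$down, c("x", "y", "z")] <- m
    new("Frame", atoms = at, time_ps = frame@time_ps)
}

#' TM6-style residue map for a synthetic helix
#'
#' Maps residue indices of a single synthetic helix to helix-6 BW codes
#' with the vertex residue (middle of the helix) at `vertex_bw`.
#'
#' @param n_res helix length in residues.
#' @param vertex_bw BW code of the middle residue, default "6.43".
#' @param seq_id label, default "synthetic".
#' @return A [ResidueMap-class].
#' @export
tm6ResidueMap <- function(n_res, vertex_bw = "6.43", seq_id = "synthetic") {
    hx <- as.integer(sub("\\..*$", "", vertex_bw))
    vpos <- as.integer(sub("^.*\\.", "", vertex_bw))
    vres <- (as.integer(n_res) + 1L) %/% 2L
    pos <- vpos + seq_len(n_res) - vres
    tab <- data.frame(resid = seq_len(as.integer(n_res)),
                      bw = sprintf("%d.%d", hx, pos),
                      helix = hx, pos = pos, stringsAsFactors = FALSE)
    new("ResidueMap", seq_id = seq_id, table = tab)
}

## stationary AR(1) draws: a_0 ~ N(mu, sd); innovations scaled by
## sqrt(1 - phi^2) keep the marginal N(mu, sd^2) for every phi in [0, 1)
.ar1Draws <- function(n, mu, sd, phi) {
    a <- numeric(n)
    a[1L] <- stats::rnorm(1L, mu, sd)
    if (n > 1L) {
        eps <- stats::rnorm(n - 1L, 0, sd * sqrt(1 - phi^2))
        for (t in 2:n) a[t] <- mu + phi * (a[t - 1L] - mu) + eps[t - 1L]
    }
    a
}

#' Generate a multi-replica kinked-helix trajectory ensemble
#'
#' Per frame t the latent vertex angle follows a stationary AR(1):
#' `a_t = mu + phi * (a_{t-1} - mu) + eps_t`,
#' `eps_t ~ N(0, sd * sqrt(1 - phi^2))`, `a_0 ~ N(mu, sd)`. Frame
#' coordinates are built by rotating the template helix downstream of the
#' vertex so the measured three-point N angle equals the drawn value (draws
#' above 180 degrees are reflected, `a -> 360 - a`, and draws outside the
#' geometrically reachable branch are clamped to it, when realised as
#' geometry; the AR(1) state keeps the latent value). The first replica
#' starts at t = 0; continuation replicas start at one frame interval.
#' Reproducible under the ensemble seed.
#'
#' @param helix a [HelixSpec-class].
#' @param kink a [KinkSpec-class].
#' @param ens an [EnsembleSpec-class].
#' @return list of [Trajectory-class], one per replica; each carries the
#'   realised per-frame target angles as attribute `"target_angles_deg"`.
#' @export
generateTrajectory <- function(helix, kink, ens) {
    tmpl <- buildIdealHelix(helix)
    vres <- (helix@n_res + 1L) %/% 2L
    setup <- .kinkSetup(tmpl, vres)
    mu <- kink@angle_mean_deg; sd <- kink@angle_sd_deg; phi <- kink@ar1_phi

    dt <- ens@frame_interval_ps
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(ens@seed)

    ## inverse of measured(beta), tabulated once; restrict to the maximal
    ## monotone (decreasing in beta) branch containing beta = 0 -- rotating
    ## past the straightest reachable geometry folds the angle back down
    grid_b <- seq(-90, 90, by = 0.5)
    grid_a <- vapply(grid_b, setup$measured, numeric(1L))
    i0 <- which(grid_b == 0)
    lo_i <- i0
    while (lo_i > 1L && grid_a[lo_i - 1L] > grid_a[lo_i]) lo_i <- lo_i - 1L
    hi_i <- i0
    while (hi_i < length(grid_a) && grid_a[hi_i + 1L] < grid_a[hi_i])
        hi_i <- hi_i + 1L
    grid_b <- grid_b[lo_i:hi_i]
    grid_a <- grid_a[lo_i:hi_i]
    reach_max <- grid_a[1L] - 0.05
    reach_min <- grid_a[length(grid_a)] + 0.05
    invert <- function(target) {
        i <- findInterval(-target, -grid_a)   # grid_a is decreasing
        if (i < 1L || i >= length(grid_b))
            stop(sprintf("target angle %.2f deg unreachable", target))
        lo <- grid_b[i]; hi <- grid_b[i + 1L]
        for (k in 1:20) {
            mid <- (lo + hi) / 2
            if (setup$measured(mid) > target) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
    }

    n_atoms <- nrow(tmpl@atoms)
    base_xyz <- as.matrix(tmpl@atoms[, c("x", "y", "z")])
    down <- setup$down
    rel_down <- sweep(base_xyz[down, , drop = FALSE], 2L, setup$Nv)

    out <- vector("list", length(ens@replica_lengths_ns))
    for (r in seq_along(ens@replica_lengths_ns)) {
        len_ps <- ens@replica_lengths_ns[r] * 1000
        nf <- as.integer(round(len_ps / dt)) + if (r == 1L) 1L else 0L
        t0 <- if (r == 1L) 0 else dt
        times <- t0 + dt * (seq_len(nf) - 1L)
        a <- .ar1Draws(nf, mu, sd, phi)
        realised <- ifelse(a > 180, 360 - a, a)
        realised <- pmin(pmax(realised, reach_min), reach_max)
        co <- array(rep(base_xyz, nf), dim = c(n_atoms, 3L, nf))
        for (t in seq_len(nf)) {
            beta <- invert(realised[t])
            m <- .rotate(rel_down, setup$u, beta * pi / 180)
            co[down, , t] <- sweep(m, 2L, setup$Nv, "+")
        }
        tr <- new("Trajectory", atoms = tmpl@atoms[, c("name", "resid",
                                                       "resname", "chain")],
                  coords = co, times_ps = times, replica_id = r,
                  frame_interval_ps = dt)
        attr(tr, "target_angles_deg") <- realised
        out[[r]] <- tr
    }
    out
}

#' Subsample ensemble frames on a coarse time grid
#'
#' Selects frames whose times fall on multiples of `interval_ns`. The first
#' replica contributes t = 0, D, 2D, ... (start inclusive); continuation
#' replicas, which begin at one frame interval, contribute t = D, ..., T
#' (start exclusive). The count therefore equals
#' `sum(floor(T_i / D)) + 1`. The subsampling interval must be a multiple
#' of the frame interval and must divide every replica length.
#'
#' @param trajs list of [Trajectory-class] (or a single Trajectory).
#' @param interval_ns subsampling interval in ns (default 10).
#' @return list with `frames` (list of [Frame-class]), `n` (count) and
#'   `times_ns`.
#' @export
subsampleFrames <- function(trajs, interval_ns = 10) {
    if (is(trajs, "Trajectory")) trajs <- list(trajs)
    D_ps <- interval_ns * 1000
    frames <- list(); times <- numeric(0)
    for (tr in trajs) {
        dt <- tr@frame_interval_ps
        if (abs(D_ps / dt - round(D_ps / dt)) > 1e-6)
            stop(sprintf(
                "subsampling interval %g ns is not a multiple of the frame interval %g ps",
                interval_ns, dt))
        len_ps <- max(tr@times_ps)
        if (abs(len_ps / D_ps - round(len_ps / D_ps)) > 1e-6)
            stop(sprintf(
                "subsampling interval %g ns does not divide the replica length %g ns",
                interval_ns, len_ps / 1000))
        sel <- which(abs(tr@times_ps / D_ps -
                             round(tr@times_ps / D_ps)) < 1e-9)
        for (i in sel) frames[[length(frames) + 1L]] <- getFrame(tr, i)
        times <- c(times, tr@times_ps[sel] / 1000)
    }
    list(frames = frames, n = length(frames), times_ns = times)
}

#' Build a toy 7-helix bundle with a central channel
#'
#' Places `n_helices` copies of an ideal helix with axes parallel to z on a
#' circle of radius `ring_radius`, enclosing a buried central channel used
#' to exercise the pocket-volume machinery. Deterministic. The default
#' radius is chosen so the channel lumen lies inside the default cavity
#' detection band (a much wider ring leaves the channel axis farther from
#' every atom than the bulk-exclusion cutoff, i.e. undetectable by
#' construction).
#'
#' @param n_helices number of helices, default 7.
#' @param ring_radius circle radius (Angstrom), default 7.5.
#' @param helix_spec a [HelixSpec-class], default 20 residues.
#' @return list with `frame` (a [Frame-class]) and `seed_point` (a point
#'   inside the channel).
#' @export
buildToyBundle <- function(n_helices = 7L, ring_radius = 7.5,
                           helix_spec = helixSpec(20L)) {
    frames <- list()
    rows <- list()
    for (k in seq_len(n_helices)) {
        h <- buildIdealHelix(helix_spec, chain = LETTERS[k])
        ang <- 2 * pi * (k - 1) / n_helices
        at <- h@atoms
        at$x <- at$x + ring_radius * cos(ang)
        at$y <- at$y + ring_radius * sin(ang)
        rows[[k]] <- at
    }
    at <- do.call(rbind, rows)
    z_mid <- mean(range(at$z))
    ## seed inside the channel, offset from the exact axis so it sits in
    ## the detectable distance band of the channel wall (the axis of a wide
    ## channel is farther from every atom than the bulk-exclusion cutoff)
    r_wall <- ring_radius - max(helix_spec@atom_offsets$r)
    seed <- c(max(0, r_wall - 4), 0, z_mid)
    list(frame = Frame(at, time_ps = 0), seed_point = seed)
}
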