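## Multi-model PDB input/output and rigid-body geometry.
##
## Fixed-column PDB (v3.3 ATOM records); tolerant reader, strict writer.
## Coordinates are Angstrom, times ps, angles degrees throughout the package.

#' Read a multi-model PDB file as a Trajectory
#'
#' One `Frame` per `MODEL`/`ENDMDL` block; a file without MODEL records
#' yields a single-frame trajectory. Atom order is preserved as written.
#' `HETATM` records are skipped unless `include_het = TRUE`; occupancy and
#' B-factor columns are ignored. Residue indices keep the file's author
#' numbering.
#'
#' @param path PDB file path.
#' @param include_het also read HETATM records (default FALSE).
#' @param replica_id replica label for the returned trajectory.
#' @param frame_interval_ps assumed frame spacing in ps (PDB stores no
#'   times), default 100.
#' @param time0_ps time of the first frame, default 0.
#' @return A [Trajectory-class].
#' @export
readMultimodelPDB <- function(path, include_het = FALSE, replica_id = 1L,
                              frame_interval_ps = 100, time0_ps = 0) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1L, 6L)
    keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
    model_starts <- grep("^MODEL", lines)

    parse_block <- function(lns) {
        data.frame(
            name = trimws(substr(lns, 13L, 16L)),
            resid = as.integer(trimws(substr(lns, 23L, 26L))),
            resname = trimws(substr(lns, 18L, 20L)),
            chain = substr(lns, 22L, 22L),
            x = as.numeric(substr(lns, 31L, 38L)),
            y = as.numeric(substr(lns, 39L, 46L)),
            z = as.numeric(substr(lns, 47L, 54L)),
            stringsAsFactors = FALSE)
    }

    if (length(model_starts) == 0L) {
        at <- parse_block(lines[keep])
        if (nrow(at) == 0L) stop("no atoms found in ", path)
        return(Trajectory(list(Frame(at, time_ps = time0_ps)),
                          replica_id = replica_id,
                          frame_interval_ps = frame_interval_ps))
    }

    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
        stop("malformed MODEL/ENDMDL records in ", path)
    frames <- vector("list", length(model_starts))
    counts <- integer(length(model_starts))
    for (m in seq_along(model_starts)) {
        sel <- keep & seq_along(lines) > model_starts[m] &
            seq_along(lines) < ends[m]
        at <- parse_block(lines[sel])
        counts[m] <- nrow(at)
        frames[[m]] <- Frame(at, time_ps = time0_ps +
                                 (m - 1L) * frame_interval_ps)
    }
    if (length(unique(counts)) != 1L) {
        bad <- which(counts != counts[1L])[1L]
        stop(sprintf(
            "inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
            bad, counts[bad], counts[1L]))
    }
    Trajectory(frames, replica_id = replica_id,
               frame_interval_ps = frame_interval_ps)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Strict fixed-column writer. Single-frame trajectories still emit
#' MODEL/ENDMDL records for uniformity; occupancy/B-factor are written as
#' 1.00/0.00.
#'
#' @param traj a [Trajectory-class] or a single [Frame-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMultimodelPDB <- function(traj, path) {
    if (is(traj, "Frame")) traj <- Trajectory(list(traj))
    nf <- nFrames(traj)
    if (nf == 0L) stop("empty trajectory")
    at <- traj@atoms
    ## PDB atom-name convention: names < 4 chars start in column 14
    anm <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1L, 4L),
                  paste0(" ", formatC(at$name, width = -3)))
    elem <- substr(trimws(at$name), 1L, 1L)
    out <- character(0)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (m in seq_len(nf)) {
        writeLines(sprintf("MODEL     %4d", m), con)
        xyz <- traj@coords[, , m, drop = FALSE]
        writeLines(sprintf(
            "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(at)) %% 100000L, anm, substr(at$resname, 1L, 3L),
            at$chain, at$resid, xyz[, 1L, 1L], xyz[, 2L, 1L], xyz[, 3L, 1L],
            elem), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Select a single atom from a frame
#'
#' @param frame a [Frame-class].
#' @param resid author residue index.
#' @param atom_name atom name (e.g. "N", "CA").
#' @param chain optional chain filter.
#' @return list with `name`, `resid`, `resname`, `chain`, `position`
#'   (numeric xyz) and `index` (row in the atom table).
#' @export
selectAtom <- function(frame, resid, atom_name, chain = NULL) {
    at <- frame@atoms
    hit <- at$resid == resid & at$name == atom_name
    if (!is.null(chain)) hit <- hit & at$chain == chain
    idx <- which(hit)
    if (length(idx) == 0L)
        stop(sprintf("atom not found: residue %d atom '%s'%s", resid,
                     atom_name,
                     if (is.null(chain)) "" else paste0(" chain ", chain)))
    if (length(idx) > 1L)
        stop(sprintf(
            "ambiguous selection: %d atoms match residue %d atom '%s' (add a chain filter)",
            length(idx), resid, atom_name))
    list(name = at$name[idx], resid = at$resid[idx],
         resname = at$resname[idx], chain = at$chain[idx],
         position = c(at$x[idx], at$y[idx], at$z[idx]), index = idx)
}

#' Minimal RMSD after optimal rigid-body superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` over the selected atoms (rotation +
#' translation, SVD with determinant correction) and returns the residual
#' RMSD in Angstrom. Invariant under any rigid transform of either frame.
#'
#' @param reference,mobile [Frame-class] objects with matching selections.
#' @param selection character vector of atom names to use (default
#'   backbone `c("N","CA","C","O")`); `NULL` uses all atoms.
#' @return non-negative RMSD in Angstrom.
#' @export
kabschRMSD <- function(reference, mobile, selection = c("N", "CA", "C", "O")) {
    pick <- function(fr) {
        m <- coords(fr)
        if (!is.null(selection)) m <- m[fr@atoms$name %in% selection, , drop = FALSE]
        m
    }
    A <- pick(reference); B <- pick(mobile)
    if (nrow(A) != nrow(B))
        stop(sprintf("selected atom counts differ: %d vs %d", nrow(A), nrow(B)))
    if (nrow(A) < 3L) stop("need at least 3 selected atoms")
    A <- sweep(A, 2L, colMeans(A))
    B <- sweep(B, 2L, colMeans(B))
    s <- svd(crossprod(B, A))            # 3x3
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    Brot <- B %*% t(R)
    sqrt(mean(rowSums((A - Brot)^2)))
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention; result in degrees in (-180, 180]. Errors when
#' three consecutive points are (near) collinear.
#'
#' @param p1,p2,p3,p4 numeric xyz points.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
        stop("degenerate geometry: three consecutive points are collinear")
    ang <- atan2(sum(.cross3(n1, n2) * b2 / sqrt(sum(b2^2))),
                 sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}

.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

## Rodrigues rotation of an n x 3 matrix about unit axis u through origin
.rotate <- function(m, u, theta_rad) {
    u <- u / sqrt(sum(u^2))
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                3L, 3L, byrow = TRUE)
    R <- diag(3) + sin(theta_rad) * K + (1 - cos(theta_rad)) * (K %*% K)
    m %*% t(R)
}
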