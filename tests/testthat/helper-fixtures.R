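# Fixtures are built in code; no binary data.

# toy class F alignment: 10 FZD-like rows with P and one SMO-like row with
# F at the column 2 residues upstream of the anchor; column 5 anchors 6.50,
# each row carries one internal gap (different columns in fzd vs smo rows)
toyAlignmentFasta <- function(path = tempfile(fileext = ".fasta")) {
    seqs <- c(sprintf(">fzd%d\nAWPLE-YHMPK", 1:10), ">smo\nAWFLEC-HMPK")
    writeLines(seqs, path)
    path
}

# equivalent FASTA/Clustal pair for the format cross-check
alignmentTwinFiles <- function() {
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">seq1", "APPLE-PIE", ">seq2", "APFLEXPIE"), fa)
    cl <- tempfile(fileext = ".aln")
    writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
                 "seq1            APPLE-PIE",
                 "seq2            APFLEXPIE"), cl)
    list(fasta = fa, clustal = cl)
}

toyScheme <- function(anchor_col = 5L, start = 1L, end = 9L, helix = 6L) {
    BWScheme(data.frame(helix = helix, anchor_col = anchor_col),
             data.frame(helix = helix, start_col = start, end_col = end))
}

# frame with an ARG (6.32-like), TRP with backbone O (7.55-like), two TYR
# with OH (6.40/2.51-like) and pseudo-centroid ring dummies, at controlled
# distances; used by the interaction-network tests
networkFixtureFrame <- function(d_switch = 3.0, d_tyr = 3.9,
                                d_ring = c(7.0, 7.0, 7.0)) {
    atoms <- rbind(
        data.frame(name = "NH1", resid = 1L, resname = "ARG", chain = "A",
                   x = 0, y = 0, z = 0),
        data.frame(name = "NE", resid = 1L, resname = "ARG", chain = "A",
                   x = 0, y = 0, z = 10),
        data.frame(name = "O", resid = 2L, resname = "TRP", chain = "A",
                   x = d_switch, y = 0, z = 0),
        data.frame(name = "OH", resid = 3L, resname = "TYR", chain = "A",
                   x = 0, y = 10, z = 0),
        data.frame(name = "OH", resid = 4L, resname = "TYR", chain = "A",
                   x = d_tyr, y = 10, z = 0),
        # pseudo-centroid ring atoms for network members
        data.frame(name = "CEN", resid = 5L, resname = "PSD", chain = "A",
                   x = 0, y = -10, z = 0),
        data.frame(name = "CEN", resid = 6L, resname = "PSD", chain = "A",
                   x = d_ring[1L], y = -10, z = 0),
        data.frame(name = "CEN", resid = 7L, resname = "PSD", chain = "A",
                   x = 0, y = -10, z = d_ring[2L]),
        # non-aromatic (alanine-like) member for drop-with-warning checks
        data.frame(name = "CB", resid = 8L, resname = "ALA", chain = "A",
                   x = 2, y = -10, z = 0))
    Frame(atoms)
}

# residue map used with networkFixtureFrame
networkFixtureMap <- function() {
    tab <- data.frame(resid = 1:8,
                      bw = c("6.32", "7.55", "6.40", "2.51",
                             "3.43", "6.36", "6.46", "6.45"),
                      helix = c(6L, 7L, 6L, 2L, 3L, 6L, 6L, 6L),
                      pos = c(32L, 55L, 40L, 51L, 43L, 36L, 46L, 45L))
    new("ResidueMap", seq_id = "fixture", table = tab)
}

# independent pure-R evaluation of the cavity rule (distance band + ray
# buriedness) by brute-force double loops; oracle for the compiled kernel
bruteForceCavityRule <- function(pts, atoms, config) {
    dirs <- ClassFKink:::.latticeDirections()
    L <- config@ray_length_A
    r2 <- config@ray_hit_radius_A^2
    apply(pts, 1L, function(p) {
        d2 <- apply(atoms, 1L, function(a) sum((a - p)^2))
        if (min(d2) < config@d_min_A^2 || min(d2) > config@d_max_A^2)
            return(FALSE)
        hits <- 0L
        for (d in seq_len(nrow(dirs))) {
            u <- dirs[d, ]
            hit <- FALSE
            for (j in seq_len(nrow(atoms))) {
                rel <- atoms[j, ] - p
                t <- sum(rel * u)
                if (t > 1e-9 && t <= L && sum(rel^2) - t^2 <= r2) {
                    hit <- TRUE; break
                }
            }
            hits <- hits + hit
        }
        hits >= config@buriedness_min_hits
    })
}

# brute-force minimal RMSD over rigid motions: centre both point sets and
# minimise over rotations (Euler angles, multi-start Nelder-Mead)
bruteForceMinRMSD <- function(A, B) {
    A <- sweep(A, 2L, colMeans(A))
    B <- sweep(B, 2L, colMeans(B))
    rotmat <- function(ang) {
        cx <- cos(ang[1L]); sx <- sin(ang[1L])
        cy <- cos(ang[2L]); sy <- sin(ang[2L])
        cz <- cos(ang[3L]); sz <- sin(ang[3L])
        Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
        Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
        Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
        Rz %*% Ry %*% Rx
    }
    obj <- function(ang) sqrt(mean(rowSums((A - B %*% t(rotmat(ang)))^2)))
    grid <- expand.grid(a = seq(0, 2 * pi, length.out = 5L)[-5L],
                        b = seq(0, pi, length.out = 3L),
                        c = seq(0, 2 * pi, length.out = 5L)[-5L])
    best <- Inf
    for (i in seq_len(nrow(grid))) {
        o <- stats::optim(as.numeric(grid[i, ]), obj,
                          control = list(reltol = 1e-12, maxit = 2000))
        if (o$value < best) best <- o$value
    }
    best
}

# rigid transform helper: random rotation + translation applied to a frame
randomRigidTransform <- function(frame) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
        1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
        2 * (q[2] * q[4] + q[1] * q[3]),
        2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[1] * q[2]),
        2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
        1 - 2 * (q[2]^2 + q[3]^2)), 3L, 3L, byrow = TRUE)
    tr <- stats::rnorm(3, 0, 10)
    at <- frame@atoms
    xyz <- coords(frame) %*% t(R)
    at$x <- xyz[, 1L] + tr[1L]
    at$y <- xyz[, 2L] + tr[2L]
    at$z <- xyz[, 3L] + tr[3L]
    list(frame = Frame(at, frame@time_ps), R = R, t = tr)
}

smallEnsemble <- function(preset = "fzd6", seed = 1L,
                          lengths = c(20, 10), n_res = 15L) {
    generateTrajectory(helixSpec(n_res), kinkPreset(preset),
                       ensembleSpec(replica_lengths_ns = lengths,
                                    seed = seed))
}
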