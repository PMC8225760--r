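## Per-frame state classification of the class F molecular switch
## (R6.32 side-chain N to W7.55 backbone O hydrogen bond), the Y6.40-Y2.51
## hydroxyl pair, and the aromatic pi-pi network over ring centroids.
## All criteria are geometric distances with inclusive cutoffs.

#' Contact classification criteria
#'
#' @slot hbond_cutoff_A hydrogen-bond distance cutoff (inclusive), default 4.
#' @slot pipi_cutoff_A centroid-centroid pi-pi cutoff (inclusive),
#'   default 7.5.
#' @slot ring_atom_sets named list: residue type -> aromatic ring atom
#'   names. Defaults cover PHE/TYR (6-ring), TRP (all 9 indole ring atoms,
#'   single centroid), HIS (5-ring) and a "PSD" pseudo-residue whose single
#'   "CEN" dummy atom stands for a ring centroid in synthetic fixtures.
#' @export
setClass("ContactCriteria",
    representation(hbond_cutoff_A = "numeric", pipi_cutoff_A = "numeric",
                   ring_atom_sets = "list"))

setValidity("ContactCriteria", function(object) {
    if (object@hbond_cutoff_A <= 0 || object@pipi_cutoff_A <= 0)
        return("cutoffs must be positive")
    TRUE
})

.defaultRingSets <- function() {
    six <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    list(PHE = six, TYR = six,
         TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
         HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
         PSD = "CEN")
}

#' Construct ContactCriteria
#' @param hbond_cutoff_A hydrogen-bond cutoff, default 4 Angstrom.
#' @param pipi_cutoff_A aromatic pi-pi cutoff, default 7.5 Angstrom.
#' @param ring_atom_sets ring definitions, see [ContactCriteria-class].
#' @return A [ContactCriteria-class].
#' @export
contactCriteria <- function(hbond_cutoff_A = 4, pipi_cutoff_A = 7.5,
                            ring_atom_sets = .defaultRingSets()) {
    new("ContactCriteria", hbond_cutoff_A = hbond_cutoff_A,
        pipi_cutoff_A = pipi_cutoff_A, ring_atom_sets = ring_atom_sets)
}

.sideChainN <- function(resname) {
    switch(resname,
           ARG = c("NE", "NH1", "NH2"),
           LYS = "NZ",
           stop("residue 6.32 must be Arg or Lys, got ", resname))
}

#' Molecular-switch state of one frame
#'
#' Minimum distance between the side-chain nitrogen atoms of the residue at
#' BW 6.32 (NE/NH1/NH2 for Arg, NZ for Lys) and the backbone oxygen of the
#' residue at BW 7.55; the switch is "closed" iff that distance is within
#' the hydrogen-bond cutoff (inclusive), "open" otherwise.
#'
#' @param frame a [Frame-class].
#' @param resmap a [ResidueMap-class] covering 6.32 and 7.55.
#' @param criteria a [ContactCriteria-class].
#' @return list with `state` ("open"/"closed") and `min_distance_A`.
#' @export
switchState <- function(frame, resmap, criteria = contactCriteria()) {
    r632 <- bwToResid(resmap, "6.32")
    r755 <- bwToResid(resmap, "7.55")
    at <- frame@atoms
    resname <- at$resname[match(r632, at$resid)]
    nn <- .sideChainN(resname)
    ni <- which(at$resid == r632 & at$name %in% nn)
    if (length(ni) == 0L)
        stop("no side-chain nitrogen atoms found for residue 6.32")
    oi <- which(at$resid == r755 & at$name == "O")
    if (length(oi) != 1L)
        stop("backbone O of residue 7.55 missing or ambiguous")
    d <- sqrt((at$x[ni] - at$x[oi])^2 + (at$y[ni] - at$y[oi])^2 +
                  (at$z[ni] - at$z[oi])^2)
    dmin <- min(d)
    list(state = if (dmin <= criteria@hbond_cutoff_A) "closed" else "open",
         min_distance_A = dmin)
}

#' Tyrosine-pair hydrogen bond (Y6.40 - Y2.51)
#'
#' Distance between the hydroxyl oxygens (OH) of the residues at BW 6.40
#' and 2.51; bonded iff within the hydrogen-bond cutoff (inclusive).
#'
#' @param frame a [Frame-class].
#' @param resmap a [ResidueMap-class] covering 6.40 and 2.51.
#' @param criteria a [ContactCriteria-class].
#' @return list with `bonded` (logical) and `distance_A`.
#' @export
tyrosinePairBond <- function(frame, resmap, criteria = contactCriteria()) {
    a <- selectAtom(frame, bwToResid(resmap, "6.40"), "OH")
    b <- selectAtom(frame, bwToResid(resmap, "2.51"), "OH")
    d <- sqrt(sum((a$position - b$position)^2))
    list(bonded = d <= criteria@hbond_cutoff_A, distance_A = d)
}

#' Unweighted centroid of a residue's aromatic ring
#'
#' @param frame a [Frame-class].
#' @param resid residue index.
#' @param criteria a [ContactCriteria-class] (supplies ring definitions).
#' @return numeric xyz centroid.
#' @export
ringCentroid <- function(frame, resid, criteria = contactCriteria()) {
    at <- frame@atoms
    rn <- at$resname[match(resid, at$resid)]
    if (is.na(rn)) stop("residue not present: ", resid)
    ring <- criteria@ring_atom_sets[[rn]]
    if (is.null(ring)) stop("no ring definition for residue type ", rn)
    i <- which(at$resid == resid & at$name %in% ring)
    if (length(i) != length(ring))
        stop(sprintf("residue %d (%s): %d of %d ring atoms present",
                     resid, rn, length(i), length(ring)))
    c(mean(at$x[i]), mean(at$y[i]), mean(at$z[i]))
}

.isAromaticMember <- function(frame, resid, criteria) {
    rn <- frame@atoms$resname[match(resid, frame@atoms$resid)]
    !is.null(criteria@ring_atom_sets[[rn]])
}

#' Aromatic pi-pi network across trajectory frames
#'
#' For the member BW positions (default 3.43, 6.36, 6.40, 7.55), draws a
#' per-frame edge between two members iff their ring-centroid distance is
#' within the pi-pi cutoff (inclusive, centroid-centroid). Non-aromatic
#' members are dropped with a warning. Edge occupancy is the fraction of
#' frames carrying the edge.
#'
#' @param frames a [Trajectory-class] or list of [Frame-class].
#' @param resmap a [ResidueMap-class].
#' @param members BW codes, default `c("3.43", "6.36", "6.40", "7.55")`.
#' @param criteria a [ContactCriteria-class].
#' @return list with `edges` (data.frame: frame, a, b, distance_A, edge),
#'   `occupancy` (data.frame: a, b, occupancy) and `metadata` (records the
#'   centroid-centroid distance convention).
#' @export
aromaticNetwork <- function(frames, resmap,
                            members = c("3.43", "6.36", "6.40", "7.55"),
                            criteria = contactCriteria()) {
    if (is(frames, "Trajectory"))
        frames <- lapply(seq_len(nFrames(frames)), function(i)
            getFrame(frames, i))
    if (length(frames) == 0L) stop("no frames supplied")
    resids <- bwToResid(resmap, members)
    keep <- vapply(resids, .isAromaticMember, logical(1L),
                   frame = frames[[1L]], criteria = criteria)
    if (any(!keep))
        warning("dropping non-aromatic member(s): ",
                paste(members[!keep], collapse = ", "))
    members <- members[keep]; resids <- resids[keep]
    if (length(members) < 2L) stop("fewer than 2 aromatic members")
    pairs <- utils::combn(seq_along(members), 2L)
    rows <- vector("list", length(frames))
    for (f in seq_along(frames)) {
        cen <- vapply(resids, ringCentroid, numeric(3L),
                      frame = frames[[f]], criteria = criteria)
        d <- apply(pairs, 2L, function(p)
            sqrt(sum((cen[, p[1L]] - cen[, p[2L]])^2)))
        rows[[f]] <- data.frame(frame = f,
                                a = members[pairs[1L, ]],
                                b = members[pairs[2L, ]],
                                distance_A = d,
                                edge = d <= criteria@pipi_cutoff_A,
                                stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, rows)
    occ <- stats::aggregate(edge ~ a + b, data = edges, FUN = mean)
    names(occ)[names(occ) == "edge"] <- "occupancy"
    list(edges = edges, occupancy = occ,
         metadata = list(distance = "centroid-centroid",
                         cutoff_A = criteria@pipi_cutoff_A,
                         comparison = "inclusive (<=)"))
}
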