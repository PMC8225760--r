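test_that("switchState classifies by the minimum side-chain-N to backbone-O distance", {
    rm <- networkFixtureMap()
    cl <- switchState(networkFixtureFrame(d_switch = 3.0), rm)
    expect_equal(cl$state, "closed")
    expect_equal(cl$min_distance_A, 3.0)
    op <- switchState(networkFixtureFrame(d_switch = 5.0), rm)
    expect_equal(op$state, "open")
    # boundary is inclusive
    expect_equal(switchState(networkFixtureFrame(d_switch = 4.0), rm)$state,
                 "closed")
    # randomised placements: min distance matches an exhaustive pairwise oracle
    set.seed(19)
    for (i in 1:10) {
        fr <- networkFixtureFrame()
        at <- fr@atoms
        mv <- at$name %in% c("NH1", "NE")
        at$x[mv] <- stats::rnorm(sum(mv), sd = 4)
        at$y[mv] <- stats::rnorm(sum(mv), sd = 4)
        at$z[mv] <- stats::rnorm(sum(mv), sd = 4)
        fr2 <- Frame(at)
        got <- switchState(fr2, rm)$min_distance_A
        ni <- which(at$name %in% c("NH1", "NE"))
        oi <- which(at$name == "O")
        oracle <- min(vapply(ni, function(j)
            sqrt((at$x[j] - at$x[oi])^2 + (at$y[j] - at$y[oi])^2 +
                     (at$z[j] - at$z[oi])^2), numeric(1L)))
        expect_equal(got, oracle)
    }
})

test_that("tyrosinePairBond uses the OH-OH distance with an inclusive 4 A cutoff", {
    rm <- networkFixtureMap()
    expect_true(tyrosinePairBond(networkFixtureFrame(d_tyr = 3.9), rm)$bonded)
    expect_false(tyrosinePairBond(networkFixtureFrame(d_tyr = 4.1), rm)$bonded)
    expect_true(tyrosinePairBond(networkFixtureFrame(d_tyr = 4.0), rm)$bonded)
})

test_that("ringCentroid averages the ring atoms and is translation-equivariant", {
    # regular hexagon of unit radius around a chosen centre
    hexFrame <- function(cx = 0, cy = 0, cz = 0) {
        th <- 2 * pi * (0:5) / 6
        Frame(data.frame(
            name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
            resid = 1L, resname = "PHE", chain = "A",
            x = cx + cos(th), y = cy + sin(th), z = cz))
    }
    expect_equal(ringCentroid(hexFrame(), 1L), c(0, 0, 0))
    expect_equal(ringCentroid(hexFrame(3, -2, 5), 1L), c(3, -2, 5))
    # Trp: all 9 indole ring atoms, hand-computed mean
    trp_names <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                   "CH2")
    set.seed(23)
    xyz <- matrix(stats::rnorm(27), 9L, 3L)
    trp <- Frame(data.frame(name = trp_names, resid = 2L, resname = "TRP",
                            chain = "A", x = xyz[, 1L], y = xyz[, 2L],
                            z = xyz[, 3L]))
    expect_equal(ringCentroid(trp, 2L), colMeans(xyz))
    # missing ring atom is an error
    broken <- Frame(trp@atoms[-1L, ])
    expect_error(ringCentroid(broken, 2L), "8 of 9")
})

test_that("aromaticNetwork draws edges at the pi-pi cutoff and computes occupancies", {
    rm <- networkFixtureMap()
    cr <- contactCriteria()
    near <- aromaticNetwork(list(networkFixtureFrame(d_ring = c(7, 20, 20))),
                            rm, members = c("3.43", "6.36"), criteria = cr)
    expect_true(all(near$edges$edge))
    far <- aromaticNetwork(list(networkFixtureFrame(d_ring = c(8, 20, 20))),
                           rm, members = c("3.43", "6.36"), criteria = cr)
    expect_false(any(far$edges$edge))
    # a non-aromatic member (alanine-like, as at 6.40 in SMO) is dropped
    # with a warning
    expect_warning(
        full <- aromaticNetwork(list(networkFixtureFrame()), rm,
                                members = c("3.43", "6.36", "6.45"),
                                criteria = cr),
        "6.45")
    expect_equal(nrow(full$occupancy), 1L)
    expect_error(
        suppressWarnings(aromaticNetwork(list(networkFixtureFrame()), rm,
                                         members = c("3.43", "6.45"))),
        "fewer than 2")
    # one member drifting 6 -> 9 A over 100 frames: occupancy equals the
    # closed-form fraction of frames within 7.5 A
    dists <- 6 + 3 * (0:99) / 99
    frames <- lapply(dists, function(d)
        networkFixtureFrame(d_ring = c(d, 20, 20)))
    drift <- aromaticNetwork(frames, rm, members = c("3.43", "6.36"),
                             criteria = cr)
    expect_equal(drift$occupancy$occupancy, mean(dists <= 7.5))
    expect_equal(drift$metadata$distance, "centroid-centroid")
})

test_that("classifications are monotone in their cutoffs", {
    rm <- networkFixtureMap()
    ds <- seq(2, 10, by = 0.5)
    for (cut in c(3, 4, 6)) {
        cr <- contactCriteria(hbond_cutoff_A = cut, pipi_cutoff_A = cut)
        cr2 <- contactCriteria(hbond_cutoff_A = cut + 1, pipi_cutoff_A = cut + 1)
        for (d in ds) {
            fr <- networkFixtureFrame(d_switch = d, d_ring = c(d, 20, 20))
            # enlarging a cutoff never opens a closed switch
            if (switchState(fr, rm, cr)$state == "closed")
                expect_equal(switchState(fr, rm, cr2)$state, "closed")
            # enlarging a cutoff never removes an edge
            e1 <- aromaticNetwork(list(fr), rm, c("3.43", "6.36"), cr)
            e2 <- aromaticNetwork(list(fr), rm, c("3.43", "6.36"), cr2)
            if (e1$edges$edge[1L]) expect_true(e2$edges$edge[1L])
        }
    }
})
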