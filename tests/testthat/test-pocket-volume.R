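# tiny helper frames for abstract grid checks
singleAtomFrame <- function() {
    Frame(data.frame(name = "CA", resid = 1L, resname = "ALA", chain = "A",
                     x = 0, y = 0, z = 0))
}

test_that("a single atom yields no cavity points (nothing is buried)", {
    cfg <- PocketConfig(seed_point = c(0, 0, 0))
    cp <- cavityPoints(singleAtomFrame(), cfg)
    expect_equal(cp$n_points, 0L)
    expect_error(cavityPoints(Frame(singleAtomFrame()@atoms[0, ]), cfg),
                 "empty")
})

test_that("the compiled cavity rule agrees with a brute-force double loop", {
    b <- buildToyBundle(helix_spec = helixSpec(10L))
    cfg <- PocketConfig(seed_point = b$seed_point)
    atoms <- coords(b$frame)
    set.seed(29)
    pts <- cbind(stats::runif(250, -12, 12), stats::runif(250, -12, 12),
                 stats::runif(250, -3, 18))
    got <- ClassFKink:::.cavityRuleCpp(
        pts, atoms, cfg@d_min_A, cfg@d_max_A,
        ClassFKink:::.latticeDirections(), cfg@buriedness_min_hits,
        cfg@ray_length_A, cfg@ray_hit_radius_A)
    expect_equal(as.logical(got), unname(bruteForceCavityRule(pts, atoms, cfg)))
    expect_gt(sum(got), 0L)   # the sample does reach the cavity band
})

test_that("frequencyMap counts frames per grid point", {
    b <- buildToyBundle(helix_spec = helixSpec(10L))
    cfg <- PocketConfig(seed_point = b$seed_point)
    fm3 <- frequencyMap(rep(list(b$frame), 3L), cfg)
    cp <- cavityPoints(b$frame, cfg, grid = fm3$grid)
    # identical frames repeated k times: every cavity point has count k
    expect_equal(fm3$counts, 3L * as.integer(cp$mask))
    fm1 <- frequencyMap(list(b$frame), cfg)
    expect_true(all(fm1$counts %in% c(0L, 1L)))
    # two frames sharing part of their cavity: per-point arithmetic oracle
    shifted <- Frame(transform(b$frame@atoms, z = z + 2))
    fm2 <- frequencyMap(list(b$frame, shifted), cfg)
    m1 <- ClassFKink:::.cavityMask(coords(b$frame), fm2$grid, cfg)
    m2 <- ClassFKink:::.cavityMask(coords(shifted), fm2$grid, cfg)
    expect_equal(fm2$counts, as.integer(m1) + as.integer(m2))
})

test_that("selectPocket takes the 26-connected component at the seed", {
    # abstract two-blob frequency map on a 10x5x3 grid
    dims <- c(10L, 5L, 3L)
    pts <- as.matrix(expand.grid(x = 0:9, y = 0:4, z = 0:2))
    counts <- integer(nrow(pts))
    blobA <- which(pts[, 1L] <= 2)            # 45 points
    blobB <- which(pts[, 1L] >= 6)            # smaller target blob
    counts[blobA] <- 5L
    counts[pts[, 1L] >= 6 & pts[, 2L] <= 1 & pts[, 3L] == 1] <- 4L
    fmap <- list(counts = counts,
                 grid = list(points = pts, dims = dims, spacing = 1,
                             origin = c(0, 0, 0)))
    cfgB <- PocketConfig(seed_point = c(7, 1, 1), isovalue = 3L)
    selB <- selectPocket(fmap, cfgB)
    expect_equal(sum(selB$component), 8L)     # the small blob only
    expect_true(all(which(selB$component) %in%
                        which(counts == 4L)))
    cfgA <- PocketConfig(seed_point = c(1, 2, 1), isovalue = 3L)
    expect_equal(sum(selectPocket(fmap, cfgA)$component), length(blobA))
    # isovalue above the maximum count
    expect_error(selectPocket(fmap, PocketConfig(seed_point = c(1, 2, 1),
                                                 isovalue = 9L)),
                 "isovalue")
    # seed far from any qualifying point
    expect_error(selectPocket(fmap, PocketConfig(seed_point = c(4.5, 8, 1),
                                                 isovalue = 3L)),
                 "seed")
})

test_that("volumeSeries tracks per-frame cavity/component intersections", {
    b <- buildToyBundle()
    cfg <- PocketConfig(seed_point = b$seed_point, isovalue = 1L)
    pr <- trackPocket(rep(list(b$frame), 3L), cfg)
    # rigid identical frames: constant series, volume = count * spacing^3
    expect_equal(pr@volumes_A3, rep(pr@volumes_A3[1L], 3L))
    expect_equal(pr@volumes_A3, pr@point_counts * cfg@grid_spacing_A^3)
    expect_gt(pr@volumes_A3[1L], 0)
    # a frame whose channel is blocked contributes (near) zero volume
    plug <- expand.grid(x = seq(-4, 4, by = 1.5), y = seq(-4, 4, by = 1.5),
                        z = seq(0, 29, by = 1.5))
    plugged <- Frame(rbind(b$frame@atoms,
                           data.frame(name = "CA", resid = 999L,
                                      resname = "PLG", chain = "Z",
                                      x = plug$x, y = plug$y, z = plug$z)))
    sel <- selectPocket(frequencyMap(list(b$frame), cfg), cfg)
    v <- volumeSeries(list(b$frame, plugged), sel, cfg)
    expect_gt(v[1L], 0)
    expect_lt(v[2L], 0.05 * v[1L])
})

test_that("grid volume agrees with a reduced Monte-Carlo oracle and rigid motion", {
    b <- buildToyBundle()
    cfg <- PocketConfig(seed_point = b$seed_point, isovalue = 1L)
    cp <- cavityPoints(b$frame, cfg)
    vol_grid <- cp$n_points * cfg@grid_spacing_A^3
    mc <- monteCarloBuriedVolume(b$frame, cfg, n_samples = 2e5, seed = 7L)
    expect_lt(abs(vol_grid - mc$volume_A3) / mc$volume_A3, 0.2)
    # pipeline output is invariant (to within a grid shell) under a rigid
    # transform of the whole frame
    set.seed(37)
    moved <- randomRigidTransform(b$frame)$frame
    cp2 <- cavityPoints(moved, cfg)
    shell <- 1.2 * (cp$n_points)^(2 / 3)      # one-cell surface allowance
    expect_lt(abs(cp2$n_points - cp$n_points), shell + 0.05 * cp$n_points)
})
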