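test_that("buildIdealHelix has exact rise, equal CA-CA steps and screw symmetry", {
    f <- buildIdealHelix(helixSpec(12L))
    ca <- f@atoms[f@atoms$name == "CA", ]
    expect_equal(diff(ca$z), rep(1.5, 11L))
    d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    expect_equal(d, rep(d[1L], 11L))
    # three-point N angle over (i, i+4, i+8) is the same for every i;
    # value frozen from direct evaluation of the default geometry
    ang <- vapply(1:4, function(i)
        threePointAngle(selectAtom(f, i, "N")$position,
                        selectAtom(f, i + 4L, "N")$position,
                        selectAtom(f, i + 8L, "N")$position), numeric(1L))
    expect_equal(ang, rep(173.561543, 4L), tolerance = 1e-6)
    expect_error(helixSpec(8L), "n_res")
})

test_that("applyKink reaches its target within 0.01 degrees and leaves upstream atoms untouched", {
    f <- buildIdealHelix(helixSpec(31L))
    measure <- function(fr) threePointAngle(
        selectAtom(fr, 12L, "N")$position,
        selectAtom(fr, 16L, "N")$position,
        selectAtom(fr, 20L, "N")$position)
    base <- measure(f)
    # fixed point: targeting the unkinked angle changes nothing beyond tol
    expect_equal(measure(applyKink(f, 16L, base)), base, tolerance = 0.01)
    for (tgt in c(158.5, 168.4, 120)) {
        k <- applyKink(f, 16L, tgt)
        expect_equal(measure(k), tgt, tolerance = 0.01)
        expect_identical(k@atoms[k@atoms$resid <= 16L, ],
                         f@atoms[f@atoms$resid <= 16L, ])
    }
    expect_error(applyKink(f, 16L, 30), "90")
    expect_error(applyKink(f, 16L, 180), "unreachable")
    expect_error(applyKink(f, 3L, 150), "termini")
})

test_that("generateTrajectory realises the drawn angles and is deterministic under seed", {
    # sigma = 0: every frame angle equals mu exactly (to solver tolerance)
    tr0 <- generateTrajectory(helixSpec(15L), kinkSpec(160, 0),
                              ensembleSpec(replica_lengths_ns = 1,
                                           seed = 5L))[[1L]]
    s0 <- tm6KinkSeries(tr0, tm6ResidueMap(15L))
    expect_equal(s0@angles_deg, rep(160, nFrames(tr0)), tolerance = 0.01)

    a <- smallEnsemble(seed = 9L)
    b <- smallEnsemble(seed = 9L)
    expect_identical(lapply(a, attr, "target_angles_deg"),
                     lapply(b, attr, "target_angles_deg"))
    expect_identical(lapply(a, coords), lapply(b, coords))
    c2 <- smallEnsemble(seed = 10L)
    expect_false(identical(attr(a[[1L]], "target_angles_deg"),
                           attr(c2[[1L]], "target_angles_deg")))
})

test_that("phi = 0 ensemble sample mean honours the CLT bound", {
    trajs <- generateTrajectory(
        helixSpec(15L), kinkPreset("fzd6"),
        ensembleSpec(replica_lengths_ns = c(50, 25), seed = 1L))
    ang <- unlist(lapply(trajs, attr, "target_angles_deg"))
    n <- length(ang)
    expect_equal(n, 501L + 250L)
    expect_lt(abs(mean(ang) - 158.5), 4 * 4.5 / sqrt(n))
})

test_that("AR(1) marginal at phi = 0 is iid Normal (KS over 100 seeds)", {
    reject <- vapply(1:100, function(s) {
        set.seed(s)
        a <- ClassFKink:::.ar1Draws(5000L, 158.5, 4.5, 0)
        stats::ks.test(a, "pnorm", 158.5, 4.5)$p.value < 0.01
    }, logical(1L))
    expect_lte(mean(reject), 0.05)
})

test_that("AR(1) autocorrelation follows phi and keeps the marginal SD", {
    set.seed(3)
    a <- ClassFKink:::.ar1Draws(20000L, 100, 5, 0.6)
    expect_equal(stats::sd(a), 5, tolerance = 0.1)
    expect_equal(stats::cor(a[-1L], a[-length(a)]), 0.6, tolerance = 0.05)
})

test_that("subsampleFrames reproduces the printed pose count and the closed form", {
    trajs <- smallEnsemble(lengths = c(50, 25, 25, 25), seed = 2L)
    sub <- subsampleFrames(trajs, 5)
    expect_equal(sub$n, sum(floor(c(50, 25, 25, 25) / 5)) + 1L)
    expect_equal(sub$times_ns[1L], 0)
    one <- smallEnsemble(lengths = 100, seed = 2L, n_res = 9L)
    expect_equal(subsampleFrames(one, 10)$n, 11L)
    expect_error(subsampleFrames(one, 7), "does not divide")
    expect_error(subsampleFrames(one, 0.25 * 0.3), "multiple")
})

test_that("toy bundle is symmetric and its seed point is clear of atoms", {
    b <- buildToyBundle()
    centres <- vapply(LETTERS[1:7], function(ch) {
        at <- b$frame@atoms[b$frame@atoms$chain == ch, ]
        c(mean(at$x), mean(at$y))
    }, numeric(2L))
    d <- as.matrix(stats::dist(t(centres)))
    adj <- vapply(1:7, function(i) d[i, i %% 7L + 1L], numeric(1L))
    expect_equal(adj, rep(adj[1L], 7L), tolerance = 1e-9)
    dmin <- min(sqrt(colSums((t(coords(b$frame)) - b$seed_point)^2)))
    expect_gt(dmin, 2)
})

test_that("generateBindingTable hits the half-saturation identity and refits cleanly", {
    spec <- bindingSpec(pKd = 6, noise_sd = 0,
                        concentrations = c(10^-7, 10^-6, 10^-5))
    tab <- generateBindingTable(spec)
    at_kd <- tab$response[!tab$is_control &
                              abs(tab$concentration_M - 1e-6) < 1e-12]
    expect_equal(at_kd, rep(0.1 + 0.5 / 2, 2L))   # baseline + amplitude/2
    expect_equal(tab$response[tab$is_control], rep(0.1, 4L))
    # seeded noisy table: refit recovers pKd within its own CI
    noisy <- generateBindingTable(bindingPreset("fzd6_wt", seed = 42L))
    fit <- fitSaturation(noisy, 3L)
    expect_lt(abs(fit@coefficients[["pKd"]] - 6.45),
              3 * fit@se[["pKd"]] + 0.05)
})

test_that("generateDoseResponse lays responses on the stated laws", {
    bell <- generateDoseResponse("bell",
        list(p0 = 0, p1 = 1, p2 = 0.2, m1 = -8, m2 = -6, h1 = 1, h2 = 1,
             x = seq(-10, -4, length.out = 9L)), seed = 1L)
    # rise/fall midpoints far apart: interior maximum
    peak <- bell$concentration_M[which.max(bell$response)]
    expect_gt(peak, 10^-10)
    expect_lt(peak, 10^-4)
    flat <- generateDoseResponse("linear",
        list(a = 0.3, b = 0, x = 0:5), seed = 1L)
    expect_equal(flat$response, rep(0.3, 12L))
    one <- generateDoseResponse("one_phase",
        list(Y0 = 0, P = 1, K = 0.5, x = c(0, 2, 4)), seed = 1L)
    expect_equal(unique(one$response), 1 - exp(-0.5 * c(0, 2, 4)))
})
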