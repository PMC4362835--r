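# build a genome with named classes at chosen ranks and the matching
# detections; decoy genes fill the remaining positions
contextFixture <- function(phage, placed, n = 14L) {
    g <- toyGenome(phage, n)
    ids <- proteinTable(g)$protein_id
    rows <- lapply(names(placed), function(cl)
        list(phage, cl, ids[placed[[cl]]], 95))
    list(genome = g, ids = ids, table = toyDetections(rows))
}

test_that("distance statistics match the direct mean/sd/tolerated oracle", {
    # canonical Ad1-Hc1-x-Tc1 arrangements at varying offsets
    fixtures <- lapply(1:4, function(i)
        contextFixture(paste0("p", i),
                       list(Ad1 = 2 + i, Hc1 = 3 + i, Tc1 = 5 + i)))
    tab <- do.call(rbind, lapply(fixtures, function(f)
        detections(f$table)))
    tab <- new("DetectionTable", detections = tab,
               diagnostics = character())
    m <- learnDistanceModel(tab, lapply(fixtures, `[[`, "genome"), 1)
    p <- m@pairs
    expect_equal(p$mean[p$class_a == "Ad1" & p$class_b == "Hc1"], 1)
    expect_equal(p$mean[p$class_a == "Hc1" & p$class_b == "Tc1"], 2)
    expect_equal(p$mean[p$class_a == "Ad1" & p$class_b == "Tc1"], 3)
    expect_equal(p$sd, rep(0, 3))
    expect_equal(p$tolerated, p$mean)  # zero spread
    expect_equal(p$n, rep(4L, 3))
})

test_that("tolerated = mean + 2*sd with sample sd, real-valued", {
    # two phages with (Hc1, Tc1) distances 1 and 3
    f1 <- contextFixture("q1", list(Hc1 = 4, Tc1 = 5))
    f2 <- contextFixture("q2", list(Hc1 = 4, Tc1 = 7))
    tab <- new("DetectionTable",
               detections = rbind(detections(f1$table),
                                  detections(f2$table)),
               diagnostics = character())
    m <- suppressWarnings(
        learnDistanceModel(tab, list(f1$genome, f2$genome), 1))
    row <- m@pairs[m@pairs$class_a == "Hc1" & m@pairs$class_b == "Tc1", ]
    expect_equal(row$mean, 2)
    expect_equal(row$sd, sqrt(2))          # sample (n-1) sd of {1, 3}
    expect_equal(row$tolerated, 2 + 2 * sqrt(2))
    # pairs never observed together are marked unavailable
    ad <- m@pairs[m@pairs$class_a == "Ad1", ]
    expect_true(all(ad$n == 0L))
})

test_that("tolerated statistics agree with a brute-force oracle on random
           samples", {
    set.seed(9)
    for (rep in 1:10) {
        n <- sample(2:8, 1)
        gaps <- sample(0:2, n, replace = TRUE)
        fx <- lapply(seq_len(n), function(i)
            contextFixture(paste0("r", i),
                           list(Ad1 = 2, Hc1 = 3 + gaps[i])))
        tab <- new("DetectionTable",
                   detections = do.call(rbind, lapply(fx, function(f)
                       detections(f$table))),
                   diagnostics = character())
        m <- suppressWarnings(
            learnDistanceModel(tab, lapply(fx, `[[`, "genome"), 1))
        row <- m@pairs[m@pairs$class_a == "Ad1" &
                       m@pairs$class_b == "Hc1", ]
        d <- 1 + gaps
        expect_equal(row$mean, mean(d))
        expect_equal(row$sd, if (n > 1) sd(d) else 0)
        expect_equal(row$tolerated, mean(d) + 2 * (if (n > 1) sd(d) else 0))
    }
})

test_that("relaxed candidates pass only at canonical positions", {
    model <- new("DistanceModel", neckType = 1L, pairs = data.frame(
        class_a = c("Ad1", "Ad1", "Hc1"),
        class_b = c("Hc1", "Tc1", "Tc1"),
        mean = c(1, 3, 2), sd = c(0.5, 1, 1),
        tolerated = c(2, 5, 4), n = c(10L, 10L, 10L),
        stringsAsFactors = FALSE))
    ss <- defaultSeedSet()

    run <- function(tcIndex, prob) {
        f <- contextFixture("z1", list(Ad1 = 3, Hc1 = 4))
        p <- toyProvider(list(f$ids[4], f$ids[tcIndex], 93, 20),
                         list("SPP1_gp17", f$ids[tcIndex], prob, 15))
        constrainedRelaxedSearch(ss, p, model, f$table, list(f$genome),
                                 relaxedThreshold = 70)
    }
    # Tc1 at distance 4 downstream of Hc1: equals tolerated -> accepted
    tab <- run(8, 75)
    d <- detections(tab)
    expect_true(any(d$class == "Tc1" & d$round == "relaxed70"))
    # distance 6 exceeds tolerated 4 -> rejected
    tab <- run(10, 75)
    expect_false(any(detections(tab)$class == "Tc1"))
    expect_match(diagnostics(tab), "inconsistent", all = FALSE)
    # below the relaxed threshold: never surfaced even at perfect position
    tab <- run(6, 65)
    expect_false(any(detections(tab)$class == "Tc1"))
    # wrong side of Hc1 (upstream): sign violation -> rejected
    tab <- run(1, 75)
    expect_false(any(detections(tab)$class == "Tc1"))
})

test_that("phage without strict anchors cannot validate relaxed candidates", {
    model <- new("DistanceModel", neckType = 1L, pairs = data.frame(
        class_a = "Hc1", class_b = "Tc1", mean = 2, sd = 1,
        tolerated = 4, n = 5L, stringsAsFactors = FALSE))
    g <- toyGenome("lone", 8L)
    ids <- proteinTable(g)$protein_id
    p <- toyProvider(list("SPP1_gp17", ids[5], 80, 15))
    empty <- new("DetectionTable")
    tab <- constrainedRelaxedSearch(defaultSeedSet(), p, model, empty,
                                    list(g))
    expect_equal(nrow(detections(tab)), 0L)
    expect_match(diagnostics(tab), "no strict anchor", all = FALSE)
})

test_that("gpW rule: >= 95%, canonical -6/-9 position, only without Ad1", {
    ss <- defaultSeedSet()
    base <- function(prob, gpwIdx = 5, withAd1 = FALSE) {
        placed <- list(Hc1 = 11, Tc1 = 14)
        if (withAd1) placed$Ad1 <- 10
        f <- contextFixture("lam", placed, n = 16L)
        p <- toyProvider(list("lambda_gpW", f$ids[gpwIdx], prob, 25))
        detectGpW(ss, p, f$table, list(f$genome))
    }
    d <- detections(base(96))
    expect_true(any(d$class == "gpW" & d$round == "gpW"))
    # below the 95 threshold
    expect_false(any(detections(base(80))$class == "gpW"))
    # wrong position (distance -3 from Hc1)
    expect_false(any(detections(base(96, gpwIdx = 8))$class == "gpW"))
    # Ad1 already present: rule skipped
    expect_false(any(detections(base(96, withAd1 = TRUE))$class == "gpW"))
})

test_that("Ne1 accepted at high confidence anywhere, mid confidence only
           between Hc1 and Tc1", {
    ss <- defaultSeedSet()
    run <- function(prob, ne1Idx) {
        f <- contextFixture("n1", list(Ad1 = 5, Hc1 = 6, Tc1 = 9), n = 12L)
        p <- toyProvider(list("SPP1_gp16.1", f$ids[ne1Idx], prob, 30))
        detectNe1(ss, p, f$table, list(f$genome))
    }
    expect_true(any(detections(run(97, 2))$class == "Ne1"))   # strict, far
    expect_true(any(detections(run(75, 7))$class == "Ne1"))   # relaxed, in slot
    expect_false(any(detections(run(75, 2))$class == "Ne1"))  # relaxed, outside
    expect_false(any(detections(run(75, 9))$class == "Ne1"))  # not strict-between
})

test_that("low-support candidates are flagged, never accepted", {
    model <- new("DistanceModel", neckType = 1L, pairs = data.frame(
        class_a = c("Ad1", "Ad1", "Hc1"),
        class_b = c("Hc1", "Tc1", "Tc1"),
        mean = c(1, 3, 2), sd = c(0, 0, 0), tolerated = c(1, 3, 2),
        n = c(5L, 5L, 5L), stringsAsFactors = FALSE))
    f <- contextFixture("fl", list(Ad1 = 4, Hc1 = 5), n = 10L)
    mkProvider <- function(nSupport) {
        makeHitProvider(
            data.frame(query_id = "u", target_id = "v",
                       probability = 50, identity = 10),
            metadata = data.frame(
                profile_id = f$ids[7],  # the canonical Tc1 slot
                n_aligned_sequences = nSupport))
    }
    out <- flagLowSupportCandidates(mkProvider(3L), model, f$table,
                                    list(f$genome))
    expect_equal(nrow(out), 1L)
    expect_equal(out$class, "Tc1")
    expect_equal(out$protein_id, f$ids[7])
    # boundary: exactly 5 sequences is NOT low support
    expect_equal(nrow(flagLowSupportCandidates(mkProvider(5L), model,
                                               f$table, list(f$genome))),
                 0L)
    # nothing missing -> nothing flagged
    full <- contextFixture("fl2", list(Ad1 = 4, Hc1 = 5, Tc1 = 7), n = 10L)
    expect_equal(nrow(flagLowSupportCandidates(mkProvider(3L), model,
                                               full$table,
                                               list(full$genome))), 0L)
})

test_that("context filter rejects every decoy at non-canonical positions
           in seeded simulations", {
    for (seed in c(101, 202, 303)) {
        u <- smallUniverse(seed = seed, decoyHitFraction = 0.5,
                           divergentFraction = 0.2)
        res <- detectModule(u$genomes, u$provider, runConfig())
        d <- detections(res$table)
        truthClass <- setNames(u$truth$proteins$class,
                               u$truth$proteins$protein_id)
        accepted_decoys <- d$protein_id[truthClass[d$protein_id] == "decoy"]
        expect_length(accepted_decoys, 0L)
        # single-copy invariant after every pass
        expect_true(validObject(res$table))
    }
})

test_that("distance model YAML round-trips", {
    f1 <- contextFixture("y1", list(Ad1 = 3, Hc1 = 4, Tc1 = 6))
    m <- learnDistanceModel(f1$table, list(f1$genome), 1)
    path <- withr::local_tempfile(fileext = ".yaml")
    saveDistanceModel(m, path)
    m2 <- loadDistanceModel(path)
    expect_equal(m2@neckType, m@neckType)
    expect_equal(m2@pairs, m@pairs)
})
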