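test_that("the generator is deterministic for a fixed seed", {
    u1 <- smallUniverse(seed = 33)
    u2 <- smallUniverse(seed = 33)
    expect_identical(hitTable(u1$provider), hitTable(u2$provider))
    expect_identical(u1$truth, u2$truth)
    expect_identical(lapply(u1$genomes, proteinTable),
                     lapply(u2$genomes, proteinTable))
    u3 <- smallUniverse(seed = 34)
    expect_false(identical(hitTable(u1$provider), hitTable(u3$provider)))
})

test_that("invalid configurations are rejected", {
    expect_error(universeConfig(withinProb = c(95, 120)), "within")
    expect_error(universeConfig(nPhagesPerType = c("1" = 4L, "2" = 0L,
                                                   "3" = 0L, "4" = 0L),
                                nClustersType1 = 6L), "more .* clusters")
    expect_error(generateUniverse(universeConfig()), "seed")
})

test_that("generated hit tables satisfy the homology invariants as-is", {
    u <- smallUniverse(seed = 3)
    h <- hitTable(u$provider)
    expect_true(all(h$probability >= 0 & h$probability <= 100))
    expect_true(all(h$identity >= 0 & h$identity <= 100))
    expect_false(any(h$query_id == h$target_id))
    expect_true(validObject(u$provider))
    # genomes validate and ranks are consecutive
    for (g in u$genomes) expect_true(validObject(g))
})

test_that("canonical arrangements reproduce the printed distance means", {
    cfg <- universeConfig(gapProb = 0, divergentFraction = 0,
                          missingFraction = 0)
    u <- generateUniverse(cfg, seed = 19)
    tab <- strictDetection(defaultSeedSet(), u$provider, u$genomes)
    m1 <- learnDistanceModel(tab, u$genomes, 1)
    expect_equal(m1@pairs$mean, c(1, 3, 2))       # (Ad1,Hc1),(Ad1,Tc1),(Hc1,Tc1)
    expect_equal(m1@pairs$sd, c(0, 0, 0))
    m2 <- learnDistanceModel(tab, u$genomes, 2)
    expect_equal(m2@pairs$mean, c(1, 2, 1))       # (Ad2,Hc2),(Ad2,Tc2),(Hc2,Tc2)
    m3 <- learnDistanceModel(tab, u$genomes, 3)
    expect_equal(m3@pairs$mean, 2)                # (Ad3,Hc3)
})

test_that("within-family probabilities track the configured band", {
    u <- smallUniverse(seed = 23, divergentFraction = 0,
                       missingFraction = 0)
    h <- hitTable(u$provider)
    cls <- setNames(u$truth$proteins$class, u$truth$proteins$protein_id)
    clu <- setNames(paste(u$truth$phages$type, u$truth$phages$cluster),
                    u$truth$phages$phage_id)
    phOf <- setNames(rep(names(u$genomes),
                         vapply(u$genomes, function(g)
                             nrow(proteinTable(g)), 1L)),
                     unlist(lapply(u$genomes, function(g)
                         proteinTable(g)$protein_id)))
    inFam <- !is.na(cls[h$query_id]) & !is.na(cls[h$target_id]) &
        cls[h$query_id] == cls[h$target_id] &
        cls[h$query_id] != "decoy" &
        clu[phOf[h$query_id]] == clu[phOf[h$target_id]]
    inFam[is.na(inFam)] <- FALSE
    x <- h$probability[inFam]
    band <- universeConfig()$withinProb
    expect_true(all(x >= band[1] & x <= band[2]))
    # empirical mean consistent with the uniform-band mean (3 SE)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mean(band)), 3 * se)
})

test_that("worked examples reproduce the reference compositions", {
    wx <- generateWorkedExamples()
    expect_identical(generateWorkedExamples()$truth, wx$truth)  # no RNG
    ref <- runBuildReference(wx$genomes, wx$provider, runConfig())
    a <- ref$assignments
    expect_identical(setNames(a$neck_type, a$phage_id)[wx$truth$phage_id],
                     setNames(as.character(wx$truth$neck_type),
                              wx$truth$phage_id))
    expect_identical(setNames(a$morphology, a$phage_id)[wx$truth$phage_id],
                     setNames(wx$truth$morphology, wx$truth$phage_id))
    # the lambda fixture goes through the gpW adaptor-replacement rule
    d <- detections(ref$table)
    expect_true(any(d$phage_id == "lambda" & d$class == "gpW" &
                    d$round == "gpW"))
})
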