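test_that("expansion is the transitive closure of the thresholded graph", {
    # chain A(seed) -> B at 95, B -> C at 92, direct A -> C only 60
    p <- toyProvider(list("SPP1_gp15", "B", 95, 20),
                     list("B", "C", 92, 15),
                     list("SPP1_gp15", "C", 60, 10))
    ss <- makeSeedSet(list(Ad1 = "SPP1_gp15"))
    res <- iterativeExpand(ss, p, threshold = 90)
    expect_setequal(res$Ad1$protein_id, c("SPP1_gp15", "B", "C"))
    # against the brute-force reachability oracle
    expect_identical(sort(res$Ad1$protein_id),
                     closureOracle(p, "SPP1_gp15", 90))
    # no hit above threshold: fixed point at the seed set
    res99 <- iterativeExpand(ss, p, threshold = 99)
    expect_identical(res99$Ad1$protein_id, "SPP1_gp15")
})

test_that("expansion agrees with the closure oracle on random graphs and
           is monotone in the threshold", {
    set.seed(21)
    for (rep in 1:8) {
        n <- 12L
        ids <- c("SPP1_gp15", sprintf("n%02d", seq_len(n)))
        rows <- list()
        for (k in 1:30) {
            qt <- sample(ids, 2L)
            rows[[k]] <- list(qt[1], qt[2], runif(1, 40, 100),
                              runif(1, 5, 30))
        }
        p <- suppressWarnings(do.call(toyProvider, rows))
        ss <- makeSeedSet(list(Ad1 = "SPP1_gp15"))
        got90 <- iterativeExpand(ss, p, threshold = 90)$Ad1$protein_id
        got70 <- iterativeExpand(ss, p, threshold = 70)$Ad1$protein_id
        expect_identical(sort(got90), closureOracle(p, "SPP1_gp15", 90))
        expect_identical(sort(got70), closureOracle(p, "SPP1_gp15", 70))
        expect_true(all(got90 %in% got70))  # 90-set subset of 70-set

        # set-level determinism: permuting stored hit rows changes nothing
        h <- hitTable(p)
        perm <- makeHitProvider(h[sample.int(nrow(h)), ])
        gotP <- iterativeExpand(ss, perm, threshold = 90)$Ad1$protein_id
        expect_identical(sort(gotP), sort(got90))
    }
})

test_that("missing seeds warn (skip) or error when a class has none", {
    p <- toyProvider(list("SPP1_gp15", "B", 95, 20))
    ss <- makeSeedSet(list(Ad1 = c("SPP1_gp15", "ghost")))
    expect_warning(res <- iterativeExpand(ss, p, 90), "absent")
    expect_setequal(res$Ad1$protein_id, c("SPP1_gp15", "B"))
    ss2 <- makeSeedSet(list(Hc1 = "only_ghost"))
    expect_error(suppressWarnings(iterativeExpand(ss2, p, 90)),
                 "all seeds")
})

test_that("cross-class conflicts resolve to the highest-probability class", {
    g <- toyGenome("ph", 4L)
    pid <- proteinTable(g)$protein_id
    perClass <- list(
        Ad1 = data.frame(protein_id = pid[2], probability = 91,
                         chain = "", stringsAsFactors = FALSE),
        Hc1 = data.frame(protein_id = pid[2], probability = 88,
                         chain = "", stringsAsFactors = FALSE))
    tab <- resolveClassConflicts(perClass, list(g))
    d <- detections(tab)
    expect_equal(nrow(d), 1L)
    expect_equal(d$class, "Ad1")
    expect_match(diagnostics(tab), "cross-class conflict", all = FALSE)
})

test_that("single-copy control keeps the best neck candidate and logs", {
    g <- toyGenome("ph", 5L)
    pid <- proteinTable(g)$protein_id
    perClass <- list(Ad3 = data.frame(
        protein_id = pid[c(2, 4)], probability = c(93, 97),
        chain = "", stringsAsFactors = FALSE))
    tab <- resolveClassConflicts(perClass, list(g))
    d <- detections(tab)
    expect_equal(nrow(d), 1L)
    expect_equal(d$protein_id, pid[4])
    expect_match(diagnostics(tab), "multiple Ad3", all = FALSE)
    expect_true(validObject(tab))
})

test_that("clean synthetic families are recovered with recall and
           precision 1 and no conflicts", {
    u <- smallUniverse(seed = 5, divergentFraction = 0,
                       missingFraction = 0, decoyHitFraction = 0,
                       gapProb = 0)
    ss <- defaultSeedSet()
    tab <- strictDetection(ss, u$provider, u$genomes)
    tab <- detectNe1(ss, u$provider, tab, u$genomes)
    d <- detections(tab)
    truth <- u$truth$proteins
    truth <- truth[truth$class != "decoy", ]
    # every truth protein detected in its true class, nothing else
    got <- setNames(d$class, d$protein_id)
    expect_setequal(names(got), truth$protein_id)
    expect_identical(unname(got[truth$protein_id]), truth$class)
    expect_length(diagnostics(tab), 0L)
})
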