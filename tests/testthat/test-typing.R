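mkTable <- function(classes, phage = "ph") {
    toyDetections(lapply(seq_along(classes), function(i)
        list(phage, classes[i], sprintf("%s_g%02d", phage, i), 95)))
}

test_that("the six reference compositions map to Types 1,1,1,2,3,4", {
    cases <- list(
        SPP1 = list(c("Ad1", "Hc1", "Tc1"), "1"),
        lambda = list(c("gpW", "Hc1", "Tc1"), "1"),
        HK97 = list(c("Ad1", "Hc1", "Tc1"), "1"),
        T4 = list(c("Ad2", "Hc2", "Tc2"), "2"),
        P22 = list(c("Ad3", "Hc3"), "3"),
        phi29 = list("Ad4", "4"))
    for (nm in names(cases)) {
        a <- assignNeckType(mkTable(cases[[nm]][[1]], nm), nm)
        expect_identical(a@neckType, cases[[nm]][[2]])
    }
})

test_that("minimum-evidence rules: Type 1/2 need two proteins, 3/4 one", {
    # lone Ad1: Type 1-like, recognizable but unclusterable
    a <- assignNeckType(mkTable("Ad1"), "ph")
    expect_identical(a@neckType, "type1_like")
    # lone Ad3 (the N4-like situation): full Type 3 call
    expect_identical(assignNeckType(mkTable("Ad3"), "ph")@neckType, "3")
    # lone Ad2 falls short of the Type 2 minimum
    a2 <- assignNeckType(mkTable("Ad2"), "ph")
    expect_identical(a2@neckType, "unassigned")
    # two of three Type 1 classes suffice (the T5-like Ad1+Tc1 case)
    expect_identical(assignNeckType(mkTable(c("Ad1", "Tc1")), "ph")@neckType,
                     "1")
    # no neck evidence at all
    expect_identical(assignNeckType(mkTable("MCP"), "ph")@neckType,
                     "unassigned")
})

test_that("conflicting Type evidence resolves by majority, ties unassigned", {
    a <- assignNeckType(mkTable(c("Ad1", "Hc1", "Tc1", "Ad3")), "ph")
    expect_identical(a@neckType, "1")
    tie <- assignNeckType(mkTable(c("Ad1", "Hc1", "Ad2", "Hc2")), "ph")
    expect_identical(tie@neckType, "unassigned")
    expect_match(tie@diagnostics, "tie", all = FALSE)
})

test_that("completeness counts Ne1 for Type 1 display", {
    full <- assignNeckType(mkTable(c("Ad1", "Hc1", "Ne1", "Tc1")), "ph")
    expect_equal(full@completeness, 1)
    noNe <- assignNeckType(mkTable(c("Ad1", "Hc1", "Tc1")), "ph")
    expect_equal(noNe@completeness, 0.75)
    expect_match(noNe@diagnostics, "incomplete", all = FALSE)
    t2 <- assignNeckType(mkTable(c("Ad2", "Hc2", "Tc2")), "ph")
    expect_equal(t2@completeness, 1)
})

test_that("morphology follows Type and sheath presence", {
    t1 <- assignNeckType(mkTable(c("Ad1", "Hc1", "Tc1")), "ph")
    expect_identical(inferMorphology(t1, TRUE)@morphology, "Myoviridae")
    expect_identical(inferMorphology(t1, FALSE)@morphology, "Siphoviridae")
    t2 <- assignNeckType(mkTable(c("Ad2", "Hc2", "Tc2")), "ph")
    expect_identical(inferMorphology(t2, TRUE)@morphology, "Myoviridae")
    t4 <- assignNeckType(mkTable("Ad4"), "ph")
    expect_identical(inferMorphology(t4, FALSE)@morphology, "Podoviridae")
    # Type 3/4 with a sheath: still Podoviridae, plus a contradiction note
    t3 <- assignNeckType(mkTable(c("Ad3", "Hc3")), "ph")
    withSheath <- inferMorphology(t3, TRUE)
    expect_identical(withSheath@morphology, "Podoviridae")
    expect_match(withSheath@diagnostics, "contradiction", all = FALSE)
    un <- assignNeckType(mkTable("MCP"), "ph")
    expect_identical(inferMorphology(un, TRUE)@morphology, "undetermined")
})

test_that("tail-completion evidence never maps to Podoviridae", {
    set.seed(17)
    perType <- list("1" = c("Ad1", "Hc1", "Tc1", "Ne1", "gpW"),
                    "2" = c("Ad2", "Hc2", "Tc2"),
                    "3" = c("Ad3", "Hc3"), "4" = "Ad4")
    for (k in 1:60) {
        pool <- perType[[sample(names(perType), 1)]]
        sel <- sample(pool, sample(seq_along(pool), 1))
        a <- assignNeckType(mkTable(sel), "ph")
        a <- inferMorphology(a, hasSheath = FALSE)
        if (a@morphology == "Podoviridae")
            expect_false(any(a@evidence$class %in% c("Tc1", "Tc2")))
    }
})
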