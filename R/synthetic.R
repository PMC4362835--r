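#' Configuration of a synthetic phage universe
#'
#' The generator emulates the regime the detection and classification
#' stages are designed for: protein families with known class labels,
#' Type-specific neck gene arrangements (Ad1-Hc1-Ne1-Tc1 for Type 1,
#' consecutive Ad2-Hc2-Tc2 for Type 2, Ad3-x-Hc3 for Type 3, a lone Ad4
#' for Type 4) embedded among decoy genes, noisy probability/identity
#' hits, and planted phage clusters with block-structured similarity.
#'
#' Probability regimes (percents): within a family, same-cluster pairs
#' draw from \code{withinProb}; cross-cluster pairs from
#' \code{betweenClusterProb} (below every detection threshold, mirroring
#' the observation that between-cluster probabilities average below 50);
#' cross-family noise from \code{noiseProb}. Identities decay with
#' cluster distance: same cluster \code{identitySameCluster}, same Type
#' different cluster \code{identityCrossCluster}, otherwise
#' \code{identityCrossType} - the very-low-identity regime (10-20 percent)
#' typical of remote homology. \code{divergentFraction} of Type 1-3
#' phages carry one neck protein whose hits straddle the relaxed band
#' \code{divergentProb} (found only by the context-constrained pass);
#' \code{decoyHitFraction} of phages receive a threshold-straddling hit
#' onto a decoy placed at a non-canonical position, exercising the
#' context filter; \code{missingFraction} of phages have one neck protein
#' with no hits at all but a low-support profile (fewer than 5 aligned
#' sequences), exercising the manual-review flagging.
#'
#' @param nPhagesPerType named integer vector, phages per neck Type.
#' @param nClustersType1 planted cluster count K for Type 1.
#' @param decoyRange min/max decoy genes per genome.
#' @param gapProb probability of inserting one extra decoy between
#'   consecutive neck genes (0 = canonical arrangements exactly).
#' @param myoFraction fraction of Type 1 phages carrying a sheath
#'   (Myoviridae-like).
#' @param withinProb,betweenClusterProb,noiseProb,divergentProb,decoyProb
#'   two-element min/max vectors of uniform probability bands (percents).
#' @param identitySameCluster,identityCrossCluster,identityCrossType
#'   two-element min/max identity bands (percents).
#' @param divergentFraction,decoyHitFraction,missingFraction see above.
#' @param lowSupportFraction fraction of decoy profiles with fewer than 5
#'   aligned sequences.
#' @param nNoise number of cross-family noise hits.
#' @return a validated config list of class \code{"UniverseConfig"}.
#' @export
universeConfig <- function(nPhagesPerType = c("1" = 12L, "2" = 6L,
                                              "3" = 6L, "4" = 4L),
                           nClustersType1 = 3L,
                           decoyRange = c(8L, 20L),
                           gapProb = 0.1,
                           myoFraction = 0.3,
                           withinProb = c(92, 100),
                           betweenClusterProb = c(20, 50),
                           noiseProb = c(5, 50),
                           divergentProb = c(72, 89),
                           decoyProb = c(70, 89),
                           identitySameCluster = c(25, 60),
                           identityCrossCluster = c(10, 25),
                           identityCrossType = c(2, 10),
                           divergentFraction = 0.15,
                           decoyHitFraction = 0.1,
                           missingFraction = 0.05,
                           lowSupportFraction = 0.05,
                           nNoise = 50L) {
    cfg <- list(nPhagesPerType = nPhagesPerType,
                nClustersType1 = as.integer(nClustersType1),
                decoyRange = decoyRange, gapProb = gapProb,
                myoFraction = myoFraction, withinProb = withinProb,
                betweenClusterProb = betweenClusterProb,
                noiseProb = noiseProb, divergentProb = divergentProb,
                decoyProb = decoyProb,
                identitySameCluster = identitySameCluster,
                identityCrossCluster = identityCrossCluster,
                identityCrossType = identityCrossType,
                divergentFraction = divergentFraction,
                decoyHitFraction = decoyHitFraction,
                missingFraction = missingFraction,
                lowSupportFraction = lowSupportFraction,
                nNoise = as.integer(nNoise))
    bands <- c("withinProb", "betweenClusterProb", "noiseProb",
               "divergentProb", "decoyProb", "identitySameCluster",
               "identityCrossCluster", "identityCrossType")
    for (b in bands) {
        v <- cfg[[b]]
        if (length(v) != 2L || any(v < 0) || any(v > 100) || v[1L] > v[2L])
            stop(b, " must be a [min, max] band within [0, 100]")
    }
    if (cfg$nClustersType1 > cfg$nPhagesPerType[["1"]])
        stop("more Type 1 clusters than Type 1 phages")
    class(cfg) <- "UniverseConfig"
    cfg
}

# class-typical sequence lengths (residues); Ne1 spans 56-231, the wide
# size range characteristic of that superfamily
.classLength <- function(class) {
    switch(class,
        MCP = 320L, TermL = 450L, Portal = 500L, MTP = 200L,
        Sheath = 420L, Ad1 = 100L, Hc1 = 120L, Tc1 = 150L,
        Ne1 = sample(56:231, 1L), gpW = 68L, Ad2 = 280L, Hc2 = 260L,
        Tc2 = 270L, Ad3 = 300L, Hc3 = 470L, Ad4 = 310L,
        sample(80:400, 1L))
}

.randAA <- function(n) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
                 replace = TRUE), collapse = "")
}

.runifBand <- function(n, band) runif(n, band[1L], band[2L])

#' Generate a ground-truthed synthetic universe
#'
#' Deterministic for a given seed. Produces ordered genomes, a hit table
#' valid under the homology module's invariants, profile metadata, and
#' the ground truth (true class per protein; true Type and cluster per
#' phage). Within each protein family, non-divergent same-cluster members
#' are connected both by a probe chain rooted at the family's reference
#' seed and by a complete graph of within-band hits, so iterative
#' expansion from the default seed set recovers the family; cross-cluster
#' pairs sit below the detection thresholds and block-structure the
#' similarity matrix.
#'
#' @param config a [universeConfig()] list.
#' @param seed integer RNG seed (mandatory).
#' @return list with elements \code{genomes} (list of
#'   [PhageGenome-class]), \code{provider} ([HomologyProvider-class],
#'   symmetrized), \code{truth} (list: \code{proteins},
#'   \code{phages} data.frames), \code{config}.
#' @export
generateUniverse <- function(config = universeConfig(), seed) {
    if (missing(seed)) stop("an explicit seed is required")
    stopifnot(inherits(config, "UniverseConfig"))
    set.seed(seed)
    seedSet <- defaultSeedSet()

    genomes <- list()
    truthProteins <- list()
    truthPhages <- list()
    members <- list()    # class -> data.frame(protein_id, phage, cluster,
                         #                     type, divergent, missing)
    phageCounter <- 0L

    for (type in c(1L, 2L, 3L, 4L)) {
        nP <- config$nPhagesPerType[[as.character(type)]]
        if (is.null(nP) || nP == 0L) next
        K <- if (type == 1L) config$nClustersType1 else 1L
        clusterOf <- rep(seq_len(K), length.out = nP)
        for (p in seq_len(nP)) {
            phageCounter <- phageCounter + 1L
            ph <- sprintf("T%d_P%03d", type, phageCounter)
            cl <- clusterOf[p]
            hasSheath <- (type == 2L) ||
                (type == 1L && runif(1) < config$myoFraction)
            headClasses <- c("TermL", "Portal", "MCP")
            tailClasses <- c(if (type %in% c(1L, 2L)) "MTP",
                             if (hasSheath) "Sheath")
            neckClasses <- switch(as.character(type),
                "1" = c("Ad1", "Hc1", "Ne1", "Tc1"),
                "2" = c("Ad2", "Hc2", "Tc2"),
                "3" = c("Ad3", "x", "Hc3"),
                "4" = "Ad4")
            nDecoy <- sample(config$decoyRange[1L]:config$decoyRange[2L], 1L)
            # neck block with optional gap noise between consecutive genes
            block <- character()
            for (g in neckClasses) {
                if (length(block) && g != "x" &&
                    block[length(block)] != "x" &&
                    runif(1) < config$gapProb)
                    block <- c(block, "x")
                block <- c(block, g)
            }
            nUp <- max(1L, floor(nDecoy * 0.4))
            nMid <- max(1L, floor(nDecoy * 0.3))
            nDown <- max(0L, nDecoy - nUp - nMid)
            layout <- c(rep("x", nUp), headClasses, rep("x", nMid),
                        block, tailClasses, rep("x", nDown))

            divergentClass <- NA_character_
            missingClass <- NA_character_
            canon <- canonicalNeckClasses(type)
            if (type != 4L && runif(1) < config$divergentFraction)
                divergentClass <- sample(canon, 1L)
            if (type != 4L && is.na(divergentClass) &&
                runif(1) < config$missingFraction)
                missingClass <- sample(canon, 1L)

            seqs <- character(length(layout))
            ids <- character(length(layout))
            classes <- character(length(layout))
            for (i in seq_along(layout)) {
                g <- layout[i]
                ids[i] <- sprintf("%s_g%03d", ph, i)
                classes[i] <- if (g == "x") "decoy" else g
                seqs[i] <- .randAA(.classLength(g))
            }
            names(seqs) <- ids
            morph <- if (type %in% c(3L, 4L)) "Podoviridae"
                     else if (hasSheath) "Myoviridae" else "Siphoviridae"
            genomes[[ph]] <- makePhageGenome(ph, seqs,
                                             declaredMorphology = morph)
            truthProteins[[ph]] <- data.frame(
                protein_id = ids, class = classes, stringsAsFactors = FALSE)
            truthPhages[[ph]] <- data.frame(
                phage_id = ph, type = type, cluster = cl,
                has_sheath = hasSheath, stringsAsFactors = FALSE)
            for (i in seq_along(layout)) {
                g <- classes[i]
                if (g == "decoy") next
                members[[g]] <- rbind(members[[g]], data.frame(
                    protein_id = ids[i], phage = ph, cluster = cl,
                    type = type,
                    divergent = identical(g, divergentClass),
                    missing = identical(g, missingClass),
                    stringsAsFactors = FALSE))
            }
        }
    }

    hits <- list()
    seen <- new.env(parent = emptyenv())
    pairKey <- function(q, t) paste(min(q, t), max(q, t), sep = "\r")
    addHit <- function(q, t, p, idn) {
        assign(pairKey(q, t), TRUE, envir = seen)
        hits[[length(hits) + 1L]] <<- data.frame(
            query_id = q, target_id = t, probability = p, identity = idn,
            stringsAsFactors = FALSE)
    }
    havePair <- function(q, t) exists(pairKey(q, t), envir = seen)
    # reference seeds of one class are mutual homologs: chain them so every
    # shipped seed exists in the hit universe
    for (cls in names(seedSet@seeds)) {
        sds <- seedSet@seeds[[cls]]
        if (length(sds) > 1L)
            for (i in seq_len(length(sds) - 1L))
                addHit(sds[i], sds[i + 1L], 99, 40)
    }
    identFor <- function(a, b) {
        if (a$cluster == b$cluster && a$type == b$type)
            .runifBand(1L, config$identitySameCluster)
        else if (a$type == b$type)
            .runifBand(1L, config$identityCrossCluster)
        else
            .runifBand(1L, config$identityCrossType)
    }

    for (cls in names(members)) {
        fam <- members[[cls]]
        fam <- fam[!fam$missing, , drop = FALSE]
        if (!nrow(fam)) next
        famSeed <- seedSet@seeds[[cls]][1L]
        # seed-rooted chain through the non-divergent members of each
        # cluster group (cluster x type), so expansion needs iteration
        grp <- paste(fam$type, fam$cluster)
        for (g in unique(grp)) {
            sub <- fam[grp == g, , drop = FALSE]
            clean <- sub[!sub$divergent, , drop = FALSE]
            if (nrow(clean)) {
                chain <- c(famSeed, clean$protein_id)
                for (i in seq_len(length(chain) - 1L))
                    addHit(chain[i], chain[i + 1L],
                           .runifBand(1L, config$withinProb),
                           .runifBand(1L, config$identitySameCluster))
            }
            div <- sub[sub$divergent, , drop = FALSE]
            for (i in seq_len(nrow(div))) {
                anchor <- if (nrow(clean))
                    clean$protein_id[sample.int(nrow(clean), 1L)]
                    else famSeed
                addHit(anchor, div$protein_id[i],
                       .runifBand(1L, config$divergentProb),
                       .runifBand(1L, config$identitySameCluster))
            }
        }
        # complete within-family graph, vectorized: cluster-dependent bands
        if (nrow(fam) > 1L) {
            ij <- utils::combn(nrow(fam), 2L)
            i <- ij[1L, ]; j <- ij[2L, ]
            dup <- vapply(seq_along(i), function(k)
                havePair(fam$protein_id[i[k]], fam$protein_id[j[k]]), TRUE)
            i <- i[!dup]; j <- j[!dup]
            n <- length(i)
            if (n) {
                sameClu <- fam$cluster[i] == fam$cluster[j] &
                           fam$type[i] == fam$type[j]
                anyDiv <- fam$divergent[i] | fam$divergent[j]
                sameType <- fam$type[i] == fam$type[j]
                p <- numeric(n)
                p[sameClu & !anyDiv] <-
                    .runifBand(sum(sameClu & !anyDiv), config$withinProb)
                p[sameClu & anyDiv] <-
                    .runifBand(sum(sameClu & anyDiv), config$divergentProb)
                p[!sameClu] <-
                    .runifBand(sum(!sameClu), config$betweenClusterProb)
                idn <- numeric(n)
                idn[sameClu] <- .runifBand(sum(sameClu),
                                           config$identitySameCluster)
                idn[!sameClu & sameType] <-
                    .runifBand(sum(!sameClu & sameType),
                               config$identityCrossCluster)
                idn[!sameType] <- .runifBand(sum(!sameType),
                                             config$identityCrossType)
                hits[[length(hits) + 1L]] <- data.frame(
                    query_id = fam$protein_id[i],
                    target_id = fam$protein_id[j],
                    probability = p, identity = idn,
                    stringsAsFactors = FALSE)
            }
        }
    }

    # cross-family noise (never reaches the relaxed threshold band)
    allFam <- do.call(rbind, members)
    allFam <- allFam[!allFam$missing, , drop = FALSE]
    famOf <- setNames(rep(names(members),
                          vapply(members, nrow, 1L)),
                      unlist(lapply(members, `[[`, "protein_id")))
    if (nrow(allFam) > 1L) {
        for (k in seq_len(config$nNoise)) {
            ij <- sample.int(nrow(allFam), 2L)
            a <- allFam$protein_id[ij[1L]]
            b <- allFam$protein_id[ij[2L]]
            if (famOf[[a]] == famOf[[b]] || havePair(a, b)) next
            addHit(a, b, min(.runifBand(1L, config$noiseProb), 65),
                   .runifBand(1L, config$identityCrossType))
        }
    }

    # threshold-straddling decoy hits at non-canonical positions
    truthP <- do.call(rbind, truthProteins)
    rownames(truthP) <- NULL
    truthF <- do.call(rbind, truthPhages)
    rownames(truthF) <- NULL
    decoyTargets <- character()
    for (ph in names(genomes)) {
        if (runif(1) >= config$decoyHitFraction) next
        type <- truthF$type[truthF$phage_id == ph]
        if (type == 4L) next
        g <- genomes[[ph]]
        tp <- truthProteins[[ph]]
        neckRanks <- g@proteins$rank[tp$class %in% neckClassLabels()]
        farDecoys <- g@proteins$protein_id[
            tp$class == "decoy" &
            vapply(g@proteins$rank, function(r)
                all(abs(r - neckRanks) > 10L), TRUE)]
        if (!length(farDecoys)) next
        cls <- sample(canonicalNeckClasses(type), 1L)
        fam <- members[[cls]]
        fam <- fam[fam$phage != ph & !fam$missing, , drop = FALSE]
        if (!nrow(fam)) next
        tgt <- sample(farDecoys, 1L)
        addHit(fam$protein_id[sample.int(nrow(fam), 1L)], tgt,
               .runifBand(1L, config$decoyProb),
               .runifBand(1L, config$identityCrossType))
        decoyTargets <- c(decoyTargets, tgt)
    }

    # profile metadata: missing neck proteins get low-support profiles, as
    # does a background fraction of decoys
    mm <- do.call(rbind, members)
    lowIds <- mm$protein_id[mm$missing]
    decoys <- truthP$protein_id[truthP$class == "decoy"]
    lowDecoys <- decoys[runif(length(decoys)) < config$lowSupportFraction]
    support <- data.frame(
        profile_id = truthP$protein_id,
        n_aligned_sequences = sample(20:100, nrow(truthP), replace = TRUE),
        stringsAsFactors = FALSE)
    low <- support$profile_id %in% c(lowIds, lowDecoys)
    support$n_aligned_sequences[low] <-
        sample(1:4, sum(low), replace = TRUE)

    provider <- symmetrizeHits(
        makeHitProvider(do.call(rbind, hits), metadata = support))
    list(genomes = genomes, provider = provider,
         truth = list(proteins = truthP, phages = truthF,
                      decoy_hit_targets = decoyTargets),
         config = config)
}

#' Minimal worked-example fixtures: the six reference phages
#'
#' Six tiny genomes whose detected neck compositions equal the reference
#' compositions of the model phages: SPP1 (Ad1+Hc1+Tc1), lambda
#' (gpW+Hc1+Tc1, the gpW adaptor replacement at its canonical -6/-9
#' position), HK97 (Ad1+Hc1+Tc1), T4 (Ad2+Hc2+Tc2 plus sheath), P22
#' (Ad3+Hc3 two genes apart) and phi29 (Ad4 only). The accompanying hit
#' table links each protein to its class seed at fixed high confidence,
#' so the strict round plus the gpW rule reproduce the compositions
#' exactly. Fully deterministic (no RNG).
#'
#' @return list: \code{genomes} (named list of [PhageGenome-class]),
#'   \code{provider}, \code{truth} (data.frame phage_id, neck_type,
#'   morphology).
#' @export
generateWorkedExamples <- function() {
    seedSet <- defaultSeedSet()
    lay <- list(
        SPP1  = c("x", "TermL", "Portal", "MCP", "x", "Ad1", "Hc1", "x",
                  "Tc1", "MTP", "x"),
        lambda = c("x", "TermL", "Portal", "MCP", "gpW", "x", "x", "x",
                   "x", "x", "Hc1", "x", "x", "Tc1", "MTP", "x"),
        HK97  = c("TermL", "Portal", "MCP", "x", "x", "Ad1", "Hc1", "x",
                  "Tc1", "MTP"),
        T4    = c("x", "TermL", "Portal", "MCP", "x", "Ad2", "Hc2", "Tc2",
                  "MTP", "Sheath", "x"),
        P22   = c("TermL", "Portal", "MCP", "x", "Ad3", "x", "Hc3", "x"),
        phi29 = c("x", "Portal", "MCP", "x", "Ad4", "x")
    )
    aaFor <- function(class, i) {
        # deterministic pseudo-sequence: class-typical length, repeated motif
        n <- switch(class, Ne1 = 120L, x = 90L, .classLength(class))
        if (is.null(n)) n <- 100L
        paste(rep(strsplit("MKLAVEQSTG", "")[[1L]],
                  length.out = n), collapse = "")
    }
    genomes <- list()
    hits <- list()
    truth <- data.frame(
        phage_id = c("SPP1", "lambda", "HK97", "T4", "P22", "phi29"),
        neck_type = c(1L, 1L, 1L, 2L, 3L, 4L),
        morphology = c("Siphoviridae", "Siphoviridae", "Siphoviridae",
                       "Myoviridae", "Podoviridae", "Podoviridae"),
        stringsAsFactors = FALSE)
    for (cls in names(seedSet@seeds)) {
        sds <- seedSet@seeds[[cls]]
        if (length(sds) > 1L)
            for (i in seq_len(length(sds) - 1L))
                hits[[length(hits) + 1L]] <- data.frame(
                    query_id = sds[i], target_id = sds[i + 1L],
                    probability = 99, identity = 40,
                    stringsAsFactors = FALSE)
    }
    for (ph in names(lay)) {
        layout <- lay[[ph]]
        ids <- sprintf("%s_g%02d", ph, seq_along(layout))
        seqs <- vapply(seq_along(layout),
                       function(i) aaFor(layout[i], i), "")
        names(seqs) <- ids
        genomes[[ph]] <- makePhageGenome(ph, seqs)
        for (i in seq_along(layout)) {
            cls <- layout[i]
            if (cls == "x") next
            sd <- seedSet@seeds[[cls]][1L]
            p <- if (cls == "gpW") 96 else 98
            hits[[length(hits) + 1L]] <- data.frame(
                query_id = sd, target_id = ids[i], probability = p,
                identity = 30, stringsAsFactors = FALSE)
        }
    }
    provider <- symmetrizeHits(makeHitProvider(do.call(rbind, hits)))
    list(genomes = genomes, provider = provider, truth = truth)
}
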