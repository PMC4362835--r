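# Shared fixtures and independent oracles, built in code.

# a toy genome with given gene classes laid out in order; ids <phage>_gNN
toyGenome <- function(phage, n = 6L) {
    seqs <- vapply(seq_len(n), function(i)
        paste(rep("MKLAVE", 20L), collapse = ""), "")
    names(seqs) <- sprintf("%s_g%02d", phage, seq_len(n))
    makePhageGenome(phage, seqs)
}

# provider from compact rows: list(q, t, prob, ident) per hit
toyProvider <- function(..., symmetrize = TRUE) {
    rows <- list(...)
    h <- do.call(rbind, lapply(rows, function(r)
        data.frame(query_id = r[[1L]], target_id = r[[2L]],
                   probability = as.numeric(r[[3L]]),
                   identity = as.numeric(r[[4L]]),
                   stringsAsFactors = FALSE)))
    p <- makeHitProvider(h)
    if (symmetrize) symmetrizeHits(p) else p
}

# detection table straight from rows (phage, class, protein, prob)
toyDetections <- function(rows) {
    det <- do.call(rbind, lapply(rows, function(r)
        data.frame(phage_id = r[[1L]], class = r[[2L]],
                   protein_id = r[[3L]],
                   probability = as.numeric(r[[4L]]),
                   round = "strict90", chain = "",
                   stringsAsFactors = FALSE)))
    new("DetectionTable", detections = det, diagnostics = character())
}

# Independent oracle: brute-force transitive closure on the thresholded
# hit graph (repeated boolean matrix products until fixpoint).
closureOracle <- function(provider, seeds, threshold) {
    h <- hitTable(provider)
    ids <- sort(unique(c(h$query_id, h$target_id, seeds)))
    n <- length(ids)
    adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    keep <- h$probability >= threshold
    adj[cbind(match(h$query_id[keep], ids), match(h$target_id[keep], ids))] <- TRUE
    reached <- ids %in% seeds
    repeat {
        new <- reached | as.logical(reached %*% adj)
        if (identical(new, reached)) break
        reached <- new
    }
    sort(ids[reached])
}

# Independent oracle: naive WPGMA on a distance matrix. Returns merge
# heights (already halved) in merge order.
wpgmaOracle <- function(dmat) {
    labs <- rownames(dmat)
    active <- as.list(labs)
    d <- dmat
    heights <- numeric()
    while (length(active) > 1L) {
        n <- length(active)
        best <- c(NA, NA)
        bestd <- Inf
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            if (d[i, j] < bestd - 1e-12) {
                bestd <- d[i, j]; best <- c(i, j)
            }
        }
        i <- best[1L]; j <- best[2L]
        heights <- c(heights, bestd / 2)
        newrow <- (d[i, ] + d[j, ]) / 2      # weighted: simple average
        keep <- setdiff(seq_len(n), c(i, j))
        d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
                    c(newrow[keep], 0))
        active <- c(active[keep], list(c(active[[i]], active[[j]])))
        rownames(d2) <- colnames(d2) <- NULL
        d <- d2
    }
    heights
}

# block-structured similarity matrix with planted clusters
blockSimilarity <- function(K, sizePer = 4L, seed = 1L,
                            within = c(90, 100), between = c(20, 50)) {
    set.seed(seed)
    n <- K * sizePer
    ids <- sprintf("P%02d", seq_len(n))
    truth <- rep(seq_len(K), each = sizePer)
    s <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        band <- if (truth[i] == truth[j]) within else between
        s[i, j] <- s[j, i] <- runif(1, band[1L], band[2L])
    }
    diag(s) <- 110
    sim <- new("SimilarityMatrix", scores = s,
               shared = matrix(5L, n, n, dimnames = list(ids, ids)),
               components = allProteinClasses())
    list(sim = sim, truth = setNames(truth, ids))
}

# Adjusted Rand Index between two labelings (closed form over the
# contingency table) - independent of any clustering package
ariOracle <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    n <- comb2(sum(tab))
    exp_ij <- si * sj / n
    (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

smallUniverse <- function(seed = 11L, ...) {
    cfg <- universeConfig(...)
    generateUniverse(cfg, seed = seed)
}
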