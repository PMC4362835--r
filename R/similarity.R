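#' Similarity score of one shared module component
#'
#' \code{score = probability + 0.1 * identity}, both percents. The 0.1
#' weight keeps the identity term a tie-breaker: it only matters once the
#' homology probability saturates at 100, where remote-homology
#' probabilities stop discriminating; scores live in \[0, 110\].
#'
#' @param probability profile-profile probability, percent.
#' @param identity sequence identity, percent.
#' @return numeric score in \[0, 110\].
#' @export
#' @examples
#' componentScore(98, 20)  # 100
componentScore <- function(probability, identity) {
    stopifnot(all(probability >= 0 & probability <= 100),
              all(identity >= 0 & identity <= 100))
    probability + 0.1 * identity
}

# resolve a component-subset keyword to class labels
resolveComponents <- function(components) {
    if (is.character(components) && length(components) == 1L) {
        switch(components,
            "all" = allProteinClasses(),
            "portal" = "Portal",
            "mcp-terml-portal" = c("MCP", "TermL", "Portal"),
            components)
    } else as.character(components)
}

#' Mean module similarity between two phages
#'
#' For each module class detected in both phages (restricted to
#' \code{components}), scores the homology hit between the two phages'
#' proteins of that class via [componentScore()] - an absent hit
#' contributes probability 0 and identity 0 - and returns the mean over
#' shared classes. Classes detected in only one phage are ignored. A pair
#' sharing no class is reported as NA with zero shared components.
#'
#' @param a,b phage ids.
#' @param table a [DetectionTable-class].
#' @param provider a [HomologyProvider-class].
#' @param components component subset: \code{"all"}, \code{"portal"},
#'   \code{"mcp-terml-portal"}, or a character vector of class labels.
#' @return list with \code{score} (numeric, NA if nothing shared) and
#'   \code{shared} (integer count of shared components).
#' @export
phagePairSimilarity <- function(a, b, table, provider,
                                components = "all") {
    classes <- resolveComponents(components)
    det <- table@detections
    det <- det[det$round != "flagged" & det$class %in% classes, ,
               drop = FALSE]
    da <- det[det$phage_id == a, , drop = FALSE]
    db <- det[det$phage_id == b, , drop = FALSE]
    shared <- intersect(da$class, db$class)
    if (!length(shared))
        return(list(score = NA_real_, shared = 0L))
    scores <- vapply(shared, function(cl) {
        pa <- da$protein_id[da$class == cl][1L]
        pb <- db$protein_id[db$class == cl][1L]
        ev <- .pairEvidence(provider, pa, pb)
        componentScore(ev[["probability"]], ev[["identity"]])
    }, 0)
    list(score = mean(scores), shared = length(shared))
}

#' Build the N x N similarity matrix for a set of phages
#'
#' Systematic cross-comparison of all phages (normally the phages of one
#' neck Type): each cell holds the mean component score of the pair, the
#' diagonal the maximal score 110, and pairs sharing no component are NA
#' (with shared count 0). Rows/columns are ordered lexicographically by
#' phage id for determinism.
#'
#' @param phages character vector of phage ids (>= 2).
#' @param table a [DetectionTable-class].
#' @param provider a [HomologyProvider-class].
#' @inheritParams phagePairSimilarity
#' @return a [SimilarityMatrix-class].
#' @export
buildSimilarityMatrix <- function(phages, table, provider,
                                  components = "all") {
    phages <- sort(unique(phages))
    n <- length(phages)
    if (n < 2L) stop("need at least 2 phages")
    scores <- matrix(NA_real_, n, n, dimnames = list(phages, phages))
    sharedm <- matrix(0L, n, n, dimnames = list(phages, phages))
    diag(scores) <- 110
    det <- table@detections
    for (i in seq_len(n)) {
        ndet <- sum(det$phage_id == phages[i] & det$round != "flagged" &
                    det$class %in% resolveComponents(components))
        sharedm[i, i] <- as.integer(ndet)
    }
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            ps <- phagePairSimilarity(phages[i], phages[j], table,
                                      provider, components)
            scores[i, j] <- scores[j, i] <- ps$score
            sharedm[i, j] <- sharedm[j, i] <- ps$shared
        }
    }
    new("SimilarityMatrix", scores = scores, shared = sharedm,
        components = resolveComponents(components))
}

#' WPGMA tree over a similarity matrix
#'
#' Computes Euclidean distances between the rows of the similarity matrix
#' (each phage's vector of mean scores against all phages, diagonal
#' included by default) and clusters them with WPGMA linkage. Merge
#' heights are half the cluster distance, making the ultrametric property
#' explicit. Phages involved in NA cells (no shared components with some
#' other phage) are pruned first, sparsest first, with a message; ties in
#' the linkage are broken deterministically by the lexicographic input
#' order.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param includeDiagonal include the self-score column in the row vectors
#'   (default TRUE).
#' @return a [NeckDendrogram-class] (clusters not yet cut; see
#'   [cutClusters()]).
#' @export
wpgmaTree <- function(sim, includeDiagonal = TRUE) {
    s <- sim@scores
    pruned <- character()
    while (any(is.na(s)) && nrow(s) > 2L) {
        worst <- names(which.max(rowSums(is.na(s))))
        pruned <- c(pruned, worst)
        keep <- setdiff(rownames(s), worst)
        s <- s[keep, keep, drop = FALSE]
    }
    if (any(is.na(s)))
        stop("cannot cluster: remaining phages share no components")
    if (length(pruned))
        message("pruned before clustering (no shared components): ",
                paste(pruned, collapse = ", "))
    if (nrow(s) < 2L) stop("fewer than 2 phages left to cluster")
    feat <- s
    if (!includeDiagonal) diag(feat) <- NA
    d <- dist(if (includeDiagonal) feat else
              t(apply(feat, 1L, function(r) r[!is.na(r)])),
              method = "euclidean")
    hc <- hclust(d, method = "mcquitty")  # WPGMA linkage
    hc$height <- hc$height / 2
    new("NeckDendrogram", hclust = hc, labels = rownames(s),
        clusters = integer(), pruned = pruned)
}

#' Cut a dendrogram into clusters
#'
#' With \code{k} given, cuts into exactly \code{k} clusters (how the
#' reference classification's labeled cluster count is reproduced). With
#' \code{k = NULL}, the cut is placed in the largest gap between
#' consecutive merge heights - the de novo heuristic.
#'
#' @param dend a [NeckDendrogram-class].
#' @param k desired number of clusters, or NULL for the largest-gap
#'   heuristic.
#' @return the dendrogram with \code{clusterLabels()} filled in (integer
#'   labels, numbered by order of first appearance over the
#'   lexicographic leaf order).
#' @export
cutClusters <- function(dend, k = NULL) {
    hc <- dend@hclust
    n <- length(dend@labels)
    if (is.null(k)) {
        h <- hc$height
        if (length(h) < 2L) {
            k <- if (length(h) == 1L && h[1L] > 1e-9) 2L else 1L
        } else {
            k <- n - which.max(diff(h))
        }
    }
    raw <- cutree(hc, k = k)
    # renumber by first appearance for label stability
    first <- raw[sort(names(raw))]
    map <- setNames(seq_along(unique(first)), unique(first))
    lab <- map[as.character(raw)]
    names(lab) <- names(raw)
    dend@clusters <- as.integer(lab[dend@labels])
    names(dend@clusters) <- dend@labels
    dend
}

#' Place a query phage into an existing clustering
#'
#' Computes the query's mean similarity (same metric as the reference
#' matrix) to the members of each reference cluster and assigns the
#' cluster with the highest mean; ties go to the lowest cluster index
#' with a warning. A query sharing no component with any reference member
#' is unplaced (NA).
#'
#' @param query query phage id.
#' @param table a [DetectionTable-class] covering the query and the
#'   reference phages.
#' @param clusters named integer vector: reference phage id -> cluster.
#' @param provider a [HomologyProvider-class].
#' @inheritParams phagePairSimilarity
#' @return list: \code{cluster} (integer or NA), \code{means} (per-cluster
#'   mean similarity), \code{tied} (logical).
#' @export
assignCluster <- function(query, table, clusters, provider,
                          components = "all") {
    ks <- sort(unique(clusters))
    means <- vapply(ks, function(k) {
        members <- names(clusters)[clusters == k]
        ss <- vapply(members, function(m)
            phagePairSimilarity(query, m, table, provider,
                                components)$score, 0)
        if (all(is.na(ss))) NA_real_ else mean(ss, na.rm = TRUE)
    }, 0)
    names(means) <- as.character(ks)
    if (all(is.na(means)))
        return(list(cluster = NA_integer_, means = means, tied = FALSE))
    best <- max(means, na.rm = TRUE)
    winners <- ks[!is.na(means) & abs(means - best) < 1e-9]
    tied <- length(winners) > 1L
    if (tied)
        warning("query ", query, " equidistant to clusters ",
                paste(winners, collapse = ","), "; assigned the lowest")
    list(cluster = as.integer(min(winners)), means = means, tied = tied)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are height deltas so that leaf depth equals the merge
#' height (the ultrametric tree).
#'
#' @param dend a [NeckDendrogram-class].
#' @param path output file; NULL returns the Newick string.
#' @return the Newick string, invisibly if written to file.
#' @export
writeNewickTree <- function(dend, path = NULL) {
    phy <- ape::as.phylo(dend@hclust)
    txt <- ape::write.tree(phy)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Dump a similarity matrix (and shared counts) as TSV
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @export
writeSimilarityMatrix <- function(sim, path) {
    out <- data.frame(phage_id = rownames(sim@scores), sim@scores,
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
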