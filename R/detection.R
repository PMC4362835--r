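#' Construct a SeedSet
#'
#' @param seeds named list mapping class labels to character vectors of
#'   seed protein/profile ids.
#' @return a [SeedSet-class].
#' @export
makeSeedSet <- function(seeds) new("SeedSet", seeds = seeds)

#' The default reference seed set
#'
#' Mirrors the functionally characterized reference proteins of the model
#' phages: SPP1 gp15/gp16/gp17 and gp16.1 for the Type 1 neck classes,
#' lambda gpW for the adaptor-replacement class, T4 gp13/gp14/gp15 for
#' Type 2, P22 gp4/gp10 for Type 3, phi29 gp11 for Type 4, and
#' structure-characterized seeds for the head and tail classes (HK97 and
#' T4 capsids; SPP1, P22 and phi29 portals; SPP1 and T4 terminases; lambda
#' gpV plus T4 gp19 for the major tail protein; T4 gp18 plus phiKZ for the
#' sheath).
#'
#' @return a [SeedSet-class].
#' @export
#' @examples
#' defaultSeedSet()
defaultSeedSet <- function() {
    path <- system.file("extdata", "default_seeds.yaml",
                        package = "phageneck")
    loadSeedSet(path)
}

#' Load / save a seed set as YAML
#'
#' @param path YAML file mapping class labels to lists of seed ids.
#' @return [SeedSet-class] (load) or \code{path} invisibly (save).
#' @export
loadSeedSet <- function(path) {
    raw <- yaml::read_yaml(path)
    makeSeedSet(lapply(raw, function(x) as.character(unlist(x))))
}

#' @rdname loadSeedSet
#' @param seedSet a [SeedSet-class].
#' @export
saveSeedSet <- function(seedSet, path) {
    yaml::write_yaml(lapply(seedSet@seeds, as.list), path)
    invisible(path)
}

#' Iterative remote-homology expansion from seeds
#'
#' Breadth-first transitive closure over the hit graph, per class: seeds
#' are the initial probes; every protein hit at probability >=
#' \code{threshold} is accepted and queued as a new probe, until a fixed
#' point. Membership is a property of the thresholded hit graph, so the
#' result is independent of dequeue order; the recorded probability is the
#' maximum over all accepted probes that reached the protein, and the
#' chain records the probe path of first discovery.
#'
#' @param seedSet a [SeedSet-class].
#' @param provider a [HomologyProvider-class] (symmetrize first unless you
#'   deliberately want directed expansion).
#' @param threshold acceptance probability threshold, percent (default 90,
#'   the strict round).
#' @param classes class labels to expand; default all classes in the seed
#'   set.
#' @return named list: class -> data.frame(protein_id, probability, chain)
#'   including the seeds themselves (probability 100, empty chain).
#' @export
iterativeExpand <- function(seedSet, provider, threshold = 90,
                            classes = NULL) {
    stopifnot(is(seedSet, "SeedSet"), is(provider, "HomologyProvider"))
    if (!(threshold > 0 && threshold <= 100))
        stop("threshold must lie in (0, 100]")
    if (is.null(classes)) classes <- names(seedSet@seeds)
    universe <- .providerUniverse(provider)
    # pre-index hits by query: same contract as hitsFor (descending
    # probability, then target id), computed once for the whole expansion
    h <- provider@hits
    ord <- order(h$query_id, -h$probability, h$target_id)
    h <- h[ord, , drop = FALSE]
    idx <- split(seq_len(nrow(h)), h$query_id)
    out <- list()
    for (cl in classes) {
        seeds <- seedSet@seeds[[cl]]
        if (is.null(seeds))
            stop("class not in seed set: ", cl)
        present <- seeds %in% universe
        if (!all(present)) {
            warning("seed(s) absent from hit universe for class ", cl, ": ",
                    paste(seeds[!present], collapse = ", "))
            seeds <- seeds[present]
        }
        if (!length(seeds))
            stop("all seeds of class ", cl, " absent from hit universe")
        prob <- setNames(rep(100, length(seeds)), seeds)
        chain <- setNames(rep("", length(seeds)), seeds)
        queue <- seeds
        qi <- 1L
        while (qi <= length(queue)) {
            probe <- queue[qi]
            qi <- qi + 1L
            rows <- idx[[probe]]
            hh <- h[rows, , drop = FALSE]
            hh <- hh[hh$probability >= threshold, , drop = FALSE]
            for (k in seq_len(nrow(hh))) {
                t <- hh$target_id[k]
                p <- hh$probability[k]
                if (!t %in% names(prob)) {
                    prob[t] <- p
                    chain[t] <- if (nzchar(chain[probe]))
                        paste(chain[probe], probe, sep = ";") else probe
                    queue <- c(queue, t)
                } else if (p > prob[t] && !t %in% seeds) {
                    prob[t] <- p  # membership unchanged; report the best probe
                }
            }
        }
        ids <- sort(names(prob))
        out[[cl]] <- data.frame(protein_id = ids,
                                probability = unname(prob[ids]),
                                chain = unname(chain[ids]),
                                stringsAsFactors = FALSE)
    }
    out
}

#' Resolve cross-class claims into a DetectionTable
#'
#' Maps expanded proteins to their phages and applies two deterministic
#' rules: a protein claimed by two or more classes goes to the class whose
#' accepting probability is highest (tie: lexicographically first class
#' label, with a diagnostic); within one phage, if two or more proteins
#' claim the same neck class, the highest-probability one is kept and the
#' single-copy violation is logged. Seed proteins that belong to no input
#' genome are dropped.
#'
#' @param perClass output of [iterativeExpand()].
#' @param genomes list of [PhageGenome-class] objects.
#' @param round provenance label for accepted rows (default
#'   \code{"strict90"}).
#' @return a [DetectionTable-class].
#' @export
resolveClassConflicts <- function(perClass, genomes, round = "strict90") {
    phageOf <- .proteinPhageMap(genomes)
    rows <- do.call(rbind, lapply(names(perClass), function(cl) {
        d <- perClass[[cl]]
        d <- d[d$protein_id %in% names(phageOf), , drop = FALSE]
        if (!nrow(d)) return(NULL)
        new_detection_frame(
            phage_id = unname(phageOf[d$protein_id]), class = cl,
            protein_id = d$protein_id, probability = d$probability,
            round = round, chain = d$chain)
    }))
    diags <- character()
    if (is.null(rows) || !nrow(rows))
        return(new("DetectionTable"))

    # cross-class conflicts: one class per protein
    split_by_prot <- split(seq_len(nrow(rows)), rows$protein_id)
    keep <- logical(nrow(rows))
    for (idx in split_by_prot) {
        if (length(idx) == 1L) { keep[idx] <- TRUE; next }
        sub <- rows[idx, , drop = FALSE]
        best <- idx[order(-sub$probability, sub$class)][1L]
        keep[best] <- TRUE
        diags <- c(diags, sprintf(
            "cross-class conflict: %s claimed by {%s}; assigned %s (p=%.1f)",
            rows$protein_id[best], paste(sort(sub$class), collapse = ","),
            rows$class[best], rows$probability[best]))
    }
    rows <- rows[keep, , drop = FALSE]

    # single-copy control per (phage, class); logged only for neck classes
    key <- paste(rows$phage_id, rows$class, sep = "\r")
    if (anyDuplicated(key)) {
        for (k in unique(key[duplicated(key)])) {
            idx <- which(key == k)
            sub <- rows[idx, , drop = FALSE]
            if (sub$class[1L] %in% neckClassLabels())
                diags <- c(diags, sprintf(
                    "multiple %s in %s: {%s}; kept best",
                    sub$class[1L], sub$phage_id[1L],
                    paste(sub$protein_id, collapse = ",")))
        }
        ord <- order(key, -rows$probability, rows$protein_id)
        rows <- rows[ord, , drop = FALSE]
        rows <- rows[!duplicated(key[ord]), , drop = FALSE]
    }
    rows <- rows[order(rows$phage_id, rows$class), , drop = FALSE]
    rownames(rows) <- NULL
    new("DetectionTable", detections = rows, diagnostics = diags)
}

#' Run the strict detection round end to end
#'
#' Convenience wrapper: expand every class at the strict threshold and
#' resolve conflicts into a [DetectionTable-class]. The relaxed,
#' context-constrained round applies only to the neck classes and is run
#' separately (see [constrainedRelaxedSearch()]).
#'
#' @inheritParams iterativeExpand
#' @param genomes list of [PhageGenome-class] objects.
#' @return a [DetectionTable-class] with round \code{"strict90"}.
#' @export
strictDetection <- function(seedSet, provider, genomes, threshold = 90,
                            classes = NULL) {
    if (is.null(classes))
        classes <- setdiff(names(seedSet@seeds), c("gpW", "Ne1"))
    # classes whose seeds are all absent have no evidence in this corpus:
    # skip them rather than abort the run
    universe <- .providerUniverse(provider)
    present <- vapply(classes, function(cl)
        any(seedSet@seeds[[cl]] %in% universe), TRUE)
    if (any(!present))
        warning("class(es) without any seed in the hit universe skipped: ",
                paste(classes[!present], collapse = ", "))
    classes <- classes[present]
    if (!length(classes))
        return(new("DetectionTable"))
    perClass <- iterativeExpand(seedSet, provider, threshold = threshold,
                                classes = classes)
    resolveClassConflicts(perClass, genomes,
                          round = sprintf("strict%g", threshold))
}

#' Dump a DetectionTable to TSV
#' @param table a [DetectionTable-class].
#' @param path output path.
#' @export
writeDetectionTable <- function(table, path) {
    write.table(table@detections, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
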