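#' Pipeline run configuration
#'
#' @param strictThreshold strict detection probability, percent
#'   (default 90).
#' @param relaxedThreshold relaxed, context-constrained probability,
#'   percent (default 70; must be below strict).
#' @param gpwThreshold gpW adaptor-replacement confidence, percent
#'   (default 95).
#' @param components component subset for similarity scoring
#'   (\code{"all"}, \code{"portal"}, \code{"mcp-terml-portal"} or a
#'   character vector).
#' @param clustersPerType optional named list Type -> fixed cluster count
#'   (NULL entries use the largest-gap heuristic).
#' @param signedDistances enforce canonical pair orientation in the
#'   context filter (default TRUE).
#' @param seed integer seed recorded with the run.
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(strictThreshold = 90, relaxedThreshold = 70,
                      gpwThreshold = 95, components = "all",
                      clustersPerType = list(), signedDistances = TRUE,
                      seed = 1L) {
    if (!(relaxedThreshold > 0 && relaxedThreshold < strictThreshold &&
          strictThreshold <= 100))
        stop("need 0 < relaxedThreshold < strictThreshold <= 100")
    cfg <- list(strictThreshold = strictThreshold,
                relaxedThreshold = relaxedThreshold,
                gpwThreshold = gpwThreshold, components = components,
                clustersPerType = clustersPerType,
                signedDistances = signedDistances, seed = as.integer(seed))
    class(cfg) <- "RunConfig"
    cfg
}

# FNV-1a over the YAML form of the config; versions a reference bundle so
# build and classify cannot silently mix thresholds
.configHash <- function(config) {
    canon <- rapply(unclass(config), as.character, how = "replace")
    txt <- yaml::as.yaml(canon)
    h <- 0
    for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 1e9
    sprintf("%09.0f", h)
}

#' Detect the head-neck-tail module in a set of genomes
#'
#' The full detection cascade: strict iterative expansion for the head,
#' tail and canonical neck classes; per-Type distance models learned from
#' the strict neck detections; the relaxed context-constrained round; the
#' gpW adaptor-replacement rule; the Ne1 rule; low-support flagging.
#'
#' @param genomes list of [PhageGenome-class] objects.
#' @param provider a [HomologyProvider-class].
#' @param config a [runConfig()] list.
#' @param seedSet a [SeedSet-class] (default [defaultSeedSet()]).
#' @param models optional pre-learned list of [DistanceModel-class]
#'   objects named by Type; learned from the strict round when NULL.
#' @return list: \code{table} ([DetectionTable-class]), \code{models}
#'   (named list by Type), \code{flagged} (data.frame).
#' @export
detectModule <- function(genomes, provider, config = runConfig(),
                         seedSet = defaultSeedSet(), models = NULL) {
    table <- strictDetection(seedSet, provider, genomes,
                             threshold = config$strictThreshold)
    learn <- is.null(models)
    if (learn) models <- list()
    for (t in 1:3) {
        key <- as.character(t)
        if (learn) {
            m <- tryCatch(
                suppressWarnings(
                    learnDistanceModel(table, genomes, t)),
                error = function(e) NULL)
            if (is.null(m) || all(m@pairs$n == 0L)) next
            models[[key]] <- m
        }
        if (is.null(models[[key]])) next
        table <- constrainedRelaxedSearch(
            seedSet, provider, models[[key]], table, genomes,
            relaxedThreshold = config$relaxedThreshold,
            signed = config$signedDistances)
    }
    table <- detectGpW(seedSet, provider, table, genomes,
                       threshold = config$gpwThreshold)
    table <- detectNe1(seedSet, provider, table, genomes,
                       strictThreshold = config$strictThreshold,
                       relaxedThreshold = config$relaxedThreshold)
    flagged <- do.call(rbind, lapply(names(models), function(key)
        flagLowSupportCandidates(provider, models[[key]], table, genomes)))
    if (is.null(flagged))
        flagged <- data.frame(phage_id = character(), class = character(),
                              protein_id = character(),
                              n_aligned_sequences = integer(),
                              stringsAsFactors = FALSE)
    list(table = table, models = models, flagged = flagged)
}

#' Build a reference bundle from a corpus
#'
#' Runs the detection cascade on a corpus, assigns Types and morphologies,
#' and for every Type with at least two classified phages builds the
#' similarity matrix, the WPGMA tree and the cluster labels. The result
#' is the reference against which query phages are classified; it is
#' stamped with a hash of the configuration so mismatched thresholds are
#' caught at classify time.
#'
#' @inheritParams detectModule
#' @return a reference bundle: list with \code{config}, \code{hash},
#'   \code{table}, \code{models}, \code{assignments}, \code{flagged},
#'   \code{similarity}, \code{trees}, \code{clusters} (the last three
#'   named by Type).
#' @export
runBuildReference <- function(genomes, provider, config = runConfig(),
                              seedSet = defaultSeedSet()) {
    det <- detectModule(genomes, provider, config, seedSet)
    assignments <- assignmentTable(det$table)
    similarity <- list()
    trees <- list()
    clusters <- list()
    for (t in c("1", "2", "3", "4")) {
        ph <- assignments$phage_id[assignments$neck_type == t]
        if (length(ph) < 2L) next
        sim <- buildSimilarityMatrix(ph, det$table, provider,
                                     components = config$components)
        dend <- tryCatch(wpgmaTree(sim), error = function(e) NULL)
        if (is.null(dend)) next
        k <- config$clustersPerType[[t]]
        dend <- cutClusters(dend, k = if (is.null(k)) NULL else k)
        similarity[[t]] <- sim
        trees[[t]] <- dend
        clusters[[t]] <- clusterLabels(dend)
    }
    list(config = config, hash = .configHash(config), table = det$table,
         models = det$models, assignments = assignments,
         flagged = det$flagged, similarity = similarity, trees = trees,
         clusters = clusters)
}

#' Classify one query phage against a reference bundle
#'
#' Detects the query's head-neck-tail components (strict round, then the
#' relaxed round gated by the reference distance models, then the gpW and
#' Ne1 rules), assigns Type and morphology, emits inter-gene distance
#' warnings, places the query into the reference clustering of its Type,
#' and lists the nearest reference proteins per detected component.
#'
#' @param genome the query [PhageGenome-class].
#' @param provider a [HomologyProvider-class] covering the query's
#'   proteins (hits to seeds and/or reference proteins).
#' @param reference a bundle from [runBuildReference()].
#' @param seedSet a [SeedSet-class].
#' @return a report list: \code{status} ("classified" or "no_neck"),
#'   \code{assignment} ([NeckAssignment-class]), \code{gene_map}
#'   (data.frame rank/protein/class), \code{warnings}, \code{cluster}
#'   (integer or NA), \code{cluster_means}, \code{tree_newick} (reference
#'   tree of the query's Type), \code{nearest} (data.frame of closest
#'   reference proteins).
#' @export
runClassify <- function(genome, provider, reference,
                        seedSet = defaultSeedSet()) {
    config <- reference$config
    if (!identical(.configHash(config), reference$hash))
        stop("reference bundle hash mismatch: bundle was edited or built ",
             "with a different configuration")
    det <- detectModule(list(genome), provider, config, seedSet,
                        models = reference$models)
    table <- det$table
    ph <- phageId(genome)
    a <- assignNeckType(table, ph)
    sub <- table@detections[table@detections$phage_id == ph &
                            table@detections$round != "flagged", ,
                            drop = FALSE]
    a <- inferMorphology(a, any(sub$class == "Sheath"))

    geneMap <- proteinTable(genome)[, c("rank", "protein_id")]
    geneMap$class <- NA_character_
    idx <- match(sub$protein_id, geneMap$protein_id)
    geneMap$class[idx] <- sub$class

    warn <- character()
    t <- a@neckType
    tkey <- if (t == "type1_like") "1" else t
    if (tkey %in% names(reference$models))
        warn <- distanceWarnings(table, genome, reference$models[[tkey]])

    cluster <- NA_integer_
    clusterMeans <- NULL
    tied <- FALSE
    treeNewick <- NA_character_
    if (t %in% c("1", "2", "3", "4") && tkey %in% names(reference$clusters)) {
        refDet <- reference$table@detections
        refDet <- refDet[refDet$phage_id != ph, , drop = FALSE]
        combined <- new("DetectionTable",
                        detections = rbind(refDet, table@detections),
                        diagnostics = character())
        placed <- assignCluster(ph, combined, reference$clusters[[tkey]],
                                provider, components = config$components)
        cluster <- placed$cluster
        clusterMeans <- placed$means
        tied <- placed$tied
        treeNewick <- writeNewickTree(reference$trees[[tkey]])
    }

    refProteins <- unique(reference$table@detections$protein_id)
    nearest <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        hh <- hitsFor(provider, sub$protein_id[i])
        hh <- hh[hh$target_id %in% refProteins, , drop = FALSE]
        hh <- head(hh, 3L)
        if (!nrow(hh)) return(NULL)
        data.frame(query_protein = sub$protein_id[i], class = sub$class[i],
                   reference_protein = hh$target_id,
                   probability = hh$probability, identity = hh$identity,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(nearest))
        nearest <- data.frame(query_protein = character(),
                              class = character(),
                              reference_protein = character(),
                              probability = numeric(),
                              identity = numeric(),
                              stringsAsFactors = FALSE)

    hasNeck <- any(sub$class %in% neckClassLabels())
    list(status = if (hasNeck) "classified" else "no_neck",
         assignment = a, gene_map = geneMap, warnings = warn,
         cluster = cluster, cluster_means = clusterMeans, tied = tied,
         tree_newick = treeNewick, nearest = nearest,
         diagnostics = table@diagnostics)
}

#' Save / load a reference bundle as a plain-text directory
#'
#' Everything is serialized as TSV/YAML/Newick so bundles are diffable
#' and portable; \code{loadReferenceBundle} restores a bundle usable by
#' [runClassify()] (similarity matrices and trees are reloaded from their
#' dumps).
#'
#' @param reference a bundle from [runBuildReference()].
#' @param dir target directory (created if needed).
#' @return \code{dir} (save) / the bundle list (load).
#' @export
saveReferenceBundle <- function(reference, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(c(unclass(reference$config),
                       list(hash = reference$hash)),
                     file.path(dir, "config.yaml"))
    writeDetectionTable(reference$table, file.path(dir, "detections.tsv"))
    writeLines(reference$table@diagnostics,
               file.path(dir, "diagnostics.txt"))
    write.table(reference$assignments, file.path(dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(reference$flagged, file.path(dir, "flagged.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (t in names(reference$models))
        saveDistanceModel(reference$models[[t]],
                          file.path(dir, sprintf("model_type%s.yaml", t)))
    clRows <- list()
    for (t in names(reference$trees)) {
        writeSimilarityMatrix(reference$similarity[[t]],
                              file.path(dir, sprintf("sim_type%s.tsv", t)))
        writeNewickTree(reference$trees[[t]],
                        file.path(dir, sprintf("tree_type%s.nwk", t)))
        cl <- reference$clusters[[t]]
        clRows[[t]] <- data.frame(neck_type = t, phage_id = names(cl),
                                  cluster = unname(cl),
                                  stringsAsFactors = FALSE)
    }
    clTab <- if (length(clRows)) do.call(rbind, clRows) else
        data.frame(neck_type = character(), phage_id = character(),
                   cluster = integer(), stringsAsFactors = FALSE)
    write.table(clTab, file.path(dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname saveReferenceBundle
#' @export
loadReferenceBundle <- function(dir) {
    raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
    hash <- raw$hash
    raw$hash <- NULL
    config <- do.call(runConfig, raw)
    det <- read.delim(file.path(dir, "detections.tsv"),
                      stringsAsFactors = FALSE,
                      colClasses = c(chain = "character"))
    det$chain[is.na(det$chain)] <- ""
    diags <- readLines(file.path(dir, "diagnostics.txt"), warn = FALSE)
    table <- new("DetectionTable", detections = det, diagnostics = diags)
    assignments <- read.delim(
        file.path(dir, "assignments.tsv"), stringsAsFactors = FALSE,
        colClasses = c(neck_type = "character", evidence = "character",
                       diagnostics = "character"))
    assignments$diagnostics[is.na(assignments$diagnostics)] <- ""
    flagged <- read.delim(file.path(dir, "flagged.tsv"),
                          stringsAsFactors = FALSE)
    models <- list()
    for (f in list.files(dir, pattern = "^model_type[0-9]+\\.yaml$")) {
        t <- sub("^model_type([0-9]+)\\.yaml$", "\\1", f)
        models[[t]] <- loadDistanceModel(file.path(dir, f))
    }
    clTab <- read.delim(file.path(dir, "clusters.tsv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(neck_type = "character"))
    clusters <- list()
    trees <- list()
    similarity <- list()
    for (t in unique(clTab$neck_type)) {
        sub <- clTab[clTab$neck_type == t, , drop = FALSE]
        clusters[[t]] <- setNames(as.integer(sub$cluster), sub$phage_id)
        simTab <- read.delim(file.path(dir, sprintf("sim_type%s.tsv", t)),
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
        m <- as.matrix(simTab[, -1L, drop = FALSE])
        rownames(m) <- simTab$phage_id
        shared <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
        shared[is.na(m)] <- 0L
        sim <- new("SimilarityMatrix", scores = m, shared = shared,
                   components = resolveComponents(config$components))
        similarity[[t]] <- sim
        dend <- tryCatch(cutClusters(wpgmaTree(sim),
                                     k = length(unique(sub$cluster))),
                         error = function(e) NULL)
        if (!is.null(dend)) trees[[t]] <- dend
    }
    list(config = config, hash = hash, table = table, models = models,
         assignments = assignments, flagged = flagged,
         similarity = similarity, trees = trees, clusters = clusters)
}
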