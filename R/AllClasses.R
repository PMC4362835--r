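#' @import methods
#' @importFrom utils read.delim write.table head
NULL

#' PhageGenome: an ordered phage proteome
#'
#' Container for the protein complement of one phage genome. The defining
#' property is gene order: protein \code{i} in the input FASTA receives rank
#' \code{i} (1-based), and all gene-context reasoning in the package is
#' arithmetic on these ranks. Distances are measured in gene-rank units,
#' never in base pairs, and genomes are treated as linear gene lists.
#'
#' @slot phageId single string identifying the phage.
#' @slot name human-readable name (defaults to \code{phageId}).
#' @slot proteins \code{data.frame} with columns \code{protein_id},
#'   \code{rank}, \code{length}, \code{description}; rows sorted by rank.
#' @slot sequences \code{AAStringSet} named by \code{protein_id}, in rank
#'   order.
#' @slot declaredMorphology optional prior annotation, one of
#'   \code{"Siphoviridae"}, \code{"Myoviridae"}, \code{"Podoviridae"},
#'   \code{"unclassified"}.
#'
#' @seealso [readOrderedProteome()], [intergeneDistance()]
#' @exportClass PhageGenome
setClass("PhageGenome",
    representation(
        phageId = "character",
        name = "character",
        proteins = "data.frame",
        sequences = "ANY",
        declaredMorphology = "character"
    ),
    prototype(declaredMorphology = "unclassified")
)

setValidity("PhageGenome", function(object) {
    p <- object@proteins
    msgs <- character()
    if (length(object@phageId) != 1L || !nzchar(object@phageId))
        msgs <- c(msgs, "phageId must be a single non-empty string")
    if (nrow(p) < 1L)
        msgs <- c(msgs, "a genome must contain at least one protein")
    needed <- c("protein_id", "rank", "length", "description")
    if (!all(needed %in% names(p)))
        return(paste("proteins must have columns:", paste(needed, collapse = ", ")))
    if (anyDuplicated(p$protein_id))
        msgs <- c(msgs, "protein_ids within a genome must be unique")
    if (nrow(p) > 0L && !identical(as.integer(p$rank), seq_len(nrow(p))))
        msgs <- c(msgs, "ranks must be consecutive 1..n in row order")
    if (any(p$length <= 0L))
        msgs <- c(msgs, "all sequences must be non-empty")
    if (!is.null(object@sequences)) {
        if (length(object@sequences) != nrow(p))
            msgs <- c(msgs, "sequences and protein table disagree in length")
        else if (!identical(names(object@sequences), p$protein_id))
            msgs <- c(msgs, "sequence names must equal protein_ids in rank order")
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' HomologyProvider: indexed profile-profile comparison evidence
#'
#' The single gateway through which detection and scoring see similarity
#' evidence. Stores hits as (query, target, probability, identity) with
#' probabilities and identities on the percent scale 0-100 (matching the
#' thresholds 90/70/95 used throughout), plus optional per-profile metadata
#' carrying the number of sequences in each profile's source alignment
#' (used only for low-support flagging).
#'
#' @slot hits \code{data.frame} with columns \code{query_id},
#'   \code{target_id}, \code{probability}, \code{identity},
#'   \code{identity_missing} (logical flag for hits whose report carried no
#'   identity; such hits score identity 0 but stay flagged).
#' @slot metadata \code{data.frame} with columns \code{profile_id},
#'   \code{n_aligned_sequences}.
#' @slot symmetrized logical; TRUE after [symmetrizeHits()].
#'
#' @exportClass HomologyProvider
setClass("HomologyProvider",
    representation(
        hits = "data.frame",
        metadata = "data.frame",
        symmetrized = "logical"
    ),
    prototype(
        metadata = data.frame(profile_id = character(),
                              n_aligned_sequences = integer()),
        symmetrized = FALSE
    )
)

setValidity("HomologyProvider", function(object) {
    h <- object@hits
    needed <- c("query_id", "target_id", "probability", "identity",
                "identity_missing")
    if (!all(needed %in% names(h)))
        return(paste("hits must have columns:", paste(needed, collapse = ", ")))
    if (nrow(h) && any(h$probability < 0 | h$probability > 100))
        return("probabilities must lie in [0, 100]")
    if (nrow(h) && any(h$identity < 0 | h$identity > 100))
        return("identities must lie in [0, 100]")
    if (nrow(h) && any(h$query_id == h$target_id))
        return("self-hits must be filtered out")
    m <- object@metadata
    if (nrow(m) && any(m$n_aligned_sequences < 1L))
        return("n_aligned_sequences must be >= 1")
    TRUE
})

#' SeedSet: reference probes per protein class
#'
#' Maps each protein class of the head-neck-tail module to the identifiers
#' of its functionally characterized reference proteins, the starting
#' probes of iterative expansion. The shipped default mirrors the classical
#' model phages: SPP1 gp15/gp16/gp17 for the Type 1 adaptor, head-closure
#' and tail-completion classes (and gp16.1 for Ne1), T4 gp13/gp14/gp15 for
#' Type 2, P22 gp4/gp10 for Type 3, phi29 gp11 for Type 4, lambda gpW for
#' the adaptor-replacement class, and structure-based seeds for the head
#' and tail classes.
#'
#' @slot seeds named list: class label -> character vector of seed ids.
#' @exportClass SeedSet
setClass("SeedSet", representation(seeds = "list"))

setValidity("SeedSet", function(object) {
    s <- object@seeds
    if (!length(s) || is.null(names(s)) || any(!nzchar(names(s))))
        return("seeds must be a non-empty named list")
    if (any(vapply(s, length, 1L) < 1L))
        return("every class must have at least one seed")
    ids <- unlist(s, use.names = FALSE)
    if (anyDuplicated(ids))
        return("a protein id may seed at most one class")
    bad <- setdiff(names(s), allProteinClasses())
    if (length(bad))
        return(paste("unknown class label(s):", paste(bad, collapse = ", ")))
    TRUE
})

#' DetectionTable: accepted detections with provenance
#'
#' One row per accepted (phage, class) pair: the winning protein, the
#' probability of the accepting hit, the round that accepted it
#' (\code{"strict90"}, \code{"relaxed70"}, \code{"gpW"}, \code{"ne1"} or
#' \code{"flagged"}), and the probe chain that reached it. Flagged rows are
#' candidates surfaced for human review only; they never count as evidence.
#'
#' @slot detections \code{data.frame} with columns \code{phage_id},
#'   \code{class}, \code{protein_id}, \code{probability}, \code{round},
#'   \code{chain}.
#' @slot diagnostics character vector of logged rule decisions (conflicts,
#'   single-copy violations, rejected candidates).
#' @exportClass DetectionTable
setClass("DetectionTable",
    representation(detections = "data.frame", diagnostics = "character"),
    prototype(
        detections = data.frame(
            phage_id = character(), class = character(),
            protein_id = character(), probability = numeric(),
            round = character(), chain = character(),
            stringsAsFactors = FALSE),
        diagnostics = character()
    )
)

setValidity("DetectionTable", function(object) {
    d <- object@detections
    needed <- c("phage_id", "class", "protein_id", "probability", "round",
                "chain")
    if (!all(needed %in% names(d)))
        return(paste("detections must have columns:",
                     paste(needed, collapse = ", ")))
    acc <- d[d$round != "flagged", , drop = FALSE]
    neck <- acc[acc$class %in% neckClassLabels(), , drop = FALSE]
    if (nrow(neck) &&
        anyDuplicated(neck[, c("phage_id", "class")]))
        return("single-copy invariant violated: >1 accepted protein for a neck class in one phage")
    TRUE
})

#' DistanceModel: inter-gene distance statistics for one neck Type
#'
#' For each ordered pair of neck classes of one Type, the mean and standard
#' deviation of the signed rank distance observed across strictly detected
#' genomes, and the tolerated distance mean + 2*sd that gates the relaxed
#' search. Tolerated values are kept real-valued; no rounding is applied.
#'
#' @slot neckType integer in 1..4.
#' @slot pairs \code{data.frame} with columns \code{class_a},
#'   \code{class_b}, \code{mean}, \code{sd}, \code{tolerated}, \code{n}
#'   (pairs with \code{n == 0} are unavailable and skipped as constraints).
#' @exportClass DistanceModel
setClass("DistanceModel",
    representation(neckType = "integer", pairs = "data.frame"))

setValidity("DistanceModel", function(object) {
    if (!(object@neckType %in% 1:4))
        return("neckType must be 1, 2, 3 or 4")
    p <- object@pairs
    needed <- c("class_a", "class_b", "mean", "sd", "tolerated", "n")
    if (!all(needed %in% names(p)))
        return(paste("pairs must have columns:", paste(needed, collapse = ", ")))
    obs <- p[p$n > 0L, , drop = FALSE]
    if (nrow(obs) && any(obs$sd < 0))
        return("sd must be non-negative")
    if (nrow(obs) && any(obs$tolerated < obs$mean - 1e-9))
        return("tolerated must be >= mean")
    TRUE
})

#' NeckAssignment: Type, morphology and completeness of one phage
#'
#' @slot phageId string.
#' @slot neckType one of \code{"1"}, \code{"2"}, \code{"3"}, \code{"4"},
#'   \code{"type1_like"}, \code{"unassigned"}.
#' @slot evidence \code{data.frame} (class, protein_id, probability) of the
#'   neck detections supporting the call.
#' @slot morphology one of \code{"Siphoviridae"}, \code{"Myoviridae"},
#'   \code{"Podoviridae"}, \code{"undetermined"}.
#' @slot completeness fraction of the Type's expected neck classes that
#'   were detected (Ne1 counts toward Type 1 completeness display).
#' @slot diagnostics character vector (ties, contradictions).
#' @exportClass NeckAssignment
setClass("NeckAssignment",
    representation(
        phageId = "character", neckType = "character",
        evidence = "data.frame", morphology = "character",
        completeness = "numeric", diagnostics = "character"),
    prototype(morphology = "undetermined", diagnostics = character())
)

#' SimilarityMatrix: averaged module scores between phages
#'
#' Symmetric matrix of mean per-component similarity scores between phages
#' of one Type, together with the per-cell count of module components
#' shared by the pair. Cells for pairs sharing zero components are NA
#' (explicitly distinct from a true score of 0); the diagonal is the
#' maximal score 110.
#'
#' @slot scores numeric N x N matrix, dimnames = phage ids.
#' @slot shared integer N x N matrix of shared-component counts.
#' @slot components character vector of the class labels scored.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(scores = "matrix", shared = "matrix",
                   components = "character"))

setValidity("SimilarityMatrix", function(object) {
    s <- object@scores
    if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE, tolerance = 1e-9)))
        return("score matrix must be symmetric")
    if (any(abs(diag(s) - 110) > 1e-9))
        return("diagonal must equal the maximal score 110")
    ok <- !is.na(s)
    if (any(s[ok] < 0 | s[ok] > 110))
        return("scores must lie in [0, 110]")
    if (any(is.na(s) & object@shared > 0L))
        return("NA cells must correspond to zero shared components")
    TRUE
})

#' NeckDendrogram: WPGMA tree over a similarity matrix
#'
#' Binary merge tree over the phages of one Type, built by WPGMA linkage on
#' Euclidean distances between similarity-matrix rows. Merge heights are
#' half the cluster distance, so they are non-decreasing (ultrametric).
#'
#' @slot hclust the underlying \code{hclust} object (heights already
#'   halved).
#' @slot labels leaf labels (phage ids), lexicographically ordered input.
#' @slot clusters integer cluster label per leaf after cutting, named by
#'   phage id.
#' @slot pruned phage ids removed before clustering because they shared no
#'   components with some other phage.
#' @exportClass NeckDendrogram
setClass("NeckDendrogram",
    representation(hclust = "ANY", labels = "character",
                   clusters = "integer", pruned = "character"),
    prototype(pruned = character())
)
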