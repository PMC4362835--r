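# Class vocabulary of the head-neck-tail module.
# Nine superfamilies: MCP + TermL (head), Portal + Ad + Hc + Tc + Ne (neck),
# MTP + Sheath (tail); Ad/Hc/Tc are refined into Type-specific subclasses,
# and gpW is the adaptor-replacement class occupying the Ad1 slot.

#' Protein class labels of the head-neck-tail module
#'
#' @return character vector of every class label the package recognises.
#' @export
#' @examples
#' allProteinClasses()
allProteinClasses <- function() {
    c(headTailClassLabels(), neckClassLabels())
}

#' @rdname allProteinClasses
#' @export
headTailClassLabels <- function() {
    c("MCP", "TermL", "Portal", "MTP", "Sheath")
}

#' @rdname allProteinClasses
#' @export
neckClassLabels <- function() {
    c("Ad1", "Hc1", "Tc1", "Ne1", "gpW",
      "Ad2", "Hc2", "Tc2", "Ad3", "Hc3", "Ad4")
}

#' Canonical neck classes of one Type, in genome order
#'
#' The canonical gene orderings are Ad1-Hc1-x-Tc1 (Type 1, the x most often
#' being Ne1), Ad2-Hc2-Tc2 (Type 2, consecutive), Ad3-x-Hc3 (Type 3) and a
#' lone Ad4 (Type 4). Ne1 and gpW are handled by dedicated rules and are
#' not part of the canonical pair set used for distance learning.
#'
#' @param neckType integer 1..4.
#' @return character vector of class labels in canonical genome order.
#' @export
#' @examples
#' canonicalNeckClasses(1)
canonicalNeckClasses <- function(neckType) {
    switch(as.character(neckType),
        "1" = c("Ad1", "Hc1", "Tc1"),
        "2" = c("Ad2", "Hc2", "Tc2"),
        "3" = c("Ad3", "Hc3"),
        "4" = "Ad4",
        stop("neckType must be 1, 2, 3 or 4"))
}

# Classes counted as Type evidence (gpW occupies the Ad1 slot for Type 1).
typeEvidenceClasses <- function(neckType) {
    switch(as.character(neckType),
        "1" = list(list("Ad1", "gpW"), list("Hc1"), list("Tc1")),
        "2" = list(list("Ad2"), list("Hc2"), list("Tc2")),
        "3" = list(list("Ad3"), list("Hc3")),
        "4" = list(list("Ad4")),
        stop("neckType must be 1, 2, 3 or 4"))
}

# Which Type a neck class belongs to; Ne1/gpW map to Type 1.
classNeckType <- function(class) {
    map <- c(Ad1 = 1L, Hc1 = 1L, Tc1 = 1L, Ne1 = 1L, gpW = 1L,
             Ad2 = 2L, Hc2 = 2L, Tc2 = 2L, Ad3 = 3L, Hc3 = 3L, Ad4 = 4L)
    unname(map[class])
}

new_detection_frame <- function(phage_id = character(), class = character(),
                                protein_id = character(),
                                probability = numeric(),
                                round = character(), chain = character()) {
    data.frame(phage_id = phage_id, class = class, protein_id = protein_id,
               probability = probability, round = round, chain = chain,
               stringsAsFactors = FALSE)
}

#' @describeIn DetectionTable-class accessor for the detection data frame.
#' @param object a \code{DetectionTable}.
#' @export
detections <- function(object) {
    stopifnot(is(object, "DetectionTable"))
    object@detections
}

#' @describeIn DetectionTable-class accessor for logged diagnostics.
#' @export
diagnostics <- function(object) {
    stopifnot(is(object, "DetectionTable"))
    object@diagnostics
}

#' @describeIn PhageGenome-class accessor for the phage identifier.
#' @param object a \code{PhageGenome}.
#' @export
phageId <- function(object) object@phageId

#' @describeIn PhageGenome-class accessor for the ordered protein table.
#' @export
proteinTable <- function(object) object@proteins

#' @describeIn HomologyProvider-class accessor for the raw hit table.
#' @param object a \code{HomologyProvider}.
#' @export
hitTable <- function(object) object@hits

#' @describeIn SimilarityMatrix-class accessor for the score matrix.
#' @param object a \code{SimilarityMatrix}.
#' @export
scoreMatrix <- function(object) object@scores

#' @describeIn SimilarityMatrix-class accessor for shared-component counts.
#' @export
sharedComponents <- function(object) object@shared

#' @describeIn NeckDendrogram-class cluster labels per leaf.
#' @param object a \code{NeckDendrogram}.
#' @export
clusterLabels <- function(object) object@clusters

setMethod("show", "PhageGenome", function(object) {
    cat("PhageGenome", object@phageId,
        sprintf("(%s)", object@name), "\n")
    cat(" ", nrow(object@proteins), "proteins, ranks 1..",
        nrow(object@proteins), "\n")
    cat("  declared morphology:", object@declaredMorphology, "\n")
})

setMethod("show", "HomologyProvider", function(object) {
    cat("HomologyProvider:", nrow(object@hits), "hits,",
        length(unique(object@hits$query_id)), "query profiles",
        if (object@symmetrized) "(symmetrized)" else "(raw)", "\n")
})

setMethod("show", "DetectionTable", function(object) {
    d <- object@detections
    cat("DetectionTable:", nrow(d), "entries over",
        length(unique(d$phage_id)), "phages\n")
    if (nrow(d)) {
        tab <- table(d$round)
        cat("  rounds:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
    if (length(object@diagnostics))
        cat(" ", length(object@diagnostics), "diagnostics logged\n")
})

setMethod("show", "DistanceModel", function(object) {
    cat("DistanceModel for neck Type", object@neckType, "\n")
    print(object@pairs, row.names = FALSE)
})

setMethod("show", "NeckAssignment", function(object) {
    cat("NeckAssignment:", object@phageId, "-> Type", object@neckType,
        sprintf("(%s, completeness %.2f)\n", object@morphology,
                object@completeness))
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat("SimilarityMatrix:", nrow(object@scores), "phages, components:",
        paste(object@components, collapse = ", "), "\n")
})

setMethod("show", "NeckDendrogram", function(object) {
    cat("NeckDendrogram:", length(object@labels), "leaves,",
        length(unique(object@clusters)), "clusters\n")
    if (length(object@pruned))
        cat("  pruned (no shared components):",
            paste(object@pruned, collapse = ", "), "\n")
})
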