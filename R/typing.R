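#' Assign a neck Type to one phage
#'
#' The Type is chosen by which Type-specific neck classes are present
#' among the accepted detections (gpW occupies the Ad1 slot for evidence
#' counting). A Type 1 or 2 call requires at least two detected
#' head-to-tail connection proteins; Types 3 and 4 require one. A phage
#' with a single Type 1 component is reported as \code{"type1_like"}:
#' recognizable but too sparse to cluster. When classes of two or more
#' Types co-occur the majority wins; a tie yields \code{"unassigned"} with
#' a diagnostic (the precedence is a package choice - the situation never
#' arises in canonical data). Ne1 counts toward Type 1 completeness
#' display but not toward the two-protein minimum.
#'
#' @param table a [DetectionTable-class].
#' @param phage phage id to assign.
#' @return a [NeckAssignment-class] (morphology still
#'   \code{"undetermined"}; see [inferMorphology()]).
#' @export
#' @examples
#' d <- new("DetectionTable", detections = data.frame(
#'     phage_id = "SPP1", class = c("Ad1", "Hc1", "Tc1"),
#'     protein_id = c("a", "b", "c"), probability = 99,
#'     round = "strict90", chain = ""), diagnostics = character())
#' assignNeckType(d, "SPP1")
assignNeckType <- function(table, phage) {
    det <- table@detections
    sub <- det[det$phage_id == phage & det$round != "flagged", , drop = FALSE]
    neck <- sub[sub$class %in% neckClassLabels(), , drop = FALSE]
    diags <- character()

    # count occupied evidence slots per Type (gpW fills the Ad1 slot)
    counts <- vapply(1:4, function(t) {
        slots <- typeEvidenceClasses(t)
        sum(vapply(slots, function(sl)
            any(neck$class %in% unlist(sl)), TRUE))
    }, 1L)
    names(counts) <- as.character(1:4)

    neckType <- "unassigned"
    if (any(counts > 0L)) {
        winners <- names(counts)[counts == max(counts)]
        if (length(winners) > 1L) {
            diags <- c(diags, sprintf(
                "Type evidence tie between Types {%s}; left unassigned (precedence undefined for co-occurring Types)",
                paste(winners, collapse = ",")))
        } else {
            t <- as.integer(winners)
            n <- counts[winners]
            minimum <- if (t %in% c(1L, 2L)) 2L else 1L
            if (n >= minimum) {
                neckType <- winners
            } else if (t == 1L) {
                neckType <- "type1_like"
                diags <- c(diags,
                    "single Type 1 component: recognizable but not clusterable")
            } else {
                diags <- c(diags, sprintf(
                    "only %d of %d required Type %d components detected",
                    n, minimum, t))
            }
        }
    }

    # completeness: detected slots / expected for the Type, Ne1 included in
    # the Type 1 display
    completeness <- NA_real_
    if (neckType %in% c("1", "2", "3", "4", "type1_like")) {
        t <- if (neckType == "type1_like") 1L else as.integer(neckType)
        expected <- length(typeEvidenceClasses(t)) +
            (if (t == 1L) 1L else 0L)  # + Ne1 slot
        have <- counts[as.character(t)] +
            (if (t == 1L && any(neck$class == "Ne1")) 1L else 0L)
        completeness <- unname(have) / expected
        if (completeness < 1)
            diags <- c(diags, sprintf(
                "incomplete neck: %d of %d components", unname(have),
                expected))
    }
    evidence <- neck[, c("class", "protein_id", "probability")]
    rownames(evidence) <- NULL
    new("NeckAssignment", phageId = phage, neckType = neckType,
        evidence = evidence, morphology = "undetermined",
        completeness = if (is.na(completeness)) 0 else completeness,
        diagnostics = diags)
}

#' Infer the morphological family from Type and sheath presence
#'
#' Type 1 necks occur in both long-tailed families: a contractile sheath
#' marks Myoviridae, its absence Siphoviridae. Type 2 is Myoviridae, Types
#' 3 and 4 are the short-tailed Podoviridae. A sheath co-occurring with a
#' Type 3/4 neck contradicts the short-tail architecture: the morphology
#' stays Podoviridae and a contradiction diagnostic is recorded.
#'
#' @param assignment a [NeckAssignment-class].
#' @param hasSheath logical: was a sheath protein detected in this phage?
#' @return the assignment with \code{morphology} (and possibly an extra
#'   diagnostic) filled in.
#' @export
inferMorphology <- function(assignment, hasSheath) {
    stopifnot(is(assignment, "NeckAssignment"))
    t <- assignment@neckType
    morph <- "undetermined"
    if (t %in% c("1", "type1_like"))
        morph <- if (hasSheath) "Myoviridae" else "Siphoviridae"
    else if (t == "2")
        morph <- "Myoviridae"
    else if (t %in% c("3", "4")) {
        morph <- "Podoviridae"
        if (hasSheath)
            assignment@diagnostics <- c(assignment@diagnostics, sprintf(
                "contradiction: Type %s neck (Podoviridae) with a detected sheath", t))
    }
    assignment@morphology <- morph
    assignment
}

#' Assign Types and morphologies for every phage in a table
#'
#' @param table a [DetectionTable-class].
#' @return data.frame with one row per phage: phage_id, neck_type,
#'   morphology, completeness, evidence (collapsed class:protein list),
#'   diagnostics.
#' @export
assignmentTable <- function(table) {
    det <- table@detections
    phages <- unique(det$phage_id)
    rows <- lapply(phages, function(ph) {
        a <- assignNeckType(table, ph)
        sub <- det[det$phage_id == ph & det$round != "flagged", , drop = FALSE]
        a <- inferMorphology(a, any(sub$class == "Sheath"))
        data.frame(
            phage_id = ph, neck_type = a@neckType,
            morphology = a@morphology, completeness = a@completeness,
            evidence = paste(a@evidence$class, a@evidence$protein_id,
                             sep = ":", collapse = ";"),
            diagnostics = paste(a@diagnostics, collapse = " | "),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
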