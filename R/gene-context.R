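#' Learn inter-gene distance statistics from strict detections
#'
#' For each ordered canonical class pair of the given neck Type (e.g.
#' (Ad1, Hc1), (Hc1, Tc1), (Ad1, Tc1) for Type 1), computes the mean and
#' sample standard deviation of the signed rank distance over every phage
#' containing both classes, and the tolerated distance mean + 2*sd used to
#' gate the relaxed search. Tolerated values are kept real-valued. A
#' single observation gives sd = 0 and tolerated = mean. Pairs observed in
#' no phage are marked unavailable (n = 0) with a warning and are skipped
#' as constraints.
#'
#' @param detections a [DetectionTable-class] (typically the strict round).
#' @param genomes list of [PhageGenome-class] objects.
#' @param neckType integer 1..4.
#' @return a [DistanceModel-class].
#' @export
#' @examples
#' # genomes arranged Ad1-Hc1-x-Tc1 yield means 1, 2, 3
learnDistanceModel <- function(detections, genomes, neckType) {
    stopifnot(is(detections, "DetectionTable"))
    classes <- canonicalNeckClasses(neckType)
    if (length(classes) < 2L)
        stop("neck Type ", neckType,
             " has a single class; no distance model is defined")
    d <- detections@detections
    d <- d[d$round != "flagged" & d$class %in% classes, , drop = FALSE]
    gmap <- setNames(genomes, vapply(genomes, phageId, ""))
    pairs <- list()
    for (i in seq_len(length(classes) - 1L)) {
        for (j in seq(i + 1L, length(classes))) {
            ca <- classes[i]; cb <- classes[j]
            ds <- numeric()
            for (ph in unique(d$phage_id)) {
                sub <- d[d$phage_id == ph, , drop = FALSE]
                pa <- sub$protein_id[sub$class == ca]
                pb <- sub$protein_id[sub$class == cb]
                if (length(pa) == 1L && length(pb) == 1L &&
                    ph %in% names(gmap))
                    ds <- c(ds, intergeneDistance(gmap[[ph]], pa, pb))
            }
            n <- length(ds)
            if (n == 0L) {
                warning("no phage carries both ", ca, " and ", cb,
                        "; pair unavailable")
                pairs[[length(pairs) + 1L]] <- data.frame(
                    class_a = ca, class_b = cb, mean = NA_real_,
                    sd = NA_real_, tolerated = NA_real_, n = 0L,
                    stringsAsFactors = FALSE)
            } else {
                m <- mean(ds)
                s <- if (n > 1L) sd(ds) else 0
                pairs[[length(pairs) + 1L]] <- data.frame(
                    class_a = ca, class_b = cb, mean = m, sd = s,
                    tolerated = m + 2 * s, n = n,
                    stringsAsFactors = FALSE)
            }
        }
    }
    new("DistanceModel", neckType = as.integer(neckType),
        pairs = do.call(rbind, pairs))
}

# tolerated entry for ordered pair (ca earlier, cb later); NA if unavailable
.toleratedFor <- function(model, ca, cb) {
    p <- model@pairs
    row <- p[p$class_a == ca & p$class_b == cb, , drop = FALSE]
    if (!nrow(row) || row$n[1L] == 0L) return(NA_real_)
    row$tolerated[1L]
}

# Check a candidate of class `cl` at protein `pid` in `genome` against every
# detected partner of the same Type, conjunctively: canonical sign (when
# `signed`) and |distance| <= tolerated. Returns TRUE/FALSE; NA constraint
# entries are skipped. Partners: data.frame(class, protein_id).
.contextConsistent <- function(genome, pid, cl, partners, model,
                               signed = TRUE) {
    classes <- canonicalNeckClasses(model@neckType)
    pos_cl <- match(cl, classes)
    ok <- TRUE
    for (k in seq_len(nrow(partners))) {
        pc <- partners$class[k]
        pos_pc <- match(pc, classes)
        if (is.na(pos_pc) || pos_pc == pos_cl) next
        if (pos_pc < pos_cl) {
            tol <- .toleratedFor(model, pc, cl)
            dd <- intergeneDistance(genome, partners$protein_id[k], pid)
        } else {
            tol <- .toleratedFor(model, cl, pc)
            dd <- intergeneDistance(genome, pid, partners$protein_id[k])
        }
        if (is.na(tol)) next
        if (signed && dd < 0) return(FALSE)
        if (abs(dd) > tol + 1e-9) return(FALSE)
    }
    ok
}

#' Relaxed-threshold search constrained by gene context
#'
#' Re-runs iterative expansion for the neck classes of one Type at the
#' relaxed probability threshold (default 70), seeding each class with its
#' reference seeds plus its strictly detected members, and accepts a new
#' candidate only when its gene position is consistent with the tolerated
#' distance matrix: for every already-detected neck partner in the same
#' phage, the signed distance must carry the canonical sign (unless
#' \code{signed = FALSE}) and its magnitude must not exceed the tolerated
#' value for that pair. Candidates in phages with no strict anchor cannot
#' be validated and are rejected with a diagnostic. The single-copy
#' invariant is enforced on the augmented table.
#'
#' @param seedSet a [SeedSet-class].
#' @param provider a [HomologyProvider-class].
#' @param model a [DistanceModel-class] learned from the strict round.
#' @param strict a [DetectionTable-class] of strict detections.
#' @param genomes list of [PhageGenome-class] objects.
#' @param relaxedThreshold percent, must be below the strict threshold
#'   (default 70).
#' @param signed enforce the canonical orientation of each pair (default
#'   TRUE; the magnitude-only reading is available for sensitivity
#'   analysis).
#' @return a [DetectionTable-class] containing strict rows plus accepted
#'   relaxed rows (round \code{"relaxed70"}).
#' @export
constrainedRelaxedSearch <- function(seedSet, provider, model, strict,
                                     genomes, relaxedThreshold = 70,
                                     signed = TRUE) {
    stopifnot(is(model, "DistanceModel"), is(strict, "DetectionTable"))
    classes <- canonicalNeckClasses(model@neckType)
    sdet <- strict@detections
    gmap <- setNames(genomes, vapply(genomes, phageId, ""))
    phageOf <- .proteinPhageMap(genomes)
    diags <- character()
    additions <- list()

    # seed each class with reference seeds + strict members
    seeds <- seedSet@seeds[classes]
    for (cl in classes) {
        extra <- sdet$protein_id[sdet$class == cl & sdet$round != "flagged"]
        seeds[[cl]] <- unique(c(seeds[[cl]], extra))
    }
    # temporary seed set bypassing the one-class-per-seed rule: expansion is
    # per class, so overlaps across classes are impossible here by input
    universe <- .providerUniverse(provider)
    relaxed <- lapply(classes, function(cl) {
        have <- intersect(seeds[[cl]], universe)
        if (!length(have))  # no probe for this class in this corpus
            return(data.frame(protein_id = character(),
                              probability = numeric(),
                              chain = character(),
                              stringsAsFactors = FALSE))
        ss <- new("SeedSet", seeds = setNames(list(have), cl))
        iterativeExpand(ss, provider, threshold = relaxedThreshold)[[cl]]
    })
    names(relaxed) <- classes

    known <- paste(sdet$protein_id)
    for (cl in classes) {
        cand <- relaxed[[cl]]
        cand <- cand[cand$protein_id %in% names(phageOf) &
                     !(cand$protein_id %in% known), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
            pid <- cand$protein_id[k]
            ph <- unname(phageOf[pid])
            sub <- sdet[sdet$phage_id == ph & sdet$round != "flagged" &
                        sdet$class %in% classes, , drop = FALSE]
            if (any(sub$class == cl)) {
                diags <- c(diags, sprintf(
                    "relaxed %s candidate %s in %s rejected: class already detected (single copy)",
                    cl, pid, ph))
                next
            }
            if (!nrow(sub)) {
                diags <- c(diags, sprintf(
                    "relaxed %s candidate %s in %s rejected: no strict anchor to validate against",
                    cl, pid, ph))
                next
            }
            if (.contextConsistent(gmap[[ph]], pid, cl, sub, model,
                                   signed = signed)) {
                additions[[length(additions) + 1L]] <- new_detection_frame(
                    ph, cl, pid, cand$probability[k],
                    sprintf("relaxed%g", relaxedThreshold), cand$chain[k])
            } else {
                diags <- c(diags, sprintf(
                    "relaxed %s candidate %s in %s rejected: position inconsistent with tolerated distances (p=%.1f)",
                    cl, pid, ph, cand$probability[k]))
            }
        }
    }
    add <- if (length(additions)) do.call(rbind, additions) else
        new_detection_frame()
    # several relaxed candidates for one (phage, class): keep the best
    if (nrow(add)) {
        key <- paste(add$phage_id, add$class, sep = "\r")
        if (anyDuplicated(key)) {
            for (kk in unique(key[duplicated(key)])) {
                idx <- which(key == kk)
                diags <- c(diags, sprintf(
                    "multiple relaxed %s in %s: {%s}; kept best",
                    add$class[idx[1L]], add$phage_id[idx[1L]],
                    paste(add$protein_id[idx], collapse = ",")))
            }
            ord <- order(key, -add$probability, add$protein_id)
            add <- add[ord, , drop = FALSE]
            add <- add[!duplicated(key[ord]), , drop = FALSE]
        }
    }
    out <- rbind(sdet, add)
    out <- out[order(out$phage_id, out$class), , drop = FALSE]
    rownames(out) <- NULL
    new("DetectionTable", detections = out,
        diagnostics = c(strict@diagnostics, diags))
}

#' Detect gpW-family adaptor replacements
#'
#' In phages carrying Hc1 and Tc1 but no Ad1, a gpW-family hit at
#' probability >= 95 located 6-7 genes upstream of Hc1 and 9 genes
#' (within \code{tcSlack}) upstream of Tc1 is accepted as the adaptor
#' replacement; the phage remains Type 1. Phages that already have an Ad1
#' are skipped.
#'
#' @param seedSet a [SeedSet-class] containing a \code{gpW} class.
#' @param provider a [HomologyProvider-class].
#' @param table a [DetectionTable-class].
#' @param genomes list of [PhageGenome-class] objects.
#' @param threshold gpW confidence threshold, percent (default 95).
#' @param tcSlack tolerance around the canonical distance 9 to Tc1
#'   (default 1).
#' @return the augmented [DetectionTable-class] (round \code{"gpW"}).
#' @export
detectGpW <- function(seedSet, provider, table, genomes, threshold = 95,
                      tcSlack = 1) {
    det <- table@detections
    diags <- table@diagnostics
    gmap <- setNames(genomes, vapply(genomes, phageId, ""))
    phageOf <- .proteinPhageMap(genomes)
    gseeds <- seedSet@seeds[["gpW"]]
    if (!any(gseeds %in% .providerUniverse(provider)))
        return(table)  # no gpW evidence available at all
    ss <- new("SeedSet", seeds = list(gpW = gseeds))
    cand <- iterativeExpand(ss, provider, threshold = threshold)[["gpW"]]
    cand <- cand[cand$protein_id %in% names(phageOf), , drop = FALSE]
    additions <- list()
    for (ph in unique(det$phage_id)) {
        sub <- det[det$phage_id == ph & det$round != "flagged", , drop = FALSE]
        if (any(sub$class == "Ad1") || any(sub$class == "gpW")) next
        if (!(any(sub$class == "Hc1") && any(sub$class == "Tc1"))) next
        hc <- sub$protein_id[sub$class == "Hc1"][1L]
        tc <- sub$protein_id[sub$class == "Tc1"][1L]
        g <- gmap[[ph]]
        here <- cand[unname(phageOf[cand$protein_id]) == ph &
                     !(cand$protein_id %in% sub$protein_id), , drop = FALSE]
        accepted <- FALSE
        for (k in seq_len(nrow(here))) {
            pid <- here$protein_id[k]
            dHc <- intergeneDistance(g, hc, pid)   # canonical: -7..-6
            dTc <- intergeneDistance(g, tc, pid)   # canonical: -9 +/- slack
            if (dHc >= -7L && dHc <= -6L &&
                abs(dTc + 9L) <= tcSlack + 1e-9) {
                additions[[length(additions) + 1L]] <- new_detection_frame(
                    ph, "gpW", pid, here$probability[k], "gpW",
                    here$chain[k])
                accepted <- TRUE
                break
            }
        }
        if (nrow(here) && !accepted)
            diags <- c(diags, sprintf(
                "gpW candidate(s) in %s rejected: position outside the canonical window",
                ph))
    }
    if (length(additions))
        det <- rbind(det, do.call(rbind, additions))
    det <- det[order(det$phage_id, det$class), , drop = FALSE]
    rownames(det) <- NULL
    new("DetectionTable", detections = det, diagnostics = diags)
}

#' Detect Ne1 neck proteins in Type 1 phages
#'
#' Ne1 (the SPP1 gp16.1 superfamily) is accepted in any phage with Type 1
#' neck evidence when its hit probability reaches the strict threshold, or
#' when it reaches the relaxed threshold and the gene lies strictly
#' between Hc1 and Tc1 - the canonical Ad1-Hc1-Ne1-Tc1 slot.
#'
#' @param seedSet a [SeedSet-class] containing an \code{Ne1} class.
#' @param provider a [HomologyProvider-class].
#' @param table a [DetectionTable-class].
#' @param genomes list of [PhageGenome-class] objects.
#' @param strictThreshold percent (default 90).
#' @param relaxedThreshold percent (default 70).
#' @return the augmented [DetectionTable-class] (round \code{"ne1"}).
#' @export
detectNe1 <- function(seedSet, provider, table, genomes,
                      strictThreshold = 90, relaxedThreshold = 70) {
    det <- table@detections
    diags <- table@diagnostics
    gmap <- setNames(genomes, vapply(genomes, phageId, ""))
    phageOf <- .proteinPhageMap(genomes)
    nseeds <- seedSet@seeds[["Ne1"]]
    if (!any(nseeds %in% .providerUniverse(provider)))
        return(table)  # no Ne1 evidence available at all
    ss <- new("SeedSet", seeds = list(Ne1 = nseeds))
    cand <- iterativeExpand(ss, provider,
                            threshold = relaxedThreshold)[["Ne1"]]
    cand <- cand[cand$protein_id %in% names(phageOf), , drop = FALSE]
    type1 <- c("Ad1", "Hc1", "Tc1", "gpW")
    additions <- list()
    for (ph in unique(det$phage_id)) {
        sub <- det[det$phage_id == ph & det$round != "flagged", , drop = FALSE]
        if (!any(sub$class %in% type1)) next
        if (any(sub$class == "Ne1")) next
        here <- cand[unname(phageOf[cand$protein_id]) == ph &
                     !(cand$protein_id %in% sub$protein_id), , drop = FALSE]
        if (!nrow(here)) next
        g <- gmap[[ph]]
        hc <- sub$protein_id[sub$class == "Hc1"]
        tc <- sub$protein_id[sub$class == "Tc1"]
        ok <- rep(FALSE, nrow(here))
        for (k in seq_len(nrow(here))) {
            if (here$probability[k] >= strictThreshold) {
                ok[k] <- TRUE
            } else if (length(hc) == 1L && length(tc) == 1L) {
                d1 <- intergeneDistance(g, hc, here$protein_id[k])
                d2 <- intergeneDistance(g, here$protein_id[k], tc)
                ok[k] <- d1 > 0L && d2 > 0L
            }
            if (!ok[k])
                diags <- c(diags, sprintf(
                    "Ne1 candidate %s in %s rejected (p=%.1f, outside Hc1-Tc1 interval)",
                    here$protein_id[k], ph, here$probability[k]))
        }
        here <- here[ok, , drop = FALSE]
        if (nrow(here)) {
            best <- which.max(here$probability)
            additions[[length(additions) + 1L]] <- new_detection_frame(
                ph, "Ne1", here$protein_id[best], here$probability[best],
                "ne1", here$chain[best])
        }
    }
    if (length(additions))
        det <- rbind(det, do.call(rbind, additions))
    det <- det[order(det$phage_id, det$class), , drop = FALSE]
    rownames(det) <- NULL
    new("DetectionTable", detections = det, diagnostics = diags)
}

#' Flag low-support candidates for a missing neck class
#'
#' For phages lacking exactly one canonical neck class of their Type,
#' proteins whose homology profile was built from fewer than
#' \code{minProfileSupport} sequences (too few for profile-profile
#' detection) and whose rank is consistent with the tolerated distance
#' matrix for the missing class are flagged for human review. Flagged
#' candidates are never auto-accepted: they carry round \code{"flagged"},
#' count as no evidence, and are merely surfaced.
#'
#' @param provider a [HomologyProvider-class] whose metadata carries
#'   \code{n_aligned_sequences} per profile.
#' @param model a [DistanceModel-class] for the Type being completed.
#' @param table a [DetectionTable-class].
#' @param genomes list of [PhageGenome-class] objects.
#' @param minProfileSupport strict upper bound on profile support
#'   (default 5: profiles with fewer than 5 aligned sequences qualify).
#' @return data.frame of flagged candidates (phage_id, class, protein_id,
#'   n_aligned_sequences).
#' @export
flagLowSupportCandidates <- function(provider, model, table, genomes,
                                     minProfileSupport = 5L) {
    empty <- data.frame(phage_id = character(), class = character(),
                        protein_id = character(),
                        n_aligned_sequences = integer(),
                        stringsAsFactors = FALSE)
    md <- provider@metadata
    if (!nrow(md)) return(empty)
    low <- md$profile_id[md$n_aligned_sequences < minProfileSupport]
    det <- table@detections
    classes <- canonicalNeckClasses(model@neckType)
    gmap <- setNames(genomes, vapply(genomes, phageId, ""))
    out <- list()
    for (ph in unique(det$phage_id)) {
        sub <- det[det$phage_id == ph & det$round != "flagged" &
                   det$class %in% classes, , drop = FALSE]
        missing <- setdiff(classes, sub$class)
        if (length(missing) != 1L || !nrow(sub)) next
        g <- gmap[[ph]]
        cands <- intersect(g@proteins$protein_id, low)
        cands <- setdiff(cands, det$protein_id[det$phage_id == ph])
        for (pid in cands) {
            if (.contextConsistent(g, pid, missing, sub, model)) {
                n_sup <- md$n_aligned_sequences[md$profile_id == pid][1L]
                out[[length(out) + 1L]] <- data.frame(
                    phage_id = ph, class = missing, protein_id = pid,
                    n_aligned_sequences = n_sup, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out)) return(empty)
    do.call(rbind, out)
}

#' Save / load a distance model as YAML
#' @param model a [DistanceModel-class].
#' @param path YAML path.
#' @export
saveDistanceModel <- function(model, path) {
    p <- model@pairs
    entries <- lapply(seq_len(nrow(p)), function(i) {
        list(pair = c(p$class_a[i], p$class_b[i]),
             mean = p$mean[i], sd = p$sd[i],
             tolerated = p$tolerated[i], n = p$n[i])
    })
    yaml::write_yaml(list(neck_type = model@neckType, pairs = entries),
                     path, precision = 15L)
    invisible(path)
}

#' @rdname saveDistanceModel
#' @export
loadDistanceModel <- function(path) {
    raw <- yaml::read_yaml(path)
    pairs <- do.call(rbind, lapply(raw$pairs, function(e) {
        data.frame(class_a = e$pair[[1L]], class_b = e$pair[[2L]],
                   mean = .yamlNum(e$mean), sd = .yamlNum(e$sd),
                   tolerated = .yamlNum(e$tolerated), n = as.integer(e$n),
                   stringsAsFactors = FALSE)
    }))
    new("DistanceModel", neckType = as.integer(raw$neck_type), pairs = pairs)
}

.yamlNum <- function(x) {
    if (is.null(x) || (is.character(x) && x %in% c("NA", ".na", ".na.real")))
        return(NA_real_)
    as.numeric(x)
}

#' Inter-gene distance warnings for one phage
#'
#' Compares every observed distance between detected neck partners to the
#' tolerated matrix and emits a warning string per violation - the gene
#' context check the classification report surfaces to the user.
#'
#' @param table a [DetectionTable-class].
#' @param genome a [PhageGenome-class].
#' @param model a [DistanceModel-class].
#' @return character vector of warning strings (possibly empty).
#' @export
distanceWarnings <- function(table, genome, model) {
    det <- table@detections
    classes <- canonicalNeckClasses(model@neckType)
    sub <- det[det$phage_id == phageId(genome) & det$round != "flagged" &
               det$class %in% classes, , drop = FALSE]
    out <- character()
    if (nrow(sub) < 2L) return(out)
    for (i in seq_len(nrow(sub) - 1L)) {
        for (j in seq(i + 1L, nrow(sub))) {
            ci <- sub$class[i]; cj <- sub$class[j]
            if (match(ci, classes) < match(cj, classes)) {
                ca <- i; cb <- j
            } else {
                ca <- j; cb <- i
            }
            tol <- .toleratedFor(model, sub$class[ca], sub$class[cb])
            if (is.na(tol)) next
            dd <- intergeneDistance(genome, sub$protein_id[ca],
                                    sub$protein_id[cb])
            if (dd < 0 || dd > tol + 1e-9)
                out <- c(out, sprintf(
                    "unusual inter-gene distance %s-%s: observed %d, tolerated %.2f",
                    sub$class[ca], sub$class[cb], dd, tol))
        }
    }
    out
}
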