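#' Build a HomologyProvider from an in-memory hit data frame
#'
#' Duplicate (query, target) pairs keep the maximum probability (with a
#' warning); the expansion steps only care about crossing a threshold, so
#' the best-scoring alignment is the informative one. Self-hits are
#' dropped silently. Probabilities and identities are percents in
#' \[0, 100\].
#'
#' @param hits data.frame with columns \code{query_id}, \code{target_id},
#'   \code{probability}, \code{identity} (optional column
#'   \code{identity_missing}).
#' @param metadata optional data.frame with columns \code{profile_id},
#'   \code{n_aligned_sequences}.
#' @return a [HomologyProvider-class].
#' @export
makeHitProvider <- function(hits, metadata = NULL) {
    needed <- c("query_id", "target_id", "probability", "identity")
    if (!all(needed %in% names(hits)))
        stop("hits must have columns: ", paste(needed, collapse = ", "))
    bad <- which(!is.finite(hits$probability) |
                 hits$probability < 0 | hits$probability > 100)
    if (length(bad))
        stop("probability outside [0,100] in row(s): ",
             paste(head(bad, 5L), collapse = ", "))
    bad <- which(!is.finite(hits$identity) |
                 hits$identity < 0 | hits$identity > 100)
    if (length(bad))
        stop("identity outside [0,100] in row(s): ",
             paste(head(bad, 5L), collapse = ", "))
    if (!"identity_missing" %in% names(hits))
        hits$identity_missing <- FALSE
    hits <- hits[hits$query_id != hits$target_id, , drop = FALSE]
    key <- paste(hits$query_id, hits$target_id, sep = "\r")
    if (anyDuplicated(key)) {
        warning("duplicate (query, target) pairs: keeping maximum probability")
        ord <- order(key, -hits$probability, -hits$identity)
        hits <- hits[ord, , drop = FALSE]
        hits <- hits[!duplicated(key[ord]), , drop = FALSE]
    }
    rownames(hits) <- NULL
    if (is.null(metadata))
        metadata <- data.frame(profile_id = character(),
                               n_aligned_sequences = integer())
    new("HomologyProvider", hits = hits, metadata = metadata,
        symmetrized = FALSE)
}

#' Load an all-vs-all hit table from TSV
#'
#' Expected columns (header required): \code{query_id}, \code{target_id},
#' \code{probability}, \code{identity}. Rows that fail to parse as numbers
#' are counted and reported in a warning; a probability outside \[0, 100\]
#' is an error naming the row.
#'
#' @param path TSV file path.
#' @param metadata optional profile metadata data.frame (or TSV path) with
#'   columns \code{profile_id}, \code{n_aligned_sequences}.
#' @return a [HomologyProvider-class].
#' @export
loadHitTable <- function(path, metadata = NULL) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = "character")
    needed <- c("query_id", "target_id", "probability", "identity")
    if (!all(needed %in% names(tab)))
        stop("hit table must have header columns: ",
             paste(needed, collapse = ", "))
    prob <- suppressWarnings(as.numeric(tab$probability))
    ident <- suppressWarnings(as.numeric(tab$identity))
    malformed <- which(is.na(prob) | is.na(ident))
    if (length(malformed)) {
        warning(length(malformed), " malformed row(s) dropped: ",
                paste(head(malformed, 5L), collapse = ", "))
        tab <- tab[-malformed, , drop = FALSE]
        prob <- prob[-malformed]
        ident <- ident[-malformed]
    }
    bad <- which(prob < 0 | prob > 100)
    if (length(bad))
        stop("probability outside [0,100] at data row ", bad[1L],
             " (", tab$query_id[bad[1L]], " -> ", tab$target_id[bad[1L]], ")")
    if (is.character(metadata) && length(metadata) == 1L)
        metadata <- read.delim(metadata, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    makeHitProvider(
        data.frame(query_id = tab$query_id, target_id = tab$target_id,
                   probability = prob, identity = ident,
                   stringsAsFactors = FALSE),
        metadata = metadata)
}

#' Write a provider's hits to TSV
#'
#' Probabilities and identities are written with two decimal places so that
#' load -> dump -> load is stable.
#'
#' @param provider a [HomologyProvider-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHitTable <- function(provider, path) {
    h <- provider@hits
    out <- data.frame(query_id = h$query_id, target_id = h$target_id,
                      probability = sprintf("%.2f", h$probability),
                      identity = sprintf("%.2f", h$identity),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Parse a profile-profile search report (HHR dialect)
#'
#' Reads the plain-text report of a profile-profile comparison run for one
#' query: the hit summary block (rank, hit id, \code{Prob} column) and the
#' per-hit alignment blocks carrying \code{Probab=} and \code{Identities=}.
#' Identity is taken from the alignment block when present; a hit whose
#' report carries no identity gets identity 0 with
#' \code{identity_missing = TRUE} (scored as 0 but surfaced in reports).
#'
#' @param text character vector of report lines, or a single string, or a
#'   file path to the report.
#' @return data.frame of hits in report order with columns
#'   \code{query_id}, \code{target_id}, \code{probability},
#'   \code{identity}, \code{identity_missing}.
#' @export
parseSearchReport <- function(text) {
    if (length(text) == 1L && file.exists(text))
        text <- readLines(text, warn = FALSE)
    if (length(text) == 1L && grepl("\n", text))
        text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    qline <- grep("^Query\\s+", text, value = TRUE)
    if (!length(qline))
        stop("unparseable report: no 'Query' header line")
    query_id <- strsplit(sub("^Query\\s+", "", qline[1L]), "\\s+")[[1L]][1L]

    # Alignment blocks: "No <i>" / ">id desc" / "Probab=.. Identities=..%"
    blk <- grep("^No\\s+\\d+\\s*$", text)
    hits <- list()
    for (i in blk) {
        idline <- text[i + 1L]
        if (is.na(idline) || !startsWith(idline, ">")) next
        target <- strsplit(sub("^>", "", idline), "\\s+")[[1L]][1L]
        stat <- text[i + 2L]
        prob <- NA_real_
        ident <- NA_real_
        if (!is.na(stat)) {
            m <- regmatches(stat, regexec("Probab=([0-9.]+)", stat))[[1L]]
            if (length(m) == 2L) prob <- as.numeric(m[2L])
            m <- regmatches(stat, regexec("Identities=([0-9.]+)%", stat))[[1L]]
            if (length(m) == 2L) ident <- as.numeric(m[2L])
        }
        hits[[length(hits) + 1L]] <- list(target = target, prob = prob,
                                          ident = ident)
    }

    # Summary table (fallback for probability when alignments are absent):
    # " No Hit ... Prob E-value ..." followed by numbered rows.
    if (!length(hits)) {
        hdr <- grep("^\\s*No\\s+Hit", text)
        if (length(hdr)) {
            j <- hdr[1L] + 1L
            while (j <= length(text) && grepl("^\\s*\\d+\\s+\\S", text[j])) {
                f <- strsplit(trimws(text[j]), "\\s+")[[1L]]
                # columns: rank, id, [description words...], Prob, ...
                # Prob is the first numeric field after the description;
                # the summary line's numeric tail starts at Prob.
                numidx <- which(grepl("^[0-9.]+$", f))
                numidx <- numidx[numidx > 2L]
                if (length(numidx))
                    hits[[length(hits) + 1L]] <-
                        list(target = f[2L],
                             prob = as.numeric(f[numidx[1L]]),
                             ident = NA_real_)
                j <- j + 1L
            }
        }
    }
    if (!length(hits))
        return(data.frame(query_id = character(), target_id = character(),
                          probability = numeric(), identity = numeric(),
                          identity_missing = logical(),
                          stringsAsFactors = FALSE))
    data.frame(
        query_id = query_id,
        target_id = vapply(hits, `[[`, "", "target"),
        probability = vapply(hits, `[[`, 0, "prob"),
        identity = ifelse(is.na(vapply(hits, `[[`, 0, "ident")), 0,
                          vapply(hits, `[[`, 0, "ident")),
        identity_missing = is.na(vapply(hits, `[[`, 0, "ident")),
        stringsAsFactors = FALSE)
}

#' Symmetrize a provider
#'
#' Profile-profile comparison is not guaranteed symmetric. For every pair,
#' the probability becomes \code{max(P(a->b), P(b->a))} and the identity is
#' taken from the direction achieving that maximum; pairs present in one
#' direction only are mirrored. Idempotent.
#'
#' @param provider a [HomologyProvider-class].
#' @return a symmetrized [HomologyProvider-class].
#' @export
symmetrizeHits <- function(provider) {
    stopifnot(is(provider, "HomologyProvider"))
    if (provider@symmetrized) return(provider)
    h <- provider@hits
    if (!nrow(h)) {
        provider@symmetrized <- TRUE
        return(provider)
    }
    a <- pmin(h$query_id, h$target_id)
    b <- pmax(h$query_id, h$target_id)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -h$probability, -h$identity)
    best <- h[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    fwd <- best
    rev <- best
    rev$query_id <- best$target_id
    rev$target_id <- best$query_id
    out <- rbind(fwd, rev)
    rownames(out) <- NULL
    new("HomologyProvider", hits = out, metadata = provider@metadata,
        symmetrized = TRUE)
}

#' Query hits above a probability threshold
#'
#' Returns every stored hit with the given query and probability >=
#' \code{minProbability}, deterministically ordered by descending
#' probability then target id.
#'
#' @param provider a [HomologyProvider-class].
#' @param query query profile/protein id.
#' @param minProbability percent threshold in \[0, 100\].
#' @return data.frame of hits (possibly zero rows).
#' @export
hitsFor <- function(provider, query, minProbability = 0) {
    h <- provider@hits
    sel <- h[h$query_id == query & h$probability >= minProbability, ,
             drop = FALSE]
    sel <- sel[order(-sel$probability, sel$target_id), , drop = FALSE]
    rownames(sel) <- NULL
    sel
}

# probability/identity of the (a, b) pair, symmetric lookup.
# identical ids compare a protein with itself: maximal evidence.
.pairEvidence <- function(provider, a, b) {
    if (a == b)
        return(c(probability = 100, identity = 100))
    h <- provider@hits
    sel <- h[(h$query_id == a & h$target_id == b) |
             (h$query_id == b & h$target_id == a), , drop = FALSE]
    if (!nrow(sel))
        return(c(probability = 0, identity = 0))
    i <- which.max(sel$probability)
    c(probability = sel$probability[i], identity = sel$identity[i])
}

# universe of ids known to the provider
.providerUniverse <- function(provider) {
    unique(c(provider@hits$query_id, provider@hits$target_id))
}
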