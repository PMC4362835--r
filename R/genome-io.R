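#' Read an ordered phage proteome from multi-FASTA
#'
#' Record order in the file is taken as gene order on the genome: record
#' \code{i} receives rank \code{i} (1-based). The first whitespace-delimited
#' token of each header is the protein id; the remainder is kept as
#' description. Wrapped and unwrapped FASTA are both accepted.
#'
#' @param path path to a multi-record amino-acid FASTA file.
#' @param phageId identifier for the phage; defaults to the file base name.
#' @param name human-readable name; defaults to \code{phageId}.
#' @param declaredMorphology optional prior annotation
#'   ("Siphoviridae", "Myoviridae", "Podoviridae" or "unclassified").
#' @return a [PhageGenome-class] object.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 portal", "MKV", ">p2", "ACDEF"), fa)
#' g <- readOrderedProteome(fa, phageId = "toy")
#' proteinTable(g)$rank
readOrderedProteome <- function(path, phageId = NULL, name = NULL,
                                declaredMorphology = "unclassified") {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(phageId))
        phageId <- sub("\\.[^.]*$", "", basename(path))
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L)
        stop("empty proteome: ", path)
    headers <- names(aa)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids))
        stop("duplicate protein_id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    # Guard against nucleotide FASTA passed by mistake: warn, don't error.
    chars <- paste(as.character(aa), collapse = "")
    nuc_frac <- mean(strsplit(chars, "")[[1]] %in%
                     c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n", "-"))
    if (is.finite(nuc_frac) && nuc_frac > 0.95)
        warning("sequences look nucleotide-like (", round(100 * nuc_frac),
                "% ACGTN-); expected amino acids")
    names(aa) <- ids
    proteins <- data.frame(
        protein_id = ids,
        rank = seq_along(ids),
        length = Biostrings::width(aa),
        description = desc,
        stringsAsFactors = FALSE)
    new("PhageGenome", phageId = phageId,
        name = if (is.null(name)) phageId else name,
        proteins = proteins, sequences = aa,
        declaredMorphology = declaredMorphology)
}

#' Write an ordered proteome back to FASTA
#'
#' Records are written in rank order so that a write/read round trip
#' preserves ranks and sequences exactly.
#'
#' @param genome a [PhageGenome-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeOrderedProteome <- function(genome, path) {
    stopifnot(is(genome, "PhageGenome"))
    aa <- genome@sequences
    desc <- genome@proteins$description
    names(aa) <- ifelse(nzchar(desc),
                        paste(genome@proteins$protein_id, desc),
                        genome@proteins$protein_id)
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Construct a PhageGenome from in-memory sequences
#'
#' @param phageId phage identifier.
#' @param sequences named character vector or \code{AAStringSet}; order is
#'   gene order.
#' @param descriptions optional character vector of descriptions.
#' @inheritParams readOrderedProteome
#' @return a [PhageGenome-class].
#' @export
makePhageGenome <- function(phageId, sequences, name = phageId,
                            descriptions = NULL,
                            declaredMorphology = "unclassified") {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    ids <- names(sequences)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("sequences must be named by protein_id")
    if (is.null(descriptions)) descriptions <- rep("", length(sequences))
    proteins <- data.frame(
        protein_id = ids, rank = seq_along(ids),
        length = Biostrings::width(sequences),
        description = descriptions, stringsAsFactors = FALSE)
    new("PhageGenome", phageId = phageId, name = name,
        proteins = proteins, sequences = sequences,
        declaredMorphology = declaredMorphology)
}

#' Signed inter-gene distance in rank units
#'
#' Returns \code{rank(b) - rank(a)}: a gene immediately downstream of
#' \code{a} is at distance +1. This is the convention under which the
#' canonical Type 1 arrangement Ad1-Hc1-x-Tc1 yields distances 1, 2 and 3
#' for the (Ad1,Hc1), (Hc1,Tc1) and (Ad1,Tc1) pairs. Distances are counted
#' on the linear gene list; no circular wrap-around is applied.
#'
#' @param genome a [PhageGenome-class].
#' @param a,b protein ids present in \code{genome}.
#' @return signed integer rank difference.
#' @export
#' @examples
#' g <- makePhageGenome("toy", c(x = "MA", y = "MC", z = "MD"))
#' intergeneDistance(g, "x", "z")  # 2
intergeneDistance <- function(genome, a, b) {
    stopifnot(is(genome, "PhageGenome"))
    ranks <- genome@proteins$rank
    names(ranks) <- genome@proteins$protein_id
    if (!a %in% names(ranks))
        stop("unknown protein_id: ", a)
    if (!b %in% names(ranks))
        stop("unknown protein_id: ", b)
    unname(as.integer(ranks[b] - ranks[a]))
}

#' Export a set of genomes as a TSV gene table
#'
#' @param genomes list of [PhageGenome-class] objects.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeTable <- function(genomes, path) {
    rows <- do.call(rbind, lapply(genomes, function(g) {
        data.frame(phage_id = g@phageId,
                   protein_id = g@proteins$protein_id,
                   rank = g@proteins$rank,
                   length = g@proteins$length,
                   stringsAsFactors = FALSE)
    }))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# rank lookup helper: named integer vector for one genome
.rankIndex <- function(genome) {
    r <- genome@proteins$rank
    names(r) <- genome@proteins$protein_id
    r
}

# map protein_id -> phage_id over a list of genomes
.proteinPhageMap <- function(genomes) {
    ids <- unlist(lapply(genomes, function(g) g@proteins$protein_id))
    ph <- unlist(lapply(genomes, function(g)
        rep(g@phageId, nrow(g@proteins))))
    names(ph) <- ids
    ph
}
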