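## Ballesteros-Weinstein numbering from a class F alignment, plus
## per-column conservation scoring. Offsets from the x.50 anchor are counted
## in ungapped sequence space per sequence (an insertion in one paralogue
## must not shift another's numbering).

#' Parse a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments via Biostrings and returns the aligned
#' sequences (gaps preserved) as a named character vector of equal-length
#' strings.
#'
#' @param path alignment file.
#' @param format "auto" (by extension/content), "fasta" or "clustal".
#' @return named character vector of aligned sequences.
#' @export
parseAlignment <- function(path, format = c("auto", "fasta", "clustal")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        first <- readLines(path, n = 1L, warn = FALSE)
        format <- if (startsWith(first, ">")) "fasta" else "clustal"
    }
    if (format == "fasta") {
        ss <- Biostrings::readAAStringSet(path)
        seqs <- as.character(ss)
    } else {
        aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
        seqs <- as.character(aln)
    }
    if (length(seqs) == 0L) stop("empty alignment: ", path)
    if (length(unique(nchar(seqs))) != 1L)
        stop("ragged alignment: aligned sequences have unequal lengths")
    seqs
}

.alnMatrix <- function(aln) {
    do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

.isGap <- function(ch) ch %in% c("-", ".")

#' Assign Ballesteros-Weinstein codes to one aligned sequence
#'
#' For each helix span of the scheme, the residue at the anchor column gets
#' code x.50 and every other non-gap residue within the span gets
#' `x.(50 + offset)`, the offset counted over the sequence's own non-gap
#' residues. Residues outside the spans are unmapped.
#'
#' @param aln alignment from [parseAlignment()].
#' @param seq_id name of the sequence to map.
#' @param scheme a [BWScheme-class].
#' @return A [ResidueMap-class].
#' @export
assignBW <- function(aln, seq_id, scheme) {
    if (!seq_id %in% names(aln))
        stop("sequence not in alignment: ", seq_id)
    chars <- strsplit(aln[[seq_id]], "", fixed = TRUE)[[1L]]
    nongap <- !.isGap(chars)
    resid_at_col <- cumsum(nongap)       # ungapped index, valid where nongap
    rows <- list()
    for (i in seq_len(nrow(scheme@anchors))) {
        hx <- scheme@anchors$helix[i]
        ac <- scheme@anchors$anchor_col[i]
        if (!nongap[ac])
            stop(sprintf("anchor column %d of helix %d is a gap for '%s'",
                         ac, hx, seq_id))
        span <- scheme@helix_ranges[scheme@helix_ranges$helix == hx, ]
        cols <- span$start_col:span$end_col
        cols <- cols[nongap[cols]]
        pos <- 50L + resid_at_col[cols] - resid_at_col[ac]
        rows[[length(rows) + 1L]] <- data.frame(
            resid = resid_at_col[cols],
            bw = sprintf("%d.%d", hx, pos),
            helix = hx, pos = pos, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    new("ResidueMap", seq_id = seq_id, table = tab)
}

#' BW code of a residue index
#' @param map a [ResidueMap-class].
#' @param resid residue index (ungapped sequence position).
#' @return BW code string, or `NA` if unmapped.
#' @export
residToBW <- function(map, resid) {
    i <- match(resid, map@table$resid)
    map@table$bw[i]
}

#' Residue index of a BW code
#' @param map a [ResidueMap-class].
#' @param bw BW code, e.g. "6.43".
#' @return integer residue index.
#' @export
bwToResid <- function(map, bw) {
    i <- match(bw, map@table$bw)
    if (any(is.na(i)))
        stop("BW code(s) not mapped: ", paste(bw[is.na(i)], collapse = ", "))
    map@table$resid[i]
}

#' Per-column conservation score
#'
#' Score of a column is the frequency of its modal non-gap residue among
#' the non-gap entries; an all-gap column scores 0. Scores lie in [0, 1]
#' and equal 1 iff the column is monomorphic ignoring gaps.
#'
#' @param aln alignment from [parseAlignment()] (at least 2 sequences).
#' @return numeric vector, one score per alignment column.
#' @export
conservation <- function(aln) {
    if (length(aln) < 2L) stop("need at least 2 sequences")
    m <- .alnMatrix(aln)
    apply(m, 2L, function(col) {
        col <- col[!.isGap(col)]
        if (length(col) == 0L) return(0)
        max(table(col)) / length(col)
    })
}

#' Residue letters at a BW position across all sequences
#'
#' Maps each sequence with the scheme and reports the amino-acid letter at
#' the requested BW code; sequences where the position is unmapped (e.g. a
#' gap in that helix region) report `"-"`.
#'
#' @param aln alignment from [parseAlignment()].
#' @param scheme a [BWScheme-class].
#' @param bw BW code, e.g. "6.43".
#' @return named character vector of single letters (or "-").
#' @export
residueAtBW <- function(aln, scheme, bw) {
    hx <- as.integer(sub("\\..*$", "", bw))
    if (!hx %in% scheme@helix_ranges$helix)
        stop("BW code outside the scheme's helix spans: ", bw)
    out <- vapply(names(aln), function(id) {
        map <- assignBW(aln, id, scheme)
        i <- match(bw, map@table$bw)
        if (is.na(i)) return("-")
        chars <- strsplit(aln[[id]], "", fixed = TRUE)[[1L]]
        chars[!.isGap(chars)][map@table$resid[i]]
    }, character(1L))
    out
}
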