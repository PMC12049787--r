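#' Convert a position frequency matrix to a position weight matrix
#'
#' Normalises raw per-position base counts to probabilities with a
#' proportional pseudocount: each position's probabilities are
#' `(count + pseudocount * total) / (total * (1 + 4 * pseudocount))` where
#' `total` is that position's count sum.  The pseudocount keeps log2-odds
#' finite without changing the rank order of bases.
#'
#' @param counts numeric L x 4 matrix of base counts (columns A, C, G, T;
#'   a 4 x L matrix with base rownames, the JASPAR file orientation, is
#'   transposed automatically).  Fractional counts are allowed.
#' @param name motif identifier (default: the matrix's `"name"` attribute
#'   as set by [readPfm()], else `"motif"`).
#' @param pseudocount fraction of the position total added to each base
#'   (default 0.01).
#' @param background length-4 background frequencies (default uniform).
#' @return A [PositionWeightMatrix-class].
#' @examples
#' pfmToPwm(matrix(c(3, 1, 0, 0), nrow = 1,
#'          dimnames = list(NULL, c("A", "C", "G", "T"))), pseudocount = 0)
#' @export
pfmToPwm <- function(counts, name = NULL, pseudocount = 0.01,
                     background = rep(0.25, 4)) {
    if (is.null(name))
        name <- if (!is.null(attr(counts, "name"))) attr(counts, "name")
                else "motif"
    counts <- as.matrix(counts)
    if (ncol(counts) != 4L && nrow(counts) == 4L &&
        !is.null(rownames(counts)) && setequal(rownames(counts), DNA_BASES4))
        counts <- t(counts)
    if (ncol(counts) == 4L && !is.null(colnames(counts))) {
        if (!setequal(colnames(counts), DNA_BASES4))
            stop("'counts' columns must be A, C, G, T")
        counts <- counts[, DNA_BASES4, drop = FALSE]
    }
    if (ncol(counts) != 4L)
        stop("'counts' must be an L x 4 matrix")
    if (any(counts < 0) || any(!is.finite(counts)))
        stop("'counts' must be finite and non-negative")
    tot <- rowSums(counts)
    if (any(tot == 0))
        stop("position(s) with all-zero counts: ",
             paste(which(tot == 0), collapse = ", "))
    probs <- (counts + pseudocount * tot) / (tot * (1 + 4 * pseudocount))
    colnames(probs) <- DNA_BASES4
    PositionWeightMatrix(probs, name = name, background = background)
}

.base_index <- function(window) {
    b <- strsplit(toupper(window), "")[[1]]
    if (!all(b %in% c(DNA_BASES4, "N")))
        stop("window contains characters outside A, C, G, T, N")
    match(b, DNA_BASES4)          # NA for N
}

# log2-odds of every placement of the motif covering snp_index on one strand
.scan_covering <- function(lods, bidx, snp_index) {
    L <- nrow(lods)
    wlen <- length(bidx)
    o_min <- max(1L, snp_index - L + 1L)
    o_max <- min(snp_index, wlen - L + 1L)
    if (o_min > o_max) return(NULL)
    offs <- o_min:o_max
    scores <- vapply(offs, function(o) {
        cols <- bidx[o:(o + L - 1L)]
        v <- lods[cbind(seq_len(L), cols)]
        v[is.na(cols)] <- 0        # N scores as background
        sum(v)
    }, numeric(1))
    list(offsets = offs, scores = scores)
}

#' Best motif score over all placements and strands covering a SNP
#'
#' Scores a SNP-flanking window against a position weight matrix: for every
#' offset at which the motif covers the SNP position, on both strands, the
#' log2-odds `sum(log2(probs[i, b_i] / background[b_i]))` is computed; `N`
#' bases contribute the background (zero) term; the reverse strand scores
#' the reverse complement.  Only SNP-covering placements are considered
#' because the question is allelic disruption at the SNP, not a full-window
#' scan.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param window character sequence over A, C, G, T, N (or a
#'   [Biostrings::DNAString]).
#' @param snp_index 1-based SNP position within the window.
#' @return list with `score` (best log2-odds), `offset` (1-based window
#'   offset of the best placement, in forward-strand coordinates) and
#'   `strand` (`"+"`/`"-"`).  Ties prefer the forward strand, then the
#'   smallest offset.
#' @examples
#' pwm <- pfmToPwm(matrix(c(10, 0, 0, 0), nrow = 1,
#'         dimnames = list(NULL, c("A", "C", "G", "T"))), pseudocount = 0)
#' scoreWindow(pwm, "A", 1)  # log2(1 / 0.25) = 2
#' @export
scoreWindow <- function(pwm, window, snp_index) {
    stopifnot(methods::is(pwm, "PositionWeightMatrix"))
    window <- as.character(window)
    wlen <- nchar(window)
    snp_index <- as.integer(snp_index)
    if (snp_index < 1L || snp_index > wlen)
        stop("'snp_index' must lie within the window")
    L <- motifLength(pwm)
    lods <- log2(motifProbs(pwm) / rep(motifBackground(pwm),
                                       each = L))
    fwd <- .scan_covering(lods, .base_index(window), snp_index)
    rcw <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(window))))
    rev <- .scan_covering(lods, .base_index(rcw), wlen - snp_index + 1L)
    if (is.null(fwd) && is.null(rev))
        stop("window too short: no placement of the ", L,
             "-bp motif covers position ", snp_index)
    cand <- rbind(
        if (!is.null(fwd))
            data.frame(score = fwd$scores, offset = fwd$offsets,
                       strand = "+", stringsAsFactors = FALSE),
        if (!is.null(rev))
            data.frame(score = rev$scores,
                       offset = wlen - (rev$offsets + L - 1L) + 1L,
                       strand = "-", stringsAsFactors = FALSE))
    cand <- cand[order(-cand$score, cand$strand, cand$offset), , drop = FALSE]
    list(score = cand$score[1L], offset = cand$offset[1L],
         strand = cand$strand[1L])
}

#' Allelic motif disruption score at a SNP
#'
#' Scores the reference and alternative allele windows with [scoreWindow()]
#' and reports `delta = score_alt - score_ref`: positive delta means the
#' alternative allele binds the motif more strongly, negative delta means
#' the alternative allele disrupts binding.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param window_ref,window_alt allele windows, identical except possibly at
#'   `snp_index`.
#' @param snp_index 1-based SNP position within the windows.
#' @param snp_id optional SNP identifier carried into the output.
#' @return one-row `data.frame`: `snp_id`, `tf_name`, `score_ref`,
#'   `score_alt`, `delta`, `best_offset_ref`, `best_offset_alt`,
#'   `strand_ref`, `strand_alt`.
#' @examples
#' pwm <- pfmToPwm(matrix(c(9, 1, 0, 0,
#'                          0, 8, 1, 1), byrow = TRUE, ncol = 4,
#'                 dimnames = list(NULL, c("A", "C", "G", "T"))))
#' scoreAlleles(pwm, "TACGT", "TTCGT", snp_index = 2)
#' @export
scoreAlleles <- function(pwm, window_ref, window_alt, snp_index,
                         snp_id = NA_character_) {
    window_ref <- toupper(as.character(window_ref))
    window_alt <- toupper(as.character(window_alt))
    if (nchar(window_ref) != nchar(window_alt))
        stop("allele windows must have equal length")
    diffs <- which(strsplit(window_ref, "")[[1]] !=
                   strsplit(window_alt, "")[[1]])
    if (length(diffs) && !identical(diffs, as.integer(snp_index)))
        stop("allele windows differ at position(s) ",
             paste(diffs, collapse = ", "),
             " but may only differ at snp_index = ", snp_index)
    r <- scoreWindow(pwm, window_ref, snp_index)
    a <- scoreWindow(pwm, window_alt, snp_index)
    data.frame(snp_id = snp_id, tf_name = motifName(pwm),
               score_ref = r$score, score_alt = a$score,
               delta = a$score - r$score,
               best_offset_ref = r$offset, best_offset_alt = a$offset,
               strand_ref = r$strand, strand_alt = a$strand,
               stringsAsFactors = FALSE)
}
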