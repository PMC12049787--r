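#' Simulate a SNP-centred sequence window with a planted motif
#'
#' Builds a pair of allele windows for testing allelic motif scoring: random
#' background sequence of length `2 * flank + 1` with the SNP at the centre,
#' the motif consensus embedded at a random offset chosen so the motif covers
#' the SNP.  The reference window carries the consensus base at the SNP
#' (or `planted_allele` when given); when `disrupt = TRUE` the alternative
#' window instead carries the motif's lowest-probability base at that motif
#' column, so the true disruption direction is known.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param planted_allele optional single base overriding the reference-window
#'   SNP base (default: the motif consensus base at the covered column).
#' @param disrupt logical; plant a disrupting alternative allele?  When
#'   `FALSE` the two windows are identical.
#' @param flank flank length either side of the SNP; must be at least the
#'   motif length.
#' @param seed integer RNG seed.
#' @return A list with `window_ref`, `window_alt` (character sequences),
#'   `snp_index` (1-based SNP position within the window, always
#'   `flank + 1`), `truth_offset` (1-based window offset of the planted
#'   motif), `motif_column` (motif column covering the SNP), and the planted
#'   `ref_base`/`alt_base`.
#' @examples
#' pwm <- pfmToPwm(matrix(c(9, 1, 0, 0,
#'                          0, 8, 1, 1,
#'                          0, 0, 9, 1), byrow = TRUE, ncol = 4),
#'                 pseudocount = 0)
#' simulateMotifSite(pwm, disrupt = TRUE, flank = 5, seed = 3)
#' @export
simulateMotifSite <- function(pwm, planted_allele = NULL, disrupt = FALSE,
                              flank = 10L, seed = 1L) {
    stopifnot(methods::is(pwm, "PositionWeightMatrix"))
    L <- motifLength(pwm)
    flank <- as.integer(flank)
    if (flank < L)
        stop("'flank' (", flank, ") must be at least the motif length (",
             L, ")")
    withr::with_seed(as.integer(seed), {
        wlen <- 2L * flank + 1L
        snp_index <- flank + 1L
        window <- sample(DNA_BASES4, wlen, replace = TRUE)
        offs <- (snp_index - L + 1L):snp_index      # placements covering SNP
        o <- offs[sample.int(length(offs), 1L)]
        consensus <- DNA_BASES4[max.col(motifProbs(pwm), "first")]
        window[o:(o + L - 1L)] <- consensus
        col <- snp_index - o + 1L
        ref_base <- if (is.null(planted_allele)) consensus[col]
                    else toupper(as.character(planted_allele))
        if (!ref_base %in% DNA_BASES4)
            stop("'planted_allele' must be one of A, C, G, T")
        window[snp_index] <- ref_base
        alt_base <- if (disrupt)
            DNA_BASES4[which.min(motifProbs(pwm)[col, ])]
        else ref_base
        window_alt <- window
        window_alt[snp_index] <- alt_base
        list(window_ref = paste0(window, collapse = ""),
             window_alt = paste0(window_alt, collapse = ""),
             snp_index = snp_index, truth_offset = o, motif_column = col,
             ref_base = ref_base, alt_base = alt_base)
    })
}
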