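#' @include ASoCkit-package.R
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# ---- PositionWeightMatrix -------------------------------------------------

#' Position weight matrix
#'
#' An S4 container for a transcription-factor binding profile: an L x 4
#' matrix of per-position base probabilities (columns A, C, G, T) plus the
#' background base frequencies used for log2-odds scoring.
#'
#' @slot name single character, transcription-factor identifier.
#' @slot probs numeric L x 4 matrix; each row sums to 1.
#' @slot background numeric length-4 base frequencies summing to 1.
#'
#' @seealso [pfmToPwm()] to build one from raw counts, [scoreWindow()] and
#'   [scoreAlleles()] to use it.
#' @exportClass PositionWeightMatrix
setClass("PositionWeightMatrix",
    slots = c(name = "character", probs = "matrix", background = "numeric"))

setValidity("PositionWeightMatrix", function(object) {
    p <- object@probs
    msg <- character()
    if (!is.numeric(p) || ncol(p) != 4L || nrow(p) < 1L)
        msg <- c(msg, "'probs' must be a numeric L x 4 matrix with L >= 1")
    else {
        if (!identical(colnames(p), DNA_BASES4))
            msg <- c(msg, "'probs' columns must be named A, C, G, T")
        if (any(p < 0))
            msg <- c(msg, "'probs' must be non-negative")
        if (any(abs(rowSums(p) - 1) > 1e-6))
            msg <- c(msg, "each row of 'probs' must sum to 1 (+/- 1e-6)")
    }
    b <- object@background
    if (length(b) != 4L || any(b <= 0) || abs(sum(b) - 1) > 1e-6)
        msg <- c(msg, "'background' must be 4 positive frequencies summing to 1")
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a PositionWeightMatrix
#'
#' @param probs numeric L x 4 matrix of base probabilities (columns in order
#'   A, C, G, T; column names optional and reordered when present).
#' @param name transcription-factor identifier.
#' @param background length-4 background base frequencies (default uniform).
#' @return A [PositionWeightMatrix-class] object.
#' @examples
#' pwm <- PositionWeightMatrix(matrix(rep(0.25, 12), ncol = 4), name = "flat")
#' motifLength(pwm)
#' @export
PositionWeightMatrix <- function(probs, name = "motif",
                                 background = rep(0.25, 4)) {
    probs <- as.matrix(probs)
    if (!is.null(colnames(probs))) {
        if (!setequal(colnames(probs), DNA_BASES4))
            stop("'probs' column names must be A, C, G, T")
        probs <- probs[, DNA_BASES4, drop = FALSE]
    } else {
        colnames(probs) <- DNA_BASES4
    }
    background <- as.numeric(background)
    new("PositionWeightMatrix", name = as.character(name), probs = probs,
        background = background)
}

#' @describeIn PositionWeightMatrix motif length L.
#' @param x,object a `PositionWeightMatrix`.
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname PositionWeightMatrix
#' @export
setMethod("motifLength", "PositionWeightMatrix", function(x) nrow(x@probs))

#' @rdname PositionWeightMatrix
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname PositionWeightMatrix
#' @export
setMethod("motifName", "PositionWeightMatrix", function(x) x@name)

#' @rdname PositionWeightMatrix
#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @rdname PositionWeightMatrix
#' @export
setMethod("motifProbs", "PositionWeightMatrix", function(x) x@probs)

#' @rdname PositionWeightMatrix
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @rdname PositionWeightMatrix
#' @export
setMethod("motifBackground", "PositionWeightMatrix", function(x) x@background)

#' @rdname PositionWeightMatrix
#' @export
setMethod("show", "PositionWeightMatrix", function(object) {
    cat("PositionWeightMatrix", sQuote(object@name),
        sprintf("(%d positions)\n", nrow(object@probs)))
    cat("consensus:", paste0(DNA_BASES4[max.col(object@probs, "first")],
        collapse = ""), "\n")
})

# ---- CocultureExperiment --------------------------------------------------

#' Dual-species co-culture expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass for
#' transcript x sample counts from a mixed human/mouse library.  `rowData`
#' carries a `species` label (`"human"` or `"mouse"`) and optionally a
#' `gene_id`; `colData` carries the two-level `group` label together with the
#' per-sample `human_total` and `mouse_total` read counts that realise the
#' cellular-composition correction factor.
#'
#' @seealso [simulateCocultureCounts()], [splitBySpecies()],
#'   [correctionFactors()], [fitNbDe()].
#' @exportClass CocultureExperiment
setClass("CocultureExperiment", contains = "SummarizedExperiment")

setValidity("CocultureExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(is.na(cnt)))
        msg <- c(msg, "counts must be non-negative and non-missing")
    rd <- SummarizedExperiment::rowData(object)
    if (!"species" %in% colnames(rd) ||
        !all(rd$species %in% c("human", "mouse")))
        msg <- c(msg, "rowData(x)$species must be 'human' or 'mouse'")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData(x)$group is required")
    if (all(c("human_total", "mouse_total") %in% colnames(cd)) &&
        "species" %in% colnames(rd)) {
        ht <- colSums(cnt[rd$species == "human", , drop = FALSE])
        mt <- colSums(cnt[rd$species == "mouse", , drop = FALSE])
        if (any(ht != cd$human_total) || any(mt != cd$mouse_total))
            msg <- c(msg, "stored species totals disagree with the counts")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CocultureExperiment
#'
#' Per-sample species read totals are computed from `counts` and stored in
#' `colData` so that downstream correction factors are always consistent with
#' the matrix.
#'
#' @param counts non-negative integer matrix, transcripts x samples.
#' @param species character vector (one per transcript), `"human"`/`"mouse"`.
#' @param group character/factor vector (one per sample) with two levels,
#'   e.g. the edited genotypes `"TT"` and `"CC"`.
#' @param gene_id optional transcript-to-gene map (one gene id per
#'   transcript); transcripts without a gene are treated as their own gene.
#' @return A [CocultureExperiment-class].
#' @export
CocultureExperiment <- function(counts, species, group, gene_id = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("tx%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
    species <- as.character(species)
    group <- as.character(group)
    stopifnot(length(species) == nrow(counts), length(group) == ncol(counts))
    if (length(unique(group)) != 2L)
        stop("exactly two distinct group labels are required, got: ",
             paste(unique(group), collapse = ", "))
    rd <- S4Vectors::DataFrame(species = species, row.names = rownames(counts))
    if (!is.null(gene_id)) rd$gene_id <- as.character(gene_id)
    cd <- S4Vectors::DataFrame(
        group = group,
        human_total = colSums(counts[species == "human", , drop = FALSE]),
        mouse_total = colSums(counts[species == "mouse", , drop = FALSE]),
        row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    new("CocultureExperiment", se)
}

#' @rdname speciesLabels
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' Accessors for CocultureExperiment
#'
#' `speciesLabels()` returns the per-transcript species, `sampleGroups()` the
#' per-sample group label, `speciesTotals()` the per-sample human and mouse
#' read totals, and `correctionFactors()` the per-sample composition
#' correction table (human:mouse ratio and the species-specific effective
#' library sizes).
#'
#' @param x a [CocultureExperiment-class].
#' @return `correctionFactors()` returns a `data.frame` with columns
#'   `sample_id`, `human_total`, `mouse_total`, `ratio`.
#' @name speciesLabels
#' @export
setMethod("speciesLabels", "CocultureExperiment", function(x)
    SummarizedExperiment::rowData(x)$species)

#' @rdname speciesLabels
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname speciesLabels
#' @export
setMethod("sampleGroups", "CocultureExperiment", function(x)
    SummarizedExperiment::colData(x)$group)

#' @rdname speciesLabels
#' @export
setGeneric("speciesTotals", function(x) standardGeneric("speciesTotals"))

#' @rdname speciesLabels
#' @export
setMethod("speciesTotals", "CocultureExperiment", function(x) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    sp <- speciesLabels(x)
    cbind(human = colSums(cnt[sp == "human", , drop = FALSE]),
          mouse = colSums(cnt[sp == "mouse", , drop = FALSE]))
})

#' @rdname speciesLabels
#' @export
setGeneric("correctionFactors", function(x) standardGeneric("correctionFactors"))

#' @rdname speciesLabels
#' @export
setMethod("correctionFactors", "CocultureExperiment", function(x) {
    tot <- speciesTotals(x)
    bad <- which(tot[, "human"] == 0 | tot[, "mouse"] == 0)
    if (length(bad))
        stop("human:mouse ratio undefined (zero species total) for sample(s): ",
             paste(rownames(tot)[bad], collapse = ", "))
    data.frame(sample_id = colnames(x),
               human_total = tot[, "human"],
               mouse_total = tot[, "mouse"],
               ratio = tot[, "human"] / tot[, "mouse"],
               row.names = NULL)
})

#' @rdname speciesLabels
#' @param object a `CocultureExperiment` (for `show`).
#' @export
setMethod("show", "CocultureExperiment", function(object) {
    sp <- table(speciesLabels(object))
    gr <- table(sampleGroups(object))
    cat(sprintf("CocultureExperiment: %d transcripts (%s) x %d samples (%s)\n",
        nrow(object),
        paste(sprintf("%s %s", sp, names(sp)), collapse = ", "),
        ncol(object),
        paste(sprintf("%s x %s", gr, names(gr)), collapse = ", ")))
    callNextMethod()
})
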