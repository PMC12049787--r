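#' Partition a co-culture experiment by species
#'
#' Splits the transcript x sample counts into the human and mouse
#' sub-matrices (losslessly: per-sample totals are conserved) and computes
#' the per-sample composition correction factors.
#'
#' @param x a [CocultureExperiment-class].
#' @return list with `human` and `mouse` (`CocultureExperiment` row subsets)
#'   and `factors` (the [correctionFactors()] table).
#' @export
splitBySpecies <- function(x) {
    stopifnot(methods::is(x, "CocultureExperiment"))
    fac <- correctionFactors(x)     # errors on zero species totals
    sp <- speciesLabels(x)
    list(human = x[sp == "human", ],
         mouse = x[sp == "mouse", ],
         factors = fac)
}

#' Filter transcripts by expression prevalence
#'
#' Retains transcripts expressed (nonzero raw count) in at least
#' `min_fraction` of samples, the prevalence criterion applied before
#' differential expression.
#'
#' @param x a [CocultureExperiment-class] or a count matrix.
#' @param min_fraction required expressed-sample fraction (default 0.75).
#' @return the row-subset object of the same class.
#' @examples
#' m <- rbind(a = c(1, 1, 0), b = c(2, 5, 9))
#' expressionFilter(m, min_fraction = 0.75)   # drops 'a' (2/3 < 0.75)
#' @export
expressionFilter <- function(x, min_fraction = 0.75) {
    .check_prob(min_fraction, "min_fraction")
    cnt <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    keep <- rowSums(cnt > 0) >= min_fraction * ncol(cnt)
    x[keep, , drop = FALSE]
}

#' Counts per million with optional species-specific library sizes
#'
#' `CPM = 1e6 * count / effective library size`.  For a
#' [CocultureExperiment-class] with `per_species = TRUE` (default) each
#' transcript is normalised by its sample's total for that transcript's
#' species -- the composition correction factor realised as effective
#' library sizes.  A plain matrix is normalised by its column sums, or by
#' `library_sizes` when supplied.
#'
#' @param x `CocultureExperiment` or count matrix.
#' @param library_sizes optional per-sample sizes (vector) or a
#'   transcript x sample matrix of effective sizes.
#' @param per_species use species-specific totals for a
#'   `CocultureExperiment`.
#' @return numeric matrix of CPM values.
#' @export
computeCpm <- function(x, library_sizes = NULL, per_species = TRUE) {
    cnt <- if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (is.null(library_sizes)) {
        if (methods::is(x, "CocultureExperiment") && per_species) {
            tot <- speciesTotals(x)
            if (any(tot == 0))
                stop("zero species library size for sample(s): ",
                     paste(rownames(tot)[rowSums(tot == 0) > 0],
                           collapse = ", "))
            hrow <- speciesLabels(x) == "human"
            sizes <- matrix(rep(tot[, "mouse"], each = nrow(cnt)),
                            nrow(cnt), ncol(cnt))
            sizes[hrow, ] <- matrix(rep(tot[, "human"], each = sum(hrow)),
                                    sum(hrow), ncol(cnt))
        } else {
            ls <- colSums(cnt)
            if (any(ls == 0)) stop("zero library size in sample(s): ",
                                   paste(which(ls == 0), collapse = ", "))
            sizes <- matrix(ls, nrow(cnt), ncol(cnt), byrow = TRUE)
        }
    } else if (is.matrix(library_sizes)) {
        sizes <- library_sizes
    } else {
        if (any(library_sizes <= 0)) stop("library sizes must be > 0")
        sizes <- matrix(library_sizes, nrow(cnt), ncol(cnt), byrow = TRUE)
    }
    if (any(sizes <= 0)) stop("library sizes must be > 0")
    1e6 * cnt / sizes
}

#' Principal components of log2(CPM + 1)
#'
#' Samples are embedded on the principal components of the
#' transcript-centred `log2(CPM + 1)` matrix, the ordination used to check
#' that samples group by genotype.
#'
#' @param cpm_matrix transcripts x samples CPM matrix (see [computeCpm()]).
#' @param n_components number of components to return.
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return list with `coordinates` (samples x components),
#'   `explained_variance` (fractions, non-increasing, summing to <= 1) and
#'   `sdev`.
#' @export
pcaEmbed <- function(cpm_matrix, n_components = 2L, log_transform = TRUE) {
    m <- as.matrix(cpm_matrix)
    if (ncol(m) < 2L) stop("at least two samples are required")
    if (n_components > ncol(m))
        stop("more components requested than samples available")
    if (log_transform) m <- log2(m + 1)
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    ev <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
    k <- min(n_components, ncol(pc$x))
    list(coordinates = pc$x[, seq_len(k), drop = FALSE],
         explained_variance = ev, sdev = pc$sdev)
}

# ---- negative-binomial two-group differential expression ------------------

# Vectorised Fisher-scoring fit of log-linear NB models with fixed offsets,
# one model per matrix row.  Design is intercept-only (null = TRUE) or
# intercept + two-level group indicator.  phi is the per-row NB dispersion
# (variance mu + phi mu^2); phi is floored internally so phi -> 0 recovers
# Poisson behaviour.
.nb_fit <- function(y, off, xg, phi, null = FALSE, maxit = 30L, tol = 1e-8) {
    G <- nrow(y); S <- ncol(y)
    phi <- pmax(phi, 1e-6)
    xm <- matrix(xg, G, S, byrow = TRUE)
    b0 <- log(rowMeans(y / exp(off)) + 1e-8)
    b1 <- numeric(G)
    for (it in seq_len(maxit)) {
        eta <- pmin(pmax(b0 + b1 * xm, -50), 50)
        mu <- pmax(exp(off + eta), 1e-10)
        w <- mu / (1 + phi * mu)
        z <- eta + (y - mu) / mu
        if (null) {
            b0n <- rowSums(w * z) / rowSums(w)
            b1n <- b1
        } else {
            wx <- w * xm
            sw <- rowSums(w);  swx <- rowSums(wx)
            swxx <- rowSums(wx * xm)
            swz <- rowSums(w * z); swxz <- rowSums(wx * z)
            det <- pmax(sw * swxx - swx^2, 1e-300)
            b1n <- (sw * swxz - swx * swz) / det
            b0n <- (swz - swx * b1n) / sw
        }
        b0n <- pmin(pmax(b0n, -50), 50)
        b1n <- pmin(pmax(b1n, -50), 50)
        delta <- max(abs(b0n - b0), abs(b1n - b1))
        b0 <- b0n; b1 <- b1n
        if (delta < tol) break
    }
    eta <- pmin(pmax(b0 + b1 * xm, -50), 50)
    mu <- pmax(exp(off + eta), 1e-10)
    k <- 1 / phi
    ll <- rowSums(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
                  k * log(k / (k + mu)) + y * log(mu / (k + mu) + 1e-300))
    # Cox-Reid adjustment term: 0.5 * log det(X' W X) for the full design
    w <- mu / (1 + phi * mu)
    wx <- w * xm
    cr <- 0.5 * log(pmax(rowSums(w) * rowSums(wx * xm) - rowSums(wx)^2,
                         1e-300))
    list(b0 = b0, b1 = b1, ll = ll, cr = cr)
}

# Cox-Reid adjusted profile-likelihood dispersion on a log grid, then
# shrinkage of log(phi) toward a lowess mean-dispersion trend weighted by
# residual vs prior df.  The CR adjustment compensates the downward bias of
# plain profile likelihood from the two estimated mean parameters.
.estimate_dispersion <- function(y, off, xg, prior_df) {
    grid <- exp(seq(log(1e-6), log(5), length.out = 30L))
    ll <- matrix(-Inf, nrow(y), length(grid))
    for (j in seq_along(grid)) {
        fit <- .nb_fit(y, off, xg, rep(grid[j], nrow(y)))
        ll[, j] <- fit$ll - fit$cr
    }
    phi_hat <- grid[max.col(ll, "first")]
    a <- rowMeans(log2(y + 0.5))
    lo <- stats::lowess(a, log(phi_hat), f = 0.5)
    trend <- stats::approx(lo$x, lo$y, xout = a, rule = 2, ties = "ordered")$y
    resid_df <- max(ncol(y) - 2L, 1L)
    exp((prior_df * trend + resid_df * log(phi_hat)) /
        (prior_df + resid_df))
}

#' Negative-binomial two-group differential expression with composition
#' correction
#'
#' Fits, per transcript, a negative-binomial log-linear model with a
#' two-level group effect and fixed offsets, and tests the group coefficient
#' with a likelihood-ratio chi-square.  Dispersions are estimated per
#' transcript by profile likelihood and shrunk toward a lowess
#' mean-dispersion trend.  For a [CocultureExperiment-class] the default
#' offsets are the log per-sample species totals of each transcript's
#' species (`offset_mode = "species"`) -- the cellular-composition
#' correction factor -- so that differential expression is invariant to
#' shifts in the human:mouse mixing ratio; `offset_mode = "whole"` instead
#' uses one whole-library size per sample.
#'
#' @param x `CocultureExperiment`, or a count matrix (then `group` is
#'   required).
#' @param group two-level sample labels; the reported `log2fc` is the second
#'   level versus the first, levels in order of first appearance (for a
#'   `CocultureExperiment`, taken from `colData(x)$group`).
#' @param offsets optional log effective library sizes: a per-sample vector
#'   or a transcript x sample matrix; overrides `offset_mode`.
#' @param offset_mode `"species"` (default) or `"whole"`, see above.
#' @param fdr significance threshold: `significant <=> fdr < 0.05` scale,
#'   i.e. `q < fdr` strictly below.
#' @param dispersion optional fixed NB dispersion (scalar or per-transcript)
#'   bypassing estimation; mainly for calibration studies.
#' @param prior_df weight of the mean-dispersion trend in the shrinkage
#'   (default 10).
#' @param transcript_to_gene optional `data.frame` (`transcript_id`,
#'   `gene_id`) or named vector used when `x` carries no gene ids.
#' @return `data.frame` with one row per tested transcript: `transcript_id`,
#'   `gene_id`, `species` (when known), `mean_count`, `log2fc`, `p_value`,
#'   `fdr`, `significant`, `gene_representative` (see [representGenes()]).
#'   Transcripts with all-zero counts are excluded with a warning.
#' @examples
#' sim <- simulateCocultureCounts(cocultureSimConfig(
#'     n_transcripts_h = 150, n_transcripts_m = 100,
#'     n_samples_per_group = 4, seed = 5))
#' de <- fitNbDe(expressionFilter(sim$experiment))
#' head(de[order(de$p_value), ])
#' @export
fitNbDe <- function(x, group = NULL, offsets = NULL,
                    offset_mode = c("species", "whole"), fdr = 0.05,
                    dispersion = NULL, prior_df = 10,
                    transcript_to_gene = NULL) {
    offset_mode <- match.arg(offset_mode)
    is_ce <- methods::is(x, "CocultureExperiment")
    cnt <- if (is_ce) SummarizedExperiment::assay(x, "counts")
           else as.matrix(x)
    if (is.null(group)) {
        if (!is_ce) stop("'group' is required for a plain count matrix")
        group <- sampleGroups(x)
    }
    group <- as.character(group)
    lev <- unique(group)
    if (length(lev) != 2L)
        stop("exactly two group levels are required, got: ",
             paste(lev, collapse = ", "))
    if (any(table(group) < 2L))
        stop("each group needs at least 2 samples")
    xg <- as.numeric(group == lev[2L])

    if (is.null(offsets)) {
        if (is_ce && offset_mode == "species") {
            tot <- speciesTotals(x)
            if (any(tot == 0))
                stop("zero species library size for sample(s): ",
                     paste(rownames(tot)[rowSums(tot == 0) > 0],
                           collapse = ", "))
            hrow <- speciesLabels(x) == "human"
            off <- matrix(rep(log(tot[, "mouse"]), each = nrow(cnt)),
                          nrow(cnt), ncol(cnt))
            off[hrow, ] <- matrix(rep(log(tot[, "human"]), each = sum(hrow)),
                                  sum(hrow), ncol(cnt))
        } else {
            ls <- colSums(cnt)
            if (any(ls == 0)) stop("zero library size")
            off <- matrix(log(ls), nrow(cnt), ncol(cnt), byrow = TRUE)
        }
    } else if (is.matrix(offsets)) {
        off <- offsets
    } else {
        off <- matrix(offsets, nrow(cnt), ncol(cnt), byrow = TRUE)
    }

    nz <- rowSums(cnt) > 0
    if (!all(nz)) {
        warning(sum(!nz), " all-zero transcript(s) excluded from testing")
        cnt <- cnt[nz, , drop = FALSE]
        off <- off[nz, , drop = FALSE]
    }
    if (nrow(cnt) == 0L) stop("no transcripts left to test")

    phi <- if (is.null(dispersion))
        .estimate_dispersion(cnt, off, xg, prior_df)
    else rep_len(dispersion, nrow(cnt))
    full <- .nb_fit(cnt, off, xg, phi)
    null <- .nb_fit(cnt, off, xg, phi, null = TRUE)
    lrt <- pmax(0, 2 * (full$ll - null$ll))
    # quasi-F reference: the denominator df credits the information behind
    # the shrunken dispersion (residual + prior df), so that dispersion
    # estimation uncertainty widens the tail relative to a plain chi-square
    # (with a known, supplied dispersion the reference is exact chi-square)
    df2 <- if (is.null(dispersion)) max(ncol(cnt) - 2L, 1L) + prior_df
           else Inf
    p <- pmax(stats::pf(lrt, df1 = 1, df2 = df2, lower.tail = FALSE),
              .Machine$double.xmin)
    q <- bhAdjust(p)

    ids <- rownames(cnt)
    if (is.null(ids)) ids <- sprintf("tx%05d", which(nz))
    gene <- rep(NA_character_, length(ids))
    if (is_ce && "gene_id" %in%
        colnames(SummarizedExperiment::rowData(x)))
        gene <- SummarizedExperiment::rowData(x)$gene_id[nz]
    if (!is.null(transcript_to_gene)) {
        map <- if (is.data.frame(transcript_to_gene))
            stats::setNames(as.character(transcript_to_gene$gene_id),
                            transcript_to_gene$transcript_id)
        else transcript_to_gene
        gene <- unname(map[ids])
    }
    out <- data.frame(transcript_id = ids, gene_id = gene,
                      species = if (is_ce) speciesLabels(x)[nz]
                                else NA_character_,
                      mean_count = rowMeans(cnt),
                      log2fc = full$b1 / log(2),
                      p_value = p, fdr = q, significant = q < fdr,
                      stringsAsFactors = FALSE, row.names = NULL)
    representGenes(out)
}

#' Flag the transcript representing each gene
#'
#' Within each gene the top-ranked transcript -- smallest p-value, ties
#' broken by larger mean expression then lexicographic transcript id -- is
#' flagged as the gene representative.  Transcripts without a gene id are
#' treated as their own gene.
#'
#' @param de a differential-expression table from [fitNbDe()] (columns
#'   `transcript_id`, `p_value`, `mean_count`, and optionally `gene_id`).
#' @param transcript_to_gene optional map (`data.frame` with
#'   `transcript_id`/`gene_id`, or a named character vector) overriding the
#'   table's `gene_id`.
#' @return `de` with a logical `gene_representative` column (and a filled
#'   `gene_id`).
#' @export
representGenes <- function(de, transcript_to_gene = NULL) {
    stopifnot(all(c("transcript_id", "p_value", "mean_count") %in% names(de)))
    gene <- if ("gene_id" %in% names(de)) de$gene_id
            else rep(NA_character_, nrow(de))
    if (!is.null(transcript_to_gene)) {
        map <- if (is.data.frame(transcript_to_gene))
            stats::setNames(as.character(transcript_to_gene$gene_id),
                            transcript_to_gene$transcript_id)
        else transcript_to_gene
        gene <- unname(map[de$transcript_id])
    }
    gene <- ifelse(is.na(gene) | gene == "", de$transcript_id, gene)
    ord <- order(gene, de$p_value, -de$mean_count, de$transcript_id)
    first <- !duplicated(gene[ord])
    rep_flag <- logical(nrow(de))
    rep_flag[ord] <- first
    de$gene_id <- gene
    de$gene_representative <- rep_flag
    de
}
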