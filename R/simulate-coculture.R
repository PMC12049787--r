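#' Configuration for the dual-species co-culture RNA-seq simulator
#'
#' Defines the generative model for transcript counts from a mixed
#' human-neuron / mouse-astrocyte library.  Each sample draws a
#' human:mouse composition ratio `r` (log-normal around `ratio_mean` with
#' log-scale sd `ratio_sd`) and a library size `L` (log-normal around
#' `libsize_mean` with log-scale sd `libsize_sd`); human transcripts share
#' the expected `L * r / (1 + r)` reads, mouse transcripts `L / (1 + r)`.
#' Per-transcript relative abundances are log-normal within species;
#' a fraction of transcripts per species is differentially expressed with a
#' planted |log2 fold change| of `log2fc` (random sign, applied in the
#' second group); counts are negative-binomial with common dispersion
#' `nb_dispersion`, then independently zeroed with probability
#' `dropout_prob` to emulate unexpressed transcripts.
#'
#' The defaults emulate the study design at desk scale: 9 biological
#' replicates per genotype group (TT vs CC) and a few thousand transcripts
#' per species.
#'
#' @param n_transcripts_h,n_transcripts_m transcripts per species.
#' @param n_samples_per_group samples in each of the two groups.
#' @param groups the two group labels; the planted effect multiplies the
#'   second group, so true log2 fold changes are `groups[2]` vs `groups[1]`.
#' @param ratio_mean,ratio_sd human:mouse composition ratio distribution
#'   (median and log-scale sd of a log-normal; `ratio_sd = 0` fixes it).
#' @param frac_de_h,frac_de_m proportion of DE transcripts per species.
#' @param log2fc planted absolute log2 fold change.
#' @param nb_dispersion common NB dispersion (0 gives Poisson counts).
#' @param libsize_mean,libsize_sd library-size distribution (median and
#'   log-scale sd).
#' @param dropout_prob probability a transcript is unexpressed in a sample.
#' @param seed integer RNG seed.
#' @return An object of class `CocultureSimConfig` (validated list).
#' @seealso [simulateCocultureCounts()]
#' @export
cocultureSimConfig <- function(n_transcripts_h = 4000L,
                               n_transcripts_m = 3000L,
                               n_samples_per_group = 9L,
                               groups = c("TT", "CC"),
                               ratio_mean = 1, ratio_sd = 0.3,
                               frac_de_h = 0.1, frac_de_m = 0.1,
                               log2fc = 1, nb_dispersion = 0.1,
                               libsize_mean = 2e6, libsize_sd = 0.1,
                               dropout_prob = 0.05, seed = 1L) {
    .check_count(n_transcripts_h, "n_transcripts_h")
    .check_count(n_transcripts_m, "n_transcripts_m")
    .check_count(n_samples_per_group, "n_samples_per_group")
    if (length(groups) != 2L || anyDuplicated(groups))
        stop("'groups' must be two distinct labels")
    if (!is.finite(ratio_mean) || ratio_mean <= 0 ||
        !is.finite(ratio_sd) || ratio_sd < 0)
        stop("'ratio_mean' must be > 0 and 'ratio_sd' >= 0")
    .check_prob(frac_de_h, "frac_de_h")
    .check_prob(frac_de_m, "frac_de_m")
    .check_prob(dropout_prob, "dropout_prob")
    if (!is.finite(nb_dispersion) || nb_dispersion < 0)
        stop("'nb_dispersion' must be >= 0")
    if (!is.finite(libsize_mean) || libsize_mean <= 0 ||
        !is.finite(libsize_sd) || libsize_sd < 0)
        stop("'libsize_mean' must be > 0 and 'libsize_sd' >= 0")
    if (!is.finite(log2fc))
        stop("'log2fc' must be finite")
    structure(list(n_transcripts_h = as.integer(n_transcripts_h),
                   n_transcripts_m = as.integer(n_transcripts_m),
                   n_samples_per_group = as.integer(n_samples_per_group),
                   groups = as.character(groups),
                   ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                   frac_de_h = frac_de_h, frac_de_m = frac_de_m,
                   log2fc = log2fc, nb_dispersion = nb_dispersion,
                   libsize_mean = libsize_mean, libsize_sd = libsize_sd,
                   dropout_prob = dropout_prob, seed = as.integer(seed)),
              class = "CocultureSimConfig")
}

#' Simulate a dual-species co-culture count matrix with known truth
#'
#' @param config a [cocultureSimConfig()].
#' @return A list with elements
#'   * `experiment`: a [CocultureExperiment-class] (assay `counts`, rowData
#'     `species`/`gene_id`, colData `group` and species totals); gene ids
#'     group consecutive transcript pairs so that gene representation is
#'     exercised;
#'   * `truth`: list of `transcripts` (`transcript_id`, `species`, `is_de`,
#'     `log2fc` signed, `groups[2]` vs `groups[1]`) and `samples`
#'     (`sample_id`, `group`, `ratio`, `libsize`).
#' @examples
#' sim <- simulateCocultureCounts(cocultureSimConfig(
#'     n_transcripts_h = 100, n_transcripts_m = 80,
#'     n_samples_per_group = 3, seed = 2))
#' sim$experiment
#' @export
simulateCocultureCounts <- function(config) {
    if (!inherits(config, "CocultureSimConfig"))
        stop("'config' must come from cocultureSimConfig()")
    withr::with_seed(config$seed, {
        nh <- config$n_transcripts_h
        nm <- config$n_transcripts_m
        ns <- 2L * config$n_samples_per_group
        group <- rep(config$groups, each = config$n_samples_per_group)
        sample_id <- sprintf("%s_rep%02d", group,
                             rep(seq_len(config$n_samples_per_group), 2L))
        ratio <- stats::rlnorm(ns, log(config$ratio_mean), config$ratio_sd)
        libsize <- stats::rlnorm(ns, log(config$libsize_mean),
                                 config$libsize_sd)
        ab_h <- stats::rlnorm(nh, 0, 1); ab_h <- ab_h / sum(ab_h)
        ab_m <- stats::rlnorm(nm, 0, 1); ab_m <- ab_m / sum(ab_m)
        de_h <- stats::runif(nh) < config$frac_de_h
        de_m <- stats::runif(nm) < config$frac_de_m
        lfc <- c(ifelse(de_h, config$log2fc, 0),
                 ifelse(de_m, config$log2fc, 0)) *
            sample(c(-1, 1), nh + nm, replace = TRUE)
        in_g2 <- as.numeric(group == config$groups[2L])
        fold <- 2^outer(lfc, in_g2)                      # G x S multiplier
        share_h <- libsize * ratio / (1 + ratio)
        share_m <- libsize / (1 + ratio)
        base <- rbind(outer(ab_h, share_h), outer(ab_m, share_m))
        mu <- base * fold
        counts <- if (config$nb_dispersion == 0)
            stats::rpois(length(mu), mu)
        else
            stats::rnbinom(length(mu), size = 1 / config$nb_dispersion,
                           mu = mu)
        counts <- matrix(counts, nrow = nh + nm)
        if (config$dropout_prob > 0)
            counts[stats::runif(length(counts)) < config$dropout_prob] <- 0L
        transcript_id <- c(sprintf("htx%05d", seq_len(nh)),
                           sprintf("mtx%05d", seq_len(nm)))
        species <- rep(c("human", "mouse"), c(nh, nm))
        gene_id <- c(sprintf("hgene%05d", (seq_len(nh) + 1L) %/% 2L),
                     sprintf("mgene%05d", (seq_len(nm) + 1L) %/% 2L))
        dimnames(counts) <- list(transcript_id, sample_id)
        exper <- CocultureExperiment(counts, species, group, gene_id)
        truth <- list(
            transcripts = data.frame(transcript_id = transcript_id,
                                     species = species,
                                     is_de = c(de_h, de_m),
                                     log2fc = lfc, stringsAsFactors = FALSE),
            samples = data.frame(sample_id = sample_id, group = group,
                                 ratio = ratio, libsize = libsize,
                                 stringsAsFactors = FALSE))
        list(experiment = exper, truth = truth)
    })
}
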