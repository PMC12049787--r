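# TSV is the canonical interchange format; VCF/BED/PFM/MTX readers are
# adapters onto it.  All writers can prepend a '#'-prefixed provenance
# header echoing the package version and the full parameter set of the run
# so that thresholds are auditable; headers carry no timestamp so that
# identical runs produce identical files.

.provenance_lines <- function(command, params = list()) {
    c(sprintf("# ASoCkit %s", as.character(utils::packageVersion("ASoCkit"))),
      sprintf("# command: %s", command),
      if (length(params))
          sprintf("# %s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         character(1))))
}

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    head_lines <- readLines(path, n = 200L)
    skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
    data.table::fread(path, skip = skip, sep = "\t", header = TRUE,
                      data.table = FALSE)
}

.write_tsv <- function(df, path, command = NULL, params = list()) {
    if (!is.null(command))
        writeLines(.provenance_lines(command, params), path)
    data.table::fwrite(df, path, sep = "\t", append = !is.null(command),
                       col.names = TRUE)
    invisible(path)
}

#' Read / write allelic count tables
#'
#' The TSV schema is one row per (SNP, sample): `snp_id`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `sample_id`, `gt`, `ref_count`, `alt_count`,
#' optionally `dp` and `tranche`.  Lines starting with `#` are treated as a
#' provenance header and skipped on read.
#'
#' @param path file path.
#' @return `readAllelicTsv()`: the records `data.frame`.
#' @export
readAllelicTsv <- function(path) {
    .check_records(.read_tsv(path))
}

#' @rdname readAllelicTsv
#' @param records allelic count records.
#' @param params named list echoed into the provenance header.
#' @export
writeAllelicTsv <- function(records, path, params = list()) {
    .check_records(records)
    .write_tsv(records, path, command = "write-allelic-tsv", params = params)
}

#' Read per-sample allelic counts from a VCF
#'
#' Parses a VCF whose FORMAT carries `GT` and `AD` (and optionally `DP`)
#' into the long allelic-record table: one record per biallelic SNV site and
#' sample, `AD` split into `ref_count`/`alt_count`.  Multiallelic and
#' non-SNV sites are skipped with a counted warning.  Records of any
#' genotype are emitted (homozygous records are removed later by
#' [filterHetRecords()]).  Depth is recomputed as `ref + alt`; a disagreeing
#' `DP` field triggers a counted warning.
#'
#' @param path VCF file path.
#' @return allelic count records `data.frame`.
#' @export
readAllelicVcf <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    fmt <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
    for (f in c("GT", "AD"))
        if (!f %in% fmt) stop("VCF FORMAT lacks required field: ", f)
    refs <- VariantAnnotation::ref(vcf)
    alts <- VariantAnnotation::alt(vcf)
    nalt <- S4Vectors::elementNROWS(alts)
    alt1 <- rep(NA_character_, length(refs))
    alt1[nalt == 1L] <- as.character(unlist(alts))[cumsum(nalt)[nalt == 1L]]
    keep <- nalt == 1L & Biostrings::width(refs) == 1L &
        !is.na(alt1) & nchar(alt1) == 1L & alt1 %in% DNA_BASES4
    if (any(!keep))
        warning(sum(!keep), " multiallelic or non-SNV site(s) skipped")
    if (!any(keep)) return(.empty_records())
    vcf <- vcf[keep, ]
    alt1 <- alt1[keep]
    rr <- SummarizedExperiment::rowRanges(vcf)
    ids <- names(rr)
    if (is.null(ids))
        ids <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(rr)),
                       GenomicRanges::start(rr))
    gt <- VariantAnnotation::geno(vcf)$GT
    ad <- VariantAnnotation::geno(vcf)$AD
    dp <- if ("DP" %in% fmt) VariantAnnotation::geno(vcf)$DP else NULL
    samples <- colnames(gt)
    rows <- list(); n_dp_mismatch <- 0L
    for (j in seq_along(samples)) {
        for (i in seq_len(nrow(gt))) {
            g <- gt[i, j]
            if (is.na(g) || g == "") next
            adv <- if (is.list(ad)) ad[[i, j]] else ad[i, j, ]
            if (all(is.na(adv))) next
            rc <- as.integer(adv[1L]); ac <- as.integer(adv[2L])
            if (!is.null(dp) && !is.na(dp[i, j]) &&
                dp[i, j] != rc + ac)
                n_dp_mismatch <- n_dp_mismatch + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                snp_id = ids[i],
                chrom = as.character(GenomicRanges::seqnames(rr))[i],
                pos = GenomicRanges::start(rr)[i],
                ref = as.character(refs[keep])[i],
                alt = alt1[i], sample_id = samples[j], gt = g,
                ref_count = rc, alt_count = ac, stringsAsFactors = FALSE)
        }
    }
    if (n_dp_mismatch)
        warning(n_dp_mismatch, " record(s) had DP disagreeing with ",
                "ref + alt allele depths; depth is recomputed downstream")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.empty_records <- function() {
    data.frame(snp_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), sample_id = character(),
               gt = character(), ref_count = integer(),
               alt_count = integer(), stringsAsFactors = FALSE)
}

#' @rdname readAllelicVcf
#' @param records allelic count records to serialise (minimal VCF with
#'   FORMAT `GT:AD:DP`; samples missing a record at a site get `./.`).
#' @export
writeAllelicVcf <- function(records, path) {
    .check_records(records)
    samples <- sort(unique(records$sample_id))
    dt <- data.table::as.data.table(records)
    data.table::setorder(dt, chrom, pos)
    sites <- unique(dt[, c("snp_id", "chrom", "pos", "ref", "alt")])
    body <- vapply(seq_len(nrow(sites)), function(i) {
        s <- sites[i, ]
        rec <- dt[dt$snp_id == s$snp_id, ]
        cells <- vapply(samples, function(sm) {
            r <- rec[rec$sample_id == sm, ]
            if (nrow(r) == 0L) return("./.:.,.:.")
            sprintf("%s:%d,%d:%d", r$gt[1L], r$ref_count[1L], r$alt_count[1L],
                    r$ref_count[1L] + r$alt_count[1L])
        }, character(1))
        paste(c(s$chrom, s$pos, s$snp_id, s$ref, s$alt, ".", ".", ".",
                "GT:AD:DP", cells), collapse = "\t")
    }, character(1))
    header <- c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read / write BED3 peak intervals
#'
#' `readBed()` parses tab-separated BED (0-based, half-open), validates
#' `end > start` (reporting the first offending line), and returns a sorted
#' 1-based [GenomicRanges::GRanges]; `writeBed()` converts back.  The
#' 0-based/1-based conversion happens only here.
#'
#' @param path BED file path.
#' @return a `GRanges` of peaks.
#' @export
readBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) return(GenomicRanges::GRanges())
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            data.table = FALSE)
    if (ncol(dt) < 3L) stop("BED requires at least 3 tab-separated columns")
    bad <- which(dt[[3L]] <= dt[[2L]])
    if (length(bad))
        stop("invalid BED interval (end <= start) at line ", bad[1L])
    ord <- order(dt[[1L]], dt[[2L]], dt[[3L]])
    GenomicRanges::GRanges(dt[[1L]][ord],
                           IRanges::IRanges(start = dt[[2L]][ord] + 1L,
                                            end = dt[[3L]][ord]))
}

#' @rdname readBed
#' @param peaks a `GRanges` (1-based, e.g. from [simulatePeaks()]).
#' @export
writeBed <- function(peaks, path) {
    stopifnot(methods::is(peaks, "GRanges"))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks) - 1L,
                     end = GenomicRanges::end(peaks))
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Parses the JASPAR flat format: a `>NAME` header line followed by four
#' rows `A [ 1 2 ... ]` (brackets optional, fractional counts allowed, base
#' rows in any order).  A headerless block of four numeric rows is accepted
#' as a single unnamed motif in A, C, G, T order.
#'
#' @param path PFM file path.
#' @param simplify return the bare matrix when the file holds one motif
#'   (default `TRUE`); otherwise a named list of matrices.
#' @return L x 4 count matrix (columns A, C, G, T, motif name in
#'   `attr(, "name")`), or a named list of such matrices.
#' @export
readPfm <- function(path, simplify = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty PFM file: ", path)
    hdr <- grep("^>", lines)
    blocks <- if (length(hdr)) {
        ends <- c(hdr[-1L] - 1L, length(lines))
        lapply(seq_along(hdr), function(i)
            list(name = sub("^>\\s*", "", lines[hdr[i]]),
                 rows = lines[seq(hdr[i] + 1L, ends[i])]))
    } else {
        list(list(name = "motif", rows = lines))
    }
    mats <- lapply(blocks, function(b) {
        parsed <- lapply(b$rows, function(r) {
            base <- NA_character_
            if (grepl("^[ACGTacgt]\\b", r) || grepl("^[ACGTacgt]\\s*\\[", r)) {
                base <- toupper(substr(r, 1L, 1L))
                r <- sub("^[ACGTacgt]", "", r)
            }
            r <- gsub("[][|]", " ", r)
            vals <- suppressWarnings(as.numeric(strsplit(trimws(r),
                                                         "\\s+")[[1L]]))
            if (any(is.na(vals))) stop("unparseable PFM row: ", r)
            list(base = base, vals = vals)
        })
        bases <- vapply(parsed, `[[`, character(1), "base")
        if (all(is.na(bases))) {
            if (length(parsed) != 4L)
                stop("headerless PFM block must have exactly 4 rows")
            bases <- DNA_BASES4
        }
        if (!setequal(bases, DNA_BASES4))
            stop("PFM block ", sQuote(b$name), " must have rows A, C, G, T",
                 " (missing: ",
                 paste(setdiff(DNA_BASES4, bases), collapse = ", "), ")")
        lens <- vapply(parsed, function(p) length(p$vals), integer(1))
        if (length(unique(lens)) != 1L)
            stop("PFM rows of unequal length in block ", sQuote(b$name))
        m <- do.call(cbind, lapply(parsed, `[[`, "vals"))
        colnames(m) <- bases
        m <- m[, DNA_BASES4, drop = FALSE]
        attr(m, "name") <- b$name
        m
    })
    names(mats) <- vapply(blocks, `[[`, character(1), "name")
    if (simplify && length(mats) == 1L) mats[[1L]] else mats
}

#' Read / write transcript count matrices and sample tables
#'
#' `readCountsTsv()` expects transcripts in rows (first column the
#' transcript id) and samples in columns; `readCountsMtx()` reads a
#' MatrixMarket file plus row/column name sidecars.  `readTsvMap()` reads
#' small key-value tables (species map, transcript-to-gene map, sample
#' groups).
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @return a numeric matrix with dimnames, or a `data.frame` for maps.
#' @export
readCountsTsv <- function(path) {
    df <- .read_tsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    m
}

#' @rdname readCountsTsv
#' @param counts matrix to write (row names become the first column).
#' @param params provenance parameters.
#' @export
writeCountsTsv <- function(counts, path, params = list()) {
    df <- data.frame(transcript_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df, path, command = "write-counts-tsv", params = params)
}

#' @rdname readCountsTsv
#' @param rows_path,cols_path sidecar files with one row/column name per
#'   line.
#' @export
readCountsMtx <- function(path, rows_path, cols_path) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rows_path)
    colnames(m) <- readLines(cols_path)
    m
}

#' @rdname readCountsTsv
#' @export
readTsvMap <- function(path) {
    .read_tsv(path)
}
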