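#' Allele read-count records
#'
#' The central input container of the package: a long-format data frame with
#' one row per (sample, locus, allele), holding the number of reads
#' supporting the allele and the mean phred base quality of those reads.
#' Loci are identified as `contig:position` with 1-based positions (VCF
#' convention). Allele labels are single bases (`A`/`C`/`G`/`T`) or the
#' single-base deletion symbol `"-"`.
#'
#' @param df data frame with columns `sample_id`, `locus_id`, `allele`,
#'   `count`, `mean_phred`.
#' @return `df` validated and classed as `allele_counts`.
#' @export
as_allele_counts <- function(df) {
  req <- c("sample_id", "locus_id", "allele", "count", "mean_phred")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("allele_counts is missing column(s): ", paste(miss, collapse = ", "))
  df$count <- as.integer(df$count)
  df$mean_phred <- as.numeric(df$mean_phred)
  if (anyNA(df$count) || any(df$count < 0L))
    stop("allele counts must be non-negative integers")
  if (any(df$mean_phred < 0, na.rm = TRUE))
    stop("mean phred qualities must be non-negative")
  dup <- duplicated(df[, c("sample_id", "locus_id", "allele")])
  if (any(dup))
    stop("duplicate allele label within a (sample, locus) record: ",
         paste(utils::head(df$locus_id[dup], 3L), collapse = ", "))
  class(df) <- unique(c("allele_counts", class(df)))
  df
}

#' Read a tabular per-sample variant table
#'
#' Reads tab-separated variant tables (one row per observed allele at a
#' variant position, in the style of per-sample variant exports from read
#' mappers) into [as_allele_counts()] long format. Column names and the
#' position base convention are declared by a dialect object so differently
#' labelled exports can be ingested without rewriting.
#'
#' @param path path to a tab-separated file with a header line.
#' @param dialect a [variant_table_dialect()].
#' @param sample_id sample identifier used when the dialect declares no
#'   sample column.
#' @return an `allele_counts` data frame; row order of alleles within each
#'   locus is preserved as read.
#' @export
read_variant_table <- function(path, dialect = variant_table_dialect(),
                               sample_id = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c(dialect$locus, dialect$allele, dialect$count, dialect$phred,
            dialect$sample)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- data.frame(sample_id = character(), locus_id = character(),
                      allele = character(), count = integer(),
                      mean_phred = numeric(), stringsAsFactors = FALSE)
    return(as_allele_counts(out))
  }
  sid <- if (is.null(dialect$sample)) {
    if (is.null(sample_id)) stop("dialect has no sample column; supply sample_id")
    rep(sample_id, nrow(df))
  } else as.character(df[[dialect$sample]])
  locus <- as.character(df[[dialect$locus]])
  if (identical(dialect$base, 0L)) {
    # convert 0-based positions in contig:pos ids to the 1-based convention
    parts <- regmatches(locus, regexpr(":[0-9]+$", locus))
    pos <- as.integer(sub(":", "", parts)) + 1L
    locus <- paste0(sub(":[0-9]+$", "", locus), ":", pos)
  }
  cnt <- df[[dialect$count]]
  if (any(cnt < 0, na.rm = TRUE)) stop("negative read count in variant table")
  out <- data.frame(sample_id = sid, locus_id = locus,
                    allele = as.character(df[[dialect$allele]]),
                    count = as.integer(cnt),
                    mean_phred = as.numeric(df[[dialect$phred]]),
                    stringsAsFactors = FALSE)
  as_allele_counts(out)
}

#' Declare the column layout of a tabular variant table
#'
#' @param locus,allele,count,phred column names holding the locus id, allele
#'   label, read count and mean phred quality.
#' @param sample optional column name holding the sample id (multi-sample
#'   tables); `NULL` for one-sample-per-file tables.
#' @param base position base convention of the locus ids: `1` (default,
#'   1-based) or `0` (converted to 1-based on read).
#' @return a dialect list consumed by [read_variant_table()].
#' @export
variant_table_dialect <- function(locus = "locus_id", allele = "allele",
                                  count = "count", phred = "mean_phred",
                                  sample = "sample_id", base = 1L) {
  base <- as.integer(base)
  if (!base %in% c(0L, 1L)) stop("base convention must be 0 or 1")
  list(locus = locus, allele = allele, count = count, phred = phred,
       sample = sample, base = base)
}

#' Read per-sample allele depths from a VCF
#'
#' Extracts the per-sample `AD` (allele depth) FORMAT field of a VCF into
#' long [as_allele_counts()] format, one record per sample x variant site.
#' Sites whose alleles are not all single bases (or the spanning-deletion
#' symbol `*`, re-coded to `"-"`) are dropped with a message, as are
#' sample-site entries without depth information. VCFs do not carry
#' per-allele base qualities, so `mean_phred` is filled with
#' `default_phred`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of sample ids to keep.
#' @param default_phred phred quality assigned to every allele (default 30,
#'   a typical Illumina base quality).
#' @param verbose emit ingestion messages to stderr.
#' @return an `allele_counts` data frame.
#' @export
read_vcf_allele_depths <- function(path, sample_subset = NULL,
                                   default_phred = 30, verbose = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  fmt_ids <- colnames(vcf@gt)[-1L]
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, fmt_ids)
    if (length(unknown))
      stop("sample(s) not present in VCF: ", paste(unknown, collapse = ", "))
    keep_s <- fmt_ids %in% sample_subset
  } else keep_s <- rep(TRUE, length(fmt_ids))
  samples <- fmt_ids[keep_s]

  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF carries no AD (allele depth) FORMAT field")
  ad <- ad[, samples, drop = FALSE]

  locus <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  alle <- strsplit(paste(fix[, "REF"], fix[, "ALT"], sep = ","), ",",
                   fixed = TRUE)
  alle <- lapply(alle, function(a) ifelse(a == "*", "-", a))
  ok_site <- vapply(alle, function(a)
    all(nchar(a) == 1L & a %in% c("A", "C", "G", "T", "-")), logical(1L))
  n_bad <- sum(!ok_site)
  if (n_bad > 0L && verbose)
    message(n_bad, " site(s) with non-SNV/multi-base alleles dropped at ingestion")

  nal <- lengths(alle)
  pieces <- vector("list", length(samples))
  n_skipped <- 0L
  for (s in seq_along(samples)) {
    adc <- ad[, s]
    usable <- ok_site & !is.na(adc) & adc != "."
    n_skipped <- n_skipped + sum(ok_site & !(!is.na(adc) & adc != "."))
    if (!any(usable)) next
    spl <- strsplit(adc[usable], ",", fixed = TRUE)
    if (!all(lengths(spl) == nal[usable]))
      stop("malformed AD field for sample ", samples[s], " (site ",
           locus[usable][which(lengths(spl) != nal[usable])[1L]], ")")
    idx <- rep(which(usable), nal[usable])
    pieces[[s]] <- data.frame(
      sample_id = samples[s],
      locus_id = locus[idx],
      allele = unlist(alle[usable], use.names = FALSE),
      count = suppressWarnings(as.integer(unlist(spl, use.names = FALSE))),
      mean_phred = default_phred,
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L && verbose)
    message(n_skipped, " sample-site entr(ies) without depth information skipped")
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(sample_id = character(), locus_id = character(),
                      allele = character(), count = integer(),
                      mean_phred = numeric(), stringsAsFactors = FALSE)
  if (anyNA(out$count)) stop("non-numeric AD entry in VCF")
  as_allele_counts(out)
}
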