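#' Filter-stage report
#'
#' Bookkeeping record emitted by every filtering operation: stage name,
#' items in, items out, and the dropped identifiers.
#'
#' @param stage stage name.
#' @param items_in,items_out item counts before and after.
#' @param dropped_ids optional character vector of removed ids.
#' @return a `filter_report` list.
#' @export
filter_report <- function(stage, items_in, items_out, dropped_ids = NULL) {
  if (items_out > items_in) stop("filter cannot create items")
  structure(list(stage = stage, items_in = as.integer(items_in),
                 items_out = as.integer(items_out),
                 dropped_ids = dropped_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d (dropped %d)\n", x$stage, x$items_in,
              x$items_out, x$items_in - x$items_out))
  invisible(x)
}

#' Summarize a list of filter reports as a data frame
#'
#' @param reports list of [filter_report()]s in execution order.
#' @return data frame with columns `stage`, `items_in`, `items_out`,
#'   `n_dropped`.
#' @export
filter_report_table <- function(reports) {
  data.frame(stage = vapply(reports, `[[`, "", "stage"),
             items_in = vapply(reports, `[[`, 0L, "items_in"),
             items_out = vapply(reports, `[[`, 0L, "items_out"),
             n_dropped = vapply(reports, function(r) r$items_in - r$items_out,
                                0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep only single-nucleotide variants and single-base deletions
#'
#' Drops loci whose observed allele labels are not all single bases
#' (`A`/`C`/`G`/`T`) or the single-base deletion symbol `"-"`.
#'
#' @param records `allele_counts` records.
#' @return list with `records` (kept rows) and `report`.
#' @export
filter_variant_type <- function(records) {
  ok_allele <- nchar(records$allele) == 1L &
    records$allele %in% c("A", "C", "G", "T", "-")
  bad_loci <- unique(records$locus_id[!ok_allele])
  loci_in <- unique(records$locus_id)
  keep <- !(records$locus_id %in% bad_loci)
  list(records = records[keep, , drop = FALSE],
       report = filter_report("variant_type", length(loci_in),
                              length(loci_in) - length(bad_loci), bad_loci))
}

#' Exclude samples with too few raw reads
#'
#' Removes samples whose raw sequencing read count is strictly below
#' `min_reads` (default one million).
#'
#' @param meta sample metadata data frame with `sample_id` and
#'   `raw_read_count`.
#' @param min_reads threshold (strict `<`; exactly `min_reads` is kept).
#' @return list with `kept_ids` and `report`.
#' @export
filter_samples_raw_reads <- function(meta, min_reads = 1e6) {
  if (anyNA(meta$raw_read_count))
    stop("raw_read_count missing for sample(s): ",
         paste(meta$sample_id[is.na(meta$raw_read_count)], collapse = ", "))
  drop <- meta$raw_read_count < min_reads
  list(kept_ids = meta$sample_id[!drop],
       report = filter_report("raw_reads", nrow(meta), sum(!drop),
                              meta$sample_id[drop]))
}

#' Keep loci present in a minimum fraction of samples
#'
#' @param gm a [genotype_matrix()].
#' @param min_presence minimum fraction of samples with a non-missing call
#'   (inclusive; default 0.8).
#' @return list with `matrix` and `report`.
#' @export
filter_locus_presence <- function(gm, min_presence = 0.8) {
  pres <- 1 - missing_fraction(gm, "locus")
  keep <- pres >= min_presence - 1e-12
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE], gm$ploidy)
  list(matrix = out,
       report = filter_report("locus_presence", ncol(gm$calls), sum(keep),
                              colnames(gm$calls)[!keep]))
}

#' Exclude samples with excessive missing data
#'
#' Removes samples whose missing fraction is strictly above `max_missing`
#' over the current locus set (apply [filter_locus_presence()] first to
#' compute missingness on the well-covered locus set).
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (strict `>`;
#'   exactly `max_missing` is kept; default 0.5).
#' @return list with `matrix` and `report`.
#' @export
filter_sample_missingness <- function(gm, max_missing = 0.5) {
  mf <- missing_fraction(gm, "sample")
  keep <- mf <= max_missing + 1e-12
  out <- genotype_matrix(gm$calls[keep, , drop = FALSE], gm$ploidy[keep])
  list(matrix = out,
       report = filter_report("sample_missingness", nrow(gm$calls), sum(keep),
                              rownames(gm$calls)[!keep]))
}

locus_allele_sets <- function(gm) {
  lapply(seq_len(ncol(gm$calls)), function(j) {
    col <- gm$calls[, j]
    sort(unique(unlist(lapply(col[!is.na(col)], function(s)
      names(parse_genotype(s))), use.names = FALSE)))
  })
}

#' Remove monomorphic loci
#'
#' Drops loci at which all non-missing calls carry a single allele (or no
#' call at all).
#'
#' @param gm a [genotype_matrix()].
#' @return list with `matrix` and `report`.
#' @export
drop_monomorphic <- function(gm) {
  nal <- lengths(locus_allele_sets(gm))
  keep <- nal >= 2L
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE], gm$ploidy)
  list(matrix = out,
       report = filter_report("monomorphic", ncol(gm$calls), sum(keep),
                              colnames(gm$calls)[!keep]))
}

#' Classify loci by allelicity
#'
#' Counts the distinct alleles across all non-missing calls at each locus.
#'
#' @param gm a [genotype_matrix()].
#' @return list with `category` (named character: `monomorphic`,
#'   `biallelic`, `triallelic`, `tetra-allelic`, `multi-allelic`) and
#'   `counts` (table).
#' @export
classify_allelicity <- function(gm) {
  nal <- lengths(locus_allele_sets(gm))
  cat_names <- c("monomorphic", "biallelic", "triallelic", "tetra-allelic")
  category <- ifelse(nal <= 4L & nal >= 1L, cat_names[pmax(nal, 1L)],
                     "multi-allelic")
  category[nal == 0L] <- "monomorphic"
  names(category) <- colnames(gm$calls)
  list(category = category, counts = table(category))
}

#' Run the canonical filtering cascade on a genotype matrix
#'
#' Applies, in order: locus presence filter, sample missingness filter
#' (computed on the well-covered locus set), locus presence re-applied to
#' the reduced sample set, and monomorphic-locus removal. Variant-type and
#' raw-read filters act upstream of genotyping ([filter_variant_type()],
#' [filter_samples_raw_reads()]); genotype-level coverage filtering lives
#' in the dosage caller, whose non-called statuses appear here as missing.
#'
#' @param gm a [genotype_matrix()].
#' @param min_presence inclusive minimum locus presence (default 0.8).
#' @param max_missing strict maximum sample missingness (default 0.5).
#' @return list with `matrix` (filtered) and `reports` (stage list).
#' @export
apply_filter_cascade <- function(gm, min_presence = 0.8, max_missing = 0.5) {
  s1 <- filter_locus_presence(gm, min_presence)
  s2 <- filter_sample_missingness(s1$matrix, max_missing)
  s3 <- filter_locus_presence(s2$matrix, min_presence)
  s4 <- drop_monomorphic(s3$matrix)
  list(matrix = s4$matrix,
       reports = list(s1$report, s2$report, s3$report, s4$report))
}
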