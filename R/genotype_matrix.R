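#' Genotype matrix with per-sample ploidy
#'
#' Samples x loci collection of allele-dosage genotype calls. Calls are
#' stored as canonical genotype strings (`"A:3,T:1"`: allele labels with
#' copy numbers, sorted by decreasing dosage then allele label); missing
#' calls are `NA`. Every non-missing call must sum to the sample's ploidy.
#'
#' @param calls character matrix (samples in rows, loci in columns, both
#'   dimnamed) of genotype strings, `NA` for missing.
#' @param ploidy named integer vector of per-sample ploidies, names matching
#'   `rownames(calls)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, ploidy) {
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have sample row names and locus column names")
  ploidy <- ploidy[rownames(calls)]
  if (anyNA(ploidy))
    stop("ploidy missing for sample(s): ",
         paste(rownames(calls)[is.na(ploidy)], collapse = ", "))
  storage.mode(calls) <- "character"
  obj <- structure(list(calls = calls, ploidy = as.integer(setNames(ploidy, rownames(calls)))),
                   class = "genotype_matrix")
  names(obj$ploidy) <- rownames(calls)
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(gm) {
  u <- unique(gm$calls[!is.na(gm$calls)])
  tot <- vapply(u, function(s) sum(parse_genotype(s)), integer(1L))
  bad_by_str <- setNames(tot, u)
  for (i in seq_len(nrow(gm$calls))) {
    row <- gm$calls[i, ]
    nz <- !is.na(row)
    if (any(nz) && any(bad_by_str[row[nz]] != gm$ploidy[i]))
      stop("call with copy-number sum != ploidy for sample ",
           rownames(gm$calls)[i])
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "loci\n")
  cat("ploidies:", paste(sprintf("%dx:%d", as.integer(names(table(x$ploidy))),
                                 as.integer(table(x$ploidy))), collapse = " "), "\n")
  mf <- mean(is.na(x$calls))
  cat(sprintf("missing: %.1f%%\n", 100 * mf))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Parse / format canonical genotype strings
#'
#' @param s genotype string such as `"A:3,T:1"`.
#' @return `parse_genotype`: named integer vector of copy numbers;
#'   `format_genotype`: canonical string (dosage-descending, allele label as
#'   tie-break), zero dosages dropped.
#' @export
parse_genotype <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(as.integer(vapply(kv, `[`, "", 2L)), vapply(kv, `[`, "", 1L))
}

#' @rdname parse_genotype
#' @param dosages named integer vector (allele -> copy number).
#' @export
format_genotype <- function(dosages) {
  dosages <- dosages[dosages > 0L]
  ord <- order(-dosages, names(dosages))
  paste(names(dosages)[ord], dosages[ord], sep = ":", collapse = ",")
}

#' Missing-data fractions of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param by `"sample"` or `"locus"`.
#' @return named numeric vector of missing fractions.
#' @export
missing_fraction <- function(gm, by = c("sample", "locus")) {
  by <- match.arg(by)
  if (by == "sample") rowMeans(is.na(gm$calls)) else colMeans(is.na(gm$calls))
}

fmt_version <- "v1"

#' Write / read the genotype-matrix interchange format
#'
#' Plain TSV with two header comment lines (format version; per-sample
#' ploidies), then a sample-by-locus table of canonical genotype strings
#' with `.` as the missing code. The round trip `read(write(m))` is
#' lossless.
#'
#' @param gm a [genotype_matrix()].
#' @param path output (input) file path.
#' @return `write_genotype_matrix`: `path`, invisibly;
#'   `read_genotype_matrix`: a [genotype_matrix()].
#' @export
write_genotype_matrix <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#radosage_genotype_matrix\t", fmt_version), con)
  writeLines(paste0("#ploidy\t", paste(names(gm$ploidy), gm$ploidy,
                                       sep = "=", collapse = "\t")), con)
  m <- gm$calls
  m[is.na(m)] <- "."
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m), apply(m, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#radosage_genotype_matrix"))
    stop("not a radosage genotype matrix file: ", path)
  ver <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2L]
  if (!identical(ver, fmt_version))
    stop("genotype matrix format version mismatch: file has ", ver,
         ", reader expects ", fmt_version)
  pl <- strsplit(sub("^#ploidy\t", "", lines[2L]), "\t", fixed = TRUE)[[1L]]
  kv <- strsplit(pl, "=", fixed = TRUE)
  ploidy <- setNames(as.integer(vapply(kv, `[`, "", 2L)),
                     vapply(kv, `[`, "", 1L))
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  loci <- header[-1L]
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  samples <- vapply(body, `[`, "", 1L)
  calls <- t(vapply(body, function(r) r[-1L], character(length(loci))))
  if (length(loci) == 1L) calls <- matrix(calls, ncol = 1L)
  calls[calls == "."] <- NA_character_
  dimnames(calls) <- list(samples, loci)
  genotype_matrix(calls, ploidy)
}

#' Export a mixed-ploidy genotype matrix in STRUCTURE format
#'
#' Writes the one-row-per-allele-copy STRUCTURE input with every individual
#' occupying exactly four rows so diploids, triploids and tetraploids can
#' be analysed together: a tetraploid's four allele copies fill all four
#' rows, a triploid's three copies fill rows 1-3, a diploid's two copies
#' fill rows 1-2, and all remaining rows carry the missing code. Missing
#' calls are the missing code in all rows. Allele codes are 1-based integer
#' indices assigned by allele sort order per locus.
#'
#' @param gm a [genotype_matrix()] with all ploidies <= 4. Only biallelic
#'   (or less variable) loci can be coded meaningfully by STRUCTURE's
#'   integer recoding; loci of any allelicity are recoded by sorted allele
#'   index.
#' @param meta optional sample metadata data frame with `sample_id` and
#'   `population_id`; if supplied, a 1-based integer population column is
#'   written after the sample id.
#' @param path output file path.
#' @param missing_code integer missing-data code (default -9).
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(gm, meta = NULL, path,
                                 missing_code = -9L) {
  if (any(gm$ploidy > 4L))
    stop("STRUCTURE export supports ploidy <= 4; offending sample(s): ",
         paste(names(gm$ploidy)[gm$ploidy > 4L], collapse = ", "))
  calls <- gm$calls
  loci <- colnames(calls)
  # per-locus allele code book: 1-based index in allele sort order
  codebook <- lapply(seq_along(loci), function(j) {
    col <- calls[, j]
    al <- sort(unique(unlist(lapply(col[!is.na(col)],
                                    function(s) names(parse_genotype(s))))))
    setNames(seq_along(al), al)
  })
  popcol <- NULL
  if (!is.null(meta)) {
    idx <- match(rownames(calls), meta$sample_id)
    if (anyNA(idx)) stop("meta lacks sample(s): ",
                         paste(rownames(calls)[is.na(idx)], collapse = ", "))
    popcol <- as.integer(factor(meta$population_id[idx]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  for (i in seq_len(nrow(calls))) {
    k <- gm$ploidy[i]
    rows <- matrix(missing_code, nrow = 4L, ncol = length(loci))
    for (j in seq_along(loci)) {
      s <- calls[i, j]
      if (is.na(s)) next
      g <- parse_genotype(s)
      codes <- sort(rep(codebook[[j]][names(g)], g))
      rows[seq_len(k), j] <- codes
    }
    lead <- if (is.null(popcol)) rownames(calls)[i] else
      paste(rownames(calls)[i], popcol[i], sep = "\t")
    writeLines(paste(lead, apply(rows, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}
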