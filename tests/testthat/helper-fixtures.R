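# Small in-code fixtures shared across test files.

# genotype matrix from a list of named rows (sample -> named vector of
# genotype strings by locus); NA entries are missing
make_gm <- function(rows, ploidy) {
  loci <- unique(unlist(lapply(rows, names)))
  calls <- matrix(NA_character_, nrow = length(rows), ncol = length(loci),
                  dimnames = list(names(rows), loci))
  for (s in names(rows)) calls[s, names(rows[[s]])] <- rows[[s]]
  genotype_matrix(calls, setNames(as.integer(ploidy[names(rows)]), names(rows)))
}

# diploid genotype matrix from a 0/1/2 dosage matrix (alleles A/T, counted T)
gm_from_dosage <- function(dos) {
  strmap <- c("A:2", "A:1,T:1", "T:2")
  calls <- matrix(strmap[dos + 1L], nrow = nrow(dos),
                  dimnames = dimnames(dos))
  if (is.null(rownames(calls)))
    dimnames(calls) <- list(sprintf("s%02d", seq_len(nrow(dos))),
                            sprintf("ctg%03d:101", seq_len(ncol(dos))))
  genotype_matrix(calls, setNames(rep(2L, nrow(calls)), rownames(calls)))
}

# one-sample allele_counts record at one locus
one_rec <- function(alleles, counts, phreds = rep(30, length(alleles)),
                    locus = "ctg1:101", sample = "S1") {
  as_allele_counts(data.frame(
    sample_id = sample, locus_id = locus, allele = alleles,
    count = as.integer(counts), mean_phred = phreds,
    stringsAsFactors = FALSE))
}
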