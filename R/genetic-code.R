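# Genetic-code tables and the structural bookkeeping shared by every codon
# model: which codon pairs differ at exactly one nucleotide, whether the
# change is a transition, and whether it is synonymous.

.codonsel_cache <- new.env(parent = emptyenv())

#' Sense-codon table for a genetic code
#'
#' Enumerates the sense (non-stop) codons of a genetic code together with
#' their one-letter amino-acid translations.  The standard code has 61 sense
#' codons; all rate matrices and alignments in this package are indexed by
#' this codon ordering.
#'
#' @param genetic_code_id NCBI translation-table number (1 = standard code).
#' @return A list with elements `codons` (character vector of sense codons,
#'   uppercase), `aa` (one-letter residues, same order), `stops` (stop
#'   codons), and `id`.
#' @export
genetic_code <- function(genetic_code_id = 1L) {
  key <- paste0("code_", genetic_code_id)
  if (!is.null(.codonsel_cache[[key]])) return(.codonsel_cache[[key]])
  all64 <- toupper(seqinr::words(3, c("t", "c", "a", "g")))
  aa <- vapply(all64, function(cod) {
    seqinr::translate(strsplit(tolower(cod), "")[[1]], numcode = genetic_code_id)
  }, character(1))
  sense <- aa != "*"
  out <- list(codons = all64[sense], aa = unname(aa[sense]),
              stops = all64[!sense], id = genetic_code_id)
  .codonsel_cache[[key]] <- out
  out
}

# Table of all ordered sense-codon pairs differing at exactly one nucleotide
# position, annotated with transition/transversion and synonymous status.
# Everything downstream (rate matrix, site opportunities, flux fractions)
# is driven by this table.
codon_pair_table <- function(code = genetic_code()) {
  key <- paste0("pairs_", code$id)
  if (!is.null(.codonsel_cache[[key]])) return(.codonsel_cache[[key]])
  n <- length(code$codons)
  mat <- do.call(rbind, strsplit(code$codons, ""))
  ti_pairs <- c("AG", "GA", "CT", "TC")
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  for (i in seq_len(n)) {
    diff_count <- (mat[, 1] != mat[i, 1]) + (mat[, 2] != mat[i, 2]) +
      (mat[, 3] != mat[i, 3])
    js <- which(diff_count == 1L)
    for (j in js) {
      pos <- which(mat[i, ] != mat[j, ])
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, paste0(mat[i, pos], mat[j, pos]) %in% ti_pairs)
      syn <- c(syn, code$aa[i] == code$aa[j])
    }
  }
  out <- data.frame(i = ii, j = jj, is_transition = ts, is_synonymous = syn)
  .codonsel_cache[[key]] <- out
  out
}

# Map codon strings (3-mers, uppercase) to indices in the sense-codon table.
# Gaps ("---"), codons containing gap or ambiguity characters, and stop
# codons map to NA (missing data).
codon_index <- function(codons, code = genetic_code()) {
  match(toupper(codons), code$codons)
}
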