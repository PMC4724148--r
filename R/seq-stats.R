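# Domain splitting of the precursor, arginine content, and Welch
# two-sample comparisons between clades.

#' Split a precursor sequence into cleaved and mature domains
#'
#' The boundary is the 1-based codon index of the first codon of the
#' mature (retained) domain: cleaved = codons `[1, boundary)`, mature =
#' codons `[boundary, end]`.
#'
#' @param precursor Character vector of codons, or a single nucleotide
#'   string with length divisible by 3.
#' @param boundary Integer, `1 < boundary <= length in codons`.
#' @return List with `cleaved` and `mature` codon vectors and their
#'   lengths (`cleaved_length`, `mature_length`, in codons).
#' @export
split_domains <- function(precursor, boundary) {
  if (length(precursor) == 1L && nchar(precursor) > 3L) {
    n <- nchar(precursor)
    if (n %% 3L != 0L)
      cs_stop("precursor length not divisible by 3", "codonsel_format_error")
    precursor <- substring(precursor, 3L * seq_len(n %/% 3L) - 2L,
                           3L * seq_len(n %/% 3L))
  }
  L <- length(precursor)
  boundary <- as.integer(boundary)
  if (is.na(boundary) || boundary <= 1L || boundary > L)
    cs_stop(sprintf("boundary must lie in (1, %d]; got %s", L, boundary))
  list(cleaved = precursor[seq_len(boundary - 1L)],
       mature = precursor[boundary:L],
       cleaved_length = boundary - 1L,
       mature_length = L - boundary + 1L)
}

# Split every sequence of an alignment at a common (alignment-coordinate)
# boundary into two domain alignments.
split_alignment_domains <- function(aln, boundary) {
  L <- n_codon_sites(aln)
  if (boundary <= 1L || boundary > L)
    cs_stop(sprintf("alignment domain boundary must lie in (1, %d]", L))
  mk <- function(cols) {
    codon_alignment(apply(aln$codons[, cols, drop = FALSE], 1,
                          paste, collapse = ""),
                    aln$taxa, aln$genetic_code_id)
  }
  list(cleaved = mk(seq_len(boundary - 1L)), mature = mk(boundary:L))
}

#' Arginine content of a protein sequence
#'
#' @param protein_seq Amino-acid sequence (string or character vector of
#'   residues); gap characters (`-`, `.`, `*`) are excluded from the
#'   denominator.
#' @return Percentage of non-gap residues that are arginine (R), in
#'   `[0, 100]`.
#' @export
arginine_percent <- function(protein_seq) {
  res <- toupper(unlist(strsplit(paste(protein_seq, collapse = ""), "")))
  res <- res[!res %in% c("-", ".", "*", "X")]
  if (length(res) == 0L) cs_stop("empty protein sequence")
  100 * sum(res == "R") / length(res)
}

# Translate one row of a codon alignment; gap/ambiguous codons -> "-".
translate_row <- function(aln, taxon) {
  code <- genetic_code(aln$genetic_code_id)
  st <- aln$states[match(taxon, aln$taxa), ]
  ifelse(is.na(st), "-", code$aa[st])
}

#' Welch two-sample t-test
#'
#' Unequal-variance comparison of two groups:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite (fractional) degrees of freedom and a two-sided p
#' from the t distribution.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values and
#'   nonzero variance overall.
#' @return A `welch_result`: list with `t`, `df`, `p`, group means.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    cs_stop("each group needs at least 2 non-missing values")
  if (stats::var(group_a) + stats::var(group_b) <= 0)
    cs_stop("zero variance in both groups")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Per-species domain sequence statistics
#'
#' Ungapped residue lengths and arginine content per species and domain.
#'
#' @param aln Precursor `codon_alignment`.
#' @param boundary Alignment-coordinate domain boundary (first mature
#'   codon, 1-based).
#' @return Data frame: `species`, `cleaved_length`, `mature_length`
#'   (ungapped residues), `arginine_pct_mature`, `arginine_pct_cleaved`.
#' @export
domain_sequence_stats <- function(aln, boundary) {
  doms <- split_alignment_domains(aln, boundary)
  out <- do.call(rbind, lapply(aln$taxa, function(sp) {
    aac <- translate_row(doms$cleaved, sp)
    aam <- translate_row(doms$mature, sp)
    data.frame(species = sp,
               cleaved_length = sum(aac != "-"),
               mature_length = sum(aam != "-"),
               arginine_pct_cleaved = arginine_percent(aac),
               arginine_pct_mature = arginine_percent(aam),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
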