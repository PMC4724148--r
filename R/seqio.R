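# IO and validation for codon alignments, trees with foreground marks, and
# domain annotations.  Trees are ape "phylo" objects carrying an extra
# `foreground` element: a list of tip-label sets, each denoting a marked
# clade (all branches of the clade plus its stem).  Storing marks as tip
# sets keeps them valid under pruning and node renumbering.

cs_stop <- function(msg, class = "codonsel_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Construct a codon alignment from nucleotide sequences
#'
#' @param sequences Character vector of aligned nucleotide sequences (equal
#'   length, length divisible by 3).
#' @param taxa Unique taxon labels, one per sequence.
#' @param genetic_code_id NCBI translation-table number (default standard).
#' @return An object of class `codon_alignment`: list with `taxa`, `codons`
#'   (character matrix, taxa x codon sites; `"---"` style entries retained),
#'   `states` (integer matrix of sense-codon indices, `NA` = gap/ambiguous),
#'   and `genetic_code_id`.
#' @details Codon sites are 1-based in all user-facing coordinates.  Gap and
#'   ambiguous codons are treated as missing data.  A stop codon at any
#'   internal site is a validation error; a terminal stop codon is accepted
#'   and treated as missing data.
#' @export
codon_alignment <- function(sequences, taxa, genetic_code_id = 1L) {
  sequences <- toupper(gsub("\\s", "", sequences))
  if (length(sequences) != length(taxa))
    cs_stop("`sequences` and `taxa` must have equal length")
  if (anyDuplicated(taxa))
    cs_stop(paste0("duplicate taxon labels: ",
                   paste(unique(taxa[duplicated(taxa)]), collapse = ", ")),
            "codonsel_validation_error")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    cs_stop("aligned sequences must all have the same length",
            "codonsel_format_error")
  if (lens[1] %% 3L != 0L)
    cs_stop(sprintf("alignment length (%d nt) is not divisible by 3", lens[1]),
            "codonsel_format_error")
  L <- lens[1] %/% 3L
  code <- genetic_code(genetic_code_id)
  codons <- t(matrix(vapply(sequences, function(s) {
    substring(s, 3L * seq_len(L) - 2L, 3L * seq_len(L))
  }, character(L)), nrow = L, ncol = length(taxa)))
  dimnames(codons) <- list(taxa, NULL)
  states <- matrix(codon_index(codons, code), nrow = length(taxa),
                   dimnames = list(taxa, NULL))
  # distinguish stop codons (invalid internally) from gaps/ambiguities
  is_stop <- matrix(codons %in% code$stops, nrow = length(taxa))
  if (L > 1L && any(is_stop[, -L, drop = FALSE])) {
    hit <- which(is_stop[, -L, drop = FALSE], arr.ind = TRUE)[1, ]
    cs_stop(sprintf("internal stop codon in taxon '%s' at codon site %d",
                    taxa[hit[1]], hit[2]),
            "codonsel_validation_error")
  }
  if (any(is_stop[, L]))
    warning("terminal stop codon(s) treated as missing data")
  structure(list(taxa = taxa, codons = codons, states = states,
                 genetic_code_id = genetic_code_id),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d codon sites (code %d)\n",
              length(x$taxa), ncol(x$states), x$genetic_code_id))
  invisible(x)
}

#' Number of codon sites in an alignment
#' @param aln A `codon_alignment`.
#' @return Integer number of codon columns.
#' @export
n_codon_sites <- function(aln) ncol(aln$states)

#' Read a codon alignment from a FASTA file
#'
#' @param path Path to a FASTA file of aligned coding sequences.
#' @param genetic_code_id NCBI translation-table number.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, genetic_code_id = 1L) {
  if (!file.exists(path)) cs_stop(paste0("file not found: ", path))
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  codon_alignment(unlist(lapply(seqs, as.character)), names(seqs),
                  genetic_code_id)
}

#' Write a codon alignment to FASTA
#' @param aln A `codon_alignment`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = aln$taxa, file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' Read a rooted tree with optional foreground marks
#'
#' Parses a Newick tree.  A `#1` tag appended to a tip or internal-node
#' label (e.g. `((A,B)#1,C);`) marks that tip, or that clade up to and
#' including its stem branch, as foreground.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return An ape `phylo` object with an extra `foreground` element (list of
#'   marked tip-label sets).
#' @export
read_tree <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "") else path
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    cs_stop("could not parse Newick input", "codonsel_format_error")
  fg <- list()
  tagged_tips <- grepl("#\\d+$", tr$tip.label)
  if (any(tagged_tips)) {
    tr$tip.label <- sub("#\\d+$", "", tr$tip.label)
    fg <- c(fg, as.list(tr$tip.label[tagged_tips]))
  }
  if (!is.null(tr$node.label)) {
    tagged_nodes <- grepl("#\\d+$", tr$node.label)
    if (any(tagged_nodes)) {
      for (k in which(tagged_nodes)) {
        node <- length(tr$tip.label) + k
        fg <- c(fg, list(clade_tips(tr, node)))
      }
      tr$node.label <- sub("#\\d+$", "", tr$node.label)
    }
    if (all(tr$node.label == "")) tr$node.label <- NULL
  }
  if (anyDuplicated(tr$tip.label))
    cs_stop(paste0("duplicate tip labels: ",
                   paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                         collapse = ", ")),
            "codonsel_validation_error")
  tr$foreground <- fg
  tr
}

#' Write a tree with foreground marks to Newick
#' @param tree A `phylo`, optionally with a `foreground` element.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_tree <- function(tree, path = NULL) {
  tr <- tree
  fg <- tree$foreground
  if (!is.null(fg) && length(fg)) {
    ntip <- length(tr$tip.label)
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    for (set in fg) {
      if (length(set) == 1L) {
        k <- match(set, tr$tip.label)
        tr$tip.label[k] <- paste0(tr$tip.label[k], "#1")
      } else {
        node <- ape::getMRCA(tr, set)
        tr$node.label[node - ntip] <- paste0(tr$node.label[node - ntip], "#1")
      }
    }
  }
  tr$foreground <- NULL
  txt <- ape::write.tree(tr, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Tip labels descending from `node` (a tip returns its own label).
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# All descendant nodes of `node`, including `node` itself.
descendant_nodes <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(node, unlist(lapply(kids, descendant_nodes, tree = tree)))
}

#' Mark a clade as foreground
#'
#' Flags all branches in the subtree of the most recent common ancestor of
#' `tip_set`, plus the ancestor's stem branch, as foreground; all other
#' branches become background.
#'
#' @param tree A `phylo`.
#' @param tip_set Character vector of tip labels forming a monophyletic
#'   group (a single tip marks only its terminal branch).
#' @return The tree with its `foreground` element replaced.
#' @export
mark_clade <- function(tree, tip_set) {
  if (length(tip_set) == 0L) cs_stop("empty tip set")
  missing <- setdiff(tip_set, tree$tip.label)
  if (length(missing))
    cs_stop(paste0("tips not in tree: ", paste(missing, collapse = ", ")))
  if (length(tip_set) > 1L) {
    mrca <- ape::getMRCA(tree, tip_set)
    below <- clade_tips(tree, mrca)
    if (!setequal(below, tip_set))
      cs_stop(paste0("tip set is not monophyletic; clade of its MRCA also ",
                     "contains: ",
                     paste(setdiff(below, tip_set), collapse = ", ")),
              "codonsel_validation_error")
  }
  tree$foreground <- list(tip_set)
  tree
}

#' Foreground status of each branch
#'
#' @param tree A `phylo` with a `foreground` element.
#' @return Logical vector along the rows of `tree$edge`: `TRUE` for branches
#'   inside a marked clade or on its stem.
#' @export
foreground_edges <- function(tree) {
  fg <- rep(FALSE, nrow(tree$edge))
  for (set in tree$foreground %||% list()) {
    node <- if (length(set) == 1L) match(set, tree$tip.label)
            else ape::getMRCA(tree, set)
    nodes <- descendant_nodes(tree, node)
    fg <- fg | tree$edge[, 2] %in% nodes
  }
  fg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prune a tree to a set of taxa
#'
#' @param tree A `phylo` with optional foreground marks.
#' @param taxa Taxon labels to retain; every label must be present in the
#'   tree (an error lists unmatched labels otherwise).
#' @return The induced rooted tree on `taxa`, foreground marks carried over
#'   (marked tips outside `taxa` are dropped from their sets).
#' @export
prune_to_taxa <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    cs_stop(paste0("taxa absent from tree: ", paste(missing, collapse = ", ")),
            "codonsel_validation_error")
  fg <- tree$foreground
  tr <- ape::keep.tip(tree, taxa)
  tr$foreground <- Filter(length, lapply(fg %||% list(),
                                         function(s) intersect(s, taxa)))
  tr
}

#' Check that a tree and alignment refer to the same taxa
#' @param tree A `phylo`.
#' @param aln A `codon_alignment`.
#' @return Invisibly `TRUE`; errors list unmatched labels on either side.
#' @export
check_tree_alignment <- function(tree, aln) {
  only_tree <- setdiff(tree$tip.label, aln$taxa)
  only_aln <- setdiff(aln$taxa, tree$tip.label)
  if (length(only_tree) || length(only_aln))
    cs_stop(paste0("tree/alignment taxon mismatch.",
                   if (length(only_tree)) paste0(" Tree only: ",
                     paste(only_tree, collapse = ", "), "."),
                   if (length(only_aln)) paste0(" Alignment only: ",
                     paste(only_aln, collapse = ", "), ".")),
            "codonsel_validation_error")
  invisible(TRUE)
}

#' Read a per-species domain annotation
#'
#' The annotation gives, per species, the 1-based codon index of the first
#' codon of the mature (retained) domain; everything before it is the
#' cleaved domain.
#'
#' @param path Tab-separated file with columns `species` and `boundary`.
#' @return Named integer vector of boundaries.
#' @export
read_domain_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "boundary") %in% names(df)))
    cs_stop("domain annotation needs columns 'species' and 'boundary'",
            "codonsel_format_error")
  b <- as.integer(df$boundary)
  if (any(is.na(b)) || any(b <= 1L))
    cs_stop("domain boundaries must be integers > 1",
            "codonsel_validation_error")
  stats::setNames(b, df$species)
}
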