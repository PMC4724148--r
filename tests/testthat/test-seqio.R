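test_that("codon alignments parse, validate and round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp1", "ATGAAACGT", ">sp2", "ATGAAGCGT"), fa)
  aln <- read_codon_alignment(fa)
  expect_equal(aln$taxa, c("sp1", "sp2"))
  expect_equal(n_codon_sites(aln), 3L)
  expect_equal(aln$codons["sp1", ], c("ATG", "AAA", "CGT"))

  # gap codon is missing data
  aln2 <- codon_alignment(c("ATG---CGT", "ATGAAACGT"), c("a", "b"))
  expect_true(is.na(aln2$states["a", 2]))
  expect_false(anyNA(aln2$states["b", ]))

  # round trip preserves states exactly
  out <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln2, out)
  back <- read_codon_alignment(out)
  expect_identical(back$states, aln2$states)

  # internal stop codon names taxon and site
  expect_error(codon_alignment(c("ATGTAACGT", "ATGAAACGT"), c("x", "y")),
               "internal stop codon.*'x'.*site 2")
  # terminal stop is tolerated as missing
  expect_warning(a3 <- codon_alignment(c("ATGTAA", "ATGAAA"), c("x", "y")),
                 "terminal stop")
  expect_true(is.na(a3$states["x", 2]))
  # length not divisible by 3
  expect_error(codon_alignment(c("ATGA", "ATGA"), c("x", "y")),
               "divisible by 3")
  expect_error(codon_alignment(c("ATG", "ATG"), c("x", "x")), "duplicate")
})

test_that("trees parse with foreground tags and round-trip", {
  tr <- read_tree("((A:0.1,B:0.1):0.05,C:0.2);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)
  expect_length(foreground_edges(tr), 4L)
  expect_false(any(foreground_edges(tr)))

  trf <- read_tree("((A:1,B:1)#1:1,C:2);")
  fg <- foreground_edges(trf)
  expect_equal(sum(fg), 3L)  # A, B, and the clade's stem
  marked_children <- sort(trf$edge[fg, 2])
  expect_equal(marked_children,
               sort(c(match(c("A", "B"), trf$tip.label), 5L)))

  # tip-level tag marks only the terminal branch
  trt <- read_tree("((A#1:1,B:1):1,C:2);")
  expect_equal(sum(foreground_edges(trt)), 1L)
  expect_false(any(grepl("#", trt$tip.label)))

  # round trip: branch lengths and marks survive
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_tree(trf, tmp)
  back <- read_tree(tmp)
  expect_equal(sum(foreground_edges(back)), 3L)
  expect_equal(sort(back$edge.length), sort(trf$edge.length),
               tolerance = 1e-10)

  expect_error(read_tree("((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(read_tree("not a newick ((("), "Newick")
})

test_that("mark_clade marks the clade plus stem and enforces monophyly", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  m <- mark_clade(tr, c("A", "B"))
  expect_equal(sum(foreground_edges(m)), 3L)
  m1 <- mark_clade(tr, "A")
  fg <- foreground_edges(m1)
  expect_equal(sum(fg), 1L)
  expect_equal(m1$edge[fg, 2], match("A", m1$tip.label))
  expect_error(mark_clade(tr, character(0)), "empty")
  expect_error(mark_clade(tr, c("A", "C")), "not monophyletic")
  expect_error(mark_clade(tr, c("A", "Z")), "not in tree")
})

test_that("taxon cross-checks list unmatched labels; pruning keeps topology", {
  tr <- read_tree("(((A:1,B:1):1,C:2):1,D:3);")
  aln <- codon_alignment(rep("ATGAAA", 3), c("A", "B", "C"))
  expect_error(check_tree_alignment(tr, aln), "D")
  pruned <- prune_to_taxa(tr, aln$taxa)
  expect_setequal(pruned$tip.label, c("A", "B", "C"))
  # induced rooted topology on retained tips is unchanged: (A,B) still sister
  expect_equal(sort(codonsel:::clade_tips(pruned,
                 ape::getMRCA(pruned, c("A", "B")))), c("A", "B"))
  expect_error(prune_to_taxa(tr, c("A", "Q")), "absent.*Q")

  # foreground marks survive pruning
  trm <- mark_clade(tr, c("A", "B", "C"))
  pr <- prune_to_taxa(trm, c("A", "B", "D"))
  expect_setequal(unlist(pr$foreground), c("A", "B"))
})

test_that("domain annotations read and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tboundary", "a\t5", "b\t5"), f)
  b <- read_domain_annotation(f)
  expect_equal(unname(b), c(5L, 5L))
  writeLines(c("species\tboundary", "a\t1"), f)
  expect_error(read_domain_annotation(f), "> 1")
})
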