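# Pruning-likelihood engine.  An engine binds one alignment/tree pair:
# site patterns are compressed once, the tree is put in postorder once, and
# eigendecompositions of the generator are cached across calls so that a
# quasi-Newton optimizer perturbing one branch length does not pay for a
# fresh 61x61 eigenproblem.

make_engine <- function(aln, tree) {
  if (!all(aln$taxa %in% tree$tip.label))
    check_tree_alignment(tree, aln)  # raises listing unmatched labels
  tr <- if (setequal(tree$tip.label, aln$taxa)) tree
        else prune_to_taxa(tree, aln$taxa)
  tr <- stats::reorder(tr, "postorder")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.2, nrow(tr$edge))
  if (any(tr$edge.length < 0)) cs_stop("negative branch length in tree")

  states <- aln$states[match(tr$tip.label, aln$taxa), , drop = FALSE]
  key <- apply(states, 2, paste, collapse = "|")
  first <- !duplicated(key)
  pat_of_site <- match(key, key[first])
  tipm <- states[, first, drop = FALSE]
  tipm[is.na(tipm)] <- 0L
  storage.mode(tipm) <- "integer"
  weights <- as.numeric(tabulate(pat_of_site, nbins = sum(first)))

  edge <- tr$edge
  storage.mode(edge) <- "integer"
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  root_rows <- which(edge[, 1] == root)
  code <- genetic_code(aln$genetic_code_id)

  cache <- new.env(parent = emptyenv())
  cache$pi_key <- ""
  cache$dec <- list()

  get_decomps <- function(kappa, pi, omegas) {
    pk <- paste(signif(pi[c(1L, 2L, 31L, length(pi))], 12), sum(pi * pi),
                collapse = ",")
    if (!identical(cache$pi_key, pk)) {
      cache$dec <- list()
      cache$pi_key <- pk
    }
    lapply(omegas, function(w) {
      k <- sprintf("%.15g_%.15g", kappa, w)
      d <- cache$dec[[k]]
      if (is.null(d)) {
        d <- codon_decomp(codon_model_params(kappa, w, pi, code$id))
        cache$dec[[k]] <- d
      }
      d
    })
  }

  pat_loglik <- function(kappa, pi, omega_edge, tlen) {
    uo <- unique(omega_edge)
    decs <- get_decomps(kappa, pi, uo)
    nc <- length(pi)
    V <- array(0, c(nc, nc, length(uo)))
    lam <- matrix(0, nc, length(uo))
    for (k in seq_along(uo)) {
      V[, , k] <- decs[[k]]$V
      lam[, k] <- decs[[k]]$lambda
    }
    res <- prune_loglik_cpp(edge, n_tip, tlen,
                            as.integer(match(omega_edge, uo)),
                            V, lam, sqrt(pi), pi, tipm, weights)
    list(total = res$total, pat = as.numeric(res$site_loglik))
  }

  list(tree = tr, edge = edge, n_tip = n_tip, n_edge = nrow(edge),
       weights = weights, pat_of_site = pat_of_site, tipm = tipm,
       root_rows = root_rows, fg = foreground_edges(tr),
       n_patterns = sum(first), pat_loglik = pat_loglik,
       genetic_code_id = aln$genetic_code_id)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Computes the pruning log-likelihood of an alignment on a tree under the
#' codon substitution process, with the root weighted by the equilibrium
#' frequencies.  Gap/ambiguous codons are summed over all sense codons.
#' Site-class mixtures (branch-site style) mix per-site likelihoods with
#' the class proportions.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `phylo` whose tips match the alignment taxa (a superset is
#'   pruned), with branch lengths in expected substitutions per codon.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon equilibrium frequencies (see
#'   [estimate_codon_frequencies()]).
#' @param omega Either a single dN/dS for all branches, or a named vector
#'   `c(background = ..., foreground = ...)` using the tree's foreground
#'   marks.
#' @param site_classes Optional data frame with columns `proportion`,
#'   `omega_background`, `omega_foreground`: a site-class mixture that
#'   overrides `omega`.
#' @return The total log-likelihood, with per-site log-likelihoods attached
#'   as attribute `"site_loglik"`.
#' @export
log_likelihood <- function(aln, tree, kappa, pi, omega = 1,
                           site_classes = NULL) {
  eng <- make_engine(aln, tree)
  tlen <- eng$tree$edge.length
  if (is.null(site_classes)) {
    oe <- expand_omega(omega, eng)
    r <- eng$pat_loglik(kappa, pi, oe, tlen)
    site <- r$pat[eng$pat_of_site]
    total <- r$total
  } else {
    stopifnot(all(c("proportion", "omega_background", "omega_foreground")
                  %in% names(site_classes)))
    ll <- sapply(seq_len(nrow(site_classes)), function(cl) {
      oe <- ifelse(eng$fg, site_classes$omega_foreground[cl],
                   site_classes$omega_background[cl])
      eng$pat_loglik(kappa, pi, oe, tlen)$pat
    })
    mixed <- logsumexp_rows(sweep(ll, 2, log(site_classes$proportion), "+"))
    site <- mixed[eng$pat_of_site]
    total <- sum(eng$weights * mixed)
  }
  if (!all(is.finite(site)))
    cs_stop(sprintf("non-finite likelihood at codon site %d",
                    which(!is.finite(site))[1]))
  structure(total, site_loglik = site)
}

expand_omega <- function(omega, eng) {
  if (length(omega) == 1L) return(rep(as.numeric(omega), eng$n_edge))
  if (!is.null(names(omega)) &&
      setequal(names(omega), c("background", "foreground"))) {
    return(ifelse(eng$fg, omega[["foreground"]], omega[["background"]]))
  }
  if (length(omega) == eng$n_edge) return(as.numeric(omega))
  cs_stop("omega must be scalar, c(background=, foreground=), or per-edge")
}
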