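# Orchestration: per-domain, per-clade model ladder with regime calls
# (the selection stage) and the comparative stage (free-ratio fits,
# root-to-tip omega, sequence statistics, Welch clade comparisons, PGLS
# suite), from one declarative configuration.

#' Load and validate a run configuration
#'
#' @param config A list, or the path of a YAML file, with elements
#'   `alignment`, `tree`, `phenotypes`, `domain_annotation` (file paths or
#'   in-memory objects), `clades` (named list of tip-label vectors),
#'   and optional `alpha` (0.05), `freq_scheme` ("F3x4"), `n_starts` (5),
#'   `seed`, `outdir`.
#' @return Normalized configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("alignment", "tree", "clades"))
    if (is.null(config[[f]])) cs_stop(paste0("config is missing '", f, "'"))
  for (f in c("alignment", "tree", "phenotypes", "domain_annotation"))
    if (is.character(config[[f]]) && length(config[[f]]) == 1L &&
        !file.exists(config[[f]]))
      cs_stop(paste0("config path does not exist: ", config[[f]]))
  config$clades <- lapply(config$clades, unlist)
  if (anyDuplicated(names(config$clades)))
    cs_stop("clade names must be unique")
  config$alpha <- config$alpha %||% 0.05
  config$freq_scheme <- config$freq_scheme %||% "F3x4"
  config$n_starts <- config$n_starts %||% 5
  config
}

pipeline_inputs <- function(cfg) {
  aln <- if (inherits(cfg$alignment, "codon_alignment")) cfg$alignment
         else read_codon_alignment(cfg$alignment)
  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree
          else read_tree(cfg$tree)
  tree <- prune_to_taxa(tree, aln$taxa)
  ann <- cfg$domain_annotation
  boundary <- if (is.null(ann)) NULL else {
    b <- if (is.character(ann)) read_domain_annotation(ann)
         else as.integer(ann)
    ub <- unique(b)
    if (length(ub) != 1L)
      cs_stop(paste0("domain boundaries must agree in alignment ",
                     "coordinates; got: ", paste(ub, collapse = ", ")))
    ub
  }
  list(aln = aln, tree = tree, boundary = boundary)
}

atomic_write_tsv <- function(df, path, header = NULL) {
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

write_manifest <- function(cfg, outdir) {
  cfg_flat <- lapply(cfg, function(x) {
    if (is.atomic(x)) x
    else if (inherits(x, c("codon_alignment", "phylo")) ||
             is.data.frame(x)) "<in-memory object>"
    else if (is.list(x)) lapply(x, function(y)
      if (is.atomic(y)) y else "<in-memory object>")
    else "<in-memory object>"
  })
  cfg_json <- jsonlite::toJSON(cfg_flat, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "codonsel",
    package_version = as.character(utils::packageVersion("codonsel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, config = cfg_flat,
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  path <- file.path(outdir, "manifest.json")
  tmp2 <- tempfile(tmpdir = outdir)
  jsonlite::write_json(manifest, tmp2, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp2, path)
  invisible(path)
}

#' Run the selection stage of the pipeline
#'
#' For each domain and each foreground clade, fits M0, MC, MCfixed, BS and
#' BSfixed, computes the likelihood ratio tests, classifies the selection
#' regime at the whole-sequence and site level, and lists positively
#' selected sites when the branch-site test is significant.  Fit failures
#' mark the affected row as failed and the run continues.
#'
#' @param config See [load_run_config()].
#' @return List with `report` (one row per domain x clade; codon sites are
#'   1-based alignment coordinates) and `fits` (nested list of model
#'   fits).  When `config$outdir` is set, writes `selection_report.tsv`
#'   and `manifest.json` there (atomically).
#' @export
run_selection_stage <- function(config) {
  cfg <- load_run_config(config)
  inp <- pipeline_inputs(cfg)
  doms <- if (is.null(inp$boundary)) list(precursor = inp$aln)
          else split_alignment_domains(inp$aln, inp$boundary)
  rows <- list()
  fits <- list()
  for (dom in names(doms)) {
    m0 <- fit_m0(doms[[dom]], inp$tree, cfg$freq_scheme)
    fits[[dom]] <- list(m0 = m0, clades = list())
    for (cl in names(cfg$clades)) {
      res <- tryCatch({
        trm <- mark_clade(inp$tree, intersect(cfg$clades[[cl]],
                                              inp$aln$taxa))
        mcfix <- fit_branch_model(doms[[dom]], trm, TRUE, m0)
        mc <- fit_branch_model(doms[[dom]], trm, FALSE, m0,
                               null_fit = mcfix)
        bsfix <- fit_branch_site(doms[[dom]], trm, TRUE, m0,
                                 n_starts = cfg$n_starts)
        bs <- fit_branch_site(doms[[dom]], trm, FALSE, m0,
                              null_fit = bsfix, n_starts = cfg$n_starts)
        l_m0_mc <- lrt(m0, mc)
        l_mcfix_mc <- lrt(mcfix, mc)
        l_bs <- lrt(bsfix, bs)
        reg <- classify_regime(l_m0_mc, l_mcfix_mc,
                               unname(mc$omega["foreground"]),
                               unname(m0$omega["omega"]), cfg$alpha)
        sreg <- classify_site_regime(l_bs, cfg$alpha)
        pss <- if (identical(sreg, "positive"))
          detect_pss(bs, threshold = 0.95) else NULL
        fits[[dom]]$clades[[cl]] <- list(mc = mc, mcfixed = mcfix,
                                         bs = bs, bsfixed = bsfix,
                                         pss = pss)
        data.frame(
          domain = dom, clade = cl, status = "ok",
          lnl_m0 = m0$loglik, lnl_mc = mc$loglik, lnl_mcfix = mcfix$loglik,
          lnl_bs = bs$loglik, lnl_bsfix = bsfix$loglik,
          two_delta_m0_mc = l_m0_mc$two_delta, p_m0_mc = l_m0_mc$p,
          two_delta_mcfix_mc = l_mcfix_mc$two_delta,
          p_mcfix_mc = l_mcfix_mc$p,
          omega_m0 = unname(m0$omega["omega"]),
          omega_mc_background = unname(mc$omega["background"]),
          omega_mc_foreground = unname(mc$omega["foreground"]),
          omega_reported = reg$effective_omega,
          two_delta_bsfix_bs = l_bs$two_delta, p_bsfix_bs = l_bs$p,
          p0 = bs$mixture$p0, p1 = bs$mixture$p1, p2a = bs$mixture$p2a,
          p2b = bs$mixture$p2b, omega0 = bs$mixture$omega0,
          omega2 = bs$mixture$omega2,
          pss = if (is.null(pss)) "" else paste(pss$label, collapse = ","),
          branch_regime = reg$label, site_regime = sreg,
          reason = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(domain = dom, clade = cl, status = "failed",
                   lnl_m0 = NA, lnl_mc = NA, lnl_mcfix = NA, lnl_bs = NA,
                   lnl_bsfix = NA, two_delta_m0_mc = NA, p_m0_mc = NA,
                   two_delta_mcfix_mc = NA, p_mcfix_mc = NA, omega_m0 = NA,
                   omega_mc_background = NA, omega_mc_foreground = NA,
                   omega_reported = NA, two_delta_bsfix_bs = NA,
                   p_bsfix_bs = NA, p0 = NA, p1 = NA, p2a = NA, p2b = NA,
                   omega0 = NA, omega2 = NA, pss = "", branch_regime = "",
                   site_regime = "", reason = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows <- c(rows, list(res))
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    atomic_write_tsv(report, file.path(cfg$outdir, "selection_report.tsv"),
                     header = "codon sites are 1-based alignment coordinates")
    write_manifest(cfg, cfg$outdir)
  }
  list(report = report, fits = fits)
}

welch_row <- function(name, a, b) {
  res <- tryCatch(welch_t_test(a, b), error = function(e) e)
  if (inherits(res, "error"))
    data.frame(comparison = name, t = NA, df = NA, p = NA,
               mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
               reason = conditionMessage(res), stringsAsFactors = FALSE)
  else
    data.frame(comparison = name, t = res$t, df = res$df, p = res$p,
               mean_a = res$mean_a, mean_b = res$mean_b, reason = "",
               stringsAsFactors = FALSE)
}

#' Run the comparative stage of the pipeline
#'
#' Free-ratio fits per domain, root-to-tip omega per species, sequence
#' statistics (domain lengths, arginine content) with Welch comparisons
#' between the first two clades, and the PGLS regression suite.
#'
#' @param config See [load_run_config()].
#' @param selection Optional result of [run_selection_stage()]; its M0
#'   fits are reused for the free-ratio branch-length starting points.
#' @return List with `omega_rtt` (per species x domain), `seq_stats`,
#'   `welch`, `regressions`, `residual_testes`, and `fits` (free-ratio
#'   fits per domain).  Reports are written to `config$outdir` when set.
#' @export
run_comparative_stage <- function(config, selection = NULL) {
  cfg <- load_run_config(config)
  inp <- pipeline_inputs(cfg)
  doms <- if (is.null(inp$boundary)) list(precursor = inp$aln)
          else split_alignment_domains(inp$aln, inp$boundary)
  clades <- lapply(cfg$clades, intersect, y = inp$aln$taxa)

  free_fits <- list()
  rtt <- list()
  for (dom in names(doms)) {
    m0 <- selection$fits[[dom]]$m0 %||%
      fit_m0(doms[[dom]], inp$tree, cfg$freq_scheme)
    fr <- fit_free_ratio(doms[[dom]], inp$tree, m0)
    free_fits[[dom]] <- fr
    tab <- root_to_tip_table(fr, clades)
    tab$domain <- dom
    rtt <- c(rtt, list(tab))
  }
  omega_rtt <- do.call(rbind, rtt)
  undef <- is.na(omega_rtt$omega_rtt)
  if (any(undef))
    message(sprintf(
      "%d root-to-tip omega value(s) undefined (zero synonymous path sum); excluded from regressions",
      sum(undef)))

  seqst <- if (is.null(inp$boundary)) NULL
           else domain_sequence_stats(inp$aln, inp$boundary)
  welch <- NULL
  if (!is.null(seqst) && length(clades) >= 2) {
    a <- seqst[seqst$species %in% clades[[1]], ]
    b <- seqst[seqst$species %in% clades[[2]], ]
    nm <- names(clades)[1:2]
    welch <- rbind(
      welch_row(sprintf("cleaved_length %s vs %s", nm[1], nm[2]),
                a$cleaved_length, b$cleaved_length),
      welch_row(sprintf("mature_length %s vs %s", nm[1], nm[2]),
                a$mature_length, b$mature_length),
      welch_row(sprintf("arginine_pct_mature %s vs %s", nm[1], nm[2]),
                a$arginine_pct_mature, b$arginine_pct_mature))
  }

  regress <- NULL
  resid_tm <- NULL
  if (!is.null(cfg$phenotypes)) {
    ph <- if (is.data.frame(cfg$phenotypes)) cfg$phenotypes
          else read_phenotypes(cfg$phenotypes)
    ph <- derive_traits(ph)
    resid_tm <- tryCatch(residual_testes_mass(ph), error = function(e) NULL)
    regress <- run_regression_suite(omega_rtt, ph, inp$tree,
                                    seq_stats = seqst,
                                    alpha = cfg$alpha)
  }

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    atomic_write_tsv(omega_rtt, file.path(cfg$outdir, "omega_rtt.tsv"),
                     header = "root-to-tip omega; path includes the clade stem branch")
    if (!is.null(seqst))
      atomic_write_tsv(seqst, file.path(cfg$outdir, "sequence_stats.tsv"),
                       header = "ungapped residue lengths; arginine % of non-gap residues")
    if (!is.null(welch))
      atomic_write_tsv(welch, file.path(cfg$outdir, "welch_tests.tsv"))
    if (!is.null(regress))
      atomic_write_tsv(regress, file.path(cfg$outdir, "regressions.tsv"),
                       header = "PGLS suite; lambda_note gives LRTs vs lambda=0 and lambda=1")
  }
  list(omega_rtt = omega_rtt, seq_stats = seqst, welch = welch,
       regressions = regress, residual_testes = resid_tm,
       fits = free_fits)
}
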