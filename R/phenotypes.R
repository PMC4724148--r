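# Phenotype-table ingestion and derived trait construction: relative
# sperm head dimensions, head elongation, and residual testes mass.

#' Read a phenotype table
#'
#' @param path Delimited text file with a header; expected columns (after
#'   optional renaming via `columns`): `species`, `body_mass` (g),
#'   `testes_mass` (g), `head_length`, `head_width`,
#'   `total_sperm_length` (all micrometres).  Missing values stay `NA`;
#'   zeros are rejected.
#' @param sep Field separator (default tab).
#' @param columns Optional named character vector mapping expected names to
#'   the file's column names, e.g. `c(body_mass = "BodyMass.g")`.
#' @return Data frame with normalized species labels (whitespace collapsed
#'   to underscores).
#' @export
read_phenotypes <- function(path, sep = "\t", columns = NULL) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns))
    for (want in names(columns)) {
      names(df)[names(df) == columns[[want]]] <- want
    }
  if (!"species" %in% names(df))
    cs_stop("phenotype table needs a 'species' column",
            "codonsel_format_error")
  df$species <- normalize_species(df$species)
  num_cols <- intersect(c("body_mass", "testes_mass", "head_length",
                          "head_width", "total_sperm_length"), names(df))
  for (cc in num_cols) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(df[[cc]] <= 0, na.rm = TRUE))
      cs_stop(sprintf("nonpositive values in column '%s'", cc),
              "codonsel_validation_error")
  }
  df
}

normalize_species <- function(x) gsub("\\s+", "_", trimws(x))

#' Derive relative sperm head traits
#'
#' Adds `relative_hl = head_length / total_sperm_length`, `relative_hw =
#' head_width / total_sperm_length` and `elongation = head_length /
#' head_width`.  Missing inputs yield missing outputs; nonpositive inputs
#' are a validation error.
#'
#' @param records Phenotype data frame (see [read_phenotypes()]).
#' @return The data frame with derived columns appended.
#' @export
derive_traits <- function(records) {
  need <- c("head_length", "head_width", "total_sperm_length")
  for (cc in intersect(need, names(records)))
    if (any(records[[cc]] <= 0, na.rm = TRUE))
      cs_stop(sprintf("nonpositive values in '%s'", cc),
              "codonsel_validation_error")
  gv <- function(cc) if (cc %in% names(records)) records[[cc]]
                     else rep(NA_real_, nrow(records))
  records$relative_hl <- gv("head_length") / gv("total_sperm_length")
  records$relative_hw <- gv("head_width") / gv("total_sperm_length")
  records$elongation <- gv("head_length") / gv("head_width")
  records
}

#' Residual testes mass
#'
#' Ordinary least squares of log testes mass on log body mass; the
#' residuals are the classical sperm-competition display variable.  They
#' are intended for plotting only, never as a regression input (body and
#' testes mass enter regressions jointly instead).
#'
#' @param records Phenotype data frame with `species`, `body_mass`,
#'   `testes_mass`.
#' @param log_base Base of the logarithm (default 10, the comparative
#'   convention).
#' @return Named numeric vector of residuals for species with both masses.
#' @export
residual_testes_mass <- function(records, log_base = 10) {
  ok <- stats::complete.cases(records[, c("body_mass", "testes_mass")])
  if (sum(ok) < 3L)
    cs_stop("need at least 3 species with both body and testes mass")
  d <- records[ok, ]
  fit <- stats::lm(log(testes_mass, log_base) ~ log(body_mass, log_base),
                   data = d)
  stats::setNames(stats::resid(fit), d$species)
}
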