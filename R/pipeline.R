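#' Default pipeline configuration
#'
#' @param ... overrides for any field: \code{fasta} (path; when NULL a
#'   synthetic proteome is generated), \code{n_proteins}, \code{rule}
#'   (cleavage rule name: \code{"pepsin_pH1.3"} or \code{"pepsin_pH2"}),
#'   \code{min_len}, \code{max_len}, \code{missed_cleavages}, \code{scores}
#'   (path or data.frame; when NULL synthetic scores are generated),
#'   \code{thresholds} (a \code{\link{consensus_thresholds}}), \code{seed},
#'   \code{top_n} (candidates reported per category), \code{out_dir}
#'   (when non-NULL, TSV/JSON artifacts are written there).
#' @return Named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    fasta = NULL, n_proteins = 100L, rule = "pepsin_pH1.3",
    min_len = 5L, max_len = 50L, missed_cleavages = 0L,
    scores = NULL, thresholds = consensus_thresholds(),
    seed = 1L, top_n = 5L, out_dir = NULL), list(...))
  if (is.character(cfg$thresholds) || is.list(cfg$thresholds) &&
      !inherits(cfg$thresholds, "consensus_thresholds"))
    cfg$thresholds <- do.call(consensus_thresholds, as.list(cfg$thresholds))
  if (cfg$min_len > cfg$max_len) stop("min_len must be <= max_len")
  cfg
}

#' Run the full virtual-screening pipeline
#'
#' Executes digestion, physicochemical profiling, consensus screening,
#' mode-of-action stratification and candidate ranking, and returns a
#' structured report. Inputs not supplied in the config are generated by the
#' seeded synthetic modules, so a bare \code{run_pipeline()} is a complete,
#' reproducible demonstration run.
#'
#' @param config a \code{\link{pipeline_config}} list, or a YAML file path
#'   with the same fields.
#' @return A list of class \code{"pepscreen_report"}: parameters, peptide
#'   totals, length-bin distribution, per-predictor and consensus counts,
#'   Venn regions, MoA tallies, top candidates per category, and the
#'   consensus property summary. Stage tables (peptides, verdicts) are
#'   attached in the \code{tables} element; when \code{out_dir} is set they
#'   are also written as TSV plus a \code{report.json}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config) && length(config) == 1L)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  rule <- switch(config$rule,
                 "pepsin_pH1.3" = pepsin_rule("pH1.3"),
                 "pepsin_pH2" = pepsin_rule("pH2"),
                 stop("unknown rule '", config$rule,
                      "'; use cleavage_rule() objects via digest() directly"))

  proteome <- if (!is.null(config$fasta)) read_fasta(config$fasta)
  else gen_proteome(config$n_proteins,
                    seed = stage_seed(config$seed, "proteome"))

  digestate <- digest_proteome(proteome, rule, config$missed_cleavages)
  peptides <- filter_and_deduplicate(digestate, config$min_len,
                                     config$max_len)
  breaks <- if (config$min_len <= 20L && config$max_len >= 36L)
    list(c(config$min_len, 20L), c(21L, 35L), c(36L, config$max_len))
  else list(c(config$min_len, config$max_len))
  bins <- length_distribution(peptides, breaks)
  props <- peptide_properties(peptides)

  scores <- config$scores
  if (is.null(scores)) {
    scores <- gen_scores(peptides$peptide,
                         seed = stage_seed(config$seed, "scores"))$scores
  } else if (is.character(scores)) {
    scores <- read_scores(scores)
  }
  verdicts <- call_predictors(scores, config$thresholds)
  venn <- venn_counts(verdicts)
  moa <- classify_moa(verdicts)

  acp_props <- props[props$peptide %in%
                       verdicts$peptide[verdicts$consensus_acp], ,
                     drop = FALSE]
  summary_panels <- property_summary(acp_props)

  top_by_category <- lapply(
    stats::setNames(nm = c("toxic_only", "cpp_only", "both", "none")),
    function(cat) {
      members <- moa$assignments$peptide[moa$assignments$moa_category == cat]
      if (!length(members)) return(NULL)
      ranked <- rank_candidates(verdicts[verdicts$peptide %in% members, ,
                                         drop = FALSE])
      utils::head(ranked[c("peptide", SCORE_COLS)], config$top_n)
    })

  report <- structure(list(
    schema_version = "1.0",
    parameters = list(
      rule = rule$name, min_len = config$min_len, max_len = config$max_len,
      missed_cleavages = config$missed_cleavages,
      thresholds = unclass(config$thresholds), seed = config$seed),
    totals = list(
      proteins = nrow(proteome),
      fragments = nrow(digestate),
      unique_peptides = nrow(peptides),
      consensus_acps = sum(verdicts$consensus_acp)),
    length_bins = as.data.frame(bins),
    predictor_counts = as.list(attr(venn, "totals")),
    venn = as.data.frame(venn),
    moa = list(category_counts = moa$category_counts,
               overlapping_totals = moa$overlapping_totals),
    top_candidates = top_by_category,
    property_summary = summary_panels,
    tables = list(peptides = peptides, verdicts = verdicts)
  ), class = "pepscreen_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peptides(peptides, file.path(config$out_dir, "peptides.tsv"))
    utils::write.table(verdicts, file.path(config$out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "tables")],
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pepscreen_report <- function(x, ...) {
  cat("pepscreen run (schema", x$schema_version, ")\n")
  cat("  rule:", x$parameters$rule, " seed:", x$parameters$seed, "\n")
  cat("  proteins:", x$totals$proteins,
      " fragments:", x$totals$fragments,
      " unique peptides:", x$totals$unique_peptides, "\n")
  cat("  length bins:\n")
  for (i in seq_len(nrow(x$length_bins)))
    cat(sprintf("    %-7s %6d (%.1f%%)\n", x$length_bins$bin[i],
                x$length_bins$count[i], x$length_bins$proportion[i]))
  pc <- x$predictor_counts
  cat("  predictor positives: AntiCP", pc$anticp, "| iACP", pc$iacp,
      "| MLACP", pc$mlacp, "\n")
  cat("  consensus ACPs:", x$totals$consensus_acps, "\n")
  cat("  mode of action:",
      paste(names(x$moa$category_counts), x$moa$category_counts,
            collapse = ", "), "\n")
  if (x$totals$consensus_acps == 0L)
    cat("  zero consensus candidates - nothing to rank\n")
  invisible(x)
}
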