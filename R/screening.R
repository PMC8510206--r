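#' Consensus screening thresholds
#'
#' Default cutoffs for the three-predictor consensus call: AntiCP-style SVM
#' score strictly over 1.00, iACP-style probability strictly over 0.5, and
#' both MLACP-style random-forest and SVM probabilities strictly over 0.5.
#' All comparisons are strict ("over").
#'
#' @param anticp_min,iacp_min,mlacp_rf_min,mlacp_svm_min numeric cutoffs.
#' @return A named list of class \code{"consensus_thresholds"}.
#' @export
consensus_thresholds <- function(anticp_min = 1.00, iacp_min = 0.5,
                                 mlacp_rf_min = 0.5, mlacp_svm_min = 0.5) {
  th <- list(anticp_min = anticp_min, iacp_min = iacp_min,
             mlacp_rf_min = mlacp_rf_min, mlacp_svm_min = mlacp_svm_min)
  if (!all(vapply(th, function(v) is.numeric(v) && is.finite(v), logical(1L))))
    stop("all thresholds must be finite numbers")
  structure(th, class = "consensus_thresholds")
}

SCORE_COLS <- c("anticp_svm", "iacp_prob", "mlacp_rf", "mlacp_svm")

check_scores <- function(scores) {
  if (!is.data.frame(scores)) stop("scores must be a data.frame")
  missing <- setdiff(c("peptide", SCORE_COLS), names(scores))
  if (length(missing))
    stop("score table missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("iacp_prob", "mlacp_rf", "mlacp_svm")) {
    bad <- which(scores[[col]] < 0 | scores[[col]] > 1)
    if (length(bad))
      stop(col, " outside [0,1] for peptide ", scores$peptide[bad[1L]])
  }
  na_rows <- !stats::complete.cases(scores[SCORE_COLS])
  if (any(na_rows))
    stop("missing score(s) for peptide ",
         paste(scores$peptide[na_rows], collapse = ", "))
  invisible(scores)
}

#' Apply the consensus thresholds to a predictor score table
#'
#' For each peptide: AntiCP positive iff \code{anticp_svm} exceeds its cutoff,
#' iACP positive iff \code{iacp_prob} exceeds its cutoff, MLACP positive iff
#' both \code{mlacp_rf} and \code{mlacp_svm} exceed theirs; the consensus ACP
#' call requires all three predictors positive.
#'
#' @param scores data.frame with columns \code{peptide}, \code{anticp_svm},
#'   \code{iacp_prob}, \code{mlacp_rf}, \code{mlacp_svm} and optionally
#'   boolean \code{toxic}/\code{cpp} mode-of-action flags (carried through).
#' @param thresholds a \code{\link{consensus_thresholds}} object.
#' @return The input with added logical columns \code{anticp_pos},
#'   \code{iacp_pos}, \code{mlacp_pos}, \code{consensus_acp}.
#' @examples
#' sc <- data.frame(peptide = "VTFVLIAAK", anticp_svm = 1.28,
#'                  iacp_prob = 0.875, mlacp_rf = 0.558, mlacp_svm = 0.787)
#' call_predictors(sc)$consensus_acp
#' @export
call_predictors <- function(scores, thresholds = consensus_thresholds()) {
  check_scores(scores)
  out <- scores
  out$anticp_pos <- scores$anticp_svm > thresholds$anticp_min
  out$iacp_pos <- scores$iacp_prob > thresholds$iacp_min
  out$mlacp_pos <- scores$mlacp_rf > thresholds$mlacp_rf_min &
    scores$mlacp_svm > thresholds$mlacp_svm_min
  out$consensus_acp <- out$anticp_pos & out$iacp_pos & out$mlacp_pos
  out
}

#' Venn region counts over the three predictor calls
#'
#' @param verdicts output of \code{\link{call_predictors}}, one row per
#'   unique peptide.
#' @return A data.frame of the 7 non-empty Venn regions (\code{region},
#'   \code{count}) with attributes \code{totals} (per-predictor positives)
#'   and \code{union} (size of the union), satisfying inclusion-exclusion.
#' @export
venn_counts <- function(verdicts) {
  if (anyDuplicated(verdicts$peptide))
    stop("duplicate peptides in verdict table")
  a <- verdicts$anticp_pos; b <- verdicts$iacp_pos; c <- verdicts$mlacp_pos
  regions <- c(
    anticp_only = sum(a & !b & !c),
    iacp_only = sum(!a & b & !c),
    mlacp_only = sum(!a & !b & c),
    anticp_iacp = sum(a & b & !c),
    anticp_mlacp = sum(a & !b & c),
    iacp_mlacp = sum(!a & b & c),
    all_three = sum(a & b & c)
  )
  structure(
    data.frame(region = names(regions), count = as.integer(regions),
               stringsAsFactors = FALSE),
    totals = c(anticp = sum(a), iacp = sum(b), mlacp = sum(c)),
    union = sum(a | b | c),
    class = c("venn_counts", "data.frame"))
}

#' @export
print.venn_counts <- function(x, ...) {
  t <- attr(x, "totals")
  cat("Predictor positives: AntiCP", t[["anticp"]], "| iACP", t[["iacp"]],
      "| MLACP", t[["mlacp"]], "\n")
  cat("Union:", attr(x, "union"), " Triple intersection:",
      x$count[x$region == "all_three"], "\n")
  print.data.frame(x)
  invisible(x)
}

#' Stratify consensus ACPs by mode of action
#'
#' Partitions consensus ACPs into exclusive categories by their toxicity and
#' cell-penetration flags: \code{toxic_only}, \code{cpp_only}, \code{both},
#' \code{none}. Overlapping totals (toxic = toxic_only + both, cpp =
#' cpp_only + both) are also reported.
#'
#' @param verdicts \code{\link{call_predictors}} output containing logical
#'   \code{toxic} and \code{cpp} columns for every consensus ACP.
#' @return A list with \code{assignments} (peptide, moa_category),
#'   \code{category_counts} (exclusive, sums to the consensus count) and
#'   \code{overlapping_totals}.
#' @export
classify_moa <- function(verdicts) {
  acp <- verdicts[verdicts$consensus_acp, , drop = FALSE]
  if (nrow(acp) && (!all(c("toxic", "cpp") %in% names(acp)) ||
                    anyNA(acp$toxic) || anyNA(acp$cpp)))
    stop("toxic/cpp flags required for every consensus ACP")
  cat_of <- function(toxic, cpp)
    ifelse(toxic & cpp, "both",
           ifelse(toxic, "toxic_only", ifelse(cpp, "cpp_only", "none")))
  cats <- c("toxic_only", "cpp_only", "both", "none")
  moa <- if (nrow(acp)) cat_of(as.logical(acp$toxic), as.logical(acp$cpp))
         else character()
  counts <- table(factor(moa, levels = cats))
  list(
    assignments = data.frame(peptide = acp$peptide, moa_category = moa,
                             stringsAsFactors = FALSE),
    category_counts = stats::setNames(as.integer(counts), cats),
    overlapping_totals = c(
      toxic = as.integer(counts[["toxic_only"]] + counts[["both"]]),
      cpp = as.integer(counts[["cpp_only"]] + counts[["both"]]))
  )
}

#' Rank candidate peptides within a category
#'
#' Sorts descending by the AntiCP-style SVM score; ties are broken by the
#' mean of the other three scores (descending), then lexicographically by
#' sequence, so the order is a deterministic total order.
#'
#' @param scores score table rows to rank.
#' @return The rows in rank order.
#' @export
rank_candidates <- function(scores) {
  if (!nrow(scores)) stop("cannot rank an empty candidate set")
  other_mean <- (scores$iacp_prob + scores$mlacp_rf + scores$mlacp_svm) / 3
  ord <- order(-scores$anticp_svm, -other_mean, scores$peptide)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize consensus-ACP properties as panel percentages
#'
#' Produces the three summary panels used to characterize a screened ACP set:
#' length class (5-20 / 21-35 / 36-50 residues), hydrophobicity class, and
#' net-charge class, as percentages rounded to one decimal; each panel sums
#' to 100 (up to rounding).
#'
#' @param properties \code{\link{peptide_properties}} output for the set.
#' @return Named list of named percentage vectors (\code{length},
#'   \code{hydrophobicity}, \code{charge}); empty input yields an object
#'   flagged via the \code{empty} attribute.
#' @export
property_summary <- function(properties) {
  n <- nrow(properties)
  if (n == 0L)
    return(structure(list(length = numeric(), hydrophobicity = numeric(),
                          charge = numeric()), empty = TRUE))
  pct <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    stats::setNames(round(100 * as.integer(tab) / n, 1L), levels)
  }
  len_class <- cut(properties$length, c(4.5, 20.5, 35.5, 50.5),
                   labels = c("5-20", "21-35", "36-50"))
  structure(list(
    length = pct(len_class, c("5-20", "21-35", "36-50")),
    hydrophobicity = pct(properties$hydro_class,
                         c("hydrophobic", "hydrophilic")),
    charge = pct(properties$charge_class, c("cationic", "anionic", "neutral"))
  ), empty = FALSE)
}

#' Read a predictor score table from TSV
#'
#' Expects a header with columns \code{peptide}, \code{anticp_svm},
#' \code{iacp_prob}, \code{mlacp_rf}, \code{mlacp_svm} and optional 0/1
#' \code{toxic}, \code{cpp}. A \code{column_map} can rename nonstandard
#' headers (names = standard, values = file headers).
#'
#' @param path TSV path.
#' @param column_map optional named character vector remapping headers.
#' @return Validated score data.frame with logical flag columns.
#' @export
read_scores <- function(path, column_map = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(x)) stop("mapped column '", src, "' not in ", path)
      names(x)[names(x) == src] <- std
    }
  }
  check_scores(x)
  for (fl in c("toxic", "cpp"))
    if (fl %in% names(x)) x[[fl]] <- as.logical(as.integer(x[[fl]]))
  x
}
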