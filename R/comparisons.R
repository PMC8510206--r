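#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way ANOVA across treatment conditions and compares every
#' condition to the shared control with Dunnett's test (single-step
#' multivariate-t adjustment via \pkg{multcomp}). Significance flags follow
#' the usual convention: \code{*} for adjusted p < 0.05, \code{**} for
#' adjusted p < 0.01.
#'
#' @param data data.frame in long format.
#' @param response name of the numeric response column (default
#'   \code{"viability"}).
#' @param condition name of the condition column (default
#'   \code{"condition"}).
#' @param control the control level of \code{condition} (default
#'   \code{"control"}).
#' @return An object of class \code{"condition_comparison"}: a list with
#'   \code{summary} (per-condition mean, SD, n), \code{anova} (F and p),
#'   \code{dunnett} (estimate, raw p, adjusted p, flag per comparison).
#' @export
compare_conditions <- function(data, response = "viability",
                               condition = "condition",
                               control = "control") {
  if (!all(c(response, condition) %in% names(data)))
    stop("data must contain columns '", response, "' and '", condition, "'")
  y <- data[[response]]
  g <- as.character(data[[condition]])
  if (!control %in% g) stop("control level '", control, "' not found")
  if (length(unique(g)) < 2L) stop("need at least 2 conditions")
  ns <- table(g)
  if (any(ns < 2L))
    stop("every condition needs >= 2 replicates (offending: ",
         paste(names(ns)[ns < 2L], collapse = ", "), ")")
  g <- stats::relevel(factor(g), ref = control)
  df <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1L]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  gs <- summary(glht_fit)  # single-step multivariate-t adjustment
  raw <- summary(glht_fit, test = multcomp::adjusted("none"))
  comparisons <- sub(" - .*$", "", names(gs$test$coefficients))
  adj_p <- pmax(as.numeric(gs$test$pvalues), as.numeric(raw$test$pvalues))
  dunnett <- data.frame(
    condition = comparisons,
    estimate = as.numeric(gs$test$coefficients),
    se = as.numeric(gs$test$sigma),
    p_raw = as.numeric(raw$test$pvalues),
    p_adjusted = adj_p,
    flag = ifelse(adj_p < 0.01, "**", ifelse(adj_p < 0.05, "*", "")),
    stringsAsFactors = FALSE
  )
  structure(list(
    summary = data.frame(
      condition = levels(g),
      mean = as.numeric(tapply(y, g, mean)),
      sd = as.numeric(tapply(y, g, stats::sd)),
      n = as.integer(table(g)),
      stringsAsFactors = FALSE),
    anova = c(F = an$`F value`[1L], p = an$`Pr(>F)`[1L]),
    dunnett = dunnett,
    control = control,
    method = "Dunnett single-step (multivariate t, multcomp::glht)"
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("One-way ANOVA: F =", format(x$anova[["F"]], digits = 4),
      ", p =", format.pval(x$anova[["p"]], digits = 3), "\n")
  cat("Dunnett comparisons vs '", x$control, "' (", x$method, "):\n",
      sep = "")
  d <- x$dunnett
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-20s diff %8.2f  adj p %s %s\n", d$condition[i],
                d$estimate[i], format.pval(d$p_adjusted[i], digits = 3),
                d$flag[i]))
  invisible(x)
}

#' Combination-grid viability analysis
#'
#' For a factorial grid of two compounds (doses \code{dose_a} x
#' \code{dose_b}, replicate viabilities), computes per-cell mean and SD and
#' tests every true combination cell (both doses > 0) against its two
#' monotherapy margins and the untreated control, using single-step
#' multivariate-t adjusted contrasts on a one-way cell-means ANOVA. The
#' output states the direction of each difference on the viability scale.
#'
#' @param data long data.frame with columns \code{dose_a}, \code{dose_b},
#'   \code{viability} (and any number of replicate rows per cell).
#' @param labels length-2 character vector naming the compounds (used in
#'   output only).
#' @return A list of class \code{"combination_analysis"} with \code{cells}
#'   (per-cell mean, sd, n) and \code{comparisons} (per combination cell vs
#'   control / margin A / margin B: estimate, adjusted p, direction, flag).
#' @export
combination_analysis <- function(data, labels = c("A", "B")) {
  need <- c("dose_a", "dose_b", "viability")
  if (!all(need %in% names(data)))
    stop("data must contain columns ", paste(need, collapse = ", "))
  cell <- paste0(data$dose_a, "|", data$dose_b)
  combos <- unique(data[data$dose_a > 0 & data$dose_b > 0,
                        c("dose_a", "dose_b")])
  if (!nrow(combos)) stop("no combination cells (both doses > 0) in grid")
  have <- unique(cell)
  for (i in seq_len(nrow(combos))) {
    a <- combos$dose_a[i]; b <- combos$dose_b[i]
    for (m in c(paste0(a, "|0"), paste0("0|", b), "0|0"))
      if (!m %in% have)
        stop("missing monotherapy margin or control cell: ", m)
  }
  cellf <- factor(cell)
  fit <- stats::aov(viability ~ 0 + cellf,
                    data = data.frame(viability = data$viability,
                                      cellf = cellf))
  lv <- levels(cellf)
  rows <- list(); labs <- character()
  for (i in seq_len(nrow(combos))) {
    a <- combos$dose_a[i]; b <- combos$dose_b[i]
    this <- paste0(a, "|", b)
    for (ref in c("0|0", paste0(a, "|0"), paste0("0|", b))) {
      k <- numeric(length(lv))
      k[lv == this] <- 1; k[lv == ref] <- k[lv == ref] - 1
      rows[[length(rows) + 1L]] <- k
      labs <- c(labs, paste0(this, " vs ", ref))
    }
  }
  K <- do.call(rbind, rows)
  rownames(K) <- labs
  gs <- summary(multcomp::glht(fit, linfct = K))
  est <- as.numeric(gs$test$coefficients)
  adj_p <- as.numeric(gs$test$pvalues)
  parts <- strsplit(labs, " vs ", fixed = TRUE)
  comparisons <- data.frame(
    combination = vapply(parts, `[`, character(1L), 1L),
    reference = vapply(parts, `[`, character(1L), 2L),
    estimate = est,
    direction = ifelse(est < 0, "lower viability", ifelse(
      est > 0, "higher viability", "equal")),
    p_adjusted = adj_p,
    flag = ifelse(adj_p < 0.01, "**", ifelse(adj_p < 0.05, "*", "")),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(data$viability, list(cell = cell), function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  ab <- strsplit(agg$cell, "|", fixed = TRUE)
  cells <- data.frame(
    dose_a = as.numeric(vapply(ab, `[`, character(1L), 1L)),
    dose_b = as.numeric(vapply(ab, `[`, character(1L), 2L)),
    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
    n = as.integer(agg$x[, "n"]), stringsAsFactors = FALSE)
  cells <- cells[order(cells$dose_a, cells$dose_b), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, comparisons = comparisons, labels = labels),
            class = "combination_analysis")
}

#' @export
print.combination_analysis <- function(x, ...) {
  cat("Combination grid:", x$labels[1L], "x", x$labels[2L], "-",
      nrow(x$cells), "cells\n")
  cat("Comparisons of combination cells vs control and margins:\n")
  d <- x$comparisons
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-22s %-9s diff %7.2f  adj p %s %s\n",
                paste(d$combination[i], "vs", d$reference[i]), "",
                d$estimate[i], format.pval(d$p_adjusted[i], digits = 3),
                d$flag[i]))
  invisible(x)
}
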