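# Background amino-acid frequencies (UniProt-like composition, normalized on
# use). F+L together ~13.5%, so a pepsin digest has geometric-ish fragment
# lengths with mean ~7 residues and a tail reaching the 36-50 residue bin.
AA_BACKGROUND_FREQ <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87)
AA_BACKGROUND_FREQ <- AA_BACKGROUND_FREQ / sum(AA_BACKGROUND_FREQ)

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed expands to independent per-stage seeds by a fixed affine
#' rule modulo 2^31 - 1, so pipeline stages do not share RNG streams.
#'
#' @param seed global integer seed.
#' @param stage one of \code{"proteome"}, \code{"scores"}, \code{"mtt"},
#'   \code{"pipeline"}.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage = c("proteome", "scores", "mtt",
                                       "pipeline")) {
  stage <- match.arg(stage)
  offset <- c(proteome = 101L, scores = 211L, mtt = 307L, pipeline = 401L)
  as.integer((as.numeric(seed) * 7919 + offset[[stage]]) %% 2147483647)
}

#' Generate a random synthetic proteome
#'
#' Protein sequences are drawn i.i.d. from a background residue-frequency
#' vector; lengths are gamma-distributed around \code{length_mean}
#' (coefficient of variation 0.3, floor 50 residues). With the default
#' frequencies a pepsin digest of 100 such proteins populates all three
#' screening length bins (5-20, 21-35, 36-50 residues).
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_mean mean protein length in residues (default 400).
#' @param aa_frequencies named frequency vector over the 20 residues, summing
#'   to 1 (within 1e-9 before normalization).
#' @param seed integer seed; output is byte-identical for a given seed.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
gen_proteome <- function(n_proteins = 100L, length_mean = 400,
                         aa_frequencies = AA_BACKGROUND_FREQ, seed = 1L) {
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (!all(AA20 %in% names(aa_frequencies)))
    stop("aa_frequencies must name all 20 residues")
  freq <- aa_frequencies[AA20]
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    stop("aa_frequencies must be non-negative and sum to 1")
  freq <- freq / sum(freq)
  with_seed(seed, {
    lens <- pmax(50L, round(stats::rgamma(n_proteins,
                                          shape = 1 / 0.3^2,
                                          scale = length_mean * 0.3^2)))
    seqs <- vapply(lens, function(n)
      paste(sample(AA20, n, replace = TRUE, prob = freq), collapse = ""),
      character(1L))
    data.frame(id = sprintf("synprot_%04d", seq_len(n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Score-model for synthetic predictor tables
#'
#' Describes the joint distribution used to emulate external predictor
#' outputs: a latent "true ACP" label with prevalence \code{prevalence}, a
#' Gaussian SVM-score column, Beta-distributed probability columns
#' conditional on the label, and Bernoulli toxicity / cell-penetration
#' mode-of-action flags. Defaults were calibrated once so marginal call rates
#' resemble a real consensus screen (one permissive predictor near 97%
#' positive, the others far stricter, consensus ~1.5% of peptides); all
#' values are package design choices, documented in the methods vignette.
#'
#' @param prevalence latent ACP prevalence in (0, 1).
#' @param anticp list of \code{pos}/\code{neg} Gaussian \code{c(mean, sd)}.
#' @param iacp,mlacp_rf,mlacp_svm lists of \code{pos}/\code{neg} Beta
#'   \code{c(a, b)} parameters.
#' @param moa named rates: \code{toxic_acp}, \code{cpp_acp} (flag
#'   probabilities given a true ACP), \code{toxic_bg}, \code{cpp_bg}
#'   (background rates).
#' @return A list of class \code{"score_model"}.
#' @export
score_model <- function(
    prevalence = 0.015,
    anticp = list(pos = c(mean = 1.70, sd = 0.25),
                  neg = c(mean = 1.47, sd = 0.25)),
    iacp = list(pos = c(a = 8, b = 2), neg = c(a = 2, b = 5)),
    mlacp_rf = list(pos = c(a = 6, b = 3), neg = c(a = 2, b = 4)),
    mlacp_svm = list(pos = c(a = 6, b = 3), neg = c(a = 2, b = 4)),
    moa = c(toxic_acp = 19 / 316, cpp_acp = 247 / 316,
            toxic_bg = 0.05, cpp_bg = 0.30)) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  structure(list(prevalence = prevalence, anticp = anticp, iacp = iacp,
                 mlacp_rf = mlacp_rf, mlacp_svm = mlacp_svm, moa = moa),
            class = "score_model")
}

#' Closed-form consensus rates implied by a score model
#'
#' Exceedance probabilities of each score column over the default thresholds,
#' multiplied across the (conditionally independent) predictors, give the
#' model-implied consensus recall (given a true ACP) and false-positive rate
#' (given a non-ACP), hence the expected consensus call rate and precision.
#'
#' @param model a \code{\link{score_model}}.
#' @param thresholds a \code{\link{consensus_thresholds}}.
#' @return List: \code{recall}, \code{fpr}, \code{consensus_rate},
#'   \code{precision}.
#' @export
consensus_rates <- function(model = score_model(),
                            thresholds = consensus_thresholds()) {
  p_norm <- function(par, cut) stats::pnorm(cut, par[["mean"]], par[["sd"]],
                                            lower.tail = FALSE)
  p_beta <- function(par, cut) stats::pbeta(cut, par[["a"]], par[["b"]],
                                            lower.tail = FALSE)
  rate <- function(which) {
    p_norm(model$anticp[[which]], thresholds$anticp_min) *
      p_beta(model$iacp[[which]], thresholds$iacp_min) *
      p_beta(model$mlacp_rf[[which]], thresholds$mlacp_rf_min) *
      p_beta(model$mlacp_svm[[which]], thresholds$mlacp_svm_min)
  }
  recall <- rate("pos"); fpr <- rate("neg")
  pi <- model$prevalence
  consensus_rate <- pi * recall + (1 - pi) * fpr
  list(recall = recall, fpr = fpr, consensus_rate = consensus_rate,
       precision = pi * recall / consensus_rate)
}

#' Generate a synthetic predictor score table with hidden truth
#'
#' Draws a latent ACP label per peptide, then predictor scores and
#' mode-of-action flags from the model's conditional distributions. The
#' latent labels are returned in a separate truth table that the screening
#' pipeline never reads; they exist so screening recall/precision can be
#' measured.
#'
#' @param peptides character vector of peptide sequences (unique).
#' @param model a \code{\link{score_model}}.
#' @param seed integer seed.
#' @return List with \code{scores} (pipeline input: peptide, four score
#'   columns, toxic, cpp) and \code{truth} (peptide, is_acp).
#' @export
gen_scores <- function(peptides, model = score_model(), seed = 1L) {
  if (anyDuplicated(peptides)) stop("peptides must be unique")
  n <- length(peptides)
  with_seed(seed, {
    is_acp <- stats::runif(n) < model$prevalence
    draw_norm <- function(spec) ifelse(
      is_acp,
      stats::rnorm(n, spec$pos[["mean"]], spec$pos[["sd"]]),
      stats::rnorm(n, spec$neg[["mean"]], spec$neg[["sd"]]))
    draw_beta <- function(spec) ifelse(
      is_acp,
      stats::rbeta(n, spec$pos[["a"]], spec$pos[["b"]]),
      stats::rbeta(n, spec$neg[["a"]], spec$neg[["b"]]))
    toxic <- stats::runif(n) < ifelse(is_acp, model$moa[["toxic_acp"]],
                                      model$moa[["toxic_bg"]])
    cpp <- stats::runif(n) < ifelse(is_acp, model$moa[["cpp_acp"]],
                                    model$moa[["cpp_bg"]])
    list(
      scores = data.frame(
        peptide = peptides,
        anticp_svm = draw_norm(model$anticp),
        iacp_prob = draw_beta(model$iacp),
        mlacp_rf = draw_beta(model$mlacp_rf),
        mlacp_svm = draw_beta(model$mlacp_svm),
        toxic = toxic, cpp = cpp, stringsAsFactors = FALSE),
      truth = data.frame(peptide = peptides, is_acp = is_acp,
                         stringsAsFactors = FALSE))
  })
}

#' MTT plate scenarios
#'
#' A scenario bundles the true dose-response parameters and the plate design
#' used by \code{\link{gen_mtt}}. Built-ins:
#' \describe{
#'   \item{C_ORI}{peptide monotherapy: true IC50 114.9 uM, top 100, bottom
#'     0, hill 1.5; doses 0/25/50/100/200/400 uM, 4 replicates, 72 h,
#'     viability noise SD 5 points.}
#'   \item{DOX}{doxorubicin monotherapy: true IC50 0.12 uM, hill 1; two-fold
#'     doses 0 to 0.25 uM.}
#'   \item{FLAT}{no inhibition: top = bottom = 100 (an inactive compound).}
#' }
#' The hill slope, noise SD, optical-density levels and the DOX point IC50
#' are package design choices (the DOX value sits inside the broad
#' literature bracket for this drug-and-assay combination).
#'
#' @param name scenario name, or pass fields directly to override.
#' @param ... overrides for any scenario field (\code{top}, \code{bottom},
#'   \code{ic50}, \code{hill}, \code{doses}, \code{replicates},
#'   \code{timepoints}, \code{noise_sd}, \code{control_od}, \code{blank_od},
#'   \code{n_blanks}).
#' @return A list of class \code{"mtt_scenario"}.
#' @export
mtt_scenario <- function(name = c("C_ORI", "DOX", "FLAT"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    C_ORI = list(top = 100, bottom = 0, ic50 = 114.9, hill = 1.5,
                 doses = c(0, 25, 50, 100, 200, 400)),
    DOX = list(top = 100, bottom = 0, ic50 = 0.12, hill = 1,
               doses = c(0, 0.25 / 16, 0.25 / 8, 0.25 / 4, 0.25 / 2, 0.25)),
    FLAT = list(top = 100, bottom = 100, ic50 = 100, hill = 1,
                doses = c(0, 25, 50, 100, 200, 400)))
  sc <- utils::modifyList(c(base, list(
    name = name, replicates = 4L, timepoints = 72,
    noise_sd = 5, control_od = 1.0, blank_od = 0.05, n_blanks = 4L)),
    list(...))
  if (!0 %in% sc$doses) stop("scenario doses must include 0")
  if (sc$replicates < 2L) stop("scenario needs >= 2 replicates")
  if (sc$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(sc, class = "mtt_scenario")
}

#' Generate a synthetic MTT plate
#'
#' Simulates a long-format absorbance table for a scenario: per timepoint,
#' \code{n_blanks} blank wells, \code{replicates} untreated control wells
#' (dose 0), and \code{replicates} treated wells per positive dose.
#' Absorbance is \code{blank_od + control_od * V(d)/100} plus Gaussian noise
#' whose SD is the scenario's viability-scale noise mapped to the absorbance
#' scale (\code{control_od * noise_sd / 100}); blanks receive no biological
#' signal and the same mapping applies, so a zero-noise scenario round-trips
#' exactly through \code{\link{plate_viability}} and \code{\link{fit_4pl}}.
#'
#' @param scenario an \code{\link{mtt_scenario}}.
#' @param seed integer seed.
#' @return Long data.frame: \code{condition}, \code{compound},
#'   \code{dose_uM}, \code{timepoint_h}, \code{replicate},
#'   \code{absorbance}, \code{role}.
#' @export
gen_mtt <- function(scenario = mtt_scenario("C_ORI"), seed = 1L) {
  if (!inherits(scenario, "mtt_scenario")) stop("scenario must be an mtt_scenario")
  sd_abs <- scenario$control_od * scenario$noise_sd / 100
  rows <- list()
  with_seed(seed, {
    for (tp in scenario$timepoints) {
      blank <- data.frame(
        condition = "blank", compound = scenario$name, dose_uM = NA_real_,
        timepoint_h = tp, replicate = seq_len(scenario$n_blanks),
        absorbance = scenario$blank_od +
          stats::rnorm(scenario$n_blanks, sd = sd_abs),
        role = "blank", stringsAsFactors = FALSE)
      well_rows <- lapply(scenario$doses, function(d) {
        v <- fourpl(d, scenario$top, scenario$bottom, scenario$ic50,
                    scenario$hill)
        data.frame(
          condition = if (d == 0) "control" else
            paste0(scenario$name, "_", d, "uM"),
          compound = scenario$name, dose_uM = d, timepoint_h = tp,
          replicate = seq_len(scenario$replicates),
          absorbance = scenario$blank_od + scenario$control_od * v / 100 +
            stats::rnorm(scenario$replicates, sd = sd_abs),
          role = if (d == 0) "control" else "treated",
          stringsAsFactors = FALSE)
      })
      rows <- c(rows, list(blank), well_rows)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$absorbance <- pmax(out$absorbance, 0)
  out
}

#' Generate a flat (no-inhibition) MTT plate
#'
#' Convenience wrapper over \code{\link{gen_mtt}} with the FLAT scenario:
#' viability stays near 100% at every dose, emulating an inactive compound.
#'
#' @param seed integer seed.
#' @param ... scenario field overrides.
#' @return Long plate data.frame.
#' @export
gen_flat_scenario <- function(seed = 1L, ...) {
  gen_mtt(mtt_scenario("FLAT", ...), seed = seed)
}
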