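# Hydropathy scales, indexed by one-letter residue code
HYDROPATHY_SCALES <- list(
  kyte_doolittle = c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                     L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2),
  hopp_woods     = c(A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
                     Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
                     L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
                     S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  eisenberg      = c(A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
                     Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
                     L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
                     S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)
)

get_scale <- function(scale) {
  if (is.numeric(scale)) {
    if (!all(AA20 %in% names(scale)))
      stop("custom scale must name all 20 residues")
    return(scale)
  }
  if (!scale %in% names(HYDROPATHY_SCALES))
    stop("unknown hydropathy scale '", scale, "'; available: ",
         paste(names(HYDROPATHY_SCALES), collapse = ", "))
  HYDROPATHY_SCALES[[scale]]
}

seq_letters <- function(sequence) {
  strsplit(validate_sequence(sequence, allow_x = FALSE), "", fixed = TRUE)[[1L]]
}

#' Net side-chain charge of a peptide
#'
#' Integer side-chain charge model at neutral pH: Lys and Arg contribute +1,
#' Asp and Glu -1, His 0, termini ignored. Set \code{pH} to a number for a
#' Henderson-Hasselbalch fractional-charge model (side chains plus termini)
#' instead.
#'
#' @param sequence peptide sequence.
#' @param pH \code{NULL} (default, integer model) or a pH value for the
#'   fractional model.
#' @return Net charge (integer in the default model, real in the pH model).
#' @examples
#' net_charge("VTFVLIAAK")  # +1, cationic
#' @export
net_charge <- function(sequence, pH = NULL) {
  letters <- seq_letters(sequence)
  if (is.null(pH)) {
    return(sum(letters %in% c("K", "R")) - sum(letters %in% c("D", "E")))
  }
  # fractional charges: base groups +1/(1+10^(pH-pKa)), acids -1/(1+10^(pKa-pH))
  pka_base <- c(K = 10.5, R = 12.5, H = 6.0)
  pka_acid <- c(D = 3.9, E = 4.1, C = 8.3, Y = 10.1)
  q <- 1 / (1 + 10^(pH - 9.0)) - 1 / (1 + 10^(2.35 - pH))  # N-/C-terminus
  for (aa in names(pka_base))
    q <- q + sum(letters == aa) / (1 + 10^(pH - pka_base[[aa]]))
  for (aa in names(pka_acid))
    q <- q - sum(letters == aa) / (1 + 10^(pka_acid[[aa]] - pH))
  q
}

#' Charge class from a net charge
#'
#' @param charge numeric net charge(s).
#' @return \code{"cationic"}, \code{"anionic"} or \code{"neutral"}.
#' @export
charge_class <- function(charge) {
  ifelse(charge > 0, "cationic", ifelse(charge < 0, "anionic", "neutral"))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean per-residue hydropathy under the chosen scale (Kyte-Doolittle by
#' default). Under that scale a peptide is classed hydrophobic when
#' GRAVY > 0, hydrophilic otherwise.
#'
#' @param sequence peptide sequence.
#' @param scale scale name (\code{"kyte_doolittle"}, \code{"hopp_woods"},
#'   \code{"eisenberg"}) or a named numeric vector over the 20 residues.
#' @return Mean hydropathy (dimensionless).
#' @examples
#' gravy("VTFVLIAAK")  # 18.5 / 9
#' @export
gravy <- function(sequence, scale = "kyte_doolittle") {
  sc <- get_scale(scale)
  mean(sc[seq_letters(sequence)])
}

#' Hydrophobicity class from GRAVY
#' @param g GRAVY value(s).
#' @return \code{"hydrophobic"} if \code{g > 0} else \code{"hydrophilic"}.
#' @export
hydro_class <- function(g) ifelse(g > 0, "hydrophobic", "hydrophilic")

#' Eisenberg hydrophobic moment
#'
#' Magnitude of the mean hydropathy vector assuming a fixed rotation per
#' residue (100 degrees for an alpha helix):
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_i h_i (\cos i\delta, \sin i\delta)\right|}
#' A peptide is called amphipathic when \eqn{\mu_H} meets the threshold
#' (default 0.2, a conventional helical-wheel cutoff; the moment is invariant
#' to the choice of starting angle).
#'
#' @param sequence peptide sequence, length >= 2.
#' @param angle rotation per residue in degrees (default 100).
#' @param scale hydropathy scale (default \code{"eisenberg"}).
#' @return The moment magnitude (dimensionless).
#' @export
hydrophobic_moment <- function(sequence, angle = 100, scale = "eisenberg") {
  letters <- seq_letters(sequence)
  n <- length(letters)
  if (n < 2L) stop("hydrophobic moment requires length >= 2")
  h <- get_scale(scale)[letters]
  delta <- angle * pi / 180
  i <- seq_len(n)
  sqrt(sum(h * cos(i * delta))^2 + sum(h * sin(i * delta))^2) / n
}

#' Residue composition
#'
#' @param sequence peptide sequence.
#' @return Named integer vector of counts over the 20 residues (zeros kept);
#'   counts sum to the peptide length.
#' @examples
#' composition("TTMICLTCAR")[["T"]]  # 3
#' @export
composition <- function(sequence) {
  letters <- seq_letters(sequence)
  counts <- table(factor(letters, levels = AA20))
  out <- as.integer(counts)
  names(out) <- AA20
  out
}

#' Full physicochemical profile for a set of peptides
#'
#' Computes, per peptide: length, net charge and charge class, GRAVY and
#' hydrophobicity class, hydrophobic moment and amphipathicity call.
#'
#' @param peptides character vector of sequences or a digest table with a
#'   \code{peptide} column.
#' @param scale hydropathy scale for GRAVY.
#' @param moment_threshold amphipathicity cutoff on the moment (default 0.2).
#' @return A data.frame, one row per peptide.
#' @export
peptide_properties <- function(peptides, scale = "kyte_doolittle",
                               moment_threshold = 0.2) {
  seqs <- if (is.data.frame(peptides)) peptides$peptide else peptides
  g <- vapply(seqs, gravy, numeric(1L), scale = scale, USE.NAMES = FALSE)
  q <- vapply(seqs, net_charge, numeric(1L), USE.NAMES = FALSE)
  mu <- vapply(seqs, function(s)
    if (nchar(s) >= 2L) hydrophobic_moment(s) else NA_real_, numeric(1L),
    USE.NAMES = FALSE)
  data.frame(
    peptide = seqs,
    length = nchar(seqs),
    net_charge = q,
    charge_class = charge_class(q),
    gravy = g,
    hydro_class = hydro_class(g),
    hydrophobic_moment = mu,
    amphipathic = !is.na(mu) & mu >= moment_threshold,
    stringsAsFactors = FALSE
  )
}
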