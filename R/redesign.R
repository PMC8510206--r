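#' Positional differences between two equal-length peptides
#'
#' @param original,variant equal-length sequences.
#' @return data.frame with columns \code{position} (1-based), \code{from},
#'   \code{to}, in N- to C-terminal order; zero rows if identical.
#' @examples
#' peptide_diff("VTFVLIAAK", "FTFVLLAAK")  # V1F, I6L
#' @export
peptide_diff <- function(original, variant) {
  a <- seq_letters(original)
  b <- seq_letters(variant)
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  pos <- which(a != b)
  data.frame(position = pos, from = a[pos], to = b[pos],
             stringsAsFactors = FALSE)
}

#' Apply substitutions to a peptide
#'
#' Inverse of \code{\link{peptide_diff}}: applying
#' \code{peptide_diff(original, v)} to \code{original} returns \code{v}.
#'
#' @param original sequence.
#' @param substitutions data.frame with \code{position}, \code{from},
#'   \code{to}.
#' @return The substituted sequence.
#' @export
apply_substitutions <- function(original, substitutions) {
  letters <- seq_letters(original)
  if (!nrow(substitutions)) return(paste(letters, collapse = ""))
  for (i in seq_len(nrow(substitutions))) {
    p <- substitutions$position[i]
    if (p < 1L || p > length(letters))
      stop("substitution position ", p, " outside peptide length ",
           length(letters))
    if (letters[p] != substitutions$from[i])
      stop("residue mismatch at position ", p, ": expected ",
           substitutions$from[i], ", found ", letters[p])
    letters[p] <- substitutions$to[i]
  }
  paste(letters, collapse = "")
}

#' Enumerate all single-residue mutants
#'
#' Every position substituted by every non-identical residue of the 20-letter
#' alphabet, in deterministic position-major, alphabetical order: a length-n
#' peptide yields exactly 19n variants.
#'
#' @param peptide sequence.
#' @param positions positions to mutate (default all).
#' @param alphabet candidate residues (default the 20 standard amino acids).
#' @return data.frame with \code{variant}, \code{position}, \code{from},
#'   \code{to}.
#' @export
enumerate_single_mutants <- function(peptide, positions = NULL,
                                     alphabet = AA20) {
  letters <- seq_letters(peptide)
  if (is.null(positions)) positions <- seq_along(letters)
  rows <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    subs <- sort(setdiff(alphabet, letters[p]))
    variants <- vapply(subs, function(aa) {
      mut <- letters; mut[p] <- aa; paste(mut, collapse = "")
    }, character(1L))
    rows[[k]] <- data.frame(variant = unname(variants), position = p,
                            from = letters[p], to = subs,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Greedy substitution redesign of a peptide
#'
#' Hill-climbing search over single-residue substitutions: each round scores
#' all single mutants of the current sequence and keeps the best one (ties
#' broken by lowest position, then alphabetical residue), stopping when the
#' best gain is \code{<= min_gain} or after \code{max_rounds} rounds. The
#' accepted variant never scores below the original.
#'
#' @param peptide starting sequence.
#' @param scorer function mapping a sequence to a numeric score (higher is
#'   better), e.g. \code{\link{additive_scorer}} or a wrapper over an
#'   external predictor's score table.
#' @param max_rounds maximum number of substitutions (default 2).
#' @param min_gain minimum score improvement to accept a round (default 0).
#' @return A list of class \code{"redesign_result"}: \code{original},
#'   \code{variant}, \code{substitutions}, \code{original_score},
#'   \code{variant_score}.
#' @examples
#' w <- stats::setNames(rep(0, 20), pepscreen:::AA20); w[["F"]] <- 1
#' redesign("AAA", additive_scorer(w), max_rounds = 3)
#' @export
redesign <- function(peptide, scorer, max_rounds = 2L, min_gain = 0) {
  if (max_rounds < 1L) stop("max_rounds must be >= 1")
  original <- validate_sequence(peptide, allow_x = FALSE)
  score_with <- function(s)
    tryCatch(scorer(s), error = function(e)
      stop("scorer failed on '", s, "': ", conditionMessage(e)))
  current <- original
  current_score <- score_with(original)
  for (round in seq_len(max_rounds)) {
    mutants <- enumerate_single_mutants(current)
    scores <- vapply(mutants$variant, score_with, numeric(1L),
                     USE.NAMES = FALSE)
    # enumeration order is position-major alphabetical, so the first maximum
    # realizes the tie-break (lowest position, then residue)
    best <- which.max(scores)
    if (scores[best] - current_score <= min_gain) break
    current <- mutants$variant[best]
    current_score <- scores[best]
  }
  structure(list(
    original = original,
    variant = current,
    substitutions = peptide_diff(original, current),
    original_score = score_with(original),
    variant_score = current_score
  ), class = "redesign_result")
}

#' @export
print.redesign_result <- function(x, ...) {
  cat("Peptide redesign\n")
  cat("  original:", x$original, sprintf("(score %.4g)\n", x$original_score))
  cat("  variant :", render_substitutions(x$original, x$substitutions),
      sprintf("(score %.4g)\n", x$variant_score))
  if (nrow(x$substitutions)) {
    for (i in seq_len(nrow(x$substitutions)))
      cat(sprintf("  %s%d%s\n", x$substitutions$from[i],
                  x$substitutions$position[i], x$substitutions$to[i]))
  } else cat("  no substitutions accepted\n")
  invisible(x)
}

#' Render a variant with substituted positions bracketed
#'
#' @param original the starting sequence.
#' @param substitutions a \code{\link{peptide_diff}} table.
#' @return The variant with each substituted residue wrapped in brackets,
#'   e.g. \code{"[F]TFVL[L]AAK"}.
#' @export
render_substitutions <- function(original, substitutions) {
  letters <- strsplit(apply_substitutions(original, substitutions), "",
                      fixed = TRUE)[[1L]]
  letters[substitutions$position] <-
    paste0("[", letters[substitutions$position], "]")
  paste(letters, collapse = "")
}

#' Additive per-residue scorer
#'
#' A transparent scorer for tests and demonstrations: the score of a peptide
#' is the sum of per-residue weights. Real screening uses external predictor
#' scores; this scorer exists so the redesign search can be exercised and
#' verified against exhaustive enumeration.
#'
#' @param weights named numeric vector over the 20 residues, or a YAML file
#'   path mapping residue to weight.
#' @return A function: sequence -> numeric score.
#' @export
additive_scorer <- function(weights) {
  if (is.character(weights) && length(weights) == 1L)
    weights <- unlist(yaml::read_yaml(weights))
  if (!all(AA20 %in% names(weights)))
    stop("weights must name all 20 residues")
  weights <- unlist(weights)
  function(sequence) sum(weights[seq_letters(sequence)])
}

#' Exhaustive bounded-substitution search (oracle mode)
#'
#' Scores every variant within \code{k} substitutions of the peptide and
#' returns the best (ties broken like \code{\link{redesign}}'s round order:
#' fewest substitutions first, then position-major alphabetical). Exponential
#' in \code{k}; intended for small peptides as an independent check on the
#' greedy search.
#'
#' @param peptide sequence.
#' @param scorer scoring function.
#' @param k maximum number of substitutions (default 1).
#' @return List with \code{variant} and \code{score}.
#' @export
exhaustive_redesign <- function(peptide, scorer, k = 1L) {
  original <- validate_sequence(peptide, allow_x = FALSE)
  frontier <- original
  seen <- original
  best_variant <- original
  best_score <- scorer(original)
  for (round in seq_len(k)) {
    nxt <- character()
    for (s in frontier) {
      muts <- enumerate_single_mutants(s)$variant
      nxt <- c(nxt, muts[!(muts %in% seen)])
    }
    nxt <- unique(nxt)
    if (!length(nxt)) break
    scores <- vapply(nxt, scorer, numeric(1L), USE.NAMES = FALSE)
    better <- which(scores > best_score)
    if (length(better)) {
      top <- better[which.max(scores[better])]
      best_score <- scores[top]
      best_variant <- nxt[top]
    }
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  list(variant = best_variant, score = best_score)
}
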