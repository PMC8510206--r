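#' Define a protease cleavage rule
#'
#' A rule cuts the peptide bond C-terminal to any residue in
#' \code{p1_residues}, unless the residue immediately C-terminal to the bond
#' (the P1' position) is in \code{p1prime_blockers}. This is the simplified
#' PeptideCutter-style specificity grammar; full-context tables are out of
#' scope, but any rule expressible as P1 residues plus P1' blockers can be
#' supplied, either directly or from a YAML config
#' (see \code{\link{load_cleavage_rules}}).
#'
#' @param name rule name.
#' @param p1_residues character vector of residues whose C-terminal bond is
#'   cut.
#' @param p1prime_blockers residues that veto cleavage when immediately
#'   C-terminal to the cut site (default proline).
#' @return An object of class \code{"cleavage_rule"}.
#' @examples
#' cleavage_rule("pepsin_pH1.3", c("F", "L"))
#' @export
cleavage_rule <- function(name, p1_residues, p1prime_blockers = "P") {
  p1_residues <- toupper(as.character(p1_residues))
  p1prime_blockers <- toupper(as.character(p1prime_blockers))
  if (length(p1_residues) == 0L)
    stop("p1_residues must be non-empty")
  if (!all(p1_residues %in% AA20))
    stop("p1_residues must be single standard amino-acid letters")
  if (length(p1prime_blockers) && !all(p1prime_blockers %in% AA20))
    stop("p1prime_blockers must be single standard amino-acid letters")
  structure(list(name = as.character(name)[1L],
                 p1_residues = p1_residues,
                 p1prime_blockers = p1prime_blockers),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat("Cleavage rule:", x$name, "\n")
  cat("  cut after  :", paste(x$p1_residues, collapse = " "), "\n")
  cat("  blocked by :", if (length(x$p1prime_blockers))
    paste(x$p1prime_blockers, collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' Built-in cleavage rules
#'
#' \code{pepsin_rule("pH1.3")} cuts after Phe and Leu; \code{pepsin_rule("pH2")}
#' additionally after Trp and Tyr. Both are vetoed by a P1' proline. These are
#' deliberately transparent simplifications of pepsin's broad specificity;
#' override with \code{\link{cleavage_rule}} or a rules file if needed.
#'
#' @param variant \code{"pH1.3"} (default) or \code{"pH2"}.
#' @return A \code{\link{cleavage_rule}}.
#' @export
pepsin_rule <- function(variant = c("pH1.3", "pH2")) {
  variant <- match.arg(variant)
  if (variant == "pH1.3")
    cleavage_rule("pepsin_pH1.3", c("F", "L"), "P")
  else
    cleavage_rule("pepsin_pH2", c("F", "L", "W", "Y"), "P")
}

#' Load cleavage rules from a YAML config
#'
#' The file maps rule name to \code{p1_residues} and (optionally)
#' \code{p1prime_blockers}, each a string or list of single letters.
#'
#' @param path YAML file path.
#' @return Named list of \code{\link{cleavage_rule}} objects.
#' @export
load_cleavage_rules <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!length(spec)) stop("no rules found in ", path)
  out <- lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    p1 <- unlist(strsplit(unlist(entry$p1_residues), "", fixed = TRUE))
    blk <- entry$p1prime_blockers
    blk <- if (is.null(blk)) character() else
      unlist(strsplit(unlist(blk), "", fixed = TRUE))
    cleavage_rule(nm, p1, blk)
  })
  names(out) <- names(spec)
  out
}

# 0-based cut positions: a cut after residue i (1-based) means position i here
cut_sites <- function(letters, rule) {
  n <- length(letters)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  hit <- letters[i] %in% rule$p1_residues &
    !(letters[i + 1L] %in% rule$p1prime_blockers)
  i[hit]
}

#' Digest a protein with a cleavage rule
#'
#' Cuts the bond after position i whenever the residue at i is a P1 residue of
#' the rule and the residue at i+1 is not a P1' blocker. Fragments are
#' returned N- to C-terminal with 1-based inclusive coordinates in the parent.
#' With \code{missed_cleavages = k}, every concatenation of up to k+1 adjacent
#' fragments is also returned.
#'
#' @param sequence protein sequence (character scalar) or a one-row
#'   data.frame with \code{id} and \code{sequence}.
#' @param rule a \code{\link{cleavage_rule}} (default pepsin at pH 1.3).
#' @param missed_cleavages non-negative integer \eqn{\le} 5.
#' @param id parent identifier recorded in the output (ignored when
#'   \code{sequence} is a data.frame).
#' @return A data.frame with columns \code{peptide}, \code{parent_id},
#'   \code{start}, \code{end}, \code{length}.
#' @examples
#' digest("AAFAAALAA")$peptide  # "AAF" "AAAL" "AA"
#' @export
digest <- function(sequence, rule = pepsin_rule(), missed_cleavages = 0L,
                   id = "protein") {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    id <- sequence$id
    sequence <- sequence$sequence
  }
  if (!inherits(rule, "cleavage_rule")) stop("rule must be a cleavage_rule")
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0L || missed_cleavages > 5L)
    stop("missed_cleavages must be an integer in 0..5")
  seq <- validate_sequence(sequence, id = id)
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]

  cuts <- cut_sites(letters, rule)
  # fragment boundaries as 1-based [start, end]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(letters))
  nfrag <- length(starts)

  out_start <- integer(); out_end <- integer()
  for (span in seq_len(min(missed_cleavages + 1L, nfrag))) {
    i <- seq_len(nfrag - span + 1L)
    out_start <- c(out_start, starts[i])
    out_end <- c(out_end, ends[i + span - 1L])
  }
  ord <- order(out_start, out_end)
  out_start <- out_start[ord]; out_end <- out_end[ord]
  data.frame(
    peptide = substring(seq, out_start, out_end),
    parent_id = rep(id, length(out_start)),
    start = out_start,
    end = out_end,
    length = out_end - out_start + 1L,
    stringsAsFactors = FALSE
  )
}

#' Digest every protein in a proteome
#'
#' @param proteome data.frame with columns \code{id}, \code{sequence} (as
#'   returned by \code{\link{read_fasta}}).
#' @inheritParams digest
#' @return Row-bound digest tables for all proteins, input order preserved.
#' @export
digest_proteome <- function(proteome, rule = pepsin_rule(),
                            missed_cleavages = 0L) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  parts <- lapply(seq_len(nrow(proteome)), function(i)
    digest(proteome$sequence[i], rule, missed_cleavages, id = proteome$id[i]))
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Length-filter and deduplicate digested peptides
#'
#' Retains peptides with \code{min_len <= length <= max_len}, drops peptides
#' containing \code{X} (their physicochemistry is undefined), and
#' deduplicates globally by sequence keeping the first occurrence in input
#' order.
#'
#' @param peptides digest table (\code{\link{digest_proteome}} output).
#' @param min_len,max_len inclusive length bounds (defaults 5 and 50).
#' @param drop_x drop peptides containing unknown residues (default TRUE; the
#'   number dropped is reported via a message when > 0).
#' @return Filtered, deduplicated digest table.
#' @export
filter_and_deduplicate <- function(peptides, min_len = 5L, max_len = 50L,
                                   drop_x = TRUE) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- peptides$length >= min_len & peptides$length <= max_len
  out <- peptides[keep, , drop = FALSE]
  if (drop_x) {
    has_x <- grepl("X", out$peptide, fixed = TRUE)
    if (any(has_x))
      message(sum(has_x), " peptide(s) containing X dropped before scoring")
    out <- out[!has_x, , drop = FALSE]
  }
  out <- out[!duplicated(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptide length distribution over bins
#'
#' Tabulates peptide lengths into inclusive bins (defaults 5-20, 21-35,
#' 36-50 residues) and reports counts and percentage proportions rounded to
#' one decimal.
#'
#' @param peptides digest table or a character vector of peptide sequences.
#' @param breaks matrix-like list of bin bounds; a list of \code{c(lo, hi)}
#'   pairs. Default \code{list(c(5, 20), c(21, 35), c(36, 50))}.
#' @return An object of class \code{"length_bins"}: data.frame with
#'   \code{bin}, \code{count}, \code{proportion} (percent) plus attributes
#'   \code{total} and \code{empty}.
#' @export
length_distribution <- function(peptides,
                                breaks = list(c(5L, 20L), c(21L, 35L),
                                              c(36L, 50L))) {
  lens <- if (is.data.frame(peptides)) peptides$length else nchar(peptides)
  labs <- vapply(breaks, function(b) paste0(b[1L], "-", b[2L]), character(1L))
  counts <- vapply(breaks, function(b) sum(lens >= b[1L] & lens <= b[2L]),
                   integer(1L))
  total <- length(lens)
  if (sum(counts) != total)
    stop("peptide length(s) outside all bins; filter before binning")
  prop <- if (total == 0L) rep(NA_real_, length(counts)) else
    round(100 * counts / total, 1L)
  structure(
    data.frame(bin = labs, count = counts, proportion = prop,
               stringsAsFactors = FALSE),
    total = total, empty = total == 0L, class = c("length_bins", "data.frame"))
}

#' @export
print.length_bins <- function(x, ...) {
  if (attr(x, "empty")) {
    cat("Length distribution: empty peptide set\n")
    return(invisible(x))
  }
  cat("Length distribution of", attr(x, "total"), "peptides:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-7s %6d  (%.1f%%)\n", x$bin[i], x$count[i],
                x$proportion[i]))
  invisible(x)
}

#' Write a digest table to TSV
#'
#' @param peptides digest table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
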