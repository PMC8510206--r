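#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

# canonical 20-letter amino-acid alphabet; X = unknown residue, tolerated on
# load but never a cleavage site and dropped before property/score stages
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_OK <- c(AA20, "X")

#' Validate an amino-acid sequence
#'
#' Checks that a sequence is non-empty and contains only the 20 standard
#' one-letter residue codes (plus \code{X} for an unknown residue, when
#' \code{allow_x = TRUE}).
#'
#' @param sequence character scalar, the amino-acid sequence.
#' @param id identifier used in error messages.
#' @param allow_x logical; tolerate \code{X}?
#' @return The upper-cased sequence, invisibly usable downstream.
#' @examples
#' validate_sequence("vtfvliaak")
#' @export
validate_sequence <- function(sequence, id = "<sequence>", allow_x = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string (record '", id, "')")
  seq <- toupper(sequence)
  if (nchar(seq) == 0L)
    stop("empty sequence in record '", id, "'")
  ok <- if (allow_x) AA_OK else AA20
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(letters %in% ok))
  if (length(bad)) {
    stop("illegal character '", letters[bad[1L]], "' at position ", bad[1L],
         " in record '", id, "'")
  }
  seq
}

#' Read protein records from a FASTA file
#'
#' Loads a (multi-record, wrapped or unwrapped) FASTA file and returns one
#' row per entry with sequences upper-cased and alphabet-checked. Record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @param allow_x logical; tolerate \code{X} residues (default \code{TRUE}).
#' @return A data.frame with columns \code{id} and \code{sequence}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "VTFVLIAAK"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, allow_x = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # readAAStringSet silently drops characters outside the AA alphabet with a
  # warning; promote that to the load error the contract requires, naming the
  # record and the offending position
  aa <- withCallingHandlers(
    tryCatch(Biostrings::readAAStringSet(path),
             error = function(e) stop("malformed FASTA '", path, "': ",
                                      conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        report_bad_fasta_char(path, allow_x)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  seqs <- vapply(seq_along(seqs), function(i)
    validate_sequence(seqs[i], id = ids[i], allow_x = allow_x), character(1L))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

# scan a FASTA file for the first illegal sequence character and raise the
# standard validation error for it
report_bad_fasta_char <- function(path, allow_x) {
  lines <- readLines(path, warn = FALSE)
  id <- "<unknown>"
  pos <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- sub("\\s.*$", "", substring(ln, 2L))
      pos <- 0L
      next
    }
    letters <- strsplit(toupper(ln), "", fixed = TRUE)[[1L]]
    ok <- if (allow_x) AA_OK else AA20
    bad <- which(!(letters %in% ok))
    if (length(bad))
      stop("illegal character '", letters[bad[1L]], "' at position ",
           pos + bad[1L], " in record '", id, "'")
    pos <- pos + length(letters)
  }
  stop("malformed FASTA '", path, "'")
}

#' Write sequences to a FASTA file
#'
#' @param x data.frame with columns \code{id} and \code{sequence}, or a named
#'   character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- x$sequence
    names(seqs) <- x$id
  } else {
    seqs <- x
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
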