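# Independent oracles used to freeze expected values. Each re-derives the
# quantity from first principles, without calling the implementation path it
# checks.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

# scan-based digestion: walk the sequence, close a fragment after every P1
# residue not followed by a blocker
oracle_digest <- function(sequence, p1 = c("F", "L"), blockers = "P") {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  frags <- character()
  cur <- ""
  for (i in seq_along(letters)) {
    cur <- paste0(cur, letters[i])
    nxt <- if (i < length(letters)) letters[i + 1L] else ""
    if (letters[i] %in% p1 && i < length(letters) && !(nxt %in% blockers)) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  c(frags, cur)
}

# all concatenations of <= k+1 adjacent base fragments
oracle_missed <- function(fragments, k) {
  out <- character()
  nf <- length(fragments)
  for (i in seq_len(nf))
    for (j in i:min(nf, i + k))
      out <- c(out, paste(fragments[i:j], collapse = ""))
  out
}

# direct trigonometric moment sum
oracle_moment <- function(sequence, scale, angle = 100) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  delta <- angle * pi / 180
  sx <- sy <- 0
  for (i in seq_along(letters)) {
    h <- scale[[letters[i]]]
    sx <- sx + h * cos(i * delta)
    sy <- sy + h * sin(i * delta)
  }
  sqrt(sx^2 + sy^2) / length(letters)
}

# explicit set algebra over three positive sets
oracle_venn <- function(a_set, b_set, c_set) {
  c(anticp_only = length(setdiff(setdiff(a_set, b_set), c_set)),
    iacp_only = length(setdiff(setdiff(b_set, a_set), c_set)),
    mlacp_only = length(setdiff(setdiff(c_set, a_set), b_set)),
    anticp_iacp = length(setdiff(intersect(a_set, b_set), c_set)),
    anticp_mlacp = length(setdiff(intersect(a_set, c_set), b_set)),
    iacp_mlacp = length(setdiff(intersect(b_set, c_set), a_set)),
    all_three = length(intersect(intersect(a_set, b_set), c_set)))
}

# Table 1 predictor scores, as printed in the source study
table1_scores <- function() {
  data.frame(
    peptide = c("TTMICLTCAR", "TTGICLTCCR", "VTFVLIAAK", "FTFVLLAAK"),
    anticp_svm = c(1.05, 1.58, 1.28, 1.62),
    iacp_prob = c(0.997, 0.997, 0.875, 0.943),
    mlacp_rf = c(0.515, 0.538, 0.558, 0.506),
    mlacp_svm = c(0.766, 0.674, 0.787, 0.541),
    stringsAsFactors = FALSE)
}
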