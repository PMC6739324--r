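# Fixtures are generated in code; oracles below are written independently of
# the implementation paths they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(L, prob = rep(0.25, 4)) {
  paste(sample(BASES, L, replace = TRUE, prob = prob), collapse = "")
}

write_tmp_fasta <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                            width = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    body <- if (is.null(width)) {
      seqs[i]
    } else {
      starts <- seq(1L, nchar(seqs[i]), by = width)
      substring(seqs[i], starts, pmin(starts + width - 1L, nchar(seqs[i])))
    }
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}

random_motif_probs <- function(width) {
  probs <- matrix(stats::rexp(width * 4L), ncol = 4L)
  probs / rowSums(probs)
}

write_tmp_meme <- function(motifs, path = NULL) {
  if (is.null(path)) {
    path <- withr::local_tempfile(fileext = ".meme", .local_envir = parent.frame())
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= %g",
      nrow(m$probs), m$evalue
    ), con)
    writeLines(apply(m$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  path
}

# two-motif set mirroring an E-value-filtered MEME result: one sharp short
# motif and one wide near-uniform motif
fixture_motifs <- function() {
  list(
    default_planted_motif(),
    motif_model("wide41", matrix(0.25, nrow = 41L, ncol = 4L), evalue = 3.3e-18)
  )
}

small_labeled_dataset <- function(n_pos = 20L, n_neg = 20L, L = 41L,
                                  strength = 1, seed = 1L, center_A = TRUE) {
  generate_dataset(synthetic_spec(
    n_pos = n_pos, n_neg = n_neg, window_length = L,
    motif_strength = strength, center_A = center_A, seed = seed
  ))
}

# ---- independent oracles -------------------------------------------------

# Mann-Whitney pairwise AUC: ties count one half
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  total <- 0
  for (a in sp) {
    total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  }
  total / (length(sp) * length(sn))
}

# textbook confusion-matrix MCC
oracle_mcc <- function(n_pos, n_neg, fn, fp) {
  tp <- n_pos - fn
  tn <- n_neg - fp
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / den
}

# all-windows brute-force max log-odds motif score (forward strand)
oracle_motif_score <- function(seq, probs, background = rep(0.25, 4),
                               pseudocount = 1e-6) {
  chars <- strsplit(seq, "")[[1L]]
  W <- nrow(probs)
  best <- -Inf
  for (s in 1:(length(chars) - W + 1L)) {
    total <- 0
    for (j in 1:W) {
      b <- match(chars[s + j - 1L], BASES)
      total <- total + log2((probs[j, b] + pseudocount) / (background[b] + pseudocount))
    }
    best <- max(best, total)
  }
  best
}
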