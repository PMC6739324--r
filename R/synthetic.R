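#' Default planted motif: sharpened ACCGATCSA
#'
#' A 9-column letter-probability matrix over the consensus `ACCGATCSA`
#' (`S` = C or G): consensus letters carry probability 0.97 and the
#' degenerate `S` column splits 0.49/0.49 between C and G, with 0.01 on
#' the remaining letters. The sharpness makes the planted signal strong
#' enough that a well-built pipeline should recover it essentially
#' perfectly at full strength.
#'
#' @return A [motif_model] named `"ACCGATCSA"` with a nominal E-value of
#'   0.029.
#' @export
default_planted_motif <- function() {
  consensus <- c("A", "C", "C", "G", "A", "T", "C", "S", "A")
  probs <- t(vapply(consensus, function(b) {
    if (b == "S") {
      c(A = 0.01, C = 0.49, G = 0.49, T = 0.01)
    } else {
      p <- c(A = 0.01, C = 0.01, G = 0.01, T = 0.01)
      p[b] <- 0.97
      p
    }
  }, numeric(4L)))
  rownames(probs) <- NULL
  motif_model("ACCGATCSA", probs, evalue = 0.029)
}

#' Specification for a synthetic 6mA benchmark
#'
#' Describes a balanced (or unbalanced) set of fixed-length DNA windows:
#' negatives are drawn from the background composition, positives
#' additionally carry a planted motif whose column distributions are mixed
#' with the background, `p_mix = strength * p_motif + (1 - strength) *
#' background`, so `motif_strength` is a continuous difficulty dial from
#' indistinguishable classes (0) to the full motif (1).
#'
#' @param n_pos,n_neg Class sizes.
#' @param window_length Window length in nt (default 41).
#' @param background_composition Background probabilities for A, C, G, T
#'   (sum 1; default uniform).
#' @param planted_motif A [motif_model] or `NULL` for no planted signal.
#'   Default [default_planted_motif()].
#' @param motif_offset 1-based start of the motif within the window;
#'   default centres the motif on the window midpoint.
#' @param motif_strength Mixing weight in `[0, 1]` (default 1, the full
#'   motif).
#' @param center_A Force an A at the window midpoint of every positive
#'   (default `TRUE`, matching windows centred on a candidate adenine).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L, window_length = 41L,
                           background_composition = rep(0.25, 4),
                           planted_motif = default_planted_motif(),
                           motif_offset = NULL,
                           motif_strength = 1,
                           center_A = TRUE,
                           seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop_validation("n_pos and n_neg must be >= 1")
  if (window_length < 1L) stop_validation("window_length must be >= 1")
  if (length(background_composition) != 4L ||
    abs(sum(background_composition) - 1) > 1e-6 ||
    any(background_composition < 0)) {
    stop_validation("background_composition must be a non-negative 4-vector summing to 1")
  }
  if (!is.null(planted_motif)) {
    if (is.null(motif_offset)) {
      center <- (window_length + 1L) %/% 2L
      motif_offset <- center - (planted_motif$width - 1L) %/% 2L
    }
    if (motif_offset < 1L || motif_offset + planted_motif$width - 1L > window_length) {
      stop_validation(
        "motif (width ", planted_motif$width, ") at offset ", motif_offset,
        " does not fit a ", window_length, "-nt window"
      )
    }
  }
  if (motif_strength < 0 || motif_strength > 1) {
    stop_validation("motif_strength must lie in [0, 1]")
  }
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      window_length = as.integer(window_length),
      background_composition = as.numeric(background_composition),
      planted_motif = planted_motif,
      motif_offset = if (is.null(planted_motif)) NA_integer_ else as.integer(motif_offset),
      motif_strength = motif_strength,
      center_A = isTRUE(center_A),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled dataset
#'
#' Positives are drawn from the background composition, then the motif span
#' is overwritten by sampling each motif column from the strength-mixed
#' distribution; when `center_A` is set, the midpoint base of every
#' positive is forced to A afterwards. Negatives are pure background.
#' Output is bitwise-deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec].
#' @return A [load_labeled_dataset()]-compatible `labeled_dataset`.
#' @export
generate_dataset <- function(spec) {
  L <- spec$window_length
  center <- (L + 1L) %/% 2L
  draw_background <- function(n) {
    matrix(
      sample(DNA_BASES, n * L, replace = TRUE, prob = spec$background_composition),
      nrow = n
    )
  }
  withr::with_seed(spec$seed, {
    pos <- draw_background(spec$n_pos)
    if (!is.null(spec$planted_motif) && spec$motif_strength > 0) {
      m <- spec$planted_motif
      for (j in seq_len(m$width)) {
        p_mix <- spec$motif_strength * m$probs[j, ] +
          (1 - spec$motif_strength) * spec$background_composition
        pos[, spec$motif_offset + j - 1L] <-
          sample(DNA_BASES, spec$n_pos, replace = TRUE, prob = p_mix)
      }
    }
    if (spec$center_A) pos[, center] <- "A"
    neg <- draw_background(spec$n_neg)
  })
  records <- data.frame(
    id = c(
      sprintf("pos_%04d", seq_len(spec$n_pos)),
      sprintf("neg_%04d", seq_len(spec$n_neg))
    ),
    seq = c(
      apply(pos, 1L, paste, collapse = ""),
      apply(neg, 1L, paste, collapse = "")
    ),
    label = rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
    stringsAsFactors = FALSE
  )
  as_labeled_dataset(records, L)
}

#' Per-class nucleotide composition of a dataset
#'
#' Empirical mono-nucleotide frequencies per class, used to verify
#' generator calibration; each row sums to 1.
#'
#' @param data A [labeled_dataset].
#' @return A 2 x 4 matrix (rows `positive`, `negative`; columns A, C, G,
#'   T).
#' @export
composition_report <- function(data) {
  if (nrow(data) == 0L) stop_validation("dataset is empty")
  freq_of <- function(seqs) {
    chars <- unlist(strsplit(seqs, "", fixed = TRUE))
    tabulate(factor(chars, levels = DNA_BASES), nbins = 4L) / length(chars)
  }
  out <- rbind(
    positive = freq_of(data$seq[data$label == "positive"]),
    negative = freq_of(data$seq[data$label == "negative"])
  )
  colnames(out) <- DNA_BASES
  out
}

synthetic_spec_to_list <- function(spec) {
  list(
    n_pos = spec$n_pos, n_neg = spec$n_neg,
    window_length = spec$window_length,
    background_composition = spec$background_composition,
    planted_motif = if (is.null(spec$planted_motif)) NULL else {
      list(
        name = spec$planted_motif$name,
        width = spec$planted_motif$width,
        evalue = spec$planted_motif$evalue,
        probs = spec$planted_motif$probs
      )
    },
    motif_offset = spec$motif_offset,
    motif_strength = spec$motif_strength,
    center_A = spec$center_A,
    seed = spec$seed
  )
}

#' Write a synthetic dataset as paired FASTA plus a JSON sidecar
#'
#' Writes `<prefix>_pos.fasta` and `<prefix>_neg.fasta` and a
#' `<prefix>_spec.json` sidecar recording the full generating specification
#' for provenance.
#'
#' @param data A `labeled_dataset` (normally from [generate_dataset()]).
#' @param spec The [synthetic_spec] that produced it.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix, default `"synthetic"`.
#' @return Named character vector of the three paths written.
#' @export
write_synthetic_fasta <- function(data, spec, dir, prefix = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pos_path <- file.path(dir, paste0(prefix, "_pos.fasta"))
  neg_path <- file.path(dir, paste0(prefix, "_neg.fasta"))
  spec_path <- file.path(dir, paste0(prefix, "_spec.json"))
  write_fasta(data[data$label == "positive", , drop = FALSE], pos_path)
  write_fasta(data[data$label == "negative", , drop = FALSE], neg_path)
  jsonlite::write_json(
    synthetic_spec_to_list(spec), spec_path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  c(pos = pos_path, neg = neg_path, spec = spec_path)
}
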