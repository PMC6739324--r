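seq_chars <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop_validation("sequence must be non-empty")
  if (any(!chars %in% DNA_BASES)) {
    stop_validation("sequence contains letters outside A/C/G/T")
  }
  chars
}

kmer_patterns <- function(k) {
  # lexicographic over A < C < G < T, last position varying fastest
  grid <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, grid), method = "radix")
}

#' Encoder configuration
#'
#' Controls which feature blocks [assemble_features()] produces and their
#' parameters. The default subset combination (motif + k-mer + binary) is the
#' optimised feature matrix used by the shipped predictor; on 41-nt windows
#' with two motifs it yields 2 + 336 + 123 = 461 features.
#'
#' @param subsets Ordered character vector drawn from
#'   `c("motif", "kmer", "ksnpf", "nsd", "binary")`.
#' @param kmer_ks Integer k values for the k-mer block (default `2:4`,
#'   giving 16 + 64 + 256 = 336 features).
#' @param ksnpf_ks Integer gap sizes for the k-spaced nucleotide pair block
#'   (default `1:4`, giving 16 x 4 = 64 features).
#' @param motif_background Background nucleotide probabilities (A, C, G, T)
#'   for motif log-odds scoring; must sum to 1. Default uniform.
#' @param motif_pseudocount Small positive pseudocount added to motif and
#'   background probabilities before taking logs. Default `1e-6`.
#' @param scan_reverse_complement Also scan the reverse complement when
#'   scoring motifs? Default `FALSE` (forward strand only).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(subsets = c("motif", "kmer", "binary"),
                           kmer_ks = 2:4,
                           ksnpf_ks = 1:4,
                           motif_background = rep(0.25, 4),
                           motif_pseudocount = 1e-6,
                           scan_reverse_complement = FALSE) {
  known <- c("motif", "kmer", "ksnpf", "nsd", "binary")
  subsets <- as.character(subsets)
  if (length(subsets) == 0L || !all(subsets %in% known) || anyDuplicated(subsets)) {
    stop_validation(
      "subsets must be a non-empty, duplicate-free selection from: ",
      paste(known, collapse = ", ")
    )
  }
  if (any(kmer_ks < 1L) || any(ksnpf_ks < 1L)) {
    stop_validation("every k must be >= 1")
  }
  if (length(motif_background) != 4L || abs(sum(motif_background) - 1) > 1e-6) {
    stop_validation("motif_background must be a 4-vector summing to 1")
  }
  if (motif_pseudocount <= 0) stop_validation("motif_pseudocount must be > 0")
  structure(
    list(
      subsets = subsets,
      kmer_ks = as.integer(kmer_ks),
      ksnpf_ks = as.integer(ksnpf_ks),
      motif_background = as.numeric(motif_background),
      motif_pseudocount = motif_pseudocount,
      scan_reverse_complement = isTRUE(scan_reverse_complement)
    ),
    class = "encoder_config"
  )
}

#' K-mer composition features
#'
#' For each `k`, the relative frequency of every length-`k` word over the
#' `L - k + 1` windows of the sequence, in lexicographic order (A < C < G < T).
#' Each block of `4^k` frequencies sums to 1; the default `k = 2, 3, 4` gives
#' 16 + 64 + 256 = 336 features.
#'
#' @param seq DNA string (A/C/G/T).
#' @param ks Integer vector of word lengths.
#' @return Named numeric vector of length `sum(4^ks)`, names prefixed
#'   `kmer:`.
#' @export
encode_kmer <- function(seq, ks = 2:4) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (length(ks) == 0L) stop_validation("ks must be non-empty")
  if (L < max(ks)) {
    stop_validation("sequence length ", L, " is shorter than k = ", max(ks))
  }
  blocks <- lapply(ks, function(k) {
    pats <- kmer_patterns(k)
    starts <- seq_len(L - k + 1L)
    words <- substring(seq, starts, starts + k - 1L)
    counts <- tabulate(factor(words, levels = pats), nbins = length(pats))
    freqs <- counts / (L - k + 1L)
    stats::setNames(freqs, paste0("kmer:", pats))
  })
  unlist(blocks)
}

#' K-spaced nucleotide pair frequencies (KSNPF)
#'
#' For each gap size `k`, the frequency of every ordered nucleotide pair
#' `(n1, n2)` observed at positions `(i, i + k + 1)` — i.e. with exactly `k`
#' arbitrary bases between them — divided by the `L - k - 1` available pair
#' positions. The 16 frequencies for each `k` sum to 1; the default
#' `k = 1..4` gives 64 features.
#'
#' @param seq DNA string.
#' @param ks Integer vector of gap sizes; each must satisfy
#'   `length(seq) - k - 1 >= 1`.
#' @return Named numeric vector of length `16 * length(ks)`, names like
#'   `ksnpf:A_gap2_G`.
#' @export
encode_ksnpf <- function(seq, ks = 1:4) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (length(ks) == 0L) stop_validation("ks must be non-empty")
  bad <- ks[L - ks - 1L < 1L]
  if (length(bad) > 0L) {
    stop_validation(
      "sequence length ", L, " leaves no gapped pair for k = ",
      paste(bad, collapse = ", ")
    )
  }
  pair_levels <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste, sep = "_")))
  blocks <- lapply(ks, function(k) {
    n_pairs <- L - k - 1L
    i <- seq_len(n_pairs)
    pairs <- paste(chars[i], chars[i + k + 1L], sep = "_")
    counts <- tabulate(factor(pairs, levels = pair_levels), nbins = 16L)
    stats::setNames(
      counts / n_pairs,
      paste0("ksnpf:", sub("_", sprintf("_gap%d_", k), pair_levels))
    )
  })
  unlist(blocks)
}

#' Nucleic shift density at one position
#'
#' The density of nucleotide `q` in the length-`i` prefix of the sequence:
#' `count of q among the first i bases, divided by i`. For the sequence
#' `"CAGCTG"` the density of `C` at positions 1..6 is 1, 0.5, 1/3, 0.5, 0.4,
#' 1/3.
#'
#' @param seq DNA string.
#' @param q Query nucleotide, one of A/C/G/T.
#' @param i 1-based position, `1 <= i <= nchar(seq)`.
#' @return A single density in `[0, 1]`.
#' @export
nsd_at <- function(seq, q, i) {
  chars <- seq_chars(seq)
  if (!is.character(q) || length(q) != 1L || !q %in% DNA_BASES) {
    stop_validation("q must be one of A, C, G, T")
  }
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > length(chars)) {
    stop_validation("position i must lie in 1..", length(chars))
  }
  sum(chars[seq_len(i)] == q) / i
}

#' Nucleic shift density features
#'
#' One feature per position: the prefix density of the nucleotide occupying
#' that position, `nsd_at(seq, seq[i], i)`. A 41-nt window yields 41
#' features; the final entry equals the overall composition fraction of the
#' last base's letter.
#'
#' @param seq DNA string.
#' @return Named numeric vector of length `nchar(seq)`, names `nsd:posNN`.
#' @export
encode_nsd <- function(seq) {
  chars <- seq_chars(seq)
  L <- length(chars)
  prefix_counts <- vapply(DNA_BASES, function(b) cumsum(chars == b), numeric(L))
  if (L == 1L) prefix_counts <- matrix(prefix_counts, nrow = 1L)
  d <- prefix_counts[cbind(seq_len(L), match(chars, DNA_BASES))] / seq_len(L)
  stats::setNames(d, sprintf("nsd:pos%02d", seq_len(L)))
}

BINARY_TRIPLES <- matrix(
  c(
    1, 1, 1, # A: purine, weak, amino
    0, 0, 1, # C
    1, 0, 0, # G
    0, 1, 0  # T
  ),
  nrow = 4L, byrow = TRUE,
  dimnames = list(DNA_BASES, c("x", "y", "z"))
)

#' Three-bit binary code features
#'
#' Encodes each position as the triple `(x, y, z)` where `x` flags purines
#' (A/G), `y` flags weak pairing (A/T) and `z` flags the amino group (A/C):
#' A = (1,1,1), C = (0,0,1), G = (1,0,0), T = (0,1,0). The four triples are
#' pairwise distinct so the encoding is invertible. A 41-nt window yields
#' 3 x 41 = 123 features.
#'
#' @param seq DNA string.
#' @return Named 0/1 vector of length `3 * nchar(seq)`, names
#'   `bin:posNN_x` / `_y` / `_z` in position order.
#' @export
encode_binary <- function(seq) {
  chars <- seq_chars(seq)
  L <- length(chars)
  triples <- BINARY_TRIPLES[match(chars, DNA_BASES), , drop = FALSE]
  out <- as.vector(t(triples))
  names(out) <- paste0(
    "bin:", rep(sprintf("pos%02d", seq_len(L)), each = 3L), "_",
    rep(c("x", "y", "z"), times = L)
  )
  out
}

#' Decode a binary-code feature vector back to the sequence
#'
#' @param bits A vector produced by [encode_binary()].
#' @return The DNA string.
#' @export
decode_binary <- function(bits) {
  if (length(bits) %% 3L != 0L) stop_validation("binary vector length must be a multiple of 3")
  triples <- matrix(bits, ncol = 3L, byrow = TRUE)
  key <- apply(BINARY_TRIPLES, 1L, paste, collapse = "")
  paste(DNA_BASES[match(apply(triples, 1L, paste, collapse = ""), key)], collapse = "")
}

reverse_complement <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[seq_chars(seq)]), collapse = "")
}

#' Best log-odds motif score of a sequence
#'
#' Slides the motif's letter-probability matrix over every window of the
#' sequence (and of the reverse complement when `scan_rc` is `TRUE`) and
#' returns the maximum of the per-window log-odds score
#' `sum over columns of log2((p + pseudocount) / (b + pseudocount))`, where
#' `p` is the motif probability of the window's letter at that column and `b`
#' the background probability of that letter.
#'
#' @param seq DNA string at least as long as the motif.
#' @param motif A [motif_model].
#' @param background Background probabilities for A, C, G, T (sum 1).
#' @param pseudocount Positive pseudocount, default `1e-6`.
#' @param scan_rc Also scan the reverse complement? Default `FALSE`.
#' @return The maximum window score (a single real; log2 scale).
#' @export
score_motif <- function(seq, motif, background = rep(0.25, 4),
                        pseudocount = 1e-6, scan_rc = FALSE) {
  chars <- seq_chars(seq)
  L <- length(chars)
  W <- motif$width
  if (W > L) {
    stop_validation(
      "motif '", motif$name, "' (width ", W, ") is wider than the sequence (", L, " nt)"
    )
  }
  lo <- log2(
    (motif$probs + pseudocount) /
      matrix(background + pseudocount, nrow = W, ncol = 4L, byrow = TRUE)
  )
  best_on <- function(chars) {
    idx <- match(chars, DNA_BASES)
    max(vapply(seq_len(length(chars) - W + 1L), function(s) {
      sum(lo[cbind(seq_len(W), idx[s + seq_len(W) - 1L])])
    }, numeric(1L)))
  }
  best <- best_on(chars)
  if (isTRUE(scan_rc)) {
    best <- max(best, best_on(seq_chars(reverse_complement(seq))))
  }
  best
}

#' Motif score features
#'
#' One feature per motif, each the best-window log-odds score from
#' [score_motif()] under the configuration's background, pseudocount and
#' strand settings.
#'
#' @param seq DNA string.
#' @param motifs Non-empty list of [motif_model] objects.
#' @param config An [encoder_config].
#' @return Named numeric vector, one entry per motif, names `motif:<name>`.
#' @export
encode_motifs <- function(seq, motifs, config = encoder_config()) {
  if (length(motifs) == 0L) {
    stop_validation("motif features requested but no motifs supplied")
  }
  scores <- vapply(motifs, function(m) {
    score_motif(
      seq, m,
      background = config$motif_background,
      pseudocount = config$motif_pseudocount,
      scan_rc = config$scan_reverse_complement
    )
  }, numeric(1L))
  nm <- make.unique(vapply(motifs, `[[`, character(1L), "name"))
  stats::setNames(scores, paste0("motif:", nm))
}

new_feature_matrix <- function(x, ids, feature_names, labels = NULL) {
  dimnames(x) <- list(ids, feature_names)
  structure(
    list(ids = ids, feature_names = feature_names, x = x, labels = labels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features%s\n",
    length(x$ids), length(x$feature_names),
    if (is.null(x$labels)) " (unlabeled)" else {
      sprintf(
        " (%d positive, %d negative)",
        sum(x$labels == "positive"), sum(x$labels == "negative")
      )
    }
  ))
  invisible(x)
}

#' Subset a feature matrix by sample
#'
#' @param fm A `feature_matrix`.
#' @param idx Integer or logical sample index.
#' @return A `feature_matrix` over the selected samples.
#' @export
fm_subset <- function(fm, idx) {
  new_feature_matrix(
    fm$x[idx, , drop = FALSE], fm$ids[idx], fm$feature_names,
    labels = if (is.null(fm$labels)) NULL else fm$labels[idx]
  )
}

#' Assemble a feature matrix from encoder blocks
#'
#' Applies the configured encoders to every window and concatenates the
#' blocks in the order `config$subsets` lists them. Sample order is
#' preserved, feature names carry their block prefix, and labels are carried
#' through. With the default configuration (motif + k-mer + binary) on 41-nt
#' windows and two motifs the matrix has 2 + 336 + 123 = 461 columns.
#'
#' Positive windows are expected to centre on an adenine; by default a
#' warning reports positives whose centre base is not A (`center_policy =
#' "strict"` turns this into an error, `"none"` disables the check).
#'
#' @param data A [labeled_dataset] (or any data.frame with `id` and `seq`;
#'   `label` optional).
#' @param config An [encoder_config].
#' @param motifs List of [motif_model] objects; required when `"motif"` is in
#'   `config$subsets`.
#' @param center_policy One of `"warn"`, `"strict"`, `"none"`.
#' @return A `feature_matrix`.
#' @export
assemble_features <- function(data, config = encoder_config(), motifs = NULL,
                              center_policy = c("warn", "strict", "none")) {
  center_policy <- match.arg(center_policy)
  if ("motif" %in% config$subsets && length(motifs) == 0L) {
    stop_validation("config requests the motif subset but no motifs were provided")
  }
  if (nrow(data) == 0L) stop_validation("dataset is empty")
  lens <- nchar(data$seq)
  if (length(unique(lens)) != 1L) {
    stop_validation("all sequences must share one window length")
  }
  L <- lens[1L]
  has_labels <- "label" %in% names(data)
  if (center_policy != "none" && has_labels) {
    center <- substr(data$seq, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
    off <- data$label == "positive" & center != "A"
    if (any(off)) {
      msg <- sprintf(
        "%d positive window(s) do not have A at the centre position %d",
        sum(off), (L + 1L) %/% 2L
      )
      if (center_policy == "strict") stop_validation(msg) else warning(msg)
    }
  }
  encode_one <- function(seq) {
    blocks <- lapply(config$subsets, function(s) {
      switch(s,
        motif = encode_motifs(seq, motifs, config),
        kmer = encode_kmer(seq, config$kmer_ks),
        ksnpf = encode_ksnpf(seq, config$ksnpf_ks),
        nsd = encode_nsd(seq),
        binary = encode_binary(seq)
      )
    })
    unlist(blocks)
  }
  first <- encode_one(data$seq[1L])
  x <- matrix(0, nrow = nrow(data), ncol = length(first))
  x[1L, ] <- first
  if (nrow(data) > 1L) {
    for (r in 2L:nrow(data)) x[r, ] <- encode_one(data$seq[r])
  }
  new_feature_matrix(
    x, data$id, names(first),
    labels = if (has_labels) factor(as.character(data$label), levels = c("negative", "positive")) else NULL
  )
}

#' Write a feature matrix to CSV
#'
#' Layout: first column `sample_id`, then (if labels are present) a `label`
#' column, then one column per feature with the block-prefixed feature names
#' as header. [read_feature_csv()] round-trips the file.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$x, check.names = FALSE)
  if (!is.null(fm$labels)) df <- cbind(label = as.character(fm$labels), df)
  df <- cbind(sample_id = fm$ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id") {
    stop_validation("feature CSV must start with a sample_id column")
  }
  ids <- as.character(df$sample_id)
  labels <- NULL
  feat_start <- 2L
  if (ncol(df) >= 2L && names(df)[2L] == "label") {
    labels <- factor(df$label, levels = c("negative", "positive"))
    feat_start <- 3L
  }
  x <- as.matrix(df[, feat_start:ncol(df), drop = FALSE])
  new_feature_matrix(x, ids, colnames(x), labels = labels)
}
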