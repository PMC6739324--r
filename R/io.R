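normalize_sequences <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Read a FASTA file of DNA windows
#'
#' Sequences are normalized to uppercase and RNA `U` is mapped to `T` at read
#' time. Letters outside `A/C/G/T` after normalization are never silently
#' altered: under `policy = "strict"` (default) they raise an error naming the
#' offending records, under `policy = "drop"` the affected records are omitted
#' with a warning giving the count.
#'
#' @param path Path to a FASTA file (multi-record; wrapped or single-line).
#' @param policy Either `"strict"` or `"drop"`; handling of non-ACGT letters.
#' @return A data.frame with columns `id` and `seq`, one row per record, in
#'   file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "cagctg", ">s2", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop_validation("FASTA file not found: ", path)
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines_keep <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines_keep) == 0L) {
    stop_validation("empty FASTA file: ", path)
  }
  first_idx <- which(nzchar(trimws(head_lines)))[1L]
  if (!startsWith(trimws(head_lines[first_idx]), ">")) {
    stop_validation(
      "malformed FASTA header at line ", first_idx, " of ", path,
      ": expected a line starting with '>'"
    )
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_validation("empty FASTA file: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_sequences(as.character(set))
  if (any(!nzchar(seqs))) {
    stop_validation(
      "zero-length sequence for record(s): ",
      paste(utils::head(ids[!nzchar(seqs)], 5L), collapse = ", ")
    )
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (policy == "strict") {
      stop_validation(
        "non-ACGT letters in record(s): ",
        paste(utils::head(ids[bad], 5L), collapse = ", "),
        if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else ""
      )
    }
    warning(sprintf("dropped %d record(s) containing non-ACGT letters", sum(bad)))
    ids <- ids[!bad]
    seqs <- seqs[!bad]
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write DNA records to a FASTA file
#'
#' @param records A data.frame with columns `id` and `seq` (a
#'   [labeled_dataset] works too; labels are not written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::DNAStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a motif model (letter-probability matrix)
#'
#' A motif is a `width x 4` matrix of per-column nucleotide probabilities
#' (columns A, C, G, T) together with the discovery E-value, as exchanged in
#' MEME minimal motif format.
#'
#' @param name Motif identifier.
#' @param probs Numeric `width x 4` matrix; each row must sum to 1 within
#'   `1e-3` (MEME prints rounded values).
#' @param evalue Non-negative E-value.
#' @param nsites Optional number of contributing sites.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, probs, evalue, nsites = NA_integer_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L) {
    stop_validation("motif '", name, "': probs must be a width x 4 matrix with width >= 1")
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop_validation("motif '", name, "': probabilities must lie in [0, 1]")
  }
  row_dev <- abs(rowSums(probs) - 1)
  if (any(row_dev > 1e-3)) {
    stop_validation(
      "motif '", name, "': row ", which.max(row_dev),
      " sums to ", format(rowSums(probs)[which.max(row_dev)]),
      " (deviation from 1 exceeds 1e-3)"
    )
  }
  if (!is.numeric(evalue) || length(evalue) != 1L || is.na(evalue) || evalue < 0) {
    stop_validation("motif '", name, "': E-value must be a single non-negative number")
  }
  colnames(probs) <- DNA_BASES
  structure(
    list(
      name = name, width = nrow(probs), probs = probs,
      evalue = evalue, nsites = nsites
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf(
    "<motif_model> %s  width=%d  E-value=%g\n", x$name, x$width, x$evalue
  ))
  invisible(x)
}

#' Read motifs from a MEME minimal motif format file
#'
#' Parses the plain-text minimal motif format written by the MEME suite:
#' `MOTIF <name>` blocks followed by a
#' `letter-probability matrix: alength= 4 w= <w> nsites= <n> E= <e>` header and
#' `w` rows of four probabilities (columns A, C, G, T).
#'
#' @param path Path to a MEME minimal-format motif file.
#' @return A list of [motif_model] objects in file order (possibly empty).
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) {
    stop_validation("motif file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  for (m in seq_along(motif_at)) {
    start <- motif_at[m]
    end <- if (m < length(motif_at)) motif_at[m + 1L] - 1L else length(lines)
    block <- lines[start:end]
    name_tokens <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    name <- if (length(name_tokens) >= 2L) name_tokens[2L] else sprintf("motif_%d", m)
    hdr_idx <- grep("letter-probability matrix", block)
    if (length(hdr_idx) == 0L) {
      stop_validation("motif '", name, "': missing letter-probability matrix header")
    }
    hdr <- block[hdr_idx[1L]]
    grab <- function(key) {
      hit <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.eE+-]+)"), hdr))[[1L]]
      if (length(hit) < 2L) NA_real_ else as.numeric(hit[2L])
    }
    w <- grab("w")
    evalue <- grab("E")
    nsites <- grab("nsites")
    if (is.na(w) || w < 1) {
      stop_validation("motif '", name, "': header lacks a valid w= width")
    }
    if (is.na(evalue)) {
      stop_validation("motif '", name, "': header lacks a valid E= value")
    }
    body <- block[-seq_len(hdr_idx[1L])]
    body <- trimws(body)
    body <- body[nzchar(body)]
    is_row <- vapply(body, function(l) {
      toks <- strsplit(l, "\\s+")[[1L]]
      length(toks) == 4L && !anyNA(suppressWarnings(as.numeric(toks)))
    }, logical(1L), USE.NAMES = FALSE)
    n_rows <- if (any(!is_row)) which(!is_row)[1L] - 1L else length(body)
    if (n_rows != w) {
      stop_validation(
        "motif '", name, "': letter-probability matrix has ", n_rows,
        " rows but header declares w= ", w
      )
    }
    probs <- do.call(rbind, lapply(body[seq_len(w)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1L]])
    }))
    motifs[[m]] <- motif_model(name, probs, evalue,
      nsites = if (is.na(nsites)) NA_integer_ else as.integer(nsites)
    )
  }
  motifs
}

#' Write motifs to a MEME minimal motif format file
#'
#' @param motifs List of [motif_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  ), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    nsites <- if (is.na(m$nsites)) 20L else m$nsites
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
      m$width, nsites, m$evalue
    ), con)
    writeLines(apply(m$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Keep motifs below an E-value threshold
#'
#' Mirrors the selection step applied to MEME output: only motifs whose
#' E-value is strictly below the threshold are retained, in their original
#' order. The operation is idempotent.
#'
#' @param motifs List of [motif_model] objects.
#' @param threshold Positive E-value cutoff (default 0.05).
#' @return The filtered list.
#' @export
filter_motifs_by_evalue <- function(motifs, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_validation("E-value threshold must be > 0")
  }
  motifs[vapply(motifs, function(m) m$evalue < threshold, logical(1L))]
}

as_labeled_dataset <- function(df, window_length) {
  df$label <- factor(as.character(df$label), levels = c("negative", "positive"))
  if (anyNA(df$label)) {
    stop_validation("labels must be 'positive' or 'negative'")
  }
  structure(
    data.frame(
      id = df$id, seq = df$seq, label = df$label,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    window_length = as.integer(window_length),
    class = c("labeled_dataset", "data.frame")
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d records (%d positive, %d negative), window %d nt\n",
    nrow(x), sum(x$label == "positive"), sum(x$label == "negative"),
    attr(x, "window_length")
  ))
  invisible(x)
}

#' Window length of a labeled dataset
#'
#' @param data A [labeled_dataset].
#' @return Integer window length shared by all records.
#' @export
window_length <- function(data) {
  attr(data, "window_length")
}

#' Load a labeled dataset from a pair of FASTA files
#'
#' Positive windows (modified adenine at the centre) and negative windows come
#' from separate FASTA files; every record must have exactly `window_length`
#' bases or the call fails listing the offenders.
#'
#' @param pos_path FASTA of positive (6mA) windows.
#' @param neg_path FASTA of negative windows.
#' @param window_length Required window length in nt (default 41).
#' @param policy Non-ACGT policy passed to [read_fasta()].
#' @return A `labeled_dataset`: a data.frame with columns `id`, `seq`,
#'   `label` and a `window_length` attribute.
#' @export
load_labeled_dataset <- function(pos_path, neg_path, window_length = 41L,
                                 policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  pos <- read_fasta(pos_path, policy)
  neg <- read_fasta(neg_path, policy)
  if (nrow(pos) == 0L) stop_validation("empty class: no positive records in ", pos_path)
  if (nrow(neg) == 0L) stop_validation("empty class: no negative records in ", neg_path)
  pos$label <- "positive"
  neg$label <- "negative"
  all_rec <- rbind(pos, neg)
  off <- nchar(all_rec$seq) != window_length
  if (any(off)) {
    stop_validation(
      "record(s) not of window length ", window_length, ": ",
      paste(sprintf(
        "%s (%d nt)",
        utils::head(all_rec$id[off], 5L), utils::head(nchar(all_rec$seq)[off], 5L)
      ), collapse = ", "),
      if (sum(off) > 5L) sprintf(" (and %d more)", sum(off) - 5L) else ""
    )
  }
  as_labeled_dataset(all_rec, window_length)
}

#' Stratified train/test split
#'
#' Per class, `round(class size * test_fraction)` records are drawn into the
#' test set; the draw is deterministic for a fixed seed and train and test
#' partition the input exactly.
#'
#' @param data A [labeled_dataset].
#' @param test_fraction Fraction held out, strictly inside (0, 1). Default 0.2
#'   (an 80/20 split).
#' @param seed Integer RNG seed.
#' @return A list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_validation("test_fraction must lie strictly inside (0, 1)")
  }
  if (!all(c("positive", "negative") %in% data$label)) {
    stop_validation("both classes must be non-empty before splitting")
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(c("positive", "negative"), function(cls) {
      idx <- which(data$label == cls)
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  wl <- window_length(data)
  list(
    train = as_labeled_dataset(data[-test_idx, , drop = FALSE], wl),
    test = as_labeled_dataset(data[test_idx, , drop = FALSE], wl)
  )
}

#' Remove duplicate windows from a labeled dataset
#'
#' Exact duplicate sequences within a class are collapsed to their first
#' occurrence. A sequence appearing in both classes is a label conflict: all
#' its copies are removed from both classes and a message reports the count.
#' (Similarity-based redundancy reduction such as CD-HIT-EST is a separate,
#' external preprocessing step and is not performed here.)
#'
#' @param data A [labeled_dataset].
#' @return The deduplicated `labeled_dataset`.
#' @export
deduplicate <- function(data) {
  pos_seqs <- data$seq[data$label == "positive"]
  neg_seqs <- data$seq[data$label == "negative"]
  conflicts <- intersect(pos_seqs, neg_seqs)
  if (length(conflicts) > 0L) {
    message(sprintf(
      "deduplicate: %d sequence(s) appear in both classes; all copies removed as label conflicts",
      length(conflicts)
    ))
  }
  keep <- !(data$seq %in% conflicts) & !duplicated(paste(data$label, data$seq))
  as_labeled_dataset(data[keep, , drop = FALSE], window_length(data))
}
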