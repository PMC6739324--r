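test_that("k-mer blocks have the documented dimensions and worked-out values", {
  s41 <- withr::with_seed(1, random_dna(41))
  v <- encode_kmer(s41, 2:4)
  expect_length(v, 336L)
  expect_equal(unname(encode_kmer("AAAA", 2L)["kmer:AA"]), 1)
  expect_equal(sum(encode_kmer("AAAA", 2L) != 0), 1L)
  # ACGT has dinucleotide windows AC, CG, GT
  v2 <- encode_kmer("ACGT", 2L)
  expect_equal(unname(v2[c("kmer:AC", "kmer:CG", "kmer:GT")]), rep(1 / 3, 3))
  expect_equal(sum(v2), 1)
  expect_error(encode_kmer("ACG", 4L), "shorter")
})

test_that("each k-mer block is a distribution over lexicographically ordered words", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      s <- random_dna(sample(10:60, 1))
      for (k in 2:4) {
        block <- encode_kmer(s, k)
        expect_equal(sum(block), 1, tolerance = 1e-12)
        expect_identical(names(block), sort(names(block), method = "radix"))
      }
    }
  })
})

test_that("KSNPF counts gapped pairs at (i, i+k+1) over L-k-1 positions", {
  s41 <- withr::with_seed(2, random_dna(41))
  expect_length(encode_ksnpf(s41, 1:4), 64L)
  # ACGT, k=1: pairs (A.G) and (C.T), denominator L-k-1 = 2
  v <- encode_ksnpf("ACGT", 1L)
  expect_equal(unname(v["ksnpf:A_gap1_G"]), 0.5)
  expect_equal(unname(v["ksnpf:C_gap1_T"]), 0.5)
  expect_equal(sum(v != 0), 2L)
  expect_error(encode_ksnpf("ACGT", 3L), "k = 3")
})

test_that("each KSNPF block is a distribution for arbitrary sequences", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      s <- random_dna(sample(10:60, 1))
      for (k in 1:4) {
        expect_equal(sum(encode_ksnpf(s, k)), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("nucleic shift density matches the worked example and prefix definition", {
  expect_equal(nsd_at("CAGCTG", "C", 1), 1)
  expect_equal(nsd_at("CAGCTG", "C", 4), 0.5)
  expect_equal(nsd_at("CAGCTG", "C", 5), 0.4)
  expect_error(nsd_at("CAGCTG", "N", 2), "A, C, G, T")
  expect_error(nsd_at("CAGCTG", "C", 7), "1..6")

  expect_equal(unname(encode_nsd("AAAA")), rep(1, 4))
  expect_equal(unname(encode_nsd("CAGCTG")), c(1, 1 / 2, 1 / 3, 2 / 4, 1 / 5, 2 / 6))
  s41 <- withr::with_seed(3, random_dna(41))
  expect_length(encode_nsd(s41), 41L)
})

test_that("the final shift-density entry equals the last letter's overall composition", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      s <- random_dna(sample(5:50, 1))
      chars <- strsplit(s, "")[[1]]
      last <- chars[length(chars)]
      expect_equal(
        unname(encode_nsd(s)[length(chars)]),
        mean(chars == last)
      )
    }
  })
})

test_that("binary code uses the four fixed triples and is invertible", {
  expect_equal(
    unname(encode_binary("ACGT")),
    c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1, 0)
  )
  s41 <- withr::with_seed(4, random_dna(41))
  bits <- encode_binary(s41)
  expect_length(bits, 123L)
  expect_true(all(bits %in% c(0, 1)))
  withr::with_seed(45, {
    for (rep in 1:10) {
      s <- random_dna(sample(2:50, 1))
      expect_identical(decode_binary(encode_binary(s)), s)
    }
  })
})

test_that("motif scoring has the closed-form limits", {
  flat <- motif_model("flat", matrix(0.25, 5L, 4L), evalue = 1)
  withr::with_seed(46, {
    for (rep in 1:5) {
      expect_equal(score_motif(random_dna(30), flat), 0, tolerance = 1e-9)
    }
  })
  sharp <- motif_model("onlyA", matrix(c(1, 0, 0, 0), 1L, 4L), evalue = 1)
  expect_equal(
    score_motif("CCACC", sharp, pseudocount = 1e-12), 2,
    tolerance = 1e-6
  )
  wide <- motif_model("wide", matrix(0.25, 10L, 4L), evalue = 1)
  expect_error(score_motif("ACGT", wide), "wider")
})

test_that("motif scores equal the brute-force all-windows oracle", {
  withr::with_seed(47, {
    for (rep in 1:40) {
      L <- sample(15:50, 1)
      W <- sample(3:10, 1)
      s <- random_dna(L)
      probs <- random_motif_probs(W)
      m <- motif_model("rnd", probs, evalue = 1)
      expect_equal(
        score_motif(s, m),
        oracle_motif_score(s, probs),
        tolerance = 1e-12
      )
    }
  })
})

test_that("reverse-complement scanning never lowers the score and finds minus-strand hits", {
  # motif matching only GGGGG; plus strand holds CCCCC
  probs <- matrix(rep(c(0.001, 0.001, 0.997, 0.001), each = 5), 5L, 4L)
  m <- motif_model("g5", probs, evalue = 1)
  seq <- "ATATCCCCCATAT"
  fwd <- score_motif(seq, m, scan_rc = FALSE)
  both <- score_motif(seq, m, scan_rc = TRUE)
  expect_gt(both, fwd)
  withr::with_seed(48, {
    for (rep in 1:10) {
      s <- random_dna(30)
      rm <- motif_model("rnd", random_motif_probs(4L), evalue = 1)
      expect_gte(score_motif(s, rm, scan_rc = TRUE), score_motif(s, rm))
    }
  })
})

test_that("encode_motifs yields one named score per motif and demands motifs", {
  s <- withr::with_seed(5, random_dna(41))
  motifs <- fixture_motifs()
  v <- encode_motifs(s, motifs)
  expect_length(v, 2L)
  expect_equal(names(v)[1], "motif:ACCGATCSA")
  expect_error(encode_motifs(s, list()), "no motifs")
  dup <- encode_motifs(s, list(motifs[[1]], motifs[[1]]))
  expect_equal(unname(dup[1]), unname(dup[2]))
})

test_that("assemble_features concatenates blocks in config order with stable names", {
  data <- small_labeled_dataset(6L, 6L, seed = 7L)
  fm <- assemble_features(data, encoder_config(subsets = c("kmer", "binary")))
  expect_equal(length(fm$feature_names), 336L + 123L)
  expect_identical(fm$ids, data$id)
  expect_equal(as.character(fm$labels), as.character(data$label))
  expect_true(all(startsWith(fm$feature_names[1:336], "kmer:")))
  expect_true(all(startsWith(fm$feature_names[337:459], "bin:")))
  expect_false(anyDuplicated(fm$feature_names) > 0)

  fm_nsd <- assemble_features(data, encoder_config(subsets = "nsd"))
  expect_equal(length(fm_nsd$feature_names), 41L)

  fm_full <- assemble_features(data, encoder_config(), motifs = fixture_motifs())
  expect_equal(length(fm_full$feature_names), 2L + 336L + 123L)

  # determinism: two assemblies are bitwise identical
  fm2 <- assemble_features(data, encoder_config(subsets = c("kmer", "binary")))
  expect_identical(fm2$x, fm$x)

  expect_error(assemble_features(data, encoder_config()), "no motifs")
})

test_that("positives without a central adenine trigger the configured policy", {
  data <- small_labeled_dataset(4L, 4L, seed = 8L)
  data$seq[1] <- paste0(substr(data$seq[1], 1, 20), "C", substr(data$seq[1], 22, 41))
  cfg <- encoder_config(subsets = "binary")
  expect_warning(assemble_features(data, cfg), "centre")
  expect_error(assemble_features(data, cfg, center_policy = "strict"), "centre")
  expect_silent(assemble_features(data, cfg, center_policy = "none"))
})

test_that("feature matrices round-trip through CSV", {
  data <- small_labeled_dataset(5L, 5L, seed = 9L)
  fm <- assemble_features(data, encoder_config(subsets = c("nsd", "binary")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_identical(back$feature_names, fm$feature_names)
  expect_identical(back$ids, fm$ids)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(fm$labels))
})
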