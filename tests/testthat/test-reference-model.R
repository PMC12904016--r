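test_that("a minimal ORF split across three exons builds and translates", {
  toy <- make_tiny_tx("+")
  expect_equal(toy$t$protein, "MK")
  expect_equal(toy$t$cds, "ATGAAATAA")
  expect_equal(toy$t$protein_length * 3L + 3L, nchar(toy$t$cds))
})

test_that("minus-strand construction is strand-symmetric", {
  plus <- make_tiny_tx("+")
  minus <- make_tiny_tx("-")
  expect_equal(minus$t$mrna, plus$t$mrna)
  expect_equal(minus$t$cds, plus$t$cds)
  expect_equal(minus$t$protein, plus$t$protein)
})

test_that("random transcripts equal the independent splice-and-translate oracle", {
  tx <- sim_transcriptome(sim_config(seed = 11, n_transcripts = 8))
  for (t in tx$transcripts) {
    expect_equal(t$protein, oracle_spliced_protein(tx$genome, t),
                 info = t$transcript_id)
    expect_equal(t$protein_length * 3L + 3L, nchar(t$cds))
    expect_identical(substr(t$protein, 1L, 1L), "M")
  }
})

test_that("translate_cds agrees with a codon-table oracle", {
  expect_equal(translate_cds("ATGTAA"), list(protein = "M", stop_found = TRUE))
  expect_equal(translate_cds("ATGAAA"), list(protein = "MK", stop_found = FALSE))
  set.seed(42)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * sample(2:60, 1),
                      replace = TRUE), collapse = "")
    expect_equal(translate_cds(s)$protein, oracle_translate(s)$protein, info = s)
  }
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
  expect_error(translate_cds("AT"), "length")
})

test_that("build_transcript rejects invalid CDS structures", {
  toy <- make_tiny_tx("+")
  bad <- toy$t
  bad$cds_end <- bad$cds_end - 1L              # CDS no longer divisible by 3
  expect_error(build_transcript(toy$genome, bad), "divisible by 3")

  g2 <- genome_ref(c(toy = paste0("CC", "ATGTAAAAATAA", "CC")))
  m2 <- transcript_model("T2", "G2", "toy", "+",
                         data.frame(start = 3, end = 14), 3, 14)
  expect_error(build_transcript(g2, m2), "internal stop")

  g3 <- genome_ref(c(toy = paste0("CC", "TTGAAATAA", "CC")))
  m3 <- transcript_model("T3", "G3", "toy", "+",
                         data.frame(start = 3, end = 11), 3, 11)
  expect_error(build_transcript(g3, m3), "start codon")

  g4 <- genome_ref(c(toy = paste0("CC", "ATGANATAA", "CC")))
  m4 <- transcript_model("T4", "G4", "toy", "+",
                         data.frame(start = 3, end = 11), 3, 11)
  expect_error(build_transcript(g4, m4), "ambiguous")
})

test_that("genomic/cDNA mapping round-trips and anchors intronic offsets per HGVS", {
  toy <- make_tiny_tx("+")
  t <- toy$t
  ## exonic CDS positions
  for (b in 1:9) {
    g <- map_c_to_g(t, b)
    cp <- map_g_to_c(t, g)
    expect_equal(cp$base, b)
    expect_equal(cp$offset, 0L)
  }
  ## first intron: 10 nt, first half anchors +k to the donor (last CDS base
  ## of exon 1 is c.4), second half -k to the acceptor (c.5)
  don_g <- map_c_to_g(t, 4L)
  cp <- map_g_to_c(t, don_g + 1L)
  expect_equal(c(cp$base, cp$offset), c(4L, 1L))
  cp <- map_g_to_c(t, don_g + 5L)
  expect_equal(c(cp$base, cp$offset), c(4L, 5L))
  cp <- map_g_to_c(t, don_g + 6L)
  expect_equal(c(cp$base, cp$offset), c(5L, -5L))
  ## UTR flagging
  expect_equal(map_g_to_c(t, t$exons$start[1])$region, "utr5")
  expect_equal(map_g_to_c(t, t$exons$end[3])$region, "utr3")
  expect_error(map_g_to_c(t, t$exons$start[1] - 2L), "outside")
})

test_that("mapping round-trip holds on fuzzed positions of random transcripts", {
  tx <- sim_transcriptome(sim_config(seed = 5, n_transcripts = 5))
  set.seed(99)
  for (t in tx$transcripts) {
    span <- min(t$exons$start):max(t$exons$end)
    for (g in sample(span, min(200, length(span)))) {
      cp <- map_g_to_c(t, g)
      expect_equal(map_c_to_g(t, cp), g,
                   info = sprintf("%s g=%d", t$transcript_id, g))
    }
  }
})

test_that("HGVS-c strings format and parse consistently", {
  expect_equal(format_hgvs_c(cdna_position(2859, 4), "A", "G"), "c.2859+4A>G")
  expect_equal(format_hgvs_c(cdna_position(634, -8)), "c.634-8")
  p <- parse_hgvs_c("c.2859+4A>G")
  expect_equal(p[c("base", "offset", "ref", "alt")],
               list(base = 2859L, offset = 4L, ref = "A", alt = "G"))
  ## unicode hyphen variants normalize
  p2 <- parse_hgvs_c("c.634‐8T>A")
  expect_equal(p2$offset, -8L)
  expect_error(parse_hgvs_c("p.V430del"), "cannot parse")
})
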