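test_that("variant classification follows codon effect and junction distance", {
  toy <- make_tiny_tx("+")
  g <- toy$genome; t <- toy$t
  don_g <- map_c_to_g(t, 4L)
  ## intronic +4 vs canonical +2
  expect_equal(classify_variant(g, t, don_g + 4L, substr(g$toy, don_g + 4L,
                                don_g + 4L), "C"), "intronic")
  expect_equal(classify_variant(g, t, don_g + 2L, "T", "C"),
               "canonical_splicing")
  ## synonymous AAA -> AAG (both K) at c.6
  p6 <- map_c_to_g(t, 6L)
  expect_equal(classify_variant(g, t, p6, "A", "G"), "synonymous")
  ## missense AAA -> GAA at c.4
  p4 <- map_c_to_g(t, 4L)
  expect_equal(classify_variant(g, t, p4, "A", "G"), "missense")
  ## stop gain AAA -> TAA at c.4
  expect_equal(classify_variant(g, t, p4, "A", "T"), "stop_gain")
  ## start loss at c.1
  p1 <- map_c_to_g(t, 1L)
  expect_equal(classify_variant(g, t, p1, "A", "C"), "start_loss")
  ## stop loss at c.7 (TAA -> CAA)
  p7 <- map_c_to_g(t, 7L)
  expect_equal(classify_variant(g, t, p7, "T", "C"), "stop_loss")
  ## UTR
  expect_equal(classify_variant(g, t, t$exons$start[1], "C", "G"), "utr")
  ## indels by length mod 3
  expect_equal(classify_variant(g, t, p4, "AA", "A"), "frameshift")
  expect_equal(classify_variant(g, t, p4, "AAAT", "A"), "nonframeshift")
  ## reference mismatch is an error
  expect_error(classify_variant(g, t, p4, "C", "G"), "mismatch")
})

test_that("SNV classification matches a re-translation oracle on random transcripts", {
  tx <- sim_transcriptome(sim_config(seed = 21, n_transcripts = 3))
  set.seed(7)
  checked <- 0L
  for (t in tx$transcripts) {
    seqc <- tx$genome[[t$contig]]
    cds_len <- nchar(t$cds)
    for (i in 1:120) {
      b <- sample(cds_len, 1)
      gpos <- map_c_to_g(t, b)
      ref <- substr(seqc, gpos, gpos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_variant(tx$genome, t, gpos, ref, alt)
      ## oracle: mutate the CDS directly and compare full translations
      cds_alt <- t$cds
      a_t <- if (t$strand == "-") oracle_revcomp(alt) else alt
      substr(cds_alt, b, b) <- a_t
      tr_ref <- oracle_translate(t$cds)
      tr_alt <- oracle_translate(cds_alt)
      expected <- if (tr_alt$protein == tr_ref$protein &&
                      tr_alt$stop_found) "synonymous"
        else if (b <= 3L && substr(tr_alt$protein, 1, 1) != "M") "start_loss"
        else if (nchar(tr_alt$protein) < nchar(tr_ref$protein)) "stop_gain"
        else if (!tr_alt$stop_found ||
                 nchar(tr_alt$protein) > nchar(tr_ref$protein)) "stop_loss"
        else "missense"
      expect_equal(got, expected,
                   info = sprintf("%s c.%d %s>%s", t$transcript_id, b, ref, alt))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 300L)
})

test_that("junction context reports signed distance to the nearest junction", {
  ## transcript with a long internal exon to probe both sides
  tx <- sim_transcriptome(sim_config(seed = 31, n_transcripts = 2))
  t <- tx$transcripts[[1]]
  don_g <- if (t$strand == "+") t$exons$end[1] else t$exons$start[1]
  dirn <- if (t$strand == "+") 1L else -1L
  jc <- junction_context(t, don_g + dirn * 4L)
  expect_equal(jc[c("side", "distance", "region")],
               list(side = "donor", distance = 4L, region = "intronic"))
  expect_true(jc$in_consensus)
  acc_g <- if (t$strand == "+") t$exons$start[2] else t$exons$end[2]
  jc <- junction_context(t, acc_g - dirn * 13L)
  expect_equal(jc[c("side", "distance")], list(side = "acceptor", distance = -13L))
  expect_false(jc$in_consensus)
  ## exonic base immediately before the donor
  jc <- junction_context(t, don_g)
  expect_equal(jc[c("side", "distance", "region")],
               list(side = "donor", distance = -1L, region = "exonic"))
  expect_true(jc$in_consensus)
  ## single-exon transcript has no junctions
  g1 <- genome_ref(c(z = "CCATGAAATAACC"))
  t1 <- build_transcript(g1, transcript_model("S1", "S", "z", "+",
                          data.frame(start = 1, end = 13), 3, 11))
  expect_null(junction_context(t1, 5))
})

test_that("consensus windows are donor -3..+8 and acceptor -12..+2", {
  expect_true(in_consensus_window("donor", -3))
  expect_true(in_consensus_window("donor", 8))
  expect_false(in_consensus_window("donor", 9))
  expect_false(in_consensus_window("donor", -4))
  expect_true(in_consensus_window("acceptor", -12))
  expect_true(in_consensus_window("acceptor", 2))
  expect_false(in_consensus_window("acceptor", -13))
  expect_false(in_consensus_window("acceptor", 3))
})

test_that("dual-threshold prioritization is an inclusive OR of the two arms", {
  res <- prioritize(spliceai = c(0.9482, 0.6563, NA, 0.49, NA),
                    spcards = c(14, 2, 15, 8, NA))
  expect_equal(res$prioritized, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$arm_spcards, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$arm_spliceai, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  ## thresholds are inclusive
  expect_true(prioritize(0.5, 0)$prioritized)
  expect_true(prioritize(0, 9)$prioritized)
  expect_error(prioritize(1.2, 3), "spliceai")
  expect_error(prioritize(0.2, 19), "spcards")
})

test_that("prioritization is monotone in both scores", {
  set.seed(3)
  for (i in 1:200) {
    ai <- runif(1); sp <- sample(0:18, 1)
    base_call <- prioritize(ai, sp)$prioritized
    sp_up <- (sp:18)[sample.int(19 - sp, 1)]
    up <- prioritize(min(1, ai + runif(1) * (1 - ai)), sp_up)$prioritized
    if (base_call) expect_true(up)
  }
})

test_that("validation selection removes LoF classes and keeps NCSV classes", {
  catalog <- data.frame(
    consequence_class = rep(c("canonical_splicing", "stop_gain", "intronic",
                              "missense", "synonymous"),
                            times = c(112, 12, 18, 35, 8)),
    prioritized = TRUE, stringsAsFactors = FALSE)
  sel <- select_for_validation(catalog)
  expect_equal(nrow(sel), 61L)
  expect_setequal(unique(sel$consequence_class),
                  c("intronic", "missense", "synonymous"))
  reasons <- attr(sel, "decisions")
  expect_equal(sum(reasons == "canonical"), 112L)
  expect_equal(sum(reasons == "lof"), 12L)
  ## empty catalog
  expect_equal(nrow(select_for_validation(catalog[0, ])), 0L)
  ## previously validated entries drop unless re-queued
  catalog$prior_validation <- "none"
  catalog$prior_validation[catalog$consequence_class == "intronic"] <- "validated"
  sel2 <- select_for_validation(catalog)
  expect_equal(nrow(sel2), 43L)
  catalog$requeue <- catalog$consequence_class == "intronic"
  expect_equal(nrow(select_for_validation(catalog)), 61L)
})
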