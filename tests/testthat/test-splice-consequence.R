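test_that("codon-aligned exon skipping keeps the frame; short retention shifts it", {
  se <- sim_transcript_event("inframe_del_skip", 120, 40, 85, seed = 2)
  ed <- apply_event(se$genome, se$transcript, se$event)
  expect_equal(nchar(se$transcript$mrna) - nchar(ed$mrna), 46L * 3L)
  cons <- event_consequence(se$genome, se$transcript, se$event)
  expect_equal(cons$kind, "inframe_deletion")
  ## 2-nt retention shifts the frame
  se2 <- sim_transcript_event("frameshift_retention", 134, 69, ret_len = 2,
                              seed = 3)
  cons2 <- event_consequence(se2$genome, se2$transcript, se2$event)
  expect_equal(cons2$kind, "frameshift")
  expect_equal(cons2$fs_first_res, 69L)
  expect_equal(disrupted_fraction(cons2, 134)$count, 65L)
})

test_that("events touching no CDS base yield kind none; start-codon loss warns", {
  tx <- sim_transcriptome(sim_config(seed = 41, n_transcripts = 3,
                                     utr_length_range = c(50L, 80L)))
  t <- tx$transcripts[[1]]
  ## delete a strictly 5'UTR sub-interval of exon 1 (UTR >= 50 nt)
  e <- splice_event("partial_exon_deletion", 1L, c(2L, 10L))
  cons <- event_consequence(tx$genome, t, e)
  expect_equal(cons$kind, "none")
  ## a partial deletion spanning the start codon loses the CDS
  lens <- t$exons$end - t$exons$start + 1L
  if (t$strand == "-") lens <- lens  # exons already stored in transcript order
  cum <- cumsum(lens)
  j <- which(t$cds_offset <= cum)[1]
  local <- t$cds_offset - c(0L, cum)[j]
  e2 <- splice_event("partial_exon_deletion", j,
                     c(max(1L, local - 1L), min(lens[j], local + 3L)))
  expect_warning(cons2 <- event_consequence(tx$genome, t, e2), "start")
  expect_true(isTRUE(attr(cons2, "cds_lost")))
})

test_that("edited mRNA equals the string-surgery oracle on random events", {
  tx <- sim_transcriptome(sim_config(seed = 13, n_transcripts = 6))
  set.seed(17)
  eligible <- Filter(function(t) nrow(t$exons) >= 4, tx$transcripts)
  for (i in 1:60) {
    t <- eligible[[sample(length(eligible), 1)]]
    e <- ncsvtools:::random_event(t)
    ed <- apply_event(tx$genome, t, e)
    expect_equal(ed$mrna, ncsvtools:::truth_alt_mrna(tx$genome, t, e),
                 info = sprintf("%s %s", t$transcript_id, e$event_type))
  }
})

test_that("HGVS-p naming covers deletion, delins, insertion, stop gain and frameshift", {
  ref <- "MKWVLFAAYK"
  ref_cds_len <- 3L * (nchar(ref) + 1L)
  ## deletion of residues 4..6 (VLF)
  del_cds <- "ATGAAATGGGCCGCATACAAATAA"
  cons <- protein_consequence(ref, del_cds)
  expect_equal(cons$hgvs_p, "p.V4_F6del")
  expect_equal(cons$kind, "inframe_deletion")
  ## delins: 4..6 replaced by G
  cons <- protein_consequence(ref, "ATGAAATGGGGTGCCGCATACAAATAA")
  expect_equal(cons$hgvs_p, "p.V4_F6delinsG")
  ## insertion of LA between 3 and 4
  cons <- protein_consequence(ref,
    "ATGAAATGGCTTGCAGTGCTGTTCGCCGCATACAAATAA")
  expect_equal(cons$kind, "inframe_insertion")
  expect_equal(cons$hgvs_p, "p.W3_V4insLA")
  ## immediate stop at residue 4
  cons <- protein_consequence(ref, "ATGAAATGGTAA")
  expect_equal(cons$kind, "stop_gain")
  expect_equal(cons$hgvs_p, "p.V4*")
  ## frameshift: 1-nt deletion inside codon 4
  fs_cds <- "ATGAAATGGTGCTGTTCGCCGCATACAAATAA"
  cons <- protein_consequence(ref, fs_cds, frame_ref_len = ref_cds_len)
  expect_equal(cons$kind, "frameshift")
  expect_equal(cons$fs_first_res, 4L)
  ## no stop anywhere -> flagged
  cons <- protein_consequence(ref, "ATGAAATGGGGGGGGGGG",
                              frame_ref_len = ref_cds_len)
  expect_true(cons$no_stop_found)
  expect_match(cons$hgvs_p, "fs\\*\\?$")
  ## identical translation -> none
  cons <- protein_consequence(ref, "ATGAAGTGGGTGCTGTTCGCCGCATACAAATAA")
  expect_equal(cons$kind, "none")
  expect_error(protein_consequence(ref, ""), "empty")
})

test_that("deletions in repeated context are placed 3'-most", {
  ## ref ...A A B...: deleting one A reports the 3'-most copy
  ref <- "MQAAW"
  cons <- protein_consequence(ref, "ATGCAAGCCTGGTAA")   # M Q A W
  expect_equal(cons$hgvs_p, "p.A4del")
})

test_that("emitted HGVS-p strings parse back to the same consequence", {
  cases <- c("p.V430_K475del", "p.A2del", "p.N43_A66delinsT",
             "p.A211_A212insLA", "p.A394*", "p.G194Rfs*7", "p.K12Efs*?",
             "p.E589_E590insEIPEERDSGNSLSGLSTLVFVLP")
  for (x in cases) {
    p <- parse_hgvs_p(x)
    expect_false(is.na(p$kind), info = x)
  }
  p <- parse_hgvs_p("p.V430_K475del")
  expect_equal(c(p$start_res, p$end_res), c(430L, 475L))
  p <- parse_hgvs_p("p.G194Rfs*7")
  expect_equal(c(p$fs_first_res, p$fs_stop_offset), c(194L, 7L))
  expect_error(parse_hgvs_p("p.K2922_R2906delinsN"), "reversed")
  expect_error(parse_hgvs_p("p.A629D*"), "cannot parse")
})

test_that("engine consequences round-trip through HGVS-p formatting", {
  tx <- sim_transcriptome(sim_config(seed = 23, n_transcripts = 5))
  set.seed(29)
  eligible <- Filter(function(t) nrow(t$exons) >= 4, tx$transcripts)
  n_done <- 0L
  while (n_done < 40L) {
    t <- eligible[[sample(length(eligible), 1)]]
    e <- ncsvtools:::random_event(t)
    cons <- suppressWarnings(event_consequence(tx$genome, t, e))
    if (cons$kind %in% c("none") || isTRUE(cons$no_stop_found)) next
    p <- parse_hgvs_p(cons$hgvs_p)
    expect_equal(p$kind, cons$kind, info = cons$hgvs_p)
    if (!is.na(cons$start_res)) {
      expect_equal(p$start_res, cons$start_res, info = cons$hgvs_p)
    }
    if (cons$kind %in% c("frameshift", "stop_gain")) {
      expect_equal(p$fs_first_res, cons$fs_first_res, info = cons$hgvs_p)
    }
    n_done <- n_done + 1L
  }
})

test_that("disrupted-count conventions reproduce the published table arithmetic", {
  ## inclusive for deletions
  fr <- disrupted_fraction(parse_hgvs_p("p.V430_K475del"), 940)
  expect_equal(fr$count, 46L)
  expect_equal(round_half_up(100 * fr$fraction), 4.89)
  ## delins counts the removed reference range
  fr <- disrupted_fraction(parse_hgvs_p("p.N43_A66delinsT"), 471)
  expect_equal(fr$count, 24L)
  expect_equal(round_half_up(100 * fr$fraction), 5.10)
  ## insertions count the inserted residues
  fr <- disrupted_fraction(parse_hgvs_p("p.A211_A212insLA"), 1512)
  expect_equal(fr$count, 2L)
  expect_equal(round_half_up(100 * fr$fraction), 0.13)
  ## frameshift counts from the first altered residue, exclusive
  fr <- disrupted_fraction(parse_hgvs_p("p.A69Sfs*12"), 134)
  expect_equal(fr$count, 65L)
  expect_equal(round_half_up(100 * fr$fraction), 48.51)
  ## boundary: frameshift at residue 1
  fr <- disrupted_fraction(parse_hgvs_p("p.M1Kfs*9"), 250)
  expect_equal(fr$count, 249L)
  ## positions outside the protein are rejected
  expect_error(disrupted_fraction(parse_hgvs_p("p.V430_K475del"), 100),
               "outside")
})

test_that("frameshift fraction strictly decreases in the first altered residue", {
  L <- 500L
  fracs <- vapply(2:499, function(f) {
    cons <- parse_hgvs_p(sprintf("p.A%dGfs*5", f))
    disrupted_fraction(cons, L)$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("a codon-aligned skipped exon disrupts exactly exon_nt/3 residues", {
  set.seed(51)
  for (i in 1:10) {
    L <- sample(150:400, 1)
    a <- sample(5:(L %/% 2), 1)
    b <- a + sample(5:40, 1)
    se <- sim_transcript_event("inframe_del_skip", L, a, b, seed = i + 60)
    exon_nt <- exon_lengths <- se$transcript$exons$end[2] -
      se$transcript$exons$start[2] + 1L
    cons <- event_consequence(se$genome, se$transcript, se$event)
    expect_equal(disrupted_fraction(cons, L)$count, exon_nt / 3)
  }
})

test_that("PVS1_Strong requires a LoF consequence above the strict 10% bound", {
  ## frameshift disrupting 86.75%
  pv <- pvs1_call(parse_hgvs_p("p.G194Rfs*7"), 1464)
  expect_equal(pv$strength, "PVS1_Strong")
  ## frameshift disrupting 5.36%
  pv <- pvs1_call(parse_hgvs_p("p.A3744Vfs*30"), 3956)
  expect_equal(pv$strength, "not_met")
  expect_match(pv$rationale, "only")
  ## in-frame deletion at 14.74% is not LoF-type
  pv <- pvs1_call(parse_hgvs_p("p.A161_P197del"), 251)
  expect_equal(pv$strength, "not_met")
  expect_match(pv$rationale, "in-frame")
  ## exactly 10.00% fails the strict inequality
  pv <- pvs1_call(parse_hgvs_p("p.A901Gfs*4"), 1000)  # 99/1000 = 9.9%
  expect_equal(pv$strength, "not_met")
  pv <- pvs1_call(parse_hgvs_p("p.A900Gfs*4"), 1000)  # exactly 10.0%
  expect_equal(pv$strength, "not_met")
  pv <- pvs1_call(parse_hgvs_p("p.A899Gfs*4"), 1000)  # 10.1%
  expect_equal(pv$strength, "PVS1_Strong")
  ## stop gains are LoF-type
  pv <- pvs1_call(parse_hgvs_p("p.A394*"), 587)
  expect_equal(pv$strength, "PVS1_Strong")
})

test_that("the six-class taxonomy combines region and outcome; compound events split", {
  expect_equal(ncsv_classify("intronic", "exon_skipping")$label, "B")
  expect_equal(ncsv_classify("exonic", "partial_exon_deletion")$label, "C")
  expect_equal(ncsv_classify("exonic",
    c("partial_exon_deletion", "intron_retention"))$label, c("C", "E"))
  expect_equal(ncsv_classify("intronic", "intron_retention")$label, "F")
  expect_error(ncsv_classify("exonic", "inversion"), "unknown")
})

test_that("outcome descriptions parse into elementary events", {
  out <- parse_outcome(c("Exon 3 skipping", "Intron 2 6bp retention",
                         "Exon 31 133bp deletion",
                         "Intron 74 retention and exon 75 65bp deletion",
                         "Intron 2 19bp;26bp;33bp retention"))
  expect_equal(nrow(out), 8L)
  expect_equal(out$event_type[1], "exon_skipping")
  expect_equal(out$length_bp[2], 6L)
  expect_equal(out$event_type[4:5],
               c("intron_retention", "partial_exon_deletion"))
  expect_equal(out$length_bp[6:8], c(19L, 26L, 33L))
})
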