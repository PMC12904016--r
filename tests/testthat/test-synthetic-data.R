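test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 2, n_transcripts = 4, n_variants = 50)
  tx1 <- sim_transcriptome(cfg)
  tx2 <- sim_transcriptome(cfg)
  expect_identical(tx1, tx2)
  expect_identical(sim_cohort(tx1, cfg), sim_cohort(tx2, cfg))
  expect_identical(sim_catalog(tx1, cfg)$catalog,
                   sim_catalog(tx2, cfg)$catalog)
  ## a different seed changes the genome
  tx3 <- sim_transcriptome(sim_config(seed = 3, n_transcripts = 4))
  expect_false(identical(tx1$genome, tx3$genome))
})

test_that("generated transcripts respect the configured geometry", {
  cfg <- sim_config(seed = 9, n_transcripts = 10)
  tx <- sim_transcriptome(cfg)
  expect_length(tx$transcripts, 10L)
  expect_true("chrX" %in% vapply(tx$transcripts, `[[`, "", "contig"))
  for (t in tx$transcripts) {
    k <- nrow(t$exons)
    expect_true(k >= cfg$exon_count_range[1] && k <= cfg$exon_count_range[2])
    expect_true(t$protein_length >= cfg$protein_length_range[1] &&
                  t$protein_length <= cfg$protein_length_range[2])
    for (i in seq_len(k - 1L)) {
      il <- ncsvtools:::intron_length(t, i)
      expect_true(il >= cfg$intron_length_range[1] &&
                    il <= cfg$intron_length_range[2])
      expect_equal(substr(ncsvtools:::intron_seq(tx$genome, t, i), 1, 2), "GT")
    }
  }
})

test_that("spiked events carry oracle truth the consequence engine reproduces", {
  cfg <- sim_config(seed = 19, n_transcripts = 8, n_variants = 600,
                    spike_fraction = 0.5)
  tx <- sim_transcriptome(cfg)
  spikes <- sim_spike_events(tx, cfg)
  events <- attr(spikes, "events")
  expect_equal(nrow(spikes), 300L)
  expect_setequal(unique(spikes$event_type),
                  c("exon_skipping", "partial_exon_deletion", "intron_retention"))
  agree <- 0L
  for (i in seq_len(nrow(spikes))) {
    t <- tx$transcripts[[spikes$transcript_id[i]]]
    cons <- event_consequence(tx$genome, t, events[[i]])
    fr <- disrupted_fraction(cons, t$protein_length)
    ok <- cons$kind == spikes$truth_kind[i] &&
      fr$count == spikes$truth_count[i] &&
      isTRUE(all.equal(fr$fraction, spikes$truth_fraction[i]))
    if (ok) agree <- agree + 1L
  }
  expect_equal(agree, nrow(spikes))
})

test_that("spiked variants sit near the junctions of their event, mostly in consensus", {
  cfg <- sim_config(seed = 29, n_transcripts = 8, n_variants = 400)
  tx <- sim_transcriptome(cfg)
  spikes <- sim_spike_events(tx, cfg)
  flags <- vapply(seq_len(nrow(spikes)), function(i) {
    t <- tx$transcripts[[spikes$transcript_id[i]]]
    junction_context(t, spikes$pos[i])$in_consensus
  }, logical(1))
  share <- mean(flags)
  expect_gt(share, 0.55)   # configured placement 0.7, binomial spread
  expect_lt(share, 0.85)
})

test_that("copula scores recover the configured correlation and thresholds", {
  cfg <- sim_config(seed = 7, rho = 0.83)
  sc <- sim_scores(rep(FALSE, 5000), cfg)
  r <- score_correlation(sc$spliceai, sc$spcards)$r
  expect_true(abs(r - 0.83) <= 0.05)
  expect_true(all(sc$spliceai >= 0 & sc$spliceai <= 1))
  expect_true(all(sc$spcards >= 0 & sc$spcards <= 18))
  ## independence at rho = 0
  sc0 <- sim_scores(rep(FALSE, 5000), sim_config(seed = 7, rho = 0))
  expect_lt(abs(score_correlation(sc0$spliceai, sc0$spcards)$r), 0.05)
  ## fully separated means give perfect threshold separation
  cfg_sep <- sim_config(seed = 7, spike_mean = 3.5, decoy_mean = -3.5)
  spiked <- rep(c(TRUE, FALSE), each = 1000)
  sc2 <- sim_scores(spiked, cfg_sep)
  pri <- prioritize(sc2$spliceai, sc2$spcards)$prioritized
  sens <- mean(pri[spiked]); spec <- mean(!pri[!spiked])
  expect_gte(sens, 0.99)
  expect_gte(spec, 0.99)
})

test_that("the planted cohort is recovered exactly by the inheritance screen", {
  cfg <- sim_config(seed = 101)
  tx <- sim_transcriptome(cfg)
  coh <- sim_cohort(tx, cfg)
  expect_equal(nrow(coh$truth), 34L)
  cand <- inheritance_screen(coh$calls)
  ## one candidate per planted patient, zero for decoys
  expect_equal(nrow(cand), 17L)
  expect_equal(sum(cand$pattern == "homozygous"), 7L)
  expect_equal(sum(cand$pattern == "compound_het"), 9L)
  expect_equal(sum(cand$pattern == "hemizygous"), 1L)
  truth_pos <- coh$truth[coh$truth$planted_pattern != "none", ]
  expect_setequal(cand$patient_id, truth_pos$patient_id)
  m <- match(cand$patient_id, truth_pos$patient_id)
  expect_equal(cand$pattern, truth_pos$planted_pattern[m])
  ## planted comp-hets carry trans phase
  expect_true(all(cand$phase_status[cand$pattern == "compound_het"] ==
                    "validated_trans"))
  ## order independence
  set.seed(5)
  cand2 <- inheritance_screen(coh$calls[sample(nrow(coh$calls)), ])
  rownames(cand2) <- NULL; rownames(cand) <- NULL
  expect_equal(cand, cand2)
})

test_that("an all-decoy cohort yields no candidates", {
  cfg <- sim_config(seed = 55, n_hom = 0L, n_comphet = 0L, n_hemi = 0L,
                    cohort_size = 12L)
  tx <- sim_transcriptome(cfg)
  coh <- sim_cohort(tx, cfg)
  expect_true(all(coh$truth$planted_pattern == "none"))
  expect_equal(nrow(inheritance_screen(coh$calls)), 0L)
})

test_that("prescribed-geometry transcripts realise their event truth", {
  se <- sim_transcript_event("inframe_del_skip", 200, 50, 80, seed = 31)
  expect_equal(se$truth$kind, "inframe_deletion")
  expect_equal(se$truth$count, 31L)
  se <- sim_transcript_event("frameshift_skip", 300, 120, seed = 32)
  expect_equal(se$truth$fs_first_res, 120L)
  se <- sim_transcript_event("insertion_retention", 150, 60, ret_len = 9,
                             seed = 33)
  expect_equal(nchar(se$truth$inserted), 3L)
})
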