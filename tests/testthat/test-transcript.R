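# Transcript-change events: rate formula, loss uniformity and guard, the
# five alternative-splicing creation mechanics, and the exon status map.

test_that("expected TC counts follow n * tc_x * k_tc * t", {
  p <- sim_params()
  lam <- expected_tc_counts(5, 0.1, p)
  expect_equal(lam[["tl"]], 5 * 0.4 * 5 * 0.1)   # = 1.0
  expect_equal(lam[["es"]] / lam[["ir"]], 4)     # 0.2 vs 0.05
  expect_true(all(expected_tc_counts(5, 0, p) == 0))
  expect_error(expected_tc_counts(-1, 0.1, p), "non-negative")
})

test_that("transcript loss is uniform and guarded at one transcript", {
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)
  t1 <- toy_tx(st, g, ids[1:2])
  t2 <- toy_tx(st, g, ids[2:3])
  # guard: single-transcript set is never emptied
  kept <- apply_transcript_loss(list(t1), st, "x")
  expect_equal(length(kept), 1)
  # uniformity: chi-square over many replicates
  set.seed(500)
  lostA <- 0L
  reps <- 4000L
  for (r in seq_len(reps)) {
    out <- apply_transcript_loss(list(t1, t2), st, "x")
    if (out[[1]]$transcript_id == t2$transcript_id) lostA <- lostA + 1L
  }
  chi <- (lostA - reps / 2)^2 / (reps / 2) +
    ((reps - lostA) - reps / 2)^2 / (reps / 2)
  expect_lt(chi, qchisq(0.999, df = 1))
})

test_that("exon skipping removes exactly one internal reference", {
  set.seed(510)
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)
  ts <- list(toy_tx(st, g, ids))
  res <- create_transcript(ts, g, "es", sim_params(), mods, st, "x")
  expect_true(res$ok)
  newtx <- res$ts[[length(res$ts)]]
  expect_equal(length(newtx$exon_refs), 2)
  expect_true(all(newtx$exon_refs %in% ids))
  expect_false(newtx$lineage_id == ts[[1]]$lineage_id)
})

test_that("mutually exclusive exons swap one of two successive exons", {
  set.seed(520)
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)
  ts <- list(toy_tx(st, g, ids[1:2]))   # e3 absent: swappable pair (e2,e3)
  res <- create_transcript(ts, g, "me", sim_params(), mods, st, "x")
  expect_true(res$ok)
  newtx <- res$ts[[length(res$ts)]]
  expect_equal(newtx$exon_refs, ids[c(1, 3)])
  # template containing every exon has no swappable pair -> skipped
  st2 <- new_sim_state(sim_params(), mods)
  g2 <- toy_gene(st2, exon_lens = c(6L, 9L))
  ts2 <- list(toy_tx(st2, g2, gene_exon_ids(g2)))
  res2 <- create_transcript(ts2, g2, "me", sim_params(), mods, st2, "x")
  expect_false(res2$ok)
})

test_that("intron retention needs gene-adjacent consecutive references", {
  set.seed(530)
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)
  ts <- list(toy_tx(st, g, ids[c(1, 3)]))   # skips e2: no retainable intron
  res <- create_transcript(ts, g, "ir", sim_params(), mods, st, "x")
  expect_false(res$ok)
  ts2 <- list(toy_tx(st, g, ids[1:2]))
  res2 <- create_transcript(ts2, g, "ir", sim_params(), mods, st, "x")
  expect_true(res2$ok)
  newtx <- res2$ts[[length(res2$ts)]]
  expect_length(newtx$retained, 1)
  # the retained intron appears verbatim in the cDNA
  cdna <- transcript_sequence(g, newtx)
  intr <- paste(splicesim:::get_segment(g, newtx$retained)$seq,
                collapse = "")
  expect_true(grepl(intr, cdna, fixed = TRUE))
})

test_that("alternative splice-site shifts are nonzero multiples of 3", {
  mods <- small_models()
  for (type in c("a5", "a3")) {
    hits <- 0L
    set.seed(540)
    st <- new_sim_state(sim_params(), mods)
    g <- toy_gene(st, exon_lens = c(30L, 30L, 30L),
                  intron_lens = c(60L, 60L))
    ids <- gene_exon_ids(g)
    ts <- list(toy_tx(st, g, ids))
    for (r in 1:40) {
      res <- create_transcript(ts, g, type, sim_params(), mods, st, "x")
      if (!res$ok) next
      hits <- hits + 1L
      g <- res$gene
      ts <- res$ts
      newtx <- ts[[length(ts)]]
      side <- if (type == "a5") "adj5" else "adj3"
      adj <- newtx[[side]]
      expect_gt(length(adj), 0)
      expect_true(all(adj %% 3 == 0) && all(adj != 0))
      expect_silent(validate_gene(g))
    }
    expect_gt(hits, 10)
  }
})

test_that("an extension rewrites a valid splice site inside the intron", {
  mods <- small_models()
  set.seed(550)
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 6L), intron_lens = 60L)
  ids <- gene_exon_ids(g)
  ts <- list(toy_tx(st, g, ids))
  found <- FALSE
  for (r in 1:200) {
    res <- create_transcript(ts, g, "a5", sim_params(), mods, st, "x")
    if (!res$ok) next
    newtx <- res$ts[[length(res$ts)]]
    a5 <- splicesim:::tx_adj(newtx, "adj5", ids[2])
    if (a5 > 0) {
      found <- TRUE
      intr <- res$gene$segments[[2]]$seq
      L <- length(intr)
      # cDNA of the new transcript starts its second block with the
      # extension region taken from the intron tail
      cdna <- transcript_sequence(res$gene, newtx)
      tail_seq <- paste(intr[(L - a5 + 1):L], collapse = "")
      expect_true(grepl(tail_seq, cdna, fixed = TRUE))
      break
    }
    ts <- res$ts; g <- res$gene
  }
  expect_true(found)
})

test_that("branch evolution runs losses before creations and logs them", {
  set.seed(560)
  mods <- small_models()
  p <- sim_params()
  st <- new_sim_state(p, mods)
  g <- toy_gene(st, exon_lens = rep(9L, 6L), intron_lens = rep(40L, 5L))
  ids <- gene_exon_ids(g)
  ts <- list(toy_tx(st, g, ids), toy_tx(st, g, ids[1:4]),
             toy_tx(st, g, ids[3:6]))
  res <- evolve_transcripts(ts, g, 1.0, p, mods, st, "x")
  ev <- splicesim:::finalize_events(st)
  ev <- ev[ev$phase == "transcript" & !grepl("skipped", ev$type), ]
  is_loss <- ev$type == "transcript_loss"
  if (any(is_loss) && any(!is_loss)) {
    expect_lt(max(which(is_loss)), min(which(!is_loss)))
  }
  # zero branch is the identity
  res0 <- evolve_transcripts(ts, g, 0, p, mods, st, "x")
  expect_identical(res0$ts, ts)
  # with tc_tl = 0 the transcript count cannot decrease
  p2 <- sim_params(tc_tl = 0, tc_rs = 0.45)
  set.seed(561)
  st2 <- new_sim_state(p2, mods)
  g2 <- toy_gene(st2, exon_lens = rep(9L, 6L), intron_lens = rep(40L, 5L))
  ts2 <- list(toy_tx(st2, g2, gene_exon_ids(g2)))
  res2 <- evolve_transcripts(ts2, g2, 0.5, p2, mods, st2, "x")
  expect_gte(length(res2$ts), length(ts2))
})

test_that("exon status partitions exons into absent/alternative/constitutive", {
  st <- new_sim_state(sim_params(), small_models())
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)
  t1 <- toy_tx(st, g, ids[1:2])
  t2 <- toy_tx(st, g, ids[1])
  s <- exon_status(g, list(t1, t2))
  expect_equal(unname(s[ids]), c("constitutive", "alternative", "absent"))
  # single transcript: included exons constitutive, others absent
  s1 <- exon_status(g, list(t1))
  expect_equal(unname(s1[ids]), c("constitutive", "constitutive", "absent"))
  expect_false("alternative" %in% s1)
  # partition property
  expect_setequal(names(s), ids)
})
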