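# Exon-intron structure change events: the rate formula, the structural
# mechanics of loss/gain/duplication, guards, and the transcript cascade.

test_that("expected EIC counts follow n * eic_x * k_eic * t", {
  p <- sim_params(eic_el = 0.4, eic_eg = 0.5, eic_ed = 0.1, k_eic = 5)
  lam <- expected_eic_counts(10, 0.05, p)
  expect_equal(lam[["loss"]], 10 * 0.4 * 5 * 0.05)   # = 1.0
  expect_equal(lam[["gain"]] / lam[["loss"]], 1.25)
  expect_equal(unname(expected_eic_counts(10, 0, p)), c(0, 0, 0))
  expect_error(expected_eic_counts(10, -0.1, p), "non-negative")
})

test_that("exon loss removes the flanking intron and cascades to transcripts", {
  st <- new_sim_state(sim_params(), small_models())
  g <- toy_gene(st, exon_lens = c(6L, 9L, 6L))
  ids <- gene_exon_ids(g)                      # e1 e2 e3
  t1 <- toy_tx(st, g, ids[1:2])                # contains e2
  t2 <- toy_tx(st, g, ids[c(1, 3)])
  res <- apply_exon_loss(g, list(t1, t2), ids[2], st, "x")
  expect_equal(gene_exon_ids(res$gene), ids[c(1, 3)])
  # middle exon takes its upstream intron with it
  kinds <- vapply(res$gene$segments, `[[`, "", "kind")
  expect_equal(kinds, c("exon", "intron", "exon"))
  expect_equal(length(res$ts), 1)
  expect_equal(res$ts[[1]]$transcript_id, t2$transcript_id)
  expect_silent(validate_gene(res$gene))

  # losing the first exon removes the downstream intron instead
  st2 <- new_sim_state(sim_params(), small_models())
  g2 <- toy_gene(st2, exon_lens = c(6L, 9L, 6L))
  ids2 <- gene_exon_ids(g2)
  res2 <- apply_exon_loss(g2, list(toy_tx(st2, g2, ids2[2:3])), ids2[1],
                          st2, "x")
  expect_equal(gene_exon_ids(res2$gene), ids2[2:3])
  expect_silent(validate_gene(res2$gene))
})

test_that("losing the last exon is refused; an emptied set is reseeded", {
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g1 <- toy_gene(st, exon_lens = 6L, intron_lens = integer(0))
  t1 <- toy_tx(st, g1, gene_exon_ids(g1))
  res <- apply_exon_loss(g1, list(t1), gene_exon_ids(g1), st, "x",
                         sim_params(), mods)
  expect_equal(gene_exon_ids(res$gene), gene_exon_ids(g1))
  ev <- splicesim:::finalize_events(st)
  expect_true("exon_loss_skipped" %in% ev$type)

  # cascade that would empty the set regenerates one random isoform
  set.seed(400)
  st2 <- new_sim_state(sim_params(), mods)
  g2 <- toy_gene(st2, exon_lens = c(6L, 9L))
  ids <- gene_exon_ids(g2)
  tboth <- toy_tx(st2, g2, ids)
  res2 <- apply_exon_loss(g2, list(tboth), ids[2], st2, "x", sim_params(),
                          mods)
  expect_equal(length(res2$ts), 1)
  ev2 <- splicesim:::finalize_events(st2)
  expect_true(any(ev2$detail == "regenerated after exon-loss cascade"))
})

test_that("exon gain splits an intron and starts absent from transcripts", {
  set.seed(410)
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = c(6L, 6L), intron_lens = 40L)
  t1 <- toy_tx(st, g, gene_exon_ids(g))
  g2 <- apply_exon_gain(g, mods, st, "x")
  kinds <- vapply(g2$segments, `[[`, "", "kind")
  expect_equal(kinds, c("exon", "intron", "exon", "intron", "exon"))
  newex <- setdiff(gene_exon_ids(g2), gene_exon_ids(g))
  expect_length(newex, 1)
  seg <- splicesim:::get_segment(g2, newex)
  expect_equal(length(seg$seq) %% 3, 0)
  expect_silent(validate_gene(g2))
  expect_equal(exon_status(g2, list(t1))[[newex]], "absent")
  # a gene without a splittable intron skips the event
  st3 <- new_sim_state(sim_params(), mods)
  g3 <- toy_gene(st3, exon_lens = 6L, intron_lens = integer(0))
  g3b <- apply_exon_gain(g3, mods, st3, "x")
  expect_identical(gene_sequence(g3b), gene_sequence(g3))
  expect_true("exon_gain_skipped" %in% splicesim:::finalize_events(st3)$type)
})

test_that("duplication copies an exon in tandem behind a fresh intron", {
  set.seed(420)
  mods <- small_models()
  st <- new_sim_state(sim_params(), mods)
  g <- toy_gene(st, exon_lens = 6L, intron_lens = integer(0))
  orig <- splicesim:::get_segment(g, gene_exon_ids(g))
  t1 <- toy_tx(st, g, gene_exon_ids(g))
  g2 <- apply_exon_duplication(g, mods, st, "x")
  kinds <- vapply(g2$segments, `[[`, "", "kind")
  expect_equal(kinds, c("exon", "intron", "exon"))
  copy <- g2$segments[[3]]
  expect_identical(copy$seq, orig$seq)          # same sequence ...
  expect_false(identical(copy$cols, orig$cols)) # ... fresh ledger columns
  expect_false(copy$id == orig$id)
  expect_equal(exon_status(g2, list(t1))[[copy$id]], "absent")
  expect_silent(validate_gene(g2))
})

test_that("a branch applies losses, then gains, then duplications", {
  set.seed(430)
  mods <- small_models()
  p <- sim_params()
  st <- new_sim_state(p, mods)
  g <- toy_gene(st, exon_lens = rep(6L, 12L), intron_lens = rep(40L, 11L))
  ts <- list(toy_tx(st, g, gene_exon_ids(g)[1]))
  res <- evolve_structure(g, ts, 0.4, p, mods, st, "x")
  expect_silent(validate_gene(res$gene))
  ev <- splicesim:::finalize_events(st)
  ev <- ev[ev$type %in% c("exon_loss", "exon_gain", "exon_dup"), ]
  expect_gt(nrow(ev), 0)
  ord <- match(ev$type, c("exon_loss", "exon_gain", "exon_dup"))
  expect_true(!is.unsorted(ord))
  # zero branch leaves everything untouched
  res0 <- evolve_structure(g, ts, 0, p, mods, st, "x")
  expect_identical(res0$gene, g)
  expect_identical(res0$ts, ts)
})

test_that("with only losses enabled the exon count never increases", {
  set.seed(440)
  mods <- small_models()
  p <- sim_params(eic_el = 1, eic_eg = 0, eic_ed = 0)
  for (r in 1:20) {
    st <- new_sim_state(p, mods)
    g <- toy_gene(st, exon_lens = rep(6L, 8L), intron_lens = rep(20L, 7L))
    ts <- list(toy_tx(st, g, gene_exon_ids(g)[1]))
    n0 <- 8L
    for (b in 1:3) {
      res <- evolve_structure(g, ts, 0.2, p, mods, st, "x")
      g <- res$gene; ts <- res$ts
      expect_lte(length(gene_exon_ids(g)), n0)
      n0 <- length(gene_exon_ids(g))
    }
    expect_gte(n0, 1L)
  }
})

test_that("mean exon count growth matches the first-order expansion", {
  # E[n'] ~ n * (1 + (eic_eg + eic_ed - eic_el) * k_eic * t) to first order
  set.seed(450)
  mods <- small_models()
  p <- sim_params()
  t <- 0.02
  n0 <- 10L
  reps <- 2000L
  tot <- 0
  for (r in seq_len(reps)) {
    st <- new_sim_state(p, mods)
    g <- toy_gene(st, exon_lens = rep(6L, n0), intron_lens = rep(20L, n0 - 1))
    ts <- list(toy_tx(st, g, gene_exon_ids(g)[1]))
    res <- evolve_structure(g, ts, t, p, mods, st, "x")
    tot <- tot + length(gene_exon_ids(res$gene))
  }
  first_order <- n0 * (1 + (p$eic_eg + p$eic_ed - p$eic_el) * p$k_eic * t)
  se <- sqrt(n0 * p$k_eic * t) / sqrt(reps) * 2   # rough event-noise scale
  expect_lt(abs(tot / reps - first_order), 3 * se + 0.05)
})
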