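# Exon-intron structure change (EIC) events: exon loss, exon gain, exon
# tandem duplication, applied along one branch.

#' Expected EIC event counts on a branch
#'
#' `lambda_x = n_exons * eic_x * k_eic * branch_len` for x in loss, gain,
#' duplication.
#'
#' @param n_exons number of exons at the top of the branch.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @return named numeric vector (loss, gain, dup).
#' @export
expected_eic_counts <- function(n_exons, branch_len, params) {
  if (!is_count(n_exons) || !is_count(branch_len)) {
    stopf("n_exons and branch_len must be non-negative numbers")
  }
  base <- n_exons * params$k_eic * branch_len
  c(loss = params$eic_el, gain = params$eic_eg, dup = params$eic_ed) * base
}

#' Remove an exon from the gene (exon loss)
#'
#' Deletes the exon segment; alternation is restored by also removing its
#' upstream intron (the downstream intron for the first exon). Every
#' transcript containing the exon is removed (a transcript-loss event is
#' logged for each); if the cascade would empty the transcript set, one
#' surviving random isoform is regenerated and logged, so the gene always
#' keeps at least one transcript. Removing the last exon of a gene is
#' refused (the event is skipped with a logged warning).
#'
#' @param gene a `gene_structure`.
#' @param ts list of transcripts.
#' @param exon_id id of the exon to remove.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @param params,models used only if a surviving isoform must be
#'   regenerated.
#' @return list with elements `gene` and `ts`.
#' @export
apply_exon_loss <- function(gene, ts, exon_id, st = NULL, node = "node",
                            params = sim_params(),
                            models = build_default_models()) {
  if (is.null(st)) st <- new_sim_state(params, models)
  i <- segment_index(gene, exon_id)
  if (is.na(i) || gene$segments[[i]]$kind != "exon") {
    stopf("exon '%s' not present in gene", exon_id)
  }
  if (n_exons(gene) == 1L) {
    log_events(st, node, "structure", "exon_loss_skipped", target = exon_id,
               detail = "last-exon guard")
    return(list(gene = gene, ts = ts))
  }
  drop <- if (i == 1L) c(i, i + 1L) else c(i - 1L, i)
  log_events(st, node, "structure", "exon_loss", target = exon_id,
             detail = gene$segments[[setdiff(drop, i)]]$id)
  gene$segments <- gene$segments[-drop]
  lost <- vapply(ts, function(tx) exon_id %in% tx$exon_refs, logical(1))
  for (tx in ts[lost]) {
    log_events(st, node, "structure", "transcript_loss",
               target = tx$transcript_id,
               detail = sprintf("cascade:%s", exon_id))
  }
  ts <- ts[!lost]
  ts <- revalidate_transcripts(gene, ts, st, node)
  if (!length(ts)) {
    tx <- sample_random_isoform(gene, models, st)
    log_events(st, node, "structure", "transcript_create_rs",
               target = tx$transcript_id,
               detail = "regenerated after exon-loss cascade")
    ts <- list(tx)
  }
  list(gene = gene, ts = ts)
}

#' Insert a new exon inside an existing intron (exon gain)
#'
#' A uniformly chosen intron (long enough for two viable halves) is split
#' at a uniform interior point; a freshly generated exon is inserted
#' between the two halves, each half receiving a freshly sampled
#' splice-site dinucleotide at its new extremity. The new exon starts with
#' status "absent" (belongs to no transcript). Genes without a usable
#' intron skip the event with a logged warning.
#'
#' @param gene a `gene_structure`.
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @return the updated `gene_structure`.
#' @export
apply_exon_gain <- function(gene, models = build_default_models(),
                            st = NULL, node = "node") {
  if (is.null(st)) st <- new_sim_state(sim_params(), models)
  cand <- intron_indices(gene)
  cand <- cand[vapply(cand, function(i) length(gene$segments[[i]]$seq) >= 8L,
                      logical(1))]
  if (!length(cand)) {
    log_events(st, node, "structure", "exon_gain_skipped",
               detail = "no intron long enough to split")
    return(gene)
  }
  i <- sample_one(cand)
  intr <- gene$segments[[i]]
  L <- length(intr$seq)
  q <- sample_one(4:(L - 4L))
  left <- new_segment("intron", intr$id, intr$seq[1:q], intr$cols[1:q],
                      intr$birth_node)
  right <- new_segment("intron", next_intron_id(st),
                       intr$seq[(q + 1L):L], intr$cols[(q + 1L):L], node)
  # fresh splice sites at the two new extremities
  ss <- sample_splice_sites(models$splice, 2L)
  left$seq[(q - 1L):q] <- strsplit(ss$acceptor[1], "", fixed = TRUE)[[1]]
  right$seq[1:2] <- strsplit(ss$donor[2], "", fixed = TRUE)[[1]]
  ex <- make_exon_segment(models, st, node)
  gene$segments <- append(gene$segments, list(ex, right), after = i)
  gene$segments[[i]] <- left
  log_events(st, node, "structure", "exon_gain", target = ex$id,
             detail = sprintf("in %s at %d", intr$id, q))
  gene
}

#' Tandem-duplicate an exon
#'
#' A uniformly chosen exon is copied immediately downstream with a fresh
#' exon id, separated from the original by a newly generated intron. The
#' copy starts "absent" from all transcripts.
#'
#' @inheritParams apply_exon_gain
#' @return the updated `gene_structure`.
#' @export
apply_exon_duplication <- function(gene, models = build_default_models(),
                                   st = NULL, node = "node") {
  if (is.null(st)) st <- new_sim_state(sim_params(), models)
  i <- sample_one(exon_indices(gene))
  orig <- gene$segments[[i]]
  intr <- make_intron_segment(models, st, node)
  copy <- new_segment("exon", next_exon_id(st), orig$seq,
                      new_cols(st, length(orig$seq)), node)
  gene$segments <- append(gene$segments, list(intr, copy), after = i)
  log_events(st, node, "structure", "exon_dup", target = copy$id,
             detail = sprintf("of %s", orig$id))
  gene
}

#' Evolve the exon-intron structure along one branch
#'
#' Applies losses, then gains, then duplications; the realized count of
#' each type is Poisson with expectation recomputed from the current exon
#' count before each phase (dynamic adjustment), targets chosen uniformly.
#'
#' @param gene a `gene_structure`.
#' @param ts list of transcripts.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @return list with elements `gene` and `ts`.
#' @export
evolve_structure <- function(gene, ts, branch_len, params = sim_params(),
                             models = build_default_models(), st = NULL,
                             node = "node") {
  if (!is_count(branch_len)) stopf("branch_len must be >= 0")
  if (is.null(st)) st <- new_sim_state(params, models)
  if (branch_len == 0) return(list(gene = gene, ts = ts))
  n_loss <- stats::rpois(1L, n_exons(gene) * params$eic_el * params$k_eic *
                           branch_len)
  for (dummy in seq_len(n_loss)) {
    if (n_exons(gene) == 1L) {
      log_events(st, node, "structure", "exon_loss_skipped",
                 detail = "last-exon guard")
      break
    }
    target <- sample_one(gene_exon_ids(gene))
    res <- apply_exon_loss(gene, ts, target, st, node, params, models)
    gene <- res$gene
    ts <- res$ts
  }
  n_gain <- stats::rpois(1L, n_exons(gene) * params$eic_eg * params$k_eic *
                           branch_len)
  for (dummy in seq_len(n_gain)) {
    gene <- apply_exon_gain(gene, models, st, node)
  }
  n_dup <- stats::rpois(1L, n_exons(gene) * params$eic_ed * params$k_eic *
                          branch_len)
  for (dummy in seq_len(n_dup)) {
    gene <- apply_exon_duplication(gene, models, st, node)
  }
  ts <- revalidate_transcripts(gene, ts, st, node)
  list(gene = gene, ts = ts)
}
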