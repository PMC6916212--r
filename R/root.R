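# Root ancestral gene synthesis: exon-intron structure, sequences and the
# initial set of alternative transcripts.

# generate a fresh exon segment; columns allocated but not yet placed
make_exon_segment <- function(models, st, node, len = NULL) {
  if (is.null(len)) len <- sample_length(models$exon_length, 1L)
  codons <- generate_codon(models$codon, len %/% 3L)
  chars <- unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE)
  new_segment("exon", next_exon_id(st), chars, new_cols(st, len), node)
}

# generate a fresh intron segment: nucleotide chain of the sampled length,
# terminal dinucleotides overwritten with the sampled splice sites
make_intron_segment <- function(models, st, node, len = NULL) {
  if (is.null(len)) len <- sample_length(models$intron_length, 1L)
  chars <- sample(NUCS, len, replace = TRUE, prob = models$intron$p0)
  ss <- sample_splice_sites(models$splice, 1L)
  chars[1:2] <- strsplit(ss$donor, "", fixed = TRUE)[[1]]
  chars[(len - 1L):len] <- strsplit(ss$acceptor, "", fixed = TRUE)[[1]]
  new_segment("intron", next_intron_id(st), chars, new_cols(st, len), node)
}

#' Build the ancestral gene at the tree root
#'
#' Samples the maximum number of exons per cDNA, m, from the
#' exons-per-transcript distribution; the gene then carries
#' `ceiling(k_nbexons * m)` exons (the ceiling guarantees an m-exon isoform
#' always exists). Exon/intron lengths, splice sites and sequences are
#' sampled from the packaged generative models. Every root nucleotide is
#' assigned a fresh homology-ledger column id in gene order.
#'
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a [new_sim_state()]; created on the fly if `NULL`.
#' @param node label recorded as the birth node of root segments.
#' @return a `gene_structure`.
#' @export
build_root_gene <- function(params = sim_params(),
                            models = build_default_models(),
                            st = NULL, node = "root") {
  if (is.null(st)) st <- new_sim_state(params, models)
  m <- sample_length(models$exons_per_transcript, 1L)
  n_ex <- as.integer(ceiling(params$k_nbexons * m))
  segments <- vector("list", 2L * n_ex - 1L)
  for (k in seq_len(n_ex)) {
    ex <- make_exon_segment(models, st, node)
    segments[[2L * k - 1L]] <- ex
    if (k < n_ex) {
      intr <- make_intron_segment(models, st, node)
      segments[[2L * k]] <- intr
    }
  }
  gene_structure(segments, m)
}

#' Sample a random isoform of a gene
#'
#' Draws a target exon count c from the exons-per-transcript distribution
#' truncated to `[1, min(m, number of exons)]` (by exact truncated pmf, not
#' rejection), then selects c exons uniformly without replacement, kept in
#' gene order. No boundary adjustments, no retained introns; the transcript
#' starts a fresh splicing-ortholog lineage.
#'
#' @param gene a `gene_structure`.
#' @param models a `splice_models` bundle.
#' @param st a [new_sim_state()]; created on the fly if `NULL`.
#' @return a `transcript`.
#' @export
sample_random_isoform <- function(gene, models = build_default_models(),
                                  st = NULL) {
  if (is.null(st)) st <- new_sim_state(sim_params(), models)
  ids <- gene_exon_ids(gene)
  cap <- max(1L, min(gene$m_max, length(ids)))
  pmf <- length_pmf(models$exons_per_transcript, cap)
  c_ex <- pmf$support[sample.int(length(pmf$support), 1L, prob = pmf$p)]
  pick <- sort(sample.int(length(ids), c_ex))
  new_transcript(st, exon_refs = ids[pick])
}

#' Build the root set of alternative transcripts
#'
#' The transcript count N is sampled from the transcripts-per-gene
#' distribution. Each transcript is created either by random isoform
#' selection (probability proportional to `tc_rs`) or by applying one
#' alternative-splicing event (type proportional to
#' `tc_a5:tc_a3:tc_es:tc_me:tc_ir`) to a uniformly chosen existing
#' transcript. The first transcript is always created by random selection
#' (in particular when `tc_rs = 0`). Duplicates are rejected and resampled
#' with bounded retries; if no novel transcript can be produced the set is
#' returned short with a logged warning.
#'
#' @param gene a `gene_structure`.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a [new_sim_state()]; created on the fly if `NULL`.
#' @param node label used in the event log.
#' @return list of `transcript` objects (a transcript set).
#' @export
build_root_transcripts <- function(gene, params = sim_params(),
                                   models = build_default_models(),
                                   st = NULL, node = "root") {
  if (is.null(st)) st <- new_sim_state(params, models)
  n_tx <- sample_length(models$transcripts_per_gene, 1L)
  mech_p <- c(rs = params$tc_rs, a5 = params$tc_a5, a3 = params$tc_a3,
              es = params$tc_es, me = params$tc_me, ir = params$tc_ir)
  ts <- list()
  for (k in seq_len(n_tx)) {
    mech <- if (length(ts) == 0L || sum(mech_p) == 0) "rs" else
      sample_cat(mech_p, 1L)
    res <- create_transcript(ts, gene, mech, params, models, st, node,
                             phase = "root")
    ts <- res$ts
    gene <- res$gene
    if (!res$ok && mech != "rs") {
      # fall back to random selection so the set can still grow
      res <- create_transcript(ts, gene, "rs", params, models, st, node,
                               phase = "root")
      ts <- res$ts
      gene <- res$gene
    }
    if (!res$ok) {
      log_events(st, node, "root", "transcript_create_failed",
                 detail = "no novel transcript after bounded retries")
      break
    }
  }
  attr(ts, "gene") <- gene
  ts
}
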