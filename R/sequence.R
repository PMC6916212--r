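# Sequence evolution along one branch: codon-level substitutions and
# indels inside exons, nucleotide-level events inside introns (rates scaled
# by k_intron, terminal splice-site dinucleotides immutable). Every
# inserted nucleotide registers a fresh column in the homology ledger;
# deletions drop columns; substitutions keep them.

#' Expected number of indel events on a segment for one branch
#'
#' Exons: `n_units * k_indel * branch_len` (units are codons). Introns:
#' `k_intron * n_units * k_indel * branch_len` (units are nucleotides).
#' The deletion share of the total is `cd` and the insertion share `ci`.
#'
#' @param n_units segment size in codons (exon) or nucleotides (intron).
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @param is_intron logical flag.
#' @return expected total indel count (a single non-negative number).
#' @export
expected_indel_count <- function(n_units, branch_len, params,
                                 is_intron = FALSE) {
  if (!is_count(n_units) || !is_count(branch_len)) {
    stopf("n_units and branch_len must be non-negative numbers")
  }
  scale <- if (is_intron) params$k_intron else 1
  scale * n_units * params$k_indel * branch_len
}

# vectorized nucleotide substitution: each hit position is redrawn from the
# intron base distribution excluding its current base; repeated hits on the
# same position are applied sequentially (round by round)
vec_substitute_nt <- function(chars, positions, p0) {
  while (length(positions)) {
    first <- !duplicated(positions)
    pos1 <- positions[first]
    base0 <- chars[pos1]            # freeze: one change per position per round
    for (b in NUCS) {
      idx <- pos1[base0 == b]
      if (!length(idx)) next
      alt <- setdiff(NUCS, b)
      pr <- p0[alt] / sum(p0[alt])
      chars[idx] <- alt[sample.int(3L, length(idx), replace = TRUE,
                                   prob = pr)]
    }
    positions <- positions[!first]
  }
  chars
}

#' Evolve one exon segment's sequence along a branch
#'
#' Order of operations: deletions, then insertions, then substitutions.
#' Indel events occur as a length-proportional event process over the
#' branch (expectation recomputed from the current codon count after each
#' event: dynamic length adjustment); indel lengths come from the indel
#' length model, truncated at the exon end; the exon never shrinks below
#' one codon. Inserted codon runs are generated from the codon Markov
#' chains and registered as new ledger columns. The substitution count is
#' Poisson(`n_codons * branch_len`); each substitution replaces the codon
#' at a uniform position by a draw from its substitution-matrix row (a
#' codon outside the 61 sense codons, e.g. a stop emitted by the chains,
#' is replaced by a uniform sense codon).
#'
#' @param seg an exon segment of a `gene_structure`.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @return the evolved segment.
#' @export
evolve_exon_sequence <- function(seg, branch_len, params = sim_params(),
                                 models = build_default_models(), st = NULL,
                                 node = "node") {
  if (!is_count(branch_len)) stopf("branch_len must be >= 0")
  if (is.null(st)) st <- new_sim_state(params, models)
  if (branch_len == 0) return(seg)

  # deletions (codon level)
  u <- 0
  del_pos <- integer(0)
  del_len <- integer(0)
  repeat {
    n <- length(seg$seq) %/% 3L
    rate <- n * params$cd * params$k_indel
    if (rate <= 0) break
    u <- u + stats::rexp(1L, rate)
    if (u > branch_len) break
    if (n <= 1L) next
    len <- sample_indel_length(models$indel, 1L)
    s <- sample.int(n, 1L)
    e <- min(s + len - 1L, n)
    if (e - s + 1L >= n) e <- s + (n - 2L)   # keep >= 1 codon
    if (e < s) next
    idx <- (3L * (s - 1L) + 1L):(3L * e)
    del_pos <- c(del_pos, s)
    del_len <- c(del_len, e - s + 1L)
    seg$seq <- seg$seq[-idx]
    seg$cols <- seg$cols[-idx]
  }
  if (length(del_pos)) {
    log_events(st, node, "sequence", "codon_del", target = seg$id,
               position = del_pos, detail = sprintf("len=%d", del_len))
  }

  # insertions (codon level)
  u <- 0
  ins_pos <- integer(0)
  ins_len <- integer(0)
  repeat {
    n <- length(seg$seq) %/% 3L
    rate <- n * params$ci * params$k_indel
    if (rate <= 0) break
    u <- u + stats::rexp(1L, rate)
    if (u > branch_len) break
    len <- sample_indel_length(models$indel, 1L)
    p <- sample.int(n + 1L, 1L) - 1L       # insert after codon p (0 = front)
    codons <- generate_codon(models$codon, len)
    chars <- unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE)
    cols <- new_cols(st, 3L * len)
    seg$seq <- append(seg$seq, chars, after = 3L * p)
    seg$cols <- append(seg$cols, cols, after = 3L * p)
    ins_pos <- c(ins_pos, p)
    ins_len <- c(ins_len, len)
  }
  if (length(ins_pos)) {
    log_events(st, node, "sequence", "codon_ins", target = seg$id,
               position = ins_pos, detail = sprintf("len=%d", ins_len))
  }

  # substitutions (codon level)
  n <- length(seg$seq) %/% 3L
  cnt <- stats::rpois(1L, n * branch_len)
  if (cnt > 0L) {
    pos <- sample.int(n, cnt, replace = TRUE)
    sub <- models$subst
    for (pcod in pos) {
      idx <- (3L * (pcod - 1L) + 1L):(3L * pcod)
      old <- paste(seg$seq[idx], collapse = "")
      new <- if (old %in% rownames(sub)) {
        rownames(sub)[sample.int(nrow(sub), 1L, prob = sub[old, ])]
      } else {
        # stop codon (or other non-sense codon): uniform sense codon
        SENSE_CODONS[sample.int(length(SENSE_CODONS), 1L)]
      }
      seg$seq[idx] <- strsplit(new, "", fixed = TRUE)[[1]]
    }
    log_events(st, node, "sequence", "codon_sub", target = seg$id,
               position = pos)
  }
  seg
}

#' Evolve one intron segment's sequence along a branch
#'
#' Same process as for exons but at nucleotide level, with all rates scaled
#' by `k_intron`. The four splice-site positions (first two and last two
#' nucleotides) are immutable: substitutions and indels only touch the
#' interior, and the intron length never drops below 4. Substituted bases
#' are redrawn from the intron base distribution excluding the current
#' base (renormalized).
#'
#' @inheritParams evolve_exon_sequence
#' @param seg an intron segment.
#' @return the evolved segment.
#' @export
evolve_intron_sequence <- function(seg, branch_len, params = sim_params(),
                                   models = build_default_models(),
                                   st = NULL, node = "node") {
  if (!is_count(branch_len)) stopf("branch_len must be >= 0")
  if (is.null(st)) st <- new_sim_state(params, models)
  if (branch_len == 0) return(seg)
  ki <- params$k_intron

  # deletions (nucleotide level, interior only)
  u <- 0
  del_pos <- integer(0)
  del_len <- integer(0)
  repeat {
    L <- length(seg$seq)
    rate <- ki * L * params$cd * params$k_indel
    if (rate <= 0) break
    u <- u + stats::rexp(1L, rate)
    if (u > branch_len) break
    if (L <= 4L) next                      # only splice sites left
    len <- sample_indel_length(models$indel, 1L)
    s <- sample.int(L - 4L, 1L) + 2L       # interior start in 3..(L-2)
    e <- min(s + len - 1L, L - 2L)
    del_pos <- c(del_pos, s)
    del_len <- c(del_len, e - s + 1L)
    seg$seq <- seg$seq[-(s:e)]
    seg$cols <- seg$cols[-(s:e)]
  }
  if (length(del_pos)) {
    log_events(st, node, "sequence", "nt_del", target = seg$id,
               position = del_pos, detail = sprintf("len=%d", del_len))
  }

  # insertions (nucleotide level, interior boundaries only)
  u <- 0
  ins_pos <- integer(0)
  ins_len <- integer(0)
  repeat {
    L <- length(seg$seq)
    rate <- ki * L * params$ci * params$k_indel
    if (rate <= 0) break
    u <- u + stats::rexp(1L, rate)
    if (u > branch_len) break
    len <- sample_indel_length(models$indel, 1L)
    p <- sample.int(L - 3L, 1L) + 1L       # insert after position p in 2..(L-2)
    chars <- sample(NUCS, len, replace = TRUE, prob = models$intron$p0)
    cols <- new_cols(st, len)
    seg$seq <- append(seg$seq, chars, after = p)
    seg$cols <- append(seg$cols, cols, after = p)
    ins_pos <- c(ins_pos, p)
    ins_len <- c(ins_len, len)
  }
  if (length(ins_pos)) {
    log_events(st, node, "sequence", "nt_ins", target = seg$id,
               position = ins_pos, detail = sprintf("len=%d", ins_len))
  }

  # substitutions (nucleotide level, interior only)
  L <- length(seg$seq)
  cnt <- stats::rpois(1L, ki * L * branch_len)
  if (cnt > 0L && L > 4L) {
    pos <- sample.int(L - 4L, cnt, replace = TRUE) + 2L
    seg$seq <- vec_substitute_nt(seg$seq, pos, models$intron$p0)
    log_events(st, node, "sequence", "nt_sub", target = seg$id,
               position = pos)
  }
  seg
}

#' Evolve all segment sequences of a gene along a branch
#'
#' Applies [evolve_exon_sequence()] / [evolve_intron_sequence()] to each
#' segment independently. When `seed` is given, each segment evolves under
#' its own RNG sub-stream derived from (seed, node, segment id), so results
#' do not depend on segment iteration order.
#'
#' @param gene a `gene_structure`.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @param seed optional integer; base seed for per-segment sub-streams.
#' @return the evolved `gene_structure`.
#' @export
evolve_gene_sequences <- function(gene, branch_len, params = sim_params(),
                                  models = build_default_models(),
                                  st = NULL, node = "node", seed = NULL) {
  if (is.null(st)) st <- new_sim_state(params, models)
  for (k in seq_along(gene$segments)) {
    seg <- gene$segments[[k]]
    if (!is.null(seed)) set.seed(mix_seed(seed, node, "seq", seg$id))
    gene$segments[[k]] <- if (seg$kind == "exon") {
      evolve_exon_sequence(seg, branch_len, params, models, st, node)
    } else {
      evolve_intron_sequence(seg, branch_len, params, models, st, node)
    }
  }
  gene
}
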