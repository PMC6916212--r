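# Simulation engine: root-to-leaf recursion over the guide tree with the
# per-branch phase order structure -> transcripts -> sequences, plus
# assembly of cDNAs, true alignments and splicing-ortholog groups.

# ---------------------------------------------------------------------------
# transcript assembly (cDNA sequence, ledger columns, genomic blocks)

assemble_transcript <- function(gene, tx) {
  off <- segment_offsets(gene)
  pieces <- list()
  K <- length(tx$exon_refs)
  for (k in seq_len(K)) {
    e <- tx$exon_refs[k]
    i <- segment_index(gene, e)
    elen <- length(gene$segments[[i]]$seq)
    a5 <- tx_adj(tx, "adj5", e)
    a3 <- tx_adj(tx, "adj3", e)
    if (a5 > 0L) {
      up <- gene$segments[[i - 1L]]
      ilen <- length(up$seq)
      pieces[[length(pieces) + 1L]] <-
        list(id = up$id, from = ilen - a5 + 1L, to = ilen)
    }
    pieces[[length(pieces) + 1L]] <-
      list(id = e, from = 1L + max(0L, -a5), to = elen - max(0L, -a3))
    if (a3 > 0L) {
      dn <- gene$segments[[i + 1L]]
      pieces[[length(pieces) + 1L]] <- list(id = dn$id, from = 1L, to = a3)
    }
    if (k < K) {
      j <- segment_index(gene, tx$exon_refs[k + 1L])
      if (j == i + 2L) {
        intr <- gene$segments[[i + 1L]]
        if (intr$id %in% tx$retained) {
          pieces[[length(pieces) + 1L]] <-
            list(id = intr$id, from = 1L, to = length(intr$seq))
        }
      }
    }
  }
  chars <- character(0)
  cols <- integer(0)
  starts <- integer(0)
  ends <- integer(0)
  for (p in pieces) {
    seg <- get_segment(gene, p$id)
    chars <- c(chars, seg$seq[p$from:p$to])
    cols <- c(cols, seg$cols[p$from:p$to])
    starts <- c(starts, off[[p$id]] + p$from)
    ends <- c(ends, off[[p$id]] + p$to)
  }
  # merge genomically contiguous pieces into exon blocks
  bs <- integer(0)
  be <- integer(0)
  for (k in seq_along(starts)) {
    if (length(bs) && starts[k] == be[length(be)] + 1L) {
      be[length(be)] <- ends[k]
    } else {
      bs <- c(bs, starts[k])
      be <- c(be, ends[k])
    }
  }
  list(chars = chars, cols = cols,
       blocks = data.frame(start = bs, end = be))
}

#' cDNA sequence of a transcript
#'
#' Concatenation of the transcript's (boundary-adjusted) exon sequences
#' and retained introns, read off the current gene.
#'
#' @param gene a `gene_structure`.
#' @param tx a `transcript`.
#' @return a single character string.
#' @export
transcript_sequence <- function(gene, tx) {
  paste(assemble_transcript(gene, tx)$chars, collapse = "")
}

# ---------------------------------------------------------------------------
# true alignments from the homology ledger

# Anchored merge of two column-id orders. Both vectors list column ids in
# their sequence order; ids present in both (inherited positions) act as
# anchors and must agree in relative order (they descend from the same
# ancestral sequence). Ids unique to either side (independent insertions)
# are interleaved between anchors, first-argument blocks first, so folding
# rows in traversal order gives the deterministic tie-break for mutually
# unalignable insertion blocks.
merge_orders <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  in_b <- a %in% b
  in_a <- b %in% a
  common_a <- a[in_b]
  common_b <- b[in_a]
  if (!identical(common_a, common_b)) {
    stopf("internal ledger error: inconsistent column orders")
  }
  slot_a <- cumsum(in_b)   # anchors seen before each position of a
  slot_b <- cumsum(in_a)
  ids <- c(a[!in_b], b[!in_a], common_a)
  slot <- c(slot_a[!in_b], slot_b[!in_a], seq_along(common_a) - 1L)
  cls <- rep.int(c(0L, 1L, 2L),
                 c(sum(!in_b), sum(!in_a), length(common_a)))
  ids[order(slot, cls)]    # stable radix sort keeps within-block order
}

# global column order from a list of per-sequence column vectors
merge_column_orders <- function(col_list) {
  Reduce(merge_orders, col_list, integer(0))
}

# rows: named list of list(cols = integer vector, chars = character vector)
align_rows <- function(master, rows) {
  allcols <- unique(unlist(lapply(rows, `[[`, "cols"), use.names = FALSE))
  keep <- master[master %in% allcols]
  if (length(keep) != length(allcols)) {
    stopf("internal ledger error: %d columns missing from the global order",
          length(allcols) - length(keep))
  }
  out <- character(length(rows))
  for (r in seq_along(rows)) {
    pos <- match(rows[[r]]$cols, keep)
    if (anyNA(pos) || is.unsorted(pos, strictly = TRUE)) {
      stopf("internal ledger error: row order inconsistent with the ledger")
    }
    v <- rep("-", length(keep))
    v[pos] <- rows[[r]]$chars
    out[r] <- paste(v, collapse = "")
  }
  names(out) <- names(rows)
  out
}

#' Rebuild the true multiple alignments of a simulation result
#'
#' Columns are the ledger's global column identities, linearized by a
#' deterministic anchored merge of the per-node column orders in tree
#' pre-order (independent insertion blocks, which are mutually
#' unalignable, are ordered by the traversal rank of the branch that
#' created them); a row's non-gap characters read left to right equal the
#' corresponding output sequence.
#'
#' @param x a `splice_sim` result.
#' @return list with elements `gene_msa` and `cdna_msa` (named character
#'   vectors, gap character `-`).
#' @export
build_true_alignments <- function(x) {
  list(
    gene_msa = align_rows(x$ledger$master, x$ledger$gene_rows),
    cdna_msa = align_rows(x$ledger$master, x$ledger$cdna_rows)
  )
}

#' Splicing-ortholog groups of a simulation result
#'
#' Groups leaf transcripts by splicing-ortholog lineage: transcripts
#' descending from the same ancestral transcript without any
#' alternative-splicing (creation) event in their history share a lineage;
#' every creation event starts a fresh lineage. The groups partition the
#' leaf transcripts.
#'
#' @param x a `splice_sim` result.
#' @return named list: lineage id -> character vector of `leaf:transcript`
#'   member ids.
#' @export
collect_ortholog_groups <- function(x) {
  members <- character(0)
  lineages <- character(0)
  for (leaf in names(x$leaves)) {
    for (tx in x$leaves[[leaf]]$transcripts) {
      members <- c(members, paste0(leaf, ":", tx$transcript_id))
      lineages <- c(lineages, tx$lineage_id)
    }
  }
  split(members, lineages)
}

# ---------------------------------------------------------------------------

#' Simulate the evolution of a gene family along a guide tree
#'
#' Generates an ancestral gene (exon-intron structure, sequences and a set
#' of alternative transcripts) at the root and evolves it recursively to
#' the leaves. On each branch the phases run in the order: exon-intron
#' structure events (exon loss/gain/duplication), then transcript events
#' (loss and creation by random selection or alternative splicing), then
#' sequence events (substitutions and indels). Branch lengths are expected
#' substitutions per codon. Fully deterministic given
#' `(tree, params, seed)`.
#'
#' @param tree a guide tree: an `ape::phylo` object, a Newick string, or a
#'   path to a Newick file (see [parse_guide_tree()]).
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle from [build_default_models()].
#' @param seed integer seed.
#' @param keep_internal keep internal-node gene/transcript states in the
#'   result (`$internal`)?
#' @return an object of class `splice_sim` with elements `leaves` (per-leaf
#'   gene structure and transcripts), `gene_sequences`, `cdna_sequences`,
#'   `gene_msa`, `cdna_msa` (true alignments), `ortholog_groups`, `events`
#'   (the full event log), `exon_tables` (per-transcript exon locations),
#'   `tree`, `params`, `seed`.
#' @examples
#' sim <- simulate_splice_evolution("(a:0.02,b:0.03);", seed = 7)
#' summary(sim)
#' @export
simulate_splice_evolution <- function(tree, params = sim_params(),
                                      models = build_default_models(),
                                      seed = 1L, keep_internal = FALSE) {
  validate_sim_params(params)
  validate_models(models)
  tree <- parse_guide_tree(tree)
  st <- new_sim_state(params, models)

  set.seed(mix_seed(seed, "root-synthesis"))
  gene0 <- build_root_gene(params, models, st, node = "root")
  ts0 <- build_root_transcripts(gene0, params, models, st, node = "root")
  gene0 <- attr(ts0, "gene")     # a5/a3 at the root may rewrite an intron
  attr(ts0, "gene") <- NULL

  leaves <- list()
  internal <- list()
  # full column vector of every node in pre-order; folding these in order
  # yields a global column order consistent with every sequence
  order_rows <- list(gene_cols(gene0))

  if (inherits(tree, "root_only_tree")) {
    leaves[[tree$label]] <- list(gene = gene0, transcripts = ts0)
  } else {
    ntip <- length(tree$tip.label)
    labels <- c(tree$tip.label, tree$node.label)
    recurse <- function(node, gene, ts) {
      rows <- which(tree$edge[, 1] == node)
      for (r in rows) {
        child <- tree$edge[r, 2]
        bl <- tree$edge.length[r]
        lab <- labels[child]
        set.seed(mix_seed(seed, lab, "structure"))
        res <- evolve_structure(gene, ts, bl, params, models, st, lab)
        set.seed(mix_seed(seed, lab, "transcript"))
        res <- evolve_transcripts(res$ts, res$gene, bl, params, models, st,
                                  lab)
        g <- evolve_gene_sequences(res$gene, bl, params, models, st, lab,
                                   seed = seed)
        t2 <- revalidate_transcripts(g, res$ts, st, lab)
        order_rows[[length(order_rows) + 1L]] <<- gene_cols(g)
        if (child <= ntip) {
          leaves[[lab]] <<- list(gene = g, transcripts = t2)
        } else {
          if (keep_internal) {
            internal[[lab]] <<- list(gene = g, transcripts = t2)
          }
          recurse(child, g, t2)
        }
      }
    }
    root <- ntip + 1L
    if (keep_internal) internal[[labels[root]]] <- list(gene = gene0,
                                                        transcripts = ts0)
    recurse(root, gene0, ts0)
    leaves <- leaves[tree$tip.label]
  }

  # assemble outputs
  gene_rows <- list()
  cdna_rows <- list()
  gene_sequences <- character(0)
  cdna_sequences <- character(0)
  exon_tables <- list()
  for (leaf in names(leaves)) {
    g <- leaves[[leaf]]$gene
    validate_gene(g)
    gene_rows[[leaf]] <- list(cols = gene_cols(g),
                              chars = unlist(lapply(g$segments, `[[`, "seq"),
                                             use.names = FALSE))
    gene_sequences[[leaf]] <- gene_sequence(g)
    for (tx in leaves[[leaf]]$transcripts) {
      asm <- assemble_transcript(g, tx)
      id <- paste0(leaf, ":", tx$transcript_id)
      cdna_rows[[id]] <- list(cols = asm$cols, chars = asm$chars)
      cdna_sequences[[id]] <- paste(asm$chars, collapse = "")
      exon_tables[[id]] <- asm$blocks
    }
  }

  x <- structure(list(
    tree = tree, params = params, seed = seed,
    leaves = leaves,
    internal = if (keep_internal) internal else NULL,
    gene_sequences = gene_sequences,
    cdna_sequences = cdna_sequences,
    exon_tables = exon_tables,
    events = finalize_events(st),
    ledger = list(
      master = merge_column_orders(order_rows),
      gene_rows = gene_rows, cdna_rows = cdna_rows)
  ), class = "splice_sim")
  aln <- build_true_alignments(x)
  x$gene_msa <- aln$gene_msa
  x$cdna_msa <- aln$cdna_msa
  x$ortholog_groups <- collect_ortholog_groups(x)
  x
}

#' @export
print.splice_sim <- function(x, ...) {
  cat(sprintf("Simulated gene family: %d leaves, %d transcripts, seed %d\n",
              length(x$leaves), length(x$cdna_sequences), x$seed))
  invisible(x)
}

#' @export
summary.splice_sim <- function(object, ...) {
  x <- object
  cat(sprintf("Gene family simulated along a %d-leaf guide tree (seed %d)\n",
              length(x$leaves), x$seed))
  for (leaf in names(x$leaves)) {
    g <- x$leaves[[leaf]]$gene
    cat(sprintf("  %-12s %3d exons, %6d nt gene, %2d transcripts\n", leaf,
                n_exons(g), nchar(x$gene_sequences[[leaf]]),
                length(x$leaves[[leaf]]$transcripts)))
  }
  cat(sprintf("Events logged: %d | ortholog groups: %d | gene MSA width: %d\n",
              nrow(x$events), length(x$ortholog_groups),
              nchar(x$gene_msa[1])))
  invisible(x)
}
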