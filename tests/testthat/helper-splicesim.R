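# Shared fixtures: scaled-down generative models (short segments, small
# counts) for fast structural tests, a deterministic toy gene, and
# independent brute-force oracles for the evaluation metrics.

small_models <- function() {
  m <- list(
    codon = codon_markov_model(),
    intron = intron_nucleotide_model(),
    splice = splice_site_distribution(),
    exon_length = length_model("exon_length", 30, 12),
    intron_length = length_model("intron_length", 60, 25),
    exons_per_transcript = length_model("exons_per_transcript", 5, 2),
    transcripts_per_gene = length_model("transcripts_per_gene", 3, 1.5),
    subst = codon_substitution_matrix(),
    indel = indel_length_model()
  )
  class(m) <- "splice_models"
  m
}

# deterministic toy gene: exon lengths multiples of 3, introns GT..AG
toy_gene <- function(st, exon_lens = c(6L, 9L, 6L),
                     intron_lens = rep(20L, length(exon_lens) - 1L),
                     m_max = 10L) {
  segs <- list()
  for (k in seq_along(exon_lens)) {
    chars <- rep_len(c("A", "T", "G"), exon_lens[k])
    segs[[length(segs) + 1L]] <- splicesim:::new_segment(
      "exon", splicesim:::next_exon_id(st), chars,
      splicesim:::new_cols(st, exon_lens[k]), "root")
    if (k < length(exon_lens)) {
      ilen <- intron_lens[k]
      ichars <- c("G", "T", rep_len(c("C", "A"), ilen - 4L), "A", "G")
      segs[[length(segs) + 1L]] <- splicesim:::new_segment(
        "intron", splicesim:::next_intron_id(st), ichars,
        splicesim:::new_cols(st, ilen), "root")
    }
  }
  splicesim:::gene_structure(segs, m_max)
}

toy_tx <- function(st, gene, refs = gene_exon_ids(gene)) {
  splicesim:::new_transcript(st, refs)
}

# independent brute-force enumeration of aligned residue pairs
oracle_pairs <- function(msa) {
  rows <- strsplit(unname(msa), "", fixed = TRUE)
  ids <- names(msa)
  counters <- rep(0L, length(rows))
  res <- character(0)
  for (j in seq_len(length(rows[[1]]))) {
    present <- integer(0)
    ridx <- integer(0)
    for (r in seq_along(rows)) {
      if (rows[[r]][j] != "-") {
        counters[r] <- counters[r] + 1L
        present <- c(present, r)
        ridx <- c(ridx, counters[r] - 1L)
      }
    }
    if (length(present) >= 2L) {
      for (u in seq_len(length(present) - 1L)) {
        for (v in (u + 1L):length(present)) {
          ia <- ids[present[u]]; ra <- ridx[u]
          ib <- ids[present[v]]; rb <- ridx[v]
          if (ia > ib) {
            tmp <- ia; ia <- ib; ib <- tmp
            tmp <- ra; ra <- rb; rb <- tmp
          }
          res <- c(res, paste0(ia, "#", ra, "|", ib, "#", rb))
        }
      }
    }
  }
  unique(res)
}

# independent Rand index by explicit pair enumeration
oracle_rand <- function(est, truth) {
  items <- names(truth)
  n <- length(items)
  if (n < 2L) return(1)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- est[[items[i]]] == est[[items[j]]]
      sb <- truth[[items[i]]] == truth[[items[j]]]
      agree <- agree + as.integer(sa == sb)
      total <- total + 1L
    }
  }
  agree / total
}

# random pair of alignments over the same ungapped sequences
random_msa_pair <- function(n_seq, width, seed) {
  set.seed(seed)
  lens <- sample(3:width, n_seq, replace = TRUE)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  ids <- paste0("s", seq_len(n_seq))
  place <- function() {
    rows <- vapply(seq_len(n_seq), function(r) {
      colsel <- sort(sample.int(width, lens[r]))
      v <- rep("-", width)
      v[colsel] <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
      paste(v, collapse = "")
    }, character(1))
    names(rows) <- ids
    rows
  }
  list(est = place(), true = place())
}

# cached small simulations reused by several property tests
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
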