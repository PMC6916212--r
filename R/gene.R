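# Gene structure container: an ordered alternation of exon and intron
# segments. Each segment carries its nucleotide characters and the parallel
# vector of global column ids (homology ledger entries).

new_segment <- function(kind, id, chars, cols, birth_node) {
  list(kind = kind, id = id, seq = chars, cols = cols,
       birth_node = birth_node)
}

#' Construct a gene structure
#'
#' @param segments list of segments strictly alternating exon, intron, ...,
#'   exon (starts and ends with an exon).
#' @param m_max the sampled maximum number of exons per cDNA (symbol m).
#' @return an object of class `gene_structure`.
#' @keywords internal
gene_structure <- function(segments, m_max) {
  g <- structure(list(segments = segments, m_max = as.integer(m_max)),
                 class = "gene_structure")
  g
}

#' Validate the structural invariants of a gene
#'
#' Checks the exon/intron alternation (first and last segments are exons),
#' that every exon length is a positive multiple of 3, that every intron is
#' at least 4 nt with 2-nt terminal splice sites, and that sequence and
#' column vectors agree in length.
#'
#' @param gene a `gene_structure`.
#' @return `gene`, invisibly; error on violation.
#' @export
validate_gene <- function(gene) {
  kinds <- vapply(gene$segments, `[[`, "", "kind")
  n <- length(kinds)
  if (n == 0L || kinds[1] != "exon" || kinds[n] != "exon") {
    stopf("gene must start and end with an exon")
  }
  if (!all(kinds == rep_len(c("exon", "intron"), n))) {
    stopf("gene segments must strictly alternate exon/intron")
  }
  for (s in gene$segments) {
    len <- length(s$seq)
    if (length(s$cols) != len) stopf("segment %s: cols/seq length mismatch", s$id)
    if (s$kind == "exon") {
      if (len < 3L || len %% 3L != 0L) {
        stopf("exon %s length %d is not a positive multiple of 3", s$id, len)
      }
    } else {
      if (len < 4L) stopf("intron %s shorter than 4 nt", s$id)
    }
    if (!all(s$seq %in% NUCS)) stopf("segment %s has non-ACGT characters", s$id)
  }
  invisible(gene)
}

exon_indices <- function(gene) {
  which(vapply(gene$segments, `[[`, "", "kind") == "exon")
}

intron_indices <- function(gene) {
  which(vapply(gene$segments, `[[`, "", "kind") == "intron")
}

#' Exon ids of a gene, in gene order
#' @param gene a `gene_structure`.
#' @return character vector of exon ids.
#' @export
gene_exon_ids <- function(gene) {
  vapply(gene$segments[exon_indices(gene)], `[[`, "", "id")
}

n_exons <- function(gene) length(exon_indices(gene))

segment_index <- function(gene, id) {
  ids <- vapply(gene$segments, `[[`, "", "id")
  match(id, ids)
}

get_segment <- function(gene, id) gene$segments[[segment_index(gene, id)]]

#' Full nucleotide sequence of a gene
#' @param gene a `gene_structure`.
#' @return single character string (concatenation of all segments).
#' @export
gene_sequence <- function(gene) {
  paste(unlist(lapply(gene$segments, `[[`, "seq"), use.names = FALSE),
        collapse = "")
}

gene_cols <- function(gene) {
  unlist(lapply(gene$segments, `[[`, "cols"), use.names = FALSE)
}

# 0-based offset of each segment within the gene sequence, named by id
segment_offsets <- function(gene) {
  lens <- vapply(gene$segments, function(s) length(s$seq), integer(1))
  off <- cumsum(c(0L, lens))[seq_along(lens)]
  names(off) <- vapply(gene$segments, `[[`, "", "id")
  off
}

#' @export
print.gene_structure <- function(x, ...) {
  kinds <- vapply(x$segments, `[[`, "", "kind")
  lens <- vapply(x$segments, function(s) length(s$seq), integer(1))
  cat(sprintf("Gene structure: %d exons, %d introns, %d nt (m = %d)\n",
              sum(kinds == "exon"), sum(kinds == "intron"), sum(lens),
              x$m_max))
  invisible(x)
}
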