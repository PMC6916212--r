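# Mutable simulation state: id counters, the global homology ledger
# (master column order) and the event log. Passed by reference (environment)
# through every operation; gene/transcript values themselves are immutable
# lists returned functionally.

#' Create a fresh simulation state
#'
#' Holds the global column identity ledger (every simulated nucleotide is
#' assigned a column id at birth; substitutions preserve ids, deletions
#' drop them, insertions mint new ids spliced into the global order), the
#' id counters for exons/introns/transcripts/lineages, and the event log.
#'
#' @param params a [sim_params()] object.
#' @param models a `splice_models` bundle.
#' @return an environment of class `sim_state`.
#' @export
new_sim_state <- function(params = sim_params(),
                          models = build_default_models()) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$models <- models
  st$exon_i <- 0L
  st$intron_i <- 0L
  st$tx_i <- 0L
  st$lineage_i <- 0L
  st$col_i <- 0L
  st$events <- vector("list", 0L)
  st$ev_n <- 0L
  class(st) <- "sim_state"
  st
}

next_exon_id <- function(st) {
  st$exon_i <- st$exon_i + 1L
  sprintf("e%d", st$exon_i)
}
next_intron_id <- function(st) {
  st$intron_i <- st$intron_i + 1L
  sprintf("i%d", st$intron_i)
}
next_tx_id <- function(st) {
  st$tx_i <- st$tx_i + 1L
  sprintf("t%d", st$tx_i)
}
next_lineage_id <- function(st) {
  st$lineage_i <- st$lineage_i + 1L
  sprintf("L%d", st$lineage_i)
}

# allocate n fresh column ids. Ids are minted in birth order; the global
# column order of the true alignment is reconstructed at output time by
# anchored merging of the per-sequence id vectors (see merge_orders), so
# no online order maintenance is needed here.
new_cols <- function(st, n) {
  if (n == 0L) return(integer(0))
  ids <- st$col_i + seq_len(n)
  st$col_i <- st$col_i + as.integer(n)
  as.integer(ids)
}

# vectorized event logging: one chunk per call, fields recycled
log_events <- function(st, node, phase, type, target = "",
                       position = NA_integer_, detail = "") {
  n <- max(length(node), length(phase), length(type), length(target),
           length(position), length(detail))
  if (n == 0L) return(invisible(NULL))
  st$ev_n <- st$ev_n + 1L
  st$events[[st$ev_n]] <- list(
    node = rep_len(as.character(node), n),
    phase = rep_len(as.character(phase), n),
    type = rep_len(as.character(type), n),
    target = rep_len(as.character(target), n),
    position = rep_len(as.integer(position), n),
    detail = rep_len(as.character(detail), n)
  )
  invisible(NULL)
}

finalize_events <- function(st) {
  ch <- st$events[seq_len(st$ev_n)]
  if (!length(ch)) {
    return(data.frame(node = character(0), phase = character(0),
                      type = character(0), target = character(0),
                      position = integer(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    node = unlist(lapply(ch, `[[`, "node"), use.names = FALSE),
    phase = unlist(lapply(ch, `[[`, "phase"), use.names = FALSE),
    type = unlist(lapply(ch, `[[`, "type"), use.names = FALSE),
    target = unlist(lapply(ch, `[[`, "target"), use.names = FALSE),
    position = unlist(lapply(ch, `[[`, "position"), use.names = FALSE),
    detail = unlist(lapply(ch, `[[`, "detail"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
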