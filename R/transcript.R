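# Transcripts and transcript-change (TC) events: loss, creation by random
# isoform selection, and the five elementary alternative-splicing event
# types (alternative 5'/3' splice-site selection, exon skipping, mutually
# exclusive exons, intron retention).

#' Construct a transcript
#'
#' @param st a `sim_state` (supplies fresh transcript and lineage ids).
#' @param exon_refs ordered character vector of exon ids (gene order).
#' @param adj5,adj3 named integer vectors of signed boundary offsets in
#'   nucleotides (multiples of 3; positive = extension into the flanking
#'   intron, negative = truncation of the exon), keyed by exon id.
#' @param retained character vector of retained intron ids.
#' @param lineage_id splicing-ortholog lineage; fresh when `NULL`.
#' @return an object of class `transcript`.
#' @keywords internal
new_transcript <- function(st, exon_refs, adj5 = integer(0),
                           adj3 = integer(0), retained = character(0),
                           lineage_id = NULL) {
  structure(list(
    transcript_id = next_tx_id(st),
    lineage_id = if (is.null(lineage_id)) next_lineage_id(st) else lineage_id,
    exon_refs = exon_refs,
    adj5 = adj5, adj3 = adj3,
    retained = retained
  ), class = "transcript")
}

tx_adj <- function(tx, side, exon_id) {
  v <- tx[[side]][exon_id]
  if (length(v) == 0L || is.na(v)) 0L else as.integer(v)
}

set_tx_adj <- function(tx, side, exon_id, value) {
  a <- tx[[side]]
  a[exon_id] <- as.integer(value)
  a <- a[a != 0L]
  tx[[side]] <- a
  tx
}

# canonical signature used for the pairwise-distinct invariant
tx_signature <- function(tx) {
  parts <- vapply(tx$exon_refs, function(e) {
    sprintf("%s(%d,%d)", e, tx_adj(tx, "adj5", e), tx_adj(tx, "adj3", e))
  }, character(1))
  paste0(paste(parts, collapse = "+"), "|R:",
         paste(sort(tx$retained), collapse = ","))
}

ts_signatures <- function(ts) vapply(ts, tx_signature, character(1))

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (lineage %s): %s\n", x$transcript_id,
              x$lineage_id, paste(x$exon_refs, collapse = "-")))
  if (length(x$retained)) {
    cat("  retained introns:", paste(x$retained, collapse = ", "), "\n")
  }
  invisible(x)
}

# maximum legal extension (multiple of 3) into an intron of length ilen,
# leaving room for the two splice-site dinucleotides
max_extension <- function(ilen, already = 0L) {
  max(0L, 3L * ((ilen - 4L - already) %/% 3L))
}

# maximum legal truncation (positive number) of an exon keeping >= 3 nt
max_truncation <- function(elen, other_trunc = 0L) {
  max(0L, 3L * ((elen - other_trunc - 3L) %/% 3L))
}

#' Expected transcript-change event counts on a branch
#'
#' `lambda_x = n_transcripts * tc_x * k_tc * branch_len` for each of the
#' seven TC event types.
#'
#' @param n_transcripts number of transcripts at the top of the branch.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @return named numeric vector (rs, a5, a3, es, me, ir, tl).
#' @export
expected_tc_counts <- function(n_transcripts, branch_len, params) {
  if (!is_count(n_transcripts) || !is_count(branch_len)) {
    stopf("n_transcripts and branch_len must be non-negative numbers")
  }
  base <- n_transcripts * params$k_tc * branch_len
  c(rs = params$tc_rs, a5 = params$tc_a5, a3 = params$tc_a3,
    es = params$tc_es, me = params$tc_me, ir = params$tc_ir,
    tl = params$tc_tl) * base
}

#' Remove one uniformly chosen transcript
#'
#' A transcript-loss event: the lost lineage stops propagating in this
#' gene lineage. If the set holds a single transcript the event is skipped
#' with a logged warning (a gene always keeps at least one transcript).
#'
#' @param ts list of transcripts.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @return the updated transcript list.
#' @export
apply_transcript_loss <- function(ts, st, node = "node") {
  if (length(ts) <= 1L) {
    log_events(st, node, "transcript", "transcript_loss_skipped",
               detail = "single-transcript guard")
    return(ts)
  }
  k <- sample.int(length(ts), 1L)
  log_events(st, node, "transcript", "transcript_loss",
             target = ts[[k]]$transcript_id,
             detail = ts[[k]]$lineage_id)
  ts[-k]
}

# internal mechanics of one creation attempt; returns NULL when the event
# is infeasible for the chosen template
attempt_create <- function(ts, gene, type, params, models, st) {
  if (type == "rs") {
    return(list(tx = sample_random_isoform(gene, models, st), gene = gene))
  }
  if (length(ts) == 0L) return(NULL)
  tpl <- ts[[sample.int(length(ts), 1L)]]
  tx <- new_transcript(st, tpl$exon_refs, tpl$adj5, tpl$adj3, tpl$retained)

  if (type %in% c("a5", "a3")) {
    side <- if (type == "a5") "adj5" else "adj3"
    step <- if (type == "a5") -1L else 1L  # relative segment index of intron
    cand <- Filter(function(e) {
      i <- segment_index(gene, e)
      j <- i + step
      j >= 1L && j <= length(gene$segments) &&
        gene$segments[[j]]$kind == "intron" &&
        !(gene$segments[[j]]$id %in% tpl$retained)
    }, tpl$exon_refs)
    if (!length(cand)) return(NULL)
    e <- sample_one(cand)
    i <- segment_index(gene, e)
    intr <- gene$segments[[i + step]]
    ilen <- length(intr$seq)
    elen <- length(get_segment(gene, e)$seq)
    cur <- tx_adj(tpl, side, e)
    other <- tx_adj(tpl, if (type == "a5") "adj3" else "adj5", e)
    # a sibling exon of the transcript may already extend into this intron
    kpos <- match(e, tpl$exon_refs)
    sib_ext <- 0L
    if (type == "a5" && kpos > 1L) {
      prev <- tpl$exon_refs[kpos - 1L]
      if (segment_index(gene, prev) == i - 2L) {
        sib_ext <- max(0L, tx_adj(tpl, "adj3", prev))
      }
    }
    if (type == "a3" && kpos < length(tpl$exon_refs)) {
      nxt <- tpl$exon_refs[kpos + 1L]
      if (segment_index(gene, nxt) == i + 2L) {
        sib_ext <- max(0L, tx_adj(tpl, "adj5", nxt))
      }
    }
    hi <- max_extension(ilen, sib_ext)
    lo <- -max_truncation(elen, max(0L, -other))
    mag <- 3L * (stats::rgeom(1L, 0.5) + 1L)
    shift <- sample(c(-1L, 1L), 1L) * mag
    val <- min(max(cur + shift, lo), hi)
    if (val == cur) return(NULL)
    tx <- set_tx_adj(tx, side, e, val)
    if (val > 0L) {
      # boundary moved into the intron: write a fresh valid splice-site
      # dinucleotide at the new boundary position in the gene sequence
      ss <- sample_splice_sites(models$splice, 1L)
      seg <- gene$segments[[i + step]]
      if (type == "a5") {
        pos <- (ilen - val - 1L):(ilen - val)
        seg$seq[pos] <- strsplit(ss$acceptor, "", fixed = TRUE)[[1]]
      } else {
        pos <- (val + 1L):(val + 2L)
        seg$seq[pos] <- strsplit(ss$donor, "", fixed = TRUE)[[1]]
      }
      gene$segments[[i + step]] <- seg
    }
    return(list(tx = tx, gene = gene, detail = sprintf("%s:%+d", e, val)))
  }

  if (type == "es") {
    if (length(tpl$exon_refs) < 2L) return(NULL)
    drop <- sample.int(length(tpl$exon_refs), 1L)
    e <- tpl$exon_refs[drop]
    tx$exon_refs <- tpl$exon_refs[-drop]
    tx$adj5 <- tx$adj5[setdiff(names(tx$adj5), e)]
    tx$adj3 <- tx$adj3[setdiff(names(tx$adj3), e)]
    tx <- drop_stale_retained(gene, tx)
    return(list(tx = tx, gene = gene, detail = e))
  }

  if (type == "me") {
    gex <- gene_exon_ids(gene)
    pairs <- which(gex[-length(gex)] %in% tpl$exon_refs !=
                     gex[-1L] %in% tpl$exon_refs)
    if (!length(pairs)) return(NULL)
    k <- sample_one(pairs)
    a <- gex[k]; b <- gex[k + 1L]
    inc <- if (a %in% tpl$exon_refs) a else b
    exc <- if (inc == a) b else a
    refs <- setdiff(tpl$exon_refs, inc)
    refs <- gex[sort(match(c(refs, exc), gex))]
    tx$exon_refs <- refs
    tx$adj5 <- tx$adj5[setdiff(names(tx$adj5), inc)]
    tx$adj3 <- tx$adj3[setdiff(names(tx$adj3), inc)]
    tx <- drop_stale_retained(gene, tx)
    return(list(tx = tx, gene = gene,
                detail = sprintf("%s->%s", inc, exc)))
  }

  if (type == "ir") {
    cand <- retainable_introns(gene, tpl)
    if (!length(cand)) return(NULL)
    id <- sample_one(cand)
    tx$retained <- c(tpl$retained, id)
    # boundary adjustments into a retained intron are void
    ii <- segment_index(gene, id)
    left <- gene$segments[[ii - 1L]]$id
    right <- gene$segments[[ii + 1L]]$id
    if (tx_adj(tx, "adj3", left) > 0L) tx <- set_tx_adj(tx, "adj3", left, 0L)
    if (tx_adj(tx, "adj5", right) > 0L) tx <- set_tx_adj(tx, "adj5", right, 0L)
    return(list(tx = tx, gene = gene, detail = id))
  }
  stopf("unknown transcript creation type '%s'", type)
}

# introns whose two flanking exons are consecutive exon_refs of the
# template and that are not yet retained
retainable_introns <- function(gene, tx) {
  out <- character(0)
  if (length(tx$exon_refs) < 2L) return(out)
  for (k in seq_len(length(tx$exon_refs) - 1L)) {
    i <- segment_index(gene, tx$exon_refs[k])
    j <- segment_index(gene, tx$exon_refs[k + 1L])
    if (j == i + 2L) {
      id <- gene$segments[[i + 1L]]$id
      if (!(id %in% tx$retained)) out <- c(out, id)
    }
  }
  out
}

drop_stale_retained <- function(gene, tx) {
  if (!length(tx$retained)) return(tx)
  tx$retained <- intersect(tx$retained, retainable_introns_all(gene, tx))
  tx
}

# like retainable_introns but including already-retained ones
retainable_introns_all <- function(gene, tx) {
  keep <- character(0)
  if (length(tx$exon_refs) < 2L) return(keep)
  for (k in seq_len(length(tx$exon_refs) - 1L)) {
    i <- segment_index(gene, tx$exon_refs[k])
    j <- segment_index(gene, tx$exon_refs[k + 1L])
    if (j == i + 2L) keep <- c(keep, gene$segments[[i + 1L]]$id)
  }
  keep
}

#' Create one transcript by a given mechanism
#'
#' Adds a new transcript with a fresh splicing-ortholog lineage to the set,
#' by random isoform selection (`"rs"`) or by applying one
#' alternative-splicing event (`"a5"`, `"a3"`, `"es"`, `"me"`, `"ir"`) to a
#' uniformly chosen template transcript. Duplicates of an existing
#' transcript are rejected and the event resampled (20 bounded retries,
#' then skipped with a logged warning). Alternative splice-site selection
#' may rewrite a dinucleotide of the gene's intron sequence (the new
#' boundary receives a valid splice site), so the possibly-updated gene is
#' returned alongside the set.
#'
#' @param ts list of transcripts.
#' @param gene the `gene_structure`.
#' @param type one of rs, a5, a3, es, me, ir.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @param phase event-log phase (`"root"` or `"transcript"`).
#' @param retries bound on duplicate/infeasibility resampling.
#' @return list with elements `ts`, `gene`, `ok`.
#' @export
create_transcript <- function(ts, gene, type, params = sim_params(),
                              models = build_default_models(), st = NULL,
                              node = "node", phase = "transcript",
                              retries = 20L) {
  if (is.null(st)) st <- new_sim_state(params, models)
  sigs <- ts_signatures(ts)
  for (attempt in seq_len(retries)) {
    res <- attempt_create(ts, gene, type, params, models, st)
    if (is.null(res)) next
    res$tx <- revalidate_transcript(res$gene, res$tx)
    if (is.null(res$tx) || tx_signature(res$tx) %in% sigs) next
    log_events(st, node, phase, paste0("transcript_create_", type),
               target = res$tx$transcript_id,
               detail = if (is.null(res$detail)) "" else res$detail)
    return(list(ts = c(ts, list(res$tx)), gene = res$gene, ok = TRUE))
  }
  log_events(st, node, phase, paste0("transcript_create_", type, "_skipped"),
             detail = "infeasible or duplicate after bounded retries")
  list(ts = ts, gene = gene, ok = FALSE)
}

# Re-impose the transcript invariants against the current gene: exon refs
# exist and are in gene order, offsets are clipped to the current segment
# lengths, retained introns still have both flanks consecutive. Returns
# NULL if the transcript no longer references any exon.
revalidate_transcript <- function(gene, tx) {
  gex <- gene_exon_ids(gene)
  tx$exon_refs <- tx$exon_refs[tx$exon_refs %in% gex]
  if (!length(tx$exon_refs)) return(NULL)
  tx$exon_refs <- gex[sort(match(tx$exon_refs, gex))]
  tx$adj5 <- tx$adj5[names(tx$adj5) %in% tx$exon_refs]
  tx$adj3 <- tx$adj3[names(tx$adj3) %in% tx$exon_refs]
  tx <- drop_stale_retained(gene, tx)
  for (k in seq_along(tx$exon_refs)) {
    e <- tx$exon_refs[k]
    i <- segment_index(gene, e)
    elen <- length(gene$segments[[i]]$seq)
    a5 <- tx_adj(tx, "adj5", e)
    a3 <- tx_adj(tx, "adj3", e)
    # 5' side
    if (a5 > 0L) {
      if (i == 1L || gene$segments[[i - 1L]]$id %in% tx$retained) {
        a5 <- 0L
      } else {
        sib <- 0L
        if (k > 1L) {
          prev <- tx$exon_refs[k - 1L]
          if (segment_index(gene, prev) == i - 2L) {
            sib <- max(0L, tx_adj(tx, "adj3", prev))
          }
        }
        a5 <- min(a5, max_extension(length(gene$segments[[i - 1L]]$seq), sib))
      }
    } else if (a5 < 0L) {
      a5 <- -min(-a5, max_truncation(elen, 0L))
    }
    # 3' side, given the (possibly clipped) 5' side
    if (a3 > 0L) {
      if (i == length(gene$segments) ||
          gene$segments[[i + 1L]]$id %in% tx$retained) {
        a3 <- 0L
      } else {
        a3 <- min(a3, max_extension(length(gene$segments[[i + 1L]]$seq), 0L))
      }
    } else if (a3 < 0L) {
      a3 <- -min(-a3, max_truncation(elen, max(0L, -a5)))
    }
    tx <- set_tx_adj(tx, "adj5", e, a5)
    tx <- set_tx_adj(tx, "adj3", e, a3)
  }
  tx
}

# apply revalidation across a set, dropping now-empty or duplicated
# transcripts (duplicates can arise from clipping after gene-level change)
revalidate_transcripts <- function(gene, ts, st = NULL, node = "node") {
  ts <- Filter(Negate(is.null), lapply(ts, revalidate_transcript,
                                       gene = gene))
  if (length(ts) < 2L) return(ts)
  sigs <- ts_signatures(ts)
  keep <- !duplicated(sigs)
  if (!all(keep) && !is.null(st)) {
    log_events(st, node, "transcript", "transcript_dedup",
               target = vapply(ts[!keep], `[[`, "", "transcript_id"))
  }
  ts[keep]
}

#' Evolve the transcript set along one branch
#'
#' First performs all transcript-loss events, then creation events per type
#' in the order rs, a5, a3, es, me, ir. The realized count of each type is
#' Poisson with expectation recomputed from the current transcript count
#' before each type's phase (`lambda_x = n * tc_x * k_tc * branch_len`).
#'
#' @param ts list of transcripts.
#' @param gene the `gene_structure`.
#' @param branch_len expected substitutions per codon on the branch.
#' @param params a [sim_params()].
#' @param models a `splice_models` bundle.
#' @param st a `sim_state`.
#' @param node node label for the event log.
#' @return list with elements `ts` and `gene`.
#' @export
evolve_transcripts <- function(ts, gene, branch_len, params = sim_params(),
                               models = build_default_models(), st = NULL,
                               node = "node") {
  if (!is_count(branch_len)) stopf("branch_len must be >= 0")
  if (is.null(st)) st <- new_sim_state(params, models)
  if (branch_len == 0) return(list(ts = ts, gene = gene))
  n_loss <- stats::rpois(1L, length(ts) * params$tc_tl * params$k_tc *
                           branch_len)
  for (dummy in seq_len(n_loss)) {
    if (length(ts) <= 1L) {
      log_events(st, node, "transcript", "transcript_loss_skipped",
                 detail = "single-transcript guard")
      break
    }
    ts <- apply_transcript_loss(ts, st, node)
  }
  for (type in c("rs", "a5", "a3", "es", "me", "ir")) {
    lam <- length(ts) * params[[paste0("tc_", type)]] * params$k_tc *
      branch_len
    cnt <- stats::rpois(1L, lam)
    for (dummy in seq_len(cnt)) {
      res <- create_transcript(ts, gene, type, params, models, st, node)
      ts <- res$ts
      gene <- res$gene
    }
  }
  list(ts = ts, gene = gene)
}

#' Exon status map
#'
#' Classifies every exon of the gene with respect to a transcript set:
#' absent (in no transcript), constitutive (in all transcripts) or
#' alternative (in some but not all).
#'
#' @param gene a `gene_structure`.
#' @param ts list of transcripts.
#' @return named character vector over exon ids.
#' @export
exon_status <- function(gene, ts) {
  ids <- gene_exon_ids(gene)
  cnt <- vapply(ids, function(e) {
    sum(vapply(ts, function(tx) e %in% tx$exon_refs, logical(1)))
  }, integer(1))
  status <- rep("alternative", length(ids))
  status[cnt == 0L] <- "absent"
  if (length(ts)) status[cnt == length(ts)] <- "constitutive"
  names(status) <- ids
  status
}
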