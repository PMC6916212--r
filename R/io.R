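# Readers/writers: Newick guide trees, FASTA (genes, cDNAs, true MSAs),
# GTF-like exon annotations, ortholog-group and event TSVs, config files,
# and the run manifest.

#' Parse a guide tree
#'
#' Accepts an `ape::phylo` object, a Newick string, or a path to a Newick
#' file. Branch lengths are required on every edge and interpreted as
#' expected substitutions per codon; they must be non-negative. Leaf
#' labels must be unique. Unnamed internal nodes are auto-labelled
#' deterministically (`n1`, `n2`, ... in ape node order). A bare label
#' with no parentheses (e.g. `"root;"`) denotes a single-node tree (root
#' only, no branches).
#'
#' @param x tree input.
#' @return a validated `phylo` object with node labels, or a
#'   `root_only_tree` for the single-node case.
#' @export
parse_guide_tree <- function(x) {
  if (inherits(x, "root_only_tree")) return(x)
  if (!inherits(x, "phylo")) {
    if (!is.character(x) || length(x) != 1L) {
      stopf("tree must be a phylo object, a Newick string or a file path")
    }
    txt <- if (file.exists(x) && !grepl("[();]", x)) {
      paste(readLines(x, warn = FALSE), collapse = "")
    } else x
    txt <- trimws(txt)
    if (!grepl("\\(", txt)) {
      lab <- sub(";.*$", "", txt)
      lab <- sub(":.*$", "", lab)
      if (!nzchar(lab)) stopf("cannot parse tree from '%s'", x)
      return(structure(list(label = lab), class = "root_only_tree"))
    }
    x <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
    if (is.null(x)) stopf("malformed Newick string: %s", txt)
  }
  if (is.null(x$edge.length) || anyNA(x$edge.length)) {
    stopf("guide tree must carry a branch length on every edge")
  }
  if (any(x$edge.length < 0)) stopf("negative branch length in guide tree")
  if (anyDuplicated(x$tip.label)) {
    stopf("duplicate leaf name(s): %s",
          paste(unique(x$tip.label[duplicated(x$tip.label)]),
                collapse = ", "))
  }
  nnode <- x$Nnode
  if (is.null(x$node.label) || !length(x$node.label)) {
    x$node.label <- paste0("n", seq_len(nnode))
  } else {
    empty <- !nzchar(x$node.label) | is.na(x$node.label)
    x$node.label[empty] <- paste0("n", which(empty))
  }
  x
}

msa_to_stringset <- function(msa) {
  Biostrings::BStringSet(msa)
}

#' Read a multi-FASTA alignment (or sequence set)
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_msa_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Read a clustering from TSV
#'
#' Two tab-separated columns: cluster/group id, item id (header optional,
#' detected from the ortholog-group writer's column names).
#'
#' @param path TSV file.
#' @return named character vector: item id -> cluster label.
#' @export
read_clusters_tsv <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(unname(tolower(unlist(d[1, ]))),
                c("group_id", "transcript_id"))) {
    d <- d[-1, , drop = FALSE]
  }
  stats::setNames(as.character(d[[1]]), as.character(d[[2]]))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(msa_to_stringset(seqs), path, width = 80L)
}

#' Write all simulation outputs to a directory
#'
#' Emits: `genes.fasta` (one record per leaf gene), `transcripts.fasta`
#' (id = `leaf:transcript`), `exons.gtf` (1-based inclusive exon
#' coordinates of each transcript on its gene, strand `+`),
#' `true_gene_msa.fasta` and `true_cdna_msa.fasta` (gap `-`),
#' `ortholog_groups.tsv`, `events.tsv` and `manifest.json` (parameters,
#' seed, versions).
#'
#' @param x a `splice_sim` result.
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing output files?
#' @return invisibly, the named vector of written file paths.
#' @export
write_outputs <- function(x, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genes = "genes.fasta", transcripts = "transcripts.fasta",
             gtf = "exons.gtf", gene_msa = "true_gene_msa.fasta",
             cdna_msa = "true_cdna_msa.fasta",
             groups = "ortholog_groups.tsv", events = "events.tsv",
             manifest = "manifest.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  if (!force && any(file.exists(paths))) {
    stopf("output files already exist in '%s' (use force = TRUE)", out_dir)
  }
  write_fasta(x$gene_sequences, paths["genes"])
  write_fasta(x$cdna_sequences, paths["transcripts"])

  gtf <- do.call(rbind, lapply(names(x$exon_tables), function(id) {
    b <- x$exon_tables[[id]]
    leaf <- sub(":.*$", "", id)
    data.frame(seqname = leaf, source = "splicesim", feature = "exon",
               start = b$start, end = b$end, score = ".", strand = "+",
               frame = ".",
               attributes = sprintf(
                 'gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                 leaf, id, seq_len(nrow(b))),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gtf, paths["gtf"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  write_fasta(x$gene_msa, paths["gene_msa"])
  write_fasta(x$cdna_msa, paths["cdna_msa"])

  groups <- do.call(rbind, lapply(names(x$ortholog_groups), function(g) {
    data.frame(group_id = g, transcript_id = x$ortholog_groups[[g]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(groups, paths["groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  utils::write.table(x$events, paths["events"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  manifest <- list(
    package = "splicesim",
    version = as.character(utils::packageVersion("splicesim")),
    r_version = R.version.string,
    seed = x$seed,
    params = unclass(x$params),
    leaves = names(x$leaves)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read a flat key-value config file into simulation parameters
#'
#' YAML mapping whose keys mirror [sim_params()] fields; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param base parameter set the file overrides.
#' @return a [sim_params()] object.
#' @export
read_config <- function(path, base = sim_params()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config file must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  args <- utils::modifyList(unclass(base), cfg)
  do.call(sim_params, args)
}
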