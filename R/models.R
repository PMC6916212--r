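# Generative models: codon Markov chains, intron nucleotide composition,
# splice-site distribution, length distributions, codon substitution matrix,
# indel length distribution.

.splicesim_cache <- new.env(parent = emptyenv())

#' Codon Markov chain model
#'
#' Three chained distributions used to emit one codon: `p1` over the first
#' position, `p2` over the second position given the first, and `p3` over
#' the third position given the first dinucleotide. Defaults are empirical
#' genome-wide codon-position frequencies from eukaryotic coding genes.
#'
#' @param p1 named length-4 probability vector (A,C,T,G).
#' @param p2 4x4 row-stochastic matrix, rows = first position.
#' @param p3 16x4 row-stochastic matrix, rows = first dinucleotide.
#' @return an object of class `codon_markov_model`.
#' @export
codon_markov_model <- function(p1 = NULL, p2 = NULL, p3 = NULL) {
  if (is.null(p1)) p1 <- c(A = 0.24, C = 0.31, T = 0.19, G = 0.25)
  if (is.null(p2)) {
    p2 <- rbind(
      A = c(0.21, 0.28, 0.21, 0.30),
      C = c(0.27, 0.38, 0.21, 0.14),
      T = c(0.12, 0.35, 0.20, 0.33),
      G = c(0.29, 0.30, 0.19, 0.22)
    )
    colnames(p2) <- NUCS
  }
  if (is.null(p3)) {
    p3 <- rbind(
      AA = c(0.16, 0.35, 0.13, 0.36),
      AC = c(0.22, 0.49, 0.14, 0.15),
      AT = c(0.02, 0.41, 0.14, 0.43),
      AG = c(0.12, 0.55, 0.20, 0.13),
      CA = c(0.09, 0.22, 0.12, 0.57),
      CC = c(0.26, 0.35, 0.28, 0.11),
      CT = c(0.07, 0.26, 0.12, 0.55),
      CG = c(0.17, 0.37, 0.20, 0.26),
      TA = c(0.01, 0.64, 0.34, 0.01),
      TC = c(0.20, 0.48, 0.20, 0.12),
      TT = c(0.10, 0.48, 0.22, 0.20),
      TG = c(0.05, 0.41, 0.30, 0.24),
      GA = c(0.21, 0.25, 0.18, 0.36),
      GC = c(0.15, 0.55, 0.18, 0.12),
      GT = c(0.08, 0.30, 0.16, 0.46),
      GG = c(0.19, 0.39, 0.13, 0.29)
    )
    colnames(p3) <- NUCS
  }
  # tables transcribed from rounded empirical frequencies can be off by
  # ~1e-2 in a row sum; renormalize proportionally, then validate strictly
  p1 <- normalize_rounded(rbind(p1), "codon chain p1")[1, ]
  p2 <- normalize_rounded(p2, "codon chain p2")
  p3 <- normalize_rounded(p3, "codon chain p3")
  m <- structure(list(p1 = p1, p2 = p2, p3 = p3),
                 class = "codon_markov_model")
  check_rows_sum_to_one(rbind(p1), "codon chain p1")
  check_rows_sum_to_one(p2, "codon chain p2")
  check_rows_sum_to_one(p3, "codon chain p3")
  m
}

#' Intron nucleotide model
#'
#' Zero-order Markov chain over A,C,T,G used to emit intron sequence;
#' defaults are empirical intron base frequencies.
#'
#' @param p0 named length-4 probability vector.
#' @return an object of class `intron_nucleotide_model`.
#' @export
intron_nucleotide_model <- function(p0 = c(A = 0.29, C = 0.20,
                                           T = 0.30, G = 0.21)) {
  check_rows_sum_to_one(rbind(p0), "intron nucleotide model")
  structure(list(p0 = p0), class = "intron_nucleotide_model")
}

#' Splice-site dinucleotide distribution
#'
#' Categories of (donor, acceptor) dinucleotide pairs flanking an intron.
#' The default is the empirical distribution: 98\% canonical GT-AG, 1\%
#' GC-AG, and 1\% any other pair (drawn uniformly among the remaining
#' dinucleotide pairs).
#'
#' @param p_gtag,p_gcag,p_other category probabilities (must sum to 1).
#' @return an object of class `splice_site_distribution`.
#' @export
splice_site_distribution <- function(p_gtag = 0.98, p_gcag = 0.01,
                                     p_other = 0.01) {
  prob <- c(`GT-AG` = p_gtag, `GC-AG` = p_gcag, other = p_other)
  check_rows_sum_to_one(rbind(prob), "splice-site distribution")
  structure(list(prob = prob), class = "splice_site_distribution")
}

# rows printed to 2 decimals may sum to 0.99/1.01; rescale proportionally
normalize_rounded <- function(m, what, tol = 0.02) {
  s <- rowSums(m)
  if (any(abs(s - 1) > tol)) {
    stopf("configuration error: rows of %s are too far from 1 (max dev %.3g)",
          what, max(abs(s - 1)))
  }
  m / s
}

# probability-table sanity check shared by all packaged models
check_rows_sum_to_one <- function(m, what, tol = 1e-9) {
  s <- rowSums(m)
  if (any(abs(s - 1) > tol)) {
    stopf("configuration error: rows of %s do not sum to 1 (max dev %.3g)",
          what, max(abs(s - 1)))
  }
  if (any(m < 0)) stopf("configuration error: %s has negative entries", what)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Length models: log-normal surrogates moment-matched to empirical
# (mean, std) pairs, discretized per kind, and (where discretization bias
# matters) recalibrated numerically so the discretized law itself has the
# target moments.

length_kinds <- c("exon_length", "intron_length",
                  "exons_per_transcript", "transcripts_per_gene")

length_kind_spec <- function(kind) {
  switch(kind,
    exon_length          = list(step = 3L, floor = 3L,  calibrate = TRUE),
    intron_length        = list(step = 1L, floor = 20L, calibrate = FALSE),
    exons_per_transcript = list(step = 1L, floor = 1L,  calibrate = TRUE),
    transcripts_per_gene = list(step = 1L, floor = 1L,  calibrate = TRUE),
    stopf("unknown length model kind '%s'", kind)
  )
}

lnorm_from_moments <- function(mean, std) {
  s2 <- log(1 + (std / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# support grid and pmf of the discretized log-normal
discretized_support <- function(mu, sigma, spec, q = 1e-10) {
  top <- stats::qlnorm(1 - q, mu, sigma)
  top <- max(spec$floor + 3 * spec$step, spec$step * ceiling(top / spec$step))
  seq(spec$floor, top, by = spec$step)
}

discretized_pmf <- function(mu, sigma, spec, support = NULL) {
  if (is.null(support)) support <- discretized_support(mu, sigma, spec)
  h <- spec$step / 2
  upper <- stats::plnorm(support + h, mu, sigma)
  lower <- stats::plnorm(support - h, mu, sigma)
  p <- upper - lower
  p[1] <- upper[1]                       # everything below the floor maps up
  p[length(p)] <- p[length(p)] + 1 - upper[length(p)]  # tail mass
  list(support = support, p = p)
}

discretized_moments <- function(mu, sigma, spec) {
  d <- discretized_pmf(mu, sigma, spec)
  m <- sum(d$support * d$p)
  v <- sum(d$support^2 * d$p) - m^2
  c(mean = m, std = sqrt(max(v, 0)))
}

calibrate_lnorm <- function(mean, std, spec) {
  start <- lnorm_from_moments(mean, std)
  obj <- function(par) {
    mo <- discretized_moments(par[1], exp(par[2]), spec)
    ((mo["mean"] - mean) / mean)^2 + ((mo["std"] - std) / std)^2
  }
  fit <- stats::optim(c(start$mu, log(start$sigma)), obj,
                      control = list(maxit = 500, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Length distribution model
#'
#' A log-normal surrogate for one of the four empirical length/count
#' distributions of gene architecture, parameterized by its target mean and
#' standard deviation and discretized according to its kind: exon lengths
#' are positive multiples of 3 (codon structure), intron lengths are
#' integers with a floor of 20 nt (room for both splice-site
#' dinucleotides), and the two counts are integers with a floor of 1. For
#' the discrete kinds the underlying log-normal is recalibrated numerically
#' so the realized moments of the discretized law match the targets.
#'
#' @param kind one of `"exon_length"`, `"intron_length"`,
#'   `"exons_per_transcript"`, `"transcripts_per_gene"`.
#' @param target_mean,target_std target moments; defaults are the packaged
#'   empirical values for the given kind.
#' @return an object of class `length_model`.
#' @examples
#' m <- length_model("exons_per_transcript")
#' mean(sample_length(m, 1e4))
#' @export
length_model <- function(kind, target_mean = NULL, target_std = NULL) {
  defaults <- list(
    exon_length          = c(170.36, 258.86),
    intron_length        = c(3730.30, 20126.39),
    exons_per_transcript = c(9.62, 8.54),
    transcripts_per_gene = c(1.45, 1.08)
  )
  spec <- length_kind_spec(kind)
  if (is.null(target_mean)) target_mean <- defaults[[kind]][1]
  if (is.null(target_std)) target_std <- defaults[[kind]][2]
  key <- sprintf("lm:%s:%.6g:%.6g", kind, target_mean, target_std)
  if (!is.null(.splicesim_cache[[key]])) return(.splicesim_cache[[key]])
  par <- if (spec$calibrate) {
    calibrate_lnorm(target_mean, target_std, spec)
  } else {
    lnorm_from_moments(target_mean, target_std)
  }
  m <- structure(list(kind = kind, target_mean = target_mean,
                      target_std = target_std, mu = par$mu,
                      sigma = par$sigma, step = spec$step,
                      floor = spec$floor),
                 class = "length_model")
  .splicesim_cache[[key]] <- m
  m
}

discretize_lengths <- function(x, model) {
  v <- as.integer(model$step * round(x / model$step))
  v[v < model$floor] <- model$floor
  v
}

#' Sample lengths or counts from a length model
#'
#' @param model a [length_model()].
#' @param n number of draws.
#' @return integer vector of `n` draws respecting the kind-specific
#'   constraints (multiples of 3 for exon lengths, floors for the rest).
#' @export
sample_length <- function(model, n = 1L) {
  discretize_lengths(stats::rlnorm(n, model$mu, model$sigma), model)
}

#' Probability mass function of a discretized length model
#'
#' Exact pmf of the discretized law on its support up to `max_value`,
#' renormalized. Used for truncated sampling (e.g. isoform sizes capped at
#' the gene's maximum exons per cDNA).
#'
#' @param model a [length_model()].
#' @param max_value upper truncation bound (inclusive).
#' @return list with integer `support` and probability vector `p`.
#' @export
length_pmf <- function(model, max_value) {
  spec <- list(step = model$step, floor = model$floor)
  support <- seq(model$floor, max(model$floor, model$step *
                                    floor(max_value / model$step)),
                 by = model$step)
  d <- discretized_pmf(model$mu, model$sigma, spec, support = support)
  # drop the tail-lump correction beyond the truncation point
  h <- model$step / 2
  d$p[length(d$p)] <- stats::plnorm(support[length(support)] + h, model$mu,
                                    model$sigma) -
    stats::plnorm(support[length(support)] - h, model$mu, model$sigma)
  d$p[1] <- stats::plnorm(support[1] + h, model$mu, model$sigma)
  d$p <- d$p / sum(d$p)
  d
}

# ---------------------------------------------------------------------------
# Codon substitution matrix

CODONS64 <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
CODONS64 <- sort(CODONS64)

codon_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

SENSE_CODONS <- CODONS64[codon_aa(CODONS64) != "*"]

#' Codon substitution matrix
#'
#' A 61x61 row-stochastic matrix over the sense codons giving the
#' probability that a substitution event converts one codon into another
#' (diagonal zero: an event always changes the codon). This is a synthetic
#' mechanistic surrogate for an empirical codon exchange matrix: the weight
#' of a change is `kappa` per transition (A<->G, C<->T), 1 per
#' transversion, damped by `multi_hit` for each nucleotide difference
#' beyond the first, and multiplied by `omega` when the amino acid changes
#' (purifying selection).
#'
#' @param kappa transition/transversion weight ratio.
#' @param omega nonsynonymous/synonymous weight ratio.
#' @param multi_hit damping factor per extra differing position.
#' @return a 61x61 matrix with codon dimnames, class
#'   `codon_substitution_matrix`.
#' @export
codon_substitution_matrix <- function(kappa = 2, omega = 0.2,
                                      multi_hit = 0.01) {
  key <- sprintf("csm:%g:%g:%g", kappa, omega, multi_hit)
  if (!is.null(.splicesim_cache[[key]])) return(.splicesim_cache[[key]])
  cods <- SENSE_CODONS
  n <- length(cods)
  aa <- codon_aa(cods)
  pos <- matrix(unlist(strsplit(cods, "")), ncol = 3, byrow = TRUE)
  w <- matrix(0, n, n, dimnames = list(cods, cods))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- pos[i, ] != pos[j, ]
      nd <- sum(diff)
      ts <- sum(is_transition(pos[i, diff], pos[j, diff]))
      wij <- kappa^ts * multi_hit^(nd - 1)
      if (aa[i] != aa[j]) wij <- wij * omega
      w[i, j] <- wij
    }
  }
  w <- w / rowSums(w)
  class(w) <- c("codon_substitution_matrix", class(w))
  .splicesim_cache[[key]] <- w
  w
}

#' Indel length distribution
#'
#' Truncated power law `P(len = k) ~ k^-alpha` over `1..max_len`, the
#' classic empirical shape of indel lengths. Units are codons inside exons
#' and nucleotides inside introns.
#'
#' @param max_len maximum indel length.
#' @param alpha power-law exponent.
#' @return an object of class `indel_length_model`.
#' @export
indel_length_model <- function(max_len = 10L, alpha = 1.7) {
  w <- (1:max_len)^(-alpha)
  structure(list(max_len = as.integer(max_len), alpha = alpha,
                 p = w / sum(w)),
            class = "indel_length_model")
}

sample_indel_length <- function(model, n = 1L) {
  sample.int(model$max_len, n, replace = TRUE, prob = model$p)
}

# ---------------------------------------------------------------------------

#' Build the packaged default generative models
#'
#' Returns all validated model objects with their packaged empirical
#' constants: the codon Markov chains, the intron nucleotide model, the
#' splice-site distribution, the four length models, the codon substitution
#' matrix and the indel length distribution. Deterministic (no sampling).
#'
#' @return a named list of class `splice_models` with elements `codon`,
#'   `intron`, `splice`, `exon_length`, `intron_length`,
#'   `exons_per_transcript`, `transcripts_per_gene`, `subst`, `indel`.
#' @examples
#' mods <- build_default_models()
#' mods$codon$p1
#' @export
build_default_models <- function() {
  m <- list(
    codon = codon_markov_model(),
    intron = intron_nucleotide_model(),
    splice = splice_site_distribution(),
    exon_length = length_model("exon_length"),
    intron_length = length_model("intron_length"),
    exons_per_transcript = length_model("exons_per_transcript"),
    transcripts_per_gene = length_model("transcripts_per_gene"),
    subst = codon_substitution_matrix(),
    indel = indel_length_model()
  )
  class(m) <- "splice_models"
  validate_models(m)
  m
}

#' Validate a `splice_models` bundle
#'
#' @param m a `splice_models` list as returned by [build_default_models()].
#' @return `m`, invisibly, or an error on an inconsistent table.
#' @export
validate_models <- function(m) {
  check_rows_sum_to_one(rbind(m$codon$p1), "codon chain p1")
  check_rows_sum_to_one(m$codon$p2, "codon chain p2")
  check_rows_sum_to_one(m$codon$p3, "codon chain p3")
  check_rows_sum_to_one(rbind(m$intron$p0), "intron nucleotide model")
  check_rows_sum_to_one(rbind(m$splice$prob), "splice-site distribution")
  check_rows_sum_to_one(unclass(m$subst), "codon substitution matrix")
  if (any(diag(m$subst) != 0)) {
    stopf("configuration error: substitution matrix diagonal must be 0")
  }
  if (is.unsorted(rev(m$indel$p))) {
    stopf("configuration error: indel length pmf must be non-increasing")
  }
  invisible(m)
}

#' Generate codons from the codon Markov chains
#'
#' Emits `n` codons: position 1 from `p1`, position 2 from `p2` given
#' position 1, position 3 from `p3` given the first dinucleotide. Stop
#' codons are not excluded (faithful sampling from the chains).
#'
#' @param model a [codon_markov_model()].
#' @param n number of codons.
#' @return character vector of `n` 3-letter codons.
#' @export
generate_codon <- function(model, n = 1L) {
  x1 <- sample_cat(model$p1, n)
  x2 <- character(n)
  for (b in NUCS) {
    idx <- which(x1 == b)
    if (length(idx)) x2[idx] <- sample_cat(model$p2[b, ], length(idx))
  }
  di <- paste0(x1, x2)
  x3 <- character(n)
  for (d in rownames(model$p3)) {
    idx <- which(di == d)
    if (length(idx)) x3[idx] <- sample_cat(model$p3[d, ], length(idx))
  }
  paste0(di, x3)
}

DINUCS16 <- as.vector(outer(NUCS, NUCS, paste0))

#' Sample splice-site dinucleotide pairs
#'
#' Draws (donor, acceptor) pairs from a [splice_site_distribution()]; the
#' "other" category draws a uniformly random pair that is neither GT-AG nor
#' GC-AG.
#'
#' @param dist a `splice_site_distribution`.
#' @param n number of pairs.
#' @return data.frame with character columns `donor` and `acceptor`.
#' @export
sample_splice_sites <- function(dist, n = 1L) {
  cat <- sample_cat(dist$prob, n)
  donor <- character(n)
  acceptor <- character(n)
  donor[cat == "GT-AG"] <- "GT"; acceptor[cat == "GT-AG"] <- "AG"
  donor[cat == "GC-AG"] <- "GC"; acceptor[cat == "GC-AG"] <- "AG"
  oth <- which(cat == "other")
  if (length(oth)) {
    pairs <- expand.grid(donor = DINUCS16, acceptor = DINUCS16,
                         stringsAsFactors = FALSE)
    keep <- !(pairs$donor == "GT" & pairs$acceptor == "AG") &
      !(pairs$donor == "GC" & pairs$acceptor == "AG")
    pairs <- pairs[keep, ]
    pick <- sample.int(nrow(pairs), length(oth), replace = TRUE)
    donor[oth] <- pairs$donor[pick]
    acceptor[oth] <- pairs$acceptor[pick]
  }
  data.frame(donor = donor, acceptor = acceptor, stringsAsFactors = FALSE)
}
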