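#' Simulation parameters
#'
#' Constructs the full set of user parameters controlling a simulation.
#' Rates are expressed relative to the codon substitution rate given by the
#' guide-tree branch lengths (a linear-rates model): along a branch of
#' length t (expected substitutions per codon), the expected number of
#' exon-intron structure change (EIC) events per exon is `k_eic * t`, the
#' expected number of transcript change (TC) events per transcript is
#' `k_tc * t`, and the expected number of indel events per codon is
#' `k_indel * t` (times `k_intron` inside introns, at nucleotide level).
#'
#' @param k_nbexons positive multiplier; the root gene carries
#'   `ceiling(k_nbexons * m)` exons where m is the sampled maximum number
#'   of exons per cDNA.
#' @param k_eic EIC events per exon per substitution.
#' @param k_tc TC events per transcript per substitution.
#' @param k_indel indel events per codon per substitution.
#' @param k_intron rate multiplier for intron sequence evolution.
#' @param eic_el,eic_eg,eic_ed relative frequencies of exon loss, gain and
#'   duplication (must sum to 1).
#' @param tc_rs,tc_a5,tc_a3,tc_es,tc_me,tc_ir,tc_tl relative frequencies of
#'   transcript creation by random isoform selection, alternative 5'/3'
#'   splice-site selection, exon skipping, mutually exclusive exons, intron
#'   retention, and of transcript loss (must sum to 1).
#' @param ci,cd relative frequencies of insertion vs deletion (sum to 1).
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$k_eic
#' @export
sim_params <- function(k_nbexons = 1.5,
                       k_eic = 5,
                       k_tc = 5,
                       k_indel = 0.1,
                       k_intron = 1.5,
                       eic_el = 0.4, eic_eg = 0.5, eic_ed = 0.1,
                       tc_rs = 0.05, tc_a5 = 0.1, tc_a3 = 0.1,
                       tc_es = 0.2, tc_me = 0.1, tc_ir = 0.05,
                       tc_tl = 0.4,
                       ci = 0.5, cd = 0.5) {
  p <- list(
    k_nbexons = k_nbexons, k_eic = k_eic, k_tc = k_tc,
    k_indel = k_indel, k_intron = k_intron,
    eic_el = eic_el, eic_eg = eic_eg, eic_ed = eic_ed,
    tc_rs = tc_rs, tc_a5 = tc_a5, tc_a3 = tc_a3, tc_es = tc_es,
    tc_me = tc_me, tc_ir = tc_ir, tc_tl = tc_tl,
    ci = ci, cd = cd
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' Validate a `sim_params` object
#'
#' Checks non-negativity of every rate and that each relative-frequency
#' block sums to one (within 1e-9).
#'
#' @param p a `sim_params` object.
#' @return `p`, invisibly, or an error.
#' @export
validate_sim_params <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0)) {
    stopf("all simulation parameters must be finite and >= 0")
  }
  if (p$k_nbexons < 1) stopf("k_nbexons must be >= 1")
  eic <- p$eic_el + p$eic_eg + p$eic_ed
  if (abs(eic - 1) > 1e-9) {
    stopf("eic_el + eic_eg + eic_ed must sum to 1 (got %.12f)", eic)
  }
  tc <- p$tc_rs + p$tc_a5 + p$tc_a3 + p$tc_es + p$tc_me + p$tc_ir + p$tc_tl
  if (abs(tc - 1) > 1e-9) {
    stopf("the seven tc_* frequencies must sum to 1 (got %.12f)", tc)
  }
  if (abs(p$ci + p$cd - 1) > 1e-9) {
    stopf("ci + cd must sum to 1 (got %.12f)", p$ci + p$cd)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (rates relative to codon substitution rate)\n")
  cat(sprintf("  k_nbexons=%g  k_eic=%g  k_tc=%g  k_indel=%g  k_intron=%g\n",
              x$k_nbexons, x$k_eic, x$k_tc, x$k_indel, x$k_intron))
  cat(sprintf("  EIC: el=%g eg=%g ed=%g\n", x$eic_el, x$eic_eg, x$eic_ed))
  cat(sprintf("  TC:  rs=%g a5=%g a3=%g es=%g me=%g ir=%g tl=%g\n",
              x$tc_rs, x$tc_a5, x$tc_a3, x$tc_es, x$tc_me, x$tc_ir, x$tc_tl))
  cat(sprintf("  indels: ci=%g cd=%g\n", x$ci, x$cd))
  invisible(x)
}
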