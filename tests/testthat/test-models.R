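# Generative model contracts: stochasticity of the packaged tables,
# law-of-large-numbers recovery of their cells, moment matching of the
# length surrogates, and the structural properties of the substitution and
# indel models.

test_that("packaged probability tables are row-stochastic within 1e-9", {
  mods <- build_default_models()
  expect_true(abs(sum(mods$codon$p1) - 1) < 1e-9)
  expect_true(all(abs(rowSums(mods$codon$p2) - 1) < 1e-9))
  expect_true(all(abs(rowSums(mods$codon$p3) - 1) < 1e-9))
  expect_true(abs(sum(mods$intron$p0) - 1) < 1e-9)
  expect_true(abs(sum(mods$splice$prob) - 1) < 1e-9)
  expect_true(all(abs(rowSums(mods$subst) - 1) < 1e-9))
  expect_true(all(diag(mods$subst) == 0))
  expect_error(codon_markov_model(p1 = c(A = 0.5, C = 0.1, T = 0.1,
                                         G = 0.1)),
               "configuration error")
  expect_error(intron_nucleotide_model(c(A = 1, C = 1, T = 0, G = 0)),
               "configuration error")
})

test_that("codon chain sampling recovers the packaged cell frequencies", {
  mods <- build_default_models()
  set.seed(101)
  n <- 2e5
  cod <- generate_codon(mods$codon, n)
  sd3 <- function(p, m) 3 * sqrt(p * (1 - p) / m)
  # position 1: P(A) ~ 0.24
  expect_lt(abs(mean(substr(cod, 1, 1) == "A") - 0.24), sd3(0.24, n) + 0.005)
  # position 2 given A: P(C|A) ~ 0.28
  withA <- cod[substr(cod, 1, 1) == "A"]
  expect_lt(abs(mean(substr(withA, 2, 2) == "C") - 0.28),
            sd3(0.28, length(withA)) + 0.005)
  # position 3 given TA: P(C|TA) ~ 0.64
  withTA <- cod[substr(cod, 1, 2) == "TA"]
  expect_lt(abs(mean(substr(withTA, 3, 3) == "C") - 0.64),
            sd3(0.64, length(withTA)) + 0.005)
  # stop codons are NOT excluded (faithful chain sampling)
  expect_gt(sum(cod %in% c("TAA", "TAG", "TGA")), 0)
})

test_that("intron base sampling recovers the packaged composition", {
  mods <- build_default_models()
  set.seed(102)
  n <- 2e5
  x <- sample(c("A", "C", "T", "G"), n, replace = TRUE,
              prob = mods$intron$p0)
  for (b in c("A", "C", "T", "G")) {
    p <- mods$intron$p0[[b]]
    expect_lt(abs(mean(x == b) - p), 3 * sqrt(p * (1 - p) / n) + 0.002)
  }
})

test_that("splice-site categories follow the 98/1/1 distribution", {
  set.seed(103)
  dist <- splice_site_distribution()
  ss <- sample_splice_sites(dist, 1e4)
  gtag <- mean(ss$donor == "GT" & ss$acceptor == "AG")
  gcag <- mean(ss$donor == "GC" & ss$acceptor == "AG")
  expect_lt(abs(gtag - 0.98), 3 * sqrt(0.98 * 0.02 / 1e4))
  expect_lt(abs(gcag - 0.01), 3 * sqrt(0.01 * 0.99 / 1e4))
  # the "other" category never produces the two named categories
  oth <- !(ss$donor == "GT" & ss$acceptor == "AG") &
    !(ss$donor == "GC" & ss$acceptor == "AG")
  expect_equal(mean(oth), 1 - gtag - gcag)
  # degenerate point mass
  one <- sample_splice_sites(splice_site_distribution(1, 0, 0), 100)
  expect_true(all(one$donor == "GT" & one$acceptor == "AG"))
})

test_that("length surrogates hit their target moments", {
  mods <- build_default_models()
  set.seed(104)
  n <- 3e5
  # analytic moments of the calibrated discretized laws are exact
  for (kind in c("exon_length", "exons_per_transcript",
                 "transcripts_per_gene")) {
    m <- mods[[kind]]
    mo <- splicesim:::discretized_moments(
      m$mu, m$sigma, list(step = m$step, floor = m$floor))
    expect_lt(abs(mo[["mean"]] / m$target_mean - 1), 0.005)
    expect_lt(abs(mo[["std"]] / m$target_std - 1), 0.005)
  }
  # the continuous intron surrogate has the target moments exactly
  mi <- mods$intron_length
  expect_equal(exp(mi$mu + mi$sigma^2 / 2), mi$target_mean, tolerance = 1e-6)
  # realized sample moments
  x <- sample_length(mods$exon_length, n)
  expect_true(all(x %% 3 == 0) && all(x >= 3))
  expect_lt(abs(mean(x) / 170.36 - 1), 0.02)
  expect_lt(abs(stats::sd(x) / 258.86 - 1), 0.05)
  y <- sample_length(mods$exons_per_transcript, n)
  expect_true(all(y >= 1))
  expect_lt(abs(mean(y) / 9.62 - 1), 0.02)
  z <- sample_length(mods$transcripts_per_gene, n)
  expect_lt(abs(mean(z) / 1.45 - 1), 0.02)
  w <- sample_length(mods$intron_length, n)
  expect_true(all(w >= 20))
  expect_lt(abs(mean(w) / 3730.30 - 1), 0.03)
})

test_that("truncated length pmf is proper and respects the cap", {
  m <- length_model("exons_per_transcript")
  d <- length_pmf(m, 7)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_true(all(d$support >= 1 & d$support <= 7))
  set.seed(105)
  draws <- d$support[sample.int(length(d$support), 1000, replace = TRUE,
                                prob = d$p)]
  expect_true(all(draws <= 7))
})

test_that("indel length model is a proper non-increasing distribution", {
  im <- indel_length_model()
  expect_equal(sum(im$p), 1, tolerance = 1e-12)
  expect_true(all(diff(im$p) <= 0))
  expect_equal(im$max_len, 10L)
  # normalization equals direct summation of unnormalized weights
  w <- (1:10)^(-1.7)
  expect_equal(im$p, w / sum(w), tolerance = 1e-12)
})

test_that("substitution matrix prefers synonymous single-hit transitions", {
  s <- codon_substitution_matrix()
  expect_equal(dim(unclass(s)), c(61L, 61L))
  expect_false(any(c("TAA", "TAG", "TGA") %in% rownames(s)))
  # synonymous transition beats nonsynonymous transversion from CTT
  expect_gt(s["CTT", "CTC"], s["CTT", "GTT"] / 1)
  # multi-nucleotide changes are strongly damped
  expect_gt(s["AAA", "AAG"], s["AAA", "TTT"])
})
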