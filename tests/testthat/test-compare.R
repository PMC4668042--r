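test_that("collapsing homographs sums frequencies per form", {
  lex <- demo_lexicon()
  fl <- collapse_homographs(lex)
  # ativa: adj 20 + nom 8 + ver 6
  expect_equal(fl$freqs[fl$forms == "ativa"], 34)
  expect_equal(fl$freqs[fl$forms == "cachorro"], 397)
  expect_lte(length(fl$forms), lex$type_total)
  expect_equal(sum(fl$freqs), lex$token_total)
  # a homograph-free lexicon collapses to itself
  df <- data.frame(orthography = c("um", "dois"), gram_cat = "num",
                   ortho_freq = c(5L, 2L))
  lex2 <- assemble_lexicon(df, seed = 1)
  fl2 <- collapse_homographs(lex2)
  expect_setequal(fl2$freqs, c(5, 2))
})

test_that("alignment keeps forms attested (> 0) in every corpus", {
  a <- corpus_freq_list("a", c("a", "b", "c"), c(1, 2, 0))
  b <- corpus_freq_list("b", c("a", "b", "c"), c(3, 0, 5))
  al <- align_corpora(list(a, b))
  expect_equal(al$form, "a")
  expect_equal(al$a, 1); expect_equal(al$b, 3)
  disjoint <- align_corpora(list(
    corpus_freq_list("x", "um", 1), corpus_freq_list("y", "dois", 1)))
  expect_equal(nrow(disjoint), 0L)
  same <- align_corpora(list(a, a))
  expect_equal(nrow(same), 2L)   # c has frequency 0
})

test_that("Zipf-scale correlations are scale-invariant and symmetric", {
  set.seed(53)
  f <- sort(rpois(50, 40) + 1, decreasing = TRUE)
  a <- corpus_freq_list("a", paste0("w", 1:50), f)
  b <- corpus_freq_list("b", paste0("w", 1:50), f * 17)  # scaled copy
  al <- align_corpora(list(a, b))
  totals <- c(a = a$token_total, b = b$token_total)
  r <- zipf_correlation(al, totals)
  expect_equal(dim(r), c(2L, 2L))
  expect_equal(diag(r), c(a = 1, b = 1))
  expect_equal(r[1, 2], 1)                    # affine invariance
  expect_equal(r, t(r))
  expect_true(all(r >= -1 & r <= 1))
  # hand-computed Pearson on a 5-form pair
  fa <- c(100, 50, 20, 10, 5); fb <- c(90, 60, 25, 8, 6)
  ca <- corpus_freq_list("ca", paste0("v", 1:5), fa)
  cb <- corpus_freq_list("cb", paste0("v", 1:5), fb)
  al2 <- align_corpora(list(ca, cb))
  r2 <- zipf_correlation(al2, c(ca = sum(fa), cb = sum(fb)))
  za <- log10(fa / sum(fa) * 1e6) + 3
  zb <- log10(fb / sum(fb) * 1e6) + 3
  hand <- sum((za - mean(za)) * (zb - mean(zb))) /
    sqrt(sum((za - mean(za))^2) * sum((zb - mean(zb))^2))
  expect_equal(unname(r2[1, 2]), hand, tolerance = 1e-12)
  expect_error(zipf_correlation(al2[1:2, ], c(ca = 1, cb = 1)), "3")
})

test_that("Fisher r-to-z contrasts follow the closed form", {
  expect_equal(fisher_rz_contrast(0.5, 100, 0.5, 200), 0)
  expect_equal(fisher_rz_contrast(0.8, 50, 0.6, 70),
               -fisher_rz_contrast(0.6, 70, 0.8, 50))
  # direct evaluation of the formula as oracle
  z <- (atanh(0.8) - atanh(0.7)) / sqrt(1 / (45968 - 3) * 2)
  expect_equal(fisher_rz_contrast(0.8, 45968, 0.7, 45968), z)
  expect_equal(round(z, 2), 35.07)
  expect_error(fisher_rz_contrast(1, 10, 0.5, 10), "strictly")
  expect_error(fisher_rz_contrast(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("containment percentages follow the shared-type identity", {
  a <- corpus_freq_list("A", c("a", "b", "c"), c(1, 1, 1))
  b <- corpus_freq_list("B", c("b", "c", "d"), c(1, 1, 1))
  m <- containment_matrix(list(a, b))
  expect_equal(diag(m), c(A = 100, B = 100))
  expect_equal(m["A", "B"], 100 * 2 / 3, tolerance = 1e-12)
  # cell(A,B) |A| = cell(B,A) |B| = 100 |A ∩ B|
  expect_equal(m["A", "B"] * 3, m["B", "A"] * 3)
  expect_equal(m["A", "B"] * 3, 100 * 2)
  expect_error(containment_matrix(list(a)), "two corpora")
})

test_that("discrepancy lists rank absent forms by frequency", {
  a <- corpus_freq_list("A", c("x", "y"), c(100, 1))
  b <- corpus_freq_list("B", c("y", "z"), c(50, 9))
  d <- estimation_discrepancies(a, b, k = 1)
  expect_equal(d$overestimated$form, "x")
  expect_equal(d$underestimated$form, "z")
  expect_equal(d$overestimated$zipf_scale,
               zipf_scale(100, a$token_total))
  same <- estimation_discrepancies(a, a)
  expect_equal(nrow(same$overestimated), 0L)
  expect_equal(nrow(same$underestimated), 0L)
  big <- estimation_discrepancies(
    corpus_freq_list("A", paste0("a", 1:20), 20:1),
    corpus_freq_list("B", "zzz", 5), k = 10)
  expect_equal(big$overestimated$form, paste0("a", 1:10))
  expect_true(all(diff(big$overestimated$freq) <= 0))
})

test_that("correlation decays with independent log-normal noise", {
  base <- 1e5 * (1:300)^-1
  rs <- vapply(c(0.1, 0.5, 1.2), function(sigma) {
    mean(vapply(1:3, function(s) {
      set.seed(s)
      fa <- pmax(1, round(base * exp(rnorm(300, 0, sigma))))
      fb <- pmax(1, round(base * exp(rnorm(300, 0, sigma))))
      a <- corpus_freq_list("a", paste0("w", 1:300), fa)
      b <- corpus_freq_list("b", paste0("w", 1:300), fb)
      al <- align_corpora(list(a, b))
      zipf_correlation(al, c(a = a$token_total,
                             b = b$token_total))[1, 2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_gt(rs[1], 0.95)
})

test_that("distribution profiles filter outliers and partition types", {
  lists <- demo_frequency_lists()
  long_word <- data.frame(orthography = strrep("z", 21),
                          gram_cat = "nom", ortho_freq = 2L)
  lex <- assemble_lexicon(c(lists, list(extra = long_word)), seed = 8)
  prof <- distribution_profile(lex)
  expect_equal(prof$n_kept, lex$type_total - 1L)
  expect_equal(prof$removed_fraction, 1 / lex$type_total)
  expect_equal(sum(prof$types_by_category$types), prof$n_kept)
  expect_equal(sum(prof$types_by_length_category$types), prof$n_kept)
  # thresholds at infinity keep everything
  all_in <- distribution_profile(lex, profile_thresholds(Inf, Inf, Inf, Inf))
  expect_equal(all_in$removed_fraction, 0)
  expect_equal(all_in$n_kept, lex$type_total)
  # rank-frequency arrays are per-category and log-scaled
  rf <- prof$rank_frequency
  expect_true(all(rf$log10_rank >= 0))
  nom <- rf[rf$gram_cat == "nom", ]
  expect_equal(nrow(nom),
               sum(prof$types_by_category$types[
                 prof$types_by_category$gram_cat == "nom"]))
})
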