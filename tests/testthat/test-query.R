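test_that("simple search folds case and accents and reports misses", {
  lex <- demo_lexicon()
  res <- simple_search(c("cachorro", "zzzz"), lex)
  expect_equal(unique(res$rows$orthography), "cachorro")
  expect_equal(res$unmatched, "zzzz")
  expect_equal(simple_search("CASA", lex)$total_found, 1L)
  expect_equal(simple_search("apos", lex)$rows$orthography, "após")
  expect_equal(simple_search("apos", lex, strict = TRUE)$total_found, 0L)
  expect_error(simple_search(character(0), lex), "empty")
})

test_that("wildcards: _ is exactly one character, % any chain", {
  fixture <- c("amor", "anos", "aloe", "após", "amora", "ama")
  expect_equal(fixture[match_pattern("a_o_", fixture)],
               c("amor", "anos", "aloe", "após"))
  fixture2 <- c("amor", "ama", "amei", "amava", "casa")
  expect_equal(fixture2[match_pattern("am%", fixture2)],
               c("amor", "ama", "amei", "amava"))
  expect_true(all(match_pattern("%", fixture)))
  # no wildcards degenerates to folded equality
  expect_equal(match_pattern("após", c("apos", "APÓS", "aposs")),
               c(TRUE, TRUE, FALSE))
  expect_equal(match_pattern("após", c("apos", "após"), strict = TRUE),
               c(FALSE, TRUE))
})

test_that("Table-style searches return the documented sets", {
  lex <- demo_lexicon()
  a_o <- complex_search(criterion("orthography", "a_o_"), lex)
  expect_setequal(a_o$rows$orthography, c("amor", "anos", "aloe", "após"))
  am <- complex_search(criterion("orthography", "am%"), lex)
  expect_true(all(c("amor", "ama", "amei", "amava") %in%
                    am$rows$orthography))
  short <- complex_search(criterion("nb_letters", "< 5"), lex)
  expect_true(all(short$rows$nb_letters <= 4))
  expect_equal(short$total_found,
               sum(lex$entries$nb_letters < 5))
  band <- complex_search(criterion("ortho_freq", "< 10 > 6"), lex)
  expect_setequal(unique(band$rows$ortho_freq), c(7L, 8L, 9L))
  expect_equal(band$total_found,
               sum(lex$entries$ortho_freq %in% 7:9))
})

test_that("criteria combine as AND; exclude negates; off disables", {
  lex <- demo_lexicon()
  crits <- list(criterion("orthography", "ama%"),
                criterion("nb_letters", "< 5"),
                criterion("orthography", "%-%", mode = "exclude"))
  res <- complex_search(crits, lex, order_by = "orthography")
  brute <- oracle_filter(crits, lex)
  expect_setequal(res$rows$orthography, brute$orthography)
  off <- complex_search(list(criterion("orthography", "am%"),
                             criterion("nb_letters", "< 4", mode = "off")),
                        lex)
  on <- complex_search(criterion("orthography", "am%"), lex)
  expect_equal(off$total_found, on$total_found)
  expect_error(complex_search(criterion("no_such_col", "x"), lex),
               "unknown column")
  expect_error(complex_search(criterion("nb_letters", "about 5"), lex),
               "malformed range")
})

test_that("complex search equals a brute-force filter on random criteria", {
  spec <- synthetic_spec(n_types = 400, seed = 2024)
  lex <- assemble_lexicon(do.call(rbind, generate_synthetic_lexicon(spec)),
                          seed = 5)
  set.seed(77)
  pats <- c("a%", "%a", "b_%", "%an%", "_a%", "t%")
  num_cols <- c("nb_letters", "ortho_freq", "zipf_scale", "ortho_neigh")
  for (i in 1:60) {
    crits <- list(
      criterion("orthography", sample(pats, 1),
                mode = sample(c("include", "exclude"), 1)),
      criterion(sample(num_cols, 1),
                sprintf("< %d > %d", sample(5:40, 1), sample(0:4, 1))))
    res <- complex_search(crits, lex)
    brute <- oracle_filter(crits, lex)
    expect_equal(sort(res$all_rows$id), sort(brute$id))
  }
})

test_that("ordering is total and paging partitions the result", {
  lex <- demo_lexicon()
  res <- complex_search(criterion("orthography", "%"), lex,
                        order_by = "orthography")
  expect_equal(res$total_found, lex$type_total)
  pages <- lapply(1:ceiling(lex$type_total / 10), function(p) {
    complex_search(criterion("orthography", "%"), lex,
                   order_by = "orthography", page = p, page_size = 10L)
  })
  expect_true(all(vapply(pages, function(p) p$total_found,
                         integer(1)) == res$total_found))
  stitched <- do.call(rbind, lapply(pages, `[[`, "rows"))
  expect_equal(stitched$id, res$rows$id)
  expect_true(all(vapply(pages, function(p) nrow(p$rows), integer(1)) <= 10))
})

test_that("result statistics give exact max/min/mean of the result", {
  lex <- demo_lexicon()
  one <- simple_search("cachorro", lex)
  s1 <- result_statistics(one)
  expect_equal(s1$max, s1$min)
  expect_equal(s1$max, s1$mean)
  two <- simple_search(c("amor", "cachorro"), lex)
  s2 <- result_statistics(two)
  nb <- s2[s2$column == "nb_letters", ]
  expect_equal(nb$mean, 6)   # 4 and 8 letters
  expect_equal(nb$max, 8); expect_equal(nb$min, 4)
  # independent recomputation over the result rows
  fr <- s2[s2$column == "ortho_freq", ]
  expect_equal(fr$mean, mean(two$rows$ortho_freq))
  empty <- complex_search(criterion("orthography", "zzzz%"), lex)
  expect_equal(nrow(result_statistics(empty)), 0L)
})

test_that("CSV export writes all rows with quoting that round-trips", {
  lex <- demo_lexicon()
  res <- complex_search(criterion("orthography", "ativa"), lex,
                        page = 1L, page_size = 1L)
  expect_equal(nrow(res$rows), 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(res, path)
  back <- utils::read.csv(path, check.names = FALSE,
                          fileEncoding = "UTF-8")
  # all three homographs exported despite the one-row page
  expect_equal(nrow(back), 3L)
  expect_equal(names(back), lexicon_columns())
  # comma-bearing fields survive RFC 4180 quoting
  expect_equal(unique(back$homographs), "adj, nom, ver")
  empty <- complex_search(criterion("orthography", "zzzz%"), lex)
  export_csv(empty, path)
  expect_equal(nrow(utils::read.csv(path, check.names = FALSE)), 0L)
})

test_that("lexicon CSV round-trips through write and read", {
  lex <- demo_lexicon()
  path <- withr::local_tempfile(fileext = ".csv")
  write_lexicon_csv(lex, path)
  back <- read_lexicon_csv(path)
  expect_equal(back$entries$orthography, lex$entries$orthography)
  expect_equal(back$entries$ortho_freq, lex$entries$ortho_freq)
  expect_equal(back$token_total, lex$token_total)
  expect_equal(back$entries$old20, lex$entries$old20)
})
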