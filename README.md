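# psycholex

Construction and analysis of psycholinguistic lexical databases in R.

Researchers selecting word stimuli need, for every word, the variables
that drive lexical processing: raw and standardized frequency, length,
orthographic structure, neighborhood density, homography. `psycholex`
builds such a database from POS-tagged word-frequency lists (plain text,
one `form count` line per entry, one file per grammatical category) and
provides the query, pseudoword and cross-corpus tooling a word-norm
database is used with.

## What it computes

For each entry the package derives 25 variables:

* **Frequency**: per-million frequency `10^6 f / N`; `log10 f`; the Zipf
  scale `log10(f per million) + 3` (a corpus-size-independent 1–7 scale);
  the dense Zipf rank (tied frequencies share a rank, ranks run 1..K).
* **Structure**: letter count; CVCV consonant/vowel coding (`cachorro` →
  `CVCCVCCV`); bounded bigram/trigram decompositions over `#word#`
  (`#c_ca_ac_ch_ho_or_rr_ro_o#`); their reversals; word-level bigram and
  trigram frequencies summed from positional type-count tables.
* **Corpus-relative**: orthographic uniqueness point; Coltheart's N
  (same-length forms at Hamming distance 1); OLD20 (mean Levenshtein
  distance to the 20 closest forms); homograph count and categories.
* **Bookkeeping**: suffix-rule grammatical information, a seeded random
  number for stimulus randomization, and the identity/rank column.

Around the lexicon sit two search engines (word lists; multi-criterion
with `_`/`%` wildcards and `< x > y` open intervals), result statistics
and CSV export, positional n-gram tables with TSV export, a pseudoword
generator that chain-samples attested positional n-grams per category,
a synthetic Zipfian lexicon generator, and cross-corpus comparison
(Zipf-scale Pearson correlations, Fisher r-to-z contrasts, containment
matrices, over/under-estimation lists, distribution profiles).

## Worked example

```r
library(psycholex)

lex <- assemble_lexicon(demo_frequency_lists(), seed = 42)
print(lex)
#> Lexicon: 35 word types, 4,041 word tokens
#>   adj         4 types           69 tokens
#>   adv         2 types           73 tokens
#>   gram        4 types        2,900 tokens
#>   nom        16 types          825 tokens
#>   num         2 types           36 tokens
#>   ver         7 types          138 tokens

e <- lex$entries
e[e$orthography == "cachorro",
  c("gram_cat", "ortho_freq", "nb_letters", "cvcv_ortho", "bigrams")]
#>  gram_cat ortho_freq nb_letters cvcv_ortho                    bigrams
#>       nom        397          8   CVCCVCCV #c_ca_ac_ch_ho_or_rr_ro_o#
```

The per-million and Zipf values above are relative to this 4,041-token
demo corpus; against a reference total they reproduce the printed norms:

```r
zipf_scale(397, 30705945)    # 4.1116
per_million(397, 31377670)   # 12.6523
```

Search with wildcards (`_` = exactly one character, `%` = any chain;
case- and accent-insensitive) and numeric ranges, then get statistics:

```r
res <- complex_search(list(criterion("orthography", "a%"),
                           criterion("nb_letters", "< 6")), lex,
                      order_by = "orthography")
res
#> Search result: 12 entries found
result_statistics(res)
#>            column      max    min      mean
#>        ortho_freq 300.0000 6.0000 60.333333
#>  log10_ortho_freq   2.4771 0.7782  1.399525
#>        zipf_scale   7.8706 6.1717  6.793042
#>       bigram_freq  17.0000 5.0000 10.583333
#>      trigram_freq   9.0000 3.0000  5.666667
#>        nb_letters   5.0000 3.0000  4.250000
#>       ortho_neigh   0.0000 0.0000  0.000000
#>             old20   3.9500 2.4500  3.370833
export_csv(res, "selection.csv")   # all matching rows, 25 columns
```

Generate noun-like pseudowords from the lexicon's positional bigrams:

```r
tab <- build_ngram_table(lex, 2)
cfg <- pseudoword_config("nom", count = 5, length_min = 4,
                         length_max = 8, seed = 7)
generate_pseudowords(cfg, tab, lex)
#> [1] "guara" "deda"  "guar"  "alor"  "anoe"
```

Every output is absent from the lexicon and uses only attested
position-specific n-grams, so the strings are wordlike but novel.

A thin command-line front end over the same functions ships in
`inst/cli/lexicon.R` (subcommands `build`, `search`, `ngrams`, `pseudo`,
`simulate`, `compare`).

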