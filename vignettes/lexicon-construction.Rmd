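---
title: "Building psycholinguistic lexicons from POS-tagged frequency lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building psycholinguistic lexicons from POS-tagged frequency lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psycholex)
```

## What the package computes

Psycholinguistic experiments need stimulus words controlled for frequency,
length, orthographic structure and neighborhood density. Given POS-tagged
word-frequency lists (one plain-text file per grammatical category, each
line a form and a raw count), `psycholex` assembles a lexicon with 25
variables per entry and exposes the search, pseudoword-generation and
cross-corpus comparison machinery a word-norm database is used for.

The pipeline is:

1. **Ingest** (`read_frequency_list`, `normalize_and_merge`,
   `filter_entries`): entries are lower-cased; case variants that collide
   within a category are merged with *summed* frequencies, so the corpus
   token total is conserved (dropping the duplicate counts instead would
   silently shrink the corpus). Entries longer than 30 characters are
   removed, as are entries containing digits — except the single digits
   0–9 and the ordinals 1º–9º/1ª–9ª when tagged as adjective, noun or
   numeral. An entry is treated as "numeric" as soon as it contains any
   digit; the whitelist is exactly the stated exception list.
2. **Assembly** (`assemble_lexicon`): entries are sorted by descending raw
   frequency and, within ties, by orthography; `id` is the resulting rank.
3. **Derived columns**: frequency transforms, orthographic structure,
   corpus-relative neighborhood measures, positional n-gram sums, a seeded
   uniform random number (8 decimals, for stimulus randomization).

## Frequency transforms

For raw count $f$ and corpus token total $N$:

* per-million frequency $f_M = 10^6 f / N$,
* common logarithm $\log_{10} f$,
* Zipf scale $z = \log_{10}(f_M) + 3$, a corpus-size-independent scale on
  which values below 3 are low-frequency and above 4 high-frequency words,
* Zipf rank: *dense* ranking by descending frequency — tied frequencies
  share a rank and ranks run exactly $1..K$ over the $K$ distinct
  frequency values. Dense ranking (rather than competition ranking) is the
  only scheme consistent with "the second most frequent word has rank 2
  while equal frequencies share a rank".

Transforms are defined for attested words only; a zero count is an error,
not a smoothing case. Reported values are stored at 4 decimals (matching
the precision word-norm databases print), computed from full precision.
`zipf_scale - log10_ortho_freq` equals $9 - \log_{10} N$ for every entry,
which the tests use as a lexicon-wide invariant.

A note on totals: the per-million column always divides by the assembled
lexicon's own token total. When reproducing published reference values,
mind which total the source used — a value computed before outlier
filtering reflects the pre-filter total, and `per_million(freq, total)`
takes the total explicitly for that reason.

## Orthographic structure

`nb_letters` counts *all* characters, hyphen included: the bigram-count
identity (a word of $L$ letters has $L+1$ bigrams and $L$ trigrams over
its bounded form `#word#`) and the presence of a punctuation class in the
structural alphabet both force this convention. CVCV coding maps each
character to consonant/vowel/number/accented/punctuation/symbol classes;
the mapping is a configurable table (`cvcv_default_mapping()`) with
accented vowels as their own class `A`, so "até" codes as `VCA`.
Decomposition always slides over the bounded string, so a 1-letter word
has 2 bigrams and the single trigram `#a#` — degenerate cases stay
continuous with the general rule.

Positional n-gram tables (`build_ngram_table`) count **word types** per
(category, position, n-gram) cell; token frequencies are deliberately
ignored, so one hapax and one 10,000-count word contribute equally to the
sub-lexical statistics. `word_ngram_frequency` sums a word's cells; since
it is not documented which marginal the original word-level sums used,
the positional, category-specific sum is the default and `collapse =
"position"/"category"/"both"` expose the marginals.

## Corpus-relative measures

These operate on the pooled set of *distinct* orthographic forms across
categories: a homograph is not its own neighbor.

* **Uniqueness point**: the smallest prefix length shared with no other
  form. A form that is a prefix of another form never becomes unique and
  receives `nb_letters + 1`, keeping the column numeric and ordered
  rather than introducing a sentinel. The implementation uses the
  sorted-neighbor longest-common-prefix bound and is oracle-tested
  against brute-force prefix comparison.
* **Coltheart's N**: same-length forms at Hamming distance exactly 1,
  counted via position-masked hashing (each neighbor pair shares exactly
  one masked key), oracle-tested against exhaustive enumeration.
* **OLD20**: mean unit-cost Levenshtein distance to the 20 closest other
  forms (`utils::adist` supplies the distances; ties at the 20th distance
  are resolved on the distance multiset, and fewer than 20 other forms
  are simply all averaged).

## Search engines

The word-list search and the multi-criterion search both fold case and
accents by default ("apos" finds "após"); a strict byte-wise mode exists.
In patterns, `_` matches **exactly one** character and `%` any chain: the
documented example output for `a_o_` contains only 4-letter words, which
rules out a one-or-more reading of `_`. Numeric criteria use strict
inequalities, with `"< x > y"` an open interval. Criteria combine as AND;
the exclude mode negates a criterion, and an `"off"` mode disables it
(the interface wording "whether a criterion should be considered" is
ambiguous between the two, so both exist). Results order under a fixed,
locale-independent collation — letters a–z, then digits, then hyphen,
accents collating with their base letter, remaining ties by code point —
so rebuilding a lexicon from shuffled input reproduces identical ids.
Statistics (max/min/mean of eight numeric columns) and CSV export always
cover the full result, not the displayed page.

## Pseudoword generation

No published description of the original engine's algorithm exists beyond
its inputs (positional n-gram structure and frequency per category), so
the generator here is the simplest process honoring those constraints,
and is documented as this package's own design: left-to-right chain
sampling over position-indexed windows of `#word#`. A chain starts at a
word-initial window, extends with windows attested at the next position
that overlap the current suffix (weights proportional to positional type
counts, or uniform for stimulus balancing), and terminates only on a
word-final window within the length bounds. Rejection sampling enforces
novelty (no lexicon collisions, no duplicates) with a budget of
`1000 × count` attempts; exhaustion returns the partial list with a
warning attribute rather than failing. Every output therefore has all
positional n-grams attested — including its boundary n-grams — and a
positive `ngram_legality` score.

## Cross-corpus comparison

External corpora are untagged, so the lexicon is first homograph-collapsed
(frequencies summed per form). Alignment keeps forms attested (> 0) in
every corpus; matching is exact after lower-casing with accents preserved,
because accent-folding across corpora would manufacture spurious overlap.
Correlations are Pearson on Zipf-scale values, each corpus scaled by its
own token total (for external lists the sum of counts, unless an explicit
total is supplied). Correlation differences use the independent-samples
Fisher r-to-z contrast $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$; a dependent-correlation variant (the
correlations share one corpus) is out of scope. Containment cell (A, B)
is the percentage of A's types present in B, so
$\mathrm{cell}(A,B)\,|A| = \mathrm{cell}(B,A)\,|B|$. Distribution
profiles apply the outlier filters (over 20 letters, over 40 neighbors,
OLD20 over 14, over 5 homographs — all configurable) before tabulating.

## The synthetic generator

`generate_synthetic_lexicon` emulates the rank-frequency shape of a real
lexicon: $f(r) = \max(1, \mathrm{round}(f_1 r^{-s}))$ with top frequency
$f_1 = 10^5$ by default, so rounding never flattens the law at the scales
used here. Forms are random consonant-vowel alternating strings (lengths
a rounded normal, mean 7, sd 2.5, clipped to 2–14 — the unimodal 7–8
letter mode typical of Romance lexicons), so CVCV coding and n-gram
chains are exercised realistically; a uniform-letter mode exists. The
category mix defaults to verbs 45%, nouns 34%, adjectives 19% and rare
closed classes, mirroring the asymmetry of POS-tagged corpora. What the
generator does *not* emulate: real morphology, genre composition,
accents/hyphens in generated forms, and any corpus-specific value — so
passing tests demonstrate algorithmic correctness on realistic shapes,
not agreement with any particular language's norms.

`demo_frequency_lists()` is the deterministic fixture embedding the
classic worked examples ("cachorro" at 397, the three-way homograph
"ativa", the wildcard demonstration sets). Corpus-relative reference
values of the full source corpus (uniqueness point 8, N = 2, OLD20 = 1.75
for "cachorro") depend on all 200k+ types and are intentionally not
reproduced by any fixture-scale object.

## Numerical choices and problem sizes

* Half-even rounding (R's `round`) at 4 decimals for reported transforms,
  8 for the random column.
* The random column draws from one seeded generator in id order, so a
  rebuild with the same seed is bit-identical.
* Oracle tests run Coltheart's N and OLD20 against brute-force
  enumeration on hundreds of random lexicons of up to 500 forms, the
  search engine against a row-by-row predicate filter on a 5,000-type
  synthetic lexicon (500 randomized criterion sets), window identities on
  10,000 random strings, and pseudoword invariants over 100 seeded runs —
  sizes chosen to exercise every code path at desk scale.
* Degenerate inputs: empty lexicons, zero counts in transforms, unmapped
  CVCV characters and malformed range expressions raise errors naming the
  offending element; an empty search result yields an empty statistics
  table, not an exception.

## Known limitations

Phonological and syllabic variables are out of scope. The grammatical-
information annotator is rule-driven (longest matching suffix per
category) and only as good as the rule table supplied; no default
dictionary ships with the package. OLD20 is quadratic in the number of
distinct forms; at 200k+ types a full build is minutes of CPU, and the
`chunk_size` argument bounds memory rather than time.
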