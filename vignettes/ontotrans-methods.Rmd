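---
title: "Transformation-based QC of ontology translations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformation-based QC of ontology translations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontotrans)
```

## The problem

A professionally translated ontology cannot be reviewed term by term by
hand: tens of thousands of labels, synonyms and definitions arrive from a
translation vendor, and the ontology itself changes monthly. `ontotrans`
automates the first review pass. Each text element is validated through
*backtranslation*: a machine translation service (whose output is an input
file here, never a live call) translates the English source forward into
the target language and the professional translation back into English.
If the professional translation is faithful, the backtranslation should
agree with the English source up to superficial differences, and the
professional translation should agree with the machine forward translation
the same way.

## The similarity score

"Superficial differences" is made precise by a set of text
transformations, applied identically to both members of a language-paired
comparison:

* character-level: case folding; diacritic stripping (canonical
  decomposition, remove combining marks, recompose); roman→arabic numeral
  rewriting of whole canonical-roman tokens (value ≤ 3999); whitespace
  removal; punctuation removal;
* word-level (require tokenization): Snowball stemming (Porter2 for
  English, the Spanish Snowball algorithm); stopword removal against small
  per-language lists; punctuation word-splitting.

Every admissible combination is tried exhaustively — 32 whole-string
combinations plus 128 tokenized ones under the default configuration —
and the pair keeps the best penalized score

$$ S \;=\; W_{pct} - W_{pct}\,\bigl(t\cdot[\text{tokenized}] + W_n W_{wt} + C_n C_{wt}\bigr) $$

where $W_{pct}$ is the order-insensitive multiset word overlap divided by
the **larger** token count (pinned by the "daltonismo" 50% example: min or
mean denominators would give 100% or 66.7%), $W_n$ and $C_n$ count the
word- and character-transform *types* applied (not instances: removing two
stopwords is one transform), and the weights default to

| parameter | default | meaning |
|---|---|---|
| `char_weight` ($C_{wt}$) | 0.02 | per character-transform type; cheap, rarely meaning-changing |
| `word_weight` ($W_{wt}$) | 0.05 | per word-transform type |
| `token_penalty` ($t$) | 0.15 | flat cost of moving from whole-string to word-level comparison |
| `cutoff` | 0.75 | classification threshold on the averaged score |

Untokenized comparisons are all-or-nothing ($W_{pct}\in\{0,1\}$); partial
credit requires paying $t$. Because every penalty is multiplied by
$W_{pct}$, the score is bounded by $[0, W_{pct}]$ and penalties shrink as
the match worsens; the configuration validator additionally requires the
maximum total penalty to stay below 1.

The two pair scores (English and target-language) are averaged and
classified: **exact** iff the average is 1, which is only attainable when
both pairs are raw-identical after Unicode composition; **passed** when
strictly above the cutoff; **pending** (manual review) at or below it —
0.75 itself is pending.

```{r}
best_match("fiebre del río de Ross", "Fiebre del río Ross", "es")
best_match("Ross River fever", "ross river fever", "en")
```

## Numerical and procedural conventions

Choices the score definition leaves open, fixed here once:

* **Application order** within a transformation set: tokenization (with
  punctuation word-split) first; then per-token (or whole-string)
  character transforms in the order case → diacritic → numeral →
  punctuation removal → space removal; then stopword removal; then
  stemming (which expects lower-case input). Both sides always receive
  the identical set.
* **Tie-breaking** among equal-scoring combinations: fewer total
  transforms, then fewer word transforms, then lexicographic identifier
  order. Determinism here is what makes golden-file tests possible.
* **Degenerate inputs**: empty vs empty scores 1 (empty set); empty vs
  non-empty scores 0. Missing unit fields are an error naming the field.
* **Roman numerals** are rewritten only as whole tokens (or whole
  letter-runs bounded by non-letters), in strict canonical form, so words
  like "mix" survive — though single letters D, I, C, M are themselves
  canonical romans; the search only ever applies the rewrite when it
  improves matching, so this is harmless in practice. Matching is
  case-insensitive exactly when the case transform is co-applied, which
  is also why a no-op case transform is never pruned from the search
  while numerals are in play.
* **Stopword lists** ship with the package (11 English, 15 Spanish
  function words, including "del"/"al" — a judgment call, replaceable per
  language via `score_config(stopwords = ...)` or `read_stopwords()`).
* **Search pruning**: transforms that provably cannot change either side
  (no diacritics present, no punctuation, already lower-case, …) are
  dropped before enumeration; since an ineffective transform only adds
  penalty, the optimum is unchanged. A 200-pair randomized test holds the
  optimized search equal to a naive 160-combination enumeration built
  from the exported primitives.
* Scores are kept at full precision internally; presentation rounds to
  two decimals.

## The ledger

The translation master table is a UTF-8 TSV (no quoting; literal tab and
newline escaped as `\t`, `\n`) keyed by the (subject, predicate, source
text) triple and sorted in binary code-point order — byte-stable across
machines, so diffs are meaningful. Reconciliation against a current
ontology export is an exact-string join on triples: full-key matches are
*carried*; current triples whose (subject, predicate) exists but whose
text differs are *changed* (their old records are *retired*); triples
with no record at all are *new untranslated*. A synonym whose scope
changes (e.g. exact → related) with identical text counts as changed,
because the predicate including scope is part of the key. Task subsets
(`needs_translation`, `pending_review`, `changed_text`) are disjoint by
construction.

Definitions systematically score below a cutoff optimized on labels
(longer texts, more phrasing variability), so a policy step releases
pending *definitions* that carry a reviewer sign-off flag
(`pending_included`); sign-offs on any other text type are ignored with a
warning. Release-eligible records (exact, passed, reviewed-accepted,
pending-included) are emitted as template tables whose second row carries
directive strings with ISO 639 language tags (`@en` / `@es`), one row per
triple, acronym annotation preserved — actual ontology-file assembly is
left to standard release tooling, as in the production pipeline.

## Calibration

`grid_search()` scores a manually labeled unit set under every grid
combination and minimizes (false positives, false negatives)
lexicographically: releasing a bad translation is categorically worse
than re-reviewing a good one. The spec gives no objective function, so
strict lexicographic order was chosen over a weighted sum; a weighted
mode (`fp_weight`) exists for sensitivity analysis. Ties break toward
the smaller cutoff, then smaller weights. Scores do not depend on the
cutoff, so the transformation search runs once per weight combination
and every cutoff reuses it. Default grids bracket the production values
($C_{wt}$ 0.01–0.05, $W_{wt}$ 0.02–0.10, $t$ 0.05–0.30, cutoff
0.50–0.95); both joint and cutoff-only calibration (grids of one) are
supported.

## The synthetic corpus: what it emulates, what it does not

There is no translation service and no ontology export in a test
environment, so `generate_corpus()` fabricates labeled units: a
disease-name grammar (optional modifier × anatomy × disorder × optional
"type N") rendered in English and in a Spanish-like order through a
~50-pair bijective lexicon. Backtranslation is the deterministic inverse
of that rendering (accent/case-insensitive lexicon lookup, function
words dropped, noun order rotated back). Perturbations mirror the
recoverable error classes — case flips, diacritic stripping, stopword
insertion/deletion, adjacent-word swaps, arabic↔roman style swaps,
punctuation and whitespace noise — plus the one *unrecoverable* class,
meaning-changing word substitution. Units allocated unfaithful are
guaranteed at least one substitution, so the ground-truth label, the
human-verdict column and the perturbation log always agree, and the
faithful/unfaithful mix is exactly `round(n * mix)`. Each unit draws
from a counter-derived substream of the corpus seed: corpora are
byte-identical under a fixed seed and units are order-independent.

Default probabilities (case 0.3, diacritic 0.2, stopword 0.3, reorder
0.15, numeral 0.15, punct 0.1, whitespace 0.1; substitution 0.9 for
unfaithful units) were chosen once as moderate noise within the ≤ 0.5
regime the recoverability property assumes.

A green synthetic run establishes that the score's *algebra* behaves:
recoverable noise stays above the cutoff (measured: ≥ 95% of faithful
units exact/passed at n = 500), meaning changes fall below it, report
percentages are consistent. It does **not** establish anything about
real Spanish: the lexicon is word-for-word bijective, real translations
paraphrase; machine-translation error is modeled as the same perturbation
noise, not as a model of any service; definition-length texts are not
emulated (the corpus assigns the `definition` predicate to short grammar
output only to exercise the report and policy plumbing). Published
corpus-level category percentages are therefore *not* reproduction
targets, by design.

## Known limitations

* Whole-string comparison treats internal whitespace changes as
  recoverable only via space removal; a space *inserted inside a word*
  is unrecoverable under tokenization (deliberately: token identity is
  the unit of matching).
* The stemmers reimplement the published Snowball algorithms in R;
  they were verified against the reference implementation on a ~2,200
  word development vocabulary and ~90 frozen cases ship in the tests,
  but exotic vocabulary outside Latin-script medical text is untested.
* The definition-specific scoring problem (longer, paraphrase-heavy
  text) is handled by policy, not by a different equation — a different
  score for definitions is explicitly out of scope.
* `reconcile()` treats any non-identical text under an existing
  (subject, predicate) as "changed", which for multi-valued predicates
  (synonyms) conflates "edited synonym" with "added synonym"; the
  release consumer treats both as needing translation, so the
  distinction is not load-bearing.
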