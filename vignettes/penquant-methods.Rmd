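---
title: "Quantifying nuclease prime editing outcomes with penquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclease prime editing outcomes with penquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penquant)
```

## The system being modelled

A nuclease prime editor (PEn) couples a catalytically active Cas9 with a
reverse transcriptase and a pegRNA. Cas9 makes a blunt double-strand break
3 nt 5' of the PAM; the pegRNA's primer binding site (PBS) anneals to the 3'
end of the protospacer strand at the break, and the reverse transcription
template (RTT) is copied onto that end, producing a 3' single-stranded
overhang on the PAM-distal side. In the HR-pegRNA configuration the RTT
encodes, read 5' to 3' on the guide, `revcomp(HR) + revcomp(PR)`:

* **PR (programmed region)** — the new top-strand sequence the RT writes at
  the break (the insertion or replacement payload; empty for pure
  deletions).
* **HR (homologous region)** — a genomic-matching segment immediately 3' of
  the edited block in the intended product. It lets the overhang base-pair
  with the (resected) downstream DSB end and thereby aligns precise repair.
  Strategic placement of the HR is what converts the same machinery into
  insertions, deletions, or replacements.

How the cell resolves this intermediate determines the observed allele:
precise annealing through the HR gives the intended product; blunt ligation
of a partially incorporated overhang to the unresected downstream end gives
"partial-HR join" alleles (intact PR plus a truncated HR fragment, i.e. a
tandem duplication relative to the intended product); microhomology-mediated
end joining (MMEJ) between the overhang and the downstream flank gives
characteristic junction deletions; and plain NHEJ of the naked break gives
classical indels. penquant implements the design arithmetic, the read-level
outcome taxonomy, and allele-level signature matching for all of these.

## Coordinates and design arithmetic

All coordinates are 0-based, half-open, on the top strand of the
orientation-normalized amplicon (`locate_protospacer()` reverse-complements
the input if the protospacer matches the bottom strand). The cut site is an
inter-base coordinate equal to the length of the upstream fragment. Edits
are specified relative to the cut (`position = 0` at the DSB); negative
offsets are rejected because the RT extends the upstream 3' end and cannot
rewrite sequence 5' of the break. For an edit at offset `p` deleting
`deleted_len` bases and writing `inserted`:

* `PR = amplicon[cut, cut + p) + inserted` (the RT must re-copy any gap
  between the cut and the edit start),
* `HR = amplicon[d, d + hr_len)` with `d = cut + p + deleted_len`,
* RTT `= revcomp(PR + HR)`; PBS `= revcomp(amplicon[cut - pbs_len, cut))`.

The round-trip identity `precise_repair_product(locus, pegrna) ==
expected_edited_sequence(locus, edit)` is enforced by property tests over
randomized loci and edits. Defaults: `pbs_len = 13` (a mid-range choice;
per-site PBS tuning is out of scope), `hr_len = 20` (the unified HR size
for fragment edits; `hr_len = 0` gives the HR-free configuration). pegRNA
sequences are stored as DNA; the RNA identity is presentational. The sgRNA
scaffold is a configurable constant and is not validated against any
specific plasmid.

## Read handling

Merged consensus reads are the unit of analysis. `merge_pairs()` finds the
best *ungapped* overlap between mate 1 and the reverse complement of
mate 2: overlap lengths are scanned from the longest possible downward and
the longest overlap with mismatch fraction at most `max_mismatch_frac`
(default 0.1) and length at least `min_overlap` (default 11) wins;
disagreeing positions take the higher-quality base, ties going to mate 1.
The exhaustive longest-first scan was chosen over heuristic seeding because
it is deterministic and directly checkable against constructed pairs. Pairs
that fail to merge are excluded from classification and reported in the
merge statistics. Barcode demultiplexing is exact-prefix by default
(barcodes are short; exactness avoids sample cross-talk) with an optional
mismatch budget; the barcode table must be prefix-free.

## Alignment

Each merged read is aligned to the reference amplicon and to the expected
edited amplicon with a fitting alignment (read global, free template end
gaps) under affine gap scoring: match +2, mismatch -4, and a gap of length
L costing -6 - L. Traceback is fully deterministic: on ties,
match/mismatch is preferred over a gap, a deletion (gap in the read) over
an insertion (gap in the template), and end-column choice is leftmost. The
scores are validated against an independent full-matrix Gotoh
implementation in the test suite. Read orientation is resolved by probe
k-mers with an alignment fallback. This bespoke two-template aligner
replaces a general mapper + CRISPResso2 stack; it is amplicon-local and
fully specified, and exact numeric agreement with CRISPResso2 is *not*
claimed.

## Quantification windows and the outcome taxonomy

Quantification windows extend `pad = 30` bases beyond the cleavage site on
one side and the RT 3'-end position on the other (on the edited template
the RT end is `cut + len(PR) + hr_len`; the reference window uses its
projection), clipped to the sequence bounds with a warning. Indels outside
the window are ignored as amplification/sequencing artifacts.

Classification per read:

1. **PR evidence.** For PRs of at least 6 nt an exact substring hit accepts
   immediately. Otherwise — short PRs, substitution edits, or a substring
   miss (e.g. a sequencing error inside the PR) — the read must align
   strictly better to the edited template than to the reference (ties go to
   the reference, which never inflates editing) *and* carry the edit locus
   without indels: exactly for substitution edits, mismatch-tolerantly for
   the rest, since substitution noise accrues at the per-base error rate
   while demanding exactness would systematically leak true edits into the
   direct-indel class. Reads with a partial PR fragment fail the locus
   check and are counted as direct indels.
2. `ACCURATE`: PR evidence, no indels inside the edit-template window, edit
   locus intact.
3. `IMPRECISE_RT`: PR evidence otherwise. `distal_indel` is set when every
   window indel sits strictly beyond the cut — in or past the RT-written
   region rather than at the guide target — the signature of partial-HR
   joins. (An indel-position criterion tied to the end of the PR would be
   unstable: leftmost placement can rotate a duplication-type insertion
   into the PR suffix.)
4. `DIRECT_INDEL`: no PR evidence and at least one indel inside the
   reference window (classical NHEJ).
5. `UNEDITED`: no PR evidence, no window indels; substitution-only
   mismatches count as sequencing error unless the edit itself is a
   substitution.
6. `DISCARD`: best alignment identity below 0.6.

`summarize_calls()` computes percentages over non-discarded reads:
accurate, imprecise RT-driven, all RT-driven (= accurate + imprecise,
exact at count level), direct indels, unintended (= direct + imprecise),
and **purity** = accurate / all RT-driven, reported as missing (never 0)
when no RT-driven reads exist.

## Allele analysis

Allele identity defaults to the exact sequence over the
quantification-window projection of each read's chosen template, so
sequencing errors far from the edit do not fragment alleles; whole-read
identity is available (`by = "read"`). Predicted constructs (partial-HR
joins, MH junctions) are projected through the same classifier path so keys
are directly comparable.

**Partial-HR joins.** For k = 0..hr_len the construct is
`upstream + PR + HR[0:k] + amplicon[cut:]` — the overhang bluntly ligated
to the *unresected* downstream end. Note two degeneracies that fall out of
the geometry: for an insertion at the cut, the k = 0 construct *is* the
precise product (the naked PR flap bluntly joined reproduces the intended
sequence), and the k = hr_len construct is a full-HR tandem duplication,
not the precise product. Constructs equal to the expected product are
annotated `PRECISE`; the rest `PARTIAL_HR_JOIN(k)`.

**MH junctions.** `predict_mh_alleles()` enumerates all substrings of
length 3-10 (the conventional MMEJ microhomology range; configurable)
shared between the predicted 3' overhang and the first 30 nt of the
downstream flank, including overlapping occurrences, and builds the allele
obtained by annealing at each microhomology and trimming flaps. Candidates
predicting the same allele are collapsed, keeping the longest
microhomology. The HR annealing at its own genomic offset is itself such a
candidate and reproduces the precise product; it is flagged `is_precise`.
The enumeration is verified against a brute-force all-pairs oracle on
randomized fixtures.

## The simulator

`make_allele_set()` + `simulate_reads()` emulate the targeted amplicon
structure of PEn/uPEn experiments: a PCR amplicon with the cut near the
center, a ground-truth mixture over outcome alleles (precise; partial-HR
joins with a distribution over k; one MH junction allele; classical NHEJ
indels; unedited), 150-bp (or 250-bp) mates read from the two fragment
ends so they overlap in the middle, substitution-type sequencing errors at
a constant per-base rate, and constant Phred qualities consistent with that
rate. Choices where no external value existed, made once:

* the partial-HR k distribution defaults to uniform over k = 1..hr_len-1
  (real spectra are only qualitatively known; k = 0 and k = hr_len are
  excluded because those blunt joins collide with the precise product or
  duplicate the full HR);
* classical indels default to small deletions centered on the cut with some
  +1 duplications of the base 5' of the cut, the typical NHEJ spectrum;
* sequencing errors are substitutions only, isolating classifier logic from
  indel-error handling; qualities are constant per run.

The simulator does **not** model PCR bias, chimeras, coverage profiles,
indel sequencing errors, or per-cycle quality decay — so passing tests
demonstrate correctness of the pipeline's logic under the stated error
model, not robustness to every artifact of real libraries. One seeded
Mersenne-Twister stream drives everything, consumed in documented order
(allele indices; mate-1 error mask and substituted bases; the same for
mate 2), so a seed fixes the output byte-for-byte.

## Aggregation statistics

`aggregate_editing()` reports per-site replicate means and standard
deviations, and per-platform medians with quartiles over the site means
(linear-interpolation quantiles, `stats::quantile` type 7, stated in the
output metadata). `fold_change()` sets the baseline platform's site mean to
1 and normalizes the other platforms per site, reporting cross-site
medians; zero baselines give missing folds that are excluded with a
warning. `compare_platforms()` uses two-tailed Student's t-tests,
equal-variance by default (Welch via `var_equal = FALSE`; the convention in
the source analyses is not stated, so equal-variance was chosen and made
switchable), plus a two-tailed one-sample t-test of the per-site folds
against 1.

## Problem sizes and validation conditions

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to keep the full suite under a couple of minutes while
leaving binomial noise well below the tested tolerances: 10,000 reads for
mixture-recovery checks (category proportions within 3 binomial standard
errors at a 0.1% error rate; exact equality with the allele draws at zero
error), 100 randomized loci for the design round trip, 50 random 100-bp
fixtures for the MH oracle, and 4,000 reads per point for the
purity-monotonicity sweep. The acceptance script emulates two study
conditions on the packaged synthetic locus — a PEn-like spectrum (RT-driven
edits dominated by imprecise joins, purity within RT-driven edits near
one third) and a uPEn-like spectrum (the same RT-driven burden resolved
almost entirely precisely, purity above 0.9, classical indels unchanged) —
with three replicates each at 6,000 read pairs, and recomputes all reported
quantities from scratch at run time.

## Known limitations

* The classifier is amplicon-local; it does not detect large structural
  outcomes, translocations, or integrations that leave the amplicon.
* Scaffold read-through insertions are not modelled separately: reads
  retaining the full PR plus scaffold-derived sequence classify as
  `IMPRECISE_RT`.
* "All RT-driven" requires the full PR; partial-PR fragments count as
  direct indels. Both conventions are stated here because the boundary is
  genuinely ambiguous in mixed repair outcomes.
* Allele tables under nonzero sequencing error are exact-match tables over
  the window projection; rare alleles can still split if errors fall inside
  the window.
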