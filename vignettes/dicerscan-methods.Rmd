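---
title: "dicerscan: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dicerscan: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicerscan)
```

## The assay and the coordinate system

A two-loop shRNA is a hairpin with a 22-bp stem, an apical (primary) loop
that DICER engages, and a secondary loop holding a 32-nt random barcode
flanked by the fixed delimiters `GCTTGC`/`GCAAGC`. The *full-length
original substrate* (FL-OS) is the construct with delimiters and barcode
removed; all coordinates live on the FL-OS (70 nt by default). Stem pair
position $i$ on the 5′ strand pairs with FL-OS position $71 - i$; pair
positions 14–21 are randomized in six overlapping 3-bp windows (one per
library group), with both strands of each pair free, giving $16^3 = 4{,}096$
variants per group and 23,296 unique sequences over the six groups
(the overlap structure makes this an inclusion–exclusion count, which
`count_unique_variants()` evaluates in closed form and the test suite
verifies against brute-force set deduplication).

Cleaved products are located in their barcode-assigned FL-OS by exact
substring search, falling back to Smith–Waterman local alignment
(match +2, mismatch −3, gap open −5, gap extend −2, minimum length 15;
equally good placements are discarded as ambiguous). The alignment start
−1 and end give the cut coordinates $(x, y)$, and the mode rules are:

| mode | condition | site |
|------|-----------|------|
| DC | $19 \le x \le 23$, $y = 72 - x$ | $x$ |
| Other | $19 \le x \le 23$, $49 \le y \le 53$, $y \ne 72 - x$ | $x$ |
| 5′-SC | $19 \le x \le 23$, $68 \le y \le 72$ | $x$ |
| 3′-SC | $0 \le x \le 4$, $49 \le y \le 53$ | $72 - y$ |

with precedence DC > Other > 3′-SC > 5′-SC. The *Other* y-range deserves a
note: the rule table as conventionally printed gives Other the range
$68 \le y \le 72$, which coincides with the 5′-SC region and makes the
$y \ne 72 - x$ clause vacuous (no $x$ in 19–23 has $72-x$ in 68–72). We
default to the corrected range 49–53 — the only window where $y = 72-x$ is
attainable, so Other captures genuinely non-2-nt-overhang double
cleavages — and keep the verbatim behaviour behind
`classify_cleavage(..., rules = "printed")`. The corrected regions are
pairwise disjoint over the whole coordinate grid (checked exhaustively in
the acceptance suite).

With `full_len = 70` and the constant $C = 72$, a DC at $x$ leaves a 3′
fragment of $x - 2$ nt — the canonical 2-nt 3′ overhang. In our default
geometry the overhang sits on the product duplex at the cut; the library
FL-OS itself ends blunt, so the `T` (3′ overhang) structure symbol appears
only in user-supplied hairpins such as pre-miRNAs.

## Score formulas

All formulas operate on counts-per-million with a 0.1 pseudocount:
local efficiency $\log_2(N_P + 0.1) - \log_2(N_S + 0.1)$; total efficiency
per mode with $\sum N_P$; accuracy $N_P / \sum N_P$ (undefined, and
excluded from averages, when every $N_P$ is zero); the DC/SC log-ratio
$\log_2(\sum N_{P,DC} + 0.1) - \log_2(\sum N_{P,SC} + 0.1)$. Cohen's $d$
uses the equal-weight pooled SD $\sqrt{SD_1^2/2 + SD_2^2/2}$ regardless of
sample sizes, with $n-1$ standard deviations (the convention is not forced
by the formula's source; we state it here). The CPM denominator is the
total of classified, reference-matched reads in each library — the exact
denominator is not prescribed anywhere, and any per-library constant
cancels from accuracies and only shifts efficiencies by a constant.

## The two-motif simulator: a stated world

The simulator is first-class, tested code. Every cleavage event falls in
one of fifteen categories (DC, 5′-SC, 3′-SC at sites 19–23) with softmax
probabilities over logits:

* baseline site logits `c(19 = -2, 20 = -0.5, 21 = 1.5, 22 = 1, 23 = -2)`
  — double cleavage concentrated at sites 21 and 22, as observed;
* a single-cleavage offset `sc_logit = -1.2` per SC branch (roughly 30% of
  events single-cleaved at baseline, rising when the dsRBD is deleted via
  `dsrbd_del_sc_boost = 0.8`);
* an mWCU whose first pair sits at stem position $N$ adds
  `beta_mwcu = 2.5` × strength to the DC logit at site $N+4$, gated by the
  enzyme: factor 1 for WT, 0 for the dsRBD deletion and R1855A (the residue
  that recognizes the central mismatch), 0.5 for E1859A (mildly reduced
  recognition);
* a YCR at $N$ adds `beta_ycr = 2.5` × strength to DC at $N+2$ and
  subtracts `ycr_sc_suppression = 1.5` × strength from the SC logit, in
  every enzyme.

Motif strength is continuous rather than all-or-none: each pair position
contributes a grade in $[0,1]$ for how closely it matches the consensus,
and the required component gates the whole motif — a mismatch in the
second position for mWCU (C-C grading highest), and for YCR both the
pyrimidine-containing first pair (purine–purine combinations are excluded
outright) and the central C-G pair. Grading reflects the view that motif
activity comes from additive contacts around one essential feature; it is
what makes rank-based parameter recovery a meaningful test. The effect
sizes (2.5 logit units ≈ an accuracy shift from ~0.55 to ~0.9 at the
targeted site) were fixed once to sit in the range of the strong
shifts seen in validation cleavage assays, before any recovery test was
run.

Each variant receives a fixed number of barcodes (default 3) drawn
uniformly from the full 32N space, and a multinomial draw of `n_reads`
cleavage events. Reads carry terminal random UMIs (6+4 nt for OS/SC, 4+4
for DC), the delimiter-flanked barcode, and the 3′ sequencing adapter.
One RNG stream per call: `simulate_library()` draws barcodes then
per-variant counts; `emit_reads()` draws barcode assignment, UMIs and
(optional) substitution errors under its own seed, so ground truth and
read emission are independently reproducible and byte-identical per seed.

What the simulator deliberately does **not** emulate: PCR amplification
and ligation biases, paired-end read structure (reads are emitted
pre-joined), base-quality variation (the upstream Q20/90% filter is a
pass-through), circularization chemistry, and folding-dependent structure
changes. Two realistic loss channels do exist and are worth knowing about:
UMI-space collisions remove a small fraction of high-count categories at
deduplication, and a random barcode occasionally contains a delimiter,
which discards that barcode's reads at the split step. Both losses are
independent of the cleavage category, so recovered site distributions
remain unbiased — which is why the round-trip chi-square criterion passes.
A green round-trip therefore establishes coordinate bookkeeping and
counting fidelity, not robustness to real library-prep artefacts.

## Structure annotation

Dot-bracket structures are converted position-wise: `b` for pairs, `L`
for the apical loop, `M` for equal-length internal loops (paired off
outside-in), `A` for unequal non-zero internal loops (every unpaired
position on both sides — no per-position assignment inside asymmetric
loops is defined anywhere, so we mark all of them), `B` for one-sided
bulges, `T` for terminal single-stranded ends. Stem length counts `b` and
`M` on the 5′ strand from the first pair to the apical loop. Only nested
single hairpins are supported; multiloops and pseudoknots raise an error.

Folding itself is delegated: the module consumes dot-bracket strings from
any folder. Because no MFE folder is part of this package's dependency
set, library variants are annotated by a rule-based duplex model
(`fold_duplex()`) that pairs the two designed stem arms position-wise
(Watson–Crick and G-U wobble), leaving mismatches in place. This is the
simulator's own stated world — register shifts and fill-induced bulges do
not occur — so every library variant keeps the designed 22-bp stem and no
motifs are excluded by the stem filter on synthetic data. With a real
folder some fills would refold and be excluded; the filter
(`window_accuracy(..., profiles = )`) implements exactly that exclusion.
When folding the two-loop construct, the secondary loop should be masked
to a constant spacer first (the annotation operates on the FL-OS, which
has it removed); whether to fold with or without the barcode is not
decidable from first principles, and masking makes annotation independent
of the random barcode.

## Motif scoring

mWCU windows 16–18, 17–19, 18–20 score DC20, DC21, DC22 from the groups
randomized at those positions; YCR windows 18–20, 19–21, 20–22 do the same
(conventionally from dsRBD-deleted data, to remove the mWCU
contribution). The 20–22 window has no fully randomized group — the
library's windows stop at 19–21 — so it is scored from the 19–21 group
with the third pair fixed at the backbone: only the 256 motifs matching
that pair obtain a third window, and all others average their DC20/DC21
windows (the documented fallback). Per-window motif means are min-max
rescaled to 0–100; a degenerate window (all means equal) maps to 0 rather
than an arbitrary 100. "Top 3 percentile" selection takes scores at or
above the 97th-percentile value, ties included, applied to averaged scores
(not per window). `motif_class()` labels by top-set membership, with mWCU
taking precedence on the rare motif qualifying under both tables; the
sequence-pattern predicates are exposed separately and are what the
pre-miRNA enrichment analysis uses.

## Pre-miRNA applications

Cleavage sites come from the mature annotations: the 5p 3′ end directly,
or the 3p 5′ end projected through the pairing table with 2-nt-overhang
geometry (first duplexed position at or after the 3p start; its partner
plus two, plus any walked-over unpaired offset). Disagreeing annotations
flag the record rather than silently choosing one. Motif triples on
hairpins are read from a pairing table augmented with symmetric-mismatch
partners (outside-in); bulged positions are skipped (at most two), while
loop, terminal or asymmetric positions break the window — an asymmetric
loop has no defensible pair assignment, so no score is safer than a
guessed one.

For upstream enrichment, "1 nt from the cleavage site" means the position
immediately 5′ of the cut ($x$ itself), so the 1–5 nt YCR window covers
first positions $x-4..x$ and the 1–7 nt mWCU window $x-6..x$; this is the
only reading under which a YCR three positions upstream targets its own
cut site. Structurally redundant families (e.g. an expanded miR-430-like
family) can be excluded by id to avoid enrichment bias. SNP events are
selected at $|\Delta score| \ge 20$ (inclusive). IsomiR DCx registers
count duplex positions only (`b`/`M`), excluding bulges and asymmetric
positions, from the hairpin 5′ end to the cut implied by the read's
5′ end; filters are strict: more than 10 raw reads per miRNA per sample,
unmodified ends (read coordinates matching the reference hairpin exactly),
and DC21 analyses restricted to miRNAs whose DC21 exceeds 5% of all DCs
in the reference sample.

## Numerical and degenerate-input choices

* Pseudocount 0.1 inside every log; efficiencies are therefore bounded
  below by $\log_2 0.1 - \log_2(N_S^{max} + 0.1)$.
* All-zero accuracy vectors yield no accuracy (excluded from averages, not
  imputed as 0) — imputing would bias low-coverage variants downward.
* Min-max over a constant window maps to 0, never 100.
* Exact-substring ties and sub-minimum alignments are discarded with
  reasons; every processing stage conserves
  `reads_in = kept + discarded`.
* Replicate averages use however many replicates report a value.
* A missing variant in a round-trip comparison counts as a failure of that
  variant, not as missing data.

## Known limitations

Adapter and delimiter matching is exact (no error tolerance), matching the
perfect-match selection philosophy of the analysis but discarding any read
with a sequencing error in those fixed regions; the simulator's default
error rate is 0 accordingly. The rule-based duplex folder is not an MFE
folder and must not be used for arbitrary hairpins — supply real
dot-brackets for pre-miRNAs. Statistical machinery beyond Cohen's $d$ is
intentionally out of scope; the effect-size object is designed to plug
into whatever test the user prefers.
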