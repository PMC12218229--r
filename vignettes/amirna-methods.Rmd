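---
title: "Engineering amiRNA scaffolds and profiling their processing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering amiRNA scaffolds and profiling their processing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the coordinate system and structural model, the four modification
classes and how the engine realises them, the read-quantification
conventions, what the simulator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The model

### Coordinates anchored at the DROSHA site

All determinants are expressed relative to the putative DROSHA 5′
cleavage site, which the package equates with the annotated start of the
5p mature arm. Internally sequences use R's native 1-based indices; a
signed *offset* overlay places offset 0 at the arm start, negative
offsets running 5′-ward into the basal stem and flank, so "the GU at
−14/−13" or "the CHC bulge at −6" read exactly as a scaffold designer
would write them. Mirrored 3′-strand positions are reached through the
pairing partner in the refolded structure. Un-annotated inputs are not
accepted: the package requires mature-arm annotations and does not
predict cleavage sites.

### Structure comes from an injected folding service

The package never computes thermodynamics. A *folding service* is any
deterministic function from an RNA string to an equal-length MFE
dot-bracket string; the default wraps ViennaRNA's `RNAfold` and memoises
results. This keeps the engine testable (tests inject hand-written
structures) and keeps the structural model honest: every claim a
validation report makes is a claim about the MFE refold of the final
sequence, not about the intermediate edits. Suboptimal-structure
ensembles are out of scope.

### What counts as "the stem"

`stem_pairs()` walks outward from the terminal loop, bridging bulges and
internal loops of up to 6 unpaired nucleotides per strand; a larger gap
is treated as the basal junction. When mature arms are annotated the
walk is additionally truncated at the top of the duplex: base pairs
formed *inside* the loop insert (the miR-30a loop carries a short helix
of its own) belong to the loop, not the stem. Under this definition the
35-bp target decomposes as 13 basal pairs plus the 22-bp mature duplex,
which is the arithmetic the determinant literature uses, and the
"loop-proximal pair" is the top pair of the duplex.

## The four modification classes

1. **Base of the stem** (`apply_base_modification`): writes the basal
   dinucleotide (default `GU`; the motif literature also writes UG, so
   the orientation is configurable) at offsets −14/−13, rebuilds the
   lower stem, and drives the refolded stem-pair count to exactly the
   35-bp target, with 10 nt refolding unpaired beyond the stem on each
   side.
2. **CHC insertion** (`apply_chc_insertion`): rewrites the 3′ lower
   strand as the Watson–Crick complement of the basal 5′ strand
   (removing every bulge between offsets 0 and −13) and inserts the
   bulged H between the partners of offsets −6 and −5, with the C/C
   context paired to G/G on the 5′ strand.
3. **Loop modification** (`apply_loop_swap`): replaces the region
   between the mature arms with the configured loop.
4. **All combined** (`apply_all`): base → CHC → loop with refolding
   between stages, then a final stem re-enforcement (the loop swap
   changes the pair budget above the DROSHA site) and a full
   seven-check validation.

### How the engine realises an edit

Each structural operation shares one mechanism: a *canonical rebuild* of
everything below the mature duplex — sampled unstructured flank, an
optional Watson–Crick extension helix, the 14 basal 5′-strand bases
(parent bases with the required motifs written in), the untouched core
from the 5p arm start to the 3p arm end, and a freshly written 3′ lower
strand pairing the top *k* basal offsets — followed by an *empirical
adjust loop*: refold, count stem pairs, and adjust (*k*, extension
length) by the observed deficit; resample the flanks when they refuse to
unpair; give up with a structured error (`stem redesign failed`,
`flank redesign failed`) after 50 attempts. Because the count is always
measured on the refold, the loop converges in a handful of iterations
and cannot silently miss its target. All sampling is driven by a seeded
RNG whose state is restored afterwards, so the same seed gives
byte-identical scaffolds and the user's RNG stream is never perturbed.

Each operation also has a fast path: if its own determinants already
hold on the input, the input is returned unchanged. That makes every
`apply_*` a fixed point on its own output, which the tests assert.

### Numerical and geometric choices

* **Basal dinucleotide orientation**: −14 = `G`, −13 = `U`, read 5′→3′
  on the 5′ strand; configurable.
* **CHC geometry**: the bulged H sits on the 3′ (passenger-side) basal
  strand, matching the known 3′-strand bulge determinant; the default H
  is `A`, because an `A` between two paired `C`s cannot form an
  ambiguous register with its neighbours (a bulged `C` inside a `CCC`
  run folds identically in several registers and the dot-bracket picks
  one arbitrarily).
* **Pairing offset 0**: the debulge window reaches offset 0, whose
  facing base is taken to be the core's 3′ terminus — a blunt lower
  duplex. The 2-nt overhang geometry of natural DROSHA products is not
  modelled; it affects only which core tail base is rewritten, and the
  refold decides the realised register in any case.
* **Loop boundaries**: the default loop is the 19-nt miR-30a loop
  region `CUGUGAAGCCACAGAUGGG` (the segment between the mature miR-30a
  arms, internal helix included). MFE refolding invariably zips one or
  two loop-edge bases onto the duplex top whatever loop sequence is
  chosen — real pre-miRNA loops are partially structured — so the loop
  check asserts sequence identity of the insert and that the terminal
  loop lies inside it, not per-base unpairedness. The loop ships as an
  editable default, not asserted ground truth.
* **Flanks**: "unstructured base of the stem" is enforced operationally
  as 10 nt per side unpaired in the refold, achieved by resampling
  A/C-rich flanks (A/C cannot pair with each other, which makes
  convergence fast).
* **Stem-length repair**: extension pairs are appended below the basal
  end with sequence sampled to avoid runs of ≥ 4; trimming removes
  extension pairs first and then unpairs basal pairs from the bottom.
* **Screening**: the CNNC motif must start 16–21 nt downstream of the
  3p arm end (configurable); ties in abundance break lexicographically
  by id.
* **Config format**: the command-line layer reads YAML.

## Read quantification

Reference windows concatenate the mature strand with 10 flanking bases
on each side (42 bases for a 22-nt strand), built per scaffold so reads
cannot cross-map. Classification accepts a read iff its CIGAR is one
pure match run with length in 18–24 nt and its flags mark a primary,
mapped, forward-strand alignment; every rejection carries a
machine-readable reason, and accepted + rejected always equals the
input. `M` is treated as alignment match — substitutions are tolerated,
since the criteria constrain only indels and length; soft-clipped reads
are rejected. Reads shorter than the core are still accepted if within
the band (isomiR trimming).

Counts are normalized as reads-per-million classified reads with one
shared library-size factor — the minimal assumption; the factor is
configurable and the reports carry the raw counts. The precision profile
tabulates start and end positions as percentages of accepted reads (each
vector sums to 100 whenever at least one read is accepted; zero accepted
reads is a defined error rather than NaN vectors), and the 5′ fidelity
is the start percentage at the expected core start. Multi-mapping
between a scaffold's own two windows is resolved by first hit, with ties
counted and reported.

## The simulator, and what passing tests show

`simulate_reads()` draws each read's strand (guide with probability
`guide_fraction`, default 0.998 ≈ 500:1 bias), independent 5′/3′ shifts
from point-mass-dominated jitter distributions over −2..+2 nt, clamps to
the 18–24 nt band by resampling (with a hard cap), and emits exact
window substrings as FASTQ plus pre-made SAM — decoupling tests from any
external aligner, while a naive exact-substring aligner exercises the
FASTQ path. Per-read ground truth is logged so aggregate truth is
recomputable, and the same seed gives byte-identical output.

The defaults emulate the processing statistics of a well-engineered
scaffold: ~99% homogeneous 5′ ends and a 10²–10³-fold guide excess. The
simulator does **not** model sequencing error, adapter artefacts,
ligation bias, or quality variation (qualities are constant), and its
reads come only from the two mature strands — no degradation fragments,
no endogenous miRNA background. Passing round-trip tests therefore shows
that the quantifier recovers known processing statistics from clean
alignments within binomial sampling error; it does not validate
behaviour on contaminated or low-quality real libraries, whose QC is
delegated to upstream tools.

Problem sizes used by the tests and the acceptance script — 10,000-read
libraries for fidelity, 20,000 for the strand-bias ratio, 1,000 fuzzed
records for the CIGAR oracle — were chosen so binomial 99% confidence
intervals are a fraction of the margins being tested.

## Assay calculators

Residual reporter expression is `median mCherry(GFP+) / median
mCherry(GFP−)` within one sample (scale-invariant; knockdown % = 100 ×
(1 − ratio)). The 2D-ddPCR intact-genome percentage is the fraction of
droplets positive for both end probes; whether the denominator should
include probe-negative droplets is ambiguous in common usage, so the
default counts probe-positive droplets only and a switch includes
negatives. No Poisson copies-per-droplet correction is applied.

## Bundled fixtures and limitations

The bundled parents use the miRBase hairpins of hsa-let-7a-1 and
hsa-mir-26b with their annotated mature arms, embedded in a synthetic
flanking context (file names and docs say so): the natural genomic
flanks are not bundled, so determinant checks on the *wild-type*
fixtures reflect the hairpin plus synthetic context, not the native
locus. The screening guide is synthetic. Other known limitations: the
engine requires ≥ 14 nt of parent sequence below the 5p arm; scaffolds
are capped at 200 nt; the validator's verdicts are only as good as the
MFE model behind the folding service; and guide selection (seed design,
off-target search) is explicitly out of scope — guides are inputs.
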