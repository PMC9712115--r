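---
title: "Design methods for Cas13a-assisted phage genome editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design methods for Cas13a-assisted phage genome editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas13design)
```

## The editing scheme this package designs for

Cas13a is an RNA-guided RNA-targeting nuclease: a crRNA consisting of a
direct repeat and a spacer directs it to a complementary transcript, and
target recognition activates promiscuous RNase activity that aborts the
infection. Expressed in the host together with a spacer against a phage
transcript, it acts as a counterselection — wildtype phage cannot plaque,
while a phage whose genome no longer encodes the targeted protospacer
plaques normally. Editing therefore proceeds in two infections: first on a
strain carrying a homologous-recombination (HR) donor, which installs the
edit in a small fraction of progeny genomes; then on the counterselection
strain, which enriches that fraction to near-purity. Everything in this
package serves one of the three design questions this scheme raises —
*where to point Cas13a*, *what edit escapes it*, and *how to score the
outcome from plaque counts*.

Two properties of LbuCas13a shape the design space. It has no PAM/PFS
requirement, so spacers can be placed anywhere on a transcript and design
reduces to window placement plus quality screens. And recognition is
RNA-level, so only transcribed sequence is targetable: the package treats
each annotated CDS (plus optional flanks) as the targetable transcript. How
polycistronic operons were delimited is not modeled; if a gene is
annotated, its mRNA-sense sequence is assumed present during infection.

## Coordinates and genome model

Internally every interval is 0-based half-open; everything user-facing
(GenBank features, TSV tables, reports) is 1-based inclusive. The
convention is pinned by span arithmetic: a deletion written
`165,257..168,510` spans `span_length(165257, 168510)` = 3,254 bp.
Sequences are upper-cased on load; IUPAC ambiguity codes other than `N` are
rejected, and any design window containing `N` is refused rather than
guessed at. Circular genomes are supported for slicing (wrap-around
windows); annotation defaults to linear unless the record declares
otherwise. GenBank input is deliberately minimal — LOCUS, CDS features with
simple or `complement()` locations (a two-segment `join()` is split into
partial-flagged rows), and ORIGIN — because annotation transfer and gene
prediction are out of scope: annotations must be supplied.

## Spacer design

The spacer (default 31 nt, configurable) is the reverse complement of the
transcript-sense protospacer. Four placements are implemented:

* **CDS start** (default): protospacer = first 31 nt of the CDS, so the
  guide covers the start codon and early coding sequence.
* **RBS**: the window opens at position −4 to −6 relative to the A of the
  start codon (position 1), covering the ribosome-binding region plus the
  5′ CDS. Offsets outside [−6, −4] are errors, matching the intent that
  this mode straddles the RBS rather than drifting upstream.
* **Custom**: any transcript offset, for mid-CDS targets.
* **Deletion verification**: the protospacer *ends* 0–15 nt past the
  deleted interval's transcript-sense 3′ boundary, so it covers the edit
  junction: the wildtype locus is targeted, and the edit necessarily
  destroys the exact target site. (A window placed entirely downstream of
  the deletion would survive the edit and could not verify it; the
  junction-covering reading is the one under which a verification guide is
  informative, and the in-silico pipeline asserts it — every deletion
  design leaves both the enrichment and verification protospacers
  unmatched in the edited genome.)

The non-targeting control is the RFP spacer
(`AACTCTTTGATAACGTCTTCGCTACTCGCCA`), a functional guide against a
transcript absent from phage and host.

Two advisory screens flag, never fail, a design. The **off-target screen**
computes the longest exact substring shared between the protospacer (either
strand) and the host genome and flags matches of ≥ 15 nt by default — about
half a spacer, a deliberately conservative proxy for cross-reactivity since
no quantitative similarity criterion is published for this effector. The
**hairpin screen** finds the longest perfect Watson–Crick stem (no wobble
pairs) with a loop of ≥ 3 nt in the mature crRNA and flags stems of ≥ 8 bp;
long self-complementarity within a spacer is associated with guide
misfolding and toxicity. Both are exact, brute-force-checkable definitions
rather than thermodynamic folding models — minimum-free-energy structure
prediction is intentionally out of scope, and the flags are meant as cheap,
reproducible tripwires. The direct repeat is effector-specific
configuration with no shipped default; until one is supplied, hairpin
screening runs on the spacer alone.

## Silent recoding

A recoding edit rewrites the protospacer with synonymous codons so the
protein is untouched while Cas13a's target is destroyed. Three scopes
mirror the published design ladder: `C` recodes a single codon, `S` the
seed region, `F` the full protospacer. The engine works codon-by-codon over
the codons overlapping the protospacer:

* Substitutions are confined to positions inside the protospacer and the
  scope window; codons straddling an edge may change only at in-window
  positions (the flanks double as recombination homology and must stay
  wildtype).
* For each in-scope codon the synonymous alternative maximizing the number
  of changed in-window positions is chosen, **excluding codons with
  relative usage below 0.10** in the supplied table. If the floor would
  freeze a codon that could otherwise change, the best rare codon is used
  and a warning recorded — "avoid rare codons" is treated as a soft
  constraint subordinate to making the edit at all.
* Ties break by higher usage, then alphabetically, so output is fully
  deterministic.
* In `C` mode the codon admitting the most silent changes is chosen, ties
  going to the protospacer 5′ end; a protospacer containing only
  non-degenerate codons (ATG/TGG) is a hard error in `C` mode and a
  warning in `S`/`F`.

The seed window defaults to spacer positions 5–12 (1-based on the spacer,
mapped to the 3′-proximal protospacer positions). This is a documented
assumption, not a published coordinate — the original work defers to prior
in vitro mapping — and it is configurable wherever it is used. The 0.10
rarity floor is likewise an explicit default for an unquantified "rare
codons avoided" instruction. Because published codon and rarity choices are
under-specified, per-scope SNP counts on real genes (e.g. the published
soc 1/3/11 and dnap 3/5/9 ladders) are a reference comparison via
`recode_snp_report()`, not a ground truth the defaults must reproduce.

The shipped E. coli usage table is derived from the classical
codon-adaptation reference set for highly expressed genes: normalizing the
relative-adaptiveness values within each amino-acid family recovers exact
within-family usage fractions. Any table with columns
`codon`/`aa`/`fraction` whose families sum to 1 can be substituted.

`predict_escape()` encodes the observed escape rule-of-thumb: designs with
fewer than 3 contiguous substitutions inside the seed window are labelled
`AT_RISK` (single-codon and seed-only recodings of a non-essential gene
went extinct under enrichment; designs with a fully recoded seed codon or
more survived). It is advisory: the exact-match `verify_escape()` criterion
will call even a 1-SNP edit `DISRUPTED`, and the two together express the
difference between "no longer a perfect target" and "likely to escape in
practice".

## Donors and golden-gate chemistry

Deletion donors carry 250 bp homology arms. For a gene deletion the arms
terminate exactly at the native start and stop codons — the UP arm ends
with the ATG, the DN arm begins with the stop — and the constant 32-nt
primer-binding verification cassette sits between them, in the gene's
transcript orientation (cassette orientation is unstated in the source
material; transcript orientation is this package's documented choice).
Span deletions take arms on the top strand and report genes fully contained
in the span (removed) versus genes overlapping a breakpoint (truncated).
Recoding donors use 52-nt arms flanking the protospacer, so the whole donor
is the wildtype locus carrying only the designed SNPs.

Cloning chemistry follows the two type IIS steps. Spacers are emitted as
two oligos whose 4-nt 5′ overhangs are **derived, not transcribed**: the
package simulates BsaI's GGTCTC(1/5) cut geometry on the printed dropout
placeholder and reads the destination overhangs off the cut positions
(yielding `AAAC`/`AGCA` on the insert). Donor fragments carry the printed
BbsI scheme — insert overhangs 5′-TATC and 5′-TCCT (bottom strand) against
vector ends 3′-ATAG-5′ / 5′-AGGA-3′; the package writes all overhangs
5′→3′, so the left vector overhang prints as `GATA`. Ligation is simulated
and checked scarless (no recognition site survives at a junction);
recognition sites *inside* a donor are reported as domestication warnings
with 1-based positions, since they would cut during assembly but are a
synthesis problem, not a design error.

`apply_edit()` requires each arm to match the genome exactly once, in
order; the reverse-complement orientation of the whole donor is tried
before failing, and ambiguous or inverted matches are errors rather than
guesses. Near-matching (mismatch-tolerant) arm placement is intentionally
unsupported.

## Plaque-assay arithmetic

Titres use the least-diluted spot whose count lies in the countable window
(default 1–50 plaques per 2 µl spot — the window itself is unpublished, so
it is explicit and configurable):
`pfu/ml = count / (volume_ml × dilution)`. Clearing without individual
plaques is interpreted as lysis from without and bounded, not discarded:
the most concentrated plaque-free dilution is scored as 1 p.f.u. and the
titre flagged `is_upper_bound`. All-`NONE` series report 0 with a
below-detection flag (mirroring "ND" extinction calls); all-`TNTC` series
are an error asking for more dilution.

EOP averages replicate p.f.u. *before* the ratio —
`mean(pfu_condition)/mean(pfu_control)` — exactly as the formula is
printed, with `1/EOP` reported as fold-restriction. Penetrance is the
opposite aggregation, per the printed definition: per-replicate ratios
`pfu_enrichment/pfu_negative` averaged across independent editing attempts,
reported mean ± s.d. MOI arithmetic is `pfu = cfu × moi` and
`MOI_i = stock × 10^−i × volume / cfu`; with the published setup (10¹¹
p.f.u./ml stock, 1 µl into 8×10⁶ c.f.u., seven 10× dilutions) the series
runs 12.5 down to 1.25×10⁻⁶.

## The enrichment model

`simulate_enrichment()` is explicitly *not* a model from the source
material; it formalizes the enrichment cartoon just enough to sanity-check
expectations. One passage maps the edited fraction *f* to
*f′ = f / (f + (1 − f)·p)* where *p* is the per-virion probability that a
wildtype infection is productive under counterselection; amplification is
assumed equal for edited and escaping phage, there is no burst-size or
latent-period structure, and no within-host MOI dependence. The stochastic
mode draws edited and escaping counts binomially at a fixed virion
population per passage. The recursion says why a single enrichment passage
is usually enough: at f₀ = 10⁻³ and p = 10⁻⁵ it returns f′ ≈ 0.99, the jump
from the ~0.01–1 % pre-enrichment regime to a nearly pure lysate.

## The synthetic-data generator

`make_toy_phage()` emulates exactly what the design layer consumes: an
annotated genome with stop-free CDSs on both strands. Defaults — five genes
of 150–300 bp on alternating strands, 60–120 bp intergenic spacers, 300 bp
terminal flanks so 250 bp arms always fit, codons sampled from the usage
table restricted to degenerate amino acids — were chosen once as the
smallest genome exercising every code path: the first gene opens with fully
degenerate codons (recoding always has room to move), the last gene's 5′
end is ATG/TGG-only (the no-silent-change error path is reachable), and
`make_host_decoy()` embeds chosen k-mers at known positions for the
off-target screen. Generation uses an isolated RNG stream (the caller's
`.Random.seed` is untouched) and the same seed yields byte-identical
output.

What the fixtures deliberately do *not* emulate: promoters, terminators,
operon structure, overlapping genes, repeats, biased base composition, or
realistic genome sizes. Passing tests therefore demonstrate coordinate
correctness, silence, oracle-equivalence and pipeline consistency — not
that a 31-mer is unique in a 170 kb genome (on real genomes
`apply_edit()`'s arm-uniqueness check and the off-target screen do that
work), and not that flagged hairpins misfold in vivo.

## Numerical and testing choices

Property suites run at fixed seeds: silence is checked codon-for-codon on
over 1,000 generated recodings; full-protospacer recoding is compared
against an exhaustive search over all synonymous codon combinations on
short windows; the off-target and hairpin scans are compared against
brute-force oracles on hundreds of random instances; ligation scarlessness
and the design→edit→verify pipeline are quantified over 100 random donors
each. The stochastic enrichment check compares the mean of 10⁴ single-
passage simulations at a population of 2,000 virions against the closed
form within three standard errors; at these sizes the finite-population
bias of the ratio is about two orders of magnitude below the Monte-Carlo
band, so the comparison is meaningful. Problem sizes throughout (2 kb toy
genomes, 300 bp off-target subjects, 60-nt hairpin inputs) are desk-scale
choices that keep the whole suite in the low minutes on one CPU.

## Known limitations

* No thermodynamic RNA folding, PFS/anti-tag scoring, or activity
  prediction — window placement plus exact-match screens only.
* Recoding optimizes per-codon change count; it does not model mRNA
  structure, codon-pair bias, or regulatory elements overlapping the CDS.
* GenBank support covers the subset needed for phage records with CDS
  annotations; rich location operators beyond a simple `join()` are
  rejected.
* The enrichment simulator is a two-parameter caricature for intuition,
  not inference.
* Arm matching is exact; donors for loci with near-repeats must be checked
  against the multiple-match error rather than resolved automatically.
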