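---
title: "Classifying plant MDAR isoforms from targeting signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plant MDAR isoforms from targeting signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdartools)
```

## The problem and the model

Plant monodehydroascorbate reductases (MDARs) form small gene families
whose members are distributed across chloroplasts/mitochondria, the
peroxisomal membrane, the peroxisomal matrix and the cytosol. The
compartment is encoded in the protein sequence itself, which makes a
rule-based classifier possible:

1. **Catalytic gate.** MDAR activity requires specific residues — an
   arginine and a tyrosine at positions 320 and 349 of the rice OsaMDAR3
   reference. A candidate with a substitution or an alignment gap at
   either position is reported as *MDAR-like* and takes no further part
   in classification or clade voting.
2. **Class II (peroxisomal membrane).** A transmembrane-like hydrophobic
   span near the C-terminus, normally followed immediately by a cluster
   of basic residues (the mPTS; the archetype tail is `...RRRRRW`).
   Members lacking the basic cluster are still class II but carry the
   `tm_no_basic_cluster` flag, since their membrane insertion is less
   certain.
3. **Class I (chloroplastic/mitochondrial).** An N-terminal extension
   relative to a cytosolic-core reference, with transit-peptide-like
   composition, and no PTS1.
4. **Class III (cytosolic/peroxisomal).** Everything else. A C-terminal
   PTS1-like tripeptide adds `dual_targeting_pts1` (these weak signals
   split the protein between cytosol and peroxisomal matrix); its absence
   adds `cytosol_specific`.

The precedence II > I > III reflects how mechanically unambiguous each
signal is: a C-terminal transmembrane anchor is a physical feature that
overrides soluble-compartment signals, whereas the extension and the
tripeptide are weaker statistical signals. Contradictory evidence — an
organellar extension together with a PTS1, or a clade vote that
disagrees with the signal class — is *flagged* (`conflict`), never
silently resolved: real families contain such sequences and they deserve
manual review.

A neighbor-joining phylogeny corroborates the signal classes. The tree
never changes a class assignment; it only supplies `clade_class` and the
`conflict` flag. This ordering (signals decide, tree confirms) matches
how the three classes were originally delineated, and it keeps the
classifier usable when no reliable alignment-wide tree exists.

## Tunable parameters

All thresholds live in `mdar_config()` and can be overridden there or via
a plain `key = value` file:

| parameter | default | meaning |
|---|---|---|
| `tm_window` | 19 | hydropathy window (residues); the classic single-span setting |
| `tm_threshold` | 1.6 | mean Kyte–Doolittle index calling a window TM-like |
| `cterm_margin` | 40 | a TM span counts as C-terminal if it ends within this many residues of the end |
| `tail_window` | 10 | how far past the TM the basic cluster may begin |
| `min_basic` | 4 | K/R count in 6 consecutive residues that makes a basic cluster (`RRRRRW` has 5) |
| `min_extension` | 30 | minimum N-terminal extension before the organellar heuristic runs (transit peptides are rarely shorter) |
| `organellar_threshold` | 0.05 | composition score above which an extension is organellar |
| `typical_length_range` | 400–552 | lengths outside this range set `atypical_length` |
| `pts1_list` | AKI, AKV, ASL, SNL, SKV, SKI, SKF, SRI, CKM, CKI | accepted tripeptides besides canonical SKL |
| `pts1_pattern_enabled` | FALSE | loose `[ASC][KRNS][LIVMF]` tier |

The PTS1 *pattern* tier is off by default: classification trusts only the
canonical tripeptide and the explicitly listed plant-functional variants.
The pattern tier exists for exploratory scans (it admits, e.g., the
algal-style `SRM>`, whose functionality in green algae is unresolved).

The organellar call is a deliberately simple composition heuristic —
`freq(S) + freq(R) − freq(D) − freq(E)` over the first 50 extension
residues — built on the long-standing observation that chloroplast and
mitochondrial transit peptides are serine/arginine-rich and depleted in
acidic residues. It is a documented, replaceable scoring rule, not a
trained predictor; users with access to dedicated targeting predictors
can substitute their calls and re-enter the pipeline at
`classify_sequence()`.

## Numerical and algorithmic choices

**Hydropathy in exact tenths.** Kyte–Doolittle indices are exact decimal
tenths, so window sums are accumulated as scaled integers. Threshold
comparisons at exactly 1.6 are then reproducible regardless of summation
order — with plain floating-point cumulative sums, borderline windows
flip unpredictably.

**Basic-cluster anchor.** Reported TM spans cover the *full* scoring
windows, so a span's end overshoots the hydrophobic stretch by half a
window and can swallow a basic cluster sitting at the very C-terminus.
The cluster search is therefore anchored at the last above-threshold
window centre (span end − window/2) and runs `tail_window` residues
forward. Among qualifying 6-residue windows the one with the most K/R
(ties: most C-terminal) is reported, so the archetype tail yields
`RRRRRW` rather than a partially overlapping window.

**Distances.** p-distance with pairwise gap deletion; `X` counts as a
mismatch against everything, including `X`. The original tree was built
with a tool whose substitution model is unrecorded ("default settings"),
so the simplest defensible distance is used and a Poisson correction
(−ln(1−p)) is available as an option. Pairs sharing fewer than 10
comparable columns are an error rather than a silent unreliable value.

**Neighbor joining.** Standard Saitou–Nei agglomeration with three fixed
conventions: (i) ties in the Q criterion are broken by lexicographic
order of the joined clusters' smallest leaf labels, making output
platform-independent; (ii) negative pendant branch lengths are clamped to
zero with the deficit moved to the sister branch, preserving the joined
pair's path length (at the terminal trifurcation, where "sister" is
ambiguous, negatives are simply clamped); (iii) two taxa split their
single distance equally — NJ proper is undefined at n = 2, so the
convention is fixed once and shared with the Newick writer.

**Bootstrap.** Column resampling with replacement, same length, NJ per
replicate; supports are attached to the full-data tree's splits only (no
consensus tree), as percentage of replicates containing each split. A
replicate that leaves some pair under the comparable-column minimum is
redrawn at most 10 times. Fixed seed, fixed output; supports are
invariant to the input row order because tie-breaking uses labels, not
indices.

**Clade voting.** The `phylo` rooting is presentational, so voting works
on unrooted splits: each sequence's candidate clades are the split sides
containing it, smallest first (whole leaf set as fallback). The smallest
clade with ≥ 3 leaves and ≥ 2 other signal-classified members votes by
majority; MDAR-like sequences neither vote nor are voted on; a tied vote
defers to the next larger clade.

**Genetics.** Gamete frequencies per locus are multiplied across (at
most two) unlinked loci; lethal genotype classes are zeroed and survivors
renormalized, an operation that is idempotent by construction. The
observed-ratio convention follows the printed form "ratio of A to B" as
B/A (61 and 78 seedlings give 1.28). The chi-squared statistic, degrees
of freedom and p-value come from the closed formula with
`stats::pchisq`; categories with zero expectation and nonzero counts are
an error rather than an infinite statistic.

## What the synthetic generator emulates — and what it does not

`generate_family()` plants exactly the features the classifier reads: an
ancestral ~435-residue core with the two catalytic residues, an S/R-rich
60-residue extension for class I, a 21-residue I/L/V/F stretch plus
`RRRRRW` for class II, a listed tripeptide for PTS1 class III, and an
R320→A substitution for MDAR-like sequences. Sequences diverge by point
substitutions in two steps (root → paralog ancestor → species), giving
each isoform class its own clade, as expected when gene duplication
precedes speciation. An undecorated, unmutated reference row `REF_CYTO`
is always included, since extension measurement is defined relative to a
cytosolic core.

Three construction guarantees make truth labels exact: planted signal
residues and catalytic positions are never mutated; the ancestral core is
rejection-sampled so no 19-window reaches the TM threshold, and mutation
rounds that would drift a window over the threshold are resampled, so
planted stretches are the only TM calls; and the core's C-terminal
tripeptide is excluded from mutation and rejection-checked against the
PTS1 tiers, so no sequence gains or loses a PTS1 by accident. Without
indels all rows share one coordinate frame, so the emitted alignment is
exact; with `indels = TRUE` coordinates diverge and no alignment is
produced (alignment construction is outside this package's scope).

The generator is a statistical stand-in, not a sequence emulator: it does
not reproduce real MDAR residue composition, real inter-species
distances, Poaceae-style class II subclade structure, or alternative
splicing. Passing tests therefore demonstrate that the *rules* are
implemented correctly and are mutually consistent with the scanners —
not that the heuristics (hydropathy cutoffs, composition score) would
achieve the same accuracy on arbitrary real proteomes, where signal
strength varies continuously.

## Problem sizes

The default study family is 5 species × (1 class I + 1 class II + 1 PTS1
class III + 2 cytosolic class III) + the reference = 26 sequences of
435-residue cores (alignment width 525), mutation rate 0.05 per site per
lineage segment. Bootstrap corroboration uses 200 replicates, which is
ample for the clean between-class splits here (supports saturate at 100);
the function defaults to 1000 for real data. Topology validation uses 50
random additive matrices of 4–6 taxa, where NJ is provably consistent and
an exhaustive least-squares search over all unrooted topologies is
feasible as an independent oracle.

## Known limitations

* The organellar heuristic and the TM/cluster thresholds are literature
  conventions, not fitted parameters; borderline real sequences (weak
  transit peptides, marginal TM spans) will be sensitive to them.
* Dual-domain (tandem) isoforms are detected only via a user-supplied
  catalytic-context motif, a proxy for a proper profile-HMM domain
  search.
* Only 1–2 unlinked loci are modelled in the genetics layer; linked loci
  would need recombination-fraction handling that is out of scope.
* The NJ tree is unrooted and no consensus tree is built; supports
  annotate the full-data topology only.
* Specific activities can be recomputed only when extract protein
  concentrations are known; the package converts, it does not measure.
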