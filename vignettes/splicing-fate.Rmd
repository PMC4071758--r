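---
title: "Classifying splice forms, predicting their protein fate, and tracing intron positions across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying splice forms, predicting their protein fate, and tracing intron positions across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefate)
```

## The problem

Meiotic genes such as the plant *SPO11* paralogs are compact, multi-exon
genes (SPO11-1-like: 15 exons; SPO11-2-like: 11 exons) whose transcripts are
extensively alternatively spliced. Most variants carry a premature
termination codon (PTC) and are candidates for nonsense-mediated decay
(NMD); a few preserve the reading frame and may encode functional,
length-altered proteins. Two analyses recur when such genes are studied:

1. **Splicing fate of individual transcripts** — classify each observed
   transcript structure against the canonical gene model, name the forms,
   and predict the protein consequence of each.
2. **Evolutionary fate of individual introns** — project intron positions
   onto a protein alignment across species, ask which positions are
   conserved, and explain absences as loss events on a species tree.

`splicefate` implements both as composable, deterministic steps over
standard formats (GFF3, FASTA, aligned FASTA, Newick), with a seeded
simulator that generates fully labelled substitutes for an RT-PCR clone
collection, so every step can be validated against ground truth without any
external data.

## Coordinate and strand conventions

GFF3 coordinates (1-based, inclusive, native strand) are converted at load
time to a single internal convention: 0-based, half-open intervals on the
*transcript-oriented* locus, with minus-strand genes reverse-complemented on
load. Every downstream module sees only this representation; the conversion
lives in one file so off-by-one drift has a single choke point. When a GFF3
holds several mRNAs per gene, the one with the longest CDS is canonical,
ties broken by lexicographic mRNA id — deterministic, and consistent with
treating the full-length cDNA as the reference form.

Inter-exon gaps shorter than `min_intron` (default **20 nt**, configurable)
fail validation: they are below plant U2-type intron minima and almost
always annotation artifacts.

## The event taxonomy

A variant exon chain and the canonical chain are compared as two coverage
sets on the locus. Each maximal interval present in exactly one of the two
must be explained:

* interval equal to a **full canonical intron** → intron retention (`IR`,
  positive length change);
* interval flush with an intron's donor end → **alt 5′ splice site**
  (`Alt5SS`); flush with its acceptor end → **alt 3′ splice site**
  (`Alt3SS`); both at once → two AltSS events on that intron;
* interval equal to a **full exon** → exon skipping (`ES`); an exon
  shortened at one edge is an AltSS on the flanking intron, not an ES —
  skipping is only called for complete absence;
* anything else (cryptic exon inside an intron, interior deletion,
  truncated terminal edge) is outside the taxonomy and raises a classed
  error rather than a guess.

`delta_nt` is always the signed change to the mature transcript, so the
canonical spliced length plus the sum of a form's deltas equals the variant
length — an invariant asserted on every classification. A form may carry
several events (e.g. an ES combined with an Alt3SS on the downstream
acceptor); multi-intron retention is reported as that many IR events on one
form.

Forms are named with Greek letters: the event-free form is α, and the
remaining forms are sorted structurally (first event anchor, then type,
then delta, then the full event signature) and named β, γ, … Naming is a
pure function of the event lists — permuting the input rows cannot change a
letter. Because historical labels in the literature were assigned in
discovery order, they need not coincide with these structural labels; the
stable, reproducible order was chosen deliberately. Forms with identical
event lists are merged and their tissue annotations unioned. Event tallies
report both views of combination forms (per-event counts and
forms-containing-type counts), since either convention is defensible.

Observed structures can come in as GFF3 exon chains or as spliced cDNA
sequences; the latter are placed by exact 20-mer anchoring across
junctions. There is deliberately no fuzzy alignment: input structures are
assumed sequence-verified, and any mismatch rejects the sequence rather
than silently repositioning it.

## Protein consequence and the PTC definition

The variant CDS starts at the canonical start codon's locus position (if
the variant lost it, that is reported explicitly, not imputed). Translation
uses the standard genetic code, halts at the first in-frame stop, and
treats codons containing ambiguity codes as `X` — never as stop.

A **PTC is called positionally**: the variant's first in-frame stop is
premature iff its first base does not sit at the locus position of the
canonical stop codon (same position implies same local reading frame, since
codon boundaries then coincide). This definition — rather than the 50-nt
exon-junction heuristic — is what reproduces the reported behaviour that
frame-preserving, stop-free events yield *functional* calls even when the
protein is longer (a retained in-frame intron) or shorter (a skipped
in-frame exon) than canonical. The junction heuristic is still available as
a secondary flag (`junction_rule = TRUE`), off by default, and never
affects the PTC call.

NMD-candidate features are annotated per variant: uORFs in the 5′UTR (ATG
opening a reading frame that terminates inside the UTR; ATGs running into
the CDS are counted separately as "overlapping"), 3′UTR length from the
variant stop (long above **350 nt** by default — the literature says "long"
without a number, so a documented default keeps runs reproducible and
configurable), and splice junctions fully downstream of the variant stop.
The report flags candidate features only; it never claims actual NMD
targeting.

## Decimal-phase projection and conservation

An intron with `o` coding nucleotides upstream interrupts codon
`ceil(o / 3)`. Phase 1 is written `.3`, phase 2 `.6`, phase 0 `.0` — offsets
52, 53, 54 project to `18.3`, `18.6`, `18.0`. Phase-0 introns (between
codons *n* and *n*+1) are keyed on the column of residue *n*, a
deterministic tie-break at gap-adjacent boundaries.

Projected residues are mapped to alignment columns by counting non-gap
characters in each gene's row (the alignment itself is an input artifact,
produced by whatever aligner the analyst prefers). Intron position classes
are keyed by the exact `(column, phase)` pair — no ±1-column tolerance,
because published comparisons of intron positions use exact identity. A
class is *conserved* when at least `k` genes carry it; the default `k` is
all genes (strict identity), and lowering `k` expresses the softer
"conserved in most species" reading. Raising `k` can only shrink the
conserved set, and inserting all-gap columns cannot change membership —
both are tested properties.

## Intron loss by Dollo parsimony

Under Dollo parsimony an intron position is gained once and never regained.
The package places the gain at the **tree root** by default: the classes
interrogated for loss are precisely those treated as ancestral for the
clade under study, so an absence shared by two sister taxa whose outgroup
retains the intron is explained by one loss on their common branch, and an
absence confined to one species by one terminal loss. Loss events are the
maximal all-absent clades — the minimum branch set covering every absence.
`gain = "mrca"` instead places the gain at the most recent common ancestor
of the present leaves, the strictly loss-minimal placement, under which
leaves outside that span simply never had the intron. Both variants are
checked against an exhaustive enumeration over all branch subsets on small
trees.

## What the simulator emulates — and what it does not

The generator produces, from one integer seed, byte-identical gene models
with a realistic compact-plant-gene shape: exons of 60–180 nt, introns of
60–150 nt, GC fraction 0.45, 120 nt 5′UTRs and 200 nt 3′UTRs by default,
`GT…AG` intron boundaries, an ATG start, a single terminal stop, and no
internal in-frame stop. Variants are built by *construction* (the requested
events realized at the coordinate level), and the expected protein outcome
for each is computed by a deliberately naive oracle — a character-by-
character codon walk kept in the simulator, not by the analysis code under
test — so recovery tests are not self-confirming. "Stop-free" introns for
the frame-preserving retention case are resampled until a naive scan
confirms retention reaches the canonical stop.

The simulator does **not** emulate: splice-site motifs beyond the literal
`GT`/`AG` dinucleotides, branch points, expression levels or clone
abundances, sequencing error, or genuine evolutionary sequence divergence
(the planted-conservation alignment uses structurally aligned pseudo-
species, not evolved sequences). Passing tests therefore demonstrate the
correctness of the coordinate arithmetic, classification, translation and
parsimony logic — not robustness to noisy annotation or ambiguous mapping,
which real data can present.

## Validation problem sizes

The recovery and oracle-equivalence properties are exercised on 5 seeds ×
10 genes × (4 single events + 6 pairwise combinations + canonical) = 550
labelled forms each, with 100% exact recovery of `(type, anchor, delta)`
required, and protein length/PTC equality against the naive oracle on every
form. Conservation planting uses 4 pseudo-species with 6 planted classes
plus species-specific extras. These sizes give each property several
hundred independent cases while keeping a full check quick on a laptop.

## Known limitations

* The classifier requires every deviation to be expressible in the four-
  event taxonomy; cryptic exons and interior deletions are rejected, by
  design, rather than approximated.
* Spliced-cDNA placement is exact-match only; a single sequencing error
  rejects the read.
* Dollo loss inference is presence/absence only — no branch lengths, no
  dating, and no regain model.
* The PTC definition is positional; organisms where the exon-junction rule
  is the better NMD predictor should consult the optional `ejc_rule` flag.
* Greek labels beyond ω cycle with a numeric suffix; inventories that large
  are better consumed from the event-signature column.
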