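---
title: "Annotating germline T cell receptor loci and extracting clonotypes with trlocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating germline T cell receptor loci and extracting clonotypes with trlocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

T cell receptor (TR) loci are arrays of V, D, J and C gene segments that
somatic V(D)J recombination assembles into antigen-receptor chains. Annotating
a newly sequenced TR locus means finding every segment in a genomic contig,
deciding whether each is functional, an ORF, a pseudogene, or a remnant,
grouping the V genes into subgroups, and naming everything in the IMGT style.
The same germline database then supports repertoire analysis: pulling CDR3
clonotypes out of RNA-seq reads and asking which V subgroups pair with which
J genes. In teleost fish, where TR loci have expanded through repeated tandem
duplication (the channel catfish TRAD locus spans more than a megabase with
140 V genes in eight subgroups), this workflow is the backbone of comparative
immunogenetics.

`trlocus` implements that workflow end to end, together with a synthetic
locus/repertoire generator that plants ground truth, so every stage can be
validated without touching external databases.

# Gene-segment discovery

Candidate segments are found by local alignment of protein seeds against all
six translated frames of the contig (`six_frame_translate()`,
`seed_search()`), the translated analogue of a translated-protein-to-genome
search. Because the loci of interest are desk-scale (tens of kb to ~1 Mb),
the package runs exact Smith–Waterman (BLOSUM62, affine gaps 11/1) with no
word-seeding heuristic: the best local alignment of each seed against each
frame is taken, the flanking subject intervals are searched recursively, and
overlapping same-strand hits are merged. `iterative_closure()` re-seeds the
search with each round's novel hits until a round adds nothing, capped at 10
rounds — this is how a single founder sequence per subgroup suffices to reach
every diverged member.

The generic `seed_search()` thresholds (35% identity over 40 aa, or score 60)
follow common practice for sensitive homolog scans and are exposed as
arguments. The pipeline wrapper `annotate_locus()` deliberately uses
score-only thresholds instead (V 150, J 65, C 120 BLOSUM62 units): with
exhaustive local alignment, the score of the best chance alignment grows only
logarithmically with locus size, so a score gate separates true segment
homologs from background far more sharply than an identity-over-length rule,
which short high-identity stretches of random sequence satisfy surprisingly
often.

D segments are too short (~12 nt) for translated search; `find_d_segments()`
locates them by near-exact nucleotide match to seed D sequences and accepts a
hit only when recombination signal sequences flank it on both sides.

# Gene models

**RSS.** A recombination signal sequence is modeled as heptamer + spacer +
nonamer with consensus `CACAGTG` / `ACAAAAACC`, the first three heptamer
bases (`CAC`) required, up to 3 mismatches per element, and spacer 12 or 23
± 1 nt (the 12/23 rule). V genes carry a 23-spacer RSS 3′ of the coding
exon; J genes a 12-spacer RSS 5′; D genes both (12/23 at TRB, 12/12
default elsewhere, configurable). Hits are ranked by total mismatches, then
spacer deviation, then distance from the expected boundary; the top hit also
refines the coding-exon edge.

**V exon structure.** A V gene is leader exon (ATG-initiated) + intron
(GT…AG) + coding exon. Given the RSS-anchored coding end, the assembler
enumerates acceptor/donor/leader-start combinations (intron 70–600 nt,
leader length from the chain-subtype window) and scores each candidate
structure by: an in-frame CYS104 codon ending exactly 6 nt before the coding
end; absence of internal stops; leader length inside the subtype window; and
splice-site strength. Splice strength is scored from the *context*, not just
the dinucleotide: 5 points per matching base of the U1 consensus `AAGT`
after the donor GT, 3 points per pyrimidine in the 10 nt before the acceptor
AG (50 total). The dinucleotides themselves contribute less (8 each) than
the context, because chance GT/AG dinucleotides are common in background
sequence while chance near-consensus context is not. Two consequences:

* a candidate leader is only believed when its context reaches
  `min_splice_context` (default 46/50) — below that, the structure is
  indistinguishable from chance and the gene is treated as leader-absent;
* a gene whose donor dinucleotide is mutated still assembles on its true
  structure (a relaxed enumeration tier allows one non-canonical
  dinucleotide when the context is near-consensus), and is then classified
  by its invalid splice rather than mis-assembled.

When several structures tie, the scorer prefers the acceptor closest to the
similarity hit and the shortest consistent leader. In the TRAD locus, where
TRAV and TRDV genes are interleaved, the subtype is assigned from the
recovered leader-exon length (TRAV 40–43 nt, TRDV 64 or 67 nt), which is the
discriminating feature of the two gene types in catfish.

**Functionality.** The classification rules are: remnant if the leader or
the 3′ end through CYS104 is missing; else pseudogene if a splice site is
invalid, or an internal stop or frame defect destroys the reading frame;
else ORF if a 3′ frameshift leaves an open reading frame that still encodes
CYS104 (detected as a CYS codon offset of 4–8 nt, rather than 6, from the
coding end); else functional. Remnant takes precedence over pseudogene when
both apply, so truncated genes are counted as remnants — the two categories
are reported separately and precedence must be fixed somewhere; this is the
package's declared choice.

# Subgroups and naming

V genes are compared over the IMGT region: 22 codons before CYS23 through
6 nt past CYS104 (codons for positions 1–106 of the IMGT unique numbering).
`imgt_trim()` finds CYS23 as the first cysteine in the 20–30 codon window
with a downstream tryptophan anchor, and CYS104 as the last cysteine with a
tyrosine among the two preceding residues (the Y-x-C profile of positions
102–104); full IMGT unique numbering with gaps is out of scope, anchors
suffice for trimming.

Percent identity is computed from a global nucleotide alignment (match +5,
mismatch −4, gap open 10, extend 0.5) as identical positions divided by the
*length of the longer sequence* — the convention of the SIAS-style identity
matrices used in comparative TR studies. The source methodology pairs a
protein matrix (BLOSUM62) with "nucleotide identity"; this package aligns
nucleotides and reports nucleotide identity, which reproduces the
denominator convention while keeping the arithmetic well-defined. The pair
is aligned in canonical order so the function is exactly symmetric.

Subgroups are the connected components of the graph joining genes with
identity ≥ 75% (inclusive: exactly 75.0 joins). Single linkage is the
default because subgroup membership by chained similarity is the IMGT
convention; complete linkage is available as an option. Components are
numbered 5′→3′ by their first member. Names follow the IMGT style: subtype +
subgroup + "-" + 5′→3′ rank within the subgroup (rank omitted for
single-member subgroups), with a "P" suffix for pseudogenes; J/D/C genes are
numbered sequentially along the locus. Remnants are left unnamed. Cassette-
level names for TRG-type loci (for example J3-4P within cassette 3) are not
reproduced; genes are numbered locus-wide.

The J motif scan (`scan_j_motif()`) looks for F-G-X-G in the 3′ portion of
the translated J, masking position 3; a single substitution at one of the
informative positions yields a variant class such as FAXG or FGXA (the
salmon-type FGKA ending is FGXA-family). PHE118 is the motif's first
residue, and ends the CDR3.

# Phylogenetics

`pairwise_p_distance()` implements the p-distance with pairwise deletion:
for each sequence pair, sites with a gap or N in either sequence are removed
and the distance is the fraction of differing retained sites. `nj_tree()` is
the standard Saitou–Nei neighbor-joining agglomeration with two declared
numerical choices: ties in the Q criterion are broken by the
lexicographically smallest label pair (so trees are deterministic), and
negative branch lengths are clamped to zero with a flag recorded in the
`negative_clamped` attribute. `bootstrap_support()` resamples alignment
columns with replacement, rebuilds the tree per replicate, and reports the
percentage of replicates containing each internal bipartition of the
full-data tree; the default of 1000 replicates keeps desk-scale runs fast
(published analyses often use 10,000; supports are stochastic either way and
the count is a parameter). Tests verify that NJ recovers the generating
topology and all path lengths on additive matrices (n ≤ 8) and agrees with
an exhaustive least-squares/minimum-evolution search over all topologies at
n = 5–6.

For self-contained runs the package ships a center-star aligner
(`align_sequences()`): all sequences are aligned globally to the longest one
and the gap patterns merged. This is adequate for the closely related
V-region sets the pipeline compares and keeps the package free of external
aligner binaries; it is *not* a progressive profile aligner, and for deeply
diverged sets an externally produced alignment can be supplied to the
distance/tree functions directly.

# Clonotype extraction

Read pairs are merged by best overlap (within 10–90 nt, minimizing the
mismatch rate; disagreements resolve to the higher-quality base), optionally
quality-trimmed (sliding-window mean Q20), and filtered at a minimum length
of 100 nt — inclusive, so a 100-nt read survives; the upstream tool this
mirrors does not document its boundary semantics, so the inclusive choice is
recorded here. Each merged read is aligned (both orientations) against every
germline V region and J gene; co-optimal hits within a score tolerance
(default 0, exact ties) form the candidate set, and ties confined to one V
subgroup collapse to a subgroup-level call — mirroring ambiguous-segment
merging in clonotyping tools, and motivated by the fact that 3′ V ends are
nearly identical within a subgroup. The CDR3 is the nucleotide span from the
start of the CYS104 codon through the end of the PHE118 codon, both
inclusive (consistent with published 13-residue examples such as
CALNTGGVNKIIF); junctions whose length is not divisible by 3 are flagged
non-productive and excluded from amino-acid statistics. The clonotype
identity key is (chain, V-subgroup set, J-gene set, CDR3 nucleotide
sequence). The chord matrix tallies unambiguous clonotypes by (J gene, V
subgroup); ambiguous ones are excluded and counted, so cells + exclusions
always equals the clonotype total.

# The synthetic generator

`simulate_locus()` builds a contig with planted, coordinate-exact truth:

* V = leader (ATG + stop-free tail, no internal ATG) + intron
  (`GTAAGT`…polypyrimidine`AG`) + coding exon carrying the CYS23/W41/Y102/
  CYS104 anchors + 23-spacer RSS;
* J = 12-spacer RSS + 19-codon exon with F-G-X-G at codon 10 + GT donor
  (real TRAJ genes encode 17–22 aa, and this places simulated TRA CDR3
  lengths in the published 11–18 aa band);
* D = RSS-flanked core (the TRB preset plants the catfish/zebrafish TRBD
  sequence `GGGACAGGGGGC` verbatim); C = a constant-region exon.

Subgroup structure comes from independent founders mutated into members at a
member-to-founder identity of 0.94 (members then share roughly 88–90%,
comfortably above the 75% threshold, while independent founders sit far
below it). Mutations avoid the anchor codons, new cysteines near the
anchors, stops, and new AG dinucleotides in the acceptor-proximal prefix —
the invariants the annotator legitimately relies on. Lesions are planted one
per gene on request: internal stop, donor-splice break, leader deletion, 3′
truncation before CYS104, and a 1-nt insertion between CYS104 and the RSS
(the ORF case). Presets encode the catfish locus architectures at 1/10
scale (for example `trb-like`: 11 V in 3 subgroups, 1 D, 3 J; `trad-like`:
14 V on the minus strand, 4 D; `trg-like`: V-J-C cassettes); tests use
further-reduced counts (4–6 V genes, contigs of ~8–10 kb) so the whole suite
runs in a few minutes on one CPU, and the acceptance script uses the preset
defaults. An optional duplication plan appends a multi-kb block and a
point-mutated copy at a target identity (~96%), the homology-unit structure
that `find_homology_units()` detects by k-mer-anchored self-comparison.

`simulate_repertoire_reads()` draws V/J uniformly, uses up to 4 D segments
for TRD (1 for TRB, 0 otherwise), applies geometric trimming (means 0.5 nt
for TRA — minimally trimmed TRAJ is the hallmark of TRA diversity — and 1.5
elsewhere, capped at 6 nt so the anchors survive) and uniform-base N
additions (means 1/2/2.5 for TRA/TRB+TRG/TRD), resamples until the junction
is productive, and cuts overlapping read pairs (overlap 40–80 nt,
merge-compatible) with optional per-base errors. Under these defaults the
simulated mean CDR3 length is ~13 aa for TRA and ~17–21 aa for TRD,
reproducing the direction and rough size of the published TRA/TRD contrast;
no quantitative trimming or N-addition distributions are published, so these
means are declared generator choices, not inferred ones.

**What passing tests do and do not show.** The generator's intergenic
background is i.i.d. uniform sequence, splice contexts are planted at
consensus, and sequencing errors are uniform substitutions. Round-trip
success therefore demonstrates that the detection, assembly, classification,
clustering and clonotyping logic is correct under the stated model; it does
not demonstrate robustness to real-genome repeat families, degenerate splice
contexts (where `min_splice_context` would need lowering), indel-containing
duplications (which fragment homology-unit diagonals), or platform-specific
error profiles.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open on the forward strand; GFF3
  output converts to 1-based inclusive. Minus-strand segments store
  forward-strand intervals and reverse-complement on extraction.
* IUPAC ambiguity codes beyond N are rejected on input; identity and
  translation semantics for them would be undefined downstream.
* Empty contig sets search to an empty result (not an error); an empty seed
  set is an error. A pair with zero retained sites is an error naming the
  pair, as is an anchor failure naming the anchor.
* `pairwise_identity()` sorts the pair before aligning, making symmetry
  exact rather than approximate.
* Two-taxon NJ returns a single edge split evenly between the leaves.

# Limitations

Constant-region genes are annotated as similarity intervals only (no
transmembrane/cytoplasmic exon roles); full IMGT unique numbering,
allele-level nomenclature, E-value statistics, model-based distances and
UMI/chimera handling are out of scope. Accession-scale reproduction of
published locus annotations requires the corresponding public sequences,
which the package does not download.
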