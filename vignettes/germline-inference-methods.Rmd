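---
title: "Methods: germline light-chain allele inference from 5'RACE AIRR-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline light-chain allele inference from 5'RACE AIRR-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airrgerm)
```

## The problem

Antibody repertoire sequencing reads are rearranged V(D)J transcripts: each
read carries one germline V segment (possibly 5'-truncated by library
effects and 3'-trimmed by junctional processing), a short junction with
non-templated nucleotides, one J segment (5'-trimmed), and the start of a
constant region. The inherited (germline) V and J alleles of an individual
mouse strain are only partially documented in curated databases, so analyses
that assign reads to database alleles mislabel reads and overestimate
somatic hypermutation (SHM) whenever the strain carries undocumented
alleles. `airrgerm` reconstructs a strain's germline V and J allele sets
directly from its 5'RACE repertoire reads, compares the reconstructed sets
across strains and against a reference database, groups strains into
locus haplotypes from SNP genotypes, and quantifies the amino-acid
divergence structure of the inferred V genes.

Every stage can be exercised against a built-in simulator with known ground
truth, which is how the package validates itself end to end.

## Preprocessing (5'RACE)

Reads begin with a library primer followed by the template-switch G-run.
`mask_primers()` locates the best primer by ungapped scan over the first 30
nt (default tolerance 2 mismatches; the tolerance absorbs sequencing error,
and an ungapped scan is sufficient because primers are synthetic and not
subject to indels), replaces it with `N` and removes an immediately
following run of three or more G. Masking instead of trimming keeps read
coordinates stable; all downstream alignment treats `N` as strictly
neutral, so masked bases can never pay or earn score. `merge_pairs()`
merges each read pair at its best ungapped overlap (minimum 20 nt, at most
10% mismatches; disagreements resolve toward the higher base quality, ties
toward read 1). `collapse_duplicates()` collapses exact duplicates and
records the multiplicity as `dupcount`; inference uses only sequences with
`dupcount >= 2`, the conventional independent-observation filter.

## Alignment

All comparisons use one affine-gap aligner (match +1, mismatch -2, gap
open -4, gap extend -1; a gap of length $k$ costs $4 + k$) with three
modes: global, glocal (query global, reference-terminal gaps free) and
local. Percent identity is $100\,m/c$ where $m$ counts matches and $c$ the
aligned columns excluding terminal gaps; columns containing `N` are
excluded entirely. The paper trail for identity definitions across
alignment tools is murky, so the package uses this single definition
everywhere and documents it. Traceback ties prefer diagonal, then query
base against a gap, then reference base against a gap; Smith-Waterman
restarts are preferred over continuing a zero-score path, so local
alignments never carry spurious leading columns. V assignment shortlists
alleles by their best ungapped placement score (exact whenever the true
alignment is gap-free, which holds for substitution-only differences) and
runs the exact DP on the shortlist; a score margin (default 9) keeps
near-ties in play.

## V allele inference

The inference procedure follows the manual light-chain workflow: assign
reads to the starting reference, estimate a per-sample clonal threshold
from the distance-to-nearest distribution of junctions (deepest valley of a
kernel density estimate between the first two modes; fallback 0.1 when the
distribution is unimodal or underpowered), group reads into clones by
single-linkage clustering of junctions within (V call, junction length)
partitions, and derive candidate germline alleles from clone consensus
sequences, keeping only candidates supported by at least 0.1% of all
clones in the sample.

Three design points deserve explanation.

**Greedy clustering tolerance.** Clones are grouped by (V call, percent
identity stratum; stratum width 2.5%) and clustered greedily: a clone joins
the first cluster whose seed it matches at >= 94% identity over their
common covered positions. Two sequences independently mutated at per-base
rate $r$ differ at about $2r$ of their positions, so a tolerance of
$1 - 2r - 3\sigma$ with $r = 2\%$ and $\sigma \approx 1.2\%$ gives roughly
0.94; a 100% tolerance would make every hypermutated clone a singleton and
no candidate could ever reach the support rule. The stratum width is set to
cover the SHM-induced spread of read identities (about $\pm 2.5\%$ at 2%
SHM) so that one allele's clones are not fragmented across strata.

**Polymorphic-position splitting.** A greedy cluster can legitimately
contain two co-alleles that differ by as little as one nucleotide. Before
consensus, every cluster is scanned for positions where a minority base is
carried by at least 5 clones and at least 20% of the position's voters; the
cluster is split on the strongest such position and the procedure recurses.
This separates co-alleles while random SHM (which is never coordinated
across clones) stays below the split threshold.

**The junction shadow.** The last few V positions sit inside the junction:
a molecule whose V was 3'-trimmed by $t$ nt aligns junction-derived bases
onto its final $t$ V positions. The J alignment bounds the trim: with
$\delta$ = (observed J start) − (expected J start had the V been
untrimmed), the trim satisfies $t \ge \max(0, -\delta)$, and positions
provably inside the trim are blanked. For the remaining shadow positions
(the last 3), consensus votes are weighted by the posterior probability
that the voter genuinely covers the position, computed from $\delta$ under
the junction model (trim and insert uniform on 0-3 and 0-4). After
clustering, `polish_inferred()` re-votes each candidate's shadow positions
over the complete collapsed read set, including dupcount-1 reads that the
clonal analysis excluded — the shadow needs raw coverage, not clonal
independence. The re-vote weights each read's base linearly by its
coverage probability; a log-likelihood vote was evaluated and rejected
because junction-derived bases are correlated across reads of one
junction context, and multiplying their small per-read evidence lets them
overwhelm genuine coverage, while a linear vote caps each voter's
influence. The polish step also drops candidates whose dupcount-weighted
read support falls below 0.1%, the read-level analogue of the clone
support rule.
Consensus artifacts attract only the reads that share their private
mutation, so this removes them without touching genuine alleles.

Interior consensus ties resolve toward the assigned reference base when it
is among the tied bases, otherwise alphabetically. An absolute cluster
floor of 5 clones complements the 0.1% rule at desk scale (0.1% of a few
thousand clones would otherwise admit 2-clone clusters whose consensus is
not statistically protected). Candidates that are substrings of longer
candidates are folded into them; candidates identical outside the shadow
are pooled and re-voted.

`validate_genotype()` implements the strict genotype-style confirmation
(an allele is kept only with at least 3 uniquely best, 100%-identity
supporting reads). It is exposed separately rather than wired into the
default pipeline: under per-base SHM of 2% an exact 285-nt match occurs in
only $0.98^{285} \approx 0.3\%$ of reads, so at desk-scale depth strict
validation would reject genuine alleles; it is appropriate for deep or
lightly mutated data.

## Novel J discovery

J segments are short (about 38 nt) and 5'-trimmed, so one novel J appears
as a family of substring-related J strings. Discovery counts distinct
J-aligned read substrings (dupcount-weighted), dismisses exact substrings
of reference J alleles, groups the remainder into substring-related
families, and accepts a family whose summed frequency exceeds 1% — the
published rate rule. The reported candidate is the family's longest member
whose own frequency is coherent with the modal member (at least 15%
of it); rare alignment-ambiguity extensions are thereby excluded. The
stored J end is anchored to the full extent of the called J on the read
rather than the raw local-alignment end, because local alignment clips
terminal mismatches and would otherwise hide polymorphisms in the last
bases of a J. Frequencies are dupcount-weighted by default (a flag switches
to unique-sequence counting, since the published rate rule does not say
which was used), and a family must contain at least two distinct member
strings: genuine novel segments always appear as several trimmed variants,
whereas a single hypermutated molecule amplified to high duplicate count
yields only one. `rebuild_and_verify()` adds accepted candidates to the
database, re-assigns, and repeats until no new candidate emerges; the
candidate set grows monotonically and is bounded, so this terminates.

A J polymorphism in the first few bases remains undetectable in
principle from junction-trimmed reads: it cannot be distinguished from
junctional nucleotides. The same ambiguity affects any inference tool.

## Strain comparison

`db_representation()` reports, for each inferred allele, its best database
match and identity; "present" demands a full-length 100% match, mirroring
the present/absent dichotomy used for database representation counts.
`sharing_sets()` computes exact-sequence sharing combinations across
strains (UpSet-style). `pairwise_set_similarity()` takes the smaller set
as query, assigns each query allele its best match by identity, then
alignment length, then name, excludes matches aligned over fewer than 275
nt, and averages; `similarity_matrix_and_clustering()` assembles the
symmetric matrix (diagonal 100) and clusters strains by average linkage on
`100 - similarity`.

## SNP haplotype grouping

Positions with a missing genotype in any strain are masked across all
strains, so missingness cannot shape the topology. Distances are
p-distances over unmasked positions, and the tree is a hand-implemented
Saitou-Nei neighbor joining with deterministic tie-breaking (smallest index
pair) and negative branch lengths clamped to zero; the final pair is
joined through a midpoint node, which preserves all path lengths and
reduces to the conventional half-split for two taxa. On any additive
matrix this reconstruction is exact. Haplotype groups are obtained by
removing the $k-1$ longest internal edges (longest terminal edges when
fewer internal edges exist, which is what lets $k = n$ produce singleton
groups); groups are labelled A, B, C... by decreasing size. The group
count $k$ is always supplied by the caller — the original analysis chose
clades by inspection, and silently guessing $k$ would hide that judgement.
Heterozygous genotype codes are rejected: the analysis concerns inbred
(homozygous) strains.

## Divergence analysis

V genes of a strain and locus are translated (standard code, trailing
partial codon dropped); sequences translating with a stop codon are
discarded. Per-gene mean pairwise identities come from global amino-acid
alignments; because percent identity is computed from a traceback, the
value can differ slightly with alignment direction for dissimilar
sequences, so the per-gene value always uses that gene as the query, and
tree distances use direction-averaged identities. The tree is neighbor
joining on `1 - identity/100`, midpoint rooted (rooting is needed to give
the height $L$ a meaning; midpoint rooting is the assumption-free choice).
Family clusters are the maximal subtrees of height at most $0.1\,L$ —
maximality is the only reading that yields a partition of the leaves.
Cluster consensus is the per-column majority (ties alphabetical) over the
cluster alignment (direct stacking for equal lengths, star alignment
against the longest member otherwise, with insertions relative to the
centre dropped); a gene's divergence is its fraction of non-matching
columns against the consensus, excluding gap-gap columns and counting
gap-versus-residue as non-matching.

## The simulator and what it does (not) show

`simulate_germline_panel()` plants founder ("database") alleles, per-group
variants and per-strain private variants with exact sharing fractions, so
set-level comparisons have closed-form expectations.
`simulate_repertoire()` emits molecules of the form primer + G-run +
5'UTR/leader + (possibly 5'-truncated) V + junction + J + constant stub.
The leader (15-30 nt, never G-initial) matters: without it, G-run trimming
would eat the leading G bases of G-starting V alleles — real 5'RACE reads
carry the transcript leader in this position. A 5'-truncated molecule
carries no leader, because truncation reflects reverse transcription
stalling inside the V with the template switch at the stall point; its
missing V 5' bases consequently align over the neutral primer mask rather
than over leader sequence. Junctions trim 0-3 nt from
the V 3' and J 5' ends and insert 0-4 random nt; SHM is uniform per base
(no hotspot model), duplicates are `1 + Poisson(mean - 1)` per molecule
with independent per-base sequencing errors, and pairs follow 2x300
geometry with guaranteed overlap. `simulate_snp_matrix()` gives each
haplotype group an independent random ancestor and perturbs strains at 2%
per position, with missing cells at the configured rate.

Defaults reflect the study conditions this package targets: 285-nt V and
38-nt J alleles, SHM 2% per base, sequencing error 0.3% per base, mean 3
duplicates, 20,000 read pairs per strain (split evenly across the two
light-chain loci in the validation runs: 10,000 per locus, mirroring
similar per-locus library sizes), 40 kappa and 3 lambda V alleles for the
recovery benchmark. The divergence-ordering simulation uses 6 families x 2
genes per strain, 60 residues, rates 2% and 10%, and a subtree bound of
0.25 L (chosen so that family subtrees retain both strains' members at
these rates).

What passing these simulations does *not* show: the SHM model has no
hotspot structure or indels, quality strings are uninformative (so merging
cannot correct errors), junction inserts are uniform rather than
N-nucleotide biased, and there is no chimerism or cross-sample
contamination. Real-data behaviour at the margins — particularly indel
novel alleles and heavily biased junctions — is outside what these tests
establish.

## Numerical and degenerate-input choices

* All containers are ordered deterministically (by name or id); outputs
  are byte-stable under input permutation and fixed seeds.
* Junction distance thresholds fall back to 0.1 with a warning when the
  distance distribution is degenerate, unimodal, or based on fewer than 50
  rearrangements.
* Density-valley detection ignores modes below 5% of the maximum density.
* A tree of height zero yields a single family cluster; `fraction = 1`
  yields a single cluster by construction.
* Zero-length junctions give distance 0 (a single clone per V call).
* Merging failure is a reported outcome, never an error; reads without a
  qualifying J simply have an empty `j_call` when `ignore_j = TRUE`.

## Problem sizes used in the test-suite and validation runs

The bundled validation uses, per run: 10,000 read pairs per locus for the
recovery benchmark (40 + 3 planted alleles), 1,500 molecules per novel-J
operating-characteristic run (10 seeds per usage rate), 324 SNP positions
for 18 strains in 3 groups (10 seeds), 100 random additive matrices up to
8 taxa, and 100 random trees for the subtree-partition oracle. These sizes
give the statistical room the checks need (for example, about 36 clones
per allele after the dupcount filter) while keeping a full validation run
in the minutes range on a single core.

## Known limitations

* Indel novel alleles are out of scope; the simulator does not emit them
  and the inference consensus assumes substitution-only variation.
* J polymorphisms in the first 1-2 bases are unidentifiable from
  junction-trimmed reads (see above).
* `validate_genotype()` is too strict for heavily mutated repertoires at
  low depth; use `polish_inferred()`'s read-support rule there.
* The greedy cluster tolerance (94%) assumes SHM loads up to about 2% per
  base; far heavier mutation would fragment clusters and lower recall.
* Database "presence" is exact full-length identity; partial or truncated
  database entries count as absent.
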