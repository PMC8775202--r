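---
title: "Domain-guided retrotransposon mining: models and methods"
author: "retromine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-guided retrotransposon mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most de novo annotation tools for long terminal repeat retrotransposons
(LTR-RTs) search for the terminal repeats first and the coding sequence
second. That strategy silently misses the large fraction of genomic copies
that are fragmented, degenerate, or have lost recognisable LTRs, even though
their conserved protein domains — reverse transcriptase (RT) above all — are
still detectable. `retromine` inverts the search: it starts from
protein-domain matches on the translated genome and only then asks about
element structure and terminal repeats. The output is a set of structurally
annotated nucleotide and per-domain amino-acid sequences ready for
comparative and phylogenetic work, not a repeat-masking track.

## Pipeline model

The pipeline is two nested homology searches with structural post-processing:

1. **Batching.** Assemblies over 1 Gbp are split for search speed: records
   below 1 Gbp stay intact (one per batch); a record of length $L \ge 1$ Gbp
   is cut into $N = \lfloor L/c \rfloor + 1$ equal pieces with the remainder
   in the last piece, $c = 100$ Mbp, giving $N-1$ breakpoints. Piece sizing
   within an oversized record is not dictated by the underlying method; equal
   cuts were chosen for reproducibility. All downstream coordinates are
   reported in original assembly coordinates (0-based half-open internally;
   1-based inclusive only in GFF3/FASTA headers).
2. **Round 1.** The single *core* profile (RT by default) is scanned against
   all six reading frames. Matches are pre-filtered by e-value
   ($\le 10^{-3}$, inclusive by convention) and matched profile fraction
   ($\ge 0.3$; the bound is deliberately permissive so that frameshift
   fragments survive for later chaining — the underlying method states only
   that matches are filtered "by length").
3. **Loci.** Each surviving match is expanded by 7500 bp on both sides,
   clipped at record bounds; overlapping or touching expansions merge into
   one locus (set semantics). Merging is our choice — it avoids annotating
   the same region twice and the delineation stage re-splits multi-element
   loci.
4. **Round 2.** The full profile set is scanned against the extracted locus
   sequences only, then chained, delineated into elements, checked for ORF
   intactness, searched for LTR pairs, scored and named.
5. **Clustering.** Core-domain peptides are clustered greedily at 0.8
   identity / 0.8 bidirectional coverage and one representative is kept per
   cluster.

## The six-frame PSSM scanner

The internal search backend scores each translated frame against a
position-specific scoring matrix and reports maximal-scoring ungapped
segments per alignment diagonal (a Kadane walk per diagonal, implemented in
C++). Stop codons and ambiguous residues score the matrix minimum, so
segments break naturally at stops. Raw scores $S$ become bit scores and
e-values through Karlin–Altschul statistics: $\lambda$ is solved per profile
from $\frac{1}{20L}\sum_{i,a} e^{\lambda s_{ia}} = 1$ (uniform residue
background), $K$ is fixed at 0.1, and $E = K m n e^{-\lambda S}$ with $m$
the profile length and $n$ the total residues scanned in the call. On
uniform random sequence this calibration reports approximately $E$ chance
hits per search at threshold $E$ (13 observed at $E \le 10$ on 1 Mb with one
profile), and zero hits at the $10^{-3}$ working threshold across 100 random
100 kb genomes. An adapter parses external RPS-BLAST tabular output
(`qseqid sseqid qstart qend sstart send evalue bitscore qframe qseq`,
1-based inclusive, converted at parse time) into the same hit table, so a
CDD-backed search can replace the internal scanner without touching
downstream stages.

## Fragment chaining

A domain interrupted by a frameshift or small insertion appears as two or
more hits of the same profile, on the same strand, in different frames, with
nearly colinear profile coordinates. Hits of one (profile, strand) group are
ordered along the element and may chain when the genomic gap is at most
600 bp, the gap is not more negative than $-3 \times 15$ bp, and the profile
coordinates advance (`profile_start >= previous profile_end - 15`). The
defaults (600 bp gap, 15 aa overlap) span small indels without bridging
tandem copies; both are configurable. The partition into chains is computed
as an exact minimum path cover of the chainability DAG (Kuhn's bipartite
matching) rather than by one-pass greedy extension: the exact cover is
deterministic, independent of input order, and provably equal to the
exhaustive best partition that the test suite checks on all small cases —
a one-pass greedy scan can close a chain too early when a later fragment
chains to an earlier hit. Chained peptides are spliced in profile order,
trimming any profile overlap from the downstream fragment.

## Delineation and ORF calls

Each core-domain chain founds one element; every non-core domain is
assigned to the nearest same-strand core, with territories bounded by
midpoints between successive cores, so tandem copies inside one merged
locus split cleanly. The assignment rule is ours; the method description
only states that multiple core domains are delineated into separate
assemblies. Structure strings read 5'→3' in element orientation
(genomic order reversed on the minus strand), e.g. `GAG.Pro.gRT.gRH.INT`.

ORF intactness is assessed per domain envelope: a domain is intact when it
is not frameshift-chained and its translated envelope contains no stop
codon; the element flag is the conjunction. Whether "uninterrupted ORFs"
means one continuous polyprotein frame or per-domain integrity is ambiguous
in the underlying description; per-domain is robust to spacers between
domains and is what the score uses (as a fraction of intact domains).

## LTR detection

LTRs are direct repeats, so the 7500 bp windows upstream of the first and
downstream of the last domain are compared in the same orientation
regardless of element strand. Aligning the full windows is quadratic
(~3 s per element measured), so candidate repeat regions are located first:
shared 8-mers (occurrences capped at 10 per side) are chained by diagonal
(drift ≤ 50, positional gap ≤ 400); chains with at least 3 seeds — at the
working thresholds a true repeat always has tens — nominate subwindows
(±250 bp margins) that are aligned locally with blastn-like scoring
(match 2, mismatch −3, gap open 12, gap extend 4). Gap penalties are set
high because the decisive signal is substitution identity; permissive gap
costs let the aligner drag in spurious gapped tails from the flanks.

Two post-processing steps keep the reported repeat honest:

* **End trimming.** The maximal-scoring run of alignment columns under
  +1 per match, −1.5 per mismatch or gap column is kept, which cuts
  terminal stretches below ~60% identity (random flank dragged in by the
  aligner) while leaving mismatch clusters inside a genuine ≥80% repeat
  alone.
* **Full-repeat extension check.** A qualifying alignment could be a
  fragment of a longer repeat whose full-length alignment was rejected
  (e.g. a 3.1 kb repeat seen through a smaller candidate window). Each
  qualifying candidate is extended ungapped along its diagonal (X-drop 12)
  and rejected when the extended repeat reaches the 3000 bp bound.

Identity is matches over alignment columns of the aligned region (the
repeat-wide alternative is not computable without knowing the true repeat
extent); length is the alignment column count. The thresholds are strict
inequalities exactly as specified: identity > 80, 100 < length < 3000;
identity exactly 80.0 or length exactly 100/3000 is rejected. Among
qualifying candidates the highest alignment score wins; ties prefer the
longer, then leftmost pair. Only the single best local alignment per
candidate region is considered.

## Scoring and naming

The underlying method names the score's ingredients — domain count, match
length/quality, ORF intactness, LTR identity — but not a formula; the
formula here is this package's own definition, fully configurable:

$$\text{score} = 100\,( w_d \min(1, n/n_\text{exp}) + w_c \overline{\text{cov}}
 + w_o f_\text{ORF} + w_\ell \,\text{id}_\text{LTR}/100 )$$

with defaults $w_d, w_c, w_o, w_\ell = 0.4, 0.3, 0.15, 0.15$,
$n_\text{exp} = 5$ (the canonical Ty3/gypsy `GAG.Pro.gRT.gRH.INT` layout),
$\overline{\text{cov}}$ the mean matched profile fraction, $f_\text{ORF}$
the intact-domain fraction, and $\text{id}_\text{LTR} = 0$ when no pair was
found. The score is bounded in [0, 100], monotone in every ingredient, and
printed with one decimal. Scores are not calibrated against any external
tool's values.

Identifiers follow
`{project}_{batch}_{num}|{structure}|{ltr}|{score}` with `num` zero-padded
to four digits and `ltr` either `LTR%{identity:.3f}-{length}` (e.g.
`LTR%99.567-232`) or `LTR%none`; `parse_element_id()` inverts the grammar.

## Clustering

Greedy incremental clustering over core-domain peptides, visited by
decreasing length: a sequence joins the first existing cluster whose
founder aligns with identity ≥ 0.8 over ≥ 0.8 coverage of *both* sequences
(ends-free global alignment; identity = matches / alignment columns), else
founds a new cluster. A shared-5-mer prefilter skips pairs that cannot
reach the identity bound, which keeps the 1000-sequence case around a
second. Bidirectional coverage is our reading of the coverage mode; it is
the stricter of the plausible options. Representatives are chosen by
structure richness (domain count), then score, then lexicographic id —
the method statement gives both criteria without precedence, and
structure-first retains maximal structural diversity, which is the stated
goal of keeping representatives at all.

## The synthetic genome generator

`plant_genome()` embeds fully specified elements — LTR, 150 bp spacer,
domain coding sequences back-translated from toy consensus peptides with
30 bp in-frame spacers, 150 bp spacer, mutated LTR copy — in i.i.d.
background (default 1 Mb, GC 0.4). Toy profiles score +7 for the consensus
residue and −4 otherwise, making planted domains unambiguous against
background. Defaults mirror the study conditions used throughout the test
suite: 10 elements per genome, five domains (90/70/120/80/100 aa), 300 bp
LTRs at 95% identity, both strands at random. Tandem mode places pairs
~3 kb apart so their loci must merge; frameshift mode inserts a 1–2 bp
indel at 40–60% of a domain's length. Non-tandem spacing defaults to
20 kb: with 7.5 kb flanks on both neighbours anything below ~15 kb would
merge loci, so the nominal "minimum 2 kb spacing" idea is honoured in its
intent (separate loci) rather than its letter. Substitution counts for the
LTR copy are exact (`round((1-p)·L)` positions), so planted identity is
exact up to rounding, not binomially noisy.

What the generator does **not** emulate: nested insertions, solo LTRs,
target-site duplications, repeat-rich or low-complexity background, indel
evolution, GC heterogeneity. Passing the suite therefore demonstrates the
pipeline's mechanics (coordinates, chaining, delineation, thresholds,
determinism), not sensitivity on real genomes, where profile quality and
repeat structure dominate.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based inclusive happens only at external boundaries (GFF3, FASTA
  headers, RPS-BLAST parsing). The conversions are unit-tested both ways.
* The scanner's segment extraction is leftmost-greedy per diagonal; two
  elements on one diagonal are separated whenever the running score returns
  to zero between them, which i.i.d. background guarantees in practice.
* Test problem sizes: 20 genomes of 1 Mb for recovery, 20 tandem genomes of
  120 kb, 50 LTR fixtures, 1000-peptide clustering. These sizes keep the
  full suite within a few minutes while leaving every rate measurable.
* Determinism: the pipeline contains no RNG; generator functions take
  explicit seeds and restore RNG state (`withr::with_seed`). Outputs carry
  no timestamps, so identical runs produce bit-identical trees.
* Degenerate inputs: empty assemblies yield empty (but valid) artifacts and
  an all-zero summary; loci without a core domain are logged, not silently
  dropped; an element with zero domains cannot be scored and is treated as
  a programming error.

## Known limitations

* The internal scanner is ungapped; a domain split by a large deletion
  inside the profile span chains only if the profile coordinates remain
  colinear within the 15-aa overlap bound.
* LTR identity is reported for the aligned region after end trimming;
  a repeat whose true ends are heavily diverged will be reported slightly
  shorter than its biological extent.
* Greedy clustering depends on founder order (longest first); the suite
  checks agreement with transitive-closure clustering only on fixtures
  whose identity structure is unambiguous, which is the regime the
  0.8/0.8 defaults target.
* The false-positive proxy (core-only fraction) is a structural upper
  bound, not a statistical estimate.
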