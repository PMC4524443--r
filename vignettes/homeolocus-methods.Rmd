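---
title: "Methods: locus-specific sequence isolation in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-specific sequence isolation in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

An allopolyploid genome carries two or more diverged ancestral genomes
(subgenomes). Homoeologous copies of a gene are typically 95–99% identical,
so assays designed on one copy cross-react with the others. The pipeline in
this package finds, for each query gene, all homoeologous genomic copies,
aligns them, and exploits the columns where exactly one copy differs from
all the others — *subgenome-diagnostic* sites — to design assays that read
out a single subgenome.

The pipeline is a chain of five stages. Their contracts, parameters and the
reasoning behind the non-obvious choices are documented here.

## Homology search

`find_hsps()` is a seed-and-extend local aligner: exact `seed_k = 11`-mers
shared between query and subject (both strands) seed an ungapped X-drop
extension (`xdrop = 20`), whose footprint is re-aligned by a full
Smith–Waterman affine-gap DP on a window around it. The window is grown
(up to ~1 kb of margin) whenever the local optimum touches its edge, so an
indel that stops the ungapped extension does not truncate the reported HSP.
Overlapping extensions are deduplicated keeping the highest raw score per
overlapping query/subject region. Scoring defaults are blastn-like
(+2/−3, gap open −5, extension −2 per position), with fixed Karlin–Altschul
parameters (λ = 0.625, K = 0.41) for bit scores and E-values
`E = K·m·n·e^(−λS)` (m = query length, n = total searched subject length).
Ambiguity codes (including N) never match anything, including themselves:
survey-style genome assemblies contain Ns and treating them as matches
would inflate identity.

`filter_hits()` applies the two search filters the pipeline runs under by
default: `E ≤ 10⁻⁵`, and at most 10 *subject sequences* per query (subjects
ranked by best bit score, all HSPs of a retained subject kept). The cap is
deliberately on subjects, not HSPs: that is the semantics of capping
reported alignments in standard BLAST usage, and a multi-exon gene
legitimately produces many HSPs on one contig.

Users with real BLAST output can skip the internal search entirely:
`read_tabular_hits()` imports standard 12-column tabular hits, converting
the 1-based inclusive, strand-encoded coordinates to the internal
convention at the file boundary. Internally every coordinate in the package
is 0-based, half-open, on the plus strand, with a separate strand flag —
one conversion point, no off-by-one drift.

## Chaining HSPs into loci

`chain_hsps()` assembles the HSPs of one (query, subject, strand) group
into gene loci by dynamic programming, maximizing summed raw score under
gene-structure constraints:

* **minimum exon** — HSPs with subject footprint < 200 bp are discarded
  before chaining: short local hits are mostly spurious or unalignable
  exon fragments, and filtering per hit is the most direct way to limit
  the retrieved coordinates. Configurable (`min_exon`).
* **maximum intron** — consecutive blocks may be separated by at most
  5,000 bp on the subject (`max_intron`); a 5,001 bp gap splits a chain, a
  4,800 bp gap does not.
* **colinearity** — query and subject order must agree (reversed on the
  minus strand). This is the standard gene-model assumption and the
  default; `colinear = FALSE` merges all nearby same-strand hits instead.
* **query-overlap slop** — consecutive HSPs may overlap by up to 40 bp on
  the *query*. Local alignment of adjacent exon hits routinely runs a few
  bases past the exon boundary (splice-site-like sequence at intron ends
  chance-matches the next exon's start), so strict non-overlap would break
  true chains. Subject-side overlap remains forbidden.

Ties in the DP break toward fewer blocks, then leftmost subject start, so
output is deterministic. Maximal chains are extracted greedily (best chain,
remove members, repeat), so one contig can yield several loci — paralog
support.

`extract_locus()` is span-based: it returns the contig sequence from chain
start − 300 bp to chain end + 300 bp (`flank`), clipped at contig ends,
introns retained. Intronic and flanking polymorphism is exactly what makes
genome-specific primers easy, and genomic PCR products include them.
Minus-strand loci are reverse-complemented so every extracted record reads
5′→3′ of the gene.

## Progressive multiple alignment

Per query, the extracted homoeolog set is aligned progressively:
k-mer set distances (`k = 6`; `d = 1 − shared/min`) feed a UPGMA guide tree
(`stats::hclust`, average linkage — UPGMA *is* average-linkage
agglomeration, so the standard implementation is used behind the module's
surface), and profiles are merged post-order with a banded affine-gap
global aligner written in C++ (sum-of-pairs column scores, "once a gap,
always a gap"). For inputs ≤ 2 kb the band covers the whole matrix, making
the pairwise score provably optimal (the test suite checks it against an
exhaustive recursion oracle); longer inputs use a band of
|ΔL| + 400 columns, ample for homoeologs at a few percent divergence. DP
score rows are rolled and only a byte-wide traceback matrix is kept, so
memory stays ~L·band bytes.

The alignment stage runs *before* conserved-block filtering: a block filter
needs an alignment as input, so this is the only mechanically possible
order. `select_conserved_blocks()` implements a compact four-parameter
variant of the classic conserved-block model (strict-majority conservation,
gap columns break blocks, non-conserved runs > 8 columns break blocks,
blocks ≥ 10 columns after trimming non-conserved flanks). Exact
reproduction of any particular trimming tool's threshold system is out of
scope; the four knobs approximate relaxed settings. Crucially, **block
filtering is applied only for conserved-region (qPCR) discovery**;
diagnostic-site scanning runs on the untrimmed alignment, because trimming
deletes exactly the divergent columns the pipeline exists to find.

## Diagnostic sites

`diagnostic_sites()` calls a column diagnostic for a target row when the
target's state differs from every other row *and* all other rows agree
(strict background). This guarantees a single primer discriminates the
target from every homoeolog simultaneously. A relaxed mode (target differs
from each row, backgrounds free) is available behind a flag.

Numerical/edge choices:

* Runs of adjacent diagnostic gap columns collapse into one indel site —
  one mutational event, one discriminating feature, one unit in the
  "two or more SNPs or indels" count.
* Columns holding an ambiguity code in any row with data are skipped.
* A row's leading and trailing gap columns are *missing data for that row
  only*: the row is ignored at those columns rather than vetoing the
  column for everyone. Extracted loci have ragged ends (and a locus split
  by the intron rule contributes two partial rows); treating terminal gaps
  as states would either fabricate indel sites at every ragged end or, if
  masked alignment-wide, silence entire genes. At least one background row
  with data is required.

`conserved_regions()` is the dual notion — maximal runs of columns with all
rows identical and gap-free, ≥ 18 columns by default (a primer length) —
for assays that must amplify all homoeologs alike.

## Primer, CAPS and in-silico PCR design

Genome-specific primers anchor a diagnostic base in their 3′-terminal
3 nt — the standard allele-specific mechanism: polymerase extension is
blocked by a 3′ mismatch on every non-target homoeolog. Because assays
resting on a single SNP often fail to discriminate in practice, a pair
must cover **≥ 2 distinct diagnostic sites** in total (both primers are
diagnostic windows here;
because paired windows cannot overlap, their site counts add). Constraints:
length 18–27 nt, Tm 50–70 °C, GC 0.30–0.70, product 80–1,500 bp, pair Tm
gap ≤ 5 °C. Ranking: covered sites (desc), Tm gap (asc), product length
(asc), then position — deterministic. Tm is the Wallace rule
`2(A+T) + 4(G+C)` below 14 nt and the GC-fraction formula
`64.9 + 41(GC − 16.4)/N` otherwise: closed-form, adequate for ranking and
for the 50–70 °C gate; nearest-neighbor thermodynamics is a non-goal.

`insilico_pcr()` reports a product wherever two binding events on opposite
strands converge within the product bounds; binding tolerates ≤ 2
mismatches but none in the 3′-terminal 3 bases, with no indels in the
duplex (stringent-but-realistic annealing; both knobs configurable). All
primer/strand combinations are enumerated. This is the computational analog
of scoring a marker on aneuploid lines: a design is subgenome-specific when
its own contig yields a product and no other homoeolog does.

`find_caps()` covers the marker-conversion route: for two allele sequences
of one locus it aligns them, and reports every catalog enzyme whose
recognition site overlapping a SNP exists in exactly one allele, with
predicted digest patterns for both. Candidates are dropped when any
differential fragment is below `min_frag = 50` bp (a 3% agarose resolution
proxy) and ranked by the distance from the hardest-to-resolve differential
fragment to the nearest band of the other allele. The built-in catalog
ships ~24 common enzymes (AciI, HaeIII, EcoRI, MspI, TaqI, ...) as a
plain-text table users can replace. Straight CAPS only: engineered-mismatch
(dCAPS) primer design is out of scope.

# The simulator and what passing means

`simulate_polyploid()` emulates the pipeline's target data: per gene an
ancestral sequence of 1–5 exons (200–600 bp; the minimum equals the
min-exon filter so true exons are recoverable) separated by introns
(60–4,800 bp; below the max-intron rule so true structures are chainable),
surrounded by 450 bp of ancestrally shared flanking sequence. Each of k = 3
subgenome copies diverges independently from the ancestor (star phylogeny)
at 2% substitutions and 0.1% indel events (1–10 bp) per base, is placed on
its own contig on a random strand and padded with a short random tail. The
query set holds the ancestral CDS. Defaults are the study conditions used
throughout the tests; everything is deterministic in `seed`.

Two deliberate departures from a naive reading of "random pad around the
gene":

* **Flanks are homologous.** Homoeologous chromosomes are homologous beyond
  a gene's CDS footprint, and the extractor takes 300 bp flanks. If flanks
  were independent random sequence, the flank region of every alignment
  would be unalignable noise in which ~19% of columns mimic diagnostic
  sites by chance, making precision against ground truth meaningless. The
  450 bp homologous pad (> 300 bp flank + chain-end fuzz) keeps every
  aligned column a genuine homology statement.
* **Truth is derived, not planted.** Every mutation event is logged with
  coordinates in both ancestral and mutated frames; the diagnostic truth is
  *derived* from the logs (positions where exactly one subgenome deviates
  while the rest share a state, with no overlapping indel in another copy).
  At 2% divergence, private exonic substitutions are dense (tens per gene),
  so a separate "planted" subset would add nothing — and deriving the full
  truth set is the only reference against which *precision* is meaningful.
  With divergence 0 the truth set is empty and the pipeline must report
  zero sites and a clean "no genome-specific pair" failure per gene, which
  the tests assert.

Evaluation conventions: detected sites are mapped back to ancestral
coordinates through the event-log coordinate maps; recall is measured over
truth events inside the gene span (the region every extracted locus is
guaranteed to cover — flank truth beyond the 300 bp extraction window is
not recoverable by construction), while precision is measured over all
detected sites against all truth events, flanks included; indel matching
tolerates ±2 bp. Primer specificity is judged on the top-ranked pair per
(gene, subgenome) against all of that gene's contigs.

What the simulator does **not** emulate: repeats and transposons (no
spurious multi-locus seeding), homoeologous exchange or gene conversion
(every diagnostic site stays private), realistic A/B/D tree topology
(divergence is star-shaped), GC heterogeneity, and assembly gaps. Passing
the simulation-based tests therefore demonstrates the machinery is correct
under clean homology, not that wet-lab success rates on real wheat would
match.

# Problem sizes, determinism and limitations

The test suite runs the full pipeline at the study scale (50 genes × 3
subgenomes, genomes of ~1 Mb total) in about two minutes on one CPU; oracle
equivalence tests use exhaustive enumeration at small sizes (alignments ≤ 8
bp, chains ≤ 8 HSPs, 200 random instances). `scripts/acceptance.R` re-runs
the study-scale simulation and reports locus recovery, site recall and
precision, primer specificity and the hit/alignment funnel.

Observed behaviour worth knowing:

* Locus recovery hovers at 96–100% across seeds. The dominant failure mode
  is principled: an exon whose true length sits just above 200 bp can yield
  a local alignment trimmed a few bases below the min-exon cutoff (terminal
  mismatches make the trimmed alignment score-optimal), the hit is then
  discarded, and if the resulting subject gap exceeds 5,000 bp the chain
  splits. The split fragments still enter the alignment as partial rows and
  lose only the dropped exon's sites, thanks to the per-row terminal-gap
  semantics above.
* The internal search is built for desk-scale validation and contigs up to
  a few tens of kb, not for chromosome-scale performance; at scale, run
  real BLAST and import the tabular hits.
* The E-value uses fixed Karlin–Altschul parameters rather than estimating
  them from the scoring scheme; with the default scheme the threshold
  behaviour matches standard blastn closely enough for the 10⁻⁵ gate.
* Primer design screens neither hairpins nor cross-dimers, and three-primer
  competitive-allele designs are out of scope by intent.
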