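---
title: "Methods and design of mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` implements the standard comparative workflow for small
circular mitochondrial genomes: composition and strand skew, codon
usage, gene architecture, divergence and diversity, and supermatrix
preparation. This vignette records the statistical definitions, the
tunable parameters, and the design decisions that were genuinely open,
so that a maintainer can see why the code is the way it is.

## Coordinates and containers

Genomes are held as a `mito_genome`: one J-strand (majority-strand)
nucleotide string plus an ordered feature table. Coordinates are
**0-based half-open** internally — junction arithmetic then reduces to
`gap = start_b - end_a`, whose sign alone distinguishes overlap
(negative), abutment (zero) and spacer (positive). GenBank's 1-based
inclusive convention is converted only at the I/O boundary. A feature
crossing the origin of the circle keeps a single interval with an
explicit `wrap` flag and `end > genome length`, so per-gene tables stay
one-row-per-gene. `N` is tolerated in sequences but excluded from all
composition counts, so partially determined genomes degrade gracefully
rather than failing.

All translation uses NCBI table 5 (invertebrate mitochondrial) as
shipped by Biostrings: ATA encodes Met, AGA/AGG Ser, TGA Trp, and only
TAA/TAG terminate. Genes whose annotated length is 1 or 2 mod 3 must
end in `T` or `TA`; the trailing bases are completed to TAA
(polyadenylation) and reported as truncated stops `T-`/`TA-`.

## Composition and skew

For a region with base counts A, C, G, T:
A+T% = 100·(A+T)/(A+C+G+T), AT-skew = (A−T)/(A+T),
GC-skew = (G−C)/(G+C); a zero denominator yields `NA` rather than an
error. Region summaries concatenate member genes **in deposited-strand
(J) orientation, in genome order**. This was an open choice: published
per-region tables do not state whether multi-gene rows are computed on
the J strand or gene-by-gene on the coding strand. The J-strand
convention was chosen because strand skew is a property of the molecule
(replication asymmetry), and mixing coding orientations would partially
cancel it; `region_composition(..., coding_orientation = TRUE)` exposes
the alternative. Percentages are carried at full precision and rounded
(A+T% to 1 decimal, skews to 3, Pi to 2) only in the reporting layer.

## Codon usage

Codon counts exclude each gene's (possibly truncated) stop, so the
total over genes obeys the bookkeeping identity
`sum(floor(length/3) - [stop is complete])`, which is what published
per-gene length/stop tables imply. Start codons are counted as their
translated residue (`include_start = FALSE` excludes them); the
reported totals of the reference genomes are only consistent with
starts included. RSCU for codon c in synonymous family F is
`count(c)·|F| / sum over F`; under the mitochondrial code Met and Trp
are two-codon families. Families with zero total give `NA` (not 0) and
are listed as missing; missing-codon reports are pooled over all 13
PCGs of a genome, matching how such statements are conventionally made.

## Architecture

The junction census walks all n consecutive feature pairs around the
circle (n features, n junctions), ignoring strand — conserved overlaps
such as trnW–trnC span opposite strands. Control-region-flanking
junctions are listed but excluded from spacer totals, since spacers are
conventionally reported "excluding the control region". Overlapping
pairs are counted once per junction. The control region itself is
located as the unannotated span from rrnS to trnI along the J strand,
wrapping the origin when necessary; an interval under 50 bp warns but
is still returned.

tRNA pairing statistics are computed from user-supplied dot-bracket
structures (structure *prediction* is out of scope). Pairs are classed
as Watson–Crick, G–U wobble, or mismatch by type; helices are counted
by decomposing the pair list into stacked runs. A canonical cloverleaf
has four helices (acceptor + three hairpin arms), so the DHU-arm flag
is false below four — the configuration of trnS1(AGN) in most insects,
where the DHU arm collapses to a loop.

## Divergence and diversity

`pairwise_stats` counts variable sites over mutually resolved columns;
in coding alignments any codon containing a gap or ambiguity in either
row is dropped whole, which keeps the invariant
synonymous + replacement = variable sites exact. Classification
substitutes the second row's base into the first row's codon one
position at a time (default `method = "site"`); `method = "pathway"`
instead averages synonymous/replacement step counts over all orderings
of the within-codon differences, discarding orderings that pass through
a stop codon — the convention of classic polymorphism software. Site
classification is the default because its counts are integers and sum
exactly, as per-gene tables require.

Nucleotide diversity Pi is the mean over unordered sequence pairs of
the per-site p-distance, each pair computed on its own resolved columns
(pairwise deletion; complete deletion available). No multiple-hit
correction is applied — Pi here is deliberately the plain p-distance
quantity. The sliding window (defaults 250 bp window, 25 bp step, the
usual scan resolution for ~12 kb concatenated mitogenome alignments)
positions windows in alignment coordinates, reports
`floor((L - window)/step) + 1` points, and labels each by midpoint
(0-based window start + window/2).

## Supermatrix preparation

Concatenation records a 1-based inclusive partition per gene and, for
coding genes, derives the three codon-position subpartitions on export
(RAxML `gene_pos1 = start-end\3` lines; NEXUS charsets). Missing taxa
are gap-filled.

**Degen recoding.** Each codon position is replaced by the IUPAC symbol
covering the bases reachable by synonymous change. The table is derived
from the genetic code algorithmically rather than hard-coded, so any
code table works. One subtlety: a single sweep of the per-position rule
is not idempotent — TTA (Leu) maps to YTR, which re-recodes to YTN,
because the pos-1 exchange TTA↔CTA is itself synonymous and merges the
TTR and CTN leucine families. The implementation therefore iterates to
a fixed point, which reproduces the published Degen1 behaviour exactly:
one degenerate symbol per synonymous single-step component (the AGN and
TCN serine families, which no single synonymous step connects, remain
separate). The test suite checks the full 64-codon table against an
independent graph-component enumeration, plus idempotence and
amino-acid preservation.

**Saturation.** The observed saturation index is the mean per-site
entropy of base frequencies divided by the entropy expected at full
saturation. With a finite number of sequences the plug-in site entropy
is biased downward (with 8 sequences a uniformly random site averages
~1.73 bits, not 2), so normalising by the pooled-frequency entropy
could never reach 1 at saturation. The denominator is therefore the
*exact expected plug-in entropy* of an i.i.d. sample from the
matrix-wide base frequencies at each site's non-gap depth, computed
from binomial marginals — the finite-OTU normalisation used by the
established saturation test. The critical values of that test come from
tree-shape simulations and are intentionally not reimplemented; the
report prints the observed index only.

## The synthetic-data generator

`genome_spec()` fixes the study conditions the generator emulates:
ancestral 37-gene order with canonical strands; per-gene lengths near
the values typical of deltocephaline leafhoppers (PCG defaults from a
published reference genome, cox2 = 682 and nad4 = 1309 implying
truncated stops; rRNAs 1199/739 bp; tRNAs drawn from 61–71 bp; control
region 847 bp); region-class A+T targets (PCG 0.76, tRNA 0.77, rRNA
0.80, CR 0.83) with J-strand AT-skew +0.08 and GC-skew −0.16; the seven
conserved overlaps (atp8–atp6 7, nad4–nad4l 7, trnW–trnC 8, trnI–trnQ
3, trnR–trnN 1, trnN–trnS1 1, nad6–cob 1 bp) and the conserved 2 bp
spacers plus a 26 bp trnY–cox1 spacer. These defaults are one fixed,
realistic condition set, not tuning knobs.

Coding genes are built codon-wise with stop codons rejected; because
rejection depletes A/T-rich codons, the base-sampling A+T fraction is
first adjusted by solving (exact 64-codon enumeration, `uniroot`) for
the value whose stop-conditioned expectation equals the target, so
realised composition tracks the spec to within sampling noise (~±1% on
the whole molecule). Overlapping coding genes share a frame-compatible
block: the biologically observed `ATGATAA` pattern for 7 bp overlaps
(upstream TAA stop containing the downstream ATG start, TGA read as
Trp) and a shared A for 1 bp overlaps; unsupported coding–coding
overlap sizes raise an error naming the junction. All randomness flows
from the single spec seed, and the caller's RNG state is restored.

`evolve_genomes()` evolves descendants along a rooted tree (branch
lengths in expected substitutions/site). Within PCGs each substitution
is synonymous with probability r/(1+r) (r = `syn_rep_ratio`, default
4), drawing the site and base from the currently available candidates
of that class, so stops are never created and the realised event ratio
matches r; a transition bias (default 2) weights base choice. Positions
covered by two annotated genes (the 28 bp of overlaps) are frozen
rather than risking a mutation that is synonymous in one frame and
nonsense in the other. No indels are simulated, so alignments of
descendants are trivially column-correct — divergence statistics are
tested against the generator's event log, not against an aligner.

What the generator does **not** emulate: codon-position-specific
composition structure (codon positions are sampled i.i.d., so the
third-position A+T excess of real mitogenomes is absent), control-region
repeat structure, indels, and rate variation within genes. Tests passing
on synthetic data therefore validate the bookkeeping and the statistics,
not biological realism of the sequences themselves.

## Problem sizes and check regimes

The test suite and `scripts/acceptance.R` run entirely on generated
data: 100 seeded genomes for the circular-conservation property, one
genome with three replicate evolutions for the
synonymous:replacement recovery check, and 10^4-site alignments for the
saturation law-of-large-numbers check. The recovery check uses short
branches (tip-path distances 0.03–0.05 substitutions/site, >3000 pooled
variable sites): at higher divergences synonymous events concentrate on
the ~30% of sites where synonymous change is possible, coincident hits
collapse into single observed differences, and naive per-site recovery
is biased low — a property of observed-difference counting (the
pathway method mitigates but does not remove it), not of the
implementation.

## Known limitations

* The GenBank parser is minimal: single-record flat files, simple or
  two-segment origin-spanning `join` locations, the feature keys CDS /
  tRNA / rRNA / D-loop / misc_feature. That covers deposited insect
  mitogenomes; it is not a general GenBank reader.
* Gene-name canonicalization is table-driven
  (`inst/extdata/gene_synonyms.tsv`) and seeded with common leafhopper
  spellings; other taxa may need additional aliases (the table is
  user-overridable).
* Pi and divergence are raw p-distance quantities; no JC/K2P correction
  or dN/dS machinery is provided, by design.
* Saturation critical values, alignment computation, model selection
  and tree inference are out of scope; exports are designed to feed the
  standard external tools.
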