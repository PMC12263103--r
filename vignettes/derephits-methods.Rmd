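---
title: "Dereplicating gene-cluster hit sets by host-genome identity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating gene-cluster hit sets by host-genome identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derephits)
```

## Why dereplicate at the genome level

Mining colocalised gene sets (biosynthetic gene clusters and similar loci)
against public sequence databases returns hit sets that mirror the
databases' redundancy: the same strain resequenced dozens of times yields
dozens of quasi-identical cluster hits. `derephits` removes this
redundancy where it originates — the host genomes — rather than at the
cluster level. Genome-level clustering preserves the evolutionary signal
of the host (two strains with a horizontally transferred cluster still
sort with their relatives), at the risk of discarding genuinely divergent
clusters carried by near-identical genomes. The hit-recovery step exists
to cap that risk.

The pipeline has three parts: resolve hit-bearing scaffolds to
assemblies, cluster the assemblies by average nucleotide identity (ANI)
and pick representatives, then re-admit discarded hits whose gene-cluster
content or homology score indicates real diversity.

## The ANI estimator

Assemblies are compared through canonical k-mer sets: every k-length
window containing only A/C/G/T contributes the lexicographic minimum of
itself and its reverse complement. For sketches $A$ and $B$ the
directional containments are

$$C_A = \frac{|A \cap B|}{|A|}, \qquad C_B = \frac{|A \cap B|}{|B|},$$

reported as aligned fractions $\mathrm{AF} = 100\,C$ per direction, and

$$\widehat{\mathrm{ANI}} = 100 \cdot \max(C_A, C_B)^{1/k},$$

because under independent per-base substitutions at rate $p$ a k-window
survives unmutated with probability $(1-p)^k$, so
$\mathbb{E}[C] \approx (1-p)^k$ and the $k$-th root recovers $1-p$.
Max-containment (rather than Jaccard) keeps the estimate stable when one
assembly is an incomplete subset of the other — the same reason the
redundancy edge below uses the *larger* directional AF.

Choices worth recording:

* **k = 16 by default.** With $4^{16} \approx 4.3\times10^9$ possible
  canonical keys, random collisions are negligible for genomes up to tens
  of Mb, while $(1-p)^{16}$ still leaves a measurable shared fraction at
  strain-level divergence. Even k admits self-complementary palindromic
  k-mers; they canonicalize to themselves and do not bias containment.
  The accepted range is 11–31.
* **Full k-mer sets, no subsampling.** Exact at the genome sizes the
  package targets; a MinHash-style fraction would be the natural
  scalability knob but is not needed for correctness and is not
  implemented.
* **Substitutions only.** Indels shift every downstream k-mer and would
  deflate containment; the estimator does not model them, and the
  synthetic generator therefore mutates by substitution only. This is the
  main divergence from alignment-chaining ANI tools.
* **Validity region.** The estimator is meaningful for closely related
  genomes (true ANI ≳ 90). Far below that, shared k-mers vanish and the
  estimate collapses toward a noise floor (observable as between-group
  "ANI" values of ~72–75 on random 15%-diverged panels); it is never used
  to *measure* such distances, only to confirm they fall far below any
  clustering threshold.

## Dereplication

The redundancy graph has an edge between assemblies $a$ and $b$ iff
$\mathrm{ANI}(a,b) \ge$ `ani_threshold` **and**
$\max(\mathrm{AF}_a, \mathrm{AF}_b) \ge$ `af_threshold`, both inclusive.
Defaults are 99% (the conventional strain-level cutoff for collapsing
resequenced genomes) and 90%.

Representatives are chosen greedily: among unassigned assemblies, take
the one with the most unassigned neighbors (connectedness), breaking ties
by larger N50, then larger total length, then lexicographically smallest
accession; it forms a cluster with all its unassigned neighbors, and the
process repeats. Two properties motivated this exact rule:

* Connectedness-first is the greedy-cover heuristic — collapse the
  densest redundancy first — and makes cluster membership the
  representative's *direct neighborhood*, giving small, cohesive clusters
  rather than sprawling connected components.
* N50-then-length prefers the least fragmented assembly as the retained
  genome when degrees tie, and the accession tie-break (C collation)
  makes the whole procedure deterministic.

The rule is deliberately simple enough to restate independently; the test
suite checks it against a separately coded step-by-step oracle on random
graphs, and checks the partition, idempotence (re-dereplicating the
representatives yields singletons) and threshold-monotonicity properties.

## Hit recovery

Within each genome cluster, hits are keyed by their **homolog-count
vector** — for each query gene, how many subject homologs the hit cluster
contains — and partitioned into subgroups with identical keys.

**Content recovery.** Every subgroup containing no hit hosted by the
cluster representative elects one member *genome* uniformly at random and
retains all of that genome's hits carrying that key. Selection is
genome-level deliberately: the unit being rescued is a representative of
the divergent cluster variant, and splitting one genome's identical hits
across retained/discarded would be incoherent. The representative's
subgroup is skipped even when the representative hosts additional hits
with other keys. The choice is driven by the run seed; changing the seed
can change *which* genome is elected, never *how many* subgroups recover.

**Score recovery.** Within each subgroup, scores are standardized with
the subgroup mean and the *population* standard deviation ($n$
denominator): a subgroup is the complete population of its genome
cluster, and the $n-1$ form is undefined for singletons, which must
yield "no outliers" rather than an error. Hits with $|z| \ge$
`z_threshold` (default 2, the conventional two-sigma rule; inclusive)
are retained unless already representative-hosted or content-recovered,
so the two recovery sets stay disjoint. Two open points were settled as
follows: z-scoring is two-sided by default (a markedly *weaker* cluster
is as interesting as a stronger one) with a `one_sided` switch, and
score recovery scans every subgroup including the representative's own,
since an outlier there is no less real. Note that at $n \le 4$ equal-ish
scores, $|z|$ cannot reach 2, so score recovery is structurally rare in
small clusters — consistent with it being the minor recovery channel.

Degenerate inputs: zero spread recovers nothing; non-finite scores are an
integrity error; an empty subgroup list recovers nothing.

## Scaffold mapping and unmapped hits

Scaffold identity is the first whitespace-delimited token of the FASTA
header. Mapping tries the exact accession, then version-stripped
comparison on both sides. A scaffold matching two assemblies is an
ambiguity error; a scaffold matching none puts its hits in the status
table as `unmapped` — excluded from dereplication and from the retained
set, with a warning (an error under `strict`). Partial results were
preferred over hard failure because stale accessions are routine in
practice; `unmapped` hits remain visible in `genome_cluster_status.txt`
so nothing is silently dropped.

## The synthetic panel generator

`generate_panel()` emulates database redundancy with a controlled
divergence structure: one seeded root sequence; each identity group's
ancestor is the root mutated at `between_divergence`; each member genome
is its group ancestor mutated independently at `within_divergence`
(substitution-only, uniform replacement by one of the three alternative
bases). Within-group pairwise divergence is therefore
$\approx 2w(1-w)$ and between-group divergence is bounded well away from
it, so identity groups are separable by construction. Genomes are split
into equal contigs at deterministic points and written as gzipped FASTA
with NCBI-like versioned accessions (`SYNT_A1C1.1`), exercising the
version-stripping path. The truth table records group membership and the
realized divergence of each genome from its ancestor, measured by direct
base comparison at generation time.

What the generator does **not** emulate: indels, rearrangements, assembly
fragmentation bias, contamination, sequencing error profiles, or
realistic BGC architectures. Passing tests on these panels demonstrate
the pipeline's logic and the estimator's calibration under its stated
model, not robustness to real assembly pathology.

## Problem sizes and determinism

The test and acceptance workloads use 12-genome panels of 100 kb genomes
(4 groups, within 0.002, between 0.15) for end-to-end dereplication,
20 kb panels for the faster structural checks, and 20 replicate seeds per
substitution rate for estimator calibration — sizes at which the full
k-mer sets are exact and a complete run takes seconds. Every stochastic
step (panel generation, subgroup election, calibration) is driven by an
explicit seed; the four machine-readable outputs (`clusters.txt`,
`genome_cluster_sizes.txt`, `genome_cluster_status.txt`,
`scaffold_assembly_pairs.txt`) are byte-identical across reruns with the
same configuration.

## Known limitations

* Containment ANI under-reports in the presence of indels and repeats
  (repeated k-mers collapse in a set); alignment-based tools remain the
  reference for accuracy claims.
* Fragmented or incomplete assemblies can fabricate homolog-count
  diversity and trigger spurious content recovery; the package does not
  screen assembly quality.
* The remote adapter is an interface with a mock-tested contract
  (batching, deduplicated fetches), not a hardened NCBI client: no
  retries, rate limiting, or live WGS master-record resolution.
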