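# derephits

Genome-level dereplication of gene cluster mining hit sets.

## The problem

Searching a set of colocalised query genes (a biosynthetic gene cluster,
BGC) against large public genome databases with tools like cblaster
typically returns hundreds of quasi-identical hits, because the databases
are saturated with (re)sequenced near-identical genomes. `derephits`
post-processes a cblaster session file: it groups the genome assemblies
hosting the hits by average nucleotide identity (ANI), keeps one
representative hit per genome cluster, and then *recovers* discarded hits
whose gene-cluster content or homology score shows diversity that the
genome-level collapse would otherwise destroy.

## Method

1. **Genome store.** Every hit-bearing scaffold accession is resolved to a
   genome assembly (local FASTA directory or a pluggable remote adapter
   that batches ID-mapping requests at 5000 accessions per call). The
   scaffold-to-assembly mapping is reconstructed locally by matching
   scaffold accessions against FASTA header tokens, with a
   version-stripped fallback.
2. **ANI sketching.** Each assembly is reduced to its set of canonical
   k-mers (default k = 16). For two sketches with directional containments
   C_a = |A∩B|/|A| and C_b = |A∩B|/|B|, the aligned fractions are
   AF = 100·C per direction and

   ANI = 100 · max(C_a, C_b)^(1/k)

   since under a per-base substitution rate *p* the expected containment is
   (1−p)^k. The estimator is intended for closely related genomes
   (true ANI ≥ 90).
3. **Greedy dereplication.** Assemblies become nodes of a redundancy graph
   with an edge when ANI ≥ 99% and max directional AF ≥ 90% (both
   inclusive, both configurable). Representatives are picked greedily by
   connectedness (degree among unassigned), then N50, then total length,
   then smallest accession; each representative absorbs its unassigned
   neighbors.
4. **Hit recovery.** Within each genome cluster, hits are subgrouped by
   their homolog-count vector (homologs per query gene). Every subgroup
   without a representative-hosted hit re-admits one randomly chosen
   member genome's hits (*content recovery*); within each subgroup, hits
   whose score has |z| ≥ 2 under the population standard deviation are
   also re-admitted (*score recovery*).

A run writes the seven standard output files: `clusters.txt`,
`filtered_binary.txt`, `filtered_session.json`, `filtered_summary.txt`,
`genome_cluster_sizes.txt`, `genome_cluster_status.txt`,
`scaffold_assembly_pairs.txt`.

## Worked example

Everything below is runnable offline: the package ships a synthetic-panel
generator with controlled pairwise divergence.

```r
library(derephits)

# 4 identity groups x 3 genomes of 20 kb; within-group substitution rate
# 0.002, between-group 0.15 -- so groups are separable by construction
pan <- generate_panel(
  panel_spec(n_groups = 4, genomes_per_group = 3, genome_length = 20000,
             within_divergence = 0.002, between_divergence = 0.15,
             seed = 71),
  "genomes")

# one hit per genome; one genome gets a divergent homolog vector (2,1,1)
counts <- matrix(1L, 12, 3); counts[5, ] <- c(2L, 1L, 1L)
generate_session(pan, "session.json", counts = counts)

run <- run_pipeline(pipeline_config("session.json", output_dir = "out",
                                    local_genomes = "genomes", seed = 5))
run
#> dereplication run: 12 hits -> 5 retained (2.40-fold), 4 genome cluster(s)
#> status
#> recovered_content         redundant    representative
#>                 1                 7                 4
```

Twelve hits collapse to one representative per identity group (4), plus
one hit recovered because its cluster content differs from its group's
representative — 5 retained, a 2.40-fold reduction. The same run from a
shell:

```sh
Rscript inst/exec/derephits -s session.json -o out --local-genomes genomes --seed 5
```

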