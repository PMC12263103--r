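# Synthetic genome panels with controlled pairwise divergence, plus matching
# session files, so the entire workflow is testable without any download.
# Mutation model is substitution-only (uniform base replacement by one of the
# three alternatives), matching the assumptions of the containment ANI
# estimator; indels and assembly fragmentation bias are deliberately not
# simulated.

#' Specify a synthetic genome panel
#'
#' A panel is `n_groups` identity groups of `genomes_per_group` genomes
#' each. One seeded root sequence (uniform ACGT) is drawn; each group's
#' ancestor is the root mutated at `between_divergence`, and each member is
#' its group ancestor mutated independently at `within_divergence`, so
#' within-group pairwise divergence is about twice `within_divergence` and
#' groups are separable by construction.
#'
#' @param n_groups Number of identity groups (>= 1).
#' @param genomes_per_group Genomes per group (>= 1).
#' @param genome_length Genome length in bases.
#' @param within_divergence Per-base substitution rate within a group, in
#'   [0, 0.1].
#' @param between_divergence Per-base substitution rate from the root to
#'   each group ancestor, in (within_divergence, 0.5].
#' @param n_contigs Contigs per genome (split at deterministic points).
#' @param seed Integer seed; panels are reproducible bit-for-bit.
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(n_groups, genomes_per_group, genome_length,
                       within_divergence, between_divergence,
                       n_contigs = 1L, seed = 1L) {
  n_groups <- as.integer(n_groups)
  genomes_per_group <- as.integer(genomes_per_group)
  genome_length <- as.integer(genome_length)
  n_contigs <- as.integer(n_contigs)
  if (n_groups < 1L || genomes_per_group < 1L)
    derep_abort("need at least one group and one genome per group",
                "derephits_domain_error")
  if (n_groups > length(LETTERS))
    derep_abort("at most 26 groups are supported", "derephits_domain_error")
  if (genome_length < n_contigs || n_contigs < 1L)
    derep_abort("genome_length must allow n_contigs >= 1 contigs",
                "derephits_domain_error")
  if (within_divergence < 0 || within_divergence > 0.1)
    derep_abort("within_divergence must be in [0, 0.1]",
                "derephits_domain_error")
  if (between_divergence <= within_divergence || between_divergence > 0.5)
    derep_abort("between_divergence must exceed within_divergence and be <= 0.5",
                "derephits_domain_error")
  structure(list(n_groups = n_groups, genomes_per_group = genomes_per_group,
                 genome_length = genome_length,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 n_contigs = n_contigs, seed = as.integer(seed)),
            class = "panel_spec")
}

mutate_seq <- function(x, p) {
  if (p <= 0) return(x)
  idx <- which(stats::runif(length(x)) < p)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    bi <- match(x[idx], bases)
    x[idx] <- bases[((bi - 1L + sample.int(3L, length(idx), replace = TRUE))
                     %% 4L) + 1L]
  }
  x
}

contig_bounds <- function(len, n_contigs) {
  cuts <- round(seq(0L, len, length.out = n_contigs + 1L))
  data.frame(start = cuts[-length(cuts)] + 1L, end = cuts[-1L])
}

#' Generate a synthetic genome panel
#'
#' Writes one gzipped FASTA per genome into `dir` (accessions follow an
#' NCBI-like versioned pattern, `SYNT_<group><member>C<contig>.1`, so
#' version-stripping code paths get exercised) and records a truth table of
#' group membership and realized divergence from each group ancestor
#' (measured by direct base comparison at generation time).
#'
#' @param spec A [panel_spec()].
#' @param dir Output directory (created if needed).
#' @return A `genome_panel`: list with `dir`, `spec`, `truth` (data frame:
#'   `assembly_id`, `group`, `member`, `fasta`, `genome_length`,
#'   `n_contigs`, `divergence_from_ancestor`) and `scaffolds` (data frame:
#'   `assembly_id`, `contig`, `accession`, `length`).
#' @export
generate_panel <- function(spec, dir) {
  stopifnot(inherits(spec, "panel_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  truth <- list()
  scaff <- list()
  with_preserved_seed(spec$seed, {
    root <- sample(bases, spec$genome_length, replace = TRUE)
    for (g in seq_len(spec$n_groups)) {
      anc <- mutate_seq(root, spec$between_divergence)
      for (m in seq_len(spec$genomes_per_group)) {
        gen <- mutate_seq(anc, spec$within_divergence)
        aid <- sprintf("SYNT_%s%d", LETTERS[g], m)
        fp <- file.path(dir, paste0(aid, ".fna.gz"))
        cb <- contig_bounds(spec$genome_length, spec$n_contigs)
        accs <- sprintf("%sC%d.1", aid, seq_len(spec$n_contigs))
        con <- gzfile(fp, "w")
        for (ci in seq_len(spec$n_contigs)) {
          writeLines(sprintf(">%s synthetic contig %d of %s",
                             accs[ci], ci, aid), con)
          writeLines(paste(gen[cb$start[ci]:cb$end[ci]], collapse = ""), con)
        }
        close(con)
        truth[[length(truth) + 1L]] <- data.frame(
          assembly_id = aid, group = g, member = m, fasta = fp,
          genome_length = spec$genome_length, n_contigs = spec$n_contigs,
          divergence_from_ancestor = mean(gen != anc),
          stringsAsFactors = FALSE)
        scaff[[length(scaff) + 1L]] <- data.frame(
          assembly_id = aid, contig = seq_len(spec$n_contigs),
          accession = accs, length = cb$end - cb$start + 1L,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth <- do.call(rbind, truth)
  scaff <- do.call(rbind, scaff)
  rownames(truth) <- rownames(scaff) <- NULL
  structure(list(dir = dir, spec = spec, truth = truth, scaffolds = scaff),
            class = "genome_panel")
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("synthetic panel: %d genome(s) in %d group(s), %d bp each\n",
              nrow(x$truth), x$spec$n_groups, x$spec$genome_length))
  invisible(x)
}

#' Default one-hit-per-genome plan
#'
#' @param panel A `genome_panel`.
#' @param score Cluster score, recycled over genomes.
#' @param cluster_span Hit width in bases (must fit the first contig).
#' @return Data frame with columns `assembly_id`, `contig`, `start`, `end`,
#'   `score`, one row per panel genome.
#' @export
default_hit_plan <- function(panel, score = 100, cluster_span = 1000L) {
  data.frame(assembly_id = panel$truth$assembly_id, contig = 1L,
             start = 0L, end = as.integer(cluster_span),
             score = score, stringsAsFactors = FALSE)
}

#' Generate a cblaster-style session for a synthetic panel
#'
#' Emits a session JSON readable by [read_session()], with one organism per
#' assembly, scaffold accessions matching the panel's FASTA header tokens
#' (so mapping reconstruction succeeds), cluster numbers 1..n in plan
#' order, and homolog counts and scores exactly as planned.
#'
#' @param panel A `genome_panel`.
#' @param path Output JSON path.
#' @param query_genes Character vector of query gene names.
#' @param plan Hit plan data frame (see [default_hit_plan()]); may have
#'   zero rows.
#' @param counts Integer matrix of homolog counts, one row per plan row and
#'   one column per query gene; defaults to all ones.
#' @return Invisibly, `path`.
#' @export
generate_session <- function(panel, path, query_genes = c("g1", "g2", "g3"),
                             plan = default_hit_plan(panel),
                             counts = NULL) {
  stopifnot(inherits(panel, "genome_panel"))
  if (is.null(counts))
    counts <- matrix(1L, nrow = nrow(plan), ncol = length(query_genes))
  if (NROW(counts) != nrow(plan) || NCOL(counts) != length(query_genes))
    derep_abort("counts must be (plan rows) x (query genes)",
                "derephits_integrity_error")
  organisms <- list()
  if (nrow(plan)) {
    for (aid in unique(plan$assembly_id)) {
      rows <- which(plan$assembly_id == aid)
      scaffolds <- list()
      for (i in rows) {
        sc <- panel$scaffolds[panel$scaffolds$assembly_id == aid &
                              panel$scaffolds$contig == plan$contig[i], ,
                              drop = FALSE]
        if (nrow(sc) != 1L)
          derep_abort(sprintf("plan references missing scaffold: %s contig %d",
                              aid, plan$contig[i]), "derephits_integrity_error")
        if (plan$end[i] > sc$length || plan$start[i] < 0 ||
            plan$end[i] <= plan$start[i])
          derep_abort(sprintf("planned hit does not fit contig %s",
                              sc$accession), "derephits_integrity_error")
        subjects <- list()
        for (j in seq_along(query_genes)) {
          for (t in seq_len(counts[i, j])) {
            subjects[[length(subjects) + 1L]] <- list(
              name = sprintf("%s_%s_h%d", aid, query_genes[j], t),
              hits = list(list(query = query_genes[j], bitscore = 50)))
          }
        }
        scaffolds[[length(scaffolds) + 1L]] <- list(
          accession = sc$accession,
          clusters = list(list(number = i, start = plan$start[i],
                               end = plan$end[i], score = plan$score[i],
                               subjects = subjects)))
      }
      organisms[[length(organisms) + 1L]] <- list(
        name = sprintf("Synthetica species %s", aid),
        scaffolds = scaffolds)
    }
  }
  doc <- list(queries = as.list(query_genes), organisms = organisms)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
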