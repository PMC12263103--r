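# k-mer containment estimator of average nucleotide identity (ANI).
#
# Sketch = set of canonical k-mers (lexicographic minimum of each k-mer and
# its reverse complement). For two sketches A, B with intersection I, the
# directional containments are C_A = |I|/|A| and C_B = |I|/|B|; the aligned
# fraction (AF) is reported as 100*C per direction and
#
#   ANI = 100 * max(C_A, C_B)^(1/k)
#
# since under an independent per-base substitution model with rate p the
# expected containment of an undiverged region is (1-p)^k. Max-containment
# keeps the estimate robust when one assembly is a subset of the other.
# The estimator assumes substitutions only (no indels) and is intended for
# closely related genomes (true ANI >= 90); far below that, shared k-mers
# vanish and the estimate collapses toward zero.

#' Build a canonical k-mer sketch of an assembly
#'
#' Collects the set of strand-canonical k-mers over all contigs. Non-ACGT
#' characters break the k-mer window: no k-mer spans an ambiguity code.
#' Contigs shorter than k are skipped. The full k-mer set is kept (no
#' subsampling), which is exact at the genome sizes this package targets.
#'
#' @param x An `assembly_record` (its FASTA is read) or a character vector
#'   of nucleotide sequences.
#' @param k k-mer length between 11 and 31 (default 16 is below the
#'   random-collision regime for genomes up to tens of Mb and sensitive at
#'   ANI >= 90). Even k admits self-complementary palindromic k-mers; these
#'   canonicalize to themselves and do not bias containment.
#' @param id Sketch label; defaults to the assembly id.
#' @return A `kmer_sketch`: list with `assembly_id`, `k`, `kmer_keys`
#'   (character vector of canonical k-mers) and `source_length`.
#' @export
sketch <- function(x, k = 16L, id = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 11L || k > 31L)
    derep_abort("k must be within [11, 31]", "derephits_domain_error")
  if (inherits(x, "assembly_record")) {
    seqs <- as.character(Biostrings::readDNAStringSet(x$fasta_path))
    id <- id %||% x$assembly_id
  } else if (is.character(x)) {
    seqs <- x
    id <- id %||% "sequence"
  } else {
    derep_abort("x must be an assembly_record or a character vector",
                "derephits_usage_error")
  }
  keys <- unique(unlist(lapply(seqs, canonical_kmers, k = k),
                        use.names = FALSE))
  if (!length(keys))
    derep_abort(sprintf("assembly '%s' yields no valid %d-mers", id, k),
                "derephits_sketch_error")
  structure(list(assembly_id = id, k = k, kmer_keys = keys,
                 source_length = sum(nchar(seqs))),
            class = "kmer_sketch")
}

canonical_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  code <- utf8ToInt(s)
  valid <- code == 65L | code == 67L | code == 71L | code == 84L  # A C G T
  bad <- cumsum(!valid)
  i <- seq_len(n - k + 1L)
  ok <- (bad[i + k - 1L] - c(0L, bad)[i]) == 0L
  i <- i[ok]
  if (!length(i)) return(character(0))
  fwd <- substring(s, i, i + k - 1L)
  rc <- chartr("ACGT", "TGCA", intToUtf8(rev(code)))
  rck <- substring(rc, n - (i + k - 1L) + 1L, n - i + 1L)
  unique(pmin(fwd, rck))
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("k-mer sketch of %s: k=%d, %d canonical k-mers, %d bp\n",
              x$assembly_id, x$k, length(x$kmer_keys), x$source_length))
  invisible(x)
}

#' Estimate ANI and aligned fractions between two sketches
#'
#' @param sa,sb `kmer_sketch` objects built with the same k.
#' @return One-row data frame with columns `a`, `b`, `ani` (percent,
#'   symmetric), `af_a`, `af_b` (directional containment percentages).
#' @export
pairwise_ani <- function(sa, sb) {
  stopifnot(inherits(sa, "kmer_sketch"), inherits(sb, "kmer_sketch"))
  if (sa$k != sb$k)
    derep_abort("sketches were built with different k", "derephits_contract_error")
  inter <- length(intersect(sa$kmer_keys, sb$kmer_keys))
  ca <- inter / length(sa$kmer_keys)
  cb <- inter / length(sb$kmer_keys)
  ani <- 100 * max(ca, cb)^(1 / sa$k)
  data.frame(a = sa$assembly_id, b = sb$assembly_id,
             ani = min(max(ani, 0), 100),
             af_a = 100 * ca, af_b = 100 * cb,
             stringsAsFactors = FALSE)
}

#' All pairwise ANI comparisons
#'
#' @param sketches List of `kmer_sketch`es (common k, length >= 2).
#' @param cores Number of worker processes for the comparisons; the output
#'   is identical to sequential evaluation.
#' @return Data frame of n(n-1)/2 rows in the format of [pairwise_ani()].
#' @export
all_pairs <- function(sketches, cores = 1L) {
  if (length(sketches) < 2L)
    derep_abort("need at least two sketches", "derephits_contract_error")
  ks <- vapply(sketches, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L)
    derep_abort("sketches were built with different k", "derephits_contract_error")
  cmb <- utils::combn(length(sketches), 2L)
  f <- function(j) pairwise_ani(sketches[[cmb[1L, j]]], sketches[[cmb[2L, j]]])
  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(ncol(cmb)), f, mc.cores = cores)
  } else {
    lapply(seq_len(ncol(cmb)), f)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write the intermediate ANI table
#'
#' @param ani Data frame from [all_pairs()].
#' @param path Output path (tab-separated: a, b, ani, af_a, af_b).
#' @return Invisibly, `path`.
#' @export
write_ani_table <- function(ani, path) {
  utils::write.table(ani, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
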