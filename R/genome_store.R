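#' Assembly N50
#'
#' The largest contig length L such that contigs of length >= L sum to at
#' least half the total assembly length. Independent of contig order.
#'
#' @param contig_lengths Non-empty vector of positive contig lengths (bases).
#' @return Integer N50 in bases.
#' @examples
#' compute_n50(c(10, 20, 30, 40))  # 30
#' @export
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L)
    derep_abort("contig length list is empty", "derephits_domain_error")
  cl <- as.numeric(contig_lengths)
  if (any(!is.finite(cl)) || any(cl <= 0))
    derep_abort("contig lengths must be positive and finite",
                "derephits_domain_error")
  cl <- sort(cl, decreasing = TRUE)
  as.integer(cl[which(cumsum(cl) >= sum(cl) / 2)[1L]])
}

strip_fasta_ext <- function(x) {
  sub("\\.(fa|fasta|fna)(\\.gz)?$", "", x, ignore.case = TRUE)
}

#' Index one genome assembly FASTA
#'
#' Reads a (possibly gzip-compressed) nucleotide FASTA, records the scaffold
#' identifiers (first whitespace-delimited token of each header, per NCBI
#' convention) and computes N50 and total length. Compression is detected
#' from the file content, not the extension.
#'
#' @param fasta_path Path to a FASTA or gzipped FASTA file.
#' @param assembly_id Assembly accession; defaults to the file name without
#'   FASTA extensions.
#' @return An `assembly_record`: list with `assembly_id`, `fasta_path`,
#'   `scaffold_ids`, `n_contigs`, `n50`, `total_length`.
#' @export
read_assembly <- function(fasta_path, assembly_id = NULL) {
  if (!file.exists(fasta_path))
    derep_abort(sprintf("assembly FASTA not found: %s", fasta_path),
                "derephits_io_error")
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) derep_abort(
                     sprintf("cannot parse FASTA '%s': %s", fasta_path,
                             conditionMessage(e)), "derephits_format_error"))
  if (length(seqs) == 0L)
    derep_abort(sprintf("no sequences in FASTA '%s'", fasta_path),
                "derephits_format_error")
  ids <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  structure(list(
    assembly_id = assembly_id %||% strip_fasta_ext(basename(fasta_path)),
    fasta_path = normalizePath(fasta_path),
    scaffold_ids = ids,
    n_contigs = length(seqs),
    n50 = compute_n50(w),
    total_length = sum(w)), class = "assembly_record")
}

#' @export
print.assembly_record <- function(x, ...) {
  cat(sprintf("assembly %s: %d contig(s), %d bp, N50 %d\n",
              x$assembly_id, x$n_contigs, x$total_length, x$n50))
  invisible(x)
}

#' Define a remote assembly-retrieval adapter
#'
#' Pluggable interface standing in for live NCBI ID mapping and download
#' clients. `map_ids` receives a batch of at most `batch_size` scaffold
#' accessions (the batching contract used to keep server round trips low)
#' and returns the corresponding assembly accessions; `fetch` downloads one
#' assembly FASTA into a destination directory and returns its path. Any
#' whole-genome-shotgun master-record redirection belongs inside the adapter;
#' the pipeline core only sees scaffold accessions and assembly ids.
#'
#' @param map_ids `function(accessions) -> character` of assembly ids.
#' @param fetch `function(assembly_id, dest_dir) -> path` to a FASTA file.
#' @param batch_size Maximum accessions per `map_ids` call (default 5000).
#' @return A `remote_adapter` object.
#' @export
remote_adapter <- function(map_ids, fetch, batch_size = 5000L) {
  if (!is.function(map_ids) || !is.function(fetch))
    derep_abort("map_ids and fetch must be functions", "derephits_usage_error")
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L)
    derep_abort("batch_size must be a positive integer", "derephits_usage_error")
  structure(list(map_ids = map_ids, fetch = fetch, batch_size = batch_size),
            class = "remote_adapter")
}

#' Acquire and index the assemblies hosting a set of scaffolds
#'
#' From a local directory, every FASTA file (`.fa`, `.fasta`, `.fna`,
#' optionally `.gz`) is indexed. Through a [remote_adapter()], scaffold
#' accessions are deduplicated, submitted to `map_ids` in batches of at most
#' `batch_size`, and each distinct assembly id is fetched exactly once.
#'
#' @param scaffold_accessions Character vector of scaffold accessions.
#' @param source Either a path to a directory of FASTA files or a
#'   `remote_adapter`.
#' @param dest_dir Directory for fetched files (remote source only).
#' @return Named list of `assembly_record`s (names = assembly ids).
#' @export
acquire_assemblies <- function(scaffold_accessions, source, dest_dir = NULL) {
  if (inherits(source, "remote_adapter")) {
    if (is.null(dest_dir))
      derep_abort("dest_dir is required for remote acquisition",
                  "derephits_usage_error")
    dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
    accs <- unique(as.character(scaffold_accessions))
    batches <- split(accs, ceiling(seq_along(accs) / source$batch_size))
    aids <- unique(unlist(lapply(batches, function(b)
      as.character(source$map_ids(b))), use.names = FALSE))
    recs <- lapply(aids, function(aid) {
      fp <- tryCatch(source$fetch(aid, dest_dir),
                     error = function(e) derep_abort(
                       sprintf("fetch failed for assembly '%s': %s", aid,
                               conditionMessage(e)), "derephits_fetch_error"))
      read_assembly(fp, assembly_id = aid)
    })
  } else if (is.character(source) && length(source) == 1L &&
             dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files))
      derep_abort(sprintf("no FASTA files found in '%s'", source),
                  "derephits_io_error")
    recs <- lapply(files, read_assembly)
  } else {
    derep_abort("source must be an existing directory or a remote_adapter",
                "derephits_usage_error")
  }
  names(recs) <- vapply(recs, `[[`, character(1), "assembly_id")
  if (anyDuplicated(names(recs)))
    derep_abort("duplicate assembly ids among acquired assemblies",
                "derephits_integrity_error")
  recs
}

strip_version <- function(x) sub("\\.[0-9]+$", "", x)

#' Reconstruct the scaffold-to-assembly mapping locally
#'
#' Matches each scaffold accession extracted from a session against the
#' scaffold identifiers indexed from the assembly FASTA files. Exact token
#' match is tried first, then a version-stripped match (accession without
#' its trailing `.N`). Accessions matching no assembly are returned in
#' `unmapped`, never silently dropped; an accession matching two or more
#' assemblies is an ambiguity error.
#'
#' @param scaffold_accessions Character vector of scaffold accessions.
#' @param assemblies List of `assembly_record`s.
#' @return A `scaffold_assembly_map`: list with `pairs` (data frame
#'   `scaffold`, `assembly_id`, sorted by scaffold) and `unmapped`
#'   (character vector).
#' @export
reconstruct_mapping <- function(scaffold_accessions, assemblies) {
  accs <- unique(as.character(scaffold_accessions))
  aid <- vapply(assemblies, `[[`, character(1), "assembly_id")
  toks <- lapply(assemblies, `[[`, "scaffold_ids")
  tok_df <- data.frame(
    token = unlist(toks, use.names = FALSE),
    assembly = rep(aid, vapply(toks, length, integer(1))),
    stringsAsFactors = FALSE)
  tok_df$stripped <- strip_version(tok_df$token)
  found <- rep(NA_character_, length(accs))
  for (i in seq_along(accs)) {
    q <- accs[i]
    cand <- unique(tok_df$assembly[tok_df$token == q])
    if (!length(cand)) {
      qs <- strip_version(q)
      cand <- unique(tok_df$assembly[tok_df$token == qs | tok_df$stripped == qs])
    }
    if (length(cand) > 1L)
      derep_abort(sprintf("scaffold '%s' matches multiple assemblies: %s",
                          q, paste(sort(cand), collapse = ", ")),
                  "derephits_ambiguity_error")
    if (length(cand)) found[i] <- cand
  }
  ok <- !is.na(found)
  pairs <- data.frame(scaffold = accs[ok], assembly_id = found[ok],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$scaffold), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmapped = sort(accs[!ok])),
            class = "scaffold_assembly_map")
}

#' @export
print.scaffold_assembly_map <- function(x, ...) {
  cat(sprintf("scaffold-assembly map: %d mapped, %d unmapped\n",
              nrow(x$pairs), length(x$unmapped)))
  invisible(x)
}
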