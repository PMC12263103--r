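#' Pipeline configuration
#'
#' @param session_path Path to the cblaster session JSON (required).
#' @param output_dir Directory for the seven output files (created if
#'   absent).
#' @param local_genomes Directory of assembly FASTA files; exactly one of
#'   `local_genomes` or `adapter` must be given.
#' @param adapter A [remote_adapter()] for assembly retrieval.
#' @param ani_threshold,af_threshold Redundancy-edge cutoffs in percent
#'   (defaults 99 and 90); see [derep_params()].
#' @param z_threshold Score-recovery z cutoff (default 2); see
#'   [recovery_params()].
#' @param by_content,by_score Recovery strategy switches (default TRUE).
#' @param one_sided One-sided score recovery (default FALSE).
#' @param seed Integer seed for the random subgroup-representative choice.
#' @param k k-mer length for the ANI sketches (default 16).
#' @param cores Worker processes for the pairwise ANI stage.
#' @param keep_intermediate Also write the ANI table and the genome file
#'   list.
#' @param strict Treat unmapped scaffolds as an error instead of a warning.
#' @param log_level One of "DEBUG", "INFO", "WARN", "ERROR".
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(session_path, output_dir = "derephits_out",
                            local_genomes = NULL, adapter = NULL,
                            ani_threshold = 99, af_threshold = 90,
                            z_threshold = 2, by_content = TRUE,
                            by_score = TRUE, one_sided = FALSE, seed = 1L,
                            k = 16L, cores = 1L, keep_intermediate = FALSE,
                            strict = FALSE, log_level = "INFO") {
  if (missing(session_path) || is.null(session_path))
    derep_abort("a session file path is required", "derephits_usage_error")
  if (is.null(local_genomes) && is.null(adapter))
    derep_abort("either local_genomes or adapter must be supplied",
                "derephits_usage_error")
  derep_params(ani_threshold, af_threshold)        # range validation
  recovery_params(z_threshold)
  cores <- as.integer(cores)
  if (is.na(cores) || cores < 1L)
    derep_abort("cores must be a positive integer", "derephits_usage_error")
  log_level <- match.arg(toupper(log_level),
                         c("DEBUG", "INFO", "WARN", "ERROR"))
  structure(list(session_path = session_path, output_dir = output_dir,
                 local_genomes = local_genomes, adapter = adapter,
                 ani_threshold = ani_threshold, af_threshold = af_threshold,
                 z_threshold = z_threshold, by_content = isTRUE(by_content),
                 by_score = isTRUE(by_score), one_sided = isTRUE(one_sided),
                 seed = as.integer(seed), k = as.integer(k), cores = cores,
                 keep_intermediate = isTRUE(keep_intermediate),
                 strict = isTRUE(strict), log_level = log_level),
            class = "pipeline_config")
}

make_logger <- function(level) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  min_lv <- levels[[level]]
  function(lv, msg) {
    if (levels[[lv]] >= min_lv)
      message(sprintf("[%s] %s", lv, msg))
    invisible(NULL)
  }
}

empty_ani <- function() {
  data.frame(a = character(0), b = character(0), ani = numeric(0),
             af_a = numeric(0), af_b = numeric(0), stringsAsFactors = FALSE)
}

#' Run the full dereplication pipeline
#'
#' Reads the session, acquires and indexes the assemblies hosting its hits,
#' reconstructs the scaffold-to-assembly mapping, estimates all pairwise
#' ANIs, clusters the assemblies with greedy representative selection,
#' recovers hits by cluster content and by score outliers, and writes the
#' seven output text files (`clusters.txt`, `filtered_binary.txt`,
#' `filtered_session.json`, `filtered_summary.txt`,
#' `genome_cluster_sizes.txt`, `genome_cluster_status.txt`,
#' `scaffold_assembly_pairs.txt`) into the output directory. Hits on
#' scaffolds that resolve to no assembly are excluded from dereplication
#' and reported with status `unmapped` (an error under `strict`).
#'
#' @param config A [pipeline_config()] object.
#' @return A `derep_run`: list with the per-hit `report` (see
#'   [assemble_report()]), `retained` cluster ids, `fold_reduction`,
#'   `clusters`, `session`, `mapping`, `ani`, and the written `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- make_logger(config$log_level)
  log("INFO", sprintf(
    "starting: ANI >= %.2f%%, AF >= %.2f%%, z >= %.2f (%s), seed = %d, k = %d",
    config$ani_threshold, config$af_threshold, config$z_threshold,
    if (config$one_sided) "one-sided" else "two-sided",
    config$seed, config$k))

  session <- with_stage("read_session", read_session(config$session_path))
  log("INFO", sprintf("session: %d query genes, %d hits",
                      length(session$query_genes), nrow(session$hits)))
  scafs <- unique(session$hits$scaffold)

  source <- config$local_genomes %||% config$adapter
  assemblies <- with_stage("acquire_assemblies",
    acquire_assemblies(scafs, source,
                       dest_dir = file.path(config$output_dir, "genomes")))
  log("INFO", sprintf("assemblies indexed: %d", length(assemblies)))

  mapping <- with_stage("reconstruct_mapping",
                        reconstruct_mapping(scafs, assemblies))
  if (length(mapping$unmapped)) {
    msg <- sprintf("%d scaffold(s) unmapped: %s", length(mapping$unmapped),
                   paste(mapping$unmapped, collapse = ", "))
    if (config$strict)
      derep_abort(paste("[stage: reconstruct_mapping]", msg),
                  "derephits_integrity_error")
    log("WARN", msg)
  }

  used_ids <- sort(unique(mapping$pairs$assembly_id))
  used <- assemblies[used_ids]
  sketches <- with_stage("sketch",
                         lapply(used, sketch, k = config$k))
  ani <- if (length(sketches) >= 2L) {
    with_stage("ani", all_pairs(sketches, cores = config$cores))
  } else {
    empty_ani()
  }
  log("DEBUG", sprintf("pairwise comparisons: %d", nrow(ani)))

  stats <- data.frame(
    assembly_id = used_ids,
    n50 = vapply(used, `[[`, integer(1), "n50"),
    total_length = vapply(used, function(a) as.numeric(a$total_length),
                          numeric(1)),
    stringsAsFactors = FALSE)
  dp <- derep_params(config$ani_threshold, config$af_threshold, config$seed)
  graph <- with_stage("dereplication",
                      build_redundancy_graph(ani, used_ids, dp))
  clusters <- with_stage("dereplication", greedy_select(graph, stats, dp))
  log("INFO", sprintf("genome clusters: %d over %d assemblies",
                      length(clusters), length(used_ids)))

  a_of <- stats::setNames(mapping$pairs$assembly_id, mapping$pairs$scaffold)
  mapped <- session$hits$scaffold %in% mapping$pairs$scaffold
  ht <- data.frame(cluster_id = session$hits$cluster_id[mapped],
                   assembly_id = unname(a_of[session$hits$scaffold[mapped]]),
                   score = session$hits$score[mapped],
                   stringsAsFactors = FALSE)
  counts <- session$homolog_counts[mapped, , drop = FALSE]
  rp <- recovery_params(config$z_threshold, config$by_content,
                        config$by_score, config$one_sided, config$seed)
  recovery <- with_stage("hit_recovery",
                         recover_hits(clusters, ht, counts, rp))
  log("INFO", sprintf("recovered: %d by content, %d by score",
                      length(recovery$recovered_content),
                      length(recovery$recovered_score)))

  report <- with_stage("hit_recovery",
                       assemble_report(session, mapping, clusters, recovery))
  retained <- attr(report, "retained")
  fold <- round(nrow(session$hits) / max(length(retained), 1L), 2L)
  log("INFO", sprintf("%d hits -> %d retained (%.2f-fold reduction)",
                      nrow(session$hits), length(retained), fold))

  files <- with_stage("write_outputs",
    write_outputs(report, session, mapping, clusters, config$output_dir,
                  keep_intermediate = config$keep_intermediate,
                  ani = ani, assemblies = used))
  log("INFO", sprintf("wrote %d output file(s) to %s", length(files),
                      config$output_dir))

  structure(list(report = report, retained = retained,
                 fold_reduction = fold, clusters = clusters,
                 session = session, mapping = mapping, ani = ani,
                 files = files, config = config),
            class = "derep_run")
}

#' Write the seven pipeline output files
#'
#' `clusters.txt` (one line of ascending comma-separated retained cluster
#' numbers), `filtered_binary.txt`, `filtered_session.json`,
#' `filtered_summary.txt` (the session restricted to retained hits),
#' `genome_cluster_sizes.txt`, `genome_cluster_status.txt` (tab-separated:
#' cluster_id, scaffold, assembly_id, representative, status) and
#' `scaffold_assembly_pairs.txt` (tab-separated scaffold/assembly pairs).
#' Partial outputs are removed on failure. With `keep_intermediate`, also
#' `ani_table.txt` and `genome_files.txt`.
#'
#' @param report A `derep_report`.
#' @param session The input `cblaster_session`.
#' @param mapping A `scaffold_assembly_map`.
#' @param clusters A `genome_clusters` object.
#' @param output_dir Output directory (created if needed).
#' @param keep_intermediate Write intermediate tables too.
#' @param ani ANI data frame (for `keep_intermediate`).
#' @param assemblies Assembly records (for `keep_intermediate`).
#' @return Invisibly, named vector of the seven file paths.
#' @export
write_outputs <- function(report, session, mapping, clusters, output_dir,
                          keep_intermediate = FALSE, ani = NULL,
                          assemblies = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fnames <- c("clusters.txt", "filtered_binary.txt", "filtered_session.json",
              "filtered_summary.txt", "genome_cluster_sizes.txt",
              "genome_cluster_status.txt", "scaffold_assembly_pairs.txt")
  files <- stats::setNames(file.path(output_dir, fnames), fnames)
  retained <- attr(report, "retained")
  tryCatch({
    writeLines(paste(sort(retained), collapse = ","), files["clusters.txt"])
    fs <- filter_session(session, retained)
    write_binary_table(fs, files["filtered_binary.txt"])
    write_session(fs, files["filtered_session.json"])
    write_summary(fs, files["filtered_summary.txt"])
    write_cluster_sizes(clusters, files["genome_cluster_sizes.txt"])
    utils::write.table(as.data.frame(report),
                       files["genome_cluster_status.txt"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mapping$pairs, files["scaffold_assembly_pairs.txt"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (keep_intermediate) {
      if (!is.null(ani))
        write_ani_table(ani, file.path(output_dir, "ani_table.txt"))
      if (!is.null(assemblies))
        writeLines(vapply(assemblies, `[[`, character(1), "fasta_path"),
                   file.path(output_dir, "genome_files.txt"))
    }
  }, error = function(e) {
    unlink(files)
    stop(e)
  })
  invisible(files)
}

#' @export
print.derep_run <- function(x, ...) {
  cat(sprintf(
    "dereplication run: %d hits -> %d retained (%.2f-fold), %d genome cluster(s)\n",
    nrow(x$session$hits), length(x$retained), x$fold_reduction,
    length(x$clusters)))
  print(table(status = x$report$status))
  invisible(x)
}

#' @method summary derep_run
#' @export
summary.derep_run <- function(object, ...) summary(object$report, ...)
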