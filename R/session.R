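#' Read a cblaster session file
#'
#' Parses a cblaster search session (JSON) into a `cblaster_session` object.
#' The session dialect is the remote-search schema: a top-level `queries`
#' list naming the query genes and an `organisms` list nesting `scaffolds`
#' and `clusters`; each cluster carries a unique numeric `number`,
#' `start`/`end` coordinates, a homology `score`, and `subjects` whose
#' `hits` name the query gene they match. The parsed document is retained
#' verbatim (unknown keys included) so filtered sessions can be rewritten
#' losslessly.
#'
#' For each cluster, `homolog_counts[i]` is the number of subject hits in
#' that cluster whose `query` equals the i-th query gene; the ordered query
#' gene list fixes the column order everywhere homolog counts appear.
#'
#' @param path Path to a cblaster session JSON file.
#' @return An object of class `cblaster_session`: a list with elements
#'   `query_genes` (character), `hits` (data frame with columns
#'   `cluster_id`, `organism`, `scaffold`, `start`, `end`, `score`),
#'   `homolog_counts` (integer matrix, one row per hit, one column per
#'   query gene), and `raw` (the parsed JSON document).
#' @examples
#' \dontrun{
#' s <- read_session("session.json")
#' s$hits
#' }
#' @export
read_session <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    derep_abort(sprintf("session file not found: %s", path), "derephits_io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) derep_abort(
      sprintf("malformed session JSON in '%s': %s", path, conditionMessage(e)),
      "derephits_parse_error"))
  session_from_document(doc)
}

query_gene_ids <- function(doc) {
  q <- doc$queries
  if (is.null(q) || length(q) == 0L)
    derep_abort("session document lacks a non-empty $.queries list",
                "derephits_schema_error")
  ids <- vapply(q, function(x) {
    if (is.character(x) && length(x) == 1L) return(x)
    if (is.list(x)) {
      nm <- x$name %||% x$id
      if (is.character(nm) && length(nm) == 1L) return(nm)
    }
    derep_abort("unrecognized entry under $.queries (need a gene name string)",
                "derephits_schema_error")
  }, character(1))
  if (anyDuplicated(ids))
    derep_abort("duplicate query gene ids in $.queries", "derephits_schema_error")
  if (any(!nzchar(ids)))
    derep_abort("empty query gene id in $.queries", "derephits_schema_error")
  ids
}

count_homologs <- function(cl, genes, where) {
  subs <- cl$subjects
  if (is.null(subs))
    derep_abort(paste0("missing 'subjects' at ", where), "derephits_schema_error")
  tab <- stats::setNames(integer(length(genes)), genes)
  for (sb in subs) {
    for (h in sb$hits %||% list()) {
      qg <- h$query
      if (is.null(qg))
        derep_abort(paste0("subject hit without 'query' at ", where),
                    "derephits_schema_error")
      if (qg %in% genes) tab[[qg]] <- tab[[qg]] + 1L
    }
  }
  tab
}

session_from_document <- function(doc) {
  genes <- query_gene_ids(doc)
  orgs <- doc$organisms
  if (is.null(orgs))
    derep_abort("session document lacks $.organisms", "derephits_schema_error")
  rows <- list()
  counts <- list()
  for (oi in seq_along(orgs)) {
    org <- orgs[[oi]]
    oname <- org$name %||% sprintf("organism_%d", oi)
    scafs <- org$scaffolds
    if (is.null(scafs))
      derep_abort(sprintf("missing $.organisms[%d].scaffolds", oi),
                  "derephits_schema_error")
    for (si in seq_along(scafs)) {
      sc <- scafs[[si]]
      acc <- sc$accession %||% sc$name
      if (is.null(acc))
        derep_abort(sprintf("missing accession at $.organisms[%d].scaffolds[%d]",
                            oi, si), "derephits_schema_error")
      for (ci in seq_along(sc$clusters %||% list())) {
        cl <- sc$clusters[[ci]]
        where <- sprintf("$.organisms[%d].scaffolds[%d].clusters[%d]", oi, si, ci)
        num <- cl$number %||% cl$id
        if (is.null(num))
          derep_abort(paste0("missing cluster number at ", where),
                      "derephits_schema_error")
        for (f in c("start", "end", "score"))
          if (is.null(cl[[f]]))
            derep_abort(sprintf("missing '%s' at %s", f, where),
                        "derephits_schema_error")
        if (as.numeric(cl$end) <= as.numeric(cl$start))
          derep_abort(paste0("cluster end <= start at ", where),
                      "derephits_schema_error")
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = as.integer(num), organism = as.character(oname),
          scaffold = as.character(acc), start = as.numeric(cl$start),
          end = as.numeric(cl$end), score = as.numeric(cl$score),
          stringsAsFactors = FALSE)
        counts[[length(counts) + 1L]] <- count_homologs(cl, genes, where)
      }
    }
  }
  if (length(rows)) {
    hits <- do.call(rbind, rows)
    cm <- do.call(rbind, counts)
  } else {
    hits <- data.frame(cluster_id = integer(0), organism = character(0),
                       scaffold = character(0), start = numeric(0),
                       end = numeric(0), score = numeric(0),
                       stringsAsFactors = FALSE)
    cm <- matrix(integer(0), nrow = 0L, ncol = length(genes))
  }
  rownames(hits) <- NULL
  dimnames(cm) <- list(NULL, genes)
  dup <- hits$cluster_id[duplicated(hits$cluster_id)]
  if (length(dup))
    derep_abort(sprintf("duplicate cluster ids in session: %s",
                        paste(sort(unique(dup)), collapse = ", ")),
                "derephits_integrity_error")
  structure(list(query_genes = genes, hits = hits, homolog_counts = cm,
                 raw = doc),
            class = "cblaster_session")
}

#' Filter a session down to a set of retained cluster hits
#'
#' Keeps exactly the hits whose cluster numbers are in `retained_ids`,
#' pruning organisms and scaffolds left without clusters from the underlying
#' document. Query genes are unchanged.
#'
#' @param session A `cblaster_session`.
#' @param retained_ids Integer vector of cluster numbers to keep; must all
#'   exist in the session.
#' @return A filtered `cblaster_session`.
#' @export
filter_session <- function(session, retained_ids) {
  stopifnot(inherits(session, "cblaster_session"))
  retained_ids <- unique(as.integer(retained_ids))
  unknown <- setdiff(retained_ids, session$hits$cluster_id)
  if (length(unknown))
    derep_abort(sprintf("unknown cluster ids in filter: %s",
                        paste(sort(unknown), collapse = ", ")),
                "derephits_integrity_error")
  doc <- session$raw
  doc$organisms <- Filter(function(org) length(org$scaffolds) > 0L,
    lapply(doc$organisms, function(org) {
      org$scaffolds <- Filter(function(sc) length(sc$clusters) > 0L,
        lapply(org$scaffolds, function(sc) {
          sc$clusters <- Filter(
            function(cl) as.integer(cl$number %||% cl$id) %in% retained_ids,
            sc$clusters %||% list())
          sc
        }))
      org
    }))
  out <- session_from_document(doc)
  out$query_genes <- session$query_genes
  out
}

#' Write a session back to JSON
#'
#' Emits the retained document so that [read_session()] recovers an equal
#' session (hits, counts, scores); unknown keys carried in the document are
#' preserved.
#'
#' @param session A `cblaster_session`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "cblaster_session"))
  json <- jsonlite::toJSON(session$raw, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  tryCatch(writeLines(json, path),
           error = function(e) derep_abort(
             sprintf("cannot write session to '%s': %s", path,
                     conditionMessage(e)), "derephits_io_error"),
           warning = function(w) derep_abort(
             sprintf("cannot write session to '%s': %s", path,
                     conditionMessage(w)), "derephits_io_error"))
  invisible(path)
}

#' Write the binary presence/absence table
#'
#' One tab-separated row per hit: organism, scaffold accession, start, end,
#' score, then one homolog-count column per query gene, in query order.
#' Coordinates are emitted exactly as read from the session.
#'
#' @inheritParams write_session
#' @return Invisibly, `path`.
#' @export
write_binary_table <- function(session, path) {
  stopifnot(inherits(session, "cblaster_session"))
  h <- session$hits
  df <- data.frame(Organism = h$organism, Scaffold = h$scaffold,
                   Start = h$start, End = h$end, Score = h$score,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (g in session$query_genes) df[[g]] <- session$homolog_counts[, g]
  tryCatch(utils::write.table(df, path, sep = "\t", quote = FALSE,
                              row.names = FALSE),
           error = function(e) derep_abort(
             sprintf("cannot write binary table to '%s'", path),
             "derephits_io_error"))
  invisible(path)
}

#' Write the human-readable per-organism summary
#'
#' One block per organism listing each retained cluster, its scaffold and
#' coordinates, its score, and its homolog-count vector.
#'
#' @inheritParams write_session
#' @return Invisibly, `path`.
#' @export
write_summary <- function(session, path) {
  stopifnot(inherits(session, "cblaster_session"))
  h <- session$hits
  lines <- character(0)
  if (nrow(h) == 0L) {
    lines <- "No gene cluster hits."
  } else {
    for (org in unique(h$organism)) {
      lines <- c(lines, sprintf("Organism: %s", org))
      idx <- which(h$organism == org)
      for (i in idx) {
        cnt <- paste(sprintf("%s=%d", session$query_genes,
                             session$homolog_counts[i, ]), collapse = " ")
        lines <- c(lines, sprintf("  Cluster %d  %s:%s-%s  score=%s  [%s]",
                                  h$cluster_id[i], h$scaffold[i],
                                  format(h$start[i], scientific = FALSE),
                                  format(h$end[i], scientific = FALSE),
                                  format(h$score[i]), cnt))
      }
      lines <- c(lines, "")
    }
  }
  tryCatch(writeLines(lines, path),
           error = function(e) derep_abort(
             sprintf("cannot write summary to '%s'", path),
             "derephits_io_error"))
  invisible(path)
}

#' @export
print.cblaster_session <- function(x, ...) {
  cat(sprintf("cblaster session: %d query genes, %d hits, %d organisms\n",
              length(x$query_genes), nrow(x$hits),
              length(unique(x$hits$organism))))
  cat("query genes:", paste(x$query_genes, collapse = ", "), "\n")
  invisible(x)
}
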