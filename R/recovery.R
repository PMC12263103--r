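#' Hit-recovery parameters
#'
#' @param z_threshold Positive z-score cutoff for score-based recovery
#'   (default 2, the conventional two-sigma outlier rule; inclusive).
#' @param by_content Enable content-based recovery (default TRUE).
#' @param by_score Enable score-based recovery (default TRUE).
#' @param one_sided If TRUE only high-score outliers are recovered; the
#'   default is two-sided (|z| >= threshold).
#' @param seed Integer seed driving the random subgroup representative
#'   choice.
#' @return A `recovery_params` object.
#' @export
recovery_params <- function(z_threshold = 2, by_content = TRUE,
                            by_score = TRUE, one_sided = FALSE, seed = 1L) {
  if (!is.numeric(z_threshold) || !is.finite(z_threshold) || z_threshold <= 0)
    derep_abort("z_threshold must be finite and positive",
                "derephits_domain_error")
  structure(list(z_threshold = z_threshold,
                 by_content = isTRUE(by_content),
                 by_score = isTRUE(by_score),
                 one_sided = isTRUE(one_sided),
                 seed = as.integer(seed)), class = "recovery_params")
}

#' Subdivide a genome cluster's hits by cluster content
#'
#' Groups hits by their homolog-count vector (how many homologs of each
#' query gene the hit cluster contains). One subgroup per distinct vector;
#' every hit of every member assembly lands in exactly one subgroup.
#' Subgroups are returned in lexicographic key order.
#'
#' @param hits Data frame with columns `cluster_id`, `assembly_id`, `score`.
#' @param counts Homolog-count matrix aligned to the rows of `hits`, or a
#'   list of integer vectors (which must share one length).
#' @param members Optional assembly ids to restrict to (a genome cluster's
#'   member set).
#' @return List of subgroups; each is a list with `key` (integer vector)
#'   and `hits` (the subset data frame).
#' @export
subgroup_hits <- function(hits, counts, members = NULL) {
  if (is.list(counts) && !is.matrix(counts)) {
    if (length(counts) && length(unique(lengths(counts))) > 1L)
      derep_abort("homolog count vectors have inconsistent lengths",
                  "derephits_integrity_error")
    counts <- do.call(rbind, lapply(counts, as.integer))
  }
  if (!is.null(counts) && nrow(hits) != NROW(counts))
    derep_abort("counts must have one row per hit", "derephits_integrity_error")
  if (!is.null(members)) {
    keep <- hits$assembly_id %in% members
    hits <- hits[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
  }
  if (!nrow(hits)) return(list())
  key <- apply(counts, 1L, paste, collapse = ",")
  lapply(sort(unique(key)), function(kk) {
    rows <- which(key == kk)
    sub <- hits[rows, , drop = FALSE]
    rownames(sub) <- NULL
    list(key = as.integer(strsplit(kk, ",", fixed = TRUE)[[1L]]), hits = sub)
  })
}

#' Content-based hit recovery within one genome cluster
#'
#' For every subgroup that contains no hit hosted by the cluster's
#' representative assembly, one member assembly is chosen uniformly at
#' random (from the caller's RNG state) as the subgroup's new
#' representative, and all of that assembly's hits in the subgroup are
#' recovered. Subgroups containing a representative-hosted hit contribute
#' nothing, even if the representative hosts additional hits with other
#' keys.
#'
#' @param subgroups List from [subgroup_hits()] for one genome cluster.
#' @param representative The cluster's representative assembly id.
#' @return Sorted integer vector of recovered cluster ids.
#' @export
recover_by_content <- function(subgroups, representative) {
  out <- integer(0)
  for (sg in subgroups) {
    if (representative %in% sg$hits$assembly_id) next
    cand <- sort(unique(sg$hits$assembly_id))
    chosen <- if (length(cand) == 1L) cand else sample(cand, 1L)
    out <- c(out, sg$hits$cluster_id[sg$hits$assembly_id == chosen])
  }
  sort(unique(out))
}

#' Score-based hit recovery within one subgroup
#'
#' Standardizes member scores with the subgroup mean and population
#' standard deviation (a subgroup is the complete population of its genome
#' cluster, and the n-1 denominator is undefined for singletons). Hits at
#' or beyond the z cutoff are recovered unless already retained. A zero
#' standard deviation recovers nothing.
#'
#' @param subgroup One subgroup from [subgroup_hits()].
#' @param z_threshold Positive cutoff (inclusive).
#' @param exclude Cluster ids already retained (representative-hosted or
#'   content-recovered).
#' @param one_sided If TRUE, only z >= threshold (high scores) qualifies.
#' @return Sorted integer vector of recovered cluster ids.
#' @export
recover_by_score <- function(subgroup, z_threshold = 2, exclude = integer(0),
                             one_sided = FALSE) {
  x <- subgroup$hits$score
  if (any(!is.finite(x)))
    derep_abort("non-finite cluster score in subgroup",
                "derephits_integrity_error")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) return(integer(0))
  z <- (x - mu) / sigma
  sel <- if (one_sided) z >= z_threshold else abs(z) >= z_threshold
  sort(setdiff(subgroup$hits$cluster_id[sel], exclude))
}

#' Run both recovery strategies over all genome clusters
#'
#' Content recovery runs first; score recovery then scans every subgroup
#' (including the representative's) but never re-reports a hit that is
#' representative-hosted or content-recovered, so the two recovered sets
#' are disjoint. Clusters are processed in representative order and the RNG
#' is seeded from `params$seed`, making the retained set reproducible.
#'
#' @param clusters A `genome_clusters` object.
#' @param hits Data frame (`cluster_id`, `assembly_id`, `score`) of all
#'   mapped hits.
#' @param counts Homolog-count matrix aligned to `hits`.
#' @param params A [recovery_params()] object.
#' @return List with sorted integer vectors `recovered_content` and
#'   `recovered_score`.
#' @export
recover_hits <- function(clusters, hits, counts, params = recovery_params()) {
  stopifnot(inherits(params, "recovery_params"))
  rc <- integer(0)
  rs <- integer(0)
  reps <- vapply(clusters, `[[`, character(1), "representative")
  with_preserved_seed(params$seed, {
    for (ci in order(reps, method = "radix")) {
      cl <- clusters[[ci]]
      sgs <- subgroup_hits(hits, counts, members = cl$members)
      if (!length(sgs)) next
      if (params$by_content)
        rc <- c(rc, recover_by_content(sgs, cl$representative))
      if (params$by_score) {
        rep_hosted <- hits$cluster_id[hits$assembly_id == cl$representative]
        for (sg in sgs)
          rs <- c(rs, recover_by_score(sg, params$z_threshold,
                                       exclude = c(rep_hosted, rc, rs),
                                       one_sided = params$one_sided))
      }
    }
  })
  list(recovered_content = sort(unique(rc)), recovered_score = sort(unique(rs)))
}

#' Assemble the per-hit dereplication status report
#'
#' Assigns each session hit exactly one status: `unmapped` (scaffold not
#' resolved to an assembly), `representative` (hosted by a genome-cluster
#' representative), `recovered_content`, `recovered_score`, or `redundant`.
#' The retained set is representatives plus both recovery categories.
#'
#' @param session A `cblaster_session`.
#' @param mapping A `scaffold_assembly_map`.
#' @param clusters A `genome_clusters` object.
#' @param recovery List with `recovered_content` and `recovered_score`
#'   (cluster id vectors), e.g. from [recover_hits()].
#' @return A `derep_report`: data frame with columns `cluster_id`,
#'   `scaffold`, `assembly_id`, `representative`, `status`; the sorted
#'   retained cluster ids are in `attr(., "retained")`.
#' @export
assemble_report <- function(session, mapping, clusters,
                            recovery = list(recovered_content = integer(0),
                                            recovered_score = integer(0))) {
  stopifnot(inherits(session, "cblaster_session"),
            inherits(mapping, "scaffold_assembly_map"))
  h <- session$hits
  a_of <- stats::setNames(mapping$pairs$assembly_id, mapping$pairs$scaffold)
  assembly <- unname(a_of[h$scaffold])
  reps <- vapply(clusters, `[[`, character(1), "representative")
  rep_of <- unlist(lapply(clusters, function(cl)
    stats::setNames(rep(cl$representative, length(cl$members)), cl$members)))
  rcon <- as.integer(recovery$recovered_content)
  rsco <- as.integer(recovery$recovered_score)
  if (length(intersect(rcon, rsco)))
    derep_abort("hit recovered by both content and score",
                "derephits_integrity_error")
  rep_hosted <- h$cluster_id[!is.na(assembly) & assembly %in% reps]
  if (length(intersect(rep_hosted, c(rcon, rsco))))
    derep_abort("representative-hosted hit double-assigned to a recovery set",
                "derephits_integrity_error")
  status <- ifelse(is.na(assembly), "unmapped",
            ifelse(assembly %in% reps, "representative",
            ifelse(h$cluster_id %in% rcon, "recovered_content",
            ifelse(h$cluster_id %in% rsco, "recovered_score", "redundant"))))
  df <- data.frame(cluster_id = h$cluster_id, scaffold = h$scaffold,
                   assembly_id = assembly,
                   representative = unname(rep_of[assembly]),
                   status = status, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  retained <- sort(df$cluster_id[df$status %in%
    c("representative", "recovered_content", "recovered_score")])
  structure(df, class = c("derep_report", "data.frame"), retained = retained)
}

#' @export
print.derep_report <- function(x, ...) {
  cat(sprintf("dereplication report: %d hits, %d retained\n",
              nrow(x), length(attr(x, "retained"))))
  print(table(status = x$status))
  invisible(x)
}

#' @method summary derep_report
#' @export
summary.derep_report <- function(object, ...) {
  tab <- table(object$status)
  retained <- attr(object, "retained")
  structure(list(n_hits = nrow(object), n_retained = length(retained),
                 fold_reduction = nrow(object) / max(length(retained), 1L),
                 status_counts = tab),
            class = "summary.derep_report")
}

#' @export
print.summary.derep_report <- function(x, ...) {
  cat(sprintf("%d hits -> %d retained (%.2f-fold reduction)\n",
              x$n_hits, x$n_retained, x$fold_reduction))
  print(x$status_counts)
  invisible(x)
}
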