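#' Dereplication parameters
#'
#' @param ani_threshold Minimum percent ANI for two assemblies to be
#'   considered redundant (default 99, the conventional strain-level cutoff).
#' @param af_threshold Minimum aligned fraction percent, compared against
#'   the larger of the two directional containments so a contained draft
#'   genome still merges with its superset assembly (default 90).
#' @param seed Integer seed recorded alongside the parameters.
#' @return A `derep_params` object.
#' @export
derep_params <- function(ani_threshold = 99, af_threshold = 90, seed = 1L) {
  if (!is.numeric(ani_threshold) || ani_threshold <= 0 || ani_threshold > 100)
    derep_abort("ani_threshold must be in (0, 100]", "derephits_domain_error")
  if (!is.numeric(af_threshold) || af_threshold < 0 || af_threshold > 100)
    derep_abort("af_threshold must be in [0, 100]", "derephits_domain_error")
  structure(list(ani_threshold = ani_threshold, af_threshold = af_threshold,
                 seed = as.integer(seed)), class = "derep_params")
}

#' Build the redundancy graph over assemblies
#'
#' Undirected graph with an edge between two assemblies iff their ANI is at
#' or above `ani_threshold` and the larger directional aligned fraction is
#' at or above `af_threshold` (both comparisons inclusive). Every assembly
#' is a node even if isolated. The ANI results must cover every unordered
#' pair of assemblies.
#'
#' @param ani Data frame from [all_pairs()] (may have zero rows when only
#'   one assembly is present).
#' @param assembly_ids Node set; defaults to the ids appearing in `ani`.
#' @param params A [derep_params()] object.
#' @return A `redundancy_graph`: list with `nodes` (sorted character) and
#'   `adj` (named list of sorted neighbor vectors).
#' @export
build_redundancy_graph <- function(ani, assembly_ids = NULL,
                                   params = derep_params()) {
  stopifnot(inherits(params, "derep_params"))
  nodes <- sort(unique(c(as.character(assembly_ids),
                         as.character(ani$a), as.character(ani$b))))
  if (!length(nodes))
    derep_abort("no assemblies to build a graph over", "derephits_contract_error")
  if (length(nodes) >= 2L) {
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    have <- unique(pair_key(ani$a, ani$b))
    cmb <- utils::combn(nodes, 2L)
    need <- pair_key(cmb[1L, ], cmb[2L, ])
    miss <- setdiff(need, have)
    if (length(miss))
      derep_abort(sprintf("ANI results missing %d assembly pair(s), e.g. %s",
                          length(miss), gsub("\r", " vs ", miss[1L])),
                  "derephits_contract_error")
  }
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) adj[[nd]] <- character(0)
  if (nrow(ani)) {
    sel <- ani$ani >= params$ani_threshold &
      pmax(ani$af_a, ani$af_b) >= params$af_threshold
    for (j in which(sel)) {
      a <- ani$a[j]; b <- ani$b[j]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  structure(list(nodes = nodes, adj = adj), class = "redundancy_graph")
}

#' Greedy representative selection
#'
#' Repeatedly picks, among unassigned assemblies, the one with the highest
#' priority — most redundancy-graph neighbors among the unassigned
#' (connectedness), then largest N50, then largest total length, then
#' lexicographically smallest assembly id — makes it the representative of a
#' cluster consisting of itself plus all its unassigned neighbors, and
#' removes them from the pool. Cluster membership is the representative's
#' direct neighborhood, not a connected component, which yields smaller,
#' more cohesive clusters. Deterministic for a fixed input.
#'
#' @param graph A `redundancy_graph`.
#' @param stats Data frame with columns `assembly_id`, `n50`,
#'   `total_length`, covering every node.
#' @param params A [derep_params()] object (unused by the rule itself;
#'   accepted for interface symmetry).
#' @return A `genome_clusters` object: list of clusters, each a list with
#'   `representative` and sorted `members` (representative included).
#' @export
greedy_select <- function(graph, stats, params = derep_params()) {
  stopifnot(inherits(graph, "redundancy_graph"))
  nodes <- graph$nodes
  if (!all(nodes %in% stats$assembly_id))
    derep_abort("stats missing for some assemblies", "derephits_contract_error")
  n50 <- stats$n50[match(nodes, stats$assembly_id)]
  len <- stats$total_length[match(nodes, stats$assembly_id)]
  names(n50) <- names(len) <- nodes
  unassigned <- nodes
  clusters <- list()
  while (length(unassigned)) {
    deg <- vapply(unassigned,
                  function(x) sum(graph$adj[[x]] %in% unassigned),
                  integer(1))
    ord <- order(-deg, -n50[unassigned], -len[unassigned], unassigned,
                 method = "radix")
    rep_id <- unassigned[ord[1L]]
    members <- sort(c(rep_id, intersect(graph$adj[[rep_id]], unassigned)))
    clusters[[length(clusters) + 1L]] <-
      list(representative = rep_id, members = members)
    unassigned <- setdiff(unassigned, members)
  }
  structure(clusters, class = "genome_clusters")
}

#' @export
print.genome_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat(sprintf("genome clusters: %d cluster(s) over %d assemblies\n",
              length(x), sum(sizes)))
  for (cl in x)
    cat(sprintf("  %s: %d member(s)\n", cl$representative,
                length(cl$members)))
  invisible(x)
}

#' Write per-cluster sizes
#'
#' One line per genome cluster: representative assembly id, tab, member
#' count, in selection order.
#'
#' @param clusters A `genome_clusters` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_sizes <- function(clusters, path) {
  writeLines(vapply(clusters, function(cl)
    sprintf("%s\t%d", cl$representative, length(cl$members)),
    character(1)), path)
  invisible(path)
}
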