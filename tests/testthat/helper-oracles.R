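# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# N50: try every observed contig length as candidate L, keep the largest
# one whose >= L contigs cover at least half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  ok <- vapply(lengths, function(L) sum(lengths[lengths >= L]) >= total / 2,
               logical(1))
  max(lengths[ok])
}

# Homolog counts by a direct walk of the session JSON file.
oracle_homolog_counts <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  genes <- vapply(doc$queries, function(q) if (is.character(q)) q else q$name,
                  character(1))
  out <- list()
  for (org in doc$organisms) for (sc in org$scaffolds)
    for (cl in sc$clusters) {
      cnt <- setNames(integer(length(genes)), genes)
      for (sb in cl$subjects) for (h in sb$hits)
        cnt[[h$query]] <- cnt[[h$query]] + 1L
      out[[as.character(cl$number)]] <- cnt
    }
  out
}

# All canonical k-mers by brute-force enumeration over both strands.
oracle_canonical_kmers <- function(s, k) {
  s <- toupper(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(x) {
    ch <- rev(strsplit(x, "")[[1]])
    paste(comp[ch], collapse = "")
  }
  keys <- character(0)
  for (i in seq_len(max(nchar(s) - k + 1, 0))) {
    km <- substr(s, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    rc <- revcomp(km)
    keys <- c(keys, if (km <= rc) km else rc)
  }
  unique(keys)
}

# Count of valid k-mer windows by explicit sliding-window scan.
oracle_valid_windows <- function(s, k) {
  n <- 0L
  for (i in seq_len(max(nchar(s) - k + 1, 0))) {
    if (!grepl("[^ACGT]", substr(toupper(s), i, i + k - 1))) n <- n + 1L
  }
  n
}

# Step-by-step greedy representative selection on an explicit edge matrix,
# re-deriving degrees from scratch each round. Priority: degree among the
# unassigned, then N50, then total length, then smallest id (C collation).
oracle_greedy <- function(nodes, edges, n50, total_length) {
  # edges: 2-column character matrix (possibly 0 rows)
  neighbors <- function(x, pool) {
    nb <- c(edges[edges[, 1] == x, 2], edges[edges[, 2] == x, 1])
    intersect(unique(nb), pool)
  }
  pool <- nodes
  clusters <- list()
  while (length(pool)) {
    best <- NULL
    for (x in sort(pool, method = "radix")) {
      key <- c(length(neighbors(x, pool)), n50[[x]], total_length[[x]])
      if (is.null(best) ||
          key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2]) ||
          (key[1] == best$key[1] && key[2] == best$key[2] &&
           key[3] > best$key[3])) {
        best <- list(id = x, key = key)
      }
    }
    members <- sort(c(best$id, neighbors(best$id, pool)))
    clusters[[length(clusters) + 1]] <-
      list(representative = best$id, members = members)
    pool <- setdiff(pool, members)
  }
  clusters
}

# Random redundancy-graph instance over n nodes.
random_graph_case <- function(n, p = 0.4) {
  ids <- sort(sprintf("G%02d_%s", sample(99, n), sample(LETTERS, n,
                                                        replace = TRUE)))
  ids <- make.unique(ids, sep = "x")
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  n50 <- setNames(sample(c(5000L, 20000L, 50000L), n, replace = TRUE), ids)
  len <- setNames(sample(c(1e6, 2e6, 4e6), n, replace = TRUE), ids)
  list(ids = ids, edges = edges, n50 = n50, len = len)
}

# Convert an explicit edge list into the package's ANI-result contract:
# edges get ANI 99.9 / AF 95, non-edges ANI 80 / AF 10.
ani_from_edges <- function(ids, edges) {
  pairs <- t(combn(ids, 2))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- if (nrow(edges)) key(edges[, 1], edges[, 2]) else character(0)
  is_edge <- key(pairs[, 1], pairs[, 2]) %in% ek
  data.frame(a = pairs[, 1], b = pairs[, 2],
             ani = ifelse(is_edge, 99.9, 80),
             af_a = ifelse(is_edge, 95, 10),
             af_b = ifelse(is_edge, 95, 10),
             stringsAsFactors = FALSE)
}
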