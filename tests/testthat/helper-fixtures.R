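# Programmatic fixtures: session document builders and small FASTA writers.

cluster_doc <- function(number, queries_hit, start = 0, end = 1000,
                        score = 100) {
  subjects <- lapply(seq_along(queries_hit), function(i) {
    list(name = paste0("subj", number, "_", i),
         hits = list(list(query = queries_hit[i], bitscore = 50)))
  })
  list(number = number, start = start, end = end, score = score,
       subjects = subjects)
}

scaffold_doc <- function(accession, clusters) {
  list(accession = accession, clusters = clusters)
}

org_doc <- function(name, scaffolds) {
  list(name = name, scaffolds = scaffolds)
}

session_doc <- function(queries, organisms) {
  list(queries = as.list(queries), organisms = organisms)
}

write_doc <- function(doc, path = tempfile(fileext = ".json")) {
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  path
}

# Standard 3-cluster / 3-gene / 2-organism fixture used across files.
# Cluster 1 on S1 has homologs (2, 1, 0); cluster 2 on S2 (1, 1, 1);
# cluster 3 on S3 (0, 1, 0).
fixture_session_doc <- function() {
  session_doc(
    c("g1", "g2", "g3"),
    list(
      org_doc("Org one", list(
        scaffold_doc("S1.1", list(
          cluster_doc(1, c("g1", "g1", "g2")))))),
      org_doc("Org two", list(
        scaffold_doc("S2.1", list(
          cluster_doc(2, c("g1", "g2", "g3"), score = 120))),
        scaffold_doc("S3.1", list(
          cluster_doc(3, "g2", score = 80)))))))
}

write_fasta <- function(seqs, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_string <- function(s, p) {
  x <- strsplit(s, "")[[1]]
  idx <- which(runif(length(x)) < p)
  bases <- c("A", "C", "G", "T")
  for (i in idx) x[i] <- sample(setdiff(bases, x[i]), 1)
  paste(x, collapse = "")
}

expect_session_equal <- function(a, b) {
  expect_equal(a$query_genes, b$query_genes)
  oa <- order(a$hits$cluster_id)
  ob <- order(b$hits$cluster_id)
  ha <- a$hits[oa, ]
  hb <- b$hits[ob, ]
  rownames(ha) <- rownames(hb) <- NULL
  expect_equal(ha, hb)
  expect_equal(unname(a$homolog_counts[oa, , drop = FALSE]),
               unname(b$homolog_counts[ob, , drop = FALSE]))
}
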