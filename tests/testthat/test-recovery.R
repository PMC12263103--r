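mk_hits <- function(ids, asm, score = 100) {
  data.frame(cluster_id = as.integer(ids), assembly_id = asm,
             score = score, stringsAsFactors = FALSE)
}

test_that("subgrouping keys on the homolog-count vector", {
  hits <- mk_hits(1:5, c("A", "B", "C", "C", "D"))
  counts <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 1, 0), c(1, 1, 1), c(1, 1, 1))
  sgs <- subgroup_hits(hits, counts)
  expect_length(sgs, 3L)
  keys <- lapply(sgs, `[[`, "key")
  expect_true(list(c(1L, 1L, 1L)) %in% keys)
  # every hit in exactly one subgroup
  all_ids <- sort(unlist(lapply(sgs, function(s) s$hits$cluster_id)))
  expect_equal(all_ids, 1:5)
  # assembly C has two hits with different vectors -> two subgroups
  c_sub <- vapply(sgs, function(s) "C" %in% s$hits$assembly_id, logical(1))
  expect_equal(sum(c_sub), 2L)

  uniform <- subgroup_hits(mk_hits(1:3, c("A", "B", "C")),
                           rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_length(uniform, 1L)

  expect_error(subgroup_hits(mk_hits(1:2, c("A", "B")),
                             list(c(1L, 1L), c(1L, 1L, 0L))),
               class = "derephits_integrity_error")
})

test_that("content recovery skips the representative's subgroup", {
  hits <- mk_hits(1:3, c("A", "B", "C"))
  counts <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 1, 1))
  sgs <- subgroup_hits(hits, counts)

  # representative A shares the (1,1,1) subgroup: only C's subgroup recovers
  set.seed(1)
  expect_equal(recover_by_content(sgs, "A"), 3L)

  # one subgroup containing the representative's hit -> nothing to recover
  uni <- subgroup_hits(hits, rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  set.seed(1)
  expect_equal(recover_by_content(uni, "A"), integer(0))
})

test_that("a representative with no hits leaves every subgroup recoverable", {
  hits <- mk_hits(1:4, c("B", "B", "C", "D"))
  counts <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))
  sgs <- subgroup_hits(hits, counts)  # three subgroups, none hosted by A
  set.seed(7)
  rec <- recover_by_content(sgs, "A")
  # one recovery per subgroup: (1,0,0)->1, (0,1,0)-> 2 or 3, (0,0,1)->4
  expect_length(rec, 3L)
  expect_true(all(c(1L, 4L) %in% rec))
  expect_true(rec[2] %in% c(2L, 3L))
})

test_that("content recovery is seed-stable and seed-sensitive only in choice", {
  hits <- mk_hits(1:4, c("R", "B", "C", "D"))
  counts <- rbind(c(1, 1), c(2, 1), c(2, 1), c(2, 1))
  sgs <- subgroup_hits(hits, counts)
  pick <- function(seed) {
    set.seed(seed)
    recover_by_content(sgs, "R")
  }
  expect_equal(pick(5), pick(5))
  # any seed recovers exactly one hit from the non-representative subgroup
  for (s in 1:10) expect_length(pick(s), 1L)
})

test_that("selected assembly brings all its same-key hits along", {
  # assembly B hosts two hits with the same key in the same subgroup
  hits <- mk_hits(1:4, c("R", "B", "B", "R"))
  counts <- rbind(c(1, 1), c(2, 1), c(2, 1), c(1, 1))
  sgs <- subgroup_hits(hits, counts)
  set.seed(3)
  expect_equal(recover_by_content(sgs, "R"), c(2L, 3L))
})

test_that("score recovery applies the two-sigma population rule", {
  sg <- list(key = c(1L, 1L),
             hits = mk_hits(1:5, paste0("A", 1:5),
                            score = c(10, 10, 10, 10, 20)))
  # mu = 12, population sigma = 4, z(20) = 2.0 -> recovered at inclusive 2.0
  expect_equal(recover_by_score(sg, 2.0), 5L)
  expect_equal(recover_by_score(sg, 2.0001), integer(0))
  expect_equal(recover_by_score(sg, 2.0, exclude = 5L), integer(0))

  flat <- list(key = 1L, hits = mk_hits(1:4, paste0("A", 1:4), score = 7))
  expect_equal(recover_by_score(flat, 2.0), integer(0))

  single <- list(key = 1L, hits = mk_hits(9L, "A", score = 3))
  expect_equal(recover_by_score(single, 2.0), integer(0))

  bad <- list(key = 1L, hits = mk_hits(1:2, c("A", "B"), score = c(1, NaN)))
  expect_error(recover_by_score(bad, 2.0), class = "derephits_integrity_error")
})

test_that("one-sided recovery ignores low outliers", {
  sg <- list(key = 1L,
             hits = mk_hits(1:5, paste0("A", 1:5),
                            score = c(20, 20, 20, 20, 10)))
  # z(10) = -2: recovered two-sided, not one-sided
  expect_equal(recover_by_score(sg, 2.0), 5L)
  expect_equal(recover_by_score(sg, 2.0, one_sided = TRUE), integer(0))
})

test_that("recover_hits keeps the two recovery sets disjoint and seeded", {
  clusters <- structure(list(
    list(representative = "R", members = c("R", "B", "C", "D", "E", "F"))),
    class = "genome_clusters")
  hits <- mk_hits(1:6, c("R", "B", "C", "D", "E", "F"),
                  score = c(10, 10, 10, 10, 20, 10))
  counts <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(2, 1))
  out <- recover_hits(clusters, hits, counts,
                      recovery_params(seed = 42))
  # F differs in content; E is the score outlier within the (1,1) subgroup
  expect_equal(out$recovered_content, 6L)
  expect_equal(out$recovered_score, 5L)
  expect_length(intersect(out$recovered_content, out$recovered_score), 0L)
  expect_equal(out, recover_hits(clusters, hits, counts,
                                 recovery_params(seed = 42)))

  off <- recover_hits(clusters, hits, counts,
                      recovery_params(by_content = FALSE, by_score = FALSE))
  expect_equal(off, list(recovered_content = integer(0),
                         recovered_score = integer(0)))
})

test_that("recovery never fires in a uniform, equal-score genome cluster", {
  clusters <- structure(list(
    list(representative = "A", members = c("A", "B", "C"))),
    class = "genome_clusters")
  hits <- mk_hits(1:3, c("A", "B", "C"), score = 50)
  counts <- rbind(c(1, 1), c(1, 1), c(1, 1))
  out <- recover_hits(clusters, hits, counts, recovery_params(seed = 1))
  expect_equal(lengths(out), c(recovered_content = 0L, recovered_score = 0L))
})

test_that("assemble_report accounts for every hit with one status", {
  doc <- session_doc(c("g1"), list(
    org_doc("o", list(
      scaffold_doc("S1.1", list(cluster_doc(1, "g1"))),
      scaffold_doc("S2.1", list(cluster_doc(2, "g1"))),
      scaffold_doc("S3.1", list(cluster_doc(3, "g1"))),
      scaffold_doc("S4.1", list(cluster_doc(4, "g1"))),
      scaffold_doc("SX.1", list(cluster_doc(5, "g1")))))))
  s <- read_session(write_doc(doc))
  mapping <- structure(list(
    pairs = data.frame(scaffold = c("S1.1", "S2.1", "S3.1", "S4.1"),
                       assembly_id = c("A", "B", "C", "D"),
                       stringsAsFactors = FALSE),
    unmapped = "SX.1"), class = "scaffold_assembly_map")
  clusters <- structure(list(
    list(representative = "A", members = c("A", "B", "C", "D"))),
    class = "genome_clusters")
  rep_ <- assemble_report(s, mapping, clusters,
                          list(recovered_content = 2L,
                               recovered_score = 3L))
  expect_equal(rep_$status,
               c("representative", "recovered_content", "recovered_score",
                 "redundant", "unmapped"))
  expect_equal(attr(rep_, "retained"), c(1L, 2L, 3L))
  expect_equal(rep_$representative[1:4], rep("A", 4))

  # double assignment is an integrity error
  expect_error(assemble_report(s, mapping, clusters,
                               list(recovered_content = 2L,
                                    recovered_score = 2L)),
               class = "derephits_integrity_error")
  expect_error(assemble_report(s, mapping, clusters,
                               list(recovered_content = 1L,
                                    recovered_score = integer(0))),
               class = "derephits_integrity_error")

  # no recoveries: retained = representative-hosted hits only
  plain <- assemble_report(s, mapping, clusters)
  expect_equal(attr(plain, "retained"), 1L)

  # every genome its own representative: all mapped hits retained
  singletons <- structure(lapply(c("A", "B", "C", "D"), function(a)
    list(representative = a, members = a)), class = "genome_clusters")
  all_rep <- assemble_report(s, mapping, singletons)
  expect_equal(attr(all_rep, "retained"), 1:4)
  expect_true(all(all_rep$status[1:4] == "representative"))
})
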