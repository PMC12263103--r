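test_that("redundancy edges need both thresholds, inclusively", {
  ids <- c("A", "B", "C")
  ani <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                    ani = c(99.0, 98.999, 99.5),
                    af_a = c(90.0, 95, 80), af_b = c(85, 95, 89.9),
                    stringsAsFactors = FALSE)
  g <- build_redundancy_graph(ani, ids, derep_params(99, 90))
  # A-B: ani exactly at threshold, max AF exactly at threshold -> edge
  expect_equal(g$adj$A, "B")
  # A-C: ani just below threshold -> no edge despite high AF
  # B-C: ani fine but max(af) = 89.9 < 90 -> no edge
  expect_equal(g$adj$C, character(0))
})

test_that("graph covers isolated nodes and enforces pair completeness", {
  ids <- c("A", "B", "C")
  low <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                    ani = 80, af_a = 10, af_b = 10, stringsAsFactors = FALSE)
  g <- build_redundancy_graph(low, ids)
  expect_equal(g$nodes, ids)
  expect_true(all(lengths(g$adj) == 0))
  cl <- greedy_select(g, data.frame(assembly_id = ids, n50 = 1,
                                    total_length = 1))
  expect_length(cl, 3L)
  expect_equal(sort(vapply(cl, `[[`, character(1), "representative")), ids)

  expect_error(build_redundancy_graph(low[1:2, ], ids),
               class = "derephits_contract_error")
})

test_that("identical assemblies form a triangle collapsing to one cluster", {
  ids <- c("A", "B", "C")
  full <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                     ani = 100, af_a = 100, af_b = 100,
                     stringsAsFactors = FALSE)
  g <- build_redundancy_graph(full, ids)
  expect_equal(g$adj$A, c("B", "C"))
  cl <- greedy_select(g, data.frame(assembly_id = ids, n50 = c(1, 5, 2),
                                    total_length = 1))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, ids)
  # equal degrees: N50 breaks the tie
  expect_equal(cl[[1]]$representative, "B")
})

test_that("two connected nodes: larger N50 becomes representative", {
  ani <- data.frame(a = "A", b = "B", ani = 99.9, af_a = 95, af_b = 95,
                    stringsAsFactors = FALSE)
  g <- build_redundancy_graph(ani, c("A", "B"))
  cl <- greedy_select(g, data.frame(assembly_id = c("A", "B"),
                                    n50 = c(5000, 20000),
                                    total_length = c(1e6, 1e6)))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$representative, "B")
})

test_that("greedy selection equals the step-by-step oracle on random graphs", {
  set.seed(9)
  for (rep in 1:200) {
    case <- random_graph_case(sample(2:8, 1))
    ani <- ani_from_edges(case$ids, case$edges)
    g <- build_redundancy_graph(ani, case$ids)
    got <- greedy_select(g, data.frame(assembly_id = case$ids,
                                       n50 = unname(case$n50),
                                       total_length = unname(case$len)))
    want <- oracle_greedy(case$ids, case$edges, case$n50, case$len)
    expect_equal(lapply(got, unclass), want, info = paste("case", rep))
  }
})

test_that("clusters partition the assemblies", {
  set.seed(10)
  for (rep in 1:50) {
    case <- random_graph_case(sample(3:8, 1))
    g <- build_redundancy_graph(ani_from_edges(case$ids, case$edges),
                                case$ids)
    cl <- greedy_select(g, data.frame(assembly_id = case$ids,
                                      n50 = unname(case$n50),
                                      total_length = unname(case$len)))
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_equal(sort(members), case$ids)          # conservation
    expect_equal(anyDuplicated(members), 0L)       # disjoint
    for (c1 in cl) expect_true(c1$representative %in% c1$members)
  }
})

test_that("re-dereplicating the representatives yields singletons", {
  set.seed(11)
  for (rep in 1:30) {
    case <- random_graph_case(sample(3:8, 1))
    ani <- ani_from_edges(case$ids, case$edges)
    stats <- data.frame(assembly_id = case$ids, n50 = unname(case$n50),
                        total_length = unname(case$len))
    cl <- greedy_select(build_redundancy_graph(ani, case$ids), stats)
    reps <- vapply(cl, `[[`, character(1), "representative")
    ani2 <- ani[ani$a %in% reps & ani$b %in% reps, , drop = FALSE]
    cl2 <- greedy_select(build_redundancy_graph(ani2, reps),
                         stats[stats$assembly_id %in% reps, ])
    expect_true(all(vapply(cl2, function(x) length(x$members), integer(1)) == 1L))
  }
})

test_that("raising the ANI threshold never decreases the cluster count", {
  set.seed(12)
  ids <- sprintf("A%02d", 1:10)
  pairs <- t(combn(ids, 2))
  ani <- data.frame(a = pairs[, 1], b = pairs[, 2],
                    ani = runif(nrow(pairs), 95, 100),
                    af_a = 95, af_b = 95, stringsAsFactors = FALSE)
  stats <- data.frame(assembly_id = ids, n50 = sample(1e4, 10),
                      total_length = 1e6)
  counts <- vapply(c(95, 96, 97, 98, 99, 99.5, 100), function(th) {
    length(greedy_select(build_redundancy_graph(ani, ids,
                                                derep_params(th, 90)),
                         stats))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("k exact duplicates collapse into one cluster of size k", {
  set.seed(13)
  seq <- random_seq(5000)
  sk <- lapply(1:5, function(i) sketch(seq, k = 16, id = paste0("D", i)))
  ani <- all_pairs(sk)
  g <- build_redundancy_graph(ani, paste0("D", 1:5))
  cl <- greedy_select(g, data.frame(assembly_id = paste0("D", 1:5),
                                    n50 = 5000, total_length = 5000))
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 5L)
})
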