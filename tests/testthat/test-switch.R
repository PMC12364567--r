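test_that("pattern classification matches the printed type definitions", {
  net <- path_network()  # A - B - C - D
  expect_identical(classify_pattern(c("A", "B", "C", "D"), net), "A")
  expect_identical(classify_pattern("B", net), "U")
  expect_identical(classify_pattern(c("B", "C"), net), "B")
  expect_identical(classify_pattern(c("A", "C"), net), "N2")
  expect_identical(classify_pattern(c("A", "B", "D"), net), "PARTIAL")
  expect_identical(pattern_edges(c("A", "B", "D"), net), "A|B")
  expect_identical(classify_pattern(character(), net), "ABSENT")
  expect_error(classify_pattern("X", net), "unknown compartment")
})

test_that("classification equals the enumeration oracle on all patterns of the path graph", {
  net <- path_network()
  adj <- matrix(FALSE, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  adj[cbind(1:3, 2:4)] <- TRUE; adj <- adj | t(adj)
  for (mask in 0:15) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:3)) != 0L)
    expect_identical(classify_pattern(LETTERS[1:4][idx], net),
                     oracle_classify(idx, adj), info = mask)
  }
})

test_that("classification agrees with the oracle on random connected graphs", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    adj <- random_connected_graph(n)
    net <- adj_to_network(adj)
    for (mask in 0:(2^n - 1)) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      expect_identical(classify_pattern(net$nodes[idx], net),
                       oracle_classify(idx, adj))
    }
  }
})

# a small deterministic presence fixture built directly from a truth table
switch_fixture <- function(dropout = 0, n = 8, seed = 2) {
  net <- star_network()
  truth <- plant_traffic_truth(net, c(A = 10, U = 10, B = 10, N2 = 10),
                               phenotypes = c("F", "M"), seed = seed)
  sim <- generate_traffic_dataset(
    traffic_sim_spec(net, truth, n_per_group = n, dropout = dropout,
                     seed = seed))
  c(sim, list(network = net))
}

test_that("planted labels are recovered exactly with no dropout", {
  fx <- switch_fixture()
  pr <- call_presence(fx$table, fx$design)
  res <- switch_analysis(pr, fx$network)
  merged <- merge(res$traffic, fx$truth, by = c("variable", "phenotype"))
  expect_equal(nrow(merged), nrow(res$traffic))
  expect_identical(merged$label, merged$planted_label)
  expect_identical(merged$compartments, merged$planted_compartments)
  # exact count table: 10 per type per phenotype
  counts <- traffic_counts(res)
  for (lab in c("A", "U", "B", "N2"))
    expect_equal(counts$n[counts$label == lab], c(10L, 10L))
})

test_that("localized sets respect their defining invariants", {
  fx <- switch_fixture()
  pr <- call_presence(fx$table, fx$design)
  res <- switch_analysis(pr, fx$network, include_a_in_edges = TRUE)
  for (p in res$phenotypes) {
    # every per-edge set member is present in both endpoints
    for (e in edge_labels(fx$network)) {
      ends <- strsplit(e, "|", fixed = TRUE)[[1]]
      for (v in res$edge_sets[[p]][[e]]) {
        pat <- presence_pattern(pr, p, v)
        expect_true(all(ends %in% pat))
      }
    }
    # with A-enrollment on, A-set variables appear in every edge set
    for (v in res$a_set[[p]])
      for (e in edge_labels(fx$network))
        expect_true(v %in% res$edge_sets[[p]][[e]])
  }
  # conservation: labels partition the non-empty patterns
  tr <- res$traffic
  for (p in res$phenotypes) {
    non_absent <- sum(tr$phenotype == p & tr$label != "ABSENT")
    by_type <- table(tr$label[tr$phenotype == p])
    expect_equal(sum(by_type[setdiff(names(by_type), "ABSENT")]), non_absent)
  }
})

test_that("A-type variables stay out of edge sets by default", {
  fx <- switch_fixture()
  pr <- call_presence(fx$table, fx$design)
  res <- switch_analysis(pr, fx$network)
  for (p in res$phenotypes)
    for (e in edge_labels(fx$network))
      expect_length(intersect(res$a_set[[p]], res$edge_sets[[p]][[e]]), 0)
})

test_that("a variable present only for one phenotype is ABSENT for the other", {
  net <- star_network()
  truth <- plant_traffic_truth(net, c(U = 1), phenotypes = c("F", "M"),
                               seed = 5)
  truth$planted_compartments[truth$phenotype == "M"] <- "vastus muscle"
  truth$planted_compartments[truth$phenotype == "F"] <- ""  # planted nowhere
  sim <- generate_traffic_dataset(
    traffic_sim_spec(net, truth, n_per_group = 4, seed = 5))
  pr <- call_presence(sim$table, sim$design)
  expect_warning(res <- switch_analysis(pr, net), "no present variables")
  v <- truth$variable[1]
  tr <- res$traffic
  expect_identical(tr$label[tr$phenotype == "M" & tr$variable == v], "U")
  expect_identical(tr$compartments[tr$phenotype == "M" & tr$variable == v],
                   "vastus muscle")
  expect_identical(tr$label[tr$phenotype == "F" & tr$variable == v], "ABSENT")
})

test_that("phenotype comparison is symmetric and consistent with set algebra", {
  fx <- switch_fixture(dropout = 0.3, seed = 9)
  pr <- call_presence(fx$table, fx$design)
  res <- switch_analysis(pr, fx$network)
  cmp12 <- compare_phenotypes(res, c("F", "M"))
  cmp21 <- compare_phenotypes(res, c("M", "F"))
  expect_equal(cmp12$table$n_shared, cmp21$table$n_shared)
  expect_equal(cmp12$table$n_only1, cmp21$table$n_only2)
  expect_equal(cmp12$table$n_only2, cmp21$table$n_only1)
  expect_equal(cmp12$table$jaccard, cmp21$table$jaccard)
  expect_equal(cmp12$table$p_value, cmp21$table$p_value)
  # three membership categories partition each union
  for (key in names(cmp12$sets)) {
    s <- cmp12$sets[[key]]
    expect_length(intersect(s$shared, s$only1), 0)
    expect_length(intersect(s$shared, s$only2), 0)
    expect_length(intersect(s$only1, s$only2), 0)
  }
})

test_that("identical traffic gives J = 1 everywhere; disjoint U-sets give J = 0", {
  fx <- switch_fixture()
  pr <- call_presence(fx$table, fx$design)
  res <- switch_analysis(pr, fx$network)
  # no dropout and shared planting => phenotypes identical
  cmp <- compare_phenotypes(res)
  nonempty <- cmp$table$n_shared + cmp$table$n_only1 + cmp$table$n_only2 > 0
  expect_true(all(cmp$table$jaccard[nonempty] == 1))
  expect_true(all(cmp$table$n_only1 == 0 & cmp$table$n_only2 == 0))
})

test_that("DG variables can be grouped with TG for the count table", {
  net <- path_network()
  vals <- matrix(1, 2, 2, dimnames = list(NULL, c("DG(36:2)", "TG(50:1)")))
  ids <- c("s1", "s2")
  tab <- toy_table(vals, ids)
  des <- study_design(ids, rep("F", 2), rep("A", 2))
  pr <- call_presence(tab, des)
  res <- switch_analysis(pr, net, group_dg_with_tg = TRUE)
  expect_true(all(res$traffic$class == "TG"))
  res2 <- switch_analysis(pr, net)
  expect_setequal(res2$traffic$class, c("DG", "TG"))
})
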