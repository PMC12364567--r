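test_that("abundance CSV round trip preserves values and canonicalises names", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   "PC(34:2)" = c(1, 0, 2.5),
                   "TG(48:1)" = c(0.1, NA, 3),
                   check.names = FALSE)
  path <- write_toy_csv(df)
  tab <- read_abundance_table(path)
  expect_identical(tab$samples, c("s1", "s2", "s3"))
  expect_identical(colnames(tab$values), c("PC(34:2)", "TG(48:1)"))
  expect_equal(tab$values[, "PC(34:2)"], c(s1 = 1, s2 = 0, s3 = 2.5))
  expect_true(is.na(tab$values["s2", "TG(48:1)"]))

  out <- tempfile(fileext = ".csv")
  write_abundance_table(tab, out)
  tab2 <- read_abundance_table(out)
  expect_equal(tab2$values, tab$values)
})

test_that("tab-delimited input is sniffed", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tPC(34:2)", "s1\t1", "s2\t2"), path)
  tab <- read_abundance_table(path)
  expect_equal(unname(tab$values[, 1]), c(1, 2))
})

test_that("negative intensities and duplicate ids are hard errors naming offenders", {
  df <- data.frame(sample_id = c("s1", "s2"), "PC(34:2)" = c(1, -2),
                   check.names = FALSE)
  expect_error(read_abundance_table(write_toy_csv(df)), "s2.*PC\\(34:2\\)")
  expect_error(abundance_table(c("s1", "s1"), matrix(1:2, 2, 1,
                  dimnames = list(NULL, "PC(34:2)"))), "duplicate sample ids")
})

test_that("unparseable headers are kept as opaque variables and reported", {
  df <- data.frame(sample_id = c("s1", "s2"),
                   "PC(34:2)" = c(1, 2), "weird" = c(3, 4),
                   check.names = FALSE)
  expect_warning(tab <- read_abundance_table(write_toy_csv(df)), "weird")
  expect_identical(tab$unparseable, "weird")
  expect_equal(ncol(tab$values), 2)
})

test_that("network JSON reading validates structure", {
  path <- tempfile(fileext = ".json")
  writeLines('{"nodes": ["serum", "liver"], "edges": [["serum", "liver"]]}',
             path)
  net <- read_network(path)
  expect_identical(sort(net$nodes), c("liver", "serum"))
  expect_true(has_edge(net, "serum", "liver"))
  expect_true(has_edge(net, "liver", "serum"))

  writeLines('{"nodes": ["serum"], "edges": [["serum", "serum"]]}', path)
  expect_error(read_network(path), "self-loop")
  writeLines('{"nodes": ["a", "b"], "edges": [["a", "b"], ["b", "a"]]}', path)
  expect_error(read_network(path), "duplicated edge")
  writeLines('{"nodes": ["a", "b"], "edges": [["a", "c"]]}', path)
  expect_error(read_network(path), "unknown node")
})

test_that("network JSON round trips through write_network", {
  net <- path_network(c("A", "B", "C"))
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- read_network(path)
  expect_identical(net2$nodes, net$nodes)
  expect_identical(net2$edges, net$edges)
})

test_that("default network is a 9-compartment serum hub", {
  net <- default_compartment_network()
  expect_length(net$nodes, 9)
  expect_equal(nrow(net$edges), 8)
  expect_true(all(apply(net$edges, 1, function(e) "serum" %in% e)))
  expect_true(has_edge(net, "serum", "vastus muscle"))
  expect_false(has_edge(net, "liver", "brain"))
})

test_that("validate_design cross-references samples, compartments and counts", {
  vals <- matrix(runif(8), 8, 1, dimnames = list(NULL, "PC(34:2)"))
  tab <- toy_table(vals)
  des <- study_design(paste0("s", 1:8),
                      rep(c("F", "M"), each = 4),
                      rep("liver", 8))
  net <- compartment_network(c("serum", "liver"), cbind("serum", "liver"))
  rep <- validate_design(tab, des, net)
  expect_identical(sort(rep$counts$n), c(4L, 4L))

  des_bad <- study_design("s99", "F", "liver")
  expect_error(validate_design(tab, des_bad, net), "s99")
  des_lung <- study_design("s1", "F", "lung")
  expect_error(validate_design(tab, des_lung, net), "lung")
})

test_that("design CSV reader requires core columns and keeps covariates", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_id = "s1", phenotype = "F",
                              compartment = "liver", bmi = 24.2), path,
                   row.names = FALSE)
  des <- read_design(path)
  expect_identical(des$bmi, 24.2)
  utils::write.csv(data.frame(sample_id = "s1", group = "F"), path,
                   row.names = FALSE)
  expect_error(read_design(path), "phenotype")
})

test_that("bundled synthetic fixtures load and cross-validate", {
  net <- read_network(system.file("extdata", "synthetic_mouse_network.json",
                                  package = "lipidtraffic"))
  expect_length(net$nodes, 9)
  tab <- read_abundance_table(system.file("extdata",
                                          "synthetic_abundance.csv",
                                          package = "lipidtraffic"))
  des <- read_design(system.file("extdata", "synthetic_design.csv",
                                 package = "lipidtraffic"))
  small_net <- compartment_network(unique(des$compartment),
                                   rbind(c("serum", "liver"),
                                         c("serum", "vastus muscle")))
  rep <- validate_design(tab, des, small_net)
  expect_true(all(rep$counts$n == 4))
  pr <- call_presence(tab, des)
  expect_s3_class(switch_analysis(pr, small_net), "traffic_result")
})
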