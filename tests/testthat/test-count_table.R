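test_that("count tables round-trip through TSV bit-identically", {
  tab <- tiny_table()
  expect_equal(dim(count_matrix(tab)), c(3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  expect_equal(read_count_table(path), tab)
})

test_that("count table validation rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tB", "t1\t1\t2", "t1\t3\t4"), path)
  expect_error(suppressWarnings(read_count_table(path)), class = "ncmtools_format_error")
  writeLines(c("id\tA\tB", "t1\t1\t2", "t2\t-1\t4"), path)
  expect_error(suppressWarnings(read_count_table(path)), class = "ncmtools_validation_error")
  writeLines(c("id\tA\tB", "t1\t1.5\t2", "t2\t1\t4"), path)
  expect_error(suppressWarnings(read_count_table(path)), class = "ncmtools_validation_error")
})

test_that("BIOM tables read back equal to their source matrix", {
  mat <- count_matrix(random_table(seed = 7))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(mat), path)
  got <- read_count_table(path, format = "biom")
  expect_equal(count_matrix(got), mat)
})

test_that("rarefaction conserves depth exactly and respects sample support", {
  # depth equal to every column total is the exhaustive subsample
  eq <- count_table(matrix(c(5, 3, 1, 2, 0, 7), nrow = 3,
                           dimnames = list(c("t1", "t2", "t3"), c("A", "B"))))
  expect_equal(rarefy(eq, depth = 9, seed = 1), eq)
  # tiny_table column sums are 8 (A) and 9 (B)
  full <- rarefy(tiny_table(), depth = 7, seed = 1)
  expect_equal(unname(colSums(count_matrix(full))), c(7, 7))

  one <- count_table(matrix(c(10, 0, 0), ncol = 1,
                            dimnames = list(c("a", "b", "c"), "S1")))
  expect_equal(unname(count_matrix(rarefy(one, 5, seed = 3))[, 1]), c(5, 0, 0))

  # never invents counts for absent taxa; columns below depth dropped with warning
  expect_warning(r <- rarefy(tiny_table(), depth = 9, seed = 2), "dropping")
  expect_equal(colnames(count_matrix(r)), "B")
  expect_error(rarefy(tiny_table(), depth = 1000), class = "ncmtools_empty_table_error")

  mat <- count_matrix(random_table(seed = 5))
  rar <- count_matrix(rarefy(random_table(seed = 5), depth = 40, seed = 9))
  expect_true(all(rar[mat == 0] == 0))
  expect_true(all(rar <= mat))
})

test_that("rarefaction matches the hypergeometric expectation", {
  tab <- count_table(matrix(c(6, 4), ncol = 1, dimnames = list(c("a", "b"), "S1")))
  firsts <- vapply(1:4000, function(s) count_matrix(rarefy(tab, 5, seed = s))[1, 1],
                   numeric(1))
  expect_lt(abs(mean(firsts) - 3), 0.05)  # E = depth * 6/10
})

test_that("rarefaction is reproducible under a fixed seed", {
  tab <- random_table(seed = 11)
  expect_identical(rarefy(tab, 40, seed = 1), rarefy(tab, 40, seed = 1))
})

test_that("rank aggregation is additive and conserves column sums", {
  tax <- parse_lineage(c("t1", "t2", "t3"),
                       c("d__X;p__Alpha", "d__X;p__Alpha", "d__X;p__Beta"))
  agg <- aggregate_by_rank(tiny_table(), tax, "phylum")
  m <- count_matrix(agg)
  expect_equal(unname(m["Alpha", ]), c(5 + 3, 2 + 0))
  expect_equal(colSums(m), colSums(count_matrix(tiny_table())))

  # all unmapped -> single Unassigned row with the column sums
  none <- parse_lineage("zzz", "d__X;p__Y")
  agg2 <- aggregate_by_rank(tiny_table(), none, "phylum")
  expect_equal(rownames(count_matrix(agg2)), "Unassigned")
  expect_equal(unname(count_matrix(agg2)[1, ]), unname(colSums(count_matrix(tiny_table()))))

  # conservation on a random fixture, against direct summation
  tab <- random_table(seed = 21)
  ids <- tab$taxon_id
  tax3 <- parse_lineage(ids, paste0("d__D;p__P", rep(1:3, length.out = length(ids))))
  agg3 <- count_matrix(aggregate_by_rank(tab, tax3, "phylum"))
  expect_equal(colSums(agg3), colSums(count_matrix(tab)))
  direct <- rowsum(count_matrix(tab), paste0("P", rep(1:3, length.out = length(ids))))
  expect_equal(unname(agg3[order(rownames(agg3)), ]), unname(direct[order(rownames(direct)), ]))

  expect_error(aggregate_by_rank(tab, tax3, "tribe"), class = "ncmtools_parameter_error")
})

test_that("lineages parse by prefix and positionally", {
  got <- parse_lineage(c("a", "b"), c("d__Archaea;p__Thaumarchaeota;c__;o__Nitrososphaerales",
                                      "Bacteria;Proteobacteria"))
  expect_equal(got$domain, c("Archaea", "Bacteria"))
  expect_equal(got$phylum, c("Thaumarchaeota", "Proteobacteria"))
  expect_equal(got$order, c("Nitrososphaerales", NA))
})

test_that("relative abundance normalises every sample to one", {
  two <- count_table(matrix(c(2, 2), ncol = 1, dimnames = list(c("a", "b"), "S1")))
  expect_equal(relative_abundance(two)$S1, c(0.5, 0.5))
  solo <- count_table(matrix(c(1, 0, 0), ncol = 1, dimnames = list(letters[1:3], "S1")))
  expect_equal(relative_abundance(solo)$S1, c(1, 0, 0))

  tab <- random_table(seed = 31)
  rel <- as.matrix(relative_abundance(tab)[, -1])
  byhand <- apply(count_matrix(tab), 2, function(x) x / sum(x))
  expect_lt(max(abs(rel - byhand)), 1e-12)
  expect_equal(unname(colSums(rel)), rep(1, ncol(rel)))

  zero <- count_table(matrix(c(1, 0), ncol = 2, dimnames = list("a", c("S1", "S2"))))
  expect_error(relative_abundance(zero), "S2", class = "ncmtools_division_error")
})

test_that("metadata reader enforces schema and ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsite\tlayer\treplicate\tpH\tWC",
               "S1\tBYH\t0-20 cm\t1\t7.1\t45.2",
               "S2\tZYW\t0-20 cm\t1\t6.4\t80.0"), path)
  md <- read_sample_metadata(path)
  expect_equal(md$site, c("BYH", "ZYW"))
  writeLines(c("sample_id\tsite\tlayer\treplicate\tWC", "S1\tBYH\t0-20 cm\t1\t120"), path)
  expect_error(read_sample_metadata(path), class = "ncmtools_validation_error")
  writeLines(c("sample_id\tsite", "S1\tBYH"), path)
  expect_error(read_sample_metadata(path), class = "ncmtools_format_error")
})
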