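test_that("TSV round trip preserves the table and sorts samples by day", {
  tab <- tiny_table()
  expect_equal(dim(tab$values), c(3L, 4L))
  p <- tempfile(fileext = ".tsv")
  write_otu_table(tab, p)
  back <- read_otu_table(p)
  expect_equal(back$values, tab$values)
  expect_equal(back$sample_days, tab$sample_days)
  expect_equal(back$taxon_ids, tab$taxon_ids)

  # out-of-day-order columns are reordered ascending
  shuffled <- otu_table(tab$values[, c(3, 1, 4, 2)], tab$taxon_ids,
                        tab$sample_days[c(3, 1, 4, 2)],
                        tab$sample_ids[c(3, 1, 4, 2)])
  expect_equal(shuffled$sample_days, tab$sample_days)
  expect_equal(shuffled$values, tab$values)
})

test_that("validation names the offending entry", {
  expect_error(otu_table(matrix(1, 2, 2), c("a", "a"), 1:2), "duplicated taxon id: a")
  expect_error(otu_table(matrix(c(1, -1, 2, 3), 2, 2), c("a", "b"), 1:2),
               "negative abundance")
  expect_error(otu_table(matrix(1, 2, 2), c("a", "b"), c(3, 3)), "duplicate sample day")
  p <- tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1", "#day\t1", "otuA\tx"), p)
  expect_error(read_otu_table(p), "non-numeric cell at taxon 'otuA'")
})

test_that("rarefaction is exact-depth, deterministic, hypergeometric in mean", {
  tab <- otu_table(matrix(c(10000L, 10000L), 2, 1), c("a", "b"), 1)
  means <- vapply(1:300, function(s) rarefy(tab, 10000, seed = s)$values[1, 1],
                  numeric(1))
  # hypergeometric: mean 5000, var = 10000 * .25 * (10000/19999) ~ 1250
  expect_lt(abs(mean(means) - 5000), 3 * sqrt(1250 / 300) + 0.7)

  big <- tiny_table()
  expect_identical(rarefy(big, 5, seed = 7)$values, rarefy(big, 5, seed = 7)$values)
  r <- rarefy(big, 5, seed = 7)
  expect_true(all(colSums(r$values) == 5))
  # depth equal to column sum returns the column unchanged
  one <- otu_table(matrix(c(3L, 4L), 2, 1), c("a", "b"), 1)
  expect_equal(rarefy(one, 7, seed = 1)$values[, 1], c(a = 3, b = 4))
  expect_error(rarefy(big, 0, seed = 1), "positive integer")
  expect_warning(rarefy(big, 9, seed = 1), "dropping")
})

test_that("relative abundance normalizes, is idempotent, conserves mass", {
  tab <- otu_table(matrix(c(2, 3, 5), 3, 1), c("a", "b", "c"), 1)
  fr <- relative_abundance(tab)
  expect_equal(fr$values[, 1], c(a = 0.2, b = 0.3, c = 0.5))
  expect_identical(relative_abundance(fr), fr)
  set.seed(4)
  rnd <- otu_table(matrix(rpois(60, 20) + 1, 6, 10), letters[1:6], 1:10)
  expect_true(all(abs(colSums(relative_abundance(rnd)$values) - 1) < 1e-12))
})

test_that("top_taxa ranks by mean relative abundance with lexicographic ties", {
  vals <- rbind(c(10, 10), c(40, 40), c(25, 25), c(25, 25))
  tab <- otu_table(vals, c("d", "a", "c", "b"), 1:2)
  expect_equal(top_taxa(tab, 2)$taxon_ids, c("a", "b"))
  expect_equal(sort(top_taxa(tab, 4)$taxon_ids), sort(tab$taxon_ids))
  expect_error(top_taxa(tab, 0), "positive integer")
})

test_that("alpha diversity matches closed forms", {
  uni <- otu_table(matrix(1, 50, 1), sprintf("t%02d", 1:50), 1)
  expect_equal(alpha_diversity(uni)$n_eff, 50)
  single <- otu_table(matrix(c(7, 0), 2, 1), c("a", "b"), 1)
  expect_equal(alpha_diversity(single)$shannon, 0)
  expect_equal(alpha_diversity(single)$n_eff, 1)
  half <- otu_table(matrix(c(0.5, 0.5), 2, 1), c("a", "b"), 1, units = "fractions")
  expect_equal(alpha_diversity(half)$n_eff, 2)
})

test_that("Jensen-Shannon divergence matches its definition", {
  same <- otu_table(matrix(c(.5, .5, .5, .5), 2, 2), c("a", "b"), 1:2,
                    units = "fractions")
  expect_equal(jensen_shannon(same)[1, 2], 0)
  disjoint <- otu_table(matrix(c(1, 0, 0, 1), 2, 2), c("a", "b"), 1:2,
                        units = "fractions")
  expect_equal(jensen_shannon(disjoint)[1, 2], log(2))
  set.seed(9)
  v <- matrix(rgamma(20, 1), 10, 2)
  v <- sweep(v, 2, colSums(v), "/")
  tab <- otu_table(v, letters[1:10], 1:2, units = "fractions")
  expect_equal(jensen_shannon(tab)[1, 2], jsd_reference(v[, 1], v[, 2]),
               tolerance = 1e-12)
})

test_that("shared taxa reports intersections and symmetric counts", {
  t1 <- otu_table(matrix(1, 3, 2), c("A", "B", "C"), 1:2)
  t2 <- otu_table(matrix(1, 3, 2), c("B", "C", "D"), 1:2)
  rep_ <- shared_taxa(list(x = t1, y = t2))
  expect_equal(rep_$pairwise_counts["x", "y"], 2L)
  expect_equal(rep_$full_intersection, c("B", "C"))
  expect_equal(rep_$pairwise_counts, t(rep_$pairwise_counts))
  expect_true(all(rep_$pairwise_counts["x", "y"] <=
                    diag(rep_$pairwise_counts)))
  same <- shared_taxa(list(a = t1, b = t1))
  expect_equal(same$pairwise_counts["a", "b"], diag(same$pairwise_counts)[["a"]])
  expect_equal(unname(rep_$abundance_fraction["x"]), 2 / 3)
  expect_error(shared_taxa(list()), "at least two")
})

test_that("n_eff is stable across rarefaction depth for abundant-taxon tables", {
  set.seed(21)
  base <- matrix(rmultinom(40, 40000, prob = c(30, 20, 15, 10, 8, 7, 5, 3, 1, 1)),
                 nrow = 10)
  tab <- otu_table(base, sprintf("t%02d", 1:10), 1:40)
  d10 <- mean(alpha_diversity(rarefy(tab, 10000, seed = 1))$n_eff)
  d5 <- mean(alpha_diversity(rarefy(tab, 5000, seed = 1))$n_eff)
  expect_lt(abs(d10 - d5) / d10, 0.05)
})

test_that("BIOM-JSON tables are read with sidecar day metadata", {
  bj <- tempfile(fileext = ".biom")
  writeLines(paste0(
    '{"id":null,"format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org","type":"OTU table",',
    '"generated_by":"test","date":"2026-01-01T00:00:00",',
    '"matrix_type":"dense","matrix_element_type":"int","shape":[2,3],',
    '"rows":[{"id":"otuA","metadata":null},{"id":"otuB","metadata":null}],',
    '"columns":[{"id":"s1","metadata":null},{"id":"s2","metadata":null},',
    '{"id":"s3","metadata":null}],',
    '"data":[[1,2,3],[4,5,6]]}'), bj)
  md <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,day", "s1,3", "s2,1", "s3,2"), md)
  tab <- read_otu_table(bj, dialect = "biom-json", metadata = md)
  expect_equal(tab$sample_days, c(1, 2, 3))       # sorted by day
  expect_equal(tab$values["otuA", ], c(s2 = 2, s3 = 3, s1 = 1))
})
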