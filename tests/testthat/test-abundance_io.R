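test_that("read_abundance parses intensities, blanks, and annotations", {
  path <- write_abundance_fixture(c(
    "gene_id\tgene_name\ts1\ts2",
    "g1\talkB\t100\t200",
    "g2\tnifH\t\t50",
    "g3\tpmoA\t10\t0"))
  tbl <- read_abundance(path)
  expect_s3_class(tbl, "abundance_table")
  expect_equal(tbl$gene_ids, c("g1", "g2", "g3"))
  expect_equal(tbl$sample_ids, c("s1", "s2"))
  expect_equal(tbl$annotations$gene_name, c("alkB", "nifH", "pmoA"))
  # one blank and one zero are both undetected
  expect_equal(sum(!tbl$detected), 2)
  expect_false(tbl$detected["g2", "s1"])
  expect_false(tbl$detected["g3", "s2"])
  expect_equal(tbl$values["g1", "s2"], 200)
})

test_that("read_abundance rejects malformed input with informative errors", {
  dup <- write_abundance_fixture(c("gene_id\ts1\ts1", "g1\t1\t2"))
  expect_error(read_abundance(dup), "s1")
  dupg <- write_abundance_fixture(c("gene_id\ts1", "g1\t1", "g1\t2"))
  expect_error(read_abundance(dupg), "g1")
  bad <- write_abundance_fixture(c("gene_id\ts1\ts2",
                                   "g1\t1\t2", "g2\tfoo\t3"))
  expect_error(read_abundance(bad), "row 2.*g2.*s1", perl = TRUE)
})

test_that("write then read round-trips values, mask, and annotations", {
  set.seed(11)
  vals <- matrix(round(10^runif(40, 1, 4), 6), 10, 4)
  vals[sample(40, 6)] <- 0
  tbl <- abundance_table(vals, gene_ids = sprintf("g%02d", 1:10),
                         sample_ids = paste0("s", 1:4),
                         annotations = data.frame(
                           gene_name = sample(letters, 10)))
  path <- tempfile(fileext = ".tsv")
  write_abundance(tbl, path)
  back <- read_abundance(path)
  expect_identical(back$detected, tbl$detected)
  expect_equal(back$values[back$detected], tbl$values[tbl$detected])
  expect_identical(back$annotations$gene_name, tbl$annotations$gene_name)
})

test_that("prevalence filter keeps genes detected in at least half the samples", {
  vals <- matrix(1, 2, 10)
  vals[1, 1:5] <- 0  # detected in 5 of 10: boundary, kept
  vals[2, 1:6] <- 0  # detected in 4 of 10: removed
  tbl <- abundance_table(vals, gene_ids = c("boundary", "below"),
                         sample_ids = paste0("s", 1:10))
  kept <- prevalence_filter(tbl, 0.5)
  expect_identical(kept$gene_ids, "boundary")
  expect_error(prevalence_filter(kept, 1), "lower min_fraction")
})

test_that("prevalence filter matches an exhaustive per-gene recount", {
  set.seed(21)
  vals <- matrix(rpois(50 * 8, 3), 50, 8) *
    matrix(rbinom(50 * 8, 1, 0.6), 50, 8)
  vals <- vals + 0.5 * (vals > 0)  # keep detected values positive
  tbl <- abundance_table(vals, gene_ids = sprintf("g%02d", 1:50),
                         sample_ids = paste0("s", 1:8))
  for (frac in c(0.25, 0.5, 0.75)) {
    expected <- tbl$gene_ids[vapply(seq_len(50), function(i)
      sum(tbl$detected[i, ]) >= ceiling(frac * 8), TRUE)]
    if (!length(expected)) next
    expect_identical(prevalence_filter(tbl, frac)$gene_ids, expected,
                     label = paste("min_fraction", frac))
  }
})

test_that("log transform is log10 and fill_small fills at the stated constant", {
  vals <- matrix(c(100, 1, 0, 10, 1000, 5), 3, 2)
  tbl <- abundance_table(vals, gene_ids = c("a", "b", "c"),
                         sample_ids = c("s1", "s2"))
  lg <- log_transform(tbl, "fill_small", small_constant = 0.01)
  expect_equal(lg$values["a", "s1"], 2)
  expect_equal(lg$values["b", "s1"], 0)
  # filled entry equals log10(small_constant * minimum detected value)
  expect_equal(lg$values["c", "s1"], log10(0.01 * 1))
  expect_true(all(lg$detected))
  lm <- log_transform(tbl, "leave_missing")
  expect_false(lm$detected["c", "s1"])
  expect_error(log_transform(lg), "already")
})

test_that("filtering and log transformation commute on retained genes", {
  set.seed(31)
  vals <- matrix(10^runif(60, 0.5, 3), 15, 4) *
    matrix(rbinom(60, 1, 0.7), 15, 4)
  tbl <- abundance_table(vals, gene_ids = sprintf("g%02d", 1:15),
                         sample_ids = paste0("s", 1:4))
  a <- log_transform(prevalence_filter(tbl, 0.5), "leave_missing")
  b_full <- log_transform(tbl, "leave_missing")
  b <- fmenet:::subset_genes(b_full, match(a$gene_ids, b_full$gene_ids))
  expect_identical(a$detected, b$detected)
  expect_equal(a$values[a$detected], b$values[b$detected])
})

test_that("trait standardization yields exact z-scores and is idempotent", {
  tr <- trait_table(cbind(x = c(1, 2, 3), y = c(10, 0, 5)),
                    sample_ids = c("s1", "s2", "s3"))
  std <- standardize_traits(tr)
  expect_true(std$standardized)
  expect_equal(unname(colMeans(std$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$values, 2, sd)), c(1, 1), tolerance = 1e-12)
  again <- standardize_traits(std)
  expect_equal(again$values, std$values, tolerance = 1e-9)
  const <- trait_table(cbind(flat = rep(2, 3)), sample_ids = paste0("s", 1:3))
  expect_error(standardize_traits(const), "flat")
})

test_that("a 10-trait, 20-sample table standardizes to machine-zero means", {
  set.seed(41)
  vals <- sapply(1:10, function(i) rnorm(20, mean = 10 * i, sd = i))
  colnames(vals) <- paste0("trait", 1:10)
  std <- standardize_traits(trait_table(vals, sample_ids = paste0("s", 1:20)))
  expect_true(all(abs(colMeans(std$values)) < 1e-9))
  expect_true(all(abs(apply(std$values, 2, sd) - 1) < 1e-9))
})
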