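test_that("benchmark bookkeeping: cells, mask sharing, determinism", {
  cfg <- benchmark_config(
    mv_rates = 0.2, mnar_rates = 0.5, n_repeats = 1L, methods = "LOD",
    base_seed = 3L,
    n_proteins = c(ecoli = 12, yeast = 11, human = 27),
    design = benchmark_design(replicates_per_group = 4L),
    verbose = FALSE)
  rep1 <- run_benchmark(cfg)
  expect_equal(nrow(rep1$accuracy), 1L)
  expect_equal(nrow(rep1$de), 3L)            # B/A, C/A, D/A
  expect_null(rep1$failed)

  # identical config twice: identical report tables
  rep2 <- run_benchmark(cfg)
  expect_identical(rep1$accuracy, rep2$accuracy)
  expect_identical(rep1$de, rep2$de)

  # 3 x 3 grid x 2 repeats x 2 methods: 36 cells over 18 distinct masks,
  # each mask shared by both methods
  cfg2 <- benchmark_config(
    mv_rates = c(0.1, 0.2, 0.3), mnar_rates = c(0.2, 0.5, 0.8),
    n_repeats = 2L, methods = c("LOD", "ND"), base_seed = 5L,
    n_proteins = c(ecoli = 12, yeast = 11, human = 27),
    design = benchmark_design(replicates_per_group = 4L),
    verbose = FALSE)
  rep3 <- run_benchmark(cfg2)
  expect_equal(nrow(rep3$accuracy), 36L)
  expect_equal(length(unique(rep3$accuracy$mask_id)), 18L)
  shared <- tapply(rep3$accuracy$mask_id,
                   interaction(rep3$accuracy$alpha, rep3$accuracy$beta,
                               rep3$accuracy$rep),
                   function(z) length(unique(z)))
  expect_true(all(shared == 1L))

  s <- summary(rep3)
  expect_equal(nrow(s$overall), 2L)
  expect_true(all(s$by_condition$nrmse_abundance_sd >= 0))
})

test_that("the full pipeline runs all seven methods and preserves their ordering", {
  cfg <- benchmark_config(
    mv_rates = 0.2, mnar_rates = 0.5, n_repeats = 1L,
    methods = all_methods, base_seed = 9L,
    n_proteins = c(ecoli = 36, yeast = 32, human = 132),
    verbose = FALSE)
  rep <- run_benchmark(cfg)
  expect_null(rep$failed)
  expect_equal(nrow(rep$accuracy), 7L)
  expect_equal(length(unique(rep$accuracy$mask_id)), 1L)
  expect_equal(nrow(rep$de), 21L)
  nr <- setNames(rep$accuracy$nrmse_abundance, rep$accuracy$method)
  expect_lt(nr[["RF"]], nr[["ND"]])
  expect_lt(nr[["ND"]], nr[["LOD"]])
  expect_true(all(rep$accuracy$nrmse_ratio > 0))
  expect_true(all(rep$de$FADR >= 0 & rep$de$FADR <= 1))
})

test_that("per-cell failures are recorded without aborting the grid", {
  cfg <- benchmark_config(
    mv_rates = 0.2, mnar_rates = 0.5, n_repeats = 1L,
    methods = c("LOD", "KNN"), base_seed = 2L,
    n_proteins = c(ecoli = 10, yeast = 10, human = 20),
    design = benchmark_design(replicates_per_group = 4L),
    method_args = list(KNN = list(k_neighbors = 500)),
    verbose = FALSE)
  rep <- run_benchmark(cfg)
  expect_equal(rep$failed$method, "KNN")
  expect_match(rep$failed$error, "k_neighbors")
  expect_equal(rep$accuracy$method, "LOD")
})

test_that("a source matrix with missing entries is refused with guidance", {
  x <- tiny_benchmark()
  x$values[1, 1] <- NA
  cfg <- benchmark_config(source = x, n_repeats = 1L, mv_rates = 0.1,
                          mnar_rates = 0.5, methods = "LOD", verbose = FALSE)
  expect_error(run_benchmark(cfg), "complete_subset")
})

test_that("abundance TSV writing and reading round-trips", {
  x <- tiny_benchmark(seed = 10)
  x$values[2, 3] <- NA                      # missing survives the trip
  path <- file.path(withr::local_tempdir(), "m.tsv")
  write_abundance_tsv(x, path)
  y <- read_abundance_tsv(path)
  expect_equal(y$values, x$values, tolerance = 1e-12)
  expect_identical(y$species, x$species)
  expect_identical(y$groups, x$groups)
  expect_identical(is.na(y$values), is.na(x$values))
  # design sidecar restored
  expect_equal(y$design$proportions, x$design$proportions)
  expect_identical(y$design$control_group, "A")
})

test_that("malformed abundance TSVs raise descriptive errors", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("protein\tspecies\tA_1\tA_2",
               "P1\thuman\t1\t2",
               "P1\thuman\t3\t4"), dup)
  expect_error(read_abundance_tsv(dup), "duplicate protein id 'P1' at line 3")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("protein\tspecies\tA_1\tA_2",
               "P1\thuman\t1\ttwo"), bad)
  expect_error(read_abundance_tsv(bad), "non-numeric value 'two'")

  ragged <- file.path(dir, "ragged.tsv")
  writeLines(c("protein\tspecies\tA_1\tA_2",
               "P1\thuman\t1\t2\t3"), ragged)
  expect_error(read_abundance_tsv(ragged), "ragged")
})

test_that("MaxQuant proteinGroups tables are parsed and filtered", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "proteinGroups.txt")
  header <- paste("Protein IDs", "Reverse", "Potential contaminant",
                  "LFQ intensity A_1", "LFQ intensity A_2",
                  "LFQ intensity B_1", "Intensity A_1", sep = "\t")
  rows <- c(
    paste("P1", "", "", "100", "200", "300", "1", sep = "\t"),
    paste("P2", "+", "", "10", "20", "30", "1", sep = "\t"),
    paste("P3", "", "", "0", "50", "60", "1", sep = "\t"),
    paste("P4", "", "+", "1", "2", "3", "1", sep = "\t"),
    paste("P5", "", "", "7", "8", "9", "1", sep = "\t"))
  writeLines(c(header, rows), f)

  x <- read_maxquant_proteingroups(f)
  expect_equal(nrow(x$values), 3L)          # reverse + contaminant removed
  expect_identical(rownames(x$values), c("P1", "P3", "P5"))
  expect_true(is.na(x$values["P3", "A_1"])) # zero -> missing
  expect_equal(x$values["P1", "A_1"], log2(100))
  expect_identical(x$groups, c("A", "A", "B"))

  # prefix override
  xi <- read_maxquant_proteingroups(f, intensity_prefix = "Intensity ",
                                    log2 = FALSE)
  expect_equal(ncol(xi$values), 1L)
  expect_error(read_maxquant_proteingroups(f, intensity_prefix = "iBAQ "),
               "available")
})

test_that("complete_subset keeps exactly the fully observed rows", {
  x <- tiny_benchmark(seed = 2)
  expect_identical(complete_subset(x)$values, x$values)

  set.seed(44)
  holes <- matrix(runif(length(x$values)) < 0.1, nrow(x$values))
  x$values[holes] <- NA
  filtered <- complete_subset(x)
  expect_identical(nrow(filtered$values),
                   sum(rowSums(is.na(x$values)) == 0L))
  expect_false(anyNA(filtered$values))

  x$values[] <- NA_real_
  expect_error(complete_subset(x), "no fully observed")
})

test_that("masked datasets round-trip through their directory format", {
  md <- tiny_masked(alpha = 0.3, beta = 0.8, seed = 6)
  dir <- file.path(withr::local_tempdir(), "masked")
  write_masked_dataset(md, dir)
  back <- read_masked_dataset(dir)
  expect_equal(back$observed, md$observed, tolerance = 1e-10)
  expect_identical(back$mask, md$mask)
  expect_identical(back$provenance, md$provenance)
  expect_equal(back$truth, md$truth, tolerance = 1e-10)
  expect_identical(back$species, md$species)
  expect_equal(back$spec$alpha, md$spec$alpha)
})

test_that("benchmark reports serialize to JSON and TSV", {
  cfg <- benchmark_config(
    mv_rates = 0.2, mnar_rates = 0.5, n_repeats = 1L, methods = "LOD",
    base_seed = 3L, n_proteins = c(ecoli = 12, yeast = 11, human = 27),
    design = benchmark_design(replicates_per_group = 4L), verbose = FALSE)
  rep <- run_benchmark(cfg)
  dir <- file.path(withr::local_tempdir(), "report")
  write_benchmark_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "report.json", "accuracy.tsv", "de.tsv",
    "summary_nrmse.tsv", "summary_de.tsv")))))
  j <- jsonlite::read_json(file.path(dir, "report.json"),
                           simplifyVector = TRUE)
  expect_equal(j$config$base_seed, 3L)
  expect_equal(nrow(j$accuracy), 1L)
})
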