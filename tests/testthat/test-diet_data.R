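test_that("CSV round-trip preserves a conforming dataset cell for cell", {
  d <- demo_dataset()
  fi <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_diet_tables(d, fi, fp)
  d2 <- read_diet_tables(fi, fp)
  expect_equal(d2$individuals[.cols <- setdiff(names(d$individuals), NULL)],
               d$individuals[.cols])
  expect_equal(d2$observations, d$observations)
  # and a second round trip is byte-identical at the file level
  fi2 <- withr::local_tempfile(fileext = ".csv")
  fp2 <- withr::local_tempfile(fileext = ".csv")
  write_diet_tables(d2, fi2, fp2)
  expect_identical(readLines(fi2), readLines(fi))
  expect_identical(readLines(fp2), readLines(fp))
})

test_that("reader rejects malformed inputs with informative errors", {
  d <- demo_dataset()
  fi <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_diet_tables(d, fi, fp)

  # missing required column is named
  ind <- read.csv(fi, colClasses = "character")
  f_bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(ind[setdiff(names(ind), "total_length_cm")], f_bad,
            row.names = FALSE)
  expect_error(read_diet_tables(f_bad, fp), "total_length_cm")

  # orphan prey row names the offending id
  prey <- read.csv(fp, colClasses = "character")
  prey$individual_id[2] <- "X9"
  write.csv(prey, f_bad, row.names = FALSE)
  expect_error(read_diet_tables(fi, f_bad), "X9")

  # category outside the closed vocabulary is rejected, not coerced
  prey <- read.csv(fp, colClasses = "character")
  prey$prey_category[1] <- "Insecta"
  write.csv(prey, f_bad, row.names = FALSE)
  expect_error(read_diet_tables(fi, f_bad), "Insecta")

  # unparseable numeric reports the row number
  prey <- read.csv(fp, colClasses = "character")
  prey$wet_mass_g[3] <- "heavy"
  write.csv(prey, f_bad, row.names = FALSE)
  expect_error(read_diet_tables(fi, f_bad), "wet_mass_g.*3")
})

test_that("dataset validation enforces the stated invariants", {
  d <- demo_dataset()
  bad <- d$individuals
  bad$total_length_cm[1] <- -5
  expect_error(diet_dataset(bad, d$observations), "positive")
  bad <- d$individuals
  bad$snout_vent_length_cm[1] <- 300
  expect_error(diet_dataset(bad, d$observations), "exceeds")
  bad_obs <- d$observations
  bad_obs$item_count[1] <- 0L
  expect_error(diet_dataset(d$individuals, bad_obs), "positive integer")
  # duplicate id without a recapture flag is rejected
  dup <- rbind(d$individuals, d$individuals[1, ])
  expect_error(diet_dataset(dup, d$observations), "duplicate")
  # ... but tolerated when the later record is flagged
  dup$recapture[4] <- TRUE
  dup$capture_date[4] <- dup$capture_date[1] + 30
  expect_s3_class(diet_dataset(dup, d$observations), "diet_dataset")
})

test_that("the packaged 5-individual fixture filters to the hand-enumerated set", {
  d <- read_diet_tables(extdata("filter_demo_individuals.csv"),
                        extdata("filter_demo_prey.csv"))
  expect_equal(nrow(d$individuals), 5)
  f <- filter_analysis_set(d)
  expect_setequal(f$individuals$individual_id, c("demo_j1", "demo_j2"))
  led <- attr(f, "filter_ledger")
  expect_equal(led$n_removed[led$stage == "recaptures"], 1)     # demo_r1
  expect_equal(led$n_removed[led$stage == "juveniles_only"], 1) # demo_a1 at 200 cm
  expect_equal(led$n_removed[led$stage == "empty_stomachs"], 1) # demo_e1
  expect_equal(led$n_out[nrow(led)], 2)
  # salinity classes: 0.5 and 18.5 ppt straddle the 15 ppt threshold
  expect_equal(f$individuals$salinity_class,
               c("freshwater_intermediate", "marine"))
})

test_that("the juvenile boundary is a strict inequality", {
  d <- demo_dataset()
  d$individuals$total_length_cm[1] <- 180.0
  f <- filter_analysis_set(d)
  expect_false("a1" %in% f$individuals$individual_id)
  d$individuals$total_length_cm[1] <- 179.9
  f <- filter_analysis_set(d)
  expect_true("a1" %in% f$individuals$individual_id)
})

test_that("disabled filters are the identity and enabled ones are idempotent and commute", {
  d <- read_diet_tables(extdata("filter_demo_individuals.csv"),
                        extdata("filter_demo_prey.csv"))
  off <- filter_config(drop_empty = FALSE, drop_recaptures = FALSE,
                       life_stage = "all")
  f <- filter_analysis_set(d, off)
  expect_equal(f$individuals$individual_id, d$individuals$individual_id)
  expect_equal(f$observations, d$observations)

  cfg <- filter_config()
  once <- filter_analysis_set(d, cfg)
  twice <- filter_analysis_set(once, cfg)
  expect_equal(twice$individuals$individual_id, once$individuals$individual_id)
  expect_equal(twice$observations, once$observations)

  # each single-rule pass commutes with the others (row predicates)
  only <- function(data, which) {
    cfg <- filter_config(
      drop_empty = which == "empty",
      drop_recaptures = which == "recap",
      life_stage = if (which == "juv") "juveniles_only" else "all")
    filter_analysis_set(data, cfg)
  }
  for (ord in list(c("juv", "empty", "recap"), c("recap", "juv", "empty"),
                   c("empty", "recap", "juv"))) {
    out <- d
    for (w in ord) out <- only(out, w)
    expect_setequal(out$individuals$individual_id, c("demo_j1", "demo_j2"))
  }
})

test_that("filtering everything out and missing lengths are fatal", {
  d <- demo_dataset()
  expect_error(filter_analysis_set(d, filter_config(life_stage = "adults_only")),
               "all individuals")
  d$individuals$total_length_cm[2] <- NA
  expect_error(filter_analysis_set(d), "missing.*a2|a2.*missing")
})

test_that("diet matrix aggregation matches a hand tally and conserves totals", {
  d <- demo_dataset()
  # split a1's crustacean items over two rows: aggregation must re-sum them
  d$observations <- rbind(d$observations,
                          data.frame(individual_id = "a1",
                                     prey_category = "crustaceans",
                                     item_count = 1L, wet_mass_g = 2.0))
  m <- build_diet_matrix(d)
  expect_equal(dim(m$counts), c(3, 10))
  expect_equal(m$counts["a1", "crustaceans"], 3L)
  expect_equal(m$masses["a1", "crustaceans"], 7.0)
  expect_equal(m$counts["a1", "insects_arachnids"], 5L)
  expect_equal(unname(rowSums(m$counts)), c(8, 1, 3))
  # conservation over surviving observations
  expect_equal(sum(m$counts), sum(d$observations$item_count))
  expect_equal(sum(m$masses), sum(d$observations$wet_mass_g))
  # a cell with zero count carries zero mass
  expect_true(all(m$masses[m$counts == 0] == 0))
  # permuting the observation rows leaves the matrix unchanged
  d2 <- d
  d2$observations <- d$observations[sample(nrow(d$observations)), ]
  m2 <- build_diet_matrix(d2)
  expect_identical(m2$counts, m$counts)
  expect_identical(m2$masses, m$masses)
})

test_that("mono-category exclusion implements both readings of the rule", {
  counts <- rbind(two_of_one = c(0L, 2L, 0L),
                  five_of_one = c(0L, 5L, 0L),
                  two_cats = c(1L, 1L, 0L),
                  rich = c(2L, 3L, 1L))
  m <- dm(counts)
  lit <- exclude_monocategory(m, "literal")
  expect_setequal(rownames(lit$counts), c("five_of_one", "two_cats", "rich"))
  expect_equal(attr(lit, "mono_dropped_ids"), "two_of_one")
  any1 <- exclude_monocategory(m, "any_single_category")
  expect_setequal(rownames(any1$counts), c("two_cats", "rich"))
  expect_setequal(attr(any1, "mono_dropped_ids"),
                  c("two_of_one", "five_of_one"))
  # fewer than two survivors is an error, not a silent degenerate result
  m2 <- dm(rbind(a = c(0L, 2L, 0L), b = c(0L, 4L, 0L), c = c(1L, 2L, 1L)))
  expect_error(exclude_monocategory(m2, "any_single_category"),
               "fewer than 2")
})
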