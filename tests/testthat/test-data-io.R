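test_that("a 3-row toy CSV parses into a cohort", {
  path <- toy_cohort_csv()
  co <- read_cohort(path)
  expect_s3_class(co, "dbn_cohort")
  expect_equal(nrow(co$meta), 3)
  expect_equal(length(co$taxa), 2)
  expect_equal(co$meta$day_of_life, c(3, 5, 6))
})

test_that("schema and parse errors are informative", {
  path <- toy_cohort_csv()
  df <- utils::read.csv(path)
  # missing required column
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df[setdiff(names(df), "day_of_life")], p2,
                   row.names = FALSE)
  expect_error(read_cohort(p2), "day_of_life")
  # negative count
  df2 <- df; df2$Bacilli[2] <- -5
  utils::write.csv(df2, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "negative")
  # non-numeric count names the row
  df3 <- df; df3$Bacilli <- as.character(df3$Bacilli); df3$Bacilli[3] <- "oops"
  utils::write.csv(df3, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "row 3")
  expect_error(read_cohort(tempfile()), "not found")
})

test_that("duplicate (subject, day) rows are rejected or summed by
           config", {
  path <- toy_cohort_csv()
  df <- utils::read.csv(path)
  df <- rbind(df, df[2, ])
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_cohort(p2), "duplicate")
  co <- read_cohort(p2, config = cohort_config(duplicates = "sum"))
  expect_equal(nrow(co$meta), 3)
  expect_equal(co$counts[co$meta$day_of_life == 5, "Bacilli"][[1]], 120)
})

test_that("column mapping renames study headers to canonical names", {
  df <- data.frame(ID = "A", DOL = c(1, 3), GA = 30, PCA = 30.2,
                   Abx = 0, Room = "open", Bacilli = c(5, 6),
                   Clostridia = c(5, 4))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  cfg <- cohort_config(column_map = c(
    subject_id = "ID", day_of_life = "DOL", gestational_age = "GA",
    postconceptional_age = "PCA", antibiotics = "Abx", open_room = "Room"))
  co <- read_cohort(p, config = cfg)
  expect_equal(co$meta$day_of_life, c(1, 3))
  # config round-trips through JSON
  pc <- tempfile(fileext = ".json")
  jsonlite::write_json(list(column_map = as.list(cfg$column_map),
                            min_fraction = 0.02), pc, auto_unbox = TRUE)
  cfg2 <- read_cohort_config(pc)
  expect_equal(cfg2$column_map, cfg$column_map)
  expect_equal(cfg2$min_fraction, 0.02)
})

test_that("relative abundance converts counts to proportions", {
  expect_equal(unname(relative_abundance(c(10, 0, 0))), c(1, 0, 0))
  expect_equal(unname(relative_abundance(c(5, 5, 10))),
               c(0.25, 0.25, 0.5))
  expect_error(relative_abundance(c(0, 0)), "degenerate")
  set.seed(301)
  for (i in 1:10) {
    v <- rpois(sample(2:8, 1), 20) + 1
    ra <- relative_abundance(v)
    expect_equal(sum(ra), 1, tolerance = 1e-12)
    expect_equal(ra, rev(relative_abundance(rev(v))))      # equivariance
    expect_equal(ra, relative_abundance(v * 17))           # scale-invariant
  }
})

test_that("transition pairing follows the k - 1 rule and never crosses
           subjects", {
  co1 <- toy_cohort(n_subjects = 1, n_samples = 5, seed = 1)
  expect_equal(nrow(build_transitions(co1)$parents), 4)
  # subject with a single sample contributes zero pairs
  single <- toy_cohort(n_subjects = 1, n_samples = 2, seed = 2)
  single$meta <- single$meta[1, , drop = FALSE]
  single$meta$subject_id <- "Z1"
  single$counts <- single$counts[1, , drop = FALSE]
  co2 <- toy_cohort(n_subjects = 2, n_samples = 3, seed = 3)
  merged <- as_cohort(rbind(single$meta, co2$meta),
                      rbind(single$counts, co2$counts))
  tr <- build_transitions(merged)
  expect_equal(nrow(tr$parents), 0 + 2 + 2)
  expect_true(all(tr$gap_days >= 1))
  # brute-force pair count on random toy cohorts
  set.seed(302)
  for (i in 1:5) {
    ns <- sample(2:5, 1)
    co <- toy_cohort(n_subjects = ns, n_samples = sample(2:6, 1),
                     seed = 400 + i)
    k <- table(co$meta$subject_id)
    expect_equal(nrow(build_transitions(co)$parents),
                 sum(pmax(as.integer(k) - 1, 0)))
  }
})

test_that("transition sources and targets are consecutive samples of one
           subject", {
  co <- toy_cohort(n_subjects = 2, n_samples = 4, seed = 5)
  tr <- build_transitions(co)
  ab <- abundances(co)
  for (i in seq_len(nrow(tr$parents))) {
    rows <- which(co$meta$subject_id == tr$subject[i])
    tgt <- rows[co$meta$day_of_life[rows] == tr$target_day[i]]
    src <- rows[which(rows == tgt) - 1]
    expect_equal(unlist(tr$children[i, co$taxa]), ab[tgt, ],
                 ignore_attr = TRUE)
    expect_equal(unlist(tr$parents[i, co$taxa]), ab[src, ],
                 ignore_attr = TRUE)
  }
})

test_that("select_taxa unions network taxa with the abundance filter in
           canonical order", {
  meta <- data.frame(subject_id = "A", day_of_life = 1:3,
                     gestational_age = 28, postconceptional_age = 28,
                     antibiotics = 0, open_room = "closed")
  counts <- cbind(Bacilli = c(990, 990, 992), Rare = c(4, 4, 4),
                  unclassified = c(6, 6, 4))
  co <- as_cohort(meta, counts)
  expect_equal(select_taxa(co, min_fraction = 0),
               c("Bacilli", "Rare", "unclassified"))
  # Rare peaks at 0.4% < 1%: excluded without a network
  expect_equal(select_taxa(co, min_fraction = 0.01), "Bacilli")
  # but retained when the network uses it
  tr <- build_transitions(co)
  st <- dbn_structure(list(Bacilli = "Rare"), tr)
  expect_equal(select_taxa(co, st, min_fraction = 0.01),
               c("Bacilli", "Rare"))
})

test_that("a cohort round-trips through the wide CSV", {
  co <- toy_cohort(n_subjects = 2, n_samples = 3, seed = 7)
  p <- tempfile(fileext = ".csv")
  write_cohort(co, p)
  back <- read_cohort(p)
  expect_equal(back$meta, co$meta)
  expect_equal(back$counts, co$counts)
  # long export has one row per (sample, taxon)
  pl <- tempfile(fileext = ".csv")
  write_cohort_long(co, pl)
  long <- utils::read.csv(pl)
  expect_equal(nrow(long), nrow(co$meta) * length(co$taxa))
  expect_equal(sum(long$count), sum(co$counts))
})
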