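test_that("single-term CSV parses into a validated collection", {
  path <- write_tmp_csv(c(
    "report_id,sex,age_group,vaccine_type,schedule,year,term",
    "a1,female,18to59,mrna,primer,2021,Taste Disorder",
    "a2,male,over59,viral_vector,booster,2022,ageusia",
    "a3,female,7to17,mrna,primer,2023,oral herpes"))
  c1 <- read_icsr_table(path, "single_term")
  expect_s3_class(c1, "icsr_collection")
  expect_equal(n_total(c1), 3L)
  expect_equal(icsr_dialect(c1), "single_term")
  expect_equal(c1$term1, c("taste disorder", "ageusia", "oral herpes"))
})

test_that("unknown enum values fall back to missing with a warning", {
  path <- write_tmp_csv(c(
    "report_id,sex,age_group,vaccine_type,schedule,year,term",
    "a1,unknown,18to59,mrna,primer,2021,ageusia"))
  expect_warning(c1 <- read_icsr_table(path, "single_term"), "sex")
  expect_equal(c1$sex, "missing")
})

test_that("format errors name the offending column or bound", {
  noterm <- write_tmp_csv(c("report_id,sex,age_group,vaccine_type,schedule,year",
                            "a1,female,18to59,mrna,primer,2021"))
  expect_error(read_icsr_table(noterm, "single_term"), "term")
  empty <- write_tmp_csv("report_id,sex,age_group,vaccine_type,schedule,year,term")
  expect_error(read_icsr_table(empty, "single_term"), "empty")
  six <- write_tmp_csv(c(
    paste0("report_id,sex,age_group,vaccine_type,schedule,year,vaccine_class,",
           paste0("term", 1:6, collapse = ",")),
    "a1,female,18to59,mrna,primer,2021,covid19,t1,t2,t3,t4,t5,t6"))
  expect_error(read_icsr_table(six, "multi_term"), "term6")
})

test_that("malformed rows are rejected with row numbers", {
  path <- write_tmp_csv(c(
    "report_id,sex,age_group,vaccine_type,schedule,year,term",
    "a1,female,18to59,mrna,primer,2021,ageusia",
    ",female,18to59,mrna,primer,2021,ageusia",
    "a3,female,18to59,mrna,primer,2021,"))
  expect_warning(c1 <- read_icsr_table(path, "single_term"), "2, 3")
  expect_equal(n_total(c1), 1L)
})

test_that("duplicate merging resolves conflicts and unions term lists", {
  # non-missing wins
  c1 <- toy_single(2)
  df <- as.data.frame(c1)
  df$report_id <- "same"
  df$sex <- c("missing", "female")
  m <- merge_duplicates(icsr_collection(df, "single_term"))
  expect_equal(n_total(m), 1L)
  expect_equal(m$sex, "female")

  # term union preserves first-seen order: {A,B} + {B,C} -> [A,B,C]
  c2 <- toy_multi(list(c("a term", "b term"), c("b term", "c term")))
  df2 <- as.data.frame(c2)
  df2$report_id <- "dup"
  m2 <- merge_duplicates(icsr_collection(df2, "multi_term"))
  expect_equal(unname(unlist(m2[1, paste0("term", 1:3)])),
               c("a term", "b term", "c term"))
  expect_true(is.na(m2$term4))
})

test_that("merge_duplicates is idempotent and a no-op without duplicates", {
  c1 <- toy_single(5)
  expect_identical(merge_duplicates(c1), c1)
  c2 <- toy_multi(list(c("x", "y"), "y", c("y", "z")))
  df <- as.data.frame(c2)
  df$report_id[2] <- df$report_id[1]
  dup <- icsr_collection(df, "multi_term")
  once <- merge_duplicates(dup)
  expect_identical(merge_duplicates(once), once)
})

test_that("term counting honours scope and dialect equivalence", {
  c1 <- toy_single(5, term = "taste disorder")
  expect_equal(term_case_count(c1, "taste disorder", "any_position"), 5L)
  expect_equal(term_case_count(c1, "taste disorder", "primary_only"), 5L)
  expect_equal(term_case_count(c1, "ageusia"), 0L)

  c2 <- toy_multi(list(c("x term", "y term")))
  expect_equal(term_case_count(c2, "x term", "any_position"), 1L)
  expect_equal(term_case_count(c2, "x term", "primary_only"), 1L)
  expect_equal(term_case_count(c2, "y term", "any_position"), 1L)
  expect_equal(term_case_count(c2, "y term", "primary_only"), 0L)
})

test_that("covariate categories partition every collection", {
  cfg <- mini_sim_config(rate = 5, n = 2000)
  for (which in c("db1", "db2")) {
    db <- generate_database(cfg, which, seed = 7)
    for (v in c("sex", "age_group", "vaccine_type", "schedule"))
      expect_equal(sum(table(db[[v]])), n_total(db))
    expect_equal(length(db$year), n_total(db))
  }
})

test_that("oral-term classification matches the vocabulary and exclusions", {
  frame <- oral_term_frame()
  expect_equal(nrow(frame), 80L)
  hit <- classify_oral_terms(c("oral herpes", "headache"), frame)
  expect_equal(hit$term, "oral herpes")
  expect_equal(hit$group, "oral_mucosa")
  expect_equal(nrow(classify_oral_terms("oral contraception", frame)), 0L)
  expect_equal(nrow(classify_oral_terms(character(), frame)), 0L)

  # output is always a subset of the frame, sorted by term
  uni <- c(sample(frame$term, 30), "influenza", "stage ii tongue cancer")
  out <- classify_oral_terms(uni, frame)
  expect_true(all(out$term %in% frame$term))
  expect_equal(out$term, sort(out$term))
})

test_that("a frame entry matching an exclusion keyword is rejected", {
  expect_error(ae_term_frame(data.frame(term = "oral contraception",
                                        group = "oral_mucosa"),
                             "contracept"), "exclusion")
})
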