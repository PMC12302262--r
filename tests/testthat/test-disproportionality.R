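test_that("2x2 construction counts classes and terms correctly", {
  c2 <- toy_multi(list("x term", "other", "x term", "other"),
                  vaccine_class = c("covid19", "covid19", "comparator", "comparator"))
  t <- build_2x2(c2, "x term")
  expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = 1L, b = 1L, c = 1L, d = 1L))

  no_comp <- toy_multi(list("x term", "other"))
  t2 <- build_2x2(no_comp, "x term")
  expect_equal(t2$c + t2$d, 0L)

  c1 <- toy_single(4)
  expect_error(build_2x2(c1, "taste disorder"), "multi_term")
})

test_that("2x2 construction agrees with a brute-force recount", {
  cfg <- mini_sim_config(rate = 20, n = 3000)
  db2 <- generate_database(cfg, "db2", seed = 17)
  t <- build_2x2(db2, "test term")
  has <- vapply(seq_len(nrow(db2)), function(i)
    "test term" %in% stats::na.omit(unlist(db2[i, paste0("term", 1:5)])),
    logical(1))
  covid <- db2$vaccine_class == "covid19"
  expect_equal(t$a, sum(has & covid))
  expect_equal(t$b, sum(!has & covid))
  expect_equal(t$c, sum(has & !covid))
  expect_equal(t$d, sum(!has & !covid))
})

test_that("PRR and ROR match hand arithmetic and guard zero cells", {
  t <- contingency_2x2(10, 990, 5, 1995)
  expect_equal(prr(t)$estimate, 4)
  expect_equal(ror(t)$estimate, (10 * 1995) / (990 * 5))   # ~4.03
  flat <- contingency_2x2(10, 90, 20, 180)                 # equal proportions
  expect_equal(prr(flat)$estimate, 1)
  expect_equal(ror(contingency_2x2(1, 1, 1, 1))$estimate, 1)
  expect_false(prr(contingency_2x2(0, 100, 5, 95))$defined)
  expect_false(ror(contingency_2x2(10, 0, 5, 95))$defined)
})

test_that("the information component matches its closed form", {
  # a = E gives IC = 0
  bal <- contingency_2x2(10, 90, 10, 90)
  expect_equal(information_component(bal)$ic, 0)
  # margins engineered so E = 25 with a = 100
  t <- contingency_2x2(100, 100, 150, 1650)
  ic <- information_component(t)
  expect_equal(ic$expected, 25)
  expect_equal(ic$ic, log2(100.5 / 25.5), tolerance = 1e-12)  # ~1.979
  expect_equal(ic$ic025,
               log2(100.5 / 25.5) - 3.3 / sqrt(100.5) - 2 * 100.5^(-1.5),
               tolerance = 1e-12)
  expect_error(information_component(contingency_2x2(0, 0, 0, 0)), "empty")
})

test_that("IC025 tracks the gamma-posterior percentile", {
  # Monte-Carlo oracle at a moderate count
  a <- 10; t <- contingency_2x2(a, 1000, a, 1000)   # margins give E = a
  ic <- information_component(t)
  draws <- local({
    set.seed(77)
    stats::rgamma(2e5, shape = a + 0.5, rate = ic$expected + 0.5)
  })
  q <- log2(stats::quantile(draws, 0.025))
  expect_lt(abs(ic$ic025 - q), 0.15)
})

test_that("qualification needs both arms populated", {
  expect_false(qualify(contingency_2x2(0, 100, 5, 95)))
  expect_false(qualify(contingency_2x2(35, 100, 0, 95)))   # hypersalivation case
  expect_true(qualify(contingency_2x2(10, 100, 5, 95)))
  expect_false(qualify(contingency_2x2(2, 100, 5, 95)))    # below min_covid
  expect_true(qualify(contingency_2x2(2, 100, 5, 95), min_covid = 2))
})

test_that("the composite SDR rule reproduces published row labels", {
  # taste disorder: all three conditions met
  expect_equal(classify_sdr(data.frame(prr = 17.57, prr_low = 10.28,
                                       ror = 17.57, ror_low = 10.28,
                                       ic = 4.14, ic025 = 3.60)), "yes")
  # oral herpes: PRR and ROR below 2
  expect_equal(classify_sdr(data.frame(prr = 1.36, prr_low = 1.17,
                                       ror = 1.36, ror_low = 1.17,
                                       ic = 0.45, ic025 = 0.29)), "no")
  # tongue movement disturbance: frequentist lower bounds < 1
  expect_equal(classify_sdr(data.frame(prr = 4.99, prr_low = 0.60,
                                       ror = 4.99, ror_low = 0.60,
                                       ic = 2.32, ic025 = 0.20)), "no")
  # unqualified
  expect_equal(classify_sdr(data.frame(prr = NA, prr_low = NA, ror = NA,
                                       ror_low = NA, ic = NA, ic025 = NA)),
               "disqualified")
})

test_that("ROR dominates PRR above one and IC grows with the signal cell", {
  set.seed(99)
  for (i in 1:25) {
    t <- contingency_2x2(sample(1:80, 1), sample(1:400, 1),
                         sample(1:80, 1), sample(1:400, 1))
    p <- prr(t)$estimate
    if (p >= 1) expect_gte(ror(t)$estimate, p - 1e-12)
  }
  # shifting mass into cell a with all margins fixed raises the IC
  ics <- vapply(10:20, function(a)
    information_component(contingency_2x2(a, 30 - a, 25 - a, 45 + a))$ic,
    numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("the screen ties qualification to the reported status", {
  cfg <- mini_sim_config(rate = 8, n = 4000, comparator_rate = 2)
  db2 <- generate_database(cfg, "db2", seed = 23)
  scr <- sdr_screen(db2, c("test term", "absent term"))
  expect_s3_class(scr, "sdr_screen")
  expect_equal(scr$sdr == "disqualified", !scr$qualified)
  expect_equal(scr$sdr[scr$term == "absent term"], "disqualified")
  s <- summary(scr)
  expect_equal(s$n_terms, 2L)
})
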