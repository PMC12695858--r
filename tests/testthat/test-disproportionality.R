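# Published margins used across these tests: a large-count row
# (3,968 cases of 76,075 reports) and small-count rows, against database
# totals of 24,485 target-event reports among 10,177,264.
NP1 <- 24485
NPP <- 10177264

test_that("cells reconstruct from printed margins", {
  ct <- contingency_from_margins(3968, 72107, NP1, NPP)
  expect_equal(ct$n01, 20517)
  expect_equal(ct$n00, 10080672)
  expect_equal(ct$n1plus, 76075)
  expect_equal(ct$nplusplus, NPP)
})

test_that("an empty report set gives an all-zero table", {
  rep_ <- label_cases(apply_exclusions(mk_srs_data(mk_demo(character(0)))),
                      10013911L)
  ct <- build_contingency(rep_, "anything")
  expect_equal(unlist(ct[c("n11", "n10", "n01", "n00")]),
               c(n11 = 0L, n10 = 0L, n01 = 0L, n00 = 0L))
})

test_that("contingency cells equal an exhaustive double-loop count", {
  set.seed(41)
  n <- 500
  demo <- mk_demo(1:n)
  drugs <- mk_drugs(1:n, sample(c("a", "b", "c"), n, replace = TRUE),
                    role = sample(c("primary_suspect", "concomitant"),
                                  n, replace = TRUE, prob = c(.7, .3)))
  events <- mk_events(1:n, sample(c(10013911L, 5L), n, replace = TRUE))
  rep_ <- label_cases(apply_exclusions(mk_srs_data(demo, drugs, events)),
                      10013911L)
  ct <- build_contingency(rep_, "a")
  # oracle: explicit loop over reports
  cells <- c(0, 0, 0, 0)
  for (i in seq_len(nrow(rep_$demo))) {
    id <- rep_$demo$case_id[i]
    exposed <- any(rep_$drugs$case_id == id &
                     rep_$drugs$drug_name == "a" &
                     rep_$drugs$role == "primary_suspect")
    case <- rep_$demo$is_case[i]
    k <- if (exposed && case) 1 else if (exposed) 2
         else if (case) 3 else 4
    cells[k] <- cells[k] + 1
  }
  expect_equal(unlist(ct[c("n11", "n10", "n01", "n00")]),
               c(n11 = cells[1], n10 = cells[2], n01 = cells[3],
                 n00 = cells[4]))
  expect_equal(ct$nplusplus, nrow(rep_$demo))
})

test_that("ROR reproduces published values at 2 decimal places", {
  r <- ror(contingency_from_margins(3968, 72107, NP1, NPP))
  expect_equal(round_half_up(r$ror), 27.04)
  expect_equal(round_half_up(r$ci_low), 26.11)
  expect_equal(round_half_up(r$ci_high), 27.99)
  expect_true(r$signal)
})

test_that("a symmetric table gives ROR exactly 1", {
  r <- ror(contingency_table(10, 10, 10, 10))
  expect_equal(r$ror, 1)
  expect_false(r$signal)
})

test_that("ROR equals the cross-product oracle on random tables", {
  set.seed(51)
  for (i in 1:25) {
    cl <- sample(1:500, 4, replace = TRUE)
    r <- ror(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    expect_equal(r$ror, (cl[1] * cl[4]) / (cl[2] * cl[3]))
    # log-scale interval symmetric about log(ROR)
    expect_equal(log(r$ci_low) + log(r$ci_high), 2 * log(r$ror))
  }
})

test_that("ROR(drug vs rest) is the reciprocal of ROR(rest vs drug)", {
  set.seed(52)
  for (i in 1:10) {
    cl <- sample(1:300, 4, replace = TRUE)
    a <- ror(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    b <- ror(contingency_table(cl[3], cl[4], cl[1], cl[2]))
    expect_equal(a$ror, 1 / b$ror)
  }
})

test_that("zero cells make the ROR degenerate, never a signal", {
  r <- ror(contingency_table(0, 10, 5, 100))
  expect_true(r$degenerate)
  expect_false(r$signal)
  expect_true(is.na(r$ror))
})

test_that("information component reproduces published values", {
  big <- information_component(contingency_from_margins(3968, 72107,
                                                        NP1, NPP))
  expect_equal(round_half_up(big$ic), 4.43)
  expect_equal(round_half_up(big$ic025), 4.38)
  small <- information_component(contingency_from_margins(10, 1139,
                                                          NP1, NPP))
  expect_equal(round_half_up(small$ic), 1.55)
  expect_equal(round_half_up(small$ic025), 0.67)
  # credible bounds are +/- 2 posterior SDs by construction
  expect_equal(small$ic025, small$ic - 2 * sqrt(small$variance))
  expect_equal(small$ic975, small$ic + 2 * sqrt(small$variance))
})

test_that("IC tends to zero at independence for large tables", {
  n1p <- 10000; np1 <- 50000; npp <- 10^7
  n11 <- n1p * np1 / npp
  ic <- information_component(contingency_table(n11, n1p - n11,
                                                np1 - n11,
                                                npp - n1p - np1 + n11))
  expect_lt(abs(ic$ic), 0.01)
})

test_that("IC is monotone in n11 with margins held fixed", {
  grid <- c(5, 20, 80, 320, 1280)
  ics <- vapply(grid, function(n11) {
    information_component(
      contingency_from_margins(n11, 20000 - n11, NP1, NPP))$ic
  }, numeric(1))
  expect_true(all(diff(ics) > 0))
})

test_that("credible interval width shrinks under proportional scaling", {
  w <- vapply(c(1, 10, 100), function(k) {
    ic <- information_component(contingency_table(20 * k, 180 * k,
                                                  480 * k, 9320 * k))
    ic$ic975 - ic$ic025
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("screening gates on case count and requires both criteria", {
  set.seed(61)
  n <- 4000
  demo <- mk_demo(1:n)
  dn <- c(rep("rare drug", 8), sample(c("x", "y"), n - 8,
                                      replace = TRUE))
  pt <- integer(n)
  pt[1:4] <- 10013911L                       # 4 cases on "rare drug"
  pt[5:n] <- sample(c(10013911L, 7L), n - 4, replace = TRUE,
                    prob = c(0.05, 0.95))
  rep_ <- label_cases(apply_exclusions(
    mk_srs_data(demo, mk_drugs(1:n, dn), mk_events(1:n, pt))),
    10013911L)
  scr <- screen_signals(rep_, c("rare drug", "x", "y"), min_cases = 5)
  rare <- scr[scr$drug_name == "rare drug", ]
  expect_equal(rare$n11, 4L)
  expect_false(rare$eligible)
  expect_false(rare$signal)                  # regardless of its ROR
  expect_true(all(scr$signal == (scr$eligible & scr$ror_signal &
                                   scr$ic_signal)))
  expect_error(screen_signals(rep_, character(0)), "non-empty")
})

test_that("cross-database intersection keeps shared signals in FAERS order", {
  mk_screen <- function(drug, n11, signal) {
    structure(data.frame(drug_name = drug, n11 = n11, signal = signal,
                         stringsAsFactors = FALSE),
              class = c("srs_signal_screen", "data.frame"))
  }
  fa <- mk_screen(c("a", "b", "c"), c(100, 50, 10), c(TRUE, TRUE, TRUE))
  ja <- mk_screen(c("b", "c", "d"), c(5, 7, 9), c(TRUE, TRUE, TRUE))
  expect_equal(cross_database_intersection(fa, ja), c("b", "c"))
  ja2 <- mk_screen("z", 3, TRUE)
  expect_equal(cross_database_intersection(fa, ja2), character(0))
})

test_that("a strongly associated drug is flagged and nulls mostly are not", {
  sc <- srs_scenario(
    n_reports = 50000,
    drug_catalog = data.frame(
      drug_name = c("drug x", "null a", "null b", "null c"),
      weight = c(0.1, 0.3, 0.3, 0.3)),
    target_ae_base_rate = 0.01,
    drug_effects = c("drug x" = 10),
    duplicate_rate = 0,
    missingness = c(age = 0, sex = 0, start_date = 0, onset_date = 0),
    precision_loss = c(year_month = 0, year = 0), seed = 71)
  rep_ <- reports_from_scenario(sc)
  scr <- screen_signals(rep_)
  expect_true(scr$signal[scr$drug_name == "drug x"])
  expect_false(any(scr$signal[scr$drug_name != "drug x"]))
})
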