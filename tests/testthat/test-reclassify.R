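test_that("residual bins partition [0,100] with the stated boundaries", {
  expect_equal(as.character(bin_residual(c(0, 0.5, 4.99, 5, 7, 19.9, 20,
                                           50, 100))),
               c("none", "sub5", "sub5", "low", "low", "low", "high",
                 "high", "high"))
  # every value maps to exactly one bin
  grid <- seq(0, 100, by = 0.25)
  expect_false(anyNA(bin_residual(grid)))
  expect_error(bin_residual(-1), "0, 100")
  expect_error(bin_residual(101), "0, 100")
})

test_that("criteria assignment follows the residual-transcript rule set", {
  m <- rpe65_model(with_sequences = FALSE)
  a <- rpe65_assays(m)
  v <- rpe65_variants()
  cls <- assign_criteria(a, v, m)

  zero <- cls[cls$c_notation == "c.999-3C>G", ]
  expect_match(zero$criteria, "PVS1_very_strong")
  expect_equal(zero$final_class, "P")

  silent_ncss <- cls[cls$c_notation == "c.353+4A>T", ]
  expect_match(silent_ncss$criteria, "BP7_strong")
  expect_equal(silent_ncss$final_class, "B")

  silent_missense <- cls[cls$c_notation == "c.425A>T", ]
  expect_false(grepl("BP7", silent_missense$criteria))
  expect_false(grepl("PVS1", silent_missense$criteria))
  expect_equal(silent_missense$final_class,
               as.character(silent_missense$acmg_aug2023))

  # a residual fraction strictly between 0 and 5 earns PVS1-strong / LP
  sub5 <- a[a$c_notation == "c.643+5G>A", ]
  sub5$wt_pct <- 3
  sub5$aberrant_pct <- 97
  expect_equal(assign_criteria(sub5, v, m)$final_class, "LP")
  expect_match(assign_criteria(sub5, v, m)$criteria, "PVS1_strong")

  # PP3 is recorded for high scores but never changes the class alone
  high_score_silent <- cls[cls$c_notation == "c.1339-4A>G", ]
  expect_match(high_score_silent$criteria, "PP3_supporting")

  # deterministic and idempotent
  cls2 <- assign_criteria(a, v, m)
  expect_equal(tidy(cls), tidy(cls2))
})

test_that("criterion strength is monotone in residual fraction", {
  m <- rpe65_model(with_sequences = FALSE)
  a <- rpe65_assays(m)[1, ]
  v <- rpe65_variants()
  strength <- function(wt) {
    x <- a
    x$wt_pct <- wt
    x$aberrant_pct <- 100 - wt
    if (wt == 100) x$aberrant[[1]] <- x$aberrant[[1]][0, ]
    crit <- assign_criteria(x, v, m)$criteria
    if (grepl("PVS1_very_strong", crit)) 2L
    else if (grepl("PVS1_strong", crit)) 1L else 0L
  }
  wt_grid <- c(0, 1, 4.9, 5, 10, 19, 20, 60, 99)
  s <- vapply(wt_grid, strength, integer(1))
  expect_true(all(diff(s) <= 0L))
})

test_that("inconsistent assays are rejected, inconsistency is flagged on read", {
  m <- rpe65_model(with_sequences = FALSE)
  a <- rpe65_assays(m)
  v <- rpe65_variants()
  # the published table itself contains exactly one arithmetic inconsistency
  expect_equal(a$c_notation[!a$consistent], "c.701G>A")
  bad <- a[a$c_notation == "c.713C>G", ]
  bad$wt_pct <- 100
  expect_error(assign_criteria(bad, v, m), "inconsistent")
})

test_that("baseline adjustment flags constitutive splice species", {
  m <- rpe65_model(with_sequences = FALSE)
  a <- rpe65_assays(m)
  a$construct <- assign_construct(a$c_notation, m,
                                  hint = rep(NA_character_, nrow(a)))
  adj <- baseline_adjust(a, m, tolerance = 10)

  # an exon-7 skip at 39% in a WT-3 assay is the constitutive baseline
  wt3 <- a[a$c_notation == "c.644-9T>G", ]   # exon 7 skip at 62%
  wt3$aberrant[[1]]$fraction[1] <- 39
  adj1 <- baseline_adjust(wt3, m, tolerance = 10)
  expect_true(adj1$aberrant[[1]]$baseline_consistent[1])

  # the same species at 92% is a real effect
  strong <- adj$aberrant[[which(a$c_notation == "c.713C>G")]]
  expect_false(strong$baseline_consistent[1])

  # constructs without a stated baseline are untouched apart from the flag
  wt2 <- adj$aberrant[[which(a$c_notation == "c.294C>A")]]
  expect_true(all(!wt2$baseline_consistent))
})

test_that("cohort summaries count bins, criteria and classes", {
  m <- rpe65_model(with_sequences = FALSE)
  a <- rpe65_assays(m)
  v <- rpe65_variants()
  cls <- assign_criteria(a, v, m)
  sm <- summarize_cohort(cls)
  expect_equal(sm$n, 59L)
  expect_equal(sm$class_P, sm$n_pvs1_very_strong)

  single <- assign_criteria(a[a$wt_pct == 0, ][1, ], v, m)
  sm1 <- summarize_cohort(single)
  expect_equal(sm1$bin_none, 1L)
  expect_equal(sm1$n, 1L)

  expect_equal(glance(cls), sm)
  td <- tidy(cls)
  expect_true(all(c("c_notation", "bin", "criteria", "final_class") %in%
                    names(td)))
})
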