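test_that("the candidate table reads with canonical types and counts", {
  v <- rpe65_variants()
  expect_equal(nrow(v), 73L)
  expect_s3_class(v$acmg_aug2023, "ordered")
  expect_true(all(v$acceptor_gain >= 0 & v$acceptor_gain <= 1))
  expect_true(all(abs(v$pos_donor_loss) < 10000))
})

test_path_fixture <- function() {
  system.file("extdata", "rpe65_variants_table1.tsv", package = "minisplice")
}

test_that("schema problems are reported precisely", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  v <- readr::read_tsv(test_path_fixture(), col_types = readr::cols(.default = "c"))
  readr::write_tsv(v[0, ], tmp)
  expect_equal(nrow(read_variant_table(tmp)), 0L)  # header only -> empty

  readr::write_tsv(dplyr::select(v, -"donor_loss"), tmp)
  expect_error(read_variant_table(tmp), "donor_loss")

  v2 <- v
  v2$acceptor_gain[3] <- "high"
  readr::write_tsv(v2, tmp)
  expect_error(read_variant_table(tmp), "row 3")
})

test_that("duplicate submissions merge with max-severity class resolution", {
  v <- rpe65_variants()[1:3, ]
  dup <- v[1, ]
  dup$source <- "LOVD"
  dup$acmg_aug2023 <- factor("LB", levels = c("B", "LB", "VUS", "LP", "P"),
                             ordered = TRUE)
  merged <- dedup_variants(dplyr::bind_rows(v, dup))
  expect_equal(nrow(merged), 3L)
  expect_equal(merged$source[merged$c_notation == v$c_notation[1]], "both")
  # VUS (more severe) retained over LB
  expect_equal(as.character(
    merged$acmg_aug2023[merged$c_notation == v$c_notation[1]]), "VUS")
  # idempotent on an already-unique table
  expect_equal(dedup_variants(v), v)
})

test_that("selection applies score, window and prior-class rules", {
  v <- rpe65_variants()
  s <- spliceai_select(v)
  # the packaged table is the post-selection set: everything passes
  expect_true(all(s$selected))

  r <- s[s$c_notation == "c.267C>T", ]
  expect_true(r$selected)  # acceptor loss 0.15 at 21 bp

  # a strong score whose predicted site is outside the window does not count
  far <- v[1, ]
  far[c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")] <-
    list(0.31, 0.05, 0.0, 0.0)
  far[paste0("pos_", c("acceptor_gain", "acceptor_loss", "donor_gain",
                       "donor_loss"))] <- list(-6000, 10, 10, 10)
  expect_equal(spliceai_select(far)$reject_reason, "outside_window")

  weak <- far
  weak[c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")] <-
    list(0.05, 0.05, 0.05, 0.05)
  expect_equal(spliceai_select(weak)$reject_reason,
               "no_score_above_threshold")

  hot <- v[1, ]
  hot$acmg_aug2023 <- factor("P", levels = c("B", "LB", "VUS", "LP", "P"),
                             ordered = TRUE)
  expect_equal(spliceai_select(hot)$reject_reason, "class_too_high")

  # boundary: the default comparison is inclusive, >0.1 strictness drops
  # exact-0.10 rows
  ten <- v[v$c_notation == "c.1040G>T", ]  # best in-window score is 0.10/0.11
  expect_true(spliceai_select(ten)$selected)
})

test_that("selection partitions the input and is monotone in threshold", {
  v <- rpe65_variants()
  s1 <- spliceai_select(v, score_threshold = 0.1)
  expect_equal(sum(s1$selected) + sum(!is.na(s1$reject_reason)), nrow(v))
  sel_prev <- s1$c_notation[s1$selected]
  for (thr in c(0.2, 0.3, 0.5, 0.8)) {
    sel <- spliceai_select(v, score_threshold = thr)
    keep <- sel$c_notation[sel$selected]
    expect_true(all(keep %in% sel_prev))
    sel_prev <- keep
  }
  s2 <- spliceai_select(v, score_threshold = 0.2)
  expect_lt(sum(s2$selected), sum(s1$selected))
})

test_that("highest score picks the max of the four deltas", {
  v <- rpe65_variants()
  expect_equal(highest_score(v[v$c_notation == "c.1334A>G", ]), 0.93)
  expect_equal(highest_score(v[v$c_notation == "c.726-3C>A", ]), 0.81)
  zero <- v[1, ]
  zero[c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")] <-
    list(0, 0, 0, 0)
  expect_equal(highest_score(zero), 0)
})
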