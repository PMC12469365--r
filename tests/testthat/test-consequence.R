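test_that("published frameshift consequences reproduce on the packaged CDS", {
  m <- rpe65_model()
  cases <- list(
    list(ev = exon_skip(7), p = "p.Asp215Valfs*4"),
    list(ev = exon_skip(c(6, 7)), p = "p.Val166Phefs*18"),
    list(ev = exon_skip(c(7, 8)), p = "p.Asp215Glyfs*7"),
    list(ev = exon_skip(10), p = "p.Phe334Leufs*7"),
    list(ev = exon_skip(12), p = "p.Phe416Leufs*2"),
    list(ev = exon_elongation("1339-2", "1339-1"), p = "p.Leu447Serfs*5"))
  for (cs in cases) {
    rep <- protein_consequence(cs$ev, m)
    expect_equal(rep$p_notation, cs$p)
    expect_equal(rep$frame, "frameshift")
  }
  # frameshift stops before exon 10, so the compound skip shares the call
  expect_equal(protein_consequence(splice_events(exon_skip(7),
                                                 exon_skip(10)), m)$p_notation,
               "p.Asp215Valfs*4")
})

test_that("in-frame and silent consequences are named correctly", {
  m <- rpe65_model()
  expect_equal(protein_consequence(splice_events(), m)$p_notation, "p.(=)")
  rep <- protein_consequence(exon_skip(4), m)
  expect_equal(rep$frame, "in_frame")
  expect_equal(rep$delta_len, -108L)
  expect_match(rep$p_notation, "^p\\..*del")
  expect_error(
    protein_consequence(exon_skip(7), rpe65_model(with_sequences = FALSE)),
    "CDS sequence")
})

test_that("a micro-CDS frameshift matches the brute-force stop count", {
  # 30-codon CDS, 4-nt deletion at an exon boundary; the expected fs*N is
  # computed by an independent naive translation of the mutated string
  set.seed(9)
  non_stop <- names(ORACLE_CODONS)[ORACLE_CODONS != "*"]
  repeat {
    cds <- paste0("ATG", paste(sample(non_stop, 28L, TRUE), collapse = ""),
                  "TAA")
    if (any(oracle_translate(cds)[1:29] == "*")) next
    mut <- oracle_apply(list(cds_sequence = cds),
                        list(list(del = c(46, 49))))
    orc <- oracle_protein(cds, mut)
    if (!is.na(orc$fs_n) && orc$fs_n >= 2L) break
  }
  model <- transcript_model(
    tibble::tibble(exon = 1:2, c_start = c(1L, 46L), c_end = c(45L, 90L)),
    cds_sequence = cds)
  rep <- protein_consequence(exon_truncation("46", "49", "5prime"), model)
  expect_equal(rep$frame, "frameshift")
  expect_match(rep$p_notation, paste0("fs\\*", orc$fs_n, "$"))
  expect_equal(rep$first_affected_codon, codon_index(46L))
})

test_that("frameshifts without a downstream stop report fs*?", {
  # all-GCA tail: removing one nt shifts into a stop-free frame
  cds <- paste0("ATG", paste(rep("GCA", 28), collapse = ""), "TAA")
  model <- transcript_model(
    tibble::tibble(exon = 1:2, c_start = c(1L, 46L), c_end = c(45L, 90L)),
    cds_sequence = cds)
  rep <- protein_consequence(exon_truncation("46", "46", "5prime"), model)
  expect_equal(rep$frame, "frameshift")
  expect_match(rep$p_notation, "fs\\*\\?$")
})

test_that("random event sets agree with the brute-force oracle", {
  model <- toy_model()
  set.seed(42)
  frame_ok <- logical(200)
  got <- want <- character()
  for (rep_i in 1:200) {
    ev <- random_events(model)
    delta <- delta_length(ev, model)
    res <- protein_consequence(ev, model)
    # frame call equals the mod-3 oracle
    frame_ok[rep_i] <- (res$frame == "in_frame") == (delta %% 3L == 0L)
    # protein call matches naive string surgery + naive translation
    mut <- oracle_apply(model, oracle_edits(ev, model))
    orc <- oracle_protein(model$cds_sequence, mut)
    if (identical(orc$p, "p.(=)")) {
      got <- c(got, res$p_notation)
      want <- c(want, "p.(=)")
    } else if (res$frame == "frameshift") {
      if (!is.na(orc$fs_n) && orc$fs_n > 1L) {
        got <- c(got, res$p_notation)
        want <- c(want, sprintf(
          "p.%s%d%sfs*%d", AA3_ORACLE[[orc$ref_aa]], orc$first_changed,
          AA3_ORACLE[[orc$mut_aa]], orc$fs_n))
      }
    } else if (grepl("del", res$p_notation)) {
      # in-frame deletions/delins: the named first residue equals the
      # oracle's first differing residue
      m1 <- regmatches(res$p_notation,
                       regexec("^p\\.[A-Za-z]{3}([0-9]+)",
                               res$p_notation))[[1]]
      got <- c(got, m1[2])
      want <- c(want, as.character(orc$first_changed))
    }
  }
  expect_true(all(frame_ok))
  expect_gt(length(got), 80)
  expect_equal(got, want)
})
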