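test_that("event constructors validate their payloads", {
  expect_error(pseudoexon("644", "725"), "intronic")
  expect_error(exon_truncation("643+5", "644"), "exonic")
  m <- rpe65_model(with_sequences = FALSE)
  expect_error(validate_events(exon_skip(99), m), "absent")
  expect_error(validate_events(pseudoexon("644-10", "999-10"), m),
               "single intron")
  expect_silent(validate_events(pseudoexon("1129-293", "1129-218"), m))
})

test_that("r. serialization covers deletions, insertions and compounds", {
  m <- rpe65_model(with_sequences = FALSE)
  expect_equal(rna_notation(exon_skip(7), m), "r.644_725del")
  expect_equal(rna_notation(splice_events(), m), "r.=")
  expect_equal(rna_notation(exon_elongation("1339-2", "1339-1"), m),
               "r.1338_1339ins1339-2_1339-1")
  expect_equal(rna_notation(exon_skip(c(6, 7)), m), "r.496_725del")
  two <- splice_events(exon_skip(7), exon_skip(10))
  expect_equal(rna_notation(two, m, dialect = "compound"),
               "r.644_725del_999_1128del")
  expect_equal(rna_notation(two, m), "r.[644_725del;999_1128del]")
  expect_equal(rna_notation(intron_retention(4), m),
               "r.353_354ins353+1_354-1")
  expect_equal(r_allele(list(exon_skip(7)), m, wt = TRUE),
               "r.[644_725del,=]")
  expect_equal(r_allele(list(splice_events()), m), "r.=")
})

test_that("every published r. string round-trips through the parser", {
  a <- rpe65_assays(rpe65_model(with_sequences = FALSE))
  for (s in a$r_notation) {
    norm <- gsub("\\s+", "", s)
    expect_equal(format_r_notation(parse_r_notation(s)), norm)
  }
})

test_that("length deltas use closed-interval arithmetic", {
  m <- rpe65_model()
  expect_equal(delta_length(exon_skip(7), m), -82L)
  expect_equal(delta_length(pseudoexon("1129-293", "1129-218"), m), 76L)
  expect_equal(delta_length(exon_skip(4), m), -108L)
  expect_equal(delta_length(exon_skip(4), m) %% 3L, 0L)  # in-frame
  expect_equal(delta_length(exon_elongation("1339-2", "1339-1"), m), 2L)
  # intron retention needs the intron length from the model
  expect_equal(delta_length(intron_retention(7), m),
               nchar(m$introns[["7"]]))
  expect_error(delta_length(intron_retention(7),
                            rpe65_model(with_sequences = FALSE)),
               "intron")
  # parsed-species deltas match
  sp <- parse_r_notation("r.1338_1339ins1339-2_1339-1")[[1]]
  expect_equal(r_species_delta(sp), 2L)
  expect_equal(r_species_delta(parse_r_notation("r.644_725del")[[1]]), -82L)
  expect_equal(r_species_delta("="), 0L)
})

test_that("first affected codon is the coordinate lower bound", {
  m <- rpe65_model(with_sequences = FALSE)
  expect_equal(first_affected_codon(exon_skip(7), m), 215L)
  expect_equal(first_affected_codon(exon_skip(12), m), 415L)
  expect_equal(first_affected_codon(exon_skip(4), m), 82L)
  expect_equal(first_affected_codon(exon_elongation("1339-2", "1339-1"), m),
               447L)
  expect_equal(first_affected_codon(intron_retention(4), m),
               codon_index(354L))
})

test_that("prose transcript identities parse into structured species", {
  m <- rpe65_model(with_sequences = FALSE)

  sp <- parse_identity("Exon 7 skipping (92%) and exon 7 + 10 skipping (1%)",
                       93, m)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$fraction, c(92, 1))
  expect_equal(sp$events[[1]]$exons[[1]], 7L)
  expect_equal(sp$events[[2]]$exons[[1]], c(7L, 10L))

  sp <- parse_identity(paste0("Exon 6 and 7 skipping (83%), exon 6 skipping",
                              " (8%), exon 7 skipping (3%), and unidentified",
                              " transcript (6%)"), 100, m)
  expect_equal(sp$fraction, c(83, 8, 3, 6))
  expect_equal(sp$events[[1]]$exons[[1]], c(6L, 7L))
  expect_true(sp$unidentified[4])

  # species named without a percentage absorbs the remainder
  sp <- parse_identity("Exon 7 skipping", 100, m)
  expect_equal(sp$fraction, 100)

  sp <- parse_identity("Exon 12 skipping (3% artefact)", 100, m)
  expect_equal(sp$fraction, c(97, 3))
  expect_equal(sp$artefact, c(FALSE, TRUE))

  sp <- parse_identity("two unidentified transcripts (8% and 6%, resp.)",
                       14, m)
  expect_equal(sp$fraction, c(8, 6))
  expect_true(all(sp$unidentified))

  sp <- parse_identity("5 basepair 3′ truncation of exon 12 (87%) (13% is a PE identified as artefact)",
                       100, m)
  expect_equal(sp$fraction, c(87, 13))
  expect_equal(sp$events[[1]]$kind, "exon_truncation")
  expect_equal(sp$events[[1]]$start, "1334")
  expect_equal(sp$events[[1]]$end, "1338")

  sp <- parse_identity("Exon 13 elongation until 1450 + 48 (15%)", 51, m)
  expect_equal(sp$events[[1]]$kind, "exon_elongation")
  expect_equal(delta_length(sp$events[[1]], m), 48L)

  sp <- parse_identity("intron 7 retention (3%)", 91, m)
  expect_equal(sp$events[[1]]$kind, "intron_retention")

  # empty identity (splice-silent row)
  expect_equal(nrow(parse_identity(NA_character_, 0, m)), 0L)
})
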