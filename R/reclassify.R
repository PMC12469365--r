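#' Parse an aberrant-transcript identity description
#'
#' Assay result tables describe each lane's aberrant products in prose, e.g.
#' `"Exon 7 skipping (92%) and exon 7 + 10 skipping (1%)"` or
#' `"2 basepair 5' elongation of exon 13 (34%), exon 12 + 13 skipping (41%)"`.
#' This parser turns such strings into structured species. Recognized forms:
#' exon skipping (single, `"exon 6 and 7"`, `"exon 7 + 10"` and
#' `"exon 3 + 4 + 5"` compounds), intron retention, N-basepair 5'/3'
#' truncations and elongations of an exon, elongation `"until <pos> + k"`,
#' unidentified transcripts (including `"two unidentified transcripts
#' (8% and 6%, resp.)"`), and parenthesized artefact fractions. A species
#' without an explicit percentage absorbs the remaining aberrant fraction.
#'
#' @param text Identity string (may be empty/NA for splice-silent rows).
#' @param total_aberrant Total aberrant percentage for the lane.
#' @param model A `transcript_model` (used to anchor truncation/elongation
#'   intervals at exon boundaries).
#' @return A tibble of species: `events` (list-column of event tibbles),
#'   `fraction`, `artefact`, `unidentified`, `description`.
#' @export
parse_identity <- function(text, total_aberrant, model) {
  empty <- tibble::tibble(events = list(), fraction = numeric(),
                          artefact = logical(), unidentified = logical(),
                          description = character())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  text <- normalize_dashes(gsub("′", "'", text))
  chunks <- strsplit(text, "(?<=\\))[,.]?\\s*(?:and\\s+)?", perl = TRUE)[[1]]
  chunks <- trimws(sub("^[,.]?\\s*(and\\s+)?", "", chunks))
  chunks <- chunks[nzchar(chunks)]
  rows <- purrr::map(chunks, parse_identity_chunk, model = model)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  # a species printed without a percentage covers the unlabelled remainder
  open <- is.na(out$fraction)
  if (any(open)) {
    rest <- total_aberrant - sum(out$fraction, na.rm = TRUE)
    out$fraction[open] <- rest / sum(open)
  }
  out
}

parse_identity_chunk <- function(chunk, model) {
  low <- tolower(chunk)
  pcts <- as.numeric(unlist(regmatches(chunk,
                                       gregexpr("[0-9]+(?=%)", chunk, perl = TRUE))))
  species <- function(events, fraction, artefact = FALSE,
                      unidentified = FALSE) {
    tibble::tibble(events = list(events), fraction = fraction,
                   artefact = artefact, unidentified = unidentified,
                   description = chunk)
  }
  if (grepl("artefact", low)) {
    art <- species(splice_events(), if (length(pcts)) pcts[1] else NA_real_,
                   artefact = TRUE)
    # "Exon 12 skipping (3% artefact)": a named species whose only
    # percentage is the artefact share - emit both species
    main_text <- trimws(sub("\\(.*$", "", chunk))
    if (nzchar(main_text)) {
      main <- parse_identity_chunk(main_text, model)
      return(dplyr::bind_rows(main, art))
    }
    return(art)
  }
  if (grepl("unidentified", low)) {
    k <- max(1L, length(pcts))
    fr <- if (length(pcts)) pcts else NA_real_
    return(dplyr::bind_rows(lapply(seq_len(k), function(i)
      species(splice_events(), fr[min(i, length(fr))],
              unidentified = TRUE))))
  }
  fraction <- if (length(pcts)) pcts[1] else NA_real_
  if (grepl("intron\\s+[0-9]+\\s+retention", low)) {
    k <- as.integer(sub(".*intron\\s+([0-9]+)\\s+retention.*", "\\1", low))
    return(species(intron_retention(k), fraction))
  }
  if (grepl("skipping", low)) {
    head <- sub("skipping.*$", "", low)
    ex <- as.integer(unlist(regmatches(head, gregexpr("[0-9]+", head))))
    return(species(exon_skip(ex), fraction))
  }
  m <- regmatches(low, regexec(
    "([0-9]+)\\s*(?:basepair|bp)\\s*([35])'?\\s*(truncation|elongation)\\s*of\\s*exon\\s*([0-9]+)", low))[[1]]
  if (length(m) > 0L) {
    nbp <- as.integer(m[2]); side <- m[3]; what <- m[4]
    exon <- as.integer(m[5])
    ex <- model$exons
    a <- ex$c_start[ex$exon == exon]; b <- ex$c_end[ex$exon == exon]
    ev <- if (what == "truncation") {
      if (side == "3") {
        exon_truncation(format_c_position(b - nbp + 1L), format_c_position(b),
                        side = "3prime")
      } else {
        exon_truncation(format_c_position(a), format_c_position(a + nbp - 1L),
                        side = "5prime")
      }
    } else {
      if (side == "5") {
        exon_elongation(format_c_position(a, -nbp), format_c_position(a, -1L),
                        side = "5prime")
      } else {
        exon_elongation(format_c_position(b, 1L), format_c_position(b, nbp),
                        side = "3prime")
      }
    }
    return(species(ev, fraction))
  }
  m <- regmatches(low, regexec(
    "exon\\s*([0-9]+)\\s*elongation\\s*until\\s*([0-9]+)\\s*\\+\\s*([0-9]+)", low))[[1]]
  if (length(m) > 0L) {
    base <- as.integer(m[3]); k <- as.integer(m[4])
    return(species(exon_elongation(format_c_position(base, 1L),
                                   format_c_position(base, k),
                                   side = "3prime"), fraction))
  }
  if (grepl("pseudo-?exon|\\bpe\\b", low)) {
    return(species(splice_events(), fraction, artefact = FALSE,
                   unidentified = TRUE))
  }
  stop("unrecognized transcript identity: ", sQuote(chunk), call. = FALSE)
}

#' Read a quantified splice-assay table
#'
#' Reads a TSV in the assay-results dialect: one row per tested variant with
#' its prior classifications, highest SpliceAI delta score, adapted protein
#' and RNA (r.) annotations, the percentage of residual wild-type
#' transcript, the total aberrant percentage, and the prose identity of the
#' aberrant species. Percent signs are stripped; identity strings are parsed
#' into structured species via [parse_identity()]; a `consistent` flag marks
#' rows whose wild-type plus per-species fractions total 100 within
#' `tolerance` (assay tables are rounded to whole percent and occasionally
#' disagree by more).
#'
#' @param path TSV path.
#' @param model A `transcript_model`.
#' @param tolerance Allowed deviation of the fraction total from 100
#'   (default 1).
#' @return A tibble with one row per assay; `aberrant` is a list-column of
#'   species tibbles.
#' @export
read_assay_table <- function(path, model, tolerance = 1) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("c_notation", "r_notation", "wt_pct", "aberrant_pct", "identity")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("assay table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pct <- function(x) suppressWarnings(as.numeric(sub("%", "", x)))
  out <- raw |>
    dplyr::mutate(
      c_notation = normalize_dashes(.data$c_notation),
      wt_pct = pct(.data$wt_pct),
      aberrant_pct = pct(.data$aberrant_pct),
      highest_spliceai = if ("highest_spliceai" %in% names(raw))
        as.numeric(.data$highest_spliceai) else NA_real_,
      dplyr::across(dplyr::any_of(c("acmg_aug2023", "acmg_oct2024")),
                    ~ factor(.x, levels = ACMG_LEVELS, ordered = TRUE)))
  if (any(is.na(out$wt_pct)) || any(out$wt_pct < 0 | out$wt_pct > 100)) {
    stop("wild-type percentages must be numbers in [0, 100]", call. = FALSE)
  }
  out$aberrant <- purrr::map2(out$identity, out$aberrant_pct,
                              parse_identity, model = model)
  out$consistent <- purrr::map2_lgl(out$wt_pct, out$aberrant, function(w, ab) {
    abs(w + sum(ab$fraction) - 100) <= tolerance
  })
  out
}

#' Bin a residual wild-type fraction
#'
#' The decision variable of splice-assay reclassification is the percentage
#' of correctly spliced (wild-type) transcript remaining. Bins:
#' `none` (exactly 0), `sub5` (0 < x < 5), `low` (5 <= x < 20) and `high`
#' (x >= 20).
#'
#' @param wt_fraction Numeric vector in \[0, 100\].
#' @return Factor with levels `none`, `sub5`, `low`, `high`.
#' @export
bin_residual <- function(wt_fraction) {
  if (any(is.na(wt_fraction)) ||
      any(wt_fraction < 0 | wt_fraction > 100)) {
    stop("wild-type fractions must lie in [0, 100]", call. = FALSE)
  }
  lab <- ifelse(wt_fraction == 0, "none",
         ifelse(wt_fraction < 5, "sub5",
         ifelse(wt_fraction < 20, "low", "high")))
  factor(lab, levels = c("none", "sub5", "low", "high"))
}

#' Apply gene-specific splice-assay ACMG criteria
#'
#' Implements the RPE65-style ClinGen rule set driven by residual wild-type
#' transcript:
#'
#' * no residual wild-type transcript (bin `none`): PVS1 at very-strong
#'   strength; final class pathogenic (P).
#' * under 5% residual (bin `sub5`): PVS1 at strong strength; final class
#'   likely pathogenic (LP).
#' * 5% or more residual: no splice criterion; the prior class stands.
#' * 100% wild-type (splice-silent) and the variant is synonymous or a
#'   non-canonical splice-site variant: BP7 at strong strength (RNA
#'   evidence); final class benign (B) - splicing was the only plausible
#'   mechanism. Splice-silent *missense* variants keep their prior class,
#'   since a protein-level mechanism remains possible.
#' * PP3 (supporting, in-silico) is recorded for reporting when the highest
#'   SpliceAI delta score is at least `pp3_threshold`; it never changes the
#'   class by itself.
#'
#' @param assays Assay tibble from [read_assay_table()] (needs `wt_pct`,
#'   `aberrant`, `acmg_aug2023`, `highest_spliceai`).
#' @param variants Optional variant tibble (adds `variant_type` and
#'   `construct` by `c_notation`); if absent, `variant_type` must already be
#'   a column of `assays`.
#' @param model A `transcript_model` (for site classification).
#' @param pp3_threshold SpliceAI score at which PP3 is noted (default 0.2).
#' @return A tibble of class `msa_classification`: per variant the residual
#'   bin, site class, criteria, final class and rationale.
#' @export
assign_criteria <- function(assays, variants = NULL, model,
                            pp3_threshold = 0.2) {
  if (!is.null(variants)) {
    assays <- dplyr::left_join(
      assays,
      dplyr::select(variants, dplyr::all_of(c("c_notation", "variant_type")),
                    dplyr::any_of("construct")),
      by = "c_notation")
  }
  if (!"variant_type" %in% names(assays)) {
    stop("variant_type unavailable: supply a variant table", call. = FALSE)
  }
  bad <- assays$wt_pct == 100 &
    purrr::map_int(assays$aberrant, nrow) > 0L
  if (any(bad)) {
    stop("inconsistent assay: aberrant species listed but 100% wild-type (",
         paste(assays$c_notation[bad], collapse = ", "), ")", call. = FALSE)
  }
  out <- assays
  out$bin <- bin_residual(out$wt_pct)
  out$site_class <- classify_variant_site(out$c_notation, model)
  prior <- as.character(out$acmg_aug2023)
  res <- purrr::pmap(list(as.character(out$bin), out$variant_type, prior,
                          out$highest_spliceai),
                     function(bin, vtype, prior, score) {
    crit <- character()
    if (!is.na(score) && score >= pp3_threshold) crit <- "PP3_supporting"
    if (bin == "none") {
      crit <- c("PVS1_very_strong", crit)
      final <- "P"
      why <- "complete absence of wild-type transcript"
    } else if (bin == "sub5") {
      crit <- c("PVS1_strong", crit)
      final <- "LP"
      why <- "less than 5% residual wild-type transcript"
    } else if (bin %in% c("low", "high")) {
      final <- prior
      why <- "residual wild-type transcript >= 5%; splice evidence not class-changing"
    }
    list(criteria = paste(crit, collapse = ";"), final_class = final,
         rationale = why)
  })
  out$criteria <- purrr::map_chr(res, "criteria")
  out$final_class <- purrr::map_chr(res, "final_class")
  out$rationale <- purrr::map_chr(res, "rationale")
  silent <- out$wt_pct == 100
  bp7 <- silent & out$variant_type %in% c("Synonymous", "NCSS")
  out$criteria[bp7] <- vapply(out$criteria[bp7], function(x) {
    paste(c("BP7_strong", setdiff(strsplit(x, ";")[[1]], "")),
          collapse = ";")
  }, character(1))
  out$final_class[bp7] <- "B"
  out$rationale[bp7] <-
    "no effect on splicing and no other plausible mechanism (BP7-strong RNA)"
  out$rationale[silent & !bp7] <-
    "no effect on splicing; non-splice mechanism still possible"
  class(out) <- c("msa_classification", class(out))
  out
}

#' Flag aberrant species explained by the construct's baseline splicing
#'
#' Wild-type minigene constructs can themselves produce aberrant species
#' (naturally occurring alternative splicing). In the optional
#' baseline-adjusted mode, an observed species whose events equal a baseline
#' species and whose fraction is within `tolerance` percentage points of the
#' baseline fraction is flagged `baseline_consistent`; callers may then
#' exclude it from the effect call. The default pipeline does not apply
#' this adjustment (assay tables report raw percentages).
#'
#' @param assays Assay tibble with `aberrant` list-column and `construct`.
#' @param model A `transcript_model` with constructs.
#' @param tolerance Fraction tolerance in percentage points (default 10).
#' @return `assays` with a `baseline_consistent` logical column added to
#'   each species tibble.
#' @export
baseline_adjust <- function(assays, model, tolerance = 10) {
  assays$aberrant <- purrr::map2(assays$aberrant, assays$construct,
                                 function(ab, cname) {
    if (nrow(ab) == 0L) {
      ab$baseline_consistent <- logical(0)
      return(ab)
    }
    cs <- model$constructs[[cname]]
    base <- if (is.null(cs)) list() else cs$baseline
    ab$baseline_consistent <- vapply(seq_len(nrow(ab)), function(i) {
      any(vapply(base, function(b) {
        same <- isTRUE(all.equal(ab$events[[i]], b$events,
                                 check.attributes = FALSE))
        same && abs(ab$fraction[i] - b$fraction) <= tolerance
      }, logical(1)))
    }, logical(1))
    ab
  })
  assays
}

#' Summarise a classified cohort
#'
#' @param assignments An `msa_classification` tibble.
#' @return A one-row tibble: counts per residual bin, number of
#'   splice-silent rows (100% wild-type), counts per final class and per
#'   assigned criterion.
#' @export
summarize_cohort <- function(assignments) {
  stopifnot(nrow(assignments) >= 1L)
  bins <- table(assignments$bin)
  classes <- table(factor(assignments$final_class, levels = ACMG_LEVELS))
  crits <- unlist(strsplit(assignments$criteria, ";"))
  crits <- crits[nzchar(crits)]
  tibble::tibble(
    n = nrow(assignments),
    bin_none = as.integer(bins[["none"]]),
    bin_sub5 = as.integer(bins[["sub5"]]),
    bin_low = as.integer(bins[["low"]]),
    bin_high = as.integer(bins[["high"]]),
    n_no_effect = sum(assignments$wt_pct == 100),
    n_pvs1_very_strong = sum(crits == "PVS1_very_strong"),
    n_pvs1_strong = sum(crits == "PVS1_strong"),
    n_bp7_strong = sum(crits == "BP7_strong"),
    n_pp3_supporting = sum(crits == "PP3_supporting"),
    class_B = as.integer(classes[["B"]]),
    class_LB = as.integer(classes[["LB"]]),
    class_VUS = as.integer(classes[["VUS"]]),
    class_LP = as.integer(classes[["LP"]]),
    class_P = as.integer(classes[["P"]]))
}

#' @export
tidy.msa_classification <- function(x, ...) {
  tibble::as_tibble(dplyr::select(
    x, dplyr::any_of(c("c_notation", "variant_type", "construct", "wt_pct",
                       "bin", "site_class", "criteria", "final_class",
                       "rationale"))))
}

#' @export
glance.msa_classification <- function(x, ...) summarize_cohort(x)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
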