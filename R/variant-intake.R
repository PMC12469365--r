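ACMG_LEVELS <- c("B", "LB", "VUS", "LP", "P")

VARIANT_REQUIRED <- c("c_notation", "variant_type", "acmg_aug2023", "source",
                      "acceptor_gain", "acceptor_loss", "donor_gain",
                      "donor_loss", "pos_acceptor_gain", "pos_acceptor_loss",
                      "pos_donor_gain", "pos_donor_loss")

SCORE_COLS <- c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")
POS_COLS <- paste0("pos_", SCORE_COLS)

#' Read a LOVD/ClinVar-style variant table
#'
#' Reads a TSV with one row per candidate variant: HGVS c./p. notation,
#' variant type, ACMG classifications at two timepoints, source database,
#' the assigned wild-type minigene construct (optional / blank allowed), the
#' four SpliceAI delta scores (acceptor gain/loss, donor gain/loss) and the
#' four nucleotide distances from the variant to each predicted gain/loss
#' site. Header matching is case- and punctuation-insensitive, so both the
#' package's canonical snake_case names and table headings like
#' `"c. Notation"` or `"Acceptor Gain"` work. Dash glyphs in variant tokens
#' are normalized.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return A tibble with canonical columns; ACMG columns are ordered factors
#'   (`B < LB < VUS < LP < P`).
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- canonical_variant_names(names(raw))
  missing <- setdiff(VARIANT_REQUIRED, names(raw))
  if (length(missing) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"construct" %in% names(raw)) raw$construct <- NA_character_
  if (!"p_notation" %in% names(raw)) raw$p_notation <- NA_character_
  if (!"acmg_oct2024" %in% names(raw)) raw$acmg_oct2024 <- NA_character_
  out <- raw |>
    dplyr::mutate(
      c_notation = normalize_dashes(.data$c_notation),
      dplyr::across(dplyr::all_of(c("acmg_aug2023", "acmg_oct2024")),
                    ~ factor(.x, levels = ACMG_LEVELS, ordered = TRUE)))
  for (col in c(SCORE_COLS, POS_COLS)) {
    val <- suppressWarnings(as.numeric(normalize_dashes(out[[col]])))
    bad <- which(is.na(val) & !is.na(out[[col]]) & out[[col]] != "")
    if (length(bad) > 0L) {
      stop("unparseable value in column ", sQuote(col), " at row ",
           bad[1], ": ", sQuote(out[[col]][bad[1]]), call. = FALSE)
    }
    out[[col]] <- val
  }
  if (any(stats::na.omit(unlist(out[SCORE_COLS])) < 0) ||
      any(stats::na.omit(unlist(out[SCORE_COLS])) > 1)) {
    stop("SpliceAI delta scores must lie in [0, 1]", call. = FALSE)
  }
  dplyr::select(out, dplyr::any_of(c(
    "c_notation", "p_notation", "variant_type", "acmg_aug2023",
    "acmg_oct2024", "source", "construct")),
    dplyr::all_of(c(SCORE_COLS, POS_COLS)))
}

canonical_variant_names <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  lookup <- c(
    cnotation = "c_notation", pnotation = "p_notation",
    varianttype = "variant_type",
    acmgclassificationaugust2023 = "acmg_aug2023",
    acmgaug2023 = "acmg_aug2023",
    acmgclassificationoctober2024 = "acmg_oct2024",
    acmgoct2024 = "acmg_oct2024",
    source = "source", wildtypeconstruct = "construct",
    construct = "construct",
    acceptorgain = "acceptor_gain", acceptorloss = "acceptor_loss",
    donorgain = "donor_gain", donorloss = "donor_loss",
    posacceptorgain = "pos_acceptor_gain",
    posacceptorloss = "pos_acceptor_loss",
    posdonorgain = "pos_donor_gain", posdonorloss = "pos_donor_loss",
    positiontopredictedgainlossacceptorgain = "pos_acceptor_gain")
  mapped <- unname(lookup[key])
  # a second occurrence of a score column name is its position column
  out <- ifelse(is.na(mapped), x, mapped)
  for (sc in SCORE_COLS) {
    hits <- which(out == sc)
    if (length(hits) == 2L) out[hits[2]] <- paste0("pos_", sc)
  }
  out
}

#' Merge duplicate variant submissions across source databases
#'
#' Rows with an identical (normalized) `c_notation` are merged into one
#' record. When the duplicates come from different databases the merged
#' `source` is `"both"`; conflicting ACMG classes resolve to the more severe
#' one (closer to P), which is conservative for the downstream
#' prior-class filter. Scores and remaining fields are taken from the first
#' occurrence. Idempotent.
#'
#' @param variants A variant tibble from [read_variant_table()].
#' @return A deduplicated tibble in first-occurrence order.
#' @export
dedup_variants <- function(variants) {
  variants |>
    dplyr::group_by(.data$c_notation) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("acmg_aug2023", "acmg_oct2024")),
                    ~ if (all(is.na(.x))) .x[1] else max(.x, na.rm = TRUE)),
      source = if (dplyr::n_distinct(.data$source) > 1L) "both"
               else .data$source[1],
      dplyr::across(!dplyr::any_of(c("acmg_aug2023", "acmg_oct2024",
                                     "source")), dplyr::first),
      .groups = "drop") |>
    dplyr::arrange(match(.data$c_notation, unique(variants$c_notation))) |>
    dplyr::relocate(dplyr::any_of(names(variants)))
}

#' Highest SpliceAI delta score per variant
#'
#' @param variants A variant tibble.
#' @return Numeric vector: the maximum of the four delta scores per row.
#' @export
highest_score <- function(variants) {
  do.call(pmax, c(unname(as.list(variants[SCORE_COLS])), na.rm = TRUE))
}

#' Apply the splice-candidate selection filter
#'
#' A variant is taken forward when (a) its prior ACMG class (first-timepoint
#' column) is at most `max_prior_class`, and (b) at least one of the four
#' SpliceAI delta scores reaches `score_threshold` *and* that same
#' component's predicted gain/loss site lies within `window_bp` of the
#' variant. A high score whose predicted site falls beyond the window does
#' not qualify. Rejected rows carry a machine-readable reason.
#'
#' @param variants A variant tibble.
#' @param score_threshold Minimum delta score (default 0.1).
#' @param window_bp Analysis window around the variant (default 5000 bp
#'   up- and downstream).
#' @param max_prior_class Most severe admissible prior class (default
#'   `"VUS"`).
#' @param inclusive Compare scores with `>=` (default) rather than `>`.
#' @return The input tibble with logical `selected` and character
#'   `reject_reason` (`NA` for selected rows; otherwise one of
#'   `"class_too_high"`, `"no_score_above_threshold"`, `"outside_window"`).
#' @export
spliceai_select <- function(variants, score_threshold = 0.1,
                            window_bp = 5000, max_prior_class = "VUS",
                            inclusive = TRUE) {
  stopifnot(score_threshold >= 0, score_threshold <= 1, window_bp > 0)
  max_cls <- factor(max_prior_class, levels = ACMG_LEVELS, ordered = TRUE)
  scores <- as.matrix(variants[SCORE_COLS])
  posn <- abs(as.matrix(variants[POS_COLS]))
  pass_score <- if (inclusive) scores >= score_threshold
                else scores > score_threshold
  pass_score[is.na(pass_score)] <- FALSE
  in_window <- posn <= window_bp
  in_window[is.na(in_window)] <- FALSE
  any_score <- rowSums(pass_score) > 0L
  any_hit <- rowSums(pass_score & in_window) > 0L
  class_ok <- !is.na(variants$acmg_aug2023) & variants$acmg_aug2023 <= max_cls
  reason <- dplyr::case_when(
    !class_ok ~ "class_too_high",
    !any_score ~ "no_score_above_threshold",
    !any_hit ~ "outside_window",
    .default = NA_character_)
  dplyr::mutate(variants, selected = is.na(reason), reject_reason = reason)
}

#' Summarise a selection run
#'
#' @param selected Output of [spliceai_select()].
#' @return One-row tibble of counts: total, selected, and one column per
#'   rejection reason.
#' @export
selection_summary <- function(selected) {
  reasons <- c("class_too_high", "no_score_above_threshold",
               "outside_window")
  counts <- vapply(reasons, function(r)
    sum(selected$reject_reason == r, na.rm = TRUE), integer(1))
  tibble::tibble(n_total = nrow(selected),
                 n_selected = sum(selected$selected),
                 !!!as.list(counts))
}
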