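#' Build a transcript model in coding coordinates
#'
#' A transcript model is the coordinate backbone of the package: an ordered
#' exon map in HGVS c. space (closed, 1-based intervals that tile the CDS
#' without gaps; introns exist only between consecutive exons), an optional
#' CDS sequence for protein-level consequence calls, optional intron
#' sequences (needed to translate insertions such as pseudo-exons), and the
#' minigene construct geometry used for fragment-size prediction.
#'
#' @param exons Data frame with columns `exon` (integer index), `c_start`,
#'   `c_end` (integer coding coordinates) and optionally `inferred`
#'   (logical provenance flag for boundaries not evidenced by data).
#' @param cds_sequence Optional single string (A/C/G/T) of length
#'   `max(exons$c_end)`; must start with ATG, end with a stop codon, and
#'   contain no internal in-frame stop.
#' @param introns Optional named list of intron sequences; names are the
#'   index of the upstream exon ("1" = intron between exons 1 and 2).
#' @param constructs List of [minigene_construct()] specifications.
#' @param gene_label Display label.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(exons, cds_sequence = NULL, introns = NULL,
                             constructs = list(), gene_label = "gene") {
  exons <- tibble::as_tibble(exons)
  stopifnot(all(c("exon", "c_start", "c_end") %in% names(exons)))
  if (!"inferred" %in% names(exons)) exons$inferred <- FALSE
  exons <- dplyr::arrange(exons, .data$exon)
  if (any(exons$c_end < exons$c_start)) {
    stop("exon with end before start", call. = FALSE)
  }
  if (exons$c_start[1] != 1L) {
    stop("first exon must start at c.1", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      !all(exons$c_start[-1] == exons$c_end[-nrow(exons)] + 1L)) {
    stop("exons must tile the coding sequence without gaps in c. space",
         call. = FALSE)
  }
  cds_length <- as.integer(max(exons$c_end))
  if (cds_length %% 3L != 0L) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  if (!is.null(cds_sequence)) {
    cds_sequence <- toupper(cds_sequence)
    if (nchar(cds_sequence) != cds_length) {
      stop("cds_sequence length (", nchar(cds_sequence),
           ") does not match the exon map (", cds_length, ")", call. = FALSE)
    }
    aa <- translate_nt(cds_sequence)
    if (aa[1] != "M" || aa[length(aa)] != "*" ||
        any(aa[-length(aa)] == "*")) {
      stop("cds_sequence must start with ATG, end with a stop codon, ",
           "and contain no internal in-frame stop", call. = FALSE)
    }
  }
  model <- structure(
    list(gene_label = gene_label, exons = exons, cds_length = cds_length,
         cds_sequence = cds_sequence, introns = introns,
         constructs = stats::setNames(
           constructs, vapply(constructs, `[[`, "", "name"))),
    class = "transcript_model")
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$gene_label, ": ", nrow(x$exons), " exons, CDS ",
      x$cds_length, " nt (", x$cds_length / 3L - 1L, " aa)",
      if (is.null(x$cds_sequence)) ", no sequence" else ", with sequence",
      ", ", length(x$constructs), " construct(s)\n", sep = "")
  invisible(x)
}

#' Specify a minigene construct
#'
#' A minigene construct clones a run of consecutive exons (with their
#' intervening introns) between two reporter flanks; RT-PCR primers sit in
#' the flanks, so every product size is `flank_5_len + flank_3_len` plus the
#' exonic content retained after splicing. `baseline` lists splice species
#' the *wild-type* construct produces constitutively (e.g. partial skipping
#' of a weakly defined exon), as `list(events = <splice_events>, fraction)`.
#'
#' @param name Construct label, e.g. `"WT-3"`.
#' @param first_exon,last_exon Inclusive exon index range.
#' @param flank_5_len,flank_3_len Reporter flank lengths (nt) amplified with
#'   the insert.
#' @param baseline List of baseline transcript specifications.
#' @return A list of class `minigene_construct`.
#' @export
minigene_construct <- function(name, first_exon, last_exon,
                               flank_5_len, flank_3_len, baseline = list()) {
  stopifnot(first_exon <= last_exon, flank_5_len >= 0, flank_3_len >= 0)
  frac <- vapply(baseline, function(b) as.numeric(b$fraction), numeric(1))
  if (length(frac) && sum(frac) > 100) {
    stop("baseline fractions exceed 100%", call. = FALSE)
  }
  structure(list(name = name, first_exon = as.integer(first_exon),
                 last_exon = as.integer(last_exon),
                 flank_5_len = as.integer(flank_5_len),
                 flank_3_len = as.integer(flank_3_len),
                 baseline = baseline),
            class = "minigene_construct")
}

#' Read a transcript model from JSON
#'
#' The model file carries the gene label, exon spans (as c. coordinates with
#' an `inferred` provenance flag), and construct geometry. Sequences live in
#' a separate JSON file (`cds` string plus named `introns`), so that a
#' synthetic stand-in sequence is clearly separated from coordinate evidence.
#'
#' @param path Path to the model JSON.
#' @param sequences_path Optional path to a sequences JSON.
#' @return A `transcript_model`.
#' @export
read_transcript_model <- function(path, sequences_path = NULL) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cds <- NULL
  introns <- NULL
  if (!is.null(sequences_path)) {
    seqs <- jsonlite::read_json(sequences_path, simplifyVector = TRUE)
    cds <- seqs$cds
    introns <- as.list(seqs$introns)
  }
  constructs <- lapply(seq_len(nrow_or_len(spec$constructs)), function(i) {
    cs <- if (is.data.frame(spec$constructs)) {
      lapply(spec$constructs, `[[`, i)
    } else spec$constructs[[i]]
    baseline <- parse_baseline(cs$baseline)
    minigene_construct(cs$name, cs$first_exon, cs$last_exon,
                       cs$flank_5_len, cs$flank_3_len, baseline)
  })
  transcript_model(spec$exons, cds_sequence = cds, introns = introns,
                   constructs = constructs, gene_label = spec$gene_label)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

# baseline entries are stored compactly as "exon_skip:7" /
# "pseudoexon:1129-293:1129-218" strings in the JSON
parse_baseline <- function(baseline) {
  if (is.null(baseline) || length(baseline) == 0L) return(list())
  if (is.data.frame(baseline)) {
    baseline <- lapply(seq_len(nrow(baseline)),
                       function(i) as.list(baseline[i, ]))
  }
  lapply(baseline, function(b) {
    parts <- strsplit(b$events, ":", fixed = TRUE)[[1]]
    ev <- switch(parts[1],
      exon_skip = exon_skip(as.integer(strsplit(parts[2], ",")[[1]])),
      pseudoexon = pseudoexon(parts[2], parts[3]),
      stop("unknown baseline event kind: ", parts[1], call. = FALSE))
    list(events = ev, fraction = as.numeric(b$fraction))
  })
}

#' Exon lengths of a transcript model
#'
#' @param model A `transcript_model`.
#' @return A tibble with columns `exon` and `length` (nt, closed-interval).
#' @export
exon_lengths <- function(model) {
  tibble::tibble(exon = model$exons$exon,
                 length = model$exons$c_end - model$exons$c_start + 1L)
}

# region lookup for a parsed position: exon index, or the intron it falls in
locate_position <- function(model, base, offset) {
  ex <- model$exons
  if (base < 1L || base > model$cds_length) {
    stop("position c.", format_c_position(base, offset),
         " lies outside the transcript model span", call. = FALSE)
  }
  k <- which(ex$c_start <= base & base <= ex$c_end)
  if (offset == 0L) {
    return(list(region = "exon", exon = ex$exon[k], intron = NA_integer_))
  }
  # +k offsets hang off a donor (exon end), -k off an acceptor (exon start)
  intron <- if (offset > 0L) ex$exon[k] else ex$exon[k] - 1L
  list(region = "intron", exon = ex$exon[k], intron = intron)
}

#' Classify where a variant sits relative to splice sites
#'
#' Variants are classed as `exonic`, `canonical_splice` (the invariant
#' +/-1/+/-2 intronic dinucleotides), `NCSS` (non-canonical splice site:
#' intronic with `3 <= |offset| <= ncss_window`), or `deep_intronic`
#' (beyond the NCSS window). The window defaults to 20 nt, wide enough that
#' positions like `+20` still count as NCSS.
#'
#' @param variant_c Character vector of variant tokens (e.g. `"c.643+5G>A"`).
#' @param model A `transcript_model`.
#' @param ncss_window Maximum `|offset|` (nt) still considered NCSS.
#' @return Character vector of site classes.
#' @examples
#' \dontrun{
#' classify_variant_site("c.643+5G>A", rpe65_model())  # "NCSS"
#' }
#' @export
classify_variant_site <- function(variant_c, model, ncss_window = 20L) {
  p <- parse_c_position(variant_c)
  vapply(seq_len(nrow(p)), function(i) {
    loc <- locate_position(model, p$base[i], p$offset[i])
    off <- abs(p$offset[i])
    if (off == 0L) "exonic"
    else if (off <= 2L) "canonical_splice"
    else if (off <= ncss_window) "NCSS"
    else "deep_intronic"
  }, character(1))
}

#' Assign a variant to the minigene construct containing it
#'
#' A construct contains a position when it lies in one of the construct's
#' exons or strictly between them (interior introns), or within `margin` nt
#' of a terminal exon in the flanking intron (minigene inserts carry some
#' flanking intronic sequence). Where several constructs contain the
#' position (exons shared between overlapping constructs), the printed
#' assignment `hint` wins when given; otherwise the construct whose exonic
#' span-center is nearest is chosen.
#'
#' @param variant_c Character vector of variant tokens.
#' @param model A `transcript_model` with constructs.
#' @param hint Optional character vector of construct names to honor on ties
#'   (NA entries ignored).
#' @param margin Flanking-intron margin (nt) beyond terminal exons.
#' @return Character vector of construct names.
#' @export
assign_construct <- function(variant_c, model, hint = NULL, margin = 100L) {
  constructs <- model$constructs
  if (length(constructs) == 0L) stop("model has no constructs", call. = FALSE)
  p <- parse_c_position(variant_c)
  if (is.null(hint)) hint <- rep(NA_character_, nrow(p))
  ex <- model$exons
  vapply(seq_len(nrow(p)), function(i) {
    loc <- locate_position(model, p$base[i], p$offset[i])
    containing <- Filter(function(cs) {
      if (loc$region == "exon") {
        loc$exon >= cs$first_exon && loc$exon <= cs$last_exon
      } else {
        interior <- loc$intron >= cs$first_exon && loc$intron < cs$last_exon
        flank5 <- loc$intron == cs$first_exon - 1L &&
          abs(p$offset[i]) <= margin
        flank3 <- loc$intron == cs$last_exon && abs(p$offset[i]) <= margin
        interior || flank5 || flank3
      }
    }, constructs)
    if (length(containing) == 0L) {
      stop("variant ", sQuote(variant_c[i]),
           " is unassignable: no construct spans it", call. = FALSE)
    }
    nms <- vapply(containing, `[[`, "", "name")
    if (!is.na(hint[i]) && hint[i] %in% nms) return(hint[i])
    if (length(containing) == 1L) return(nms[1])
    centers <- vapply(containing, function(cs) {
      (ex$c_start[ex$exon == cs$first_exon] +
         ex$c_end[ex$exon == cs$last_exon]) / 2
    }, numeric(1))
    nms[which.min(abs(p$base[i] - centers))]
  }, character(1))
}
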