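#' Splice-event constructors
#'
#' Observed aberrant splice products are described as small sets of events
#' over the transcript model. Each constructor returns a one-row tibble;
#' multi-event transcripts (e.g. skipping of exons 7 and 10 on one molecule)
#' are built with [splice_events()] or `dplyr::bind_rows()`.
#'
#' * `exon_skip(exons)` - one or more exons absent from the product. A
#'   contiguous run serializes as a single deletion; non-adjacent exons in
#'   one call are treated as independent deletions of the same molecule.
#' * `pseudoexon(start, end)` - an intronic segment included as if exonic;
#'   both endpoints are intronic offset positions inside one intron.
#' * `exon_truncation(start, end, side)` - loss of a segment abutting an
#'   exon boundary (`side` `"5prime"`/`"3prime"`).
#' * `exon_elongation(start, end, side)` - inclusion of intronic sequence
#'   immediately adjacent to an exon boundary.
#' * `intron_retention(intron)` - a whole intron retained (intron `k` lies
#'   between exons `k` and `k + 1`).
#'
#' @param exons Integer vector of exon indices.
#' @param start,end Coding-position tokens delimiting the interval.
#' @param side `"5prime"` or `"3prime"`.
#' @param intron Integer intron index.
#' @return A tibble with columns `kind`, `exons`, `start`, `end`, `side`,
#'   `intron`.
#' @name splice_event
NULL

event_row <- function(kind, exons = list(integer()), start = NA_character_,
                      end = NA_character_, side = NA_character_,
                      intron = NA_integer_) {
  tibble::tibble(kind = kind, exons = exons,
                 start = start, end = end, side = side, intron = intron)
}

#' @rdname splice_event
#' @export
exon_skip <- function(exons) {
  stopifnot(length(exons) >= 1L, !anyNA(exons))
  event_row("exon_skip", exons = list(sort(as.integer(exons))))
}

#' @rdname splice_event
#' @export
pseudoexon <- function(start, end) {
  p <- parse_c_position(c(start, end))
  if (any(p$offset == 0L)) {
    stop("pseudo-exon endpoints must be intronic positions", call. = FALSE)
  }
  event_row("pseudoexon", start = p$token[1], end = p$token[2])
}

#' @rdname splice_event
#' @export
exon_truncation <- function(start, end, side = c("3prime", "5prime")) {
  side <- match.arg(side)
  p <- parse_c_position(c(start, end))
  if (any(p$offset != 0L)) {
    stop("truncation endpoints must be exonic positions", call. = FALSE)
  }
  event_row("exon_truncation", start = p$token[1], end = p$token[2],
            side = side)
}

#' @rdname splice_event
#' @export
exon_elongation <- function(start, end, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  p <- parse_c_position(c(start, end))
  if (any(p$offset == 0L)) {
    stop("elongation endpoints must be intronic positions", call. = FALSE)
  }
  event_row("exon_elongation", start = p$token[1], end = p$token[2],
            side = side)
}

#' @rdname splice_event
#' @export
intron_retention <- function(intron) {
  event_row("intron_retention", intron = as.integer(intron))
}

#' @rdname splice_event
#' @param ... Event tibbles to combine into one transcript's event set.
#' @export
splice_events <- function(...) dplyr::bind_rows(...)

#' Validate an event set against a transcript model
#'
#' Checks that skipped exons exist, that contiguity-sensitive payloads are
#' well-formed, that pseudo-exon intervals lie strictly inside one intron,
#' and that truncation intervals abut an exon boundary.
#'
#' @param events Event tibble.
#' @param model A `transcript_model`.
#' @return `events`, invisibly, on success; otherwise an error.
#' @export
validate_events <- function(events, model) {
  ex <- model$exons
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    if (kind == "exon_skip") {
      ek <- events$exons[[i]]
      if (!all(ek %in% ex$exon)) {
        stop("exon_skip references exon(s) absent from the model",
             call. = FALSE)
      }
    } else if (kind == "pseudoexon") {
      a <- parse_c_position(events$start[i])
      b <- parse_c_position(events$end[i])
      ia <- locate_position(model, a$base, a$offset)$intron
      ib <- locate_position(model, b$base, b$offset)$intron
      if (is.na(ia) || ia != ib) {
        stop("pseudo-exon interval must lie inside a single intron",
             call. = FALSE)
      }
    } else if (kind == "exon_truncation") {
      a <- parse_c_position(events$start[i])
      b <- parse_c_position(events$end[i])
      at_start <- any(ex$c_start == a$base)
      at_end <- any(ex$c_end == b$base)
      if (!at_start && !at_end) {
        stop("truncation interval must abut an exon boundary", call. = FALSE)
      }
    } else if (kind == "intron_retention") {
      if (events$intron[i] < 1L || events$intron[i] >= max(ex$exon)) {
        stop("intron index out of range", call. = FALSE)
      }
    }
  }
  invisible(events)
}

# ---------------------------------------------------------------------------
# event -> edit operations (deletions / insertions in c. space)

# Each op: op ("del"/"ins"), del_start, del_end (exonic bases),
# ins_after (exonic base the insertion follows), ins_start/ins_end
# (intronic tokens of the inserted segment).
events_to_ops <- function(events, model) {
  ex <- model$exons
  ops <- list()
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    if (kind == "exon_skip") {
      ek <- sort(events$exons[[i]])
      runs <- split(ek, cumsum(c(1L, diff(ek) != 1L)))
      for (r in runs) {
        ops[[length(ops) + 1L]] <- list(
          op = "del",
          del_start = ex$c_start[ex$exon == r[1]],
          del_end = ex$c_end[ex$exon == r[length(r)]])
      }
    } else if (kind == "exon_truncation") {
      a <- parse_c_position(events$start[i])$base
      b <- parse_c_position(events$end[i])$base
      ops[[length(ops) + 1L]] <- list(op = "del", del_start = a, del_end = b)
    } else if (kind %in% c("pseudoexon", "exon_elongation")) {
      a <- parse_c_position(events$start[i])
      b <- parse_c_position(events$end[i])
      anchor <- if (a$offset > 0L) a$base else a$base - 1L
      ops[[length(ops) + 1L]] <- list(
        op = "ins", ins_after = anchor,
        ins_start = a$token, ins_end = b$token)
    } else if (kind == "intron_retention") {
      k <- events$intron[i]
      donor <- ex$c_end[ex$exon == k]
      ops[[length(ops) + 1L]] <- list(
        op = "ins", ins_after = donor,
        ins_start = format_c_position(donor, 1L),
        ins_end = format_c_position(donor + 1L, -1L))
    } else {
      stop("unknown event kind: ", kind, call. = FALSE)
    }
  }
  ord <- order(vapply(ops, function(o)
    if (o$op == "del") o$del_start else o$ins_after + 0.5, numeric(1)))
  ops[ord]
}

op_delta <- function(op, model) {
  if (op$op == "del") {
    return(-(op$del_end - op$del_start + 1L))
  }
  a <- parse_c_position(op$ins_start)
  b <- parse_c_position(op$ins_end)
  if (a$base == b$base && sign(a$offset) == sign(b$offset)) {
    return(b$offset - a$offset + 1L)
  }
  # spans a whole intron (retention): needs intron length from the model
  loc <- locate_position(model, a$base, a$offset)
  k <- as.character(loc$intron)
  if (is.null(model$introns) || is.null(model$introns[[k]])) {
    stop("length of intron ", k, " unknown: supply intron sequences ",
         "in the model", call. = FALSE)
  }
  nchar(model$introns[[k]]) - (a$offset - 1L) - (-b$offset - 1L) -
    0L  # full intron when offsets are +1 / -1
}

#' Net length change of an event set
#'
#' Sum of insertion lengths minus deletion lengths, closed-interval
#' arithmetic throughout. A change that is not a multiple of 3 shifts the
#' reading frame.
#'
#' @param events Event tibble.
#' @param model A `transcript_model`.
#' @return Signed integer, nt.
#' @examples
#' \dontrun{
#' delta_length(exon_skip(7), rpe65_model())  # -82
#' }
#' @export
delta_length <- function(events, model) {
  validate_events(events, model)
  ops <- events_to_ops(events, model)
  as.integer(sum(vapply(ops, op_delta, numeric(1), model = model)))
}

# ---------------------------------------------------------------------------
# r. notation

op_token <- function(op) {
  if (op$op == "del") {
    paste0(op$del_start, "_", op$del_end, "del")
  } else {
    paste0(op$ins_after, "_", op$ins_after + 1L, "ins",
           op$ins_start, "_", op$ins_end)
  }
}

#' Serialize splice events as an HGVS-style RNA (r.) description
#'
#' One transcript's event set becomes a single r. string: deletions as
#' `r.<start>_<end>del`, insertions (pseudo-exons, elongations, retained
#' introns) as `r.<a>_<b>ins<c>_<d>` with intronic-offset tokens. An empty
#' event set is the wild-type product `r.=`. Several ops on one molecule are
#' joined either in the standard bracketed style `r.[x;y]` or, with
#' `dialect = "compound"`, in the run-on deletion style (`644_725del_999_1128del`)
#' used in assay result tables.
#'
#' @param events Event tibble.
#' @param model A `transcript_model`.
#' @param dialect `"hgvs"` or `"compound"`.
#' @return A single r. string.
#' @export
rna_notation <- function(events, model, dialect = c("hgvs", "compound")) {
  dialect <- match.arg(dialect)
  if (nrow(events) == 0L) return("r.=")
  validate_events(events, model)
  toks <- vapply(events_to_ops(events, model), op_token, character(1))
  if (length(toks) == 1L) return(paste0("r.", toks))
  if (dialect == "compound") {
    paste0("r.", paste(toks, collapse = "_"))
  } else {
    paste0("r.[", paste(toks, collapse = ";"), "]")
  }
}

#' Serialize a set of transcript species as one allele-level r. string
#'
#' @param species List of event tibbles (one per transcript species).
#' @param model A `transcript_model`.
#' @param wt Append `=` (residual wild-type product) last.
#' @return A string such as `"r.[644_725del,=]"`.
#' @export
r_allele <- function(species, model, wt = FALSE) {
  parts <- vapply(species, function(ev) {
    sub("^r\\.", "", rna_notation(ev, model, dialect = "compound"))
  }, character(1))
  if (wt) parts <- c(parts, "=")
  if (length(parts) == 1L && parts == "=") return("r.=")
  paste0("r.[", paste(parts, collapse = ","), "]")
}

#' Parse an RNA-level (r.) variant string
#'
#' Understands the dialect used in assay result tables: `r.=`, single
#' species (`r.644_725del`), bracketed multi-species alleles
#' (`r.[644_725del,=]`), run-on compound deletions on one species
#' (`644_725del_999_1128del`) and junction insertions with intronic tokens
#' (`1338_1339ins1339-2_1339-1`). Whitespace and dash glyph variants are
#' normalized. The result round-trips through [format_r_notation()].
#'
#' @param x A single r. string.
#' @return A list of class `r_parse`: one element per species, each either
#'   the string `"="` or a list of ops (`del` with `del_start`/`del_end`
#'   tokens, `ins` with `ins_after`, `ins_start`, `ins_end`).
#' @export
parse_r_notation <- function(x) {
  stopifnot(length(x) == 1L)
  s <- gsub("\\s+", "", normalize_dashes(x))
  s <- sub("^r\\.", "", s)
  bracketed <- grepl("^\\[.*\\]$", s)
  if (bracketed) s <- sub("^\\[(.*)\\]$", "\\1", s)
  species <- strsplit(s, ",", fixed = TRUE)[[1]]
  parsed <- lapply(species, parse_r_species)
  structure(parsed, class = "r_parse", bracketed = bracketed)
}

parse_r_species <- function(s) {
  if (s == "=") return("=")
  pos <- "[0-9]+(?:[+-][0-9]+)?"
  ins_re <- paste0("^(", pos, ")_(", pos, ")ins(", pos, ")_(", pos, ")$")
  if (grepl(ins_re, s)) {
    g <- regmatches(s, regexec(ins_re, s))[[1]]
    return(list(list(op = "ins", before = g[2], after = g[3],
                     ins_start = g[4], ins_end = g[5])))
  }
  # one or more run-on deletions: a_bdel(_c_ddel)*
  del_re <- paste0("^(?:(", pos, ")_(", pos, ")del)")
  ops <- list()
  rest <- s
  while (nchar(rest) > 0L) {
    rest <- sub("^_", "", rest)
    g <- regmatches(rest, regexec(del_re, rest))[[1]]
    if (length(g) == 0L) {
      stop("cannot parse r. species token: ", sQuote(s), call. = FALSE)
    }
    ops[[length(ops) + 1L]] <- list(op = "del", del_start = g[2],
                                    del_end = g[3])
    rest <- substr(rest, nchar(g[1]) + 1L, nchar(rest))
  }
  ops
}

#' Serialize a parsed r. structure back to its string
#'
#' @param parsed An `r_parse` object from [parse_r_notation()].
#' @return The normalized r. string.
#' @export
format_r_notation <- function(parsed) {
  parts <- vapply(parsed, function(sp) {
    if (identical(sp, "=")) return("=")
    toks <- vapply(sp, function(op) {
      if (op$op == "del") {
        paste0(op$del_start, "_", op$del_end, "del")
      } else {
        paste0(op$before, "_", op$after, "ins", op$ins_start, "_", op$ins_end)
      }
    }, character(1))
    paste(toks, collapse = "_")
  }, character(1))
  if (isTRUE(attr(parsed, "bracketed"))) {
    paste0("r.[", paste(parts, collapse = ","), "]")
  } else {
    paste0("r.", paste(parts, collapse = ","))
  }
}

#' Length change implied by one parsed r. species
#'
#' Closed-interval arithmetic on the parsed tokens: deletions count
#' `end - start + 1` nt removed; insertions with both endpoints in the same
#' intronic context count `end_offset - start_offset + 1` nt inserted.
#'
#' @param species One element of an [parse_r_notation()] result.
#' @return Signed integer, nt (`0L` for `"="`).
#' @export
r_species_delta <- function(species) {
  if (identical(species, "=")) return(0L)
  total <- 0L
  for (op in species) {
    if (op$op == "del") {
      total <- total - c_interval_length(op$del_start, op$del_end)
    } else {
      total <- total + c_interval_length(op$ins_start, op$ins_end)
    }
  }
  as.integer(total)
}

#' Coordinate-only lower bound for the first protein residue affected
#'
#' Returns the codon index of the smallest exonic coding position altered by
#' any event: the start of the first skipped/truncated exonic segment, or,
#' for pure insertions (pseudo-exon, elongation, intron retention), the
#' first exonic position downstream of the insertion junction. Because
#' junction codons can resynthesize the reference residue, the true HGVS p.
#' position (first *changed* residue, which needs sequence) may be slightly
#' larger; see [protein_consequence()].
#'
#' @param events Event tibble.
#' @param model A `transcript_model`.
#' @return Integer codon index.
#' @export
first_affected_codon <- function(events, model) {
  validate_events(events, model)
  ops <- events_to_ops(events, model)
  if (length(ops) == 0L) stop("no events supplied", call. = FALSE)
  pos <- min(vapply(ops, function(op) {
    if (op$op == "del") op$del_start else op$ins_after + 1L
  }, numeric(1)))
  codon_index(as.integer(pos))
}
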