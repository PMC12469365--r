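#' Parse HGVS coding (c.) position tokens
#'
#' Parses positions in HGVS coding-DNA notation, including intronic offsets
#' (`"643+5"`, `"1129-293"`). The `"c."` prefix is optional, en-dash /
#' minus-sign glyphs are normalized to a plain hyphen, and a trailing change
#' description (`"G>A"`, `"del"`, ...) is tolerated and ignored, so whole
#' variant tokens such as `"c.643+5G>A"` parse directly.
#'
#' @param x Character vector of position or variant tokens.
#' @return A tibble with one row per token and columns `token` (normalized
#'   position token), `base` (1-based coding coordinate of the anchoring
#'   exonic nucleotide) and `offset` (signed intronic offset; 0 for exonic
#'   positions, +k for k nt downstream of a donor site, -k for k nt upstream
#'   of an acceptor site).
#' @examples
#' parse_c_position(c("643+5", "675", "c.1129-293", "c.650A>T"))
#' @export
parse_c_position <- function(x) {
  stopifnot(is.character(x))
  norm <- normalize_dashes(x)
  norm <- sub("^c\\.?", "", norm)
  m <- regmatches(norm, regexec("^([0-9]+)([+-][0-9]+)?", norm))
  base <- vapply(m, function(g) {
    if (length(g) == 0L || g[1] == "") NA_integer_ else as.integer(g[2])
  }, integer(1))
  off_tok <- vapply(m, function(g) if (length(g) >= 3L) g[3] else "", character(1))
  bad <- is.na(base)
  if (any(bad)) {
    stop("malformed c. position token(s): ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  zero_off <- off_tok %in% c("+0", "-0")
  if (any(zero_off)) {
    stop("explicit zero intronic offset is not a valid position: ",
         paste(sQuote(x[zero_off]), collapse = ", "), call. = FALSE)
  }
  offset <- ifelse(off_tok == "", 0L, suppressWarnings(as.integer(off_tok)))
  tibble::tibble(
    token = format_c_position(base, offset),
    base = base,
    offset = offset
  )
}

#' Serialize a coding position back to its token form
#'
#' Inverse of [parse_c_position()] after dash normalization:
#' `format_c_position(parse_c_position(t)$base, parse_c_position(t)$offset)`
#' reproduces the normalized token.
#'
#' @param base Integer vector of coding coordinates (>= 1).
#' @param offset Integer vector of signed intronic offsets (0 = exonic).
#' @return Character vector of tokens such as `"643+5"` or `"675"`.
#' @export
format_c_position <- function(base, offset = 0L) {
  stopifnot(all(base >= 1L))
  paste0(base, ifelse(offset == 0L, "",
                      paste0(ifelse(offset > 0L, "+", "-"), abs(offset))))
}

#' Closed-interval length between two coding positions
#'
#' Lengths follow the HGVS closed-interval convention
#' (`end - start + 1`). Both endpoints must live in the same coordinate
#' context: either both exonic, or both intronic with the same sign of
#' offset relative to the same junction (e.g. the 76-nt pseudo-exon
#' `1129-293 .. 1129-218`). Spans crossing an exon/intron boundary need the
#' transcript model to resolve and are rejected here.
#'
#' @param start,end Position tokens (scalar character).
#' @return Integer length in nucleotides.
#' @examples
#' c_interval_length("644", "725")          # 82, exon-7 span
#' c_interval_length("1129-293", "1129-218") # 76, intron-10 pseudo-exon
#' @export
c_interval_length <- function(start, end) {
  a <- parse_c_position(start)
  b <- parse_c_position(end)
  if (a$offset == 0L && b$offset == 0L) {
    len <- b$base - a$base + 1L
  } else if (a$base == b$base && sign(a$offset) == sign(b$offset) &&
             a$offset != 0L && b$offset != 0L) {
    len <- b$offset - a$offset + 1L
  } else {
    stop("interval ", sQuote(start), "..", sQuote(end),
         " crosses an exon/intron boundary; use the transcript model",
         call. = FALSE)
  }
  if (len < 1L) stop("interval end precedes start", call. = FALSE)
  as.integer(len)
}

#' Codon index of an exonic coding position
#'
#' Maps a coding coordinate to the 1-based index of the codon containing it:
#' `floor((base - 1) / 3) + 1`. Intronic positions have no codon and are
#' rejected.
#'
#' @param base Integer vector of coding coordinates, or character tokens.
#' @param offset Integer vector of intronic offsets (must be 0).
#' @return Integer vector of codon indices.
#' @examples
#' codon_index(644)   # 215
#' codon_index(1244)  # 415
#' @export
codon_index <- function(base, offset = 0L) {
  if (is.character(base)) {
    p <- parse_c_position(base)
    base <- p$base
    offset <- p$offset
  }
  if (any(offset != 0L)) {
    stop("intronic positions have no codon index", call. = FALSE)
  }
  stopifnot(all(base >= 1L))
  as.integer((base - 1L) %/% 3L + 1L)
}

# en-dash, minus sign, non-breaking hyphen -> ASCII hyphen
normalize_dashes <- function(x) {
  gsub("–|—|−|‑", "-", x)
}
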