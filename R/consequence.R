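AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

# translate a nucleotide string (trimmed to whole codons) to a 1-letter
# amino-acid vector; stops are "*"
translate_nt <- function(x) {
  n <- (nchar(x) %/% 3L) * 3L
  if (n == 0L) return(character())
  aa <- Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)))
  strsplit(as.character(aa), "")[[1]]
}

# retrieve the nucleotides of an intronic interval from the model's intron
# sequences; offsets are +k from the donor / -k from the acceptor
intron_segment <- function(model, start_token, end_token) {
  a <- parse_c_position(start_token)
  b <- parse_c_position(end_token)
  loc <- locate_position(model, a$base, a$offset)
  k <- as.character(loc$intron)
  if (is.null(model$introns) || is.null(model$introns[[k]])) {
    stop("intron ", k, " sequence unavailable: cannot build the altered ",
         "transcript (supply intron sequences in the model)", call. = FALSE)
  }
  iseq <- model$introns[[k]]
  L <- nchar(iseq)
  idx <- function(p) if (p$offset > 0L) p$offset else L + p$offset + 1L
  i <- idx(a); j <- idx(b)
  if (i < 1L || j > L || j < i) {
    stop("intronic interval outside intron ", k, call. = FALSE)
  }
  substr(iseq, i, j)
}

# apply event ops to the CDS string
build_altered_cds <- function(events, model) {
  ops <- events_to_ops(events, model)
  seq <- model$cds_sequence
  # apply right-to-left so earlier coordinates stay valid
  for (op in rev(ops)) {
    if (op$op == "del") {
      seq <- paste0(substr(seq, 1L, op$del_start - 1L),
                    substr(seq, op$del_end + 1L, nchar(seq)))
    } else {
      insert <- intron_segment(model, op$ins_start, op$ins_end)
      seq <- paste0(substr(seq, 1L, op$ins_after), insert,
                    substr(seq, op$ins_after + 1L, nchar(seq)))
    }
  }
  seq
}

#' Protein-level consequence of a splice event set
#'
#' Builds the altered coding sequence implied by the events, translates it
#' from the start codon, and derives the HGVS protein description from the
#' first residue differing from the reference translation:
#'
#' * frameshift (length change not a multiple of 3):
#'   `p.<Ref><pos><New>fs*N`, where N counts residues from the first changed
#'   one to the new stop codon inclusive (HGVS convention, so an immediate
#'   stop would be `p.<Ref><pos>*`). If translation runs off the end of the
#'   altered sequence without a stop, N is reported as `"?"`.
#' * in-frame: deletion (`p.X83_Y118del`) or delins when the junction
#'   introduces new residues; a single-residue deletion is `p.X83del`.
#' * no change: `p.(=)`.
#'
#' @param events Event tibble (may have zero rows for the wild-type
#'   product).
#' @param model A `transcript_model` whose `cds_sequence` is set (and whose
#'   intron sequences are present if the events insert intronic material).
#' @return A one-row tibble: `r_notation`, `delta_len`, `frame`
#'   (`"in_frame"`/`"frameshift"`), `p_notation`, `first_affected_codon`.
#' @export
protein_consequence <- function(events, model) {
  if (is.null(model$cds_sequence)) {
    stop("protein consequences need a CDS sequence in the model",
         call. = FALSE)
  }
  if (nrow(events) == 0L) {
    return(tibble::tibble(r_notation = "r.=", delta_len = 0L,
                          frame = "in_frame", p_notation = "p.(=)",
                          first_affected_codon = NA_integer_))
  }
  validate_events(events, model)
  delta <- delta_length(events, model)
  frame <- if (delta %% 3L == 0L) "in_frame" else "frameshift"
  ref_aa <- translate_nt(model$cds_sequence)
  mut_aa <- translate_nt(build_altered_cds(events, model))
  # translation stops at the first stop codon
  trim_at_stop <- function(aa) {
    s <- which(aa == "*")[1]
    if (is.na(s)) list(aa = aa, stopped = FALSE)
    else list(aa = aa[seq_len(s)], stopped = TRUE)
  }
  ref <- trim_at_stop(ref_aa)$aa
  mut_t <- trim_at_stop(mut_aa)
  mut <- mut_t$aa
  n <- min(length(ref), length(mut))
  i <- which(ref[seq_len(n)] != mut[seq_len(n)])[1]
  p <- if (is.na(i) && length(ref) == length(mut)) {
    "p.(=)"
  } else if (frame == "frameshift") {
    if (is.na(i)) i <- n + 1L  # degenerate: difference past common prefix
    stop_at <- if (i <= length(mut)) which(mut[i:length(mut)] == "*")[1]
               else NA_integer_
    nname <- if (mut_t$stopped && !is.na(stop_at)) as.character(stop_at)
             else "?"
    if (identical(nname, "1")) {
      sprintf("p.%s%d*", AA_THREE[[ref[i]]], i)
    } else if (i > length(mut)) {
      # altered transcript ends inside the reference: no new residue to name
      sprintf("p.%s%dfs*?", AA_THREE[[ref[i]]], i)
    } else {
      sprintf("p.%s%d%sfs*%s", AA_THREE[[ref[i]]], i,
              AA_THREE[[mut[i]]], nname)
    }
  } else {
    in_frame_notation(ref, mut)
  }
  tibble::tibble(r_notation = rna_notation(events, model),
                 delta_len = delta, frame = frame, p_notation = p,
                 first_affected_codon = first_affected_codon(events, model))
}

# HGVS deletion / delins naming for two stop-trimmed translations of equal
# frame; assumes both end in "*"
in_frame_notation <- function(ref, mut) {
  n <- min(length(ref), length(mut))
  i <- which(ref[seq_len(n)] != mut[seq_len(n)])[1]
  if (is.na(i)) return("p.(=)")
  # longest common suffix
  j <- 0L
  while (j < (length(ref) - i + 1L) && j < (length(mut) - i + 1L) &&
         ref[length(ref) - j] == mut[length(mut) - j]) {
    j <- j + 1L
  }
  del_to <- length(ref) - j         # last changed ref residue
  ins <- mut[seq.int(i, length(mut) - j, length.out =
                       max(0L, length(mut) - j - i + 1L))]
  if (length(mut) - j < i) ins <- character()
  if (del_to < i) {
    # nothing deleted: pure insertion between residues i-1 and i
    return(sprintf("p.%s%d_%s%dins%s", AA_THREE[[ref[i - 1L]]], i - 1L,
                   AA_THREE[[ref[i]]], i,
                   paste(AA_THREE[ins], collapse = "")))
  }
  ref_part <- if (del_to == i) {
    sprintf("%s%d", AA_THREE[[ref[i]]], i)
  } else {
    sprintf("%s%d_%s%d", AA_THREE[[ref[i]]], i, AA_THREE[[ref[del_to]]],
            del_to)
  }
  if (length(ins) == 0L) {
    paste0("p.", ref_part, "del")
  } else {
    paste0("p.", ref_part, "delins",
           paste(AA_THREE[ins], collapse = ""))
  }
}
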