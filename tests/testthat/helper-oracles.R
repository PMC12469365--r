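# Independent oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: translation is a
# naive codon loop over a hand-written table, and sequence surgery is done
# by direct string arithmetic on the exon map.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

AA3_ORACLE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- unname(ORACLE_CODONS[substr(nt, 3L * i - 2L, 3L * i)])
  }
  out
}

# brute-force protein comparison: first differing residue, and for
# frameshifts the 1-based distance from it to the first stop (inclusive)
oracle_protein <- function(ref_nt, mut_nt) {
  refa <- oracle_translate(ref_nt)
  refa <- refa[seq_len(which(refa == "*")[1])]
  muta <- oracle_translate(mut_nt)
  stop_idx <- which(muta == "*")[1]
  stopped <- !is.na(stop_idx)
  if (stopped) muta <- muta[seq_len(stop_idx)]
  n <- min(length(refa), length(muta))
  i <- which(refa[seq_len(n)] != muta[seq_len(n)])[1]
  if (is.na(i) && length(refa) == length(muta)) {
    return(list(p = "p.(=)", first_changed = NA_integer_))
  }
  if (is.na(i)) i <- n + 1L
  fs_stop <- which(muta[i:length(muta)] == "*")[1]
  list(first_changed = i,
       ref_aa = refa[i], mut_aa = muta[i],
       fs_n = if (stopped) fs_stop else NA_integer_)
}

# apply exon-skip / pseudoexon / elongation / truncation / retention edits
# to the CDS by direct string surgery, reading coordinates off the exon map
oracle_apply <- function(model, edits) {
  seq <- model$cds_sequence
  # edits: list of list(del = c(a, b)) or list(ins_after = a, seq = s)
  ord <- order(vapply(edits, function(e)
    if (!is.null(e$del)) e$del[1] else e$ins_after + 0.5, numeric(1)),
    decreasing = TRUE)
  for (e in edits[ord]) {
    if (!is.null(e$del)) {
      seq <- paste0(substr(seq, 1, e$del[1] - 1),
                    substr(seq, e$del[2] + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, e$ins_after), e$seq,
                    substr(seq, e$ins_after + 1, nchar(seq)))
    }
  }
  seq
}

# a small deterministic model with sequence for property tests
toy_model <- function(seed = 11L) {
  set.seed(seed)
  lens <- c(30L, 45L, 52L, 33L, 60L, 26L)   # mixed frames, sum = 246
  ends <- cumsum(lens)
  starts <- c(1L, ends[-length(ends)] + 1L)
  n_codons <- sum(lens) / 3L
  non_stop <- names(ORACLE_CODONS)[ORACLE_CODONS != "*"]
  repeat {
    cds <- paste0("ATG",
                  paste(sample(non_stop, n_codons - 2L, TRUE), collapse = ""),
                  "TAA")
    if (!any(oracle_translate(cds)[seq_len(n_codons - 1L)] == "*")) break
  }
  introns <- lapply(seq_len(length(lens) - 1L), function(i) {
    paste0("GT", paste(sample(c("A", "C", "G", "T"), 96L, TRUE),
                       collapse = ""), "AG")
  })
  names(introns) <- as.character(seq_len(length(lens) - 1L))
  transcript_model(
    tibble::tibble(exon = seq_along(lens), c_start = starts, c_end = ends),
    cds_sequence = cds, introns = introns,
    constructs = list(
      minigene_construct("TOY-1", 1L, 4L, 120L, 100L),
      minigene_construct("TOY-2", 3L, 6L, 120L, 100L)),
    gene_label = "toygene")
}

# draw a random valid event set on a model (used in frame/protein
# property tests); returns an event tibble
random_events <- function(model) {
  ex <- model$exons
  n_ex <- nrow(ex)
  kinds <- sample(c("skip", "pe", "elong", "trunc", "ret"), 1L,
                  prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
  switch(kinds,
    skip = {
      a <- sample(2:(n_ex - 1L), 1L)
      b <- min(n_ex - 1L, a + sample(0:1, 1L))
      exon_skip(a:b)
    },
    pe = {
      k <- sample(n_ex - 1L, 1L)
      L <- nchar(model$introns[[as.character(k)]])
      len <- sample(5:40, 1L)
      s <- sample(3:(L - len - 3L), 1L)
      acceptor <- ex$c_start[k + 1L]
      pseudoexon(format_c_position(acceptor, -(L - s + 1L)),
                 format_c_position(acceptor, -(L - s - len + 2L)))
    },
    elong = {
      k <- sample(n_ex - 1L, 1L)
      len <- sample(1:20, 1L)
      if (stats::runif(1) < 0.5) {
        donor <- ex$c_end[k]
        exon_elongation(format_c_position(donor, 1L),
                        format_c_position(donor, len), side = "3prime")
      } else {
        acceptor <- ex$c_start[k + 1L]
        exon_elongation(format_c_position(acceptor, -len),
                        format_c_position(acceptor, -1L), side = "5prime")
      }
    },
    trunc = {
      k <- sample(2:n_ex, 1L)
      width <- ex$c_end[k] - ex$c_start[k] + 1L
      len <- sample(seq_len(min(15L, width - 1L)), 1L)
      if (stats::runif(1) < 0.5) {
        exon_truncation(format_c_position(ex$c_start[k]),
                        format_c_position(ex$c_start[k] + len - 1L),
                        side = "5prime")
      } else {
        exon_truncation(format_c_position(ex$c_end[k] - len + 1L),
                        format_c_position(ex$c_end[k]), side = "3prime")
      }
    },
    ret = intron_retention(sample(n_ex - 1L, 1L))
  )
}

# translate an event tibble into oracle edits (independent re-derivation)
oracle_edits <- function(events, model) {
  ex <- model$exons
  out <- list()
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]
    if (kind == "exon_skip") {
      for (e in events$exons[[i]]) {
        out[[length(out) + 1L]] <- list(del = c(ex$c_start[e], ex$c_end[e]))
      }
    } else if (kind == "exon_truncation") {
      a <- parse_c_position(events$start[i])$base
      b <- parse_c_position(events$end[i])$base
      out[[length(out) + 1L]] <- list(del = c(a, b))
    } else if (kind %in% c("pseudoexon", "exon_elongation")) {
      a <- parse_c_position(events$start[i])
      b <- parse_c_position(events$end[i])
      if (a$offset > 0L) {
        iseq <- model$introns[[as.character(ex$exon[ex$c_end == a$base])]]
        out[[length(out) + 1L]] <- list(
          ins_after = a$base, seq = substr(iseq, a$offset, b$offset))
      } else {
        k <- ex$exon[ex$c_start == a$base] - 1L
        iseq <- model$introns[[as.character(k)]]
        L <- nchar(iseq)
        out[[length(out) + 1L]] <- list(
          ins_after = a$base - 1L,
          seq = substr(iseq, L + a$offset + 1L, L + b$offset + 1L))
      }
    } else if (kind == "intron_retention") {
      k <- events$intron[i]
      out[[length(out) + 1L]] <- list(
        ins_after = ex$c_end[ex$exon == k],
        seq = model$introns[[as.character(k)]])
    }
  }
  out
}

# merged skips that cross adjacent exons must delete one contiguous block;
# oracle_edits already deletes per-exon which is equivalent

trapezoid_area <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# simple Gaussian lane built without the package generator
gauss_profile <- function(centers, areas, sigma = 6, n = 1200,
                          offset = 0, slope = 0, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n)
  y <- rep(0, n)
  for (i in seq_along(centers)) {
    y <- y + areas[i] * stats::dnorm(x, centers[i], sigma)
  }
  y <- y + offset + slope * x
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  lane_profile(x, pmax(y, 0))
}
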