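#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs of the three generators. Defaults emulate the shape of
#' a real minigene study of a mid-size retinal-disease gene: a transcript of
#' about a dozen exons, a prioritized variant table in which most candidates
#' clear the SpliceAI threshold, and gel lanes whose band widths, crowding
#' and noise match a clean agarose gel scanned at moderate resolution
#' (duplicate transfections, signal-to-noise around 20).
#'
#' @param seed Integer seed; the same seed reproduces every output exactly.
#' @param n_exons Number of exons for [sim_model()].
#' @param exon_length_range,intron_length_range Min/max lengths (nt).
#' @param n_variants Rows for [sim_variant_table()].
#' @param p_above Fraction of variants engineered to pass the default
#'   selection filter.
#' @param p_exonic,p_ncss Placement proportions (remainder deep-intronic).
#' @param p_in_window Probability that a passing score's predicted site
#'   falls inside the 5000-bp analysis window.
#' @param score_shape1,score_shape2 Beta parameters for above-threshold
#'   delta scores (rescaled to \[0.1, 1\]); sub-threshold scores are uniform
#'   below 0.1.
#' @param band_sigma Gaussian band width (pixels).
#' @param snr Peak signal-to-noise ratio of the tallest band.
#' @param n_points Samples per lane profile.
#' @param baseline_offset Constant lane background (a.u.).
#' @param baseline_slope Linear background drift per pixel.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_exons = 13L,
                       exon_length_range = c(81L, 150L),
                       intron_length_range = c(300L, 600L),
                       n_variants = 73L, p_above = 0.7, p_exonic = 0.55,
                       p_ncss = 0.3, p_in_window = 0.9,
                       score_shape1 = 1.2, score_shape2 = 2.5,
                       band_sigma = 6, snr = 20, n_points = 1200L,
                       baseline_offset = 60, baseline_slope = 0.02) {
  stopifnot(n_exons >= 2L, all(exon_length_range > 0L),
            all(intron_length_range > 0L), p_above >= 0, p_above <= 1,
            p_exonic + p_ncss <= 1, band_sigma > 0, snr > 0)
  structure(as.list(environment()), class = "sim_config")
}

sample_codon <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  sample(setdiff(codons, stops), n, replace = TRUE)
}

#' Generate a random transcript model with CDS
#'
#' Exon lengths are drawn from the configured range (re-drawn until at least
#' one exon length is not a multiple of 3, so single-exon skips can shift
#' the frame); the total is trimmed to a multiple of 3. The CDS starts with
#' ATG, ends with a stop codon and has no internal in-frame stop. Intron
#' sequences are generated with canonical GT...AG ends. Minigene constructs
#' are derived as overlapping sliding windows of exons, mirroring how
#' wild-type vectors partition a gene.
#'
#' @param cfg A [sim_config()].
#' @return A `transcript_model` with sequence.
#' @export
sim_model <- function(cfg) {
  set.seed(cfg$seed)
  for (attempt in 1:100) {
    lens <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                   cfg$n_exons, replace = TRUE)
    excess <- sum(lens) %% 3L
    lens[cfg$n_exons] <- lens[cfg$n_exons] - excess
    if (any(lens %% 3L != 0L)) break
  }
  if (all(lens %% 3L == 0L)) {
    stop("could not draw a frame-shifting exon under these constraints",
         call. = FALSE)
  }
  ends <- cumsum(lens)
  starts <- c(1L, ends[-cfg$n_exons] + 1L)
  exons <- tibble::tibble(exon = seq_len(cfg$n_exons), c_start = starts,
                          c_end = ends, inferred = FALSE)
  n_codons <- sum(lens) %/% 3L
  repeat {
    cods <- c("ATG", sample_codon(n_codons - 2L), "TAA")
    cds <- paste(cods, collapse = "")
    if (!any(translate_nt(cds)[seq_len(n_codons - 1L)] == "*")) break
  }
  introns <- lapply(seq_len(cfg$n_exons - 1L), function(i) {
    L <- sample(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]), 1L)
    paste0("GT", paste(sample(c("A", "C", "G", "T"), L - 4L, TRUE),
                       collapse = ""), "AG")
  })
  names(introns) <- as.character(seq_len(cfg$n_exons - 1L))
  win <- max(2L, ceiling(cfg$n_exons / 4L) + 1L)
  firsts <- unique(pmin(seq(1L, cfg$n_exons, by = win - 1L),
                        cfg$n_exons - win + 1L))
  constructs <- lapply(seq_along(firsts), function(i) {
    minigene_construct(paste0("WT-", i), firsts[i],
                       min(firsts[i] + win - 1L, cfg$n_exons),
                       flank_5_len = 150L, flank_3_len = 130L)
  })
  transcript_model(exons, cds_sequence = cds, introns = introns,
                   constructs = constructs, gene_label = "simgene")
}

#' Generate a variant table with SpliceAI-style score vectors
#'
#' Variants are placed exonic, near-splice-site (NCSS) or deep-intronic in
#' the configured proportions. A configurable fraction is engineered to pass
#' the default selection filter: one of the four delta-score components is
#' drawn above 0.1 (Beta-distributed with a high-score tail) with its
#' predicted site inside the analysis window (with probability
#' `p_in_window`; otherwise beyond it, exercising the window rule).
#' Sub-threshold variants have all four scores below 0.1. The ground truth
#' (`truth_above`: would the generative intent pass the filter) is attached
#' as extra columns.
#'
#' @param cfg A [sim_config()].
#' @param model A `transcript_model` from [sim_model()].
#' @return A tibble in the variant-table dialect plus `truth_above`.
#' @export
sim_variant_table <- function(cfg, model) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_variants
  ex <- model$exons
  kind <- sample(c("exonic", "ncss", "deep"), n, replace = TRUE,
                 prob = c(cfg$p_exonic, cfg$p_ncss,
                          1 - cfg$p_exonic - cfg$p_ncss))
  tokens <- vapply(kind, function(k) {
    if (k == "exonic") {
      format_c_position(sample(model$cds_length, 1L))
    } else {
      donor <- sample(ex$c_end[-nrow(ex)], 1L)
      off <- if (k == "ncss") sample(3:20, 1L) else sample(50:200, 1L)
      format_c_position(donor, off)
    }
  }, character(1))
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  above <- stats::runif(n) < cfg$p_above
  scores <- matrix(stats::runif(n * 4L, 0, 0.0999), nrow = n)
  posn <- matrix(sample(c(-4999:-1, 1:4999), n * 4L, TRUE), nrow = n)
  for (i in which(above)) {
    j <- sample(4L, 1L)
    scores[i, j] <- 0.1 + 0.9 * stats::rbeta(1, cfg$score_shape1,
                                             cfg$score_shape2)
    posn[i, j] <- if (stats::runif(1) < cfg$p_in_window) {
      sample(c(-4999:-1, 1:4999), 1L)
    } else {
      sample(5001:9000, 1L) * sample(c(-1L, 1L), 1L)
    }
  }
  vtype <- ifelse(kind == "exonic",
                  sample(c("Missense", "Synonymous"), n, TRUE), "NCSS")
  tibble::tibble(
    c_notation = paste0("c.", tokens, ref, ">", alt),
    p_notation = "p.(?)",
    variant_type = vtype,
    acmg_aug2023 = factor(sample(c("LB", "VUS"), n, TRUE, prob = c(0.3, 0.7)),
                          levels = ACMG_LEVELS, ordered = TRUE),
    acmg_oct2024 = factor("VUS", levels = ACMG_LEVELS, ordered = TRUE),
    source = sample(c("ClinVar", "LOVD"), n, TRUE, prob = c(0.8, 0.2)),
    construct = NA_character_,
    acceptor_gain = scores[, 1], acceptor_loss = scores[, 2],
    donor_gain = scores[, 3], donor_loss = scores[, 4],
    pos_acceptor_gain = posn[, 1], pos_acceptor_loss = posn[, 2],
    pos_donor_gain = posn[, 3], pos_donor_loss = posn[, 4],
    truth_above = above)
}

#' Default ladder for simulated gels
#'
#' Eight rungs from 100 to 2000 bp, migrating linearly in log10(size)
#' across the lane.
#'
#' @param n_points Lane length in pixels.
#' @return Tibble with `position` and `size_bp`.
#' @export
sim_ladder <- function(n_points = 1200L) {
  sizes <- round(10^seq(log10(2000), log10(100), length.out = 8L))
  span <- c(0.08, 0.92) * n_points
  pos <- span[1] + (log10(2000) - log10(sizes)) /
    (log10(2000) - log10(100)) * diff(span)
  tibble::tibble(position = pos, size_bp = sizes)
}

size_to_position <- function(size_bp, ladder) {
  stats::approx(log10(ladder$size_bp), ladder$position, xout = log10(size_bp),
                rule = 2)$y
}

#' Simulate one gel lane from a known transcript mixture
#'
#' Each mixture component becomes a Gaussian band centered at the migration
#' position implied by its predicted fragment size and the internal ladder;
#' band areas are proportional to mixture fractions. A constant-plus-drift
#' background and white noise at the configured signal-to-noise ratio are
#' added. The emitted ground truth records each component's size, center and
#' fraction, and flags the lane `crowded` when two band centers lie closer
#' than one band sigma.
#'
#' @param cfg A [sim_config()].
#' @param construct A [minigene_construct()].
#' @param mixture Tibble with `events` (list-column) and `fraction`
#'   (percent; must total 100).
#' @param model A `transcript_model`.
#' @param seed Optional seed override (defaults to `cfg$seed`).
#' @return List: `profile` (a `lane_profile`), `ladder`, and `truth`.
#' @export
sim_lane <- function(cfg, construct, mixture, model, seed = cfg$seed) {
  set.seed(seed)
  stopifnot(abs(sum(mixture$fraction) - 100) < 1e-6)
  ladder <- sim_ladder(cfg$n_points)
  sizes <- vapply(mixture$events, predict_fragment_size, integer(1),
                  construct = construct, model = model)
  centers <- size_to_position(sizes, ladder)
  x <- seq_len(cfg$n_points)
  clean <- rep(0, cfg$n_points)
  for (i in seq_along(centers)) {
    clean <- clean + mixture$fraction[i] *
      stats::dnorm(x, centers[i], cfg$band_sigma)
  }
  # scale so the tallest band peaks at 1000 a.u.; the configured SNR is the
  # peak-to-noise ratio of the *weakest* band, so every component of a
  # qualifying lane clears the stated detectability condition
  scale <- 1000 / max(clean)
  clean <- clean * scale
  min_height <- min(mixture$fraction) / max(mixture$fraction) * 1000
  noise_sd <- min_height / cfg$snr
  y <- clean + cfg$baseline_offset + cfg$baseline_slope * x +
    stats::rnorm(cfg$n_points, 0, noise_sd)
  y <- pmax(y, 0)
  crowded <- any(diff(sort(centers)) < cfg$band_sigma)
  truth <- tibble::tibble(size_bp = sizes, center = centers,
                          fraction = mixture$fraction,
                          events = mixture$events)
  list(profile = lane_profile(x, y, lane_id = construct$name),
       ladder = ladder,
       truth = truth, crowded = crowded)
}

# draw a residual wild-type fraction resembling an observed assay cohort:
# a point mass at 0 (complete splice defects), a 5-20% band, and a >= 20%
# majority including fully splice-silent variants
draw_wt_fraction <- function(n) {
  bin <- sample(c("none", "low", "high"), n, replace = TRUE,
                prob = c(7, 11, 41) / 59)
  vapply(bin, function(b) {
    switch(b,
           none = 0,
           low = sample(6:19, 1L),
           high = if (stats::runif(1) < 15 / 41) 100 else sample(22:97, 1L))
  }, numeric(1))
}

#' Simulate a full assay cohort with ground truth
#'
#' For each synthetic variant a construct is chosen, a true residual
#' wild-type fraction is drawn (mimicking the empirical distribution of a
#' minigene cohort: a point mass at zero, a 5-20% band, and a splice-silent
#' / high-residual majority), the aberrant remainder is split over one or
#' two well-separated candidate skip products, and duplicate lanes are
#' rendered with [sim_lane()].
#'
#' @param cfg A [sim_config()].
#' @param n_assays Number of simulated variants (default 40).
#' @param n_replicates Lanes per variant (default 2, as assays are run in
#'   duplicate).
#' @return List: `model`, and `assays` - a tibble with `c_notation`,
#'   `construct`, `truth_wt`, `truth_bin` and a `lanes` list-column.
#' @export
sim_cohort <- function(cfg, n_assays = 40L, n_replicates = 2L) {
  model <- sim_model(cfg)
  set.seed(cfg$seed + 2L)
  constructs <- model$constructs
  wt_true <- draw_wt_fraction(n_assays)
  ladder <- sim_ladder(cfg$n_points)
  rows <- lapply(seq_len(n_assays), function(i) {
    cs <- constructs[[sample(length(constructs), 1L)]]
    span <- cs$first_exon:cs$last_exon
    # pick one or two skip products whose fragments stay resolvable
    # (band centers at least 4 sigma apart, incl. the wild-type band)
    k <- if (stats::runif(1) < 0.3 && length(span) >= 3L) 2L else 1L
    events <- list()
    for (attempt in 1:25) {
      skip_exons <- sample(span[-length(span)], k)
      events <- lapply(skip_exons, exon_skip)
      sizes <- vapply(c(list(splice_events()), events),
                      predict_fragment_size, integer(1),
                      construct = cs, model = model)
      centers <- size_to_position(sizes, ladder)
      if (all(diff(sort(centers)) >= 4 * cfg$band_sigma)) break
      if (attempt == 25L) {
        k <- 1L
        skip_exons <- span[which.max(exon_lengths(model)$length[span])]
        events <- lapply(skip_exons, exon_skip)
      }
    }
    wt <- wt_true[i]
    fr <- if (wt >= 100) numeric() else {
      split_points <- if (k == 2L) {
        p <- stats::runif(1, 0.25, 0.75)
        c(p, 1 - p) * (100 - wt)
      } else 100 - wt
      split_points
    }
    mixture <- tibble::tibble(
      events = c(if (wt > 0) list(splice_events()) else list(),
                 if (wt < 100) events[seq_along(fr)] else list()),
      fraction = c(if (wt > 0) wt else numeric(), fr))
    # drop components whose fragment sizes collide (< 4 sigma apart)
    sizes <- vapply(mixture$events, predict_fragment_size, integer(1),
                    construct = cs, model = model)
    keep <- !duplicated(sizes)
    mixture <- mixture[keep, ]
    mixture$fraction <- mixture$fraction / sum(mixture$fraction) * 100
    lanes <- lapply(seq_len(n_replicates), function(r) {
      sim_lane(cfg, cs, mixture, model, seed = cfg$seed + 100L * i + r)
    })
    tibble::tibble(c_notation = sprintf("sim_var_%03d", i),
                   construct = cs$name, truth_wt = wt,
                   lanes = list(lanes))
  })
  assays <- dplyr::bind_rows(rows)
  assays$truth_bin <- bin_residual(assays$truth_wt)
  list(model = model, assays = assays)
}

#' Quantify a simulated assay back to a residual wild-type fraction
#'
#' Runs the full densitometry pipeline on each replicate lane of a
#' simulated assay and averages the wild-type fraction across replicates
#' (a band matched to the wild-type fragment size contributes its
#' fraction; a lane with no wild-type band scores 0).
#'
#' @param lanes List of [sim_lane()] bundles.
#' @param construct A [minigene_construct()].
#' @param model A `transcript_model`.
#' @return Mean recovered wild-type percentage.
#' @export
recover_wt_fraction <- function(lanes, construct, model) {
  candidates <- candidate_transcripts(construct, model)
  wt <- vapply(lanes, function(ln) {
    bands <- quantify_lane(ln$profile, ln$ladder, construct, model,
                           candidates = candidates)
    sum(bands$fraction[bands$identity == "WT"])
  }, numeric(1))
  mean(wt)
}
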