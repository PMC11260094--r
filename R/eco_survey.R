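# Ecological survey statistics over metagenome SC scores: biome
# aggregation, bimodality valley detection, score-depth correlation,
# moving averages and per-species score ranges.

#' Score a metagenome protein set
#'
#' Identical computation to [score_genome()] on the pooled protein
#' predictions of one assembly. Note the community caveat: the features
#' driving the score may originate from different member organisms, so a
#' high score flags the assembly, not any single genome.
#'
#' @param model a trained [train_sc_model()] object.
#' @param metagenome_proteins named character vector of protein sequences.
#' @return an `sc_score` (see [score_genome()]).
#' @export
score_metagenome <- function(model, metagenome_proteins) {
  score_genome(model, metagenome_proteins)
}

#' Summarize survey scores per biome
#'
#' Biomes with fewer than `min_records` associated datasets are pooled
#' into `"Others"`. A biome "has a high scorer" iff any of its scores
#' strictly exceeds `high_cutoff`.
#'
#' @param records data.frame with columns `biome` and `score`.
#' @param high_cutoff high-score threshold (default the 0.68 band limit).
#' @param min_records pooling threshold.
#' @return data.frame with per-biome `n`, `median`, `max`,
#'   `has_high_scorer`, sorted by median.
#' @export
summarize_biomes <- function(records, high_cutoff = 0.68, min_records = 3L) {
  if (nrow(records) < 1L) stop("need at least one record")
  tab <- table(records$biome)
  biome <- as.character(records$biome)
  biome[biome %in% names(tab)[tab < min_records]] <- "Others"
  agg <- lapply(split(records$score, biome), function(s)
    data.frame(n = length(s), median = median(s), max = max(s),
               has_high_scorer = any(s > high_cutoff)))
  out <- do.call(rbind, agg)
  out <- data.frame(biome = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$median), , drop = FALSE]
}

#' Detect the valley between the two main modes of a score distribution
#'
#' A Gaussian kernel density (Silverman bandwidth by default) is estimated
#' on \[0, 1\]; the cutoff is the location of the minimum density between
#' the two highest local maxima. A unimodal density yields `NA` — no
#' cutoff is fabricated.
#'
#' @param scores numeric scores in \[0, 1\] (>= 50 values).
#' @param grid_resolution number of evaluation points.
#' @param bw kernel bandwidth (default Silverman's rule, `"nrd0"`).
#' @param min_peak_frac a local maximum only counts as a mode when its
#'   density reaches this fraction of the global maximum (suppresses
#'   spurious tail bumps of the kernel estimate).
#' @param min_dip minimum relative depth of the density dip separating two
#'   modes: a local maximum is merged into a taller neighbour unless the
#'   density between them falls below `(1 - min_dip)` times the lower
#'   peak (suppresses wiggles on top of a single mode).
#' @return the cutoff score, or `NA_real_` when the density is unimodal.
#' @export
detect_score_valley <- function(scores, grid_resolution = 512L, bw = "nrd0",
                                min_peak_frac = 0.1, min_dip = 0.1) {
  if (length(scores) < 50L) stop("need at least 50 scores")
  den <- density(scores, bw = bw, n = grid_resolution, from = 0, to = 1)
  y <- den$y; n <- length(y)
  # local maxima (plateau-tolerant ends included)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  peaks <- which(is_max)
  peaks <- peaks[y[peaks] >= min_peak_frac * max(y)]
  if (length(peaks) < 2L) return(NA_real_)
  # accept peaks as modes tallest-first, requiring a real dip towards
  # every mode already accepted
  ord <- peaks[order(y[peaks], decreasing = TRUE)]
  modes <- ord[1]
  for (p in ord[-1]) {
    dips <- vapply(modes, function(m) {
      rng <- min(m, p):max(m, p)
      min(y[rng]) <= (1 - min_dip) * min(y[m], y[p])
    }, TRUE)
    if (all(dips)) modes <- c(modes, p)
  }
  if (length(modes) < 2L) return(NA_real_)
  top2 <- modes[order(y[modes], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  den$x[valley]
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the p-value from the
#' t-approximation on n - 2 degrees of freedom (adequate at survey sample
#' sizes); an exact permutation p-value is used when `n <= exact_n`
#' (full enumeration of n! rank permutations, so keep `exact_n` small).
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @param exact_n maximum n for the exact permutation p-value.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y, exact_n = 7L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    # exact permutation distribution of rho given the observed rank ties
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p_value <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p_value <- min(1, max(p_value, 1e-300))
  }
  list(rho = rho, p_value = p_value, n = n)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Centered moving average
#'
#' Edges use the available (shorter) window; a window longer than the
#' series collapses to the global mean with a warning.
#'
#' @param series numeric vector.
#' @param window window size (>= 1 data points).
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(series, window = 20L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(series)
  if (window > n) {
    warning("window longer than series; returning the global mean")
    return(rep(mean(series), n))
  }
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - half_lo):min(n, i + half_hi)])
  }, 0)
}

#' Per-species score ranges
#'
#' For every species with at least `min_genomes` genomes, the mean of its
#' five smallest and five largest scores (the ends of the per-species range
#' bar).
#'
#' @param scores_by_species named list of numeric score vectors.
#' @param min_genomes inclusion threshold.
#' @param n_extremes how many extreme scores to average at each end.
#' @return data.frame with `species`, `n`, `mean_min`, `mean_max`.
#' @export
species_score_range <- function(scores_by_species, min_genomes = 10L,
                                n_extremes = 5L) {
  keep <- vapply(scores_by_species, length, 0L) >= min_genomes
  rows <- lapply(names(scores_by_species)[keep], function(sp) {
    s <- sort(scores_by_species[[sp]])
    k <- min(n_extremes, length(s))
    data.frame(species = sp, n = length(s),
               mean_min = mean(s[seq_len(k)]),
               mean_max = mean(s[seq.int(length(s) - k + 1L, length(s))]),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(species = character(0), n = integer(0),
                      mean_min = numeric(0), mean_max = numeric(0)))
  do.call(rbind, rows)
}

#' Read/write survey tables
#'
#' TSV with columns `subject_id`, `biome`, `depth`, `score`; missing
#' depths allowed (dropped before correlation analyses).
#'
#' @param path file path.
#' @return data.frame for the reader.
#' @export
read_survey_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  stringsAsFactors = FALSE)
  need <- c("subject_id", "biome", "depth", "score")
  if (!all(need %in% colnames(d))) stop("survey TSV needs columns: ",
                                        paste(need, collapse = ", "))
  d
}

#' @rdname read_survey_tsv
#' @param records survey data.frame.
#' @export
write_survey_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
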