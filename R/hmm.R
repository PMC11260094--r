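# Profile hidden Markov models built from per-family protein alignments,
# used to call binary family presence in genomes and metagenomes.
# The architecture is a simplified Plan7: match/insert/delete states with
# local alignment; bit scores are emission log-odds against a background
# model, with gap penalties derived from the transition probabilities and
# normalized so the pure match path carries no transition cost.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.encode_aa <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(ch, .AA) - 1L
  n_unknown <- sum(is.na(idx))
  idx[is.na(idx)] <- -1L
  if (n_unknown > 0L)
    warning(n_unknown, " unknown residue(s) scored as background")
  as.integer(idx)
}

#' Build a profile HMM from a protein multiple alignment
#'
#' Alignment columns with more than 50% gap characters become insert
#' columns; the remaining columns define the match states. Match emissions
#' are the observed residue counts plus `pseudocount_weight` times the
#' background frequencies, normalized. Transition probabilities among
#' match/insert/delete states are estimated from the observed alignment
#' paths with Laplace (add-one) smoothing. The default presence-call
#' threshold is 90% of the minimum Viterbi bit score of the (degapped)
#' training sequences.
#'
#' @param msa named character vector of aligned sequences (equal length;
#'   gaps as `-` or `.`); at least two sequences.
#' @param pseudocount_weight weight of the background pseudocount on match
#'   emissions.
#' @param background amino-acid background frequencies (20 values summing
#'   to 1); uniform by default.
#' @param family_id optional family identifier.
#' @param presence_threshold override for the presence bit-score cutoff.
#' @return object of class `profile_hmm`.
#' @export
build_msa_profile <- function(msa, pseudocount_weight = 1,
                              background = rep(1 / 20, 20),
                              family_id = NULL, presence_threshold = NULL) {
  if (length(msa) < 2L) stop("need at least two aligned sequences")
  chars <- lapply(toupper(msa), function(s) strsplit(s, "")[[1]])
  w <- unique(lengths(chars))
  if (length(w) != 1L) stop("aligned sequences differ in length")
  if (w == 0L) stop("alignment of length 0")
  A <- do.call(rbind, chars)
  is_gap <- A == "-" | A == "."
  match_cols <- which(colMeans(is_gap) <= 0.5)
  M <- length(match_cols)
  if (M == 0L) stop("no match columns (all columns > 50% gaps)")
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-6)

  # match emissions with background pseudocounts
  emis <- matrix(0, M, 20L, dimnames = list(NULL, .AA))
  for (j in seq_len(M)) {
    col <- A[, match_cols[j]]
    cnt <- table(factor(col[col %in% .AA], levels = .AA))
    emis[j, ] <- (as.numeric(cnt) + pseudocount_weight * background) /
      (sum(cnt) + pseudocount_weight)
  }

  # per-boundary transition counts from the observed alignment paths
  # state per sequence and match column: M (residue) or D (gap); inserts
  # are residues in insert columns between consecutive match columns
  nb <- max(M - 1L, 1L)
  cnt <- matrix(0, nb, 7L,
                dimnames = list(NULL, c("MM", "MI", "MD", "II", "IM", "DD", "DM")))
  if (M > 1L) {
    ins_cols <- setdiff(seq_len(w), match_cols)
    for (s in seq_along(chars)) {
      st <- ifelse(is_gap[s, match_cols], "D", "M")
      for (j in seq_len(M - 1L)) {
        between <- ins_cols[ins_cols > match_cols[j] &
                              ins_cols < match_cols[j + 1L]]
        n_ins <- sum(!is_gap[s, between])
        from <- st[j]; to <- st[j + 1L]
        if (n_ins > 0L) {
          cnt[j, "MI"] <- cnt[j, "MI"] + (from == "M")
          cnt[j, "II"] <- cnt[j, "II"] + n_ins - 1L
          cnt[j, "IM"] <- cnt[j, "IM"] + 1L
        } else {
          key <- paste0(from, to)
          if (key %in% colnames(cnt)) cnt[j, key] <- cnt[j, key] + 1L
        }
      }
    }
  }
  # Laplace smoothing; normalize transitions out of each state
  tM <- cnt[, c("MM", "MI", "MD"), drop = FALSE] + 1
  tM <- tM / rowSums(tM)
  tI <- cnt[, c("II", "IM"), drop = FALSE] + 1
  tI <- tI / rowSums(tI)
  tD <- cnt[, c("DD", "DM"), drop = FALSE] + 1
  tD <- tD / rowSums(tD)

  lodds <- log2(pmax(emis, 1e-12)) -
    matrix(log2(background), M, 20L, byrow = TRUE)
  colnames(lodds) <- .AA

  hmm <- structure(list(
    family_id = family_id, model_length = M,
    emissions = emis, lodds = lodds,
    t_match = tM, t_insert = tI, t_delete = tD,
    background = background, pseudocount_weight = pseudocount_weight,
    match_cols = match_cols
  ), class = "profile_hmm")

  # gap penalties (bits), zero-cost for the pure match path
  pen <- function(v) pmax(v, 0)
  io <- pen(log2(tM[, "MM"] / tM[, "MI"]))
  de <- pen(-log2(tD[, "DD"]))
  ie <- pen(-log2(tI[, "II"]))
  do_ <- pen(log2(tM[, "MM"] / tM[, "MD"]))
  idx <- pmin(seq_len(M), nb)
  hmm$ins_open <- io[idx]; hmm$ins_ext <- ie[idx]
  hmm$del_open <- do_[idx]; hmm$del_ext <- de[idx]

  train <- vapply(msa, function(s) gsub("[-.]", "", toupper(s)), "")
  train <- train[nchar(train) > 0L]
  hmm$training_scores <- setNames(.score_encoded(hmm, .encode_proteome(train)),
                                  names(train))
  hmm$presence_threshold <- if (!is.null(presence_threshold))
    presence_threshold else 0.9 * min(hmm$training_scores)
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM%s: %d match states, presence threshold %.1f bits\n",
              if (!is.null(x$family_id)) paste0(" ", x$family_id) else "",
              x$model_length, x$presence_threshold))
  invisible(x)
}

#' Viterbi bit score of a sequence against a profile
#'
#' Best local-alignment log-odds score of the sequence versus the
#' background model, in bits. Unknown residues are emitted as background
#' (score contribution 0, with a warning). Sequence metadata is ignored;
#' the score depends only on the residues.
#'
#' @param hmm a `profile_hmm`.
#' @param sequence non-empty amino-acid string.
#' @return bit score (>= 0; local alignment).
#' @export
viterbi_score <- function(hmm, sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  .viterbi_local_cpp(hmm$lodds, hmm$ins_open, hmm$ins_ext,
                     hmm$del_open, hmm$del_ext, .encode_aa(sequence))
}

# encode a whole proteome once; scoring against every profile reuses it
.encode_proteome <- function(proteome) {
  lapply(proteome, function(s) {
    if (!nzchar(s)) stop("empty sequence")
    .encode_aa(s)
  })
}

.score_encoded <- function(hmm, encoded) {
  .viterbi_batch_cpp(hmm$lodds, hmm$ins_open, hmm$ins_ext,
                     hmm$del_open, hmm$del_ext, encoded)
}

#' Call family presence in a proteome
#'
#' A family is present iff the maximum bit score over the proteome's
#' proteins reaches the profile's presence threshold.
#'
#' @param hmm a `profile_hmm`.
#' @param proteome named character vector of protein sequences (may be
#'   empty).
#' @return list with `present` (logical) and `best_hit` (list of
#'   `sequence_id`, `bit_score`; `NULL` for an empty proteome).
#' @export
call_family_presence <- function(hmm, proteome) {
  if (length(proteome) == 0L)
    return(list(present = FALSE, best_hit = NULL))
  scores <- .score_encoded(hmm, .encode_proteome(proteome))
  i <- which.max(scores)
  list(present = unname(scores[i]) >= hmm$presence_threshold,
       best_hit = list(sequence_id = names(proteome)[i],
                       bit_score = unname(scores[i])))
}

#' Build a library of profile HMMs from per-family alignments
#'
#' @param msas named list of alignments (each a named character vector),
#'   one per ortholog family; families with fewer than two sequences are
#'   skipped with a message.
#' @param ... passed to [build_msa_profile()].
#' @return object of class `hmm_library` (named list of `profile_hmm`).
#' @export
build_hmm_library <- function(msas, ...) {
  keep <- vapply(msas, function(m) length(m) >= 2L, TRUE)
  if (any(!keep))
    message("build_hmm_library: skipping ", sum(!keep),
            " family(ies) with < 2 sequences")
  lib <- lapply(names(msas)[keep], function(f)
    build_msa_profile(msas[[f]], family_id = f, ...))
  names(lib) <- names(msas)[keep]
  structure(lib, class = "hmm_library")
}

#' Binary feature vector of one proteome against an HMM library
#'
#' @param hmm_library an `hmm_library`.
#' @param proteome named character vector of protein sequences.
#' @return named integer 0/1 vector in library order.
#' @export
genome_feature_vector <- function(hmm_library, proteome) {
  if (length(hmm_library) == 0L) stop("empty HMM library")
  if (length(proteome) == 0L)
    return(setNames(integer(length(hmm_library)), names(hmm_library)))
  enc <- .encode_proteome(proteome)
  vapply(hmm_library, function(h)
    as.integer(max(.score_encoded(h, enc)) >= h$presence_threshold), 0L)
}

#' Feature table of many proteomes against an HMM library
#'
#' @param hmm_library an `hmm_library`.
#' @param proteomes named list of proteomes.
#' @return a [feature_table()] (genomes x families, library order).
#' @export
build_feature_table <- function(hmm_library, proteomes) {
  rows <- t(vapply(proteomes, function(p)
    genome_feature_vector(hmm_library, p), integer(length(hmm_library))))
  feature_table(rows, genome_ids = names(proteomes),
                feature_ids = names(hmm_library))
}

#' Serialize an HMM library as plain text
#'
#' One block per family: identifier, model length, presence threshold,
#' background frequencies, match emission probabilities (one row per match
#' state) and per-boundary transition probabilities
#' (MM MI MD II IM DD DM), terminated by `//`.
#'
#' @param lib an `hmm_library`.
#' @param path file path.
#' @export
write_hmm_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  for (h in lib) {
    writeLines(c(paste("FAMILY", h$family_id),
                 paste("LENGTH", h$model_length),
                 paste("THRESHOLD", sprintf("%.10g", h$presence_threshold)),
                 paste("PSEUDOCOUNT", sprintf("%.10g", h$pseudocount_weight)),
                 paste("BACKGROUND", fmt(h$background))), con)
    writeLines("EMISSIONS", con)
    for (j in seq_len(h$model_length)) writeLines(fmt(h$emissions[j, ]), con)
    writeLines("TRANSITIONS", con)
    for (j in seq_len(nrow(h$t_match)))
      writeLines(fmt(c(h$t_match[j, ], h$t_insert[j, ], h$t_delete[j, ])), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' @rdname write_hmm_library
#' @export
read_hmm_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lib <- list(); i <- 1L
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "FAMILY")) { i <- i + 1L; next }
    fam <- sub("^FAMILY\\s+", "", lines[i])
    M <- as.integer(sub("^LENGTH\\s+", "", lines[i + 1L]))
    thr <- as.numeric(sub("^THRESHOLD\\s+", "", lines[i + 2L]))
    pc <- as.numeric(sub("^PSEUDOCOUNT\\s+", "", lines[i + 3L]))
    bg <- num(sub("^BACKGROUND\\s+", "", lines[i + 4L]))
    stopifnot(lines[i + 5L] == "EMISSIONS")
    emis <- do.call(rbind, lapply(lines[(i + 6L):(i + 5L + M)], num))
    colnames(emis) <- .AA
    j0 <- i + 6L + M
    stopifnot(lines[j0] == "TRANSITIONS")
    nb <- max(M - 1L, 1L)
    tr <- do.call(rbind, lapply(lines[(j0 + 1L):(j0 + nb)], num))
    tM <- tr[, 1:3, drop = FALSE]; tI <- tr[, 4:5, drop = FALSE]
    tD <- tr[, 6:7, drop = FALSE]
    colnames(tM) <- c("MM", "MI", "MD"); colnames(tI) <- c("II", "IM")
    colnames(tD) <- c("DD", "DM")
    lodds <- log2(pmax(emis, 1e-12)) -
      matrix(log2(bg), M, 20L, byrow = TRUE)
    colnames(lodds) <- .AA
    h <- structure(list(
      family_id = fam, model_length = M, emissions = emis, lodds = lodds,
      t_match = tM, t_insert = tI, t_delete = tD, background = bg,
      pseudocount_weight = pc, presence_threshold = thr
    ), class = "profile_hmm")
    pen <- function(v) pmax(v, 0)
    idx <- pmin(seq_len(M), nb)
    h$ins_open <- pen(log2(tM[, "MM"] / tM[, "MI"]))[idx]
    h$ins_ext <- pen(-log2(tI[, "II"]))[idx]
    h$del_open <- pen(log2(tM[, "MM"] / tM[, "MD"]))[idx]
    h$del_ext <- pen(-log2(tD[, "DD"]))[idx]
    lib[[fam]] <- h
    i <- j0 + nb + 1L
  }
  structure(lib, class = "hmm_library")
}

#' Parse HMMER3 `--tblout` output into a feature table
#'
#' Comment lines (`#`) are skipped. A (genome, family) pair is called
#' present iff any hit for that pair has a full-sequence bit score at or
#' above the family's threshold. Genome ids are taken from the target
#' name prefix before the first `|` (the whole name when there is none),
#' overridable via `genome_of`.
#'
#' @param path tblout file.
#' @param score_thresholds named numeric vector of per-family bit-score
#'   cutoffs; names fix the feature order.
#' @param genome_ids optional genome universe (rows of the output); by
#'   default the genomes seen in the file.
#' @param genome_of function mapping target names to genome ids.
#' @return a [feature_table()].
#' @export
parse_hmmsearch_tblout <- function(path, score_thresholds, genome_ids = NULL,
                                   genome_of = function(x) sub("\\|.*$", "", x)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  fams <- names(score_thresholds)
  rows <- which(keep)
  tgt <- character(0); qry <- character(0); sc <- numeric(0)
  for (k in rows) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 6L) stop("malformed tblout line ", k)
    s <- suppressWarnings(as.numeric(f[6]))
    if (is.na(s)) stop("malformed tblout line ", k, ": bad score field")
    tgt <- c(tgt, f[1]); qry <- c(qry, f[3]); sc <- c(sc, s)
  }
  gen <- genome_of(tgt)
  if (is.null(genome_ids)) genome_ids <- unique(gen)
  calls <- matrix(0L, length(genome_ids), length(fams),
                  dimnames = list(genome_ids, fams))
  ok <- qry %in% fams & gen %in% genome_ids &
    sc >= score_thresholds[qry] - 1e-12
  for (k in which(ok)) calls[gen[k], qry[k]] <- 1L
  feature_table(calls)
}

#' Write hits in HMMER3 `--tblout` layout
#'
#' Companion to [parse_hmmsearch_tblout()] for round-tripping the built-in
#' scorer's hits through the external-table interface.
#'
#' @param hits data.frame with columns `target`, `family`, `score` and
#'   optionally `evalue`.
#' @param path output path.
#' @export
write_tblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target name        accession  query name           accession    E-value  score  bias", con)
  for (k in seq_len(nrow(hits))) {
    ev <- if ("evalue" %in% names(hits)) hits$evalue[k] else NA
    writeLines(sprintf("%-20s -          %-20s -          %9s %6.1f    0.0",
                       hits$target[k], hits$family[k],
                       ifelse(is.na(ev), "-", sprintf("%.2g", ev)),
                       hits$score[k]), con)
  }
  invisible(path)
}
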