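#' @useDynLib iridetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rexp rnorm runif rbinom setNames quantile density
#'   pnorm qnorm pbinom dhyper p.adjust hclust dist cutree cor pt complete.cases
#' @importFrom utils read.table write.table count.fields
NULL

# Roary's fixed metadata columns; versions differ, so any unrecognized column
# appearing before the last recognized one is also treated as metadata.
.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC",
  "Min group size nuc", "Max group size nuc", "Avg group size nuc"
)

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  # count separators outside quotes
  chars <- strsplit(first, "")[[1]]
  inq <- FALSE; nc <- 0L; nt <- 0L
  for (ch in chars) {
    if (ch == '"') inq <- !inq
    else if (!inq && ch == ",") nc <- nc + 1L
    else if (!inq && ch == "\t") nt <- nt + 1L
  }
  if (nt > nc) "\t" else ","
}

#' Construct an ortholog presence/absence matrix
#'
#' The central pan-genome container: a binary strains x ortholog-families
#' matrix, 1 meaning the strain carries at least one member gene of the
#' family.
#'
#' @param presence numeric matrix coercible to 0/1, strains in rows.
#' @param strain_ids,family_ids optional identifier vectors; taken from
#'   `dimnames(presence)` when missing.
#' @return an integer matrix of class `ortholog_matrix` with strain row names
#'   and family column names.
#' @export
ortholog_matrix <- function(presence, strain_ids = rownames(presence),
                            family_ids = colnames(presence)) {
  m <- as.matrix(presence)
  if (is.null(strain_ids) || is.null(family_ids))
    stop("strain and family ids are required")
  if (anyDuplicated(strain_ids)) stop("duplicate strain ids")
  if (anyDuplicated(family_ids)) stop("duplicate family ids")
  if (nrow(m) != length(strain_ids) || ncol(m) != length(family_ids))
    stop("id lengths do not match matrix dimensions")
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("presence entries must be 0 or 1")
  dimnames(m) <- list(strain_ids, family_ids)
  class(m) <- c("ortholog_matrix", class(matrix()))
  m
}

#' @export
print.ortholog_matrix <- function(x, ...) {
  cat(sprintf("ortholog presence/absence matrix: %d strains x %d families\n",
              nrow(x), ncol(x)))
  cat(sprintf("  overall presence frequency: %.3f\n", mean(x)))
  invisible(x)
}

#' Read a Roary-style gene presence/absence CSV
#'
#' Reads the `gene_presence_absence.csv` dialect: one row per ortholog
#' family, fixed metadata columns first, then one column per strain whose
#' cells hold the member gene names (empty means absent). Cells listing
#' several paralogs (separated by `;`) collapse to presence = 1.
#'
#' @param path file path; the field separator (comma or tab) is sniffed from
#'   the first line.
#' @return an [ortholog_matrix()] (strains x families).
#' @export
read_gpa_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path)
  nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, " at line ", bad)
  }
  d <- read.table(path, sep = sep, header = TRUE, quote = "\"",
                  check.names = FALSE, colClasses = "character",
                  comment.char = "")
  meta_idx <- which(colnames(d) %in% .roary_meta_cols)
  last_meta <- if (length(meta_idx)) max(meta_idx) else 1L
  if (last_meta >= ncol(d)) stop("no strain columns found")
  fam <- d[[1]]
  if (anyDuplicated(fam)) stop("duplicate family id: ",
                               fam[duplicated(fam)][1])
  strains <- colnames(d)[(last_meta + 1L):ncol(d)]
  cells <- as.matrix(d[, (last_meta + 1L):ncol(d), drop = FALSE])
  pres <- t((!is.na(cells)) & nchar(trimws(cells)) > 0L) * 1L
  ortholog_matrix(pres, strain_ids = strains, family_ids = fam)
}

#' Write an ortholog matrix in the Roary CSV dialect
#'
#' Inverse of [read_gpa_csv()]: present cells are filled with a placeholder
#' gene name `<family>_<strain>`, absent cells left empty.
#'
#' @param x an [ortholog_matrix()].
#' @param path output path.
#' @export
write_gpa_csv <- function(x, path) {
  fam <- colnames(x); strains <- rownames(x)
  cells <- matrix("", nrow = ncol(x), ncol = nrow(x),
                  dimnames = list(NULL, strains))
  for (i in seq_along(strains))
    cells[x[i, ] == 1L, i] <- paste0(fam[x[i, ] == 1L], "_", strains[i])
  out <- data.frame(Gene = fam, Annotation = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cells, check.names = FALSE))
  write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a strain phenotype table
#'
#' @param strain_id character vector of unique strain ids.
#' @param label phenotype per strain: `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @param gram gram status per strain (same three-state coding,
#'   `"unknown"` by default).
#' @param taxon optional taxon annotation.
#' @return a data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(strain_id, label,
                            gram = rep("unknown", length(strain_id)),
                            taxon = rep(NA_character_, length(strain_id))) {
  strain_id <- as.character(strain_id)
  if (anyDuplicated(strain_id)) stop("duplicate strain id: ",
                                     strain_id[duplicated(strain_id)][1])
  ok <- c("positive", "negative", "unknown")
  label <- as.character(label); gram <- as.character(gram)
  if (!all(label %in% ok)) stop("labels must be positive/negative/unknown")
  if (!all(gram %in% ok)) stop("gram must be positive/negative/unknown")
  out <- data.frame(strain_id = strain_id, label = label, gram = gram,
                    taxon = as.character(taxon), stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

.decode_binary_label <- function(x, what) {
  x <- trimws(as.character(x))
  out <- rep("unknown", length(x))
  out[x == "1"] <- "positive"
  out[x == "0"] <- "negative"
  bad <- !(x %in% c("0", "1", "", "NA")) & !is.na(x)
  if (any(bad)) stop(what, " values must be 0, 1 or blank; got '",
                     x[bad][1], "'")
  out[is.na(x)] <- "unknown"
  out
}

#' Read a traits CSV of binary phenotype labels
#'
#' Expects the trait-file dialect used by pan-GWAS tools: first column strain
#' id, remaining columns binary traits coded 1 (positive), 0 (negative) or
#' blank (unknown). Columns named `gram` (0 = gram-negative, 1 =
#' gram-positive) and `taxon` are recognized as annotations rather than
#' traits.
#'
#' @param path file path (comma or tab separated, sniffed).
#' @param trait trait column name; defaults to the first non-annotation
#'   column after the strain id.
#' @return a [phenotype_table()]. An empty file yields an empty table.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(phenotype_table(character(), character()))
  sep <- .sniff_sep(path)
  d <- read.table(path, sep = sep, header = TRUE, quote = "\"",
                  check.names = FALSE, colClasses = "character",
                  comment.char = "")
  if (nrow(d) == 0L) return(phenotype_table(character(), character()))
  ids <- d[[1]]
  ann <- tolower(colnames(d)) %in% c("gram", "taxon")
  candidates <- setdiff(which(!ann), 1L)
  if (is.null(trait)) {
    if (!length(candidates)) stop("no trait column found")
    trait_col <- candidates[1]
  } else {
    trait_col <- match(trait, colnames(d))
    if (is.na(trait_col)) stop("trait column not found: ", trait)
  }
  label <- .decode_binary_label(d[[trait_col]], "trait")
  gram <- if ("gram" %in% tolower(colnames(d))) {
    g <- d[[which(tolower(colnames(d)) == "gram")[1]]]
    # gram file coding: 0 = gram-negative, 1 = gram-positive
    gg <- .decode_binary_label(g, "gram")
    gg
  } else rep("unknown", length(ids))
  taxon <- if ("taxon" %in% tolower(colnames(d)))
    d[[which(tolower(colnames(d)) == "taxon")[1]]]
  else rep(NA_character_, length(ids))
  phenotype_table(ids, label, gram, taxon)
}

#' Write a phenotype table as a traits CSV
#'
#' @param x a [phenotype_table()].
#' @param path output path.
#' @param trait name for the trait column.
#' @export
write_phenotypes <- function(x, path, trait = "SC") {
  enc <- function(v) ifelse(v == "positive", "1",
                            ifelse(v == "negative", "0", ""))
  out <- data.frame(strain = x$strain_id, enc(x$label),
                    gram = enc(x$gram), taxon = x$taxon,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[2] <- trait
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read a rooted strain tree in newick format
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object; a multifurcating root is
#'   retained and flagged via `attr(tree, "multifurcating_root")`.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree")
  root <- ape::Ntip(tr) + 1L
  attr(tr, "multifurcating_root") <- sum(tr$edge[, 1] == root) > 2L
  tr
}

#' Restrict matrix and phenotypes to shared, labeled strains
#'
#' Both inputs are cut down to the intersection of their strain ids,
#' excluding strains with unknown phenotype, in the matrix's strain order.
#' Dropped strains are reported via [message()].
#'
#' @param matrix an [ortholog_matrix()].
#' @param phenotypes a [phenotype_table()].
#' @return list with elements `matrix` and `phenotypes`, equally ordered.
#' @export
align_matrix_phenotypes <- function(matrix, phenotypes) {
  labeled <- phenotypes$strain_id[phenotypes$label != "unknown"]
  keep <- rownames(matrix)[rownames(matrix) %in% labeled]
  if (!length(keep)) stop("no labeled strains shared between matrix and phenotypes")
  dropped <- setdiff(union(rownames(matrix), phenotypes$strain_id), keep)
  if (length(dropped))
    message("align_matrix_phenotypes: dropped ", length(dropped),
            " strain(s): ", paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  m <- matrix[keep, , drop = FALSE]
  class(m) <- c("ortholog_matrix", class(matrix()))
  ph <- phenotypes[match(keep, phenotypes$strain_id), , drop = FALSE]
  rownames(ph) <- NULL
  class(ph) <- c("phenotype_table", "data.frame")
  list(matrix = m, phenotypes = ph)
}

#' Construct a binary feature table
#'
#' Genomes x features binary matrix of profile-HMM presence calls, the input
#' format of the random-forest classifier. Feature order is significant and
#' must match the order used at training time when predicting.
#'
#' @param calls binary matrix (genomes in rows) or coercible.
#' @param genome_ids,feature_ids optional ids, default from dimnames.
#' @return integer matrix of class `feature_table`.
#' @export
feature_table <- function(calls, genome_ids = rownames(calls),
                          feature_ids = colnames(calls)) {
  m <- as.matrix(calls)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("feature calls must be 0 or 1")
  if (is.null(genome_ids) || is.null(feature_ids))
    stop("genome and feature ids are required")
  if (anyDuplicated(genome_ids)) stop("duplicate genome ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  dimnames(m) <- list(genome_ids, feature_ids)
  class(m) <- c("feature_table", class(matrix()))
  m
}

#' Read/write feature tables as TSV
#'
#' The serialization is a plain TSV with a header row of feature ids and the
#' genome id in the first column.
#'
#' @param path file path.
#' @return [feature_table()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_feature_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  row.names = 1L)
  feature_table(as.matrix(d))
}

#' @rdname read_feature_tsv
#' @param x a [feature_table()].
#' @export
write_feature_tsv <- function(x, path) {
  out <- data.frame(genome = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write protein FASTA files
#'
#' Minimal FASTA support for protein sets: sequence names are the word after
#' `>`; sequences may wrap over multiple lines.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nchar(lines) > 0L]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("not a FASTA file: ", path)
  if (!length(lines)) return(setNames(character(), character()))
  idx <- cumsum(hdr)
  names_full <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(names_full, "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste0, "", collapse = "")
  # preserve record order; records with no sequence lines become ""
  out <- setNames(rep("", sum(hdr)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
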