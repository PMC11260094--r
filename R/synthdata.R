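# Seeded generators for pan-genomes, phenotypes, protein families, survey
# tables and goniometer spectra with the statistical structure the pipeline
# assumes, so every stage can be exercised without downloads.

#' Default simulation configuration
#'
#' The defaults define the reference synthetic study: 120 strains, 200
#' ortholog families of which 20 causally determine a binary colony
#' phenotype (positive when at least 10 causal families are present, labels
#' flipped with probability 0.05), gene gain/loss along a Yule tree with
#' symmetric rates (stationary presence frequency 0.5, matching the
#' intermediate-frequency profile expected of phenotype-informative
#' accessory genes), ungapped protein families of length 120 at 5% per-site
#' divergence, and a 450-record depth survey targeting a score-depth
#' Spearman correlation of 0.41.
#'
#' @param ... overrides of any default element.
#' @return named list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_strains = 120L, n_families = 200L, n_causal = 20L,
    gain = 0.5, loss = 0.5, root_prob = 0.5,
    pathway_gain = 0.3, pathway_loss = 0.3, causal_deviation = 0.1,
    threshold = 10L, noise = 0.05,
    seq_len = 120L, mutation_rate = 0.05,
    survey_n = 450L, depth_range = c(0, 4000), target_rho = 0.41,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_causal > cfg$n_families) stop("n_causal must be <= n_families")
  if (cfg$noise < 0 || cfg$noise >= 0.5) stop("noise rate must be in [0, 0.5)")
  if (cfg$gain < 0 || cfg$loss < 0) stop("rates must be >= 0")
  cfg
}

#' Simulate a Yule strain tree
#'
#' Pure-birth topology (a uniformly chosen tip bifurcates at each step)
#' with i.i.d. exponential branch lengths (mean 0.2); leaves are named
#' `s1 ... sn`.
#'
#' @param n_strains number of leaves (>= 2).
#' @param seed RNG seed.
#' @param mean_branch mean branch length.
#' @return a rooted binary `phylo` object.
#' @export
simulate_tree <- function(n_strains, seed = 1L, mean_branch = 0.2) {
  if (n_strains < 2L) stop("need at least 2 strains")
  set.seed(as.integer(seed))
  # children[[k]]: internal node k's two children (negative = leaf index)
  children <- list(c(-1L, -2L))
  leaf_parent <- c(1L, 1L)     # internal node owning each current leaf
  leaf_slot <- c(1L, 2L)
  while (length(leaf_parent) < n_strains) {
    i <- sample.int(length(leaf_parent), 1L)
    k <- length(children) + 1L
    new_leaf <- length(leaf_parent) + 1L
    children[[k]] <- c(-i, -new_leaf)
    children[[leaf_parent[i]]][leaf_slot[i]] <- k
    leaf_parent[new_leaf] <- k; leaf_slot[new_leaf] <- 2L
    leaf_parent[i] <- k; leaf_slot[i] <- 1L
  }
  build <- function(node) {
    kids <- vapply(children[[node]], function(ch) {
      bl <- sprintf(":%.6f", rexp(1, rate = 1 / mean_branch))
      if (ch < 0L) paste0("s", -ch, bl) else paste0(build(ch), bl)
    }, "")
    paste0("(", paste(kids, collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(build(1L), ";"))
  tr
}

#' Evolve binary gene content along a tree
#'
#' Each family follows an independent two-state continuous-time Markov
#' chain (rates `gain` for 0 to 1, `loss` for 1 to 0) along the branches,
#' starting from Bernoulli(`root_prob`) root states.
#'
#' @param tree a `phylo` with branch lengths.
#' @param n_families number of families.
#' @param gain,loss transition rates per unit branch length.
#' @param root_prob presence probability at the root.
#' @param seed RNG seed.
#' @param family_ids optional family names, default `fam001 ...`.
#' @return an [ortholog_matrix()] (tips x families).
#' @export
evolve_gene_content <- function(tree, n_families, gain = 0.5, loss = 0.5,
                                root_prob = NULL, seed = 1L,
                                family_ids = NULL) {
  if (gain < 0 || loss < 0) stop("rates must be >= 0")
  set.seed(as.integer(seed))
  rate <- gain + loss
  pi1 <- if (rate > 0) gain / rate else 0.5
  if (is.null(root_prob)) root_prob <- pi1
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_families)
  root <- ntip + 1L
  states[root, ] <- rbinom(n_families, 1L, root_prob)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    decay <- if (rate > 0) exp(-rate * t) else 1
    p1 <- pi1 + (states[par, ] - pi1) * decay    # P(child = 1 | parent)
    states[child, ] <- rbinom(n_families, 1L, p1)
  }
  if (is.null(family_ids))
    family_ids <- sprintf("fam%03d", seq_len(n_families))
  ortholog_matrix(states[seq_len(ntip), , drop = FALSE],
                  strain_ids = tree$tip.label, family_ids = family_ids)
}

#' Assign binary phenotypes from causal gene content
#'
#' A strain is phenotype-positive iff it carries at least `threshold` of
#' the causal families; each label is then flipped independently with
#' probability `noise`.
#'
#' @param matrix an [ortholog_matrix()].
#' @param causal_ids causal family ids (subset of the matrix columns).
#' @param threshold causal-gene count needed for a positive phenotype.
#' @param noise label flip probability in \[0, 0.5).
#' @param seed RNG seed.
#' @return a [phenotype_table()] (all strains gram-negative).
#' @export
assign_phenotypes <- function(matrix, causal_ids, threshold = 10L,
                              noise = 0.05, seed = 1L) {
  if (!all(causal_ids %in% colnames(matrix)))
    stop("causal ids must be matrix families")
  if (noise < 0 || noise >= 0.5) stop("noise rate must be in [0, 0.5)")
  set.seed(as.integer(seed))
  count <- rowSums(matrix[, causal_ids, drop = FALSE])
  pos <- count >= threshold
  flip <- runif(nrow(matrix)) < noise
  pos <- xor(pos, flip)
  phenotype_table(rownames(matrix),
                  ifelse(pos, "positive", "negative"),
                  gram = rep("negative", nrow(matrix)))
}

#' Generate per-strain proteomes and per-family alignments
#'
#' One random ancestral sequence is drawn per family; every member gene is
#' the ancestor with i.i.d. substitutions (at `mutation_rate`, the
#' substituted residue drawn uniformly from all 20 amino acids). Members
#' are ungapped and equal-length, so the family alignment is the plain
#' stack of member sequences.
#'
#' @param matrix an [ortholog_matrix()].
#' @param seq_len protein length (>= 10).
#' @param mutation_rate per-site substitution probability.
#' @param seed RNG seed.
#' @return list with `proteomes` (named list per strain of named protein
#'   vectors `<family>|<strain>`) and `msas` (named list per family).
#' @export
generate_proteomes <- function(matrix, seq_len = 120L, mutation_rate = 0.05,
                               seed = 1L) {
  if (seq_len < 10L) stop("seq_len must be >= 10")
  set.seed(as.integer(seed))
  strains <- rownames(matrix); fams <- colnames(matrix)
  msas <- setNames(vector("list", length(fams)), fams)
  prots <- lapply(strains, function(s) character(0))
  names(prots) <- strains
  for (f in fams) {
    anc <- sample(.AA, seq_len, replace = TRUE)
    members <- strains[matrix[, f] == 1L]
    if (!length(members)) { msas[[f]] <- character(0); next }
    seqs <- vapply(members, function(s) {
      mut <- runif(seq_len) < mutation_rate
      x <- anc
      if (any(mut)) x[mut] <- sample(.AA, sum(mut), replace = TRUE)
      paste(x, collapse = "")
    }, "")
    names(seqs) <- paste0(f, "|", members)
    msas[[f]] <- seqs
    for (s in members) prots[[s]] <- c(prots[[s]], seqs[paste0(f, "|", s)])
  }
  list(proteomes = prots, msas = msas)
}

#' Simulate the full synthetic study
#'
#' Bundles [simulate_tree()], [evolve_gene_content()],
#' [assign_phenotypes()] and [generate_proteomes()] under one
#' configuration and seed. Background families evolve independently; the
#' causal families form a co-evolving pathway block: a single latent
#' pathway presence state evolves along the tree (rates `pathway_gain`,
#' `pathway_loss`) and each causal family copies it with an independent
#' per-tip deviation probability `causal_deviation`, emulating the
#' co-present gene-cluster structure of a pathway-determined colony
#' phenotype.
#'
#' @param cfg a [sim_config()].
#' @return list with `tree`, `matrix`, `phenotypes`, `proteomes`, `msas`,
#'   `causal_ids` and the `config` used.
#' @export
simulate_sc_study <- function(cfg = sim_config()) {
  tree <- simulate_tree(cfg$n_strains, seed = cfg$seed)
  mat <- evolve_gene_content(tree, cfg$n_families, gain = cfg$gain,
                             loss = cfg$loss, root_prob = cfg$root_prob,
                             seed = cfg$seed + 1L)
  causal <- colnames(mat)[seq_len(cfg$n_causal)]
  # overwrite the causal block with the pathway-coupled states
  pathway <- evolve_gene_content(tree, 1L, gain = cfg$pathway_gain,
                                 loss = cfg$pathway_loss,
                                 root_prob = 0.5, seed = cfg$seed + 10L)[, 1]
  set.seed(cfg$seed + 11L)
  dev <- matrix(runif(cfg$n_strains * cfg$n_causal) < cfg$causal_deviation,
                cfg$n_strains, cfg$n_causal)
  causal_states <- (matrix(pathway, cfg$n_strains, cfg$n_causal) + dev) %% 2L
  m2 <- unclass(mat)
  m2[, causal] <- causal_states
  mat <- ortholog_matrix(m2)
  ph <- assign_phenotypes(mat, causal, threshold = cfg$threshold,
                          noise = cfg$noise, seed = cfg$seed + 2L)
  pr <- generate_proteomes(mat, seq_len = cfg$seq_len,
                           mutation_rate = cfg$mutation_rate,
                           seed = cfg$seed + 3L)
  list(tree = tree, matrix = mat, phenotypes = ph,
       proteomes = pr$proteomes, msas = pr$msas,
       causal_ids = causal, config = cfg)
}

#' Generate a survey table with a target score-depth correlation
#'
#' Depths are uniform on `depth_range`; scores are coupled to depth by a
#' Gaussian copula whose Pearson parameter `2 sin(pi * rho / 6)` yields the
#' requested Spearman correlation. Score marginals are uniform on \[0, 1\]
#' by default, or the empirical quantiles of `scores` when supplied.
#'
#' @param n number of records (>= 10).
#' @param target_rho target Spearman correlation, |rho| <= 1.
#' @param depth_range depth interval in meters.
#' @param seed RNG seed.
#' @param scores optional score sample defining the score marginal.
#' @param biome biome label attached to every record.
#' @return data.frame with `subject_id`, `biome`, `depth`, `score`.
#' @export
generate_survey_records <- function(n = 450L, target_rho = 0.41,
                                    depth_range = c(0, 4000), seed = 1L,
                                    scores = NULL, biome = "marine") {
  if (n < 10L) stop("n must be >= 10")
  if (abs(target_rho) > 1) stop("|target_rho| must be <= 1")
  set.seed(as.integer(seed))
  r <- 2 * sin(pi * target_rho / 6)
  z1 <- rnorm(n)
  z2 <- if (abs(r) >= 1) sign(r) * z1
  else r * z1 + sqrt(1 - r^2) * rnorm(n)
  depth <- depth_range[1] + (depth_range[2] - depth_range[1]) * pnorm(z1)
  u <- pnorm(z2)
  score <- if (is.null(scores)) u else
    as.numeric(quantile(scores, probs = u, type = 8))
  data.frame(subject_id = sprintf("mg%04d", seq_len(n)),
             biome = biome, depth = depth, score = score,
             stringsAsFactors = FALSE)
}

#' Forward-model an angle-resolved reflectance spectrum
#'
#' Gaussian intensity ridges are placed at the diffraction wavelengths
#' `predict_spot_wavelength(d, theta_in, theta_out, m)` for every grid
#' angle and order, plus optional additive noise. The specular band at
#' `theta_out = -theta_in` is marked as masked (the goniometer cannot
#' measure there).
#'
#' @param d lattice constant (nm).
#' @param theta_in incident angle (degrees, default -45).
#' @param angle_grid detection angles (degrees).
#' @param lambda_grid wavelengths (nm, ascending).
#' @param orders diffraction orders to render.
#' @param peak_width Gaussian ridge width (nm).
#' @param noise additive noise standard deviation.
#' @param seed RNG seed.
#' @param mask_halfwidth half-width (degrees) of the specular mask.
#' @return a [spectra_matrix()].
#' @export
generate_goniometer_spectrum <- function(d, theta_in = -45,
                                         angle_grid = seq(-60, 60, by = 2),
                                         lambda_grid = seq(380, 780, by = 2),
                                         orders = c(-1L, 1L), peak_width = 10,
                                         noise = 0, seed = 1L,
                                         mask_halfwidth = 5) {
  if (d <= 0) stop("d must be > 0")
  set.seed(as.integer(seed))
  I <- matrix(0, length(lambda_grid), length(angle_grid))
  for (ai in seq_along(angle_grid)) {
    for (m in orders) {
      lam <- predict_spot_wavelength(d, theta_in, angle_grid[ai], m)
      if (is.na(lam)) next
      I[, ai] <- I[, ai] + exp(-(lambda_grid - lam)^2 / (2 * peak_width^2))
    }
  }
  if (noise > 0) I <- I + abs(rnorm(length(I), sd = noise))
  spectra_matrix(lambda_grid, angle_grid, I, theta_in = theta_in,
                 specular_mask = c(-theta_in - mask_halfwidth,
                                   -theta_in + mask_halfwidth))
}
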