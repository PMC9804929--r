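#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministic counter scheme: stage k maps to
#' `((seed + 104729 * k) mod (2^31 - 1)) + 1`, keeping every derived seed a
#' valid 32-bit integer. Used by the pipeline so each stage is individually
#' reproducible from the single global seed.
#'
#' @param seed Integer global seed.
#' @param k Integer stage counter (>= 0).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, k = 0L) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483646) + 1L
}

#' The 13 olfactory-receptor subfamily labels
#'
#' Class I subfamilies (OR51, OR52, OR55, OR56) and the nine Class II
#' subfamily groups commonly recovered from bat olfactory transcriptomes.
#'
#' @return Character vector of length 13.
#' @export
or_subfamilies <- function() {
  c("OR51", "OR52", "OR55", "OR56",
    "OR1/3/7", "OR2/13", "OR4", "OR5/8/9", "OR6",
    "OR10", "OR11", "OR12", "OR14")
}

#' Default per-subfamily simulation settings
#'
#' Each subfamily gets a linear codon-on-nucleotide coupling (slope,
#' intercept), a gene count, and a lognormal rate-noise SD. Default slopes
#' spread evenly across subfamilies around 1 (codon branch lengths per codon
#' site are of the same order as nucleotide lengths per nucleotide site, with
#' subfamily-specific selection regimes shifting the coupling up or down).
#'
#' @param labels Subfamily labels.
#' @param slopes Numeric vector of codon-vs-nucleotide slopes (recycled).
#' @param intercepts Numeric vector of codon intercepts (recycled).
#' @param gene_count_per_species Genes per subfamily.
#' @param rate_lognorm_sd Lognormal SD of per-gene and per-edge rate noise.
#' @return Data frame with one row per subfamily.
#' @export
default_subfamilies <- function(labels = or_subfamilies(),
                                slopes = seq(0.7, 1.3,
                                             length.out = length(labels)),
                                intercepts = 0,
                                gene_count_per_species = 10L,
                                rate_lognorm_sd = 0.3) {
  data.frame(
    label = labels,
    codon_slope = rep_len(slopes, length(labels)),
    codon_intercept = rep_len(intercepts, length(labels)),
    gene_count_per_species = rep_len(as.integer(gene_count_per_species),
                                     length(labels)),
    rate_lognorm_sd = rep_len(rate_lognorm_sd, length(labels)),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Defaults emulate the study system: a timetree of about 30 bat species,
#' roughly half plant-visiting, log-log allometry of olfactory epithelium
#' surface area on body mass with a phylogenetically structured species
#' effect, 13 OR subfamilies whose codon branch lengths scale linearly with
#' nucleotide branch lengths, and partial gene detection at 55% (the midpoint
#' of the 50-60% recovery reported for olfactory transcriptomes). Species
#' effects entering the multiresponse scenario are drawn jointly for the
#' codon-rate level and log surface area with a default correlation of -0.7,
#' the inverse rate-morphology coupling the multiresponse suite is designed
#' to detect.
#'
#' @param seed Integer seed.
#' @param n_species Number of tips in the species tree.
#' @param birth_rate Yule birth rate (per unit time).
#' @param plant_fraction Fraction of species given a negative dietary index.
#' @param allometry Named list with elements `plant` and `animal`, each a
#'   list(intercept=, slope=) on the log-log scale (log mm^2 vs log g).
#' @param phylo_var Variance of the Brownian species effect on log surface
#'   area (per unit tree depth; the tree is rescaled to depth 1 internally).
#' @param resid_var Residual variance of log surface area.
#' @param mass_logmean,mass_logsd Log-scale mean/SD of body mass (g).
#' @param subfamilies Data frame as from [default_subfamilies()].
#' @param detection_prob Probability a gene is recovered for a species.
#' @param species_covariance 2x2 PSD matrix: joint species-effect covariance
#'   for (codon-rate level, log surface area).
#' @param n_mormoopids Number of species flagged as the atypical clade whose
#'   exclusion is rerun (a clade of about this size is flagged).
#' @return List of class "sim_config".
#' @export
sim_config <- function(seed = 1L,
                       n_species = 30L,
                       birth_rate = 1,
                       plant_fraction = 0.5,
                       allometry = list(
                         plant = list(intercept = 2.0, slope = 0.6),
                         animal = list(intercept = 1.8, slope = 0.4)
                       ),
                       phylo_var = 0.05,
                       resid_var = 0.05,
                       mass_logmean = 3.0,
                       mass_logsd = 0.8,
                       subfamilies = default_subfamilies(),
                       detection_prob = 0.55,
                       species_covariance = matrix(
                         c(0.09, -0.7 * 0.09, -0.7 * 0.09, 0.09), 2, 2),
                       n_mormoopids = 3L) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              birth_rate = birth_rate, plant_fraction = plant_fraction,
              allometry = allometry, phylo_var = phylo_var,
              resid_var = resid_var, mass_logmean = mass_logmean,
              mass_logsd = mass_logsd, subfamilies = subfamilies,
              detection_prob = detection_prob,
              species_covariance = species_covariance,
              n_mormoopids = as.integer(n_mormoopids))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_species < 2L) stop("n_species must be >= 2", call. = FALSE)
  if (cfg$birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (cfg$plant_fraction < 0 || cfg$plant_fraction > 1) {
    stop("plant_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$phylo_var < 0) stop("phylo_var must be >= 0", call. = FALSE)
  if (cfg$resid_var <= 0) stop("resid_var must be > 0", call. = FALSE)
  if (cfg$detection_prob <= 0 || cfg$detection_prob > 1) {
    stop("detection_prob must be in (0, 1]", call. = FALSE)
  }
  sf <- cfg$subfamilies
  req <- c("label", "codon_slope", "codon_intercept",
           "gene_count_per_species", "rate_lognorm_sd")
  if (!is.data.frame(sf) || !all(req %in% names(sf)) || nrow(sf) == 0) {
    stop("subfamilies must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(sf$codon_slope <= 0)) stop("codon_slope must be > 0", call. = FALSE)
  if (any(sf$rate_lognorm_sd < 0)) {
    stop("rate_lognorm_sd must be >= 0", call. = FALSE)
  }
  if (!all(sf$label %in% or_subfamilies())) {
    stop("subfamily labels must be drawn from or_subfamilies()",
         call. = FALSE)
  }
  S <- cfg$species_covariance
  if (!is.matrix(S) || !all(dim(S) == 2) || max(abs(S - t(S))) > 1e-12 ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("species_covariance must be a symmetric PSD 2x2 matrix",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate an ultrametric Yule (pure-birth) species tree
#'
#' Forward simulation: starting from two lineages at the root, waiting times
#' between speciation events are exponential with rate `birth_rate` times the
#' number of extant lineages, and the splitting lineage is chosen uniformly.
#' After the n-th lineage appears, a final exponential waiting time is added
#' so tips do not terminate exactly at a speciation event. The result is
#' ultrametric by construction. Deterministic given `seed`.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed (sets the RNG).
#' @return A "phylo" object with tip labels `sp01 ... spNN`.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # lineages: parent node key and start time; nodes accumulate children
  children <- list(root = character(0))
  node_time <- c(root = 0)
  lineages <- data.frame(parent = c("root", "root"), start = c(0, 0),
                         stringsAsFactors = FALSE)
  t_now <- 0
  next_id <- 1L
  while (nrow(lineages) < n) {
    k <- nrow(lineages)
    t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
    j <- sample.int(k, 1L)
    key <- sprintf("n%d", next_id); next_id <- next_id + 1L
    children[[key]] <- character(0)
    node_time[key] <- t_now
    children[[lineages$parent[j]]] <- c(children[[lineages$parent[j]]], key)
    lineages <- rbind(lineages[-j, , drop = FALSE],
                      data.frame(parent = c(key, key), start = c(t_now, t_now),
                                 stringsAsFactors = FALSE))
  }
  t_end <- t_now + stats::rexp(1, rate = birth_rate * n)
  tip_labels <- sprintf("sp%02d", seq_len(n))
  for (i in seq_len(n)) {
    key <- tip_labels[i]
    node_time[key] <- t_end
    children[[lineages$parent[i]]] <- c(children[[lineages$parent[i]]], key)
  }
  build <- function(key) {
    kids <- children[[key]]
    if (length(kids) == 0L) return(key)
    inner <- vapply(kids, function(k) {
      sprintf("%s:%.15g", build(k), node_time[[k]] - node_time[[key]])
    }, character(1))
    sprintf("(%s)", paste(inner, collapse = ","))
  }
  read_newick(paste0(build("root"), ";"))
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Each edge adds an independent normal increment with variance
#' `sigma2 * edge length`; tip values are returned. The tip covariance is
#' therefore `sigma2 * phylo_vcv(tree)` in expectation.
#'
#' @param tree A validated "phylo" object.
#' @param sigma2 Brownian rate (variance per unit branch length, >= 0).
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  validate_phylogeny(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (n == 1L) {
    out <- root_value + stats::rnorm(1, 0, sqrt(sigma2 * sum(tree$edge.length)))
    names(out) <- tree$tip.label
    return(out)
  }
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- root_value
  ord <- rev(ape::postorder(tree))
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (k in ord) {
    val[tree$edge[k, 2L]] <- val[tree$edge[k, 1L]] + inc[k]
  }
  out <- val[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Simulate the species trait table
#'
#' Generates, per species: a continuous dietary index (a `plant_fraction`
#' share of species drawn negative, the rest positive), body mass (lognormal),
#' and log olfactory epithelium surface area as a diet-specific affine
#' function of log mass plus a Brownian phylogenetic species effect
#' (variance `phylo_var` at unit depth), a joint species effect shared with
#' the codon-rate level (correlated Brownian motions with tip covariance
#' `species_covariance` at unit depth), and iid residual noise
#' (variance `resid_var`). A clade of about `n_mormoopids` species is
#' flagged `is_mormoopid`. RNA Integrity Numbers are drawn uniform on [5, 10].
#'
#' @param tree Species phylogeny (its tips define the species).
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed (defaults to `config$seed + 1`).
#' @return Data frame with one row per species: `species`, `mass_g`,
#'   `surface_area` (mm^2), `diet_index`, `diet_class`, `is_mormoopid`,
#'   `rin`, `n_or_detected` (NA until genes are simulated), plus the latent
#'   `codon_offset` consumed by [simulate_gene_tree_pairs()].
#' @export
simulate_species_table <- function(tree, config, seed = NULL) {
  validate_sim_config(config)
  validate_phylogeny(tree)
  if (is.null(seed)) seed <- derive_seed(config$seed, 1L)
  set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  if (n < 2L) stop("species tree must have >= 2 tips", call. = FALSE)

  n_plant <- round(config$plant_fraction * n)
  plant_idx <- sample.int(n, n_plant)
  diet_index <- stats::runif(n, 0, 1)
  diet_index[plant_idx] <- -stats::runif(n_plant, 0, 1)
  diet_class <- vapply(diet_index, function(d)
    suppressWarnings(classify_diet(d)), character(1))

  log_mass <- stats::rnorm(n, config$mass_logmean, config$mass_logsd)

  depth <- max(root_to_tip(tree))
  bm <- if (config$phylo_var > 0) {
    simulate_bm(tree, sigma2 = config$phylo_var / depth, root_value = 0)
  } else {
    stats::setNames(numeric(n), sp)
  }

  # Joint species effects (codon-rate level, log surface area): correlated
  # Brownian motions on the tree, so the tip covariance is S %x% A with A
  # the unit-depth relatedness — the structure the multiresponse animal
  # model assumes. The whitened draws are orthonormalized before mixing, so
  # every dataset realizes the configured covariance exactly (conditional
  # simulation): the generator defines the condition, not a draw around it.
  L <- chol_psd(config$species_covariance)
  RA <- chol(phylo_vcv(tree)[sp, sp] / depth)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  e1 <- z1 / sqrt(sum(z1^2))
  z2p <- z2 - sum(e1 * z2) * e1
  e2 <- z2p / sqrt(sum(z2p^2))
  joint <- (t(RA) %*% cbind(e1, e2) * sqrt(n)) %*% t(L)

  a <- config$allometry
  coef_int <- ifelse(diet_class == "plant", a$plant$intercept,
                     a$animal$intercept)
  coef_slo <- ifelse(diet_class == "plant", a$plant$slope, a$animal$slope)
  log_sa <- coef_int + coef_slo * log_mass + bm[sp] + joint[, 2] +
    stats::rnorm(n, 0, sqrt(config$resid_var))

  morm <- flag_clade(tree, config$n_mormoopids)

  data.frame(
    species = sp,
    mass_g = exp(log_mass),
    surface_area = exp(log_sa),
    diet_index = diet_index,
    diet_class = diet_class,
    is_mormoopid = sp %in% morm,
    rin = stats::runif(n, 5, 10),
    n_or_detected = NA_integer_,
    codon_offset = joint[, 1],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Cholesky factor tolerant of PSD (rank-deficient) matrices
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S))
}

# pick the clade whose size is closest to k (used for the mormoopid flag)
flag_clade <- function(tree, k) {
  if (k <= 0L) return(character(0))
  n <- length(tree$tip.label)
  if (k >= n) return(tree$tip.label)
  best <- NULL; best_diff <- Inf
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[clade_tips(tree, node)]
    d <- abs(length(tips) - k)
    if (d < best_diff || (d == best_diff && length(tips) < length(best))) {
      best <- tips; best_diff <- d
    }
  }
  best
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  stack <- node; tips <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= n) tips <- c(tips, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == v, 2L])
  }
  tips
}

#' Simulate paired codon/nucleotide gene trees
#'
#' For each subfamily and gene: the species-tree topology is copied; tips are
#' thinned independently with probability `detection_prob` (genes with fewer
#' than two surviving tips are dropped, emulating partial transcriptome
#' recovery); nucleotide edge lengths are the species edge lengths times a
#' per-gene lognormal rate multiplier (mean 1, SD `rate_lognorm_sd`); codon
#' edge lengths are `codon_slope` times the nucleotide edge times per-edge
#' lognormal noise (mean 1, same SD), with `codon_intercept` added to each
#' terminal edge so every tip's codon root-to-tip length gains the intercept
#' exactly once. Per-species codon-rate offsets (column `codon_offset` of the
#' species table, if given) are likewise added to terminal codon edges,
#' clamped at zero.
#'
#' @param tree Species phylogeny.
#' @param config A [sim_config()] object.
#' @param species_table Optional species table carrying `codon_offset`.
#' @param seed Optional integer seed (defaults to `config$seed + 2`).
#' @return List of gene records, each
#'   `list(gene_id, subfamily, codon_tree, nucleotide_tree)`; both trees
#'   share the thinned topology.
#' @export
simulate_gene_tree_pairs <- function(tree, config, species_table = NULL,
                                     seed = NULL) {
  validate_sim_config(config)
  validate_phylogeny(tree)
  if (is.null(seed)) seed <- derive_seed(config$seed, 2L)
  set.seed(seed)
  offsets <- stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label)
  if (!is.null(species_table) && "codon_offset" %in% names(species_table)) {
    offsets[species_table$species] <- species_table$codon_offset
  }
  pairs <- list()
  for (i in seq_len(nrow(config$subfamilies))) {
    sf <- config$subfamilies[i, ]
    for (g in seq_len(sf$gene_count_per_species)) {
      keep <- tree$tip.label[stats::runif(length(tree$tip.label)) <=
                               config$detection_prob]
      if (length(keep) < 2L) next
      gtree <- prune_tips(tree, keep)
      gene_mult <- if (sf$rate_lognorm_sd > 0) {
        stats::rlnorm(1, -sf$rate_lognorm_sd^2 / 2, sf$rate_lognorm_sd)
      } else 1
      nucl <- gtree
      nucl$edge.length <- gtree$edge.length * gene_mult
      edge_noise <- if (sf$rate_lognorm_sd > 0) {
        stats::rlnorm(nrow(gtree$edge), -sf$rate_lognorm_sd^2 / 2,
                      sf$rate_lognorm_sd)
      } else rep(1, nrow(gtree$edge))
      codon <- gtree
      codon$edge.length <- sf$codon_slope * nucl$edge.length * edge_noise
      term <- gtree$edge[, 2L] <= length(gtree$tip.label)
      tip_of_edge <- gtree$tip.label[gtree$edge[term, 2L]]
      codon$edge.length[term] <- pmax(
        0, codon$edge.length[term] + sf$codon_intercept +
          offsets[tip_of_edge])
      gene_id <- sprintf("%s_g%03d", gsub("[^A-Za-z0-9]", "", sf$label), g)
      pairs[[gene_id]] <- list(gene_id = gene_id, subfamily = sf$label,
                               codon_tree = codon, nucleotide_tree = nucl)
    }
  }
  pairs
}

#' Simulate a full synthetic dataset
#'
#' Runs the species-tree, species-table, and gene-tree-pair generators with
#' sub-seeds derived from `config$seed`, fills the per-species detected-gene
#' counts, and returns everything with the generating parameters attached.
#'
#' @param config A [sim_config()] object.
#' @return List of class "synthetic_dataset": `species_tree`,
#'   `species_table`, `gene_tree_pairs`, `truth` (the config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = derive_seed(config$seed, 0L))
  spt <- simulate_species_table(tree, config,
                                seed = derive_seed(config$seed, 1L))
  pairs <- simulate_gene_tree_pairs(tree, config, species_table = spt,
                                    seed = derive_seed(config$seed, 2L))
  counts <- table(unlist(lapply(pairs, function(p) p$codon_tree$tip.label)))
  spt$n_or_detected <- as.integer(counts[spt$species])
  spt$n_or_detected[is.na(spt$n_or_detected)] <- 0L
  structure(list(species_tree = tree, species_table = spt,
                 gene_tree_pairs = pairs, truth = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory
#'
#' Plain-text layout, reloadable by [load_dataset()]:
#' `species_tree.nwk`; `species_table.tsv`; `codon_trees.nwk` and
#' `nucleotide_trees.nwk` (one tree per line, aligned with `gene_index.tsv`);
#' `truth.yaml` with the generating parameters.
#'
#' @param dataset A "synthetic_dataset".
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$species_tree, file.path(dir, "species_tree.nwk"))
  spt <- dataset$species_table
  utils::write.table(spt, file.path(dir, "species_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pairs <- dataset$gene_tree_pairs
  idx <- data.frame(
    gene_id = vapply(pairs, `[[`, character(1), "gene_id"),
    subfamily = vapply(pairs, `[[`, character(1), "subfamily"),
    stringsAsFactors = FALSE
  )
  utils::write.table(idx, file.path(dir, "gene_index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(vapply(pairs, function(p) write_newick(p$codon_tree),
                    character(1)),
             file.path(dir, "codon_trees.nwk"))
  writeLines(vapply(pairs, function(p) write_newick(p$nucleotide_tree),
                    character(1)),
             file.path(dir, "nucleotide_trees.nwk"))
  truth <- unclass(dataset$truth)
  truth$subfamilies <- as.list(truth$subfamilies)
  truth$species_covariance <- as.vector(truth$species_covariance)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Load a dataset written by [emit_dataset()]
#'
#' @param dir Directory produced by [emit_dataset()].
#' @return A "synthetic_dataset" (truth restored from `truth.yaml`).
#' @export
load_dataset <- function(dir) {
  tree <- read_newick(file = file.path(dir, "species_tree.nwk"))
  spt <- utils::read.table(file.path(dir, "species_table.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  idx <- utils::read.table(file.path(dir, "gene_index.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  codon_lines <- readLines(file.path(dir, "codon_trees.nwk"))
  nucl_lines <- readLines(file.path(dir, "nucleotide_trees.nwk"))
  stopifnot(length(codon_lines) == nrow(idx),
            length(nucl_lines) == nrow(idx))
  pairs <- lapply(seq_len(nrow(idx)), function(i) {
    list(gene_id = idx$gene_id[i], subfamily = idx$subfamily[i],
         codon_tree = read_newick(codon_lines[i]),
         nucleotide_tree = read_newick(nucl_lines[i]))
  })
  names(pairs) <- idx$gene_id
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  truth$subfamilies <- as.data.frame(truth$subfamilies,
                                     stringsAsFactors = FALSE)
  truth$species_covariance <- matrix(unlist(truth$species_covariance), 2, 2)
  structure(list(species_tree = tree, species_table = spt,
                 gene_tree_pairs = pairs, truth = truth),
            class = "synthetic_dataset")
}
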