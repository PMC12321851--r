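# Synthetic cohort generator with known ground truth: genus abundances with
# planted block correlation (the CAGs), case/control effects, matching
# covariates, and a linear genus -> pathway layer. A Gaussian copula with
# log-normal marginals is used throughout: Spearman correlation is invariant
# to the monotone exp() transform, so the realized rank correlation tracks the
# latent Pearson value (slightly below it: 6/pi * asin(rho/2) for a bivariate
# normal).

#' Default matching-covariate specification
#'
#' Covariates mirror the usual microbiota-confounder set for gut cohorts:
#' age, BMI, height, weight, sex, alcohol consumption frequency and five
#' dietary intake frequencies. Each entry is a list with a `family`
#' (`"normal"`, `"binary"` or `"ordinal"`) plus family parameters and an
#' `assoc` group-association strength: cases have their latent mean shifted by
#' `assoc` standard deviations, which is what one-to-one matching is later
#' asked to remove. Defaults plant a mild imbalance on age and BMI only.
#'
#' @return named list of covariate specifications.
#' @export
default_covariates <- function() {
  ord <- function(assoc = 0) list(family = "ordinal", levels = 0:4, assoc = assoc)
  list(
    age    = list(family = "normal", mean = 45,  sd = 14, assoc = 0.3),
    bmi    = list(family = "normal", mean = 25,  sd = 4,  assoc = 0.2),
    height = list(family = "normal", mean = 170, sd = 10, assoc = 0),
    weight = list(family = "normal", mean = 72,  sd = 14, assoc = 0),
    sex    = list(family = "binary", p = 0.5, assoc = 0),
    alcohol_freq       = ord(),
    diet_meat          = ord(),
    diet_dairy         = ord(),
    diet_vegetables    = ord(),
    diet_whole_grains  = ord(),
    diet_salted_snacks = ord()
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. The defaults emulate the
#' diarrhea-predominant sub-cohort scale: 365 cases plus a 2:1 candidate pool
#' of 730 controls (one-to-one matching later selects 365 of them), 44 genera
#' in 8 planted co-abundance blocks of sizes 9..2, within-block latent
#' correlation 0.8, and multiplicative case effects on three blocks (one up,
#' two down). Covariate defaults plant a mild case-control imbalance on age
#' and BMI that the matching stage is expected to reduce.
#'
#' @param n_cases,n_controls sample counts per group (>= 0).
#' @param n_genera total number of genera; genera beyond `sum(block_sizes)`
#'   form an unstructured background (block 0), mutually independent in the
#'   latent layer.
#' @param n_blocks number of planted blocks (CAGs).
#' @param block_sizes integer vector of length `n_blocks`; must sum to at most
#'   `n_genera`.
#' @param within_block_rho latent Pearson correlation inside a block, in `[0, 1)`.
#' @param between_block_rho latent correlation across different blocks
#'   (default 0); must be strictly below `within_block_rho`.
#' @param effect_blocks named numeric vector mapping block id (as character)
#'   to a log-fold-change applied multiplicatively to case samples before
#'   compositional closure.
#' @param covariates covariate specification, see [default_covariates()].
#' @param n_pathways number of predicted metabolic pathways.
#' @param contrib_density fraction of nonzero genus-to-pathway weights.
#' @param pathway_noise_sd standard deviation of the multiplicative log-normal
#'   pathway noise (>= 0).
#' @param subtype label attached to case samples (controls get `"non-IBS"`).
#' @param seed integer master seed; each stage draws from a named substream so
#'   tables can be regenerated independently.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 365, n_controls = 730,
                       n_genera = 44, n_blocks = 8,
                       block_sizes = c(9, 8, 7, 6, 5, 4, 3, 2),
                       within_block_rho = 0.8, between_block_rho = 0,
                       effect_blocks = c("1" = -0.5, "2" = -0.5, "3" = 0.5),
                       covariates = default_covariates(),
                       n_pathways = 60, contrib_density = 0.15,
                       pathway_noise_sd = 0.3,
                       subtype = "IBS-D", seed = 1L) {
  stopifnot(n_cases >= 0, n_controls >= 0, n_genera >= 1,
            n_blocks >= 0, length(block_sizes) == n_blocks,
            all(block_sizes >= 1), n_pathways >= 1,
            contrib_density > 0, contrib_density <= 1,
            pathway_noise_sd >= 0)
  if (sum(block_sizes) > n_genera) {
    stop("sum(block_sizes) exceeds n_genera")
  }
  if (!(within_block_rho >= 0 && within_block_rho < 1)) {
    stop("within_block_rho must lie in [0, 1)")
  }
  if (between_block_rho >= within_block_rho) {
    stop("between_block_rho must be strictly below within_block_rho")
  }
  if (!is.null(effect_blocks) && length(effect_blocks) &&
      is.null(names(effect_blocks))) {
    stop("effect_blocks must be a named vector (block id -> log-fold-change)")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_genera = as.integer(n_genera), n_blocks = as.integer(n_blocks),
         block_sizes = as.integer(block_sizes),
         within_block_rho = within_block_rho,
         between_block_rho = between_block_rho,
         effect_blocks = effect_blocks, covariates = covariates,
         n_pathways = as.integer(n_pathways),
         contrib_density = contrib_density,
         pathway_noise_sd = pathway_noise_sd,
         subtype = subtype, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Named substream scheme: one master seed feeds independent per-stage seeds
# (kept below 2^31) so the genus table, metadata and pathway layer can each be
# regenerated on their own.
substream_seed <- function(seed, stream) {
  k <- match(stream, c("table", "metadata", "pathways", "match", "split",
                       "rf", "shap", "misc"))
  if (is.na(k)) stop("unknown substream: ", stream)
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}

#' Simulate a genus relative-abundance table with planted CAG structure
#'
#' Latent multivariate normal with block covariance (within-block correlation
#' `within_block_rho`, cross-block `between_block_rho`, background genera
#' independent), exponentiated to log-normal abundances, case-group
#' multiplicative shifts `exp(effect)` applied to effect-block genera, then
#' each sample closed to sum 1. Because effects are applied before closure,
#' closure induces a small negative spillover on non-effect genera; this is a
#' property of compositional data and is deliberately not removed.
#'
#' @param config a [sim_config()].
#' @return list with `abundance` (samples x genera matrix, rows closed to 1,
#'   with a `"group"` attribute) and `truth` (block assignment, planted
#'   effects; the pathway contribution matrix is filled in by
#'   [simulate_pathway_table()]).
#' @export
simulate_genus_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "table"))
  G <- config$n_genera
  n <- config$n_cases + config$n_controls
  block <- integer(G)  # 0 = unstructured background
  if (config$n_blocks > 0) {
    block[seq_len(sum(config$block_sizes))] <-
      rep(seq_len(config$n_blocks), times = config$block_sizes)
  }
  w <- config$within_block_rho
  b <- config$between_block_rho
  Sigma <- diag(G)
  if (config$n_blocks > 0) {
    structured <- block > 0
    same <- outer(block, block, "==") & structured & t(matrix(structured, G, G))
    cross <- outer(block > 0, block > 0, "&") & !same
    Sigma[cross] <- b
    Sigma[same] <- w
    diag(Sigma) <- 1
  }
  ch <- tryCatch(chol(Sigma), error = function(e) {
    stop(sprintf(paste0("requested block covariance is not positive ",
                        "definite (within_block_rho = %g, ",
                        "between_block_rho = %g)"), w, b))
  })
  mu <- stats::rnorm(G, mean = 0, sd = 1.2)  # genus base log-abundance
  Z <- matrix(stats::rnorm(n * G), n, G) %*% ch
  A <- exp(sweep(Z, 2L, mu, "+"))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  if (length(config$effect_blocks) && config$n_cases > 0) {
    for (bid in names(config$effect_blocks)) {
      members <- which(block == as.integer(bid))
      if (length(members)) {
        A[group == "case", members] <-
          A[group == "case", members] * exp(config$effect_blocks[[bid]])
      }
    }
  }
  A <- A / rowSums(A)
  genus_ids <- sprintf("g%03d", seq_len(G))
  sample_ids <- c(sprintf("case_%04d", seq_len(config$n_cases)),
                  sprintf("ctrl_%04d", seq_len(config$n_controls)))
  dimnames(A) <- list(sample_ids, genus_ids)
  attr(A, "group") <- group
  names(block) <- genus_ids
  list(abundance = A,
       truth = list(block_assignment = block,
                    effect_blocks = config$effect_blocks,
                    contribution_matrix = NULL))
}

#' Simulate sample metadata with matching covariates
#'
#' One row per sample. Every covariate family is driven by a latent standard
#' normal whose mean is shifted by `assoc` for case samples: continuous
#' covariates are `mean + sd * latent`, binary covariates threshold the latent
#' at the quantile implied by `p`, ordinal covariates cut the latent at equal
#' population quantiles across the stated levels. This gives a monotone,
#' single-parameter control of covariate-group confounding.
#'
#' @param config a [sim_config()].
#' @param table genus table from [simulate_genus_table()] (supplies sample ids
#'   and group labels).
#' @return data.frame with `sample_id`, `group`, `subtype` and one column per
#'   covariate.
#' @export
simulate_metadata <- function(config, table) {
  stopifnot(inherits(config, "sim_config"))
  A <- if (is.list(table)) table$abundance else table
  ids <- rownames(A)
  group <- attr(A, "group")
  if (is.null(group)) stop("abundance table lacks a 'group' attribute")
  set.seed(substream_seed(config$seed, "metadata"))
  n <- length(ids)
  is_case <- group == "case"
  md <- data.frame(sample_id = ids,
                   group = group,
                   subtype = ifelse(is_case, config$subtype, "non-IBS"),
                   stringsAsFactors = FALSE)
  for (nm in names(config$covariates)) {
    sp <- config$covariates[[nm]]
    assoc <- if (is.null(sp$assoc)) 0 else sp$assoc
    latent <- stats::rnorm(n, mean = ifelse(is_case, assoc, 0), sd = 1)
    md[[nm]] <- switch(
      sp$family,
      normal = sp$mean + sp$sd * latent,
      binary = as.integer(latent > stats::qnorm(1 - sp$p)),
      ordinal = {
        lv <- sp$levels
        cuts <- stats::qnorm(seq_len(length(lv) - 1L) / length(lv))
        lv[findInterval(latent, cuts) + 1L]
      },
      stop(sprintf("unknown covariate family '%s' for covariate '%s'",
                   sp$family, nm))
    )
  }
  md
}

# Hierarchical classes used for the round-robin pathway category assignment.
default_pathway_categories <- function() {
  c("energy", "carbohydrate", "amino_acid", "lipid",
    "nucleic_acid", "vitamin_cofactor")
}

#' Simulate a predicted-pathway abundance table
#'
#' Emulates the structure of reference-genome pathway prediction from 16S
#' profiles: pathway abundance is a nonnegative linear map of the genus
#' abundances (`abundance %*% contribution`) times multiplicative log-normal
#' noise. Categories are assigned round-robin from the standard metabolic
#' classes, and focal pathway groups (acetate, propionate and butyrate
#' biosynthesis, LPS-associated, tryptophan-associated) are carved out of the
#' leading pathway ids so paired focal tests have a known target.
#'
#' @param table genus table (or the list returned by
#'   [simulate_genus_table()]).
#' @param truth ground-truth list; its `contribution_matrix` is filled in.
#' @param config a [sim_config()].
#' @param contribution optional genera x pathways nonnegative weight matrix;
#'   generated at density `config$contrib_density` when NULL.
#' @param categories category labels to cycle over.
#' @return list with `pathways` (samples x pathways matrix), `category_map`
#'   (data.frame pathway/category), `focal_groups` (named list of pathway id
#'   vectors) and `truth` with the contribution matrix recorded.
#' @export
simulate_pathway_table <- function(table, truth, config, contribution = NULL,
                                   categories = default_pathway_categories()) {
  stopifnot(inherits(config, "sim_config"))
  A <- if (is.list(table)) table$abundance else table
  G <- ncol(A)
  P <- config$n_pathways
  set.seed(substream_seed(config$seed, "pathways"))
  if (is.null(contribution)) {
    W <- matrix(stats::rbinom(G * P, 1L, config$contrib_density) *
                  stats::runif(G * P, 0.2, 1), G, P)
    empty <- which(colSums(W) == 0)
    for (j in empty) W[sample.int(G, 1L), j] <- stats::runif(1, 0.2, 1)
  } else {
    if (nrow(contribution) != G || ncol(contribution) != P) {
      stop(sprintf("contribution matrix must be %d x %d (got %d x %d)",
                   G, P, nrow(contribution), ncol(contribution)))
    }
    if (any(contribution < 0)) stop("contribution matrix has negative entries")
    W <- contribution
  }
  Pw <- A %*% W
  if (config$pathway_noise_sd > 0) {
    Pw <- Pw * exp(matrix(stats::rnorm(length(Pw), 0, config$pathway_noise_sd),
                          nrow(Pw), ncol(Pw)))
  }
  path_ids <- sprintf("PWY%03d", seq_len(P))
  dimnames(Pw) <- list(rownames(A), path_ids)
  dimnames(W) <- list(colnames(A), path_ids)
  category_map <- data.frame(
    pathway = path_ids,
    category = rep_len(categories, P),
    stringsAsFactors = FALSE
  )
  focal_spec <- list(acetate = 1:2, propionate = 3:4, butyrate = 5:6,
                     LPS = 7:9, tryptophan = 10:12)
  focal_groups <- lapply(focal_spec, function(ix) path_ids[ix[ix <= P]])
  focal_groups <- focal_groups[vapply(focal_groups, length, 1L) > 0]
  truth$contribution_matrix <- W
  list(pathways = Pw, category_map = category_map,
       focal_groups = focal_groups, truth = truth)
}

#' Simulate a complete matched-cohort study
#'
#' Convenience wrapper running [simulate_genus_table()],
#' [simulate_metadata()] and [simulate_pathway_table()] under one master seed.
#'
#' @param config a [sim_config()].
#' @return list with `abundance`, `metadata`, `pathways`, `category_map`,
#'   `focal_groups`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  gt <- simulate_genus_table(config)
  md <- simulate_metadata(config, gt)
  pw <- simulate_pathway_table(gt, gt$truth, config)
  list(abundance = gt$abundance, metadata = md,
       pathways = pw$pathways, category_map = pw$category_map,
       focal_groups = pw$focal_groups, truth = pw$truth, config = config)
}

#' Write a simulated study to disk
#'
#' Writes the genus and pathway tables and metadata as TSV (samples in rows,
#' first column `sample_id`), the category map as TSV, and the ground truth as
#' JSON. Optionally exports the genus table in BIOM format (via biomformat)
#' when that package is available.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param biom logical; also write `genus.biom`.
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, biom = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    genus = file.path(dir, "genus.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    category_map = file.path(dir, "category_map.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_abundance(sim$abundance, files[["genus"]])
  utils::write.table(sim$metadata, files[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_abundance(sim$pathways, files[["pathways"]])
  utils::write.table(sim$category_map, files[["category_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(block_assignment = as.list(truth$block_assignment),
         effect_blocks = as.list(truth$effect_blocks),
         contribution_matrix = truth$contribution_matrix,
         focal_groups = sim$focal_groups),
    files[["truth"]], auto_unbox = TRUE, digits = NA
  )
  if (biom) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      warning("biomformat not available; skipping BIOM export")
    } else {
      bf <- file.path(dir, "genus.biom")
      bm <- biomformat::make_biom(t(sim$abundance))
      biomformat::write_biom(bm, bf)
      files <- c(files, biom = bf)
    }
  }
  invisible(files)
}
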