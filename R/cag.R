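# Genus filtering, group-specific Spearman co-abundance networks, Ward
# clustering of the pooled correlation matrix into co-abundance groups
# (CAGs), CAG abundance summaries and disease-vs-control contrasts.

#' Filter low-count features from a raw count table
#'
#' A feature is removed only when it fails BOTH thresholds: present in fewer
#' than `min_sample_presence` samples AND carrying fewer than
#' `min_total_reads` reads in total (`rule = "and"`, the default). With
#' `rule = "or"` a feature failing either threshold is removed. The applied
#' interpretation is recorded in the `filter_log` attribute.
#'
#' @param counts samples x features matrix of nonnegative counts.
#' @param min_sample_presence presence threshold (default 30 samples).
#' @param min_total_reads total-read threshold (default 10 reads).
#' @param rule `"and"` (exclude only when both conditions fail) or `"or"`.
#' @return filtered count table with a `filter_log` attribute.
#' @export
filter_low_count_features <- function(counts, min_sample_presence = 30,
                                      min_total_reads = 10,
                                      rule = c("and", "or")) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  if (length(counts) == 0 || ncol(counts) == 0) return(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  presence <- colSums(counts > 0)
  total <- colSums(counts)
  pass_presence <- presence >= min_sample_presence
  pass_reads <- total >= min_total_reads
  keep <- if (rule == "and") pass_presence | pass_reads else pass_presence & pass_reads
  out <- counts[, keep, drop = FALSE]
  attr(out, "filter_log") <- list(
    rule = sprintf("exclude when presence < %d %s total reads < %d",
                   min_sample_presence,
                   if (rule == "and") "AND" else "OR",
                   min_total_reads),
    removed = colnames(counts)[!keep]
  )
  out
}

#' Filter genera by prevalence and mean relative abundance
#'
#' Keeps genera present in at least `min_prevalence` of the samples with mean
#' relative abundance at least `min_mean_abundance` (defaults: 20% and 0.05%).
#' Survivors keep their original scale: rows are deliberately not re-closed to
#' 1, so downstream correlations and CAG summaries operate on the same
#' relative-abundance values the full table carried.
#'
#' @param rel samples x genera relative-abundance matrix.
#' @param min_prevalence minimum fraction of samples with nonzero abundance.
#' @param min_mean_abundance minimum mean relative abundance.
#' @return filtered table (columns subset of `rel`).
#' @export
filter_genera <- function(rel, min_prevalence = 0.20,
                          min_mean_abundance = 0.0005) {
  rel <- as.matrix(rel)
  keep <- colMeans(rel > 0) >= min_prevalence &
    colMeans(rel) >= min_mean_abundance
  rel[, keep, drop = FALSE]
}

# Spearman correlation matrix with t-approximation p-values for every pair.
# Constant columns get NA correlations and are reported in the result.
spearman_matrix <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(table, 2L, stats::sd)
  constant <- sds == 0
  r <- suppressWarnings(stats::cor(table, method = "spearman"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  list(rho = r, p = p, n = n, constant = colnames(table)[constant])
}

#' Build a co-abundance network for one cohort group
#'
#' Computes Spearman correlations for every genus pair in the given group's
#' table, applies Benjamini-Hochberg correction over the full set of pairs,
#' and retains edges with `q < q_max` and `rho > threshold` (positive-only
#' default, matching networks that display only positive co-abundances) or
#' `|rho| > threshold` when `positive_only = FALSE`. Constant genera cannot
#' carry a rank correlation; they are excluded from edges and recorded.
#'
#' @param table samples x genera relative-abundance matrix for one group.
#' @param threshold correlation threshold (default 0.4).
#' @param positive_only logical; keep only positive correlations (default TRUE).
#' @param q_max BH q-value cutoff (default 0.05).
#' @param group optional group label stored on the network.
#' @return object of class `cag_network`: list with `group`, `nodes`
#'   (data.frame genus/mean_abundance), `edges` (data.frame from/to/rho/p/q/
#'   sign, canonical i < j order), `rho_matrix`, `threshold`,
#'   `positive_only`, `constant_genera`, `n_samples`.
#' @export
build_network <- function(table, threshold = 0.4, positive_only = TRUE,
                          q_max = 0.05, group = NULL) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("need at least 2 genera")
  sm <- spearman_matrix(table)
  if (length(sm$constant)) {
    warning("constant genera excluded from edges: ",
            paste(sm$constant, collapse = ", "))
  }
  genera <- colnames(table)
  ut <- which(upper.tri(sm$rho), arr.ind = TRUE)
  rho <- sm$rho[ut]
  p <- sm$p[ut]
  ok <- !is.na(rho)
  q <- rep(NA_real_, length(p))
  q[ok] <- bh_adjust(p[ok])
  pass <- ok & q < q_max &
    (if (positive_only) rho > threshold else abs(rho) > threshold)
  edges <- data.frame(
    from = genera[ut[pass, 1L]],
    to = genera[ut[pass, 2L]],
    rho = rho[pass], p = p[pass], q = q[pass],
    sign = ifelse(rho[pass] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  structure(
    list(group = group,
         nodes = data.frame(genus = genera,
                            mean_abundance = colMeans(table),
                            stringsAsFactors = FALSE),
         edges = edges, rho_matrix = sm$rho,
         threshold = threshold, positive_only = positive_only,
         q_max = q_max, constant_genera = sm$constant,
         n_samples = nrow(table)),
    class = "cag_network"
  )
}

#' @export
print.cag_network <- function(x, ...) {
  cat(sprintf("<cag_network%s> %d genera, %d edge(s) (%srho > %g, q < %g)\n",
              if (is.null(x$group)) "" else paste0(": ", x$group),
              nrow(x$nodes), nrow(x$edges),
              if (x$positive_only) "" else "|", x$threshold, x$q_max))
  invisible(x)
}

#' Cluster genera into co-abundance groups
#'
#' Ward (Ward.D2) hierarchical clustering of the correlation-based distance
#' `d = 1 - rho`, with the tree cut into `k` clusters. The correlation matrix
#' should be the full (unthresholded) Spearman matrix computed on the pooled
#' case+control samples. Cluster size bounds are a quality report, not a
#' constraint: violations are listed, never silently fixed.
#'
#' @param rho_mat square symmetric correlation matrix (e.g. the `rho_matrix`
#'   of a pooled [build_network()], or [spearman_matrix] output).
#' @param k number of CAGs (default 8).
#' @param size_bounds expected per-CAG size range, default `c(2, 10)`.
#' @return object of class `cag_partition`: list with `assignment` (named
#'   genus -> CAG id integer vector), `k`, `linkage`, `sizes`,
#'   `size_bounds`, `violations` (CAG ids outside the bounds), `hclust`.
#' @export
cluster_cags <- function(rho_mat, k = 8, size_bounds = c(2, 10)) {
  rho_mat <- as.matrix(rho_mat)
  G <- ncol(rho_mat)
  if (k > G) stop(sprintf("k = %d exceeds the number of genera (%d)", k, G))
  if (anyNA(rho_mat)) stop("correlation matrix contains NA (constant genus?)")
  d <- stats::as.dist(1 - rho_mat)
  hc <- stats::hclust(d, method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  sizes <- tabulate(assignment, nbins = k)
  names(sizes) <- sprintf("CAG%d", seq_len(k))
  violations <- which(sizes < size_bounds[1L] | sizes > size_bounds[2L])
  structure(
    list(assignment = assignment, k = as.integer(k), linkage = "ward.D2",
         sizes = sizes, size_bounds = size_bounds,
         violations = names(sizes)[violations], hclust = hc),
    class = "cag_partition"
  )
}

#' @export
print.cag_partition <- function(x, ...) {
  cat(sprintf("<cag_partition> %d genera in %d CAGs (%s linkage); sizes: %s\n",
              length(x$assignment), x$k, x$linkage,
              paste(x$sizes, collapse = ", ")))
  if (length(x$violations)) {
    cat("  size-bound violations:", paste(x$violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-sample CAG abundance summaries
#'
#' Per sample and CAG, the mean (used for differential testing) or sum (used
#' as classifier features) of member-genus relative abundances. With the sum
#' summary, each row total equals the total abundance of all partitioned
#' genera in that sample (conservation).
#'
#' @param table samples x genera relative-abundance matrix; every column must
#'   be present in the partition.
#' @param partition a [cluster_cags()] result.
#' @param summary `"mean"` or `"sum"`.
#' @return samples x CAG matrix with columns `CAG1..CAGk`.
#' @export
cag_abundance <- function(table, partition, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  table <- as.matrix(table)
  missing <- setdiff(colnames(table), names(partition$assignment))
  if (length(missing)) {
    stop("genera absent from partition: ", paste(missing, collapse = ", "))
  }
  k <- partition$k
  out <- matrix(0, nrow(table), k,
                dimnames = list(rownames(table), sprintf("CAG%d", seq_len(k))))
  for (c_id in seq_len(k)) {
    members <- intersect(names(partition$assignment)[partition$assignment == c_id],
                         colnames(table))
    if (length(members) == 0) next
    sub <- table[, members, drop = FALSE]
    out[, c_id] <- if (summary == "mean") rowMeans(sub) else rowSums(sub)
  }
  out
}

#' Disease-vs-control contrast of CAG abundances
#'
#' Two-sided Wilcoxon rank-sum test per CAG, with the direction of the shift
#' (sign of the case-minus-control median difference) and significance stars
#' at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param cag_table samples x CAG matrix from [cag_abundance()].
#' @param groups character/factor of group labels, one per row of `cag_table`.
#' @param case_label label identifying the disease group (default `"case"`).
#' @return data.frame: cag, n_case, n_control, statistic, p_value, direction,
#'   stars, note.
#' @export
cag_differential <- function(cag_table, groups, case_label = "case") {
  cag_table <- as.matrix(cag_table)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(cag_table))
  is_case <- groups == case_label
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("both groups need at least 2 samples")
  }
  rows <- lapply(colnames(cag_table), function(cg) {
    a <- cag_table[is_case, cg]
    b <- cag_table[!is_case, cg]
    res <- wilcoxon_ranksum(a, b)
    dmed <- stats::median(a) - stats::median(b)
    data.frame(cag = cg, n_case = length(a), n_control = length(b),
               statistic = res$statistic, p_value = res$p_value,
               direction = if (dmed > 0) "up" else if (dmed < 0) "down" else "none",
               stars = signif_stars(res$p_value),
               note = if (is.null(res$note)) "" else res$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap counts of genus sets across subtype runs
#'
#' Counts every intersection region across two or more genus sets (the
#' classic Venn breakdown: for three sets, the common core, the three
#' pairwise-only regions and the three exclusive regions).
#'
#' @param sets named list of character vectors (at least 2 sets).
#' @return data.frame with `region` (set names joined by `&`) and `count`:
#'   elements belonging to exactly that combination of sets.
#' @export
genus_venn <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- sprintf("set%d", seq_along(sets))
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  rows <- apply(combos, 1L, function(cmb) {
    cmb <- as.logical(cmb)
    inside <- rep(TRUE, length(universe))
    for (i in seq_len(n)) {
      inside <- inside & (membership[, i] == cmb[i])
    }
    data.frame(region = paste(names(sets)[cmb], collapse = " & "),
               n_sets = sum(cmb), count = sum(inside),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_sets, out$region), c("region", "count")]
}
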