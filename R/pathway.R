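# Genus-pathway bipartite association: cross Spearman correlations, a
# thresholded bipartite network per cohort group, per-(CAG, category)
# disease-vs-control contrasts of the correlation values, and paired tests on
# focal pathway groups (SCFA, LPS-associated, tryptophan-associated).

#' Genus-pathway bipartite co-abundance network
#'
#' Spearman correlation between every genus and every pathway over the same
#' samples. Edges retain pairs with `|rho| > threshold` (default 0.2), signs
#' kept: bipartite displays show positive and negative associations. The full
#' unthresholded correlation matrix is carried along because the per-cell
#' contrasts in [cell_tests()] must compare equal-length, selection-free
#' vectors between groups.
#'
#' @param genus_table samples x genera matrix.
#' @param pathway_table samples x pathways matrix; sample ids must match the
#'   genus table (a mismatch is an error listing the differences).
#' @param threshold edge threshold on `|rho|` (default 0.2).
#' @param group optional group label.
#' @return object of class `cag_bipartite`: list with `group`, `rho` (genera
#'   x pathways), `edges` (data.frame genus/pathway/rho/sign), `threshold`,
#'   `n_samples`.
#' @export
genus_pathway_network <- function(genus_table, pathway_table, threshold = 0.2,
                                  group = NULL) {
  genus_table <- as.matrix(genus_table)
  pathway_table <- as.matrix(pathway_table)
  gids <- rownames(genus_table); pids <- rownames(pathway_table)
  if (!identical(gids, pids)) {
    if (!is.null(gids) && !is.null(pids) && setequal(gids, pids)) {
      pathway_table <- pathway_table[gids, , drop = FALSE]
    } else {
      only_g <- setdiff(gids, pids); only_p <- setdiff(pids, gids)
      stop("sample ids differ between genus and pathway tables; ",
           "only in genus table: ", paste(utils::head(only_g, 5), collapse = ", "),
           "; only in pathway table: ", paste(utils::head(only_p, 5), collapse = ", "))
    }
  }
  if (nrow(genus_table) < 3) stop("need at least 3 samples")
  rho <- suppressWarnings(
    stats::cor(genus_table, pathway_table, method = "spearman")
  )
  idx <- which(!is.na(rho) & abs(rho) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    genus = rownames(rho)[idx[, 1L]],
    pathway = colnames(rho)[idx[, 2L]],
    rho = rho[idx],
    sign = ifelse(rho[idx] >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$genus, edges$pathway), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(group = group, rho = rho, edges = edges, threshold = threshold,
         n_samples = nrow(genus_table)),
    class = "cag_bipartite"
  )
}

#' @export
print.cag_bipartite <- function(x, ...) {
  cat(sprintf("<cag_bipartite%s> %d genera x %d pathways, %d edge(s) (|rho| > %g)\n",
              if (is.null(x$group)) "" else paste0(": ", x$group),
              nrow(x$rho), ncol(x$rho), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Per-(CAG, category) contrast of genus-pathway correlations
#'
#' For each CAG and pathway category, collects the unthresholded correlation
#' values of every member-genus x category-pathway pair in the disease and
#' control networks (the two vectors therefore have identical length and
#' composition; the edge threshold never enters) and compares them with a
#' two-sided Wilcoxon rank-sum test. Cells with no pairs are marked empty;
#' single-pair cells cannot carry a rank test and get an undefined marker.
#' No multiplicity correction is applied across cells by default;
#' `bh_across_cells = TRUE` adds a BH-adjusted column.
#'
#' @param net_case,net_control [genus_pathway_network()] results computed on
#'   the same genus x pathway universe.
#' @param partition a [cluster_cags()] result.
#' @param category_map data.frame with columns `pathway`, `category`.
#' @param bh_across_cells logical; add BH-adjusted q-values across cells.
#' @return data.frame: cag, category, n_pairs, mean_rho_case,
#'   mean_rho_control, shift direction, statistic, p_value, stars, note
#'   (and `q_value` when requested).
#' @export
cell_tests <- function(net_case, net_control, partition, category_map,
                       bh_across_cells = FALSE) {
  stopifnot(inherits(net_case, "cag_bipartite"),
            inherits(net_control, "cag_bipartite"))
  if (!identical(dimnames(net_case$rho), dimnames(net_control$rho))) {
    stop("disease and control networks must share the same genus x pathway universe")
  }
  genera <- rownames(net_case$rho)
  cats <- unique(category_map$category)
  rows <- list()
  for (c_id in seq_len(partition$k)) {
    members <- intersect(
      names(partition$assignment)[partition$assignment == c_id], genera)
    for (ct in cats) {
      paths <- intersect(category_map$pathway[category_map$category == ct],
                         colnames(net_case$rho))
      cg <- sprintf("CAG%d", c_id)
      if (length(members) == 0 || length(paths) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          cag = cg, category = ct, n_pairs = 0L,
          mean_rho_case = NA_real_, mean_rho_control = NA_real_,
          shift = "empty", statistic = NA_real_, p_value = NA_real_,
          stars = "", note = "empty cell", stringsAsFactors = FALSE)
        next
      }
      vd <- as.vector(net_case$rho[members, paths, drop = FALSE])
      vc <- as.vector(net_control$rho[members, paths, drop = FALSE])
      keep <- !is.na(vd) & !is.na(vc)
      vd <- vd[keep]; vc <- vc[keep]
      md <- mean(vd); mc <- mean(vc)
      shift <- if (isTRUE(md > mc)) "up" else if (isTRUE(md < mc)) "down" else "none"
      if (length(vd) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          cag = cg, category = ct, n_pairs = length(vd),
          mean_rho_case = md, mean_rho_control = mc, shift = shift,
          statistic = NA_real_, p_value = NA_real_, stars = "",
          note = "undefined (fewer than 2 pairs)", stringsAsFactors = FALSE)
        next
      }
      res <- wilcoxon_ranksum(vd, vc)
      rows[[length(rows) + 1L]] <- data.frame(
        cag = cg, category = ct, n_pairs = length(vd),
        mean_rho_case = md, mean_rho_control = mc, shift = shift,
        statistic = res$statistic, p_value = res$p_value,
        stars = signif_stars(res$p_value),
        note = if (is.null(res$note)) "" else res$note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh_across_cells) {
    ok <- !is.na(out$p_value)
    out$q_value <- NA_real_
    out$q_value[ok] <- bh_adjust(out$p_value[ok])
  }
  out
}

#' Paired test on focal pathway groups
#'
#' For each focal group (e.g. acetate, propionate, butyrate biosynthesis,
#' LPS-associated, tryptophan-associated pathways), the member pathway
#' abundances are aggregated per sample (`mode = "sum"`, the additive
#' abundance reading; `mode = "per_pathway"` tests each member pathway
#' separately), case-minus-control differences are formed over the matched
#' pairs, and a two-sided paired t-test is applied. Pairs with a missing
#' member sample are dropped with a warning.
#'
#' @param pathway_table samples x pathways matrix.
#' @param cohort a [match_cohort()] result.
#' @param focal_groups named list of pathway id vectors.
#' @param mode `"sum"` (default) or `"per_pathway"`.
#' @return data.frame: group, pathway (`"(sum)"` in sum mode), n_pairs,
#'   mean_diff, statistic, p_value, stars, note.
#' @export
focal_pathway_paired_test <- function(pathway_table, cohort, focal_groups,
                                      mode = c("sum", "per_pathway")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "matched_cohort"))
  pathway_table <- as.matrix(pathway_table)
  pairs <- cohort$pairs
  present <- pairs$case_id %in% rownames(pathway_table) &
    pairs$control_id %in% rownames(pathway_table)
  if (any(!present)) {
    warning(sprintf("%d pair(s) dropped: member(s) missing from pathway table",
                    sum(!present)))
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no usable matched pairs")
  one_test <- function(grp, pw_label, score) {
    d <- score[pairs$case_id] - score[pairs$control_id]
    if (length(d) < 3 || stats::sd(d) == 0) {
      data.frame(group = grp, pathway = pw_label, n_pairs = length(d),
                 mean_diff = mean(d), statistic = NA_real_,
                 p_value = NA_real_, stars = "",
                 note = "undefined (zero variance or <3 pairs)",
                 stringsAsFactors = FALSE)
    } else {
      tt <- paired_t(d)
      data.frame(group = grp, pathway = pw_label, n_pairs = length(d),
                 mean_diff = mean(d), statistic = tt$statistic,
                 p_value = tt$p_value, stars = signif_stars(tt$p_value),
                 note = "", stringsAsFactors = FALSE)
    }
  }
  rows <- list()
  for (grp in names(focal_groups)) {
    members <- intersect(focal_groups[[grp]], colnames(pathway_table))
    if (length(members) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, pathway = NA_character_, n_pairs = 0L,
        mean_diff = NA_real_, statistic = NA_real_, p_value = NA_real_,
        stars = "", note = "no member pathways in table",
        stringsAsFactors = FALSE)
      next
    }
    if (mode == "sum") {
      score <- rowSums(pathway_table[, members, drop = FALSE])
      names(score) <- rownames(pathway_table)
      rows[[length(rows) + 1L]] <- one_test(grp, "(sum)", score)
    } else {
      for (pw in members) {
        score <- pathway_table[, pw]
        names(score) <- rownames(pathway_table)
        rows[[length(rows) + 1L]] <- one_test(grp, pw, score)
      }
    }
  }
  do.call(rbind, rows)
}
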