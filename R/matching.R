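# One-to-one case/control matching on standardized covariates, with covariate
# balance reporting. Both a greedy nearest-pair scheme (parity with common
# open-source matching scripts) and an optimal assignment (Hungarian /
# shortest-augmenting-path) are provided; optimal is the default.

#' Standardize a covariate table
#'
#' Encodes and z-scores matching covariates over the pooled case+control
#' sample (sample standard deviation, n - 1 denominator) so each retained
#' column has mean 0 and variance 1. Character/factor covariates are encoded
#' through `codebook`, a named list mapping covariate name to a named numeric
#' vector (the default covers `sex` as female = 0, male = 1). Constant
#' covariates are dropped with a warning; rows with missing values in any
#' retained covariate are excluded and recorded in the `dropped_samples`
#' attribute.
#'
#' @param metadata data.frame with a `sample_id` column (or rownames) and the
#'   covariate columns.
#' @param covariates character vector of covariate columns to use; default =
#'   all columns except `sample_id`, `group`, `subtype`.
#' @param codebook named list of named numeric vectors used to encode
#'   non-numeric covariates.
#' @return object of class `covariate_matrix`: list with `values` (samples x
#'   covariates z-score matrix), `center`, `scale`, `dropped_covariates`,
#'   `dropped_samples`.
#' @export
standardize_covariates <- function(metadata, covariates = NULL,
                                   codebook = default_codebook()) {
  md <- as.data.frame(metadata)
  ids <- if ("sample_id" %in% names(md)) as.character(md$sample_id) else rownames(md)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("metadata needs unique sample ids ('sample_id' column or rownames)")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(md), c("sample_id", "group", "subtype"))
  }
  missing_cols <- setdiff(covariates, names(md))
  if (length(missing_cols)) {
    stop("covariates absent from metadata: ", paste(missing_cols, collapse = ", "))
  }
  enc <- matrix(NA_real_, nrow(md), length(covariates),
                dimnames = list(ids, covariates))
  for (nm in covariates) {
    v <- md[[nm]]
    if (is.numeric(v)) {
      enc[, nm] <- v
    } else {
      v <- as.character(v)
      cb <- codebook[[nm]]
      if (is.null(cb)) {
        stop(sprintf("covariate '%s' is non-numeric and has no codebook entry", nm))
      }
      bad <- !is.na(v) & !(v %in% names(cb))
      if (any(bad)) {
        stop(sprintf("covariate '%s': no codebook value for '%s' (sample %s)",
                     nm, v[which(bad)[1L]], ids[which(bad)[1L]]))
      }
      enc[, nm] <- unname(cb[v])
    }
  }
  complete <- stats::complete.cases(enc)
  dropped_samples <- ids[!complete]
  enc <- enc[complete, , drop = FALSE]
  sds <- apply(enc, 2L, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
  }
  enc <- enc[, !constant, drop = FALSE]
  center <- colMeans(enc)
  scale <- apply(enc, 2L, stats::sd)
  z <- sweep(sweep(enc, 2L, center, "-"), 2L, scale, "/")
  structure(
    list(values = z, center = center, scale = scale,
         dropped_covariates = covariates[constant],
         dropped_samples = dropped_samples),
    class = "covariate_matrix"
  )
}

#' Default ordinal codebook for categorical matching covariates
#'
#' Sex is coded 1 (male) / 0 (female); frequency scales get their natural
#' 0..4 ordering.
#'
#' @return named list of named numeric vectors.
#' @export
default_codebook <- function() {
  freq <- c("never" = 0, "rarely" = 1, "occasionally" = 2,
            "regularly" = 3, "daily" = 4)
  list(
    sex = c("female" = 0, "male" = 1, "F" = 0, "M" = 1),
    alcohol_freq = freq, diet_meat = freq, diet_dairy = freq,
    diet_vegetables = freq, diet_whole_grains = freq,
    diet_salted_snacks = freq
  )
}

#' Pairwise Euclidean distances between cases and controls
#'
#' `d(i, j) = sqrt(sum_k (x_ik - y_jk)^2)` over the shared covariate columns.
#'
#' @param cases,controls numeric matrices with identical column sets (rows =
#'   samples); typically row subsets of a [standardize_covariates()] result.
#' @return cases x controls distance matrix with sample ids as dimnames.
#' @export
pairwise_distances <- function(cases, controls) {
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  if (!identical(colnames(cases), colnames(controls))) {
    if (is.null(colnames(cases)) || is.null(colnames(controls)) ||
        !setequal(colnames(cases), colnames(controls))) {
      stop("cases and controls must share the same covariate columns")
    }
    controls <- controls[, colnames(cases), drop = FALSE]
  }
  d2 <- outer(rowSums(cases^2), rowSums(controls^2), "+") -
    2 * cases %*% t(controls)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  d <- sqrt(d2)
  dimnames(d) <- list(rownames(cases), rownames(controls))
  d
}

# Shortest-augmenting-path (Jonker-Volgenant style Hungarian) solver for the
# rectangular linear assignment problem, nrow <= ncol. Returns for each row
# the assigned column. Deterministic: ties resolve to the lowest column index.
lsap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n >= 1, n <= m, all(is.finite(cost)))
  u <- numeric(n + 1L)       # row potentials, u[i + 1]
  v <- numeric(m + 1L)       # column potentials, v[j + 1]; j = 0 is virtual
  p <- integer(m + 1L)       # p[j + 1] = row currently assigned to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      imp <- cur < minv[free]
      if (any(imp)) {
        minv[free[imp]] <- cur[imp]
        way[free[imp] + 1L] <- j0
      }
      jsel <- free[which.min(minv[free])]
      delta <- minv[jsel]
      usedcols <- which(used) - 1L
      rows_touched <- p[usedcols + 1L] + 1L
      u[rows_touched] <- u[rows_touched] + delta
      v[usedcols + 1L] <- v[usedcols + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- jsel
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assigned <- which(p[-1L] > 0L)
  assignment[p[assigned + 1L]] <- assigned
  assignment
}

# Greedy matching: repeatedly take the globally smallest remaining distance;
# ties broken by lowest case (row) index, then lowest control (column) index.
greedy_match_idx <- function(cost) {
  n <- nrow(cost); m <- ncol(cost); k <- min(n, m)
  work <- cost
  pairs <- matrix(0L, k, 2L)
  for (s in seq_len(k)) {
    mn <- min(work)
    cand <- which(work == mn, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    pairs[s, ] <- c(i, j)
    work[i, ] <- Inf
    work[, j] <- Inf
  }
  pairs
}

#' One-to-one matching from a distance matrix
#'
#' `algorithm = "optimal"` (default) minimizes the total matched distance via
#' a shortest-augmenting-path assignment solver; `"greedy"` repeatedly takes
#' the globally smallest remaining case-control distance (ties broken by
#' lowest case index, then lowest control index). Both are deterministic.
#' When there are more cases than controls, the surplus cases are reported in
#' `unmatched_cases` rather than causing failure.
#'
#' @param dist_mat cases x controls matrix of finite nonnegative distances,
#'   with sample ids as dimnames (defaults are generated when absent).
#' @param algorithm `"optimal"` or `"greedy"`.
#' @return object of class `matched_cohort`: list with `pairs` (data.frame
#'   `case_id`, `control_id`, `distance`), `unmatched_cases`, `algorithm`,
#'   `total_distance`.
#' @export
match_cohort <- function(dist_mat, algorithm = c("optimal", "greedy")) {
  algorithm <- match.arg(algorithm)
  dist_mat <- as.matrix(dist_mat)
  if (!all(is.finite(dist_mat))) stop("distance matrix must be finite")
  if (is.null(rownames(dist_mat))) {
    rownames(dist_mat) <- sprintf("case_%d", seq_len(nrow(dist_mat)))
  }
  if (is.null(colnames(dist_mat))) {
    colnames(dist_mat) <- sprintf("control_%d", seq_len(ncol(dist_mat)))
  }
  n <- nrow(dist_mat); m <- ncol(dist_mat)
  if (algorithm == "optimal") {
    if (n <= m) {
      assignment <- lsap_solve(dist_mat)
      idx <- cbind(seq_len(n), assignment)
    } else {
      assignment <- lsap_solve(t(dist_mat))  # rows = controls
      idx <- cbind(assignment, seq_len(m))
    }
    idx <- idx[order(idx[, 1L]), , drop = FALSE]
  } else {
    idx <- greedy_match_idx(dist_mat)
  }
  pairs <- data.frame(
    case_id = rownames(dist_mat)[idx[, 1L]],
    control_id = colnames(dist_mat)[idx[, 2L]],
    distance = dist_mat[idx],
    stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs,
         unmatched_cases = setdiff(rownames(dist_mat), pairs$case_id),
         algorithm = algorithm,
         total_distance = sum(pairs$distance)),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs (%s), total distance %.4f, %d unmatched case(s)\n",
              nrow(x$pairs), x$algorithm, x$total_distance,
              length(x$unmatched_cases)))
  invisible(x)
}

#' Covariate balance report for a matched cohort
#'
#' One row per covariate with the standardized mean difference
#' (`mean(case - control) / pooled sd`, pooled over the two matched arms) and
#' the two-sided paired t-test over matched pairs. With fewer than 3 pairs or
#' zero variance of the differences the p-value carries an undefined marker.
#' When `subtype_col` is given and case samples span more than one subtype, a
#' per-covariate one-way ANOVA across case subtypes is reported as well.
#'
#' @param cohort a [match_cohort()] result.
#' @param metadata data.frame with `sample_id` and the covariate columns
#'   (raw, unstandardized values; non-numeric columns are encoded through
#'   `codebook`).
#' @param covariates covariate columns to report on; default as in
#'   [standardize_covariates()].
#' @param codebook see [standardize_covariates()].
#' @param subtype_col optional name of a subtype label column.
#' @return list with `paired` (data.frame: covariate, mean_case, mean_control,
#'   smd, statistic, p_value, note) and, when applicable, `anova`.
#' @export
balance_report <- function(cohort, metadata, covariates = NULL,
                           codebook = default_codebook(),
                           subtype_col = NULL) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (nrow(cohort$pairs) == 0) stop("cohort has no matched pairs")
  md <- as.data.frame(metadata)
  ids <- if ("sample_id" %in% names(md)) as.character(md$sample_id) else rownames(md)
  rownames(md) <- ids
  if (is.null(covariates)) {
    covariates <- setdiff(names(md), c("sample_id", "group", "subtype"))
  }
  enc <- function(nm) {
    v <- md[[nm]]
    if (is.numeric(v)) return(stats::setNames(v, ids))
    cb <- codebook[[nm]]
    if (is.null(cb)) stop(sprintf("no codebook entry for covariate '%s'", nm))
    stats::setNames(unname(cb[as.character(v)]), ids)
  }
  case_ids <- cohort$pairs$case_id
  ctrl_ids <- cohort$pairs$control_id
  rows <- lapply(covariates, function(nm) {
    v <- enc(nm)
    a <- v[case_ids]; b <- v[ctrl_ids]
    pooled_sd <- sqrt((stats::var(a) + stats::var(b)) / 2)
    smd <- if (is.na(pooled_sd) || pooled_sd == 0) {
      if (mean(a - b) == 0) 0 else NA_real_
    } else mean(a - b) / pooled_sd
    if (length(a) < 3 || stats::sd(a - b) == 0) {
      data.frame(covariate = nm, mean_case = mean(a), mean_control = mean(b),
                 smd = smd, statistic = NA_real_, p_value = NA_real_,
                 note = "undefined (zero variance or <3 pairs)",
                 stringsAsFactors = FALSE)
    } else {
      tt <- paired_t(a, b)
      data.frame(covariate = nm, mean_case = mean(a), mean_control = mean(b),
                 smd = smd, statistic = tt$statistic, p_value = tt$p_value,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- list(paired = do.call(rbind, rows))
  if (!is.null(subtype_col) && subtype_col %in% names(md)) {
    case_md <- md[case_ids, , drop = FALSE]
    subtypes <- as.factor(case_md[[subtype_col]])
    if (nlevels(droplevels(subtypes)) > 1) {
      arows <- lapply(covariates, function(nm) {
        v <- enc(nm)[case_ids]
        res <- anova_oneway(v, subtypes)
        data.frame(covariate = nm, statistic = res$statistic,
                   p_value = res$p_value,
                   note = if (res$undefined) res$note else "",
                   stringsAsFactors = FALSE)
      })
      out$anova <- do.call(rbind, arows)
    }
  }
  out
}
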