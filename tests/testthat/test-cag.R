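test_that("low-count filter removes features only when both thresholds fail", {
  counts <- matrix(0L, 40, 5,
                   dimnames = list(NULL, c("wide", "deep", "rare", "edge", "gone")))
  counts[1:31, "wide"] <- 1L            # present in 31 samples, 31 reads
  counts[1:2, "deep"] <- c(500L, 500L)  # 2 samples but 1000 reads
  counts[1:2, "rare"] <- c(3L, 2L)      # fails both -> removed
  counts[1:30, "edge"] <- 1L            # exactly 30 samples -> kept
  counts[1, "gone"] <- 9L               # 1 sample, 9 reads -> removed
  out <- filter_low_count_features(counts)
  expect_equal(colnames(out), c("wide", "deep", "edge"))
  expect_equal(attr(out, "filter_log")$removed, c("rare", "gone"))
  # OR-exclusion reading removes anything failing either threshold
  out_or <- filter_low_count_features(counts, rule = "or")
  expect_equal(colnames(out_or), c("wide", "edge"))
  # empty table passes through
  empty <- matrix(integer(0), 10, 0)
  expect_equal(ncol(filter_low_count_features(empty)), 0)
})

test_that("genus filter applies the 20% prevalence / 0.05% abundance rule", {
  n <- 100
  rel <- matrix(0, n, 4, dimnames = list(NULL, c("ok", "sparse", "faint", "both_bad")))
  rel[1:50, "ok"] <- 0.01          # prevalence 50%, mean 5e-3
  rel[1:19, "sparse"] <- 0.05      # prevalence 19% -> removed
  rel[1:50, "faint"] <- 0.0008     # mean 4e-4 < 5e-4 -> removed
  rel[1:10, "both_bad"] <- 0.001
  out <- filter_genera(rel)
  expect_equal(colnames(out), "ok")
  # survivors keep their original scale (no re-closure)
  expect_equal(out[, "ok"], rel[, "ok"])
})

test_that("duplicated genera produce a single perfect edge", {
  set.seed(61)
  base <- matrix(runif(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  tab <- cbind(base, dup = base[, "a"])
  net <- build_network(tab, threshold = 0.4, positive_only = TRUE)
  perfect <- net$edges[net$edges$rho > 0.999, ]
  expect_equal(nrow(perfect), 1)
  expect_setequal(unlist(perfect[, c("from", "to")]), c("a", "dup"))
})

test_that("independent genera produce empty networks almost always", {
  zero_edge_runs <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_cases = 200, n_controls = 200, n_genera = 20,
                      n_blocks = 0, block_sizes = integer(0),
                      effect_blocks = NULL, seed = seed)
    s <- simulate_genus_table(cfg)
    net <- build_network(s$abundance)
    zero_edge_runs <- zero_edge_runs + (nrow(net$edges) == 0)
  }
  expect_gte(zero_edge_runs, 19)
})

test_that("a planted block of 4 yields exactly its 6 within-block edges", {
  exact_runs <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_cases = 200, n_controls = 200, n_genera = 12,
                      n_blocks = 1, block_sizes = 4, within_block_rho = 0.9,
                      effect_blocks = NULL, seed = seed)
    s <- simulate_genus_table(cfg)
    net <- build_network(s$abundance)
    members <- names(s$truth$block_assignment)[s$truth$block_assignment == 1]
    within <- net$edges$from %in% members & net$edges$to %in% members
    exact_runs <- exact_runs + (nrow(net$edges) == 6 && all(within))
  }
  expect_gte(exact_runs, 18)
})

test_that("network edges are invariant to sample and genus order", {
  cfg <- small_config(seed = 29)
  s <- simulate_genus_table(cfg)
  tab <- s$abundance
  net <- build_network(tab, threshold = 0.3)
  canon <- function(net) {
    e <- net$edges
    key <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
    e <- e[order(key), ]
    rownames(e) <- NULL
    num <- vapply(e, is.numeric, TRUE)
    e[num] <- lapply(e[num], round, 10)
    e$from2 <- pmin(e$from, e$to); e$to2 <- pmax(e$from, e$to)
    e$from <- e$from2; e$to <- e$to2
    e[, c("from", "to", "rho", "p", "q", "sign")]
  }
  perm_samples <- tab[sample(nrow(tab)), ]
  perm_genera <- tab[, sample(ncol(tab))]
  expect_equal(canon(build_network(perm_samples, threshold = 0.3)), canon(net))
  expect_equal(canon(build_network(perm_genera, threshold = 0.3)), canon(net))
})

test_that("Ward clustering recovers exact block-diagonal structure", {
  # rho = 1 within, 0 between: zero within-block distance forces recovery
  sizes <- c(3, 2, 4, 2, 3, 2, 2, 2)
  truth <- rep(seq_along(sizes), sizes)
  G <- length(truth)
  rho <- outer(truth, truth, function(a, b) as.numeric(a == b))
  dimnames(rho) <- list(sprintf("g%02d", 1:G), sprintf("g%02d", 1:G))
  part <- cluster_cags(rho, k = 8)
  tab <- table(part$assignment, truth)
  expect_true(all(rowSums(tab > 0) == 1))  # one planted block per CAG
  expect_equal(length(part$violations), 0)
  # determinism
  expect_identical(cluster_cags(rho, k = 8)$assignment, part$assignment)
})

test_that("cluster size bounds are reported, k is validated, k=1 pools all", {
  set.seed(31)
  tab <- matrix(runif(30 * 6), 30, 6, dimnames = list(NULL, letters[1:6]))
  rho <- cor(tab, method = "spearman")
  singletons <- cluster_cags(rho, k = 6)
  expect_equal(unname(singletons$sizes), rep(1L, 6))
  expect_length(singletons$violations, 6)  # all below the lower bound of 2
  expect_error(cluster_cags(rho, k = 7), "exceeds")
  one <- cluster_cags(rho, k = 1)
  expect_true(all(one$assignment == 1))
})

test_that("CAG abundance summaries are exact and conservative", {
  tab <- matrix(c(0.1, 0.2, 0.3, 0.4,
                  0.05, 0.15, 0.35, 0.45), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b", "c", "d")))
  part <- structure(list(assignment = c(a = 1L, b = 1L, c = 1L, d = 2L),
                         k = 2L, linkage = "ward.D2",
                         sizes = c(CAG1 = 3L, CAG2 = 1L),
                         size_bounds = c(2, 10), violations = "CAG2"),
                    class = "cag_partition")
  m <- cag_abundance(tab, part, "mean")
  s <- cag_abundance(tab, part, "sum")
  expect_equal(m["s1", "CAG1"], 0.2)   # mean of 0.1, 0.2, 0.3
  expect_equal(s["s1", "CAG1"], 0.6)
  # a single-genus CAG equals that genus under both summaries
  expect_equal(m[, "CAG2"], tab[, "d"])
  expect_equal(s[, "CAG2"], tab[, "d"])
  # conservation: sum-summary row totals equal partitioned-genus row totals
  expect_equal(rowSums(s), rowSums(tab), tolerance = 1e-12)
  expect_error(cag_abundance(cbind(tab, e = c(0, 0)), part), "absent")
})

test_that("CAG differential testing is calibrated and detects planted effects", {
  # identical groups: all p = 1
  tab <- matrix(rep(c(0.2, 0.3, 0.5), each = 8), 8, 3,
                dimnames = list(NULL, c("CAG1", "CAG2", "CAG3")))
  res <- cag_differential(tab, rep(c("case", "control"), each = 4))
  expect_true(all(res$p_value == 1))
  # planted log-fold effect on one block is detected across seeds
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_cases = 100, n_controls = 100, n_genera = 12,
                      n_blocks = 2, block_sizes = c(4, 4),
                      effect_blocks = c("1" = 1.0), seed = seed)
    s <- simulate_genus_table(cfg)
    sm <- cagnet:::spearman_matrix(s$abundance)
    part <- cluster_cags(sm$rho, k = 3)
    cm <- cag_abundance(s$abundance, part, "mean")
    res <- cag_differential(cm, attr(s$abundance, "group"))
    # the CAG holding most block-1 genera must be significant at 0.01
    members <- names(s$truth$block_assignment)[s$truth$block_assignment == 1]
    target <- names(which.max(table(part$assignment[members])))
    hits <- hits + (res$p_value[res$cag == paste0("CAG", target)] < 0.01)
  }
  expect_gte(hits, 9)
})

test_that("null-label CAG differential rejects at the nominal rate", {
  set.seed(37)
  rejections <- 0L
  n_sims <- 1000L
  for (i in seq_len(n_sims)) {
    v <- matrix(rnorm(40), 40, 2, dimnames = list(NULL, c("CAG1", "CAG2")))
    labels <- sample(rep(c("case", "control"), each = 20))
    res <- cag_differential(v, labels)
    rejections <- rejections + (res$p_value[1] < 0.05)
  }
  expect_gte(rejections / n_sims, 0.03)
  expect_lte(rejections / n_sims, 0.07)
})

test_that("genus set overlaps enumerate all Venn regions", {
  same <- replicate(3, sprintf("g%d", 1:10), simplify = FALSE)
  names(same) <- c("A", "B", "C")
  v1 <- genus_venn(same)
  expect_equal(v1$count[v1$region == "A & B & C"], 10)
  expect_true(all(v1$count[v1$region != "A & B & C"] == 0))
  disjoint <- list(A = c("a1", "a2"), B = c("b1"), C = c("c1", "c2"))
  v2 <- genus_venn(disjoint)
  expect_equal(v2$count[v2$region == "A & B & C"], 0)
  expect_equal(v2$count[v2$region == "A"], 2)
  # hand-enumerated: A={a,b,c}, B={b,c,d}, C={c,d,e}
  v3 <- genus_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                        C = c("c", "d", "e")))
  get <- function(region) v3$count[v3$region == region]
  expect_equal(get("A & B & C"), 1)  # c
  expect_equal(get("A & B"), 1)      # b
  expect_equal(get("B & C"), 1)      # d
  expect_equal(get("A & C"), 0)
  expect_equal(get("A"), 1)          # a
  expect_equal(get("B"), 0)
  expect_equal(get("C"), 1)          # e
})
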