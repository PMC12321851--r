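make_cohort <- function(case_ids, ctrl_ids) {
  structure(
    list(pairs = data.frame(case_id = case_ids, control_id = ctrl_ids,
                            distance = 0, stringsAsFactors = FALSE),
         unmatched_cases = character(0), algorithm = "optimal",
         total_distance = 0),
    class = "matched_cohort")
}

test_that("a pathway equal to a genus column yields a perfect bipartite edge", {
  set.seed(71)
  genus <- matrix(runif(40 * 3), 40, 3,
                  dimnames = list(sprintf("s%02d", 1:40), c("ga", "gb", "gc")))
  pathways <- cbind(p1 = genus[, "ga"], p2 = runif(40))
  rownames(pathways) <- rownames(genus)
  net <- genus_pathway_network(genus, pathways)
  hit <- net$edges[net$edges$genus == "ga" & net$edges$pathway == "p1", ]
  expect_equal(hit$rho, 1)
  expect_equal(hit$sign, "+")
})

test_that("below-threshold correlations give an empty but valid network", {
  genus <- matrix(rep(1:10, 2), 10, 2,
                  dimnames = list(sprintf("s%d", 1:10), c("ga", "gb")))
  pathways <- matrix(c(5, 1, 4, 2, 6, 3, 8, 7, 10, 9), 10, 1,
                     dimnames = list(sprintf("s%d", 1:10), "p1"))
  net <- genus_pathway_network(genus, pathways, threshold = 0.9)
  expect_equal(nrow(net$edges), 0)
  expect_s3_class(net, "cag_bipartite")
})

test_that("sample mismatches are errors listing the differences", {
  genus <- matrix(runif(9), 3, 3, dimnames = list(c("s1", "s2", "s3"), NULL))
  pathways <- matrix(runif(6), 3, 2, dimnames = list(c("s1", "s2", "s9"), NULL))
  expect_error(genus_pathway_network(genus, pathways), "s9")
  # same ids in a different order are silently aligned
  genus2 <- matrix(runif(12), 4, 3,
                   dimnames = list(c("s1", "s2", "s3", "s4"), c("a", "b", "c")))
  pw2 <- matrix(runif(8), 4, 2,
                dimnames = list(c("s4", "s3", "s2", "s1"), c("p", "q")))
  expect_silent(genus_pathway_network(genus2, pw2))
})

test_that("null pathway retention stays at the |rho| > 0.2 null rate", {
  retained <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed + 100)
    n <- 400
    genus <- matrix(runif(n * 10), n, 10,
                    dimnames = list(sprintf("s%d", 1:n), sprintf("g%d", 1:10)))
    pathways <- matrix(runif(n * 5), n, 5,
                       dimnames = list(sprintf("s%d", 1:n), sprintf("p%d", 1:5)))
    net <- genus_pathway_network(genus, pathways)
    retained[seed] <- nrow(net$edges) / (10 * 5)
  }
  expect_lt(mean(retained), 0.05)
})

fixed_partition <- function(assignment) {
  k <- max(assignment)
  sizes <- tabulate(assignment, k)
  names(sizes) <- sprintf("CAG%d", seq_len(k))
  structure(list(assignment = assignment, k = as.integer(k),
                 linkage = "ward.D2", sizes = sizes,
                 size_bounds = c(2, 10), violations = character(0)),
            class = "cag_partition")
}

test_that("cell tests: identical groups are null, degenerate cells are marked", {
  set.seed(73)
  rho <- matrix(runif(6 * 4, -0.5, 0.5), 6, 4,
                dimnames = list(sprintf("g%d", 1:6), sprintf("p%d", 1:4)))
  net <- structure(list(group = "case", rho = rho, edges = NULL,
                        threshold = 0.2, n_samples = 50),
                   class = "cag_bipartite")
  part <- fixed_partition(c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L, g5 = 2L, g6 = 3L))
  catmap <- data.frame(pathway = sprintf("p%d", 1:4),
                       category = c("energy", "energy", "lipid", "lipid"))
  res <- cell_tests(net, net, part, catmap)
  defined <- !is.na(res$p_value)
  expect_true(all(res$p_value[defined] == 1))
  expect_true(all(res$shift[defined] == "none"))
  # single genus x single pathway cell -> undefined marker
  catmap2 <- data.frame(pathway = sprintf("p%d", 1:4),
                        category = c("energy", "lipid", "lipid", "lipid"))
  res2 <- cell_tests(net, net, part, catmap2)
  solo <- res2[res2$cag == "CAG3" & res2$category == "energy", ]
  expect_equal(solo$n_pairs, 1L)
  expect_match(solo$note, "undefined")
  # empty cell (category with no pathways present in the universe)
  catmap3 <- rbind(catmap, data.frame(pathway = "p99", category = "vitamin"))
  res3 <- cell_tests(net, net, part, catmap3)
  expect_true(all(res3$note[res3$category == "vitamin"] == "empty cell"))
})

test_that("cell mean correlations are bounded by their constituent values", {
  set.seed(79)
  rho_case <- matrix(runif(8 * 6, -1, 1), 8, 6,
                     dimnames = list(sprintf("g%d", 1:8), sprintf("p%d", 1:6)))
  rho_ctrl <- matrix(runif(8 * 6, -1, 1), 8, 6, dimnames = dimnames(rho_case))
  mknet <- function(r, g) structure(list(group = g, rho = r, edges = NULL,
                                         threshold = 0.2, n_samples = 50),
                                    class = "cag_bipartite")
  part <- fixed_partition(stats::setNames(rep(1:2, each = 4L),
                                          sprintf("g%d", 1:8)))
  catmap <- data.frame(pathway = sprintf("p%d", 1:6),
                       category = rep(c("energy", "lipid"), 3))
  res <- cell_tests(mknet(rho_case, "case"), mknet(rho_ctrl, "control"),
                    part, catmap)
  for (i in seq_len(nrow(res))) {
    members <- names(part$assignment)[part$assignment ==
                                        as.integer(sub("CAG", "", res$cag[i]))]
    paths <- catmap$pathway[catmap$category == res$category[i]]
    vals <- rho_case[members, paths]
    expect_gte(res$mean_rho_case[i], min(vals) - 1e-12)
    expect_lte(res$mean_rho_case[i], max(vals) + 1e-12)
  }
  # invariance to genus and pathway order (both groups permuted consistently)
  gperm <- sample(8); pperm <- sample(6)
  res_perm <- cell_tests(mknet(rho_case[gperm, pperm], "case"),
                         mknet(rho_ctrl[gperm, pperm], "control"),
                         part, catmap)
  expect_equal(res_perm, res)
})

test_that("rewiring the pathway layer for one block shifts only its cells", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_cases = 150, n_controls = 150, n_genera = 12,
                      n_blocks = 2, block_sizes = c(5, 5),
                      within_block_rho = 0.8, effect_blocks = NULL,
                      n_pathways = 8, pathway_noise_sd = 0.1, seed = seed)
    s <- simulate_genus_table(cfg)
    grp <- attr(s$abundance, "group")
    # pathways driven by block 1 for controls; rewired to block 2 for cases
    W_ctrl <- matrix(0, 12, 8)
    W_ctrl[s$truth$block_assignment == 1, ] <- 1
    W_case <- matrix(0, 12, 8)
    W_case[s$truth$block_assignment == 2, ] <- 1
    pw_ctrl <- simulate_pathway_table(s, s$truth, cfg, contribution = W_ctrl)
    pw_case <- simulate_pathway_table(s, s$truth, cfg, contribution = W_case)
    pathways <- rbind(pw_case$pathways[grp == "case", ],
                      pw_ctrl$pathways[grp == "control", ])
    net_case <- genus_pathway_network(s$abundance[grp == "case", ],
                                      pathways[grp == "case", ])
    net_ctrl <- genus_pathway_network(s$abundance[grp == "control", ],
                                      pathways[grp == "control", ])
    part <- fixed_partition(s$truth$block_assignment[
      s$truth$block_assignment > 0])
    catmap <- data.frame(pathway = colnames(pathways), category = "energy")
    res <- cell_tests(net_case, net_ctrl, part, catmap)
    hits <- hits + all(res$p_value < 0.01, na.rm = TRUE)
  }
  expect_gte(hits, 8)
})

test_that("focal paired tests flag planted shifts and mark degenerate input", {
  # identical case/control tables: zero-variance marker
  ids <- c(sprintf("case_%d", 1:5), sprintf("ctrl_%d", 1:5))
  pw <- matrix(rep(runif(5 * 2), 2), 10, 2, byrow = FALSE)
  pw <- rbind(pw[1:5, ], pw[1:5, ])
  dimnames(pw) <- list(ids, c("PWY001", "PWY002"))
  cohort <- make_cohort(sprintf("case_%d", 1:5), sprintf("ctrl_%d", 1:5))
  res <- focal_pathway_paired_test(pw, cohort, list(acetate = c("PWY001", "PWY002")))
  expect_true(is.na(res$p_value))
  expect_match(res$note, "undefined")
  # planted +20% acetate shift in cases, full study scale, no other effects
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_controls = 365, effect_blocks = NULL, seed = seed)
    s <- simulate_study(cfg)
    grp <- attr(s$abundance, "group")
    acetate <- s$focal_groups$acetate
    pwt <- s$pathways
    pwt[grp == "case", acetate] <- pwt[grp == "case", acetate] * 1.2
    cohort <- make_cohort(rownames(pwt)[grp == "case"],
                          rownames(pwt)[grp == "control"])
    res <- focal_pathway_paired_test(pwt, cohort, s$focal_groups["acetate"])
    hits <- hits + (res$p_value < 0.05 && res$mean_diff > 0)
  }
  expect_gte(hits, 18)
})

test_that("focal paired test is calibrated under no shift", {
  set.seed(83)
  rejections <- 0L
  n_sims <- 1000L
  ids <- c(sprintf("case_%d", 1:30), sprintf("ctrl_%d", 1:30))
  cohort <- make_cohort(ids[1:30], ids[31:60])
  for (i in seq_len(n_sims)) {
    pw <- matrix(exp(rnorm(60 * 2)), 60, 2,
                 dimnames = list(ids, c("PWY001", "PWY002")))
    res <- focal_pathway_paired_test(pw, cohort,
                                     list(acetate = c("PWY001", "PWY002")))
    rejections <- rejections + (res$p_value < 0.05)
  }
  expect_gte(rejections / n_sims, 0.03)
  expect_lte(rejections / n_sims, 0.07)
})

test_that("pairs with missing members are dropped with a warning", {
  ids <- c(sprintf("case_%d", 1:4), sprintf("ctrl_%d", 1:4))
  pw <- matrix(runif(8), 8, 1, dimnames = list(ids, "PWY001"))
  pw <- pw[1:7, , drop = FALSE]  # drop ctrl_4
  cohort <- make_cohort(sprintf("case_%d", 1:4), sprintf("ctrl_%d", 1:4))
  expect_warning(
    res <- focal_pathway_paired_test(pw, cohort, list(f = "PWY001")),
    "dropped")
  expect_equal(res$n_pairs, 3L)
})
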