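rel_table <- function(m) {
  m <- sweep(m, 2, colSums(m), "/")
  genus_from_matrix(m, "relative")
}

test_that("prevalence filter keeps genera present in at least min_prevalence samples", {
  m <- rbind(a = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
             b = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
             c = rep(1, 10))
  colnames(m) <- paste0("S", 1:10)
  gt <- rel_table(m)
  expect_setequal(prevalence_filter(gt, 5)$genus, c("b", "c"))   # 4 out, 5 in
  expect_identical(prevalence_filter(gt, 0)$genus, gt$genus)
  expect_true("c" %in% prevalence_filter(gt, 10)$genus)
})

test_that("Spearman matrix uses average ranks and flags constant genera", {
  m <- rbind(x = c(1, 2, 2, 4), y = c(1, 3, 3, 5), z = c(4, 3, 2, 1),
             w = c(1, 2, 3, 4), k = c(2, 2, 2, 2))
  colnames(m) <- paste0("S", 1:4)
  rho <- spearman_matrix(m)
  expect_equal(rho["x", "x"], 1)
  expect_equal(rho["x", "y"], 1)            # identical rank vectors after ties
  expect_equal(rho["w", "z"], -1)           # strictly increasing vs decreasing
  expect_true(is.na(rho["x", "k"]))         # undefined for a constant genus
  expect_error(spearman_matrix(m[, 1:2]), "3 samples")
})

test_that("permutation P-values are calibrated at the null and sharp for monotone pairs", {
  # rho_obs = 0 on exchangeable data -> P well above significance
  m0 <- rbind(a = c(1, 2, 3, 4, 5, 6, 7, 8),
              b = c(4, 7, 1, 8, 2, 6, 3, 5))   # rho = -0.048
  rho0 <- spearman_matrix(m0)["a", "b"]
  p0 <- permutation_pvalues(m0, n_perm = 1000, seed = 1, renormalize = FALSE)
  expect_lt(abs(rho0), 0.3)
  expect_gte(p0$p["a", "b"], 0.5)
  # perfectly co-monotone pair inside a closed composition, n = 25
  withr::with_seed(4, {
    base <- sort(rlnorm(25))
    m <- rbind(p = base, q = base * 2, r = rlnorm(25), s = rlnorm(25), t = rlnorm(25))
    colnames(m) <- paste0("S", 1:25)
  })
  gt <- rel_table(m)
  pp <- permutation_pvalues(gt, n_perm = 1000, seed = 2)
  expect_equal(pp$rho["p", "q"], 1)
  expect_lte(pp$p["p", "q"], 0.005)          # at most tied with the null
  expect_error(permutation_pvalues(gt, n_perm = 0), "n_perm")
  # reproducible under a fixed seed
  pp2 <- permutation_pvalues(gt, n_perm = 200, seed = 9)
  pp3 <- permutation_pvalues(gt, n_perm = 200, seed = 9)
  expect_identical(pp2$p, pp3$p)
})

test_that("the edge rule is conjunctive in rho and P", {
  rho <- matrix(c(1, 0.6, 0.4, 0.6, 1, 0.7, 0.4, 0.7, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(c(NA, 0.01, 0.001, 0.01, NA, 0.2, 0.001, 0.2, NA), 3, 3,
              dimnames = dimnames(rho))
  ed <- build_edges(rho, p, network_config())
  expect_equal(nrow(ed), 1)                  # only a-b: rho .6 & p .01
  expect_equal(ed$genus_a, "a")
  expect_equal(ed$genus_b, "b")
  # absolute mode admits strong negative correlations
  rho["a", "c"] <- rho["c", "a"] <- -0.8
  ed2 <- build_edges(rho, p, network_config(mode = "absolute"))
  expect_true(any(ed2$genus_a == "a" & ed2$genus_b == "c"))
})

test_that("season-driven edges are removed, season-free edges retained", {
  withr::with_seed(6, {
    season <- rep(c("winter", "summer"), length.out = 24)
    w <- season == "winter"
    # u, v: independent within season, jointly elevated in winter
    u <- exp(rnorm(24, 0, 0.4) + 2.5 * w)
    v <- exp(rnorm(24, 0, 0.4) + 2.5 * w)
    # p, q: co-monotone regardless of season
    base <- rlnorm(24)
    m <- rbind(u = u, v = v, p = base, q = base^1.2,
               r = rlnorm(24), s = rlnorm(24), t = rlnorm(24))
    colnames(m) <- paste0("S", 1:24)
  })
  gt <- rel_table(m)
  meta <- tibble::tibble(sample_id = colnames(m), group = "control",
                         season = season, gc_treatment = FALSE,
                         conc_run1 = 1, conc_run2 = 1, conc_run3 = 1)
  cfg <- network_config(seed = 3, n_perm = 1000)
  pp <- permutation_pvalues(gt, n_perm = 1000, seed = 3)
  ed <- build_edges(pp$rho, pp$p, cfg)
  expect_true(any(ed$genus_a == "u" & ed$genus_b == "v"))
  expect_true(any(ed$genus_a == "p" & ed$genus_b == "q"))
  ed2 <- season_robustness_filter(ed, gt, meta, cfg)
  expect_false(ed2$robust[ed2$genus_a == "u" & ed2$genus_b == "v"])
  expect_true(ed2$robust[ed2$genus_a == "p" & ed2$genus_b == "q"])
  # empty edge set passes through
  empty <- season_robustness_filter(ed[0, ], gt, meta, cfg)
  expect_equal(nrow(empty), 0)
  expect_true("robust" %in% names(empty))
})

test_that("connected components define communities with a reporting size cutoff", {
  ed <- tibble::tibble(genus_a = c("A", "B", "D"), genus_b = c("B", "C", "E"))
  comm <- network_communities(ed, 3)
  big <- comm$genus[comm$reported]
  expect_setequal(big, c("A", "B", "C"))
  small <- comm[comm$genus %in% c("D", "E"), ]
  expect_true(all(!small$reported))          # kept in data, flagged unreported
  expect_equal(nrow(network_communities(ed[0, ], 3)), 0)
  k4 <- t(utils::combn(c("w", "x", "y", "z"), 2))
  comm4 <- network_communities(tibble::tibble(genus_a = k4[, 1], genus_b = k4[, 2]), 3)
  expect_equal(unique(comm4$community_size), 4)
})

test_that("node association scores sign severe- vs mild/control-enrichment", {
  m <- rbind(eq = rep(1, 6), sev = c(2, 2, 2, 0, 0, 0), ctl = c(0, 0, 0, 2, 2, 2))
  colnames(m) <- paste0("S", 1:6)
  gt <- rel_table(m)
  meta <- tibble::tibble(sample_id = colnames(m),
                         group = rep(c("severe", "control"), each = 3),
                         season = "winter", gc_treatment = FALSE,
                         conc_run1 = 1, conc_run2 = 1, conc_run3 = 1)
  assoc <- node_association(gt, meta)
  expect_equal(unname(assoc$association[assoc$genus == "eq"]), 0)
  expect_gt(assoc$association[assoc$genus == "sev"], 0)
  expect_lt(assoc$association[assoc$genus == "ctl"], 0)
})

test_that("planted severe-enriched genera score positive across seeds", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_dataset(sim_config(seed = 300 + s, n_contaminant_otus = 0L,
                                     n_season_affected = 0L))
    g <- suppressMessages(aggregate_genus(d$counts))
    assoc <- node_association(to_relative(g), d$metadata)
    sev <- names(d$truth$differential_genera)[d$truth$differential_genera == "severe"]
    mean(assoc$association[assoc$genus %in% sev] > 0)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("heatmap data orders genera by community then degree", {
  withr::with_seed(7, {
    f1 <- sort(rlnorm(20)); f2 <- rev(sort(rlnorm(20)))
    m <- rbind(a1 = f1 * exp(rnorm(20, 0, .1)), a2 = f1 * exp(rnorm(20, 0, .1)),
               a3 = f1 * exp(rnorm(20, 0, .1)),
               b1 = f2 * exp(rnorm(20, 0, .1)), b2 = f2 * exp(rnorm(20, 0, .1)),
               b3 = f2 * exp(rnorm(20, 0, .1)))
    colnames(m) <- paste0("S", 1:20)
  })
  gt <- rel_table(m)
  meta <- tibble::tibble(sample_id = colnames(m),
                         group = rep(c("severe", "control"), 10),
                         season = rep(c("winter", "summer"), each = 10),
                         gc_treatment = FALSE, conc_run1 = 1, conc_run2 = 1,
                         conc_run3 = 1)
  net <- cooccurrence_network(gt, meta, network_config(seed = 1, n_perm = 200,
                                                       min_prevalence = 0L))
  hm <- community_heatmap_data(net)
  ord_comm <- hm$bands$community
  expect_true(all(diff(ord_comm) >= 0))      # contiguous community blocks
  expect_setequal(substr(hm$bands$genus[ord_comm == ord_comm[1]], 1, 1),
                  substr(hm$bands$genus[1], 1, 1))  # blocks stay together
  p <- ggplot2::autoplot(net)
  expect_s3_class(p, "ggplot")
})

test_that("the assembled network object is internally consistent", {
  d <- simulate_dataset(sim_config(seed = 31, n_contaminant_otus = 0L,
                                   n_season_affected = 0L))
  g <- to_genus_counts(d$counts, seed = 31)
  net <- cooccurrence_network(to_relative(g), d$metadata,
                              network_config(seed = 31, n_perm = 300))
  # every edge satisfies the rule and touches only prevalence-passing genera
  expect_true(all(net$edges$rho >= 0.5 & net$edges$p < 0.05))
  expect_true(all(c(net$edges$genus_a, net$edges$genus_b) %in% net$nodes$genus))
  # communities partition exactly the robust-edge-incident genera
  incident <- unique(c(net$edges$genus_a[net$edges$robust],
                       net$edges$genus_b[net$edges$robust]))
  expect_setequal(net$communities$genus, incident)
  gl <- generics::glance(net)
  expect_equal(gl$n_edges_robust, sum(net$edges$robust))
  expect_identical(generics::tidy(net), net$edges)
  # deterministic under the config seed
  net2 <- cooccurrence_network(to_relative(g), d$metadata,
                               network_config(seed = 31, n_perm = 300))
  expect_identical(net$edges, net2$edges)
})
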