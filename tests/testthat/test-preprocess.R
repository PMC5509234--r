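test_that("an OTU inversely proportional to concentration is flagged, others are not", {
  conc <- c(1, 2, 3, 4, 5, 6, 8, 10, 12, 15, 20, 24)
  contam <- 240 / conc                      # relative abundance exactly prop. 1/conc
  benign <- 10 * conc                       # positively proportional: sign rule
  flat <- rep(50, 12)                       # constant relative abundance
  rest <- 1000 - contam - benign - flat
  m <- rbind(contam, benign, flat, rest)
  counts <- toy_counts(m)
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:12), group = "control",
                         season = "winter", gc_treatment = FALSE,
                         conc_run1 = conc, conc_run2 = conc, conc_run3 = conc)
  res <- suppressMessages(filter_contaminants(counts, meta))
  expect_true(res$report$flagged[1])        # rho = -1, P << 0.05
  expect_equal(unname(res$report$rho_run1[1]), -1)
  expect_false(res$report$flagged[2])       # positive correlation never flagged
  expect_false(res$report$flagged[3])       # undefined rho never flagged
  expect_equal(unname(res$report$rho_run1[2]), 1)
  # reads_removed equals the count mass of flagged OTUs
  expect_equal(res$reads_removed, sum(contam))
  expect_false("OTU01" %in% res$counts$otu_id)
})

test_that("contamination screen needs 4 samples and warns on constant concentration", {
  m <- matrix(5, 3, 3)
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:3), group = "control",
                         season = "winter", gc_treatment = FALSE,
                         conc_run1 = 1:3, conc_run2 = 1:3, conc_run3 = 1:3)
  expect_error(filter_contaminants(toy_counts(m), meta), "4 samples")
  m2 <- matrix(rpois(48, 20), 4, 12)
  meta2 <- tibble::tibble(sample_id = sprintf("S%02d", 1:12), group = "control",
                          season = "winter", gc_treatment = FALSE,
                          conc_run1 = rep(2, 12), conc_run2 = 1:12, conc_run3 = 1:12)
  expect_warning(suppressMessages(filter_contaminants(toy_counts(m2), meta2)),
                 "constant")
})

test_that("low-depth samples are discarded at the stated boundary", {
  m <- cbind(S1 = c(400, 299), S2 = c(350, 350), S3 = c(500, 4289))
  counts <- toy_counts(m)
  kept <- suppressMessages(discard_low_depth(counts, 700))
  expect_equal(otu_sample_ids(kept), c("S2", "S3"))  # 699 dropped, 700 kept
  # depths {500, 722, 4789} with min 700 -> 2 remain
  m2 <- cbind(A = c(250, 250), B = c(361, 361), C = c(2389, 2400))
  expect_length(otu_sample_ids(suppressMessages(discard_low_depth(toy_counts(m2), 700))), 2)
  # all deep -> identity; all shallow -> error
  expect_identical(discard_low_depth(counts, 100), counts)
  expect_error(discard_low_depth(counts, 10000), "all samples")
})

test_that("rarefaction yields exact target depth and preserves already-exact columns", {
  d <- simulate_dataset(sim_config(seed = 1))
  deep <- suppressMessages(discard_low_depth(d$counts, 722))
  r <- rarefy_counts(deep, 722, seed = 42)
  expect_true(all(colSums(otu_matrix(r)) == 722))
  expect_identical(r$otu_id, deep$otu_id)   # zero rows retained, ids stable
  # a column already at depth is untouched
  m <- cbind(S1 = c(300, 422), S2 = c(500, 500))
  r2 <- rarefy_counts(toy_counts(m), 722, seed = 1)
  expect_equal(unname(otu_matrix(r2)[, "S1"]), c(300, 422))
  # reproducible under a fixed seed
  expect_identical(rarefy_counts(deep, 722, seed = 9), rarefy_counts(deep, 722, seed = 9))
  expect_error(rarefy_counts(toy_counts(m), 1001, seed = 1), "S1")
})

test_that("rarefied counts follow the hypergeometric mean", {
  # [600, 400] reads rarefied to 500: E[OTU1] = 300, SD = sqrt(500*.6*.4*500/999)
  m <- cbind(S1 = c(600, 400))
  means <- vapply(1:1000, function(s) {
    otu_matrix(rarefy_counts(toy_counts(m), 500, seed = s))[1, 1]
  }, numeric(1))
  se <- sqrt(500 * 0.6 * 0.4 * (1000 - 500) / 999) / sqrt(1000)
  expect_lt(abs(mean(means) - 300), 3 * se)
})

test_that("rarefy-then-aggregate matches aggregate-then-rarefy in mean", {
  m <- cbind(S1 = c(120, 80, 60, 90, 50), S2 = c(40, 160, 90, 70, 40))
  tax <- sprintf("k__B;g__%s", c("A", "A", "A", "B", "B"))
  counts <- toy_counts(m, taxonomy = tax)
  a <- vapply(1:300, function(s) {
    genus_matrix(suppressMessages(aggregate_genus(rarefy_counts(counts, 200, seed = s))))[1, 1]
  }, numeric(1))
  agg <- suppressMessages(aggregate_genus(counts))
  gm <- genus_matrix(agg)
  b <- vapply(301:600, function(s) {
    g <- toy_counts(gm, taxonomy = sprintf("k__B;g__%s", rownames(gm)))
    otu_matrix(rarefy_counts(g, 200, seed = s))[1, 1]
  }, numeric(1))
  # both are hypergeometric draws of genus A (260 of 400 reads) at depth 200
  expect_lt(abs(mean(a) - mean(b)), 4 * sqrt(var(a) / 300 + var(b) / 300))
})

test_that("genus aggregation sums classified OTUs and drops unclassified ones", {
  m <- cbind(S1 = c(3, 1, 7), S2 = c(4, 0, 2))
  tax <- c("k__B;g__G", "k__B;g__G", "k__B;f__F")   # third has no genus rank
  g <- suppressMessages(aggregate_genus(toy_counts(m, taxonomy = tax)))
  expect_equal(nrow(g), 1)
  expect_equal(unname(genus_matrix(g)["G", ]), c(4, 4))
  # all classified: row count = number of genera, mass conserved
  d <- simulate_dataset(sim_config(seed = 2, n_contaminant_otus = 0L,
                                   otus_per_genus = 3L))
  g2 <- suppressMessages(aggregate_genus(d$counts))
  expect_equal(nrow(g2), 40)
  expect_equal(sum(genus_matrix(g2)), sum(otu_matrix(d$counts)))
})

test_that("rare-genus filter uses the grand-total read fraction", {
  m <- cbind(S1 = c(1, 2, 9000), S2 = c(0, 0, 9047))  # grand total 18050
  tax <- sprintf("k__B;g__%s", c("A", "B", "C"))
  g <- suppressMessages(aggregate_genus(toy_counts(m, taxonomy = tax)))
  kept <- suppressMessages(filter_rare_genera(g, 1e-4))
  expect_setequal(kept$genus, c("B", "C"))  # 1/18050 < 1e-4 <= 2/18050
  expect_identical(filter_rare_genera(g, 0)$genus, g$genus)
  one <- suppressMessages(aggregate_genus(toy_counts(
    cbind(S1 = 5, S2 = 1), taxonomy = "k__B;g__Solo", otu_id = "O1")))
  expect_equal(filter_rare_genera(one)$genus, "Solo")
})

test_that("abundance transforms have the declared geometry", {
  m <- cbind(S1 = c(3, 1), S2 = c(4, 1), S3 = c(0, 0))
  g <- genus_table(tibble::tibble(genus = c("A", "B"),
                                  S1 = m[, 1], S2 = m[, 2], S3 = m[, 3]))
  rel <- to_relative(g)
  expect_equal(unname(genus_matrix(rel)[, "S1"]), c(0.75, 0.25))
  expect_equal(colSums(genus_matrix(rel))[1:2], c(S1 = 1, S2 = 1))
  expect_equal(unname(genus_matrix(rel)[, "S3"]), c(0, 0))  # all-zero stays zero
  hel <- hellinger_transform(g)
  expect_equal(unname(genus_matrix(hel)[, "S2"]), c(sqrt(0.8), sqrt(0.2)))
  expect_equal(unname(sqrt(colSums(genus_matrix(hel)^2)))[1:2], c(1, 1))
  expect_equal(genus_transform(rel), "relative")
  expect_equal(genus_transform(hel), "hellinger")
})

test_that("stage state flags forbid out-of-order pipelines", {
  g <- genus_table(tibble::tibble(genus = "A", S1 = 5, S2 = 3))
  rel <- to_relative(g)
  expect_error(to_relative(rel), class = "otunet_state_error")
  expect_error(filter_rare_genera(rel), class = "otunet_state_error")
  expect_error(hellinger_transform(hellinger_transform(g)),
               class = "otunet_state_error")
  expect_error(prevalence_filter(g), class = "otunet_state_error")
})

test_that("season correction subtracts the per-season median", {
  x <- c(1, 2, 3, 10, 20, 30)
  season <- c("w", "w", "w", "s", "s", "s")
  expect_equal(season_correct(x, season), c(-1, 0, 1, -10, 0, 10))
  expect_equal(median(season_correct(1:7, rep("w", 7))), 0)
  expect_equal(season_correct(rep(4, 5), c("w", "w", "s", "s", "s")), rep(0, 5))
  expect_error(season_correct(1:3, c("w", "s")), "lengths differ")
})
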