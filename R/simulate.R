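#' Configuration for the synthetic lung-microbiome generator
#'
#' Parameterizes a genus-level compositional count simulator whose planted
#' structure matches what the downstream pipeline is designed to detect:
#' blocks of positively co-varying genera (a shared log-scale latent factor
#' per block), block-level disease-group effects (severe vs mild+control),
#' seasonal processing-batch shifts on a subset of genera, reagent
#' contaminant OTUs whose relative abundance falls with per-sample amplicon
#' concentration, and variable sequencing depth.
#'
#' Defaults emulate a small bronchoscopy cohort: 25 samples (12 severe
#' subtype, 4 mild subtype, 9 controls), read depths between 722 and 4789,
#' four co-occurring genus blocks of sizes 6/6/5/5.
#'
#' @param n_samples_per_group Named integer vector `c(severe=, mild=, control=)`.
#' @param n_genera Number of genuine (non-contaminant) genera.
#' @param block_sizes Integer vector, one entry per planted block;
#'   `sum(block_sizes) <= n_genera`.
#' @param n_blocks Number of blocks; defaults to `length(block_sizes)`.
#' @param within_block_latent_sd SD of the shared per-block latent factor on
#'   the natural-log abundance scale. Association strength within a block is
#'   governed by its ratio to `genus_noise_sd`.
#' @param genus_noise_sd SD of independent per-genus, per-sample log-scale noise.
#' @param baseline_sd SD of per-genus baseline log abundances (controls how
#'   uneven the average community is).
#' @param block_group_effect Numeric vector, one signed log-fold effect per
#'   block, added to block members in severe-subtype samples.
#' @param n_contaminant_otus Number of planted contaminant OTUs.
#' @param contaminant_strength Positive slope of log abundance vs
#'   log concentration; the negative sign is applied internally, so expected
#'   contaminant relative abundance is proportional to
#'   `concentration^(-contaminant_strength)`.
#' @param n_season_affected Number of genera receiving the seasonal shift.
#'   Drawn from genera outside the blocks, so planted co-occurrence and
#'   planted seasonal artefacts stay disjoint.
#' @param season_shift Signed log-scale shift added to season-affected genera
#'   in winter-processed samples.
#' @param depth_range Integer pair; per-sample read depth is uniform on this
#'   range.
#' @param otus_per_genus How many OTUs each genus's reads are split across.
#' @param seed Master seed; a fixed seed makes the generated dataset
#'   bit-identical across calls.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples_per_group = c(severe = 12, mild = 4, control = 9),
                       n_genera = 40L,
                       block_sizes = c(6L, 6L, 5L, 5L),
                       n_blocks = length(block_sizes),
                       within_block_latent_sd = 1.8,
                       genus_noise_sd = 0.5,
                       baseline_sd = 1.0,
                       block_group_effect = NULL,
                       n_contaminant_otus = 10L,
                       contaminant_strength = 2.0,
                       n_season_affected = 6L,
                       season_shift = 2.0,
                       depth_range = c(722L, 4789L),
                       otus_per_genus = 1L,
                       seed = 1L) {
  if (is.null(block_group_effect)) {
    # one severe-enriched block, two mild/control-enriched, one neutral
    block_group_effect <- head(c(1.5, -1.5, -1.5, 0), n_blocks)
    if (n_blocks > 4) block_group_effect <- c(block_group_effect, rep(0, n_blocks - 4))
  }
  cfg <- list(
    n_samples_per_group = n_samples_per_group,
    n_genera = as.integer(n_genera),
    block_sizes = as.integer(block_sizes),
    n_blocks = as.integer(n_blocks),
    within_block_latent_sd = within_block_latent_sd,
    genus_noise_sd = genus_noise_sd,
    baseline_sd = baseline_sd,
    block_group_effect = as.numeric(block_group_effect),
    n_contaminant_otus = as.integer(n_contaminant_otus),
    contaminant_strength = contaminant_strength,
    n_season_affected = as.integer(n_season_affected),
    season_shift = season_shift,
    depth_range = as.integer(depth_range),
    otus_per_genus = as.integer(otus_per_genus),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "otunet_config_error")
  }
  g <- cfg$n_samples_per_group
  if (is.null(names(g)) || !setequal(names(g), c("severe", "mild", "control")) ||
      any(g < 1)) {
    bad("n_samples_per_group", "must be a named vector severe/mild/control, all >= 1")
  }
  stopifnot_scalar_count(cfg$n_genera, "n_genera")
  if (length(cfg$block_sizes) != cfg$n_blocks) {
    bad("block_sizes", "length must equal n_blocks")
  }
  if (any(cfg$block_sizes < 1)) bad("block_sizes", "entries must be positive")
  if (sum(cfg$block_sizes) > cfg$n_genera) {
    bad("block_sizes", "sum(block_sizes) must be <= n_genera")
  }
  if (length(cfg$block_group_effect) != cfg$n_blocks) {
    bad("block_group_effect", "one effect per block required")
  }
  if (cfg$within_block_latent_sd <= 0) bad("within_block_latent_sd", "must be positive")
  if (cfg$genus_noise_sd <= 0) bad("genus_noise_sd", "must be positive")
  if (cfg$n_contaminant_otus < 0) bad("n_contaminant_otus", "must be >= 0")
  if (cfg$contaminant_strength <= 0) bad("contaminant_strength", "must be positive")
  if (cfg$n_season_affected < 0) bad("n_season_affected", "must be >= 0")
  if (cfg$n_season_affected > cfg$n_genera - sum(cfg$block_sizes)) {
    bad("n_season_affected", "must fit among non-block genera")
  }
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] < 1 ||
      cfg$depth_range[1] > cfg$depth_range[2]) {
    bad("depth_range", "need 1 <= lower <= upper")
  }
  stopifnot_scalar_count(cfg$otus_per_genus, "otus_per_genus")
  invisible(cfg)
}

sim_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")

#' Simulate an OTU count table with planted structure
#'
#' Draws genus log abundances as baseline + shared block latent factor +
#' severe-group effect (block members) + winter season shift (season-affected
#' genera) + independent noise, closes them to a composition per sample, and
#' samples reads by multinomial draws at a per-sample depth uniform on
#' `depth_range`, so column sums equal the drawn depths exactly (the table
#' looks like a real, closed, variable-depth library). Contaminant OTUs enter
#' the composition with expected relative abundance proportional to
#' `concentration^(-contaminant_strength)`, concentration being drawn
#' log-normally per sample and recorded in the metadata (the same value for
#' all three library runs). Each genus's reads are split uniformly across
#' `otus_per_genus` OTUs.
#'
#' @param config A [sim_config()].
#' @return A list with class `sim_dataset`:
#' \describe{
#'   \item{counts}{OTU count tibble (`otu_id`, `taxonomy`, sample columns).}
#'   \item{metadata}{Tibble `sample_id`, `group`, `season`, `gc_treatment`,
#'     `conc_run1..3`.}
#'   \item{truth}{[synthetic_truth] ground truth: block memberships,
#'     contaminant OTU ids, differential genera with direction, season-affected
#'     genera.}
#' }
#' @examples
#' d <- simulate_dataset(sim_config(seed = 42))
#' dim(d$counts)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  grp_n <- cfg$n_samples_per_group[c("severe", "mild", "control")]
  group <- rep(names(grp_n), grp_n)
  n <- length(group)
  sample_id <- sprintf("S%02d", seq_len(n))
  # alternate seasons within each group so season and group are not confounded
  season <- unlist(lapply(grp_n, function(k) rep_len(c("winter", "summer"), k)),
                   use.names = FALSE)
  gc_treatment <- ifelse(group == "control", FALSE,
                         rep_len(c(TRUE, FALSE), n))

  conc <- rlnorm(n, meanlog = log(10), sdlog = 0.6)

  G <- cfg$n_genera
  genus_ids <- sprintf("Genus%03d", seq_len(G))
  phylum <- rep_len(sim_phyla, G)
  block_of <- rep(NA_integer_, G)
  if (cfg$n_blocks > 0) {
    block_of[seq_len(sum(cfg$block_sizes))] <- rep(seq_len(cfg$n_blocks), cfg$block_sizes)
  }
  nonblock <- which(is.na(block_of))
  season_affected_idx <- if (cfg$n_season_affected > 0) {
    sort(sample(nonblock, cfg$n_season_affected))
  } else integer(0)

  baseline <- rnorm(G, 0, cfg$baseline_sd)
  eta <- matrix(baseline, G, n)
  member <- !is.na(block_of)
  if (cfg$n_blocks > 0) {
    # block latent factors: Gaussian scores orthogonalized against the
    # intercept and each other, scaled to sd = within_block_latent_sd. The
    # planted truth is that blocks are distinct communities; at ~25 samples a
    # raw independent draw would regularly show chance alignment between two
    # factors, contradicting the truth the dataset is meant to carry.
    raw <- matrix(rnorm(n * cfg$n_blocks), n, cfg$n_blocks)
    qm <- qr.Q(qr(cbind(1, raw)))[, -1, drop = FALSE]
    z <- t(qm) * cfg$within_block_latent_sd * sqrt(n - 1)
    eta[member, ] <- eta[member, ] + z[block_of[member], ]
    sev <- group == "severe"
    eta[member, sev] <- eta[member, sev] +
      cfg$block_group_effect[block_of[member]]
  }
  if (length(season_affected_idx)) {
    wint <- season == "winter"
    eta[season_affected_idx, wint] <- eta[season_affected_idx, wint] + cfg$season_shift
  }
  # planted genera (block members, season-affected) carry small residual
  # noise: their structured variation comes from the shared factor or the
  # season indicator. Unplanted background genera get independent
  # overdispersion of matching total sd, so block membership shapes the
  # correlation structure rather than the per-genus marginal variance.
  planted <- member | seq_len(G) %in% season_affected_idx
  noise_sd <- ifelse(planted, cfg$genus_noise_sd,
                     sqrt(cfg$within_block_latent_sd^2 + cfg$genus_noise_sd^2))
  eta <- eta + matrix(rnorm(G * n), G, n) * noise_sd

  C <- cfg$n_contaminant_otus
  if (C > 0) {
    b_c <- rnorm(C, 0, cfg$baseline_sd) + cfg$contaminant_strength * mean(log(conc))
    eta_c <- outer(rep(1, C), -cfg$contaminant_strength * log(conc)) + b_c +
      matrix(rnorm(C * n, 0, cfg$genus_noise_sd), C, n)
    eta <- rbind(eta, eta_c)
  }

  # closure + multinomial sampling at the drawn depth
  p <- apply(eta, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
  depth <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n, replace = TRUE)
  unit_counts <- vapply(seq_len(n), function(s) rmultinom(1, depth[s], p[, s])[, 1],
                        numeric(G + C))

  genus_counts <- unit_counts[seq_len(G), , drop = FALSE]
  contam_counts <- if (C > 0) unit_counts[G + seq_len(C), , drop = FALSE] else NULL

  k <- cfg$otus_per_genus
  if (k > 1) {
    otu_counts <- matrix(0, G * k, n)
    for (g in seq_len(G)) {
      for (s in seq_len(n)) {
        tot <- genus_counts[g, s]
        if (tot > 0) {
          otu_counts[(g - 1L) * k + seq_len(k), s] <- rmultinom(1, tot, rep(1 / k, k))[, 1]
        }
      }
    }
  } else {
    otu_counts <- genus_counts
  }
  otu_id <- sprintf("OTU%04d", seq_len(G * k))
  otu_genus <- rep(seq_len(G), each = k)
  taxonomy <- sprintf("k__Bacteria;p__%s;f__Family%03d;g__%s",
                      phylum[otu_genus], otu_genus, genus_ids[otu_genus])

  if (C > 0) {
    contam_genus <- sprintf("Contam%02d", seq_len(C))
    otu_id <- c(otu_id, sprintf("OTU_C%02d", seq_len(C)))
    taxonomy <- c(taxonomy,
                  sprintf("k__Bacteria;p__Proteobacteria;f__FamilyC%02d;g__%s",
                          seq_len(C), contam_genus))
    otu_counts <- rbind(otu_counts, contam_counts)
  }

  counts <- tibble::as_tibble(cbind(
    tibble::tibble(otu_id = otu_id, taxonomy = taxonomy),
    tibble::as_tibble(`colnames<-`(otu_counts, sample_id))
  ))

  metadata <- tibble::tibble(
    sample_id = sample_id, group = group, season = season,
    gc_treatment = gc_treatment,
    conc_run1 = conc, conc_run2 = conc, conc_run3 = conc
  )

  diff_idx <- which(!is.na(block_of) & cfg$block_group_effect[block_of] != 0)
  truth <- synthetic_truth(
    block_membership = setNames(block_of[!is.na(block_of)], genus_ids[!is.na(block_of)]),
    contaminant_otus = if (C > 0) sprintf("OTU_C%02d", seq_len(C)) else character(0),
    differential_genera = setNames(
      ifelse(cfg$block_group_effect[block_of[diff_idx]] > 0, "severe", "mild_control"),
      genus_ids[diff_idx]),
    season_affected = genus_ids[season_affected_idx]
  )

  structure(list(counts = counts, metadata = metadata, truth = truth),
            class = "sim_dataset")
}

#' Ground truth of a simulated dataset
#'
#' @param block_membership Named integer vector, genus -> block id.
#' @param contaminant_otus Character vector of planted contaminant OTU ids.
#' @param differential_genera Named character vector, genus -> `"severe"` or
#'   `"mild_control"` (which side the genus is enriched in).
#' @param season_affected Character vector of genera carrying the season shift.
#' @return A `synthetic_truth` list with canonically sorted components.
#' @export
synthetic_truth <- function(block_membership = setNames(integer(0), character(0)),
                            contaminant_otus = character(0),
                            differential_genera = setNames(character(0), character(0)),
                            season_affected = character(0)) {
  structure(list(
    block_membership = block_membership[order(names(block_membership))],
    contaminant_otus = sort(unique(as.character(contaminant_otus))),
    differential_genera = differential_genera[order(names(differential_genera))],
    season_affected = sort(unique(as.character(season_affected)))
  ), class = "synthetic_truth")
}

#' Write / read ground truth as JSON
#'
#' `read_truth(write_truth(t, path))` reproduces `t` exactly.
#'
#' @param truth A [synthetic_truth()].
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` a
#'   `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(list(
    block_membership = as.list(truth$block_membership),
    contaminant_otus = truth$contaminant_otus,
    differential_genera = as.list(truth$differential_genera),
    season_affected = truth$season_affected
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path)
  synthetic_truth(
    block_membership = setNames(vapply(x$block_membership, as.integer, 1L),
                                names(x$block_membership)),
    contaminant_otus = unlist(x$contaminant_otus) %||% character(0),
    differential_genera = setNames(vapply(x$differential_genera, as.character, ""),
                                   names(x$differential_genera)),
    season_affected = unlist(x$season_affected) %||% character(0)
  )
}
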