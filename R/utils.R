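#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats cor cor.test median p.adjust rlnorm rmultinom rnorm
#'   setNames wilcox.test cmdscale
#' @importFrom utils head read.delim write.table
NULL

# Run `code` under `seed` if given, leaving the caller's RNG untouched;
# otherwise use the current RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "otunet_config_error")
  }
}

# sample column order helper: metadata rows aligned to table sample columns
align_meta <- function(meta, sample_ids) {
  if (!all(sample_ids %in% meta$sample_id)) {
    missing <- setdiff(sample_ids, meta$sample_id)
    abort(sprintf("metadata missing sample(s): %s", paste(missing, collapse = ", ")),
          class = "otunet_data_error")
  }
  meta[match(sample_ids, meta$sample_id), , drop = FALSE]
}

#' Extract the count matrix from an OTU count tibble
#'
#' An OTU count table is a tibble with character columns `otu_id` and
#' `taxonomy` followed by one integer column per sample.
#'
#' @param counts OTU count tibble.
#' @return Integer matrix, OTUs in rows (named by `otu_id`), samples in
#'   columns.
#' @export
otu_matrix <- function(counts) {
  samp <- otu_sample_ids(counts)
  m <- as.matrix(counts[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$otu_id
  m
}

#' @rdname otu_matrix
#' @export
otu_sample_ids <- function(counts) {
  setdiff(names(counts), c("otu_id", "taxonomy"))
}

check_otu_table <- function(counts) {
  if (!all(c("otu_id", "taxonomy") %in% names(counts))) {
    abort("an OTU count table needs `otu_id` and `taxonomy` columns",
          class = "otunet_data_error")
  }
  if (anyDuplicated(counts$otu_id)) {
    abort("duplicate `otu_id` values", class = "otunet_data_error")
  }
  m <- otu_matrix(counts)
  if (any(m < 0)) abort("negative counts", class = "otunet_data_error")
  invisible(counts)
}
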