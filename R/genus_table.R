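#' Genus abundance tables
#'
#' A genus abundance table is a tibble with a character `genus` column
#' followed by one numeric column per sample, plus a `transform` attribute
#' recording its state: `"counts"` (raw summed reads), `"relative"`
#' (columns sum to one) or `"hellinger"` (square roots of relative
#' abundances; columns have unit Euclidean norm). Stage functions check the
#' state so the pipeline cannot be run out of order.
#'
#' @param tbl Tibble with `genus` plus sample columns.
#' @param transform One of `"counts"`, `"relative"`, `"hellinger"`.
#' @return A `genus_tbl`.
#' @export
genus_table <- function(tbl, transform = c("counts", "relative", "hellinger")) {
  transform <- match.arg(transform)
  if (!"genus" %in% names(tbl)) {
    abort("a genus table needs a `genus` column", class = "otunet_data_error")
  }
  if (anyDuplicated(tbl$genus)) {
    abort("duplicate genus ids", class = "otunet_data_error")
  }
  out <- tibble::as_tibble(tbl)
  attr(out, "transform") <- transform
  class(out) <- c("genus_tbl", class(tibble::tibble()))
  out
}

#' @rdname genus_table
#' @param x A `genus_tbl`.
#' @export
genus_transform <- function(x) {
  attr(x, "transform") %||% "counts"
}

#' @rdname genus_table
#' @export
genus_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "genus"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$genus
  m
}

#' @rdname genus_table
#' @export
genus_sample_ids <- function(x) setdiff(names(x), "genus")

# rebuild a genus_tbl from a matrix, keeping genus order
genus_from_matrix <- function(m, transform) {
  genus_table(
    tibble::as_tibble(cbind(tibble::tibble(genus = rownames(m)),
                            tibble::as_tibble(m))),
    transform = transform
  )
}

require_transform <- function(x, allowed, op) {
  tr <- genus_transform(x)
  if (!tr %in% allowed) {
    abort(sprintf("%s expects a table in state %s, got \"%s\" (pipeline run out of order?)",
                  op, paste(sprintf('"%s"', allowed), collapse = "/"), tr),
          class = "otunet_state_error")
  }
  invisible(x)
}

#' @export
print.genus_tbl <- function(x, ...) {
  cat(sprintf("# Genus abundance table (%d genera x %d samples, transform = %s)\n",
              nrow(x), length(genus_sample_ids(x)), genus_transform(x)))
  NextMethod()
}
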