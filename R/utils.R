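#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov fisher.test hclust as.dist cutree dist lm
#'   median p.adjust pnorm quantile rbinom rnbinom rnorm rpois runif sd var
#'   setNames wilcox.test prcomp coef
#' @importFrom utils read.delim write.table head
NULL

# Internal: stop with a classed condition so callers/tests can match on class.
sg_stop <- function(msg, class) {
  stop(structure(class = c(class, "solgrn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write a data frame as a TSV file
#'
#' Deterministic, unquoted, tab-separated output used for all tabular
#' artifacts so that fixed-seed runs are byte-identical.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Canonical gene-id generator: zero-padded so lexicographic == numeric order.
gene_ids <- function(n, prefix = "g") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}
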