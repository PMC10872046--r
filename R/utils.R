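#' Derive a stage-specific sub-seed from a master seed
#'
#' Randomized stages of the pipeline each draw their own seed from the master
#' seed and a stage label, so that inserting or reordering stages never
#' perturbs the random stream of the others.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. \code{"balance"}).
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  # modular mix kept in double precision, well below 2^53
  as.integer((abs(as.numeric(master)) * 48271 + h * 69621) %% 2147483646)
}

#' Write a data frame as tab-separated values
#'
#' All tabular outputs of the pipeline are TSV with a header row.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path input path.
#' @return a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# shared column-presence check with a precise error message
.require_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
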