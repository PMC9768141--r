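#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame split metadata metadata<-
#' @importFrom BiocGenerics start end width strand
#' @importFrom methods is as
#' @importFrom stats aov TukeyHSD rpois rnbinom runif setNames aggregate
#' @importFrom utils read.table write.table packageVersion
NULL

# Package-level logging: message() so suppressMessages() works; prefixed so
# pipeline logs are greppable.
rt_log <- function(..., level = "INFO") {
  message(sprintf("[readthroughr %s] %s", level, paste0(...)))
}

rt_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strand helper: TRUE for "-" inputs, errors on anything not +/-.
is_minus <- function(strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-', got: ", paste(unique(strand), collapse = ","))
  strand == "-"
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(name, " must be a single integer >= ", min)
  invisible(as.integer(x))
}

# Write a TSV the way every exporter in this package does (no quotes, no
# rownames, tab-separated, NA as "NA").
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "", ...)
}
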