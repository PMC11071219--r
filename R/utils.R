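#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats fisher.test p.adjust prcomp t.test kruskal.test cor
#'   median quantile rbinom rpois rnorm runif rlnorm setNames pt sd
#' @importFrom utils read.delim write.table head combn
NULL

# internal: stop with a sprintf-style message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check a scalar fraction lies in [lo, hi]
.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    .fail("`%s` must be a single number in [%g, %g]", name, lo, hi)
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .fail("`%s` must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# run expr under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# 0-based half-open intervals -> IRanges (1-based closed)
.ir <- function(start0, end0) IRanges::IRanges(start = start0 + 1L, end = end0)

# IRanges -> 0-based half-open data.frame
.from_ir <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# total width of the union of 0-based half-open intervals
.union_width <- function(start0, end0) {
  if (length(start0) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(.ir(start0, end0))))
}
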