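#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats prcomp rnbinom rpois rlnorm rgamma runif rnorm sd
#'   t.test wilcox.test ks.test setNames quantile var
#' @importFrom utils read.csv write.csv read.delim head
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so module sub-streams stay decoupled.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Log a pipeline stage
#'
#' Lightweight stage logger: records the stage name, key parameters and
#' input/output shapes as a single message. Suppress with
#' `options(pdniche.verbose = FALSE)`.
#'
#' @param stage character stage name.
#' @param ... named values appended as `name=value` pairs.
#' @return Invisibly, the formatted message.
#' @export
pd_log <- function(stage, ...) {
  vals <- list(...)
  txt <- if (length(vals)) {
    paste(names(vals), vapply(vals, function(v) paste(format(v), collapse = ","),
                              character(1)),
          sep = "=", collapse = " ")
  } else ""
  msg <- sprintf("[pdniche:%s] %s", stage, txt)
  if (isTRUE(getOption("pdniche.verbose", TRUE))) message(msg)
  invisible(msg)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of `score` for discriminating
#' `label == TRUE` from `label == FALSE`.
#'
#' @param score numeric vector.
#' @param label logical vector, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  stopifnot(length(score) == length(label), is.logical(label))
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("auroc: both classes must be present")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# row-wise log-sum-exp of a matrix, numerically stabilized
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

col_logsumexp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx))))
}
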