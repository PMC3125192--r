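#' @keywords internal
#' @importFrom stats median sd cor dist rlnorm rnorm runif pchisq pnorm
#'   setNames ave
#' @importFrom utils read.delim write.table modifyList combn head
#' @importFrom tools md5sum
#' @importFrom grDevices png dev.off colorRampPalette
#' @importFrom graphics image axis par
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the previous
#' RNG state afterwards, so that seeded operations (simulation, permutation)
#' do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Fast row medians without per-row apply(): one vectorised order() over the
# whole matrix, rows re-assembled in sorted order. Even-width rows take the
# mean of the central pair (6 patients make this matter).
row_medians <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n == 0L) return(numeric(0))
  if (k == 1L) return(as.numeric(m[, 1L]))
  if (anyNA(m)) {
    return(apply(m, 1L, stats::median, na.rm = FALSE))
  }
  s <- matrix(m[order(row(m), m)], nrow = n, byrow = TRUE)
  if (k %% 2L == 1L) {
    s[, (k + 1L) %/% 2L]
  } else {
    (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
  }
}

# 6-significant-digit fixed formatting used for all numeric TSV output.
format_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- ""
  out
}

TISSUES <- c("normal", "cancer")
PRIMINGS <- c("oligo_dT", "random")
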