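#' @importFrom rlang abort %||%
#' @importFrom stats binom.test cor fisher.test optim pnorm quantile rnorm
#'   runif setNames wilcox.test predict
#' @importFrom utils head
NULL

# The seven PBMC subtypes resolved by the surface-marker panel.
# "TCRgd+" denotes gamma-delta T cells (TCR gamma/delta surface receptor).
PBMC_SUBTYPES <- c("CD3+", "CD4+", "CD8a+", "CD14+", "CD19+", "CD56+", "TCRgd+")

#' PBMC subtype vocabulary
#'
#' The seven peripheral-blood mononuclear cell subtypes the assay resolves:
#' T cells (CD3+, CD4+, CD8a+, TCRgd+), monocytes (CD14+), B cells (CD19+)
#' and NK cells (CD56+).
#'
#' @return Character vector of the seven canonical subtype labels.
#' @export
pbmc_subtypes <- function() PBMC_SUBTYPES

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (global seed, stage name) to an integer seed below
#' 2^31, so adding a pipeline stage never perturbs the random streams of
#' earlier stages.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Rank-based all-pairs AUC (ties count 1/2); labels coerced to 0/1.
auc_rank <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute an AUC",
          class = "drc_error_domain")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stop_config <- function(msg) abort(msg, class = "drc_error_config")
stop_domain <- function(msg) abort(msg, class = "drc_error_domain")
stop_incomplete <- function(msg) abort(msg, class = "drc_error_incomplete")
stop_parse <- function(msg) abort(msg, class = "drc_error_parse")
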