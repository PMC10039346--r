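#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded generators never disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Epoch used for integer day arithmetic; all dates are stored as Date
# (integer days), printed as ISO-8601.
.ehr_epoch <- as.Date("1970-01-01")

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels. Used for
#' internal metric computation; model benchmarking cross-checks against
#' \pkg{pROC} in the test-suite.
#'
#' @param labels 0/1 or logical vector, 1 = positive class.
#' @param scores Numeric predicted scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), length(labels) == length(scores))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ICD-10 prefix matching
#'
#' A filter code matches a record code when it is a leading prefix aligned to
#' the 3-character block: "I63" matches "I63" and "I63.9" but not "I630"
#' interpreted as a different block only if the block structure disagrees.
#' Matching is on the plain leading prefix, which respects the 3-character
#' block because ICD-10 subcodes extend the block ("I63.9", "I639").
#'
#' @param codes Character vector of record codes.
#' @param prefixes Character vector of filter prefixes.
#' @return Logical vector: does each code match any prefix?
#' @export
icd10_prefix_match <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) {
    hit <- hit | startsWith(codes, p)
  }
  hit
}

# stable argmin: first index of the minimum
.which_min <- function(x) which.min(x)
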