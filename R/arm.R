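#' @name arm
#' @title Association-rule mining of extreme-value itemsets
#'
#' @description
#' Each person's latest sex/age-adjusted values are discretised into items
#' `CODE_LOW` (z < -1) / `CODE_HIGH` (z > 1); the resulting transactions are
#' mined for frequent itemsets with an FP-Growth implementation. Candidate
#' rules are those whose support among cases strictly exceeds their support
#' in every one of `n_iter` (default 20) random control samples of equal
#' size, and are scored by the observed/expected support ratio
#' (joint support over the product of marginal supports; 1 under
#' independence).
#'
#' Support fractions are computed over all transactions including empty
#' ones: persons without extreme values are informative denominators.
NULL

#' Discretise latest z-scores into transactions
#'
#' z > 1 yields `KEY_HIGH`, z < -1 yields `KEY_LOW` (strict inequalities;
#' a code contributes at most one item per person since the latest value is
#' unique). Persons without extreme values are retained as empty
#' transactions.
#'
#' @param latest_adjusted data.frame with columns `person_id`, `key`
#'   (analyte key) and `z`, one row per (person, key) — the latest adjusted
#'   observation.
#' @param persons Character vector of all person ids that define the
#'   transaction universe (defaults to those present in the input).
#' @return Named list of character item vectors, one per person (possibly
#'   empty).
#' @export
discretize_items <- function(latest_adjusted,
                             persons = unique(latest_adjusted$person_id)) {
  x <- latest_adjusted
  hi <- x$z > 1
  lo <- x$z < -1
  item <- character(nrow(x))
  item[hi] <- paste0(x$key[hi], "_HIGH")
  item[lo] <- paste0(x$key[lo], "_LOW")
  keep <- hi | lo
  tx <- split(item[keep], factor(x$person_id[keep], levels = persons))
  lapply(tx, function(v) sort(unique(v)))
}

# grow-able FP-tree builder: paths are integer item-rank vectors in
# decreasing-frequency order, counts their weights
.fp_build <- function(paths, counts, n_items) {
  cap <- 128L
  item <- integer(cap); cnt <- numeric(cap); parent <- integer(cap)
  child <- matrix(0L, nrow = cap, ncol = n_items)
  n_nodes <- 1L  # node 1 = root (item 0)
  header <- vector("list", n_items)
  for (p in seq_along(paths)) {
    path <- paths[[p]]
    w <- counts[p]
    cur <- 1L
    for (it in path) {
      nxt <- child[cur, it]
      if (nxt == 0L) {
        n_nodes <- n_nodes + 1L
        if (n_nodes > cap) {
          cap <- cap * 2L
          length(item) <- cap; length(cnt) <- cap; length(parent) <- cap
          item[is.na(item)] <- 0L; cnt[is.na(cnt)] <- 0; parent[is.na(parent)] <- 0L
          child <- rbind(child, matrix(0L, nrow = cap - nrow(child),
                                       ncol = n_items))
        }
        item[n_nodes] <- it
        cnt[n_nodes] <- 0
        parent[n_nodes] <- cur
        child[cur, it] <- n_nodes
        header[[it]] <- c(header[[it]], n_nodes)
        nxt <- n_nodes
      }
      cnt[nxt] <- cnt[nxt] + w
      cur <- nxt
    }
  }
  list(item = item[seq_len(n_nodes)], count = cnt[seq_len(n_nodes)],
       parent = parent[seq_len(n_nodes)], header = header)
}

# recursive FP-growth over a built tree; emits (itemset ranks, support) pairs
# through the accumulator environment
.fp_mine <- function(tree, suffix, minsup, max_size, n_items, acc) {
  for (it in rev(seq_len(n_items))) {
    nodes <- tree$header[[it]]
    if (is.null(nodes)) next
    support <- sum(tree$count[nodes])
    if (support < minsup) next
    newset <- c(it, suffix)
    acc$sets[[length(acc$sets) + 1L]] <- newset
    acc$counts[[length(acc$counts) + 1L]] <- support
    if (length(newset) >= max_size) next
    # conditional pattern base: prefix path of every node carrying `it`
    paths <- vector("list", length(nodes))
    wts <- numeric(length(nodes))
    np <- 0L
    for (nd in nodes) {
      path <- integer(0)
      cur <- tree$parent[nd]
      while (cur != 1L) {
        path <- c(tree$item[cur], path)
        cur <- tree$parent[cur]
      }
      if (length(path) > 0L) {
        np <- np + 1L
        paths[[np]] <- path
        wts[np] <- tree$count[nd]
      }
    }
    if (np == 0L) next
    paths <- paths[seq_len(np)]
    wts <- wts[seq_len(np)]
    # prune conditionally infrequent items
    tab <- numeric(n_items)
    for (p in seq_len(np)) tab[paths[[p]]] <- tab[paths[[p]]] + wts[p]
    keep <- tab >= minsup
    paths <- lapply(paths, function(pp) pp[keep[pp]])
    nz <- lengths(paths) > 0L
    if (!any(nz)) next
    cond <- .fp_build(paths[nz], wts[nz], n_items)
    .fp_mine(cond, newset, minsup, max_size, n_items, acc)
  }
}

#' Frequent itemset mining with FP-Growth
#'
#' Builds a frequent-pattern tree over the transactions and mines all
#' itemsets of size at most `max_size` whose support count is at least
#' `min_support_count`, with exact counts. The result is independent of
#' transaction order.
#'
#' @param transactions List of character item vectors (may contain empty
#'   transactions; duplicates within a transaction are ignored).
#' @param min_support_count Minimum support as an absolute count (>= 1).
#' @param max_size Maximum itemset size (default unlimited).
#' @return data.frame with `items` (comma-joined, lexicographically sorted),
#'   `size`, `count`, sorted by size then items.
#' @export
fp_growth <- function(transactions, min_support_count = 1L, max_size = Inf) {
  stopifnot(min_support_count >= 1)
  empty <- data.frame(items = character(), size = integer(), count = numeric(),
                      stringsAsFactors = FALSE)
  if (length(transactions) == 0L) return(empty)
  tx <- lapply(transactions, unique)
  itab <- sort(table(unlist(tx, use.names = FALSE)), decreasing = TRUE)
  itab <- itab[itab >= min_support_count]
  if (length(itab) == 0L) return(empty)
  # frequency-descending item order, ties lexicographic for determinism
  flist <- names(itab)[order(-as.numeric(itab), names(itab))]
  n_items <- length(flist)
  enc <- lapply(tx, function(v) sort(match(v, flist), na.last = NA))
  enc <- enc[lengths(enc) > 0L]
  if (length(enc) == 0L) return(empty)
  tree <- .fp_build(enc, rep(1, length(enc)), n_items)
  acc <- new.env(parent = emptyenv())
  acc$sets <- list()
  acc$counts <- list()
  .fp_mine(tree, integer(0), min_support_count, max_size, n_items, acc)
  if (length(acc$sets) == 0L) return(empty)
  items <- vapply(acc$sets,
                  function(s) paste(sort(flist[s]), collapse = ","),
                  character(1))
  out <- data.frame(items = items, size = lengths(acc$sets),
                    count = unlist(acc$counts), stringsAsFactors = FALSE)
  out <- out[order(out$size, out$items), ]
  rownames(out) <- NULL
  out
}

# exact support count of one itemset (character vector) in transactions
.support_count <- function(itemset, transactions) {
  sum(vapply(transactions, function(tx) all(itemset %in% tx), logical(1)))
}

#' Observed/expected support ratio of an itemset
#'
#' Joint support fraction divided by the product of the items' marginal
#' support fractions; 1 under independence, 0 for disjoint items. All
#' fractions use the full transaction list (including empty transactions) as
#' denominator.
#'
#' @param itemset Character vector of items (size >= 2).
#' @param transactions List of character item vectors.
#' @return The ratio (numeric scalar). Zero marginal support is an error.
#' @export
support_ratio <- function(itemset, transactions) {
  n <- length(transactions)
  marg <- vapply(itemset, function(it) .support_count(it, transactions), 0)
  if (any(marg == 0))
    stop("undefined support ratio: zero marginal support for item(s) ",
         paste(itemset[marg == 0], collapse = ", "))
  joint <- .support_count(itemset, transactions) / n
  joint / prod(marg / n)
}

#' Candidate rule selection by a control-resampling null
#'
#' Mines the case transactions once; then, for each of `n_iter` iterations,
#' draws `N` controls without replacement from the pool (size `M`, roughly
#' `5 N`) and computes the exact support of every case-frequent itemset in
#' that sample. A rule is `selected` iff its case support fraction strictly
#' exceeds its support fraction in every iteration.
#'
#' @param case_tx List of case transactions (size `N`).
#' @param control_pool List of candidate control transactions (size
#'   `M >= N`).
#' @param n_iter Number of control resamples (default 20).
#' @param min_support Minimum case support fraction for mining (default
#'   0.05).
#' @param max_size Maximum itemset size (default 3).
#' @param seed Integer seed for the control draws.
#' @return data.frame of itemsets of size >= 2: `items`, `size`,
#'   `case_count`, `case_support`, `max_control_support`, `selected`, plus a
#'   matrix attribute `control_supports` (rules x iterations).
#' @export
resampling_null <- function(case_tx, control_pool, n_iter = 20,
                            min_support = 0.05, max_size = 3, seed = 1) {
  n_case <- length(case_tx)
  m <- length(control_pool)
  if (m < n_case)
    stop("control pool (", m, ") smaller than case group (", n_case, ")")
  minc <- max(1L, ceiling(min_support * n_case))
  mined <- fp_growth(case_tx, min_support_count = minc, max_size = max_size)
  mined <- mined[mined$size >= 2L, , drop = FALSE]
  if (nrow(mined) == 0L) {
    out <- data.frame(items = character(), size = integer(),
                      case_count = numeric(), case_support = numeric(),
                      max_control_support = numeric(), selected = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "control_supports") <- matrix(0, 0, n_iter)
    return(out)
  }
  sets <- strsplit(mined$items, ",", fixed = TRUE)
  ctrl <- matrix(0, nrow = nrow(mined), ncol = n_iter)
  with_seed(seed, {
    for (j in seq_len(n_iter)) {
      samp <- control_pool[sample.int(m, n_case)]
      ctrl[, j] <- vapply(sets, .support_count, 0, transactions = samp) / n_case
    }
  })
  case_supp <- mined$count / n_case
  out <- data.frame(items = mined$items, size = mined$size,
                    case_count = mined$count, case_support = case_supp,
                    max_control_support = apply(ctrl, 1, max),
                    selected = case_supp > apply(ctrl, 1, max),
                    stringsAsFactors = FALSE)
  # strict dominance over every iteration, not just the max (equivalent)
  out$selected <- vapply(seq_len(nrow(out)),
                         function(i) all(case_supp[i] > ctrl[i, ]),
                         logical(1))
  attr(out, "control_supports") <- ctrl
  out
}

#' Final rule filtering
#'
#' Retains rules meeting all of: selected by the resampling null; itemset
#' size <= `max_size`; case support fraction >= `s_min`; support ratio
#' >= `r_min`; and, when `significance = TRUE`, a bootstrap lower 95%
#' confidence bound of the support ratio above 1 (B resamples of the case
#' transactions).
#'
#' @param rules Output of [resampling_null()].
#' @param case_tx The case transactions used for mining.
#' @param s_min Minimum case support fraction (default 0.05).
#' @param r_min Minimum support ratio (default 1.5).
#' @param max_size Maximum itemset size (default 3).
#' @param significance Require the bootstrap lower bound > 1 (default TRUE).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Filtered data.frame with added `support_ratio` and
#'   `ratio_lower95` columns.
#' @export
filter_rules <- function(rules, case_tx, s_min = 0.05, r_min = 1.5,
                         max_size = 3, significance = TRUE, B = 1000,
                         seed = 1) {
  keep <- rules$selected & rules$size <= max_size & rules$case_support >= s_min
  out <- rules[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$support_ratio <- numeric(0)
    out$ratio_lower95 <- numeric(0)
    return(out)
  }
  sets <- strsplit(out$items, ",", fixed = TRUE)
  out$support_ratio <- vapply(sets, support_ratio, 0,
                              transactions = case_tx)
  out$ratio_lower95 <- NA_real_
  keep2 <- out$support_ratio >= r_min
  out <- out[keep2, , drop = FALSE]
  sets <- sets[keep2]
  if (significance && nrow(out) > 0L) {
    n <- length(case_tx)
    lower <- with_seed(seed, {
      vapply(seq_along(sets), function(i) {
        # per-item transaction membership, so each bootstrap draw is O(n)
        mem <- vapply(sets[[i]],
                      function(it) vapply(case_tx, function(tx) it %in% tx,
                                          logical(1)),
                      logical(length(case_tx)))
        joint <- rowSums(mem) == ncol(mem)
        ratios <- vapply(seq_len(B), function(b) {
          idx <- sample.int(n, n, replace = TRUE)
          marg <- colSums(mem[idx, , drop = FALSE])
          if (any(marg == 0)) return(NA_real_)
          (sum(joint[idx]) / n) / prod(marg / n)
        }, 0)
        stats::quantile(ratios, 0.025, na.rm = TRUE, names = FALSE)
      }, 0)
    })
    out$ratio_lower95 <- lower
    out <- out[!is.na(lower) & lower > 1, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
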