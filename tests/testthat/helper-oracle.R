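# Independent brute-force oracle for the ambiguity-resolving frequency
# estimator. It recomputes Hardy-Weinberg genotype probabilities by
# explicitly enumerating every ordered allele tuple (rather than the
# multinomial closed form used by the implementation) and allocates weights
# with naive loops. Labels are assumed pre-normalized.

oracle_multiset_prob <- function(m, g) {
  alle <- names(g)
  k <- length(m)
  tuples <- expand.grid(rep(list(alle), k), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  target <- sort(m)
  pr <- 0
  for (r in seq_len(nrow(tuples))) {
    tup <- unname(unlist(tuples[r, ]))
    if (identical(sort(tup), target)) pr <- pr + prod(g[tup])
  }
  unname(pr)
}

oracle_estimate <- function(cand_list) {
  unamb <- vapply(cand_list, function(cc) length(cc) == 1L, logical(1))
  universe <- sort(unique(unlist(cand_list, use.names = FALSE)))
  counts <- stats::setNames(rep(0, length(universe)), universe)
  for (i in which(unamb)) {
    for (a in cand_list[[i]][[1L]]) counts[[a]] <- counts[[a]] + 1
  }
  g <- if (sum(counts) > 0) counts / sum(counts) else counts
  alloc <- stats::setNames(rep(0, length(universe)), universe)
  for (i in which(!unamb)) {
    sets <- cand_list[[i]]
    w <- numeric(length(sets))
    for (j in seq_along(sets)) w[[j]] <- oracle_multiset_prob(sets[[j]], g)
    if (sum(w) == 0) w <- rep(1 / length(sets), length(sets)) else w <- w / sum(w)
    for (j in seq_along(sets)) {
      for (a in sets[[j]]) alloc[[a]] <- alloc[[a]] + w[[j]]
    }
  }
  total <- counts + alloc
  total / sum(total)
}

# random micro-cohort over bare labels (<= 5 alleles, <= 50 samples); about
# 40% of calls ambiguous with 2-3 candidate multisets containing the truth
random_micro_cohort <- function(seed) {
  set.seed(seed)
  n_alle <- sample(2:5, 1L)
  alle <- LETTERS[seq_len(n_alle)]
  p <- as.numeric(stats::rgamma(n_alle, 1)); p <- p / sum(p)
  n <- sample(5:50, 1L)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    true_pair <- sort(sample(alle, 2L, replace = TRUE, prob = p))
    if (stats::runif(1) < 0.4) {
      k <- sample(2:3, 1L)
      sets <- list(true_pair)
      guard <- 0L
      while (length(sets) < k && guard < 25L) {
        guard <- guard + 1L
        decoy <- sort(sample(alle, 2L, replace = TRUE))
        if (!any(vapply(sets, identical, logical(1), y = decoy))) {
          sets <- c(sets, list(decoy))
        }
      }
      cand[[i]] <- sets
    } else {
      cand[[i]] <- list(true_pair)
    }
  }
  cand
}
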