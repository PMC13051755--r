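#' Levins niche breadth of one taxon
#'
#' B = 1 / sum_j p_j^2 where p_j is the share of the taxon's reads found in
#' sample j. Ranges from 1 (all reads in one sample: extreme specialist) to
#' the number of samples (perfectly even: extreme generalist), and is
#' invariant to scaling the counts.
#'
#' @param counts numeric vector of the taxon's counts over samples.
#' @return Levins B.
#' @export
levins_b <- function(counts) {
  if (sum(counts) <= 0) abort("levins_b needs a vector with positive total")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

# vectorized over all taxa of a matrix (rows)
levins_b_all <- function(m) {
  p <- m / rowSums(m)
  1 / rowSums(p^2)
}

#' Classify taxa as specialists, neutral taxa or generalists
#'
#' Observed Levins B per taxon is compared against its null distribution
#' over fixed-fixed randomizations of the count matrix (quasiswap count
#' algorithm: every permuted table preserves all row and column sums
#' exactly). Taxa below the null 2.5% quantile are specialists, above the
#' 97.5% quantile generalists, otherwise neutral taxa (95% band, empirical
#' type-7 quantiles).
#'
#' @param x a `count_table`.
#' @param n_perm number of permutations (1000 by default; < 100 warns).
#' @param seed integer seed.
#' @return data.frame of class `niche_classification`: taxon_id, b_obs,
#'   null_mean, null_lo, null_hi, label, single_sample flag. Attribute
#'   `n_perm` records the permutation count.
#' @export
classify_niche <- function(x, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(x, "count_table"))
  if (n_perm < 100L) warning("n_perm < 100 gives unstable niche quantiles")
  m <- x$counts
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  b_obs <- levins_b_all(m)
  sims <- tryCatch({
    nm <- vegan::nullmodel(m, "quasiswap_count")
    stats::simulate(nm, nsim = n_perm, seed = seed)
  }, error = function(e) {
    warning(sprintf(paste("fixed-fixed randomization degenerate (%s);",
                          "all taxa classified neutral"), conditionMessage(e)))
    array(m, dim = c(dim(m), n_perm))
  })
  bnull <- apply(sims, 3L, levins_b_all)
  if (is.null(dim(bnull))) bnull <- matrix(bnull, nrow = 1L)
  qs <- apply(bnull, 1L, stats::quantile, probs = c(0.025, 0.975), type = 7L)
  label <- ifelse(b_obs < qs[1L, ], "specialist",
           ifelse(b_obs > qs[2L, ], "generalist", "neutral_taxon"))
  out <- data.frame(taxon_id = rownames(m), b_obs = b_obs,
                    null_mean = rowMeans(bnull),
                    null_lo = qs[1L, ], null_hi = qs[2L, ],
                    label = factor(label, levels = c("specialist",
                                                     "neutral_taxon",
                                                     "generalist")),
                    single_sample = rowSums(m > 0) == 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  class(out) <- c("niche_classification", "data.frame")
  out
}

#' Compare niche breadth between communities
#'
#' t-test on per-taxon Levins B between two classifications (e.g.
#' susceptible vs resistant cultivar tables) and, given a 4-level design
#' grouping over samples, one-way ANOVA with LSD letters on per-sample
#' community-weighted mean breadth.
#'
#' @param class_a,class_b `niche_classification` objects.
#' @param labels names for the two communities.
#' @return list: per-community mean B, t statistic, p, and the direction of
#'   the difference.
#' @export
compare_breadth <- function(class_a, class_b, labels = c("A", "B")) {
  tt <- stats::t.test(class_a$b_obs, class_b$b_obs)
  res <- list(means = stats::setNames(c(mean(class_a$b_obs),
                                        mean(class_b$b_obs)), labels),
              statistic = unname(tt$statistic), p = tt$p.value)
  res$direction <- if (res$means[1L] > res$means[2L]) labels[1L] else labels[2L]
  res
}

#' Per-sample mean niche breadth for design-group comparisons
#'
#' Community-level breadth of each sample: abundance-weighted mean of
#' taxon Levins B over the taxa present, ready for ANOVA + LSD across the
#' CS/CR/FS/FR groups via [group_tests()].
#'
#' @param x a `count_table`.
#' @param niche a `niche_classification` for the same table.
#' @return named numeric vector over samples.
#' @export
sample_breadth <- function(x, niche) {
  b <- stats::setNames(niche$b_obs, niche$taxon_id)
  m <- x$counts[niche$taxon_id, , drop = FALSE]
  rel <- prop.table(m, 2L)
  colSums(rel * b)
}
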