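#' Abundance-weighted beta mean nearest taxon distance
#'
#' For communities A, B with relative abundances f and patristic distances
#' d: betaMNTD(A,B) = 1/2 [ sum_{i in A} f_iA min_{j in B} d(i,j) +
#' sum_{j in B} f_jB min_{i in A} d(j,i) ]. Taxa shared by both communities
#' contribute zero nearest-taxon distance. Unweighted mode replaces f by
#' uniform weights over present taxa.
#'
#' @param x a `count_table`.
#' @param tree `phylo` covering all taxa of `x`.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return a symmetric matrix of betaMNTD values over samples.
#' @export
beta_mntd <- function(x, tree, weighted = TRUE) {
  stopifnot(inherits(x, "count_table"))
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing))
    abort("%d taxa missing from tree (e.g. %s)", length(missing), missing[1L])
  d <- ape::cophenetic.phylo(tree)[taxon_ids(x), taxon_ids(x)]
  bmntd_from_dist(x$counts, d, weighted)
}

# core shared with the null loop: counts (taxa x samples) + taxon distance
bmntd_from_dist <- function(counts, d, weighted = TRUE) {
  f <- if (weighted) prop.table(counts, 2L) else
    prop.table((counts > 0) + 0, 2L)
  M <- nearest_taxon_dist(counts > 0, d)
  X <- crossprod(f, M)             # X[A,B] = sum_i f_iA * min_{j in B} d(i,j)
  b <- (X + t(X)) / 2
  dimnames(b) <- list(colnames(counts), colnames(counts))
  b
}

# M[i, s] = min over taxa j present in sample s of d[i, j]
nearest_taxon_dist <- function(pres, d) {
  vapply(seq_len(ncol(pres)), function(s) {
    idx <- which(pres[, s])
    if (length(idx) == 1L) d[, idx] else
      do.call(pmin, lapply(idx, function(j) d[, j]))
  }, numeric(nrow(pres)))
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of observed betaMNTD against a null built by shuffling tip
#' labels across the whole tree (equivalently, jointly permuting rows and
#' columns of the patristic distance matrix); one shuffle per null
#' replicate is applied to all sample pairs. |betaNTI| > 2 indicates
#' deterministic selection (homogeneous below -2, heterogeneous above +2).
#'
#' @param x a `count_table`.
#' @param tree `phylo` covering all taxa.
#' @param n_null number of tip-shuffle replicates (999 by default).
#' @param seed integer seed.
#' @param weighted abundance-weighted betaMNTD.
#' @return list: `bnti` (samples x samples matrix, NA where null sd = 0),
#'   `obs` betaMNTD matrix, `null_mean`, `null_sd`.
#' @export
beta_nti <- function(x, tree, n_null = 999L, seed = 1L, weighted = TRUE) {
  stopifnot(inherits(x, "count_table"), n_null >= 2)
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing))
    abort("%d taxa missing from tree (e.g. %s)", length(missing), missing[1L])
  d <- ape::cophenetic.phylo(tree)[taxon_ids(x), taxon_ids(x)]
  obs <- bmntd_from_dist(x$counts, d, weighted)
  T <- nrow(x$counts)
  set.seed(seed)
  # Welford running moments over null replicates, per sample pair
  mean_b <- matrix(0, nrow(obs), ncol(obs))
  m2_b <- matrix(0, nrow(obs), ncol(obs))
  for (r in seq_len(n_null)) {
    perm <- sample.int(T)
    b <- bmntd_from_dist(x$counts, d[perm, perm, drop = FALSE], weighted)
    delta <- b - mean_b
    mean_b <- mean_b + delta / r
    m2_b <- m2_b + delta * (b - mean_b)
  }
  sd_b <- sqrt(m2_b / (n_null - 1L))
  bnti <- (obs - mean_b) / sd_b
  degenerate <- sd_b == 0 & upper.tri(sd_b)
  if (any(degenerate)) {
    warning(sprintf("betaNTI undefined (null sd = 0) for %d pair(s); reported NA",
                    sum(degenerate)))
    bnti[sd_b == 0] <- NA_real_
  }
  diag(bnti) <- NA_real_
  dimnames(bnti) <- dimnames(obs)
  list(bnti = bnti, obs = obs, null_mean = mean_b, null_sd = sd_b)
}

#' Raup-Crick metric on Bray-Curtis distances
#'
#' Null communities preserve each sample's observed richness and read
#' total: taxa are drawn without replacement with probability proportional
#' to metacommunity occupancy, then reads are assigned by a multinomial
#' over metacommunity relative abundances restricted to the drawn taxa.
#' RC = 2 ((#{null < obs} + 0.5 #{null = obs}) / n_null - 0.5), in [-1, 1].
#'
#' @param x a `count_table`.
#' @param n_null number of null replicates (999 by default).
#' @param seed integer seed.
#' @return samples x samples matrix of RC values (diagonal NA).
#' @export
rc_bray <- function(x, n_null = 999L, seed = 1L) {
  stopifnot(inherits(x, "count_table"), n_null >= 2)
  counts <- x$counts
  S <- ncol(counts)
  occ <- rowSums(counts > 0)
  q <- rowSums(counts); q <- q / sum(q)
  rich <- colSums(counts > 0)
  totals <- colSums(counts)
  obs <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  n_lt <- matrix(0, S, S)
  n_eq <- matrix(0, S, S)
  set.seed(seed)
  for (r in seq_len(n_null)) {
    nullc <- vapply(seq_len(S), function(s) {
      pick <- sample.int(length(occ), rich[s], prob = occ)
      out <- numeric(length(occ))
      out[pick] <- stats::rmultinom(1L, totals[s], q[pick])[, 1L]
      out
    }, numeric(nrow(counts)))
    dn <- as.matrix(vegan::vegdist(t(nullc), method = "bray"))
    n_lt <- n_lt + (dn < obs)
    n_eq <- n_eq + (dn == obs)
  }
  rc <- 2 * ((n_lt + 0.5 * n_eq) / n_null - 0.5)
  diag(rc) <- NA_real_
  dimnames(rc) <- dimnames(obs)
  rc
}

#' Assign ecological assembly processes from betaNTI and RC-Bray
#'
#' betaNTI < -2: homogeneous selection; betaNTI > 2: heterogeneous
#' selection; otherwise RC > 0.95: dispersal limitation; RC < -0.95:
#' homogenizing dispersal; else drift.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC-Bray values (same length).
#' @return factor with the five process levels (NA where betaNTI is NA).
#' @export
assign_process <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc))
  out <- ifelse(bnti < -2, "homogeneous_selection",
         ifelse(bnti > 2, "heterogeneous_selection",
         ifelse(rc > 0.95, "dispersal_limitation",
         ifelse(rc < -0.95, "homogenizing_dispersal", "drift"))))
  factor(out, levels = c("homogeneous_selection", "heterogeneous_selection",
                         "homogenizing_dispersal", "dispersal_limitation",
                         "drift"))
}

#' Relative importance of assembly processes
#'
#' @param process factor from [assign_process()].
#' @return named numeric: fraction of classified pairs per process (sums to 1).
#' @export
process_fractions <- function(process) {
  tab <- table(process[!is.na(process)])
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Full assembly analysis within sample groups
#'
#' Computes betaNTI and RC-Bray for every within-group sample pair and
#' partitions pairs into the five ecological processes; groups follow the
#' cultivar-class contrast (pairs are formed within each group only).
#'
#' @param x a `count_table`.
#' @param tree `phylo` covering all taxa.
#' @param groups factor-like, one level per sample of `x`.
#' @param n_null null replicates for both betaNTI and RC-Bray.
#' @param seed integer seed.
#' @param weighted abundance-weighted betaMNTD.
#' @return list of class `assembly_result`: `pairs` data.frame (sample_1,
#'   sample_2, group, beta_mntd, bnti, rc_bray, process) and `fractions`
#'   (per-group process-fraction matrix).
#' @export
assembly_analysis <- function(x, tree, groups, n_null = 999L, seed = 1L,
                              weighted = TRUE) {
  g <- factor(groups)
  stopifnot(length(g) == ncol(x$counts))
  pairs <- do.call(rbind, lapply(levels(g), function(lv) {
    ids <- sample_ids(x)[g == lv]
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(ids, 2L)
    data.frame(sample_1 = cmb[1L, ], sample_2 = cmb[2L, ], group = lv,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) abort("no group has >= 2 samples")
  bn <- beta_nti(x, tree, n_null = n_null, seed = derive_seed(seed, "bnti"),
                 weighted = weighted)
  rc <- rc_bray(x, n_null = n_null, seed = derive_seed(seed, "rcbray"))
  idx <- cbind(match(pairs$sample_1, sample_ids(x)),
               match(pairs$sample_2, sample_ids(x)))
  pairs$beta_mntd <- bn$obs[idx]
  pairs$bnti <- bn$bnti[idx]
  pairs$rc_bray <- rc[idx]
  pairs$process <- assign_process(pairs$bnti, pairs$rc_bray)
  fr <- do.call(rbind, lapply(split(pairs$process, pairs$group), function(p) {
    tab <- table(p[!is.na(p)])
    as.numeric(tab) / max(1L, sum(tab))
  }))
  colnames(fr) <- levels(pairs$process)
  structure(list(pairs = pairs, fractions = fr), class = "assembly_result")
}
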