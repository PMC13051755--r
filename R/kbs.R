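#' Screen for keystone beneficial specialists (KBS)
#'
#' The three-criterion intersection: taxa that are simultaneously
#' (i) keystone in the co-occurrence network (module hub, connector or
#' network hub by Zi-Pi), (ii) niche specialists under the Levins
#' permutation null, and (iii) annotated as potentially beneficial by
#' matching the taxonomy at the beneficial list's rank (case-insensitive
#' exact match). Bacteria-only by default.
#'
#' @param net a `co_network` after [zi_pi()].
#' @param niche a `niche_classification` on the same sample set.
#' @param taxonomy a `taxonomy` covering the network's taxa.
#' @param beneficial a `beneficial_list`.
#' @param kingdoms kingdoms eligible for the screen (default "bacteria").
#' @return list of class `kbs_result`: `kbs_taxa`, `provenance` data.frame
#'   (taxon_id, keystone_role, niche_label, beneficial_key), and `counts`
#'   (per-criterion and intersection sizes).
#' @export
screen_kbs <- function(net, niche, taxonomy, beneficial,
                       kingdoms = "bacteria") {
  if (is.null(net$nodes$role)) abort("run detect_modules() and zi_pi() first")
  eligible <- net$nodes$taxon_id[net$nodes$kingdom %in% kingdoms]
  keystone <- net$nodes$taxon_id[net$nodes$keystone &
                                 net$nodes$kingdom %in% kingdoms]
  specialist <- intersect(niche$taxon_id[niche$label == "specialist"], eligible)
  rank_col <- taxonomy[[beneficial$rank]]
  hit <- tolower(rank_col) %in% tolower(beneficial$keys)
  beneficial_taxa <- intersect(taxonomy$taxon_id[hit], eligible)
  if (!length(keystone)) warning("empty keystone set: KBS screen returns none")
  kbs <- Reduce(intersect, list(keystone, specialist, beneficial_taxa))
  prov <- data.frame(
    taxon_id = kbs,
    keystone_role = as.character(net$nodes$role[match(kbs, net$nodes$taxon_id)]),
    niche_label = rep("specialist", length(kbs)),
    beneficial_key = rank_col[match(kbs, taxonomy$taxon_id)],
    stringsAsFactors = FALSE)
  counts <- c(keystone = length(keystone), specialist = length(specialist),
              beneficial = length(beneficial_taxa),
              keystone_specialist = length(intersect(keystone, specialist)),
              keystone_beneficial = length(intersect(keystone, beneficial_taxa)),
              specialist_beneficial = length(intersect(specialist,
                                                       beneficial_taxa)),
              kbs = length(kbs))
  structure(list(kbs_taxa = kbs, provenance = prov, counts = counts),
            class = "kbs_result")
}

#' Per-sample KBS relative abundance
#'
#' Summed relative abundance of the KBS taxa in each sample of the
#' (rarefied) count table, with group summaries and a t-test between
#' resistance classes when metadata is supplied.
#'
#' @param result a `kbs_result`.
#' @param x a `count_table`.
#' @param meta optional `sample_metadata` for the class comparison.
#' @return list: `per_sample` named numeric in [0,1]; with metadata also
#'   `group_summary` (mean, se, n per class) and `t_test`.
#' @export
kbs_abundance <- function(result, x, meta = NULL) {
  rel <- prop.table(x$counts, 2L)
  taxa <- intersect(result$kbs_taxa, rownames(rel))
  ab <- if (length(taxa)) colSums(rel[taxa, , drop = FALSE])
        else stats::setNames(numeric(ncol(rel)), colnames(rel))
  out <- list(per_sample = ab)
  if (!is.null(meta)) {
    cls <- meta$resistance[match(names(ab), meta$sample_id)]
    sm <- do.call(rbind, lapply(split(ab, cls), function(v)
      data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                 n = length(v))))
    out$group_summary <- sm
    out$t_test <- if (length(unique(cls)) == 2L && stats::sd(ab) > 0)
      stats::t.test(ab ~ cls) else NULL
  }
  out
}

#' Class-level taxonomic composition of the KBS set
#'
#' Mean relative abundance per taxonomic class (e.g. Bacilli,
#' Bacteroidia), normalized within the KBS set.
#'
#' @param result a `kbs_result`.
#' @param x a `count_table`.
#' @param taxonomy a `taxonomy`.
#' @return named numeric: shares per class, summing to 1 (empty if no KBS
#'   reads).
#' @export
kbs_composition <- function(result, x, taxonomy) {
  taxa <- intersect(result$kbs_taxa, rownames(x$counts))
  if (!length(taxa)) return(stats::setNames(numeric(0), character(0)))
  rel <- prop.table(x$counts, 2L)[taxa, , drop = FALSE]
  cls <- taxonomy$class[match(taxa, taxonomy$taxon_id)]
  per_taxon <- rowMeans(rel)
  shares <- tapply(per_taxon, cls, sum)
  stats::setNames(as.numeric(shares / sum(shares)), names(shares))
}

#' KBS abundance vs yield, per resistance class
#'
#' Pearson correlation and least-squares slope of yield on per-sample KBS
#' relative abundance, separately within resistant and susceptible
#' cultivars. Undefined correlations (constant input) are reported as NA.
#'
#' @param result a `kbs_result`.
#' @param x a `count_table`.
#' @param meta a `sample_metadata`.
#' @return data.frame: class, n, r, p, slope.
#' @export
kbs_yield_correlation <- function(result, x, meta) {
  ab <- kbs_abundance(result, x)$per_sample
  meta <- meta[match(names(ab), meta$sample_id), , drop = FALSE]
  do.call(rbind, lapply(split(seq_along(ab), meta$resistance), function(i) {
    cls <- meta$resistance[i[1L]]
    if (stats::sd(ab[i]) == 0 || stats::sd(meta$yield[i]) == 0)
      return(data.frame(class = cls, n = length(i), r = NA_real_,
                        p = NA_real_, slope = NA_real_))
    ct <- stats::cor.test(ab[i], meta$yield[i])
    data.frame(class = cls, n = length(i), r = unname(ct$estimate),
               p = ct$p.value,
               slope = unname(stats::coef(stats::lm(meta$yield[i] ~ ab[i]))[2L]))
  }))
}
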