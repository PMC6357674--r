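# Group-wise diversity and differentiation: Nei gene diversity, Hudson F_ST
# (ratio of per-site sums), and minor-allele-frequency spectra.

#' Nei's gene diversity for a sample subset
#'
#' Per site, gene diversity is `h = 1 - sum(f_a^2)` over the allele
#' frequencies within the subset (for biallelic data `h = 2 f (1 - f)`,
#' bounded by 0.5). The index is the mean of `h` over used sites.
#'
#' @param gm `geno_matrix`.
#' @param samples Sample ids to use (default: all).
#' @param mode `"all"` averages over every site with at least one call
#'   (monomorphic sites contribute 0, giving the panel-wide average);
#'   `"polymorphic"` restricts the mean to sites segregating within the
#'   subset. The two modes differ only in scale.
#' @return List with `nei_index`, `n_sites_used` and `per_site` diversity
#'   vector (named by site id; `NA` for unused sites).
#' @export
nei_diversity <- function(gm, samples = NULL, mode = c("all", "polymorphic")) {
  stopifnot(inherits(gm, "geno_matrix"))
  mode <- match.arg(mode)
  samples <- samples %||% sample_ids(gm)
  if (length(samples) == 0) stop("empty sample subset")
  if (!all(samples %in% sample_ids(gm))) stop("unknown sample id(s)")
  af <- .allele_freq(gm$calls[samples, , drop = FALSE])
  h <- 2 * af$freq * (1 - af$freq)
  used <- af$n_call > 0
  if (mode == "polymorphic") used <- used & !is.na(h) & h > 0
  names(h) <- gm$sites$id
  list(nei_index = mean(h[used]), n_sites_used = sum(used), per_site = h)
}

#' Pairwise Hudson F_ST between groups
#'
#' Hudson's estimator accumulated as a ratio of per-site sums: per site
#' `num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and
#' `den = p1 (1 - p2) + p2 (1 - p1)`, where `p_i` is the alternate-allele
#' frequency and `n_i` the allele-call count (two per non-missing genotype)
#' in group i. `F_ST = sum(num) / sum(den)` over sites with `den > 0` and at
#' least two allele calls per group; the estimate is reported unclamped with
#' a warning when negative.
#'
#' @param gm `geno_matrix`.
#' @param partition Sample partition.
#' @param groups Groups to compare (default: all groups in the partition
#'   that have samples in the matrix).
#' @return List with `fst` (symmetric matrix, zero diagonal) and `pairs`
#'   (data frame with per-pair numerator/denominator sums and site counts).
#' @export
pairwise_fst <- function(gm, partition, groups = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  partition <- as_partition(partition)
  partition <- partition[names(partition) %in% sample_ids(gm)]
  groups <- groups %||% unique(unname(partition))
  if (length(groups) < 2) stop("need at least two groups")

  gstat <- lapply(groups, function(g) {
    ids <- intersect(group_samples(partition, g), sample_ids(gm))
    if (length(ids) < 2) stop("group with <2 samples: ", g)
    af <- .allele_freq(gm$calls[ids, , drop = FALSE])
    if (!any(af$n_call > 0)) stop("group with no callable sites: ", g)
    list(p = af$freq, n = 2 * af$n_call)
  })
  names(gstat) <- groups

  fst <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  pairs <- list()
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      s1 <- gstat[[i]]; s2 <- gstat[[j]]
      valid <- s1$n >= 2 & s2$n >= 2 & !is.na(s1$p) & !is.na(s2$p)
      p1 <- s1$p[valid]; p2 <- s2$p[valid]
      n1 <- s1$n[valid]; n2 <- s2$n[valid]
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      use <- den > 0
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      v <- sum(num[use]) / sum(den[use])
      if (is.finite(v) && v < 0) {
        warning("negative F_ST estimate for ", groups[j], " vs ", groups[i])
      }
      fst[i, j] <- fst[j, i] <- v
      pairs[[length(pairs) + 1L]] <-
        data.frame(group1 = groups[j], group2 = groups[i],
                   fst = v, num_sum = sum(num[use]), den_sum = sum(den[use]),
                   n_sites_used = sum(use), stringsAsFactors = FALSE)
    }
  }
  list(fst = fst, pairs = do.call(rbind, pairs))
}

#' Group-wise minor-allele-frequency spectra
#'
#' @param gm `geno_matrix`.
#' @param partition Sample partition.
#' @param groups Groups to profile (default: first two groups present).
#' @return List with `maf` (data frame: site id plus one MAF column per
#'   group), and for the first two groups a `joint` data frame and summary
#'   counts `n_seg_first_fixed_second` / `n_seg_second_fixed_first` of sites
#'   segregating in one group and fixed in the other.
#' @export
maf_spectrum <- function(gm, partition, groups = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  partition <- as_partition(partition)
  groups <- groups %||% utils::head(unique(unname(partition)), 2)
  maf <- data.frame(site = gm$sites$id, stringsAsFactors = FALSE)
  freq <- list()
  for (g in groups) {
    ids <- intersect(group_samples(partition, g), sample_ids(gm))
    if (length(ids) == 0) stop("group has no samples in the matrix: ", g)
    af <- .allele_freq(gm$calls[ids, , drop = FALSE])
    freq[[g]] <- af$freq
    maf[[paste0("maf_", g)]] <- pmin(af$freq, 1 - af$freq)
  }
  out <- list(maf = maf)
  if (length(groups) >= 2) {
    f1 <- freq[[groups[1]]]; f2 <- freq[[groups[2]]]
    ok <- !is.na(f1) & !is.na(f2)
    seg1 <- ok & f1 > 0 & f1 < 1
    seg2 <- ok & f2 > 0 & f2 < 1
    fix1 <- ok & (f1 == 0 | f1 == 1)
    fix2 <- ok & (f2 == 0 | f2 == 1)
    out$joint <- data.frame(site = gm$sites$id,
                            maf_1 = pmin(f1, 1 - f1), maf_2 = pmin(f2, 1 - f2),
                            stringsAsFactors = FALSE)
    out$n_seg_first_fixed_second <- sum(seg1 & fix2)
    out$n_seg_second_fixed_first <- sum(seg2 & fix1)
  }
  out
}
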