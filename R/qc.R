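# Quality-control filter cascade for GBS-style SNP panels:
# site filters (MAF / missingness / heterozygosity), an exact-test screen for
# paralogous (non-allelic) tags, sample filters, and removal of sites private
# to one group. Cascade order: sites -> tag test -> samples -> group-private.

#' Per-site summary statistics
#'
#' @param gm `geno_matrix`.
#' @return Data frame with one row per site: `site`, `maf` (minor-allele
#'   frequency over non-missing calls, dosage-weighted so heterozygotes
#'   contribute one allele each), `missing_fraction` (over all samples),
#'   `het_fraction` (het calls over non-missing calls) and `call_count`.
#'   Sites with zero calls get `NA` statistics.
#' @export
site_stats <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (n_samples(gm) == 0 || n_sites(gm) == 0) stop("empty genotype matrix")
  af <- .allele_freq(gm$calls)
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  data.frame(site = gm$sites$id,
             maf = pmin(af$freq, 1 - af$freq),
             missing_fraction = colSums(is.na(gm$calls)) / n_samples(gm),
             het_fraction = ifelse(af$n_call > 0, het / af$n_call, NA_real_),
             call_count = af$n_call,
             stringsAsFactors = FALSE)
}

#' Per-sample summary statistics
#'
#' @param gm `geno_matrix`.
#' @return Data frame with `id`, `missing_fraction` and `het_fraction`
#'   (het calls over the sample's non-missing calls).
#' @export
sample_stats <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  cc <- rowSums(!is.na(gm$calls))
  data.frame(id = sample_ids(gm),
             missing_fraction = rowSums(is.na(gm$calls)) / n_sites(gm),
             het_fraction = ifelse(cc > 0,
                                   rowSums(gm$calls == 1L, na.rm = TRUE) / cc,
                                   NA_real_),
             stringsAsFactors = FALSE)
}

#' Filter sites on MAF, missingness and heterozygosity
#'
#' Retains sites with `maf >= maf_min`, `missing_fraction <= missing_max`
#' and `het_fraction <= het_max`. A site failing several criteria is counted
#' under each.
#'
#' @param gm `geno_matrix`.
#' @param maf_min,missing_max,het_max Thresholds in \[0, 1\].
#' @return List with `geno` (filtered matrix) and `log` (list with
#'   per-criterion `counts` and a `removed` data frame of site ids with
#'   semicolon-joined reasons).
#' @export
filter_sites <- function(gm, maf_min = 0.01, missing_max = 0.20, het_max = 0.05) {
  for (v in c(maf_min, missing_max, het_max)) .assert_prob(v, "threshold")
  st <- site_stats(gm)
  # zero-call sites have NA maf/het; they fail (only) the missing criterion
  fail_maf <- !is.na(st$maf) & st$maf < maf_min
  fail_mis <- st$missing_fraction > missing_max
  fail_het <- !is.na(st$het_fraction) & st$het_fraction > het_max
  drop <- fail_maf | fail_mis | fail_het
  reasons <- apply(cbind(maf = fail_maf, missing = fail_mis, het = fail_het),
                   1, function(r) paste(names(r)[r], collapse = ";"))
  log <- list(counts = c(maf = sum(fail_maf), missing = sum(fail_mis),
                         het = sum(fail_het), total_removed = sum(drop)),
              removed = data.frame(site = st$site[drop],
                                   reason = reasons[drop],
                                   stringsAsFactors = FALSE))
  if (all(drop)) warning("all sites removed by site filters")
  keep <- which(!drop)
  list(geno = gm[, keep], log = log)
}

# two-sided Fisher exact p-value for the 2x2 table [[a, b], [c, d]], by
# direct hypergeometric enumeration; ties handled with the conventional
# (1 + 1e-7) relative tolerance
.fisher_p2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  supp <- lo:hi
  dens <- stats::dhyper(supp, m, n, k)
  sum(dens[dens <= dens[supp == a] * (1 + 1e-7)])
}

#' Exact-test screen for non-allelic (paralogous) tags
#'
#' For each site builds the 2x2 table
#' \code{[[n_het, n_hom_ref], [n_hom_alt, n_missing]]} from genotype calls
#' and computes a two-sided Fisher exact p-value by hypergeometric
#' enumeration. Collapsed paralogous tags inflate joint het/absent patterns,
#' so a site is flagged only when the Bonferroni-corrected test is
#' significant *and* the table odds ratio
#' `(n_het * n_missing) / (n_hom_ref * n_hom_alt)` exceeds 1; significant
#' negative association is left alone.
#'
#' @param gm `geno_matrix`.
#' @param alpha Family-wise significance level (Bonferroni denominator =
#'   number of sites tested).
#' @return Data frame per site: table cells, `p_value`, `odds_ratio`,
#'   `flagged`.
#' @export
allelic_tag_test <- function(gm, alpha = 0.001) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  calls <- gm$calls
  a <- colSums(calls == 1L, na.rm = TRUE)      # het
  b <- colSums(calls == 0L, na.rm = TRUE)      # hom ref
  c_ <- colSums(calls == 2L, na.rm = TRUE)     # hom alt
  d <- colSums(is.na(calls))                   # missing
  p <- mapply(.fisher_p2, a, b, c_, d)
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c_
  or <- ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
  thr <- alpha / n_sites(gm)
  data.frame(site = gm$sites$id, n_het = a, n_hom_ref = b, n_hom_alt = c_,
             n_missing = d, p_value = p, odds_ratio = or,
             flagged = p < thr & or > 1, stringsAsFactors = FALSE)
}

#' Filter samples on missingness and heterozygosity
#'
#' Removes samples exceeding either threshold.
#'
#' @param gm `geno_matrix`.
#' @param missing_max,het_max Thresholds in \[0, 1\].
#' @return List with `geno` and `log` (data frame of removed ids + reasons).
#' @export
filter_samples <- function(gm, missing_max = 0.80, het_max = 0.05) {
  for (v in c(missing_max, het_max)) .assert_prob(v, "threshold")
  ss <- sample_stats(gm)
  fail_mis <- ss$missing_fraction > missing_max
  fail_het <- !is.na(ss$het_fraction) & ss$het_fraction > het_max
  drop <- fail_mis | fail_het
  if (all(drop)) stop("all samples removed by sample filters")
  reasons <- apply(cbind(missing = fail_mis, het = fail_het), 1,
                   function(r) paste(names(r)[r], collapse = ";"))
  list(geno = gm[which(!drop), ],
       log = data.frame(id = ss$id[drop], reason = reasons[drop],
                        stringsAsFactors = FALSE))
}

#' Remove sites whose polymorphism is private to one group
#'
#' Drops sites where one allele segregates only within `group` while all
#' remaining samples are fixed — i.e. the site would be monomorphic if the
#' group were removed.
#'
#' @param gm `geno_matrix`.
#' @param partition Sample partition ([as_partition()]).
#' @param group Group whose private sites are removed.
#' @return List with `geno`, `removed` (site ids) and `count`.
#' @export
drop_group_private_sites <- function(gm, partition, group) {
  partition <- as_partition(partition)
  in_grp <- sample_ids(gm) %in% group_samples(partition, group)
  if (!any(in_grp)) stop("group has no samples in the matrix: ", group)
  if (all(in_grp)) stop("group covers the whole matrix: ", group)
  fo <- .allele_freq(gm$calls[!in_grp, , drop = FALSE])
  fg <- .allele_freq(gm$calls[in_grp, , drop = FALSE])
  ok <- fo$n_call > 0 & fg$n_call > 0
  priv <- ok & ((fo$freq == 0 & fg$freq > 0) | (fo$freq == 1 & fg$freq < 1))
  removed <- gm$sites$id[priv]
  list(geno = gm[, which(!priv)], removed = removed, count = sum(priv))
}

#' Run the full QC cascade
#'
#' Site filters, tag-test removal, sample filters, then group-private site
#' removal (when a partition and group are supplied), in that fixed order.
#' Stage input/output dimensions are recorded so the cascade is auditable.
#'
#' @param gm `geno_matrix`.
#' @param partition Optional partition for the group-private stage.
#' @param private_group Group whose private sites are dropped last (e.g.
#'   `"wheat"`); ignored when `partition` is `NULL`.
#' @param maf_min,missing_max,het_max Site thresholds (see [filter_sites()]).
#' @param alpha Tag-test level (see [allelic_tag_test()]).
#' @param sample_missing_max,sample_het_max Sample thresholds.
#' @return List with `geno` and `log` (per-stage dimensions and removals).
#' @export
qc_pipeline <- function(gm, partition = NULL, private_group = "wheat",
                        maf_min = 0.01, missing_max = 0.20, het_max = 0.05,
                        alpha = 0.001, sample_missing_max = 0.80,
                        sample_het_max = 0.05) {
  log <- list(input = dim(gm$calls))
  s1 <- filter_sites(gm, maf_min, missing_max, het_max)
  log$site_filter <- s1$log
  tt <- allelic_tag_test(s1$geno, alpha)
  keep <- which(!tt$flagged)
  g2 <- s1$geno[, keep]
  log$tag_test <- list(flagged = sum(tt$flagged),
                       sites = tt$site[tt$flagged])
  s3 <- filter_samples(g2, sample_missing_max, sample_het_max)
  log$sample_filter <- s3$log
  out <- s3$geno
  if (!is.null(partition) && !is.null(private_group) &&
      private_group %in% as_partition(partition)) {
    s4 <- drop_group_private_sites(out, partition, private_group)
    log$group_private <- list(group = private_group, count = s4$count,
                              sites = s4$removed)
    out <- s4$geno
  }
  log$output <- dim(out$calls)
  list(geno = out, log = log)
}
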