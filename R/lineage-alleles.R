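# Lineage-private allele machinery: discovery, per-sample lineage
# contribution, hybrid classification, chromosome painting, parentage
# matching, group-private alleles, and the consensus introgression rule for
# a derived panel. This is the analytical heart of the package: an allele
# segregating in one lineage but entirely absent from the other is a
# diagnostic marker of ancestry, and counting such alleles in a sample reads
# out its lineage composition without any model fitting.

#' Find lineage-private alleles
#'
#' A site yields an allele private to lineage A when the allele's frequency
#' is exactly 0 in lineage B and strictly between 0 and 1 in A (segregating,
#' so fixed inter-lineage differences are excluded), with both lineages
#' meeting a minimum call fraction; symmetrically for B. Each site
#' contributes at most one private allele.
#'
#' @param gm `geno_matrix`.
#' @param partition Sample partition.
#' @param lineages Length-2 character vector naming the two lineages.
#' @param min_call_fraction Minimum fraction of non-missing calls required in
#'   *each* lineage for a site to be assessed (guards privacy calls against
#'   missingness artifacts).
#' @param include_fixed Also report fixed inter-lineage differences
#'   (frequency 1 vs 0) as private alleles; off by default, provided for
#'   sensitivity analysis.
#' @return Data frame of class `private_allele_table`: `site`, `chrom`,
#'   `pos`, `donor` (lineage name), `allele` (`"ref"`/`"alt"`),
#'   `freq_donor` (private-allele frequency within the donor) and per-lineage
#'   call counts. The lineage pair is kept in attribute `lineages`.
#' @export
find_private_alleles <- function(gm, partition, lineages = c("L1", "L2"),
                                 min_call_fraction = 0.5,
                                 include_fixed = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"), length(lineages) == 2)
  partition <- as_partition(partition)
  ids1 <- intersect(group_samples(partition, lineages[1]), sample_ids(gm))
  ids2 <- intersect(group_samples(partition, lineages[2]), sample_ids(gm))
  if (length(ids1) == 0 || length(ids2) == 0) {
    stop("both lineages must have samples in the matrix")
  }
  a1 <- .allele_freq(gm$calls[ids1, , drop = FALSE])
  a2 <- .allele_freq(gm$calls[ids2, , drop = FALSE])
  ok <- a1$n_call / length(ids1) >= min_call_fraction &
        a2$n_call / length(ids2) >= min_call_fraction &
        a1$n_call > 0 & a2$n_call > 0
  f1 <- a1$freq; f2 <- a2$freq

  seg1 <- f1 > 0 & f1 < 1
  seg2 <- f2 > 0 & f2 < 1
  don1 <- ok & seg1 & (f2 == 0 | f2 == 1)   # segregates in 1, absent from 2
  don2 <- ok & seg2 & (f1 == 0 | f1 == 1)
  idx <- c(which(don1), which(don2))
  rows <- data.frame(
    idx = idx,
    donor = rep(lineages, c(sum(don1, na.rm = TRUE), sum(don2, na.rm = TRUE))),
    allele = rep(NA_character_, length(idx)),
    freq_donor = rep(NA_real_, length(idx)),
    stringsAsFactors = FALSE)
  if (nrow(rows)) {
    other_fixed_alt <- ifelse(rows$donor == lineages[1],
                              f2[rows$idx] == 0, f1[rows$idx] == 0)
    rows$allele <- ifelse(other_fixed_alt, "alt", "ref")
    fd <- ifelse(rows$donor == lineages[1], f1[rows$idx], f2[rows$idx])
    rows$freq_donor <- ifelse(rows$allele == "alt", fd, 1 - fd)
  }
  if (include_fixed) {
    # fixed inter-lineage differences: the allele fixed in one lineage is
    # absent from the other; reported with the allele fixed in its donor
    fix1 <- which(ok & ((f1 == 1 & f2 == 0) | (f1 == 0 & f2 == 1)))
    if (length(fix1)) {
      rows <- rbind(rows,
        data.frame(idx = fix1, donor = lineages[1],
                   allele = ifelse(f1[fix1] == 1, "alt", "ref"),
                   freq_donor = 1, stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(rows$idx), , drop = FALSE]
  out <- data.frame(site = gm$sites$id[rows$idx],
                    chrom = gm$sites$chrom[rows$idx],
                    pos = gm$sites$pos[rows$idx],
                    donor = rows$donor, allele = rows$allele,
                    freq_donor = rows$freq_donor,
                    n_call_1 = a1$n_call[rows$idx],
                    n_call_2 = a2$n_call[rows$idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lineages") <- lineages
  class(out) <- c("private_allele_table", "data.frame")
  out
}

# samples x private-sites matrix of private-allele dosage (0/1/2, NA missing)
.private_dosage <- function(gm, pat, samples = NULL) {
  samples <- samples %||% sample_ids(gm)
  j <- match(pat$site, gm$sites$id)
  if (anyNA(j)) stop("private-allele table refers to sites absent from the matrix")
  d <- gm$calls[samples, j, drop = FALSE]
  is_ref <- pat$allele == "ref"
  d[, is_ref] <- 2L - d[, is_ref, drop = FALSE]
  colnames(d) <- pat$site
  d
}

#' Per-sample lineage contribution from private alleles
#'
#' Counts the copies of each lineage's private alleles a sample carries
#' (dosage-weighted: heterozygotes contribute one copy, homozygotes two) and
#' expresses the lineage contribution as
#' `pct_1 = count_1 / (count_1 + count_2)`. An informative site is one where
#' the sample carries at least one private-allele copy.
#'
#' @param gm `geno_matrix`.
#' @param pat Private-allele table from [find_private_alleles()].
#' @param samples Sample ids (default: all).
#' @return Data frame: `id`, `informative`, `count_1`, `count_2`, `pct_1`,
#'   `pct_2`, where suffixes 1/2 follow the order of `attr(pat, "lineages")`.
#'   Samples with zero informative sites get `NA` percentages with a warning.
#' @export
lineage_contribution <- function(gm, pat, samples = NULL) {
  lineages <- attr(pat, "lineages")
  samples <- samples %||% sample_ids(gm)
  d <- .private_dosage(gm, pat, samples)
  is1 <- pat$donor == lineages[1]
  c1 <- rowSums(d[, is1, drop = FALSE], na.rm = TRUE)
  c2 <- rowSums(d[, !is1, drop = FALSE], na.rm = TRUE)
  informative <- rowSums(d > 0, na.rm = TRUE)
  tot <- c1 + c2
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sample(s) with zero informative private sites")
  }
  out <- data.frame(id = samples, informative = informative,
                    count_1 = c1, count_2 = c2,
                    pct_1 = ifelse(tot > 0, c1 / tot, NA_real_),
                    pct_2 = ifelse(tot > 0, c2 / tot, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lineages") <- lineages
  out
}

#' Flag putative inter-lineage hybrids
#'
#' A sample is flagged when its minor-lineage contribution reaches
#' `minor_fraction_min` with at least `min_informative` informative private
#' sites. Pure-lineage samples sit at a minor contribution of ~0 (exactly 0
#' in error-free data), while even the weakest real hybrids carry tens of
#' percent, so the default threshold of 0.10 separates the regimes cleanly.
#'
#' @param gm `geno_matrix`.
#' @param pat Private-allele table.
#' @param partition Optional partition; group labels are attached to the
#'   report when given.
#' @param minor_fraction_min Minimum minor-lineage contribution.
#' @param min_informative Minimum informative private sites.
#' @return Data frame of flagged samples sorted by minor fraction
#'   (descending): `id`, `group` (if partition given), `minor_fraction`,
#'   `pct_1`, `pct_2`, `informative`.
#' @export
classify_hybrids <- function(gm, pat, partition = NULL,
                             minor_fraction_min = 0.10,
                             min_informative = 100) {
  contrib <- suppressWarnings(lineage_contribution(gm, pat))
  minor <- pmin(contrib$pct_1, contrib$pct_2)
  flag <- !is.na(minor) & minor >= minor_fraction_min &
    contrib$informative >= min_informative
  out <- contrib[flag, , drop = FALSE]
  out$minor_fraction <- minor[flag]
  if (!is.null(partition)) {
    partition <- as_partition(partition)
    out$group <- unname(partition[out$id])
  }
  out <- out[order(-out$minor_fraction, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromosome painting of a sample by private alleles
#'
#' Walks each chromosome in positional order and records, at every site where
#' the sample carries a private allele, the donor lineage of that allele. A
#' clean inter-lineage mosaic (recombinant inbred) paints as long single-
#' lineage runs with few switches; an interleaved pattern signals a fixed
#' hybrid lineage or noise. `clarity = 1 - switches / max(informative - 1, 1)`
#' summarises this (1 = perfectly demarcated).
#'
#' @param gm `geno_matrix`.
#' @param pat Private-allele table.
#' @param sample Sample id.
#' @return List of class `painting_track`: `events` (chrom, pos, site,
#'   lineage), `per_chrom` (informative count, switches, clarity per
#'   chromosome), and overall `informative`, `switches`, `clarity`.
#' @export
paint_sample <- function(gm, pat, sample) {
  stopifnot(length(sample) == 1, sample %in% sample_ids(gm))
  d <- .private_dosage(gm, pat, sample)[1, ]
  carried <- !is.na(d) & d > 0
  ev <- data.frame(chrom = pat$chrom[carried], pos = pat$pos[carried],
                   site = pat$site[carried], lineage = pat$donor[carried],
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$chrom, ev$pos, ev$site), , drop = FALSE]
  rownames(ev) <- NULL
  per <- lapply(split(ev, ev$chrom), function(e) {
    sw <- if (nrow(e) > 1) sum(e$lineage[-1] != e$lineage[-nrow(e)]) else 0L
    data.frame(chrom = e$chrom[1], informative = nrow(e), switches = sw,
               clarity = 1 - sw / max(nrow(e) - 1, 1),
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(chrom = character(0), informative = integer(0),
               switches = integer(0), clarity = numeric(0))
  rownames(per) <- NULL
  informative <- nrow(ev)
  switches <- sum(per$switches)
  structure(list(sample = sample, events = ev, per_chrom = per,
                 informative = informative, switches = switches,
                 clarity = 1 - switches / max(informative - 1, 1)),
            class = "painting_track")
}

#' @export
print.painting_track <- function(x, ...) {
  cat(sprintf("painting_track for %s: %d informative sites, %d switch(es), clarity %.3f\n",
              x$sample, x$informative, x$switches, x$clarity))
  invisible(x)
}

#' Export a painting track as BED intervals
#'
#' Runs of a single lineage label become 0-based half-open intervals spanning
#' the first to last informative site of the run.
#'
#' @param track `painting_track` from [paint_sample()].
#' @param path Optional output path; when given, a BED file (chrom, start,
#'   end, lineage) is written.
#' @return Data frame of intervals, invisibly when writing.
#' @export
painting_bed <- function(track, path = NULL) {
  ev <- track$events
  out <- list()
  for (cr in unique(ev$chrom)) {
    e <- ev[ev$chrom == cr, , drop = FALSE]
    run <- cumsum(c(TRUE, e$lineage[-1] != e$lineage[-nrow(e)]))
    for (r in split(seq_len(nrow(e)), run)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cr, start = e$pos[r[1]] - 1L, end = e$pos[r[length(r)]],
        lineage = e$lineage[r[1]], stringsAsFactors = FALSE)
    }
  }
  bed <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               lineage = character(0))
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Match a hybrid to candidate parents by private-allele identity
#'
#' Percent identity between the query and a candidate is the share of
#' private-allele sites, co-genotyped in both, where the dosages are equal.
#' The best-matching accession per candidate group is the putative parent
#' from that lineage.
#'
#' @param gm `geno_matrix`.
#' @param pat Private-allele table.
#' @param sample Query sample id.
#' @param partition Sample partition.
#' @param candidate_groups Groups to search (default the lineage pair).
#' @param exclude Sample ids excluded from candidacy (the query itself is
#'   always excluded; pass other flagged hybrids here).
#' @return List with one element per candidate group: `best` (one-row data
#'   frame) and `ranking` (all candidates sorted by identity descending, ties
#'   by id). Candidates with no co-genotyped sites are skipped with a
#'   warning.
#' @export
parentage_match <- function(gm, pat, sample, partition,
                            candidate_groups = attr(pat, "lineages"),
                            exclude = NULL) {
  stopifnot(sample %in% sample_ids(gm))
  partition <- as_partition(partition)
  j <- match(pat$site, gm$sites$id)
  q <- gm$calls[sample, j]
  out <- list()
  for (g in candidate_groups) {
    cand <- setdiff(intersect(group_samples(partition, g), sample_ids(gm)),
                    c(sample, exclude))
    if (length(cand) == 0) stop("no candidates in group ", g)
    res <- lapply(cand, function(cd) {
      x <- gm$calls[cd, j]
      ok <- !is.na(q) & !is.na(x)
      if (!any(ok)) {
        warning("no co-genotyped private sites with candidate ", cd)
        return(NULL)
      }
      data.frame(candidate = cd, identity = 100 * mean(q[ok] == x[ok]),
                 n_sites = sum(ok), stringsAsFactors = FALSE)
    })
    rk <- do.call(rbind, res)
    rk <- rk[order(-rk$identity, rk$candidate), , drop = FALSE]
    rownames(rk) <- NULL
    out[[g]] <- list(best = rk[1, , drop = FALSE], ranking = rk)
  }
  out
}

#' Alleles private to a target group against background groups
#'
#' Finds alleles with frequency exactly 0 in every background group and
#' greater than 0 in the target, splitting them into fixed-in-target
#' (frequency 1) and segregating-in-target.
#'
#' @param gm `geno_matrix`.
#' @param partition Sample partition.
#' @param target Target group name, or a character vector of sample ids.
#' @param background Background group names (must not overlap the target).
#' @return List with `sites` (data frame: site, allele, freq_target, fixed),
#'   `n_fixed` and `n_segregating`.
#' @export
group_private_alleles <- function(gm, partition, target, background) {
  partition <- as_partition(partition)
  t_ids <- if (all(target %in% partition)) {
    unlist(lapply(target, group_samples, partition = partition))
  } else target
  t_ids <- intersect(t_ids, sample_ids(gm))
  b_ids <- intersect(unlist(lapply(background, group_samples,
                                   partition = partition)), sample_ids(gm))
  if (length(t_ids) == 0 || length(b_ids) == 0) {
    stop("target and background must both have samples in the matrix")
  }
  if (length(intersect(t_ids, b_ids))) {
    stop("target and background groups overlap")
  }
  ft <- .allele_freq(gm$calls[t_ids, , drop = FALSE])
  fb <- .allele_freq(gm$calls[b_ids, , drop = FALSE])
  ok <- ft$n_call > 0 & fb$n_call > 0
  alt_priv <- ok & fb$freq == 0 & ft$freq > 0
  ref_priv <- ok & fb$freq == 1 & ft$freq < 1
  idx <- c(which(alt_priv), which(ref_priv))
  allele <- rep(c("alt", "ref"), c(sum(alt_priv), sum(ref_priv)))
  freq_t <- ifelse(allele == "alt", ft$freq[idx], 1 - ft$freq[idx])
  ord <- order(idx)
  sites <- data.frame(site = gm$sites$id[idx], allele = allele,
                      freq_target = freq_t, fixed = freq_t == 1,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, n_fixed = sum(sites$fixed),
       n_segregating = sum(!sites$fixed))
}

#' Consensus lineage assignment of private sites in a derived panel
#'
#' Applies the consensus introgression rule to a derived group (e.g. the
#' wheat D genome): a private site enters the consensus as an L1
#' introgression only when at least `min_carriers` different derived lines
#' carry the first lineage's private allele — one carrier could be error —
#' while a single carrier of the second lineage's private allele suffices
#' for an L2 call, the second lineage being the assumed donor background.
#'
#' @param gm `geno_matrix`.
#' @param pat Private-allele table (lineage order gives rule asymmetry:
#'   first = introgressing lineage, second = donor background).
#' @param partition Sample partition.
#' @param derived_group Name of the derived group (default `"wheat"`).
#' @param min_carriers Minimum carriers for a first-lineage call.
#' @return List with `calls` (data frame: site, chrom, pos, lineage,
#'   n_carriers, carriers), `summary` (counts and percentages per lineage)
#'   and `by_chromosome`.
#' @export
consensus_introgression <- function(gm, pat, partition,
                                    derived_group = "wheat",
                                    min_carriers = 2) {
  lineages <- attr(pat, "lineages")
  partition <- as_partition(partition)
  ids <- intersect(group_samples(partition, derived_group), sample_ids(gm))
  if (length(ids) == 0) stop("derived group has no samples: ", derived_group)
  d <- .private_dosage(gm, pat, ids)
  carriers_n <- colSums(d > 0, na.rm = TRUE)
  carrier_ids <- apply(d > 0, 2, function(z) paste(ids[which(z)], collapse = ","))
  is1 <- pat$donor == lineages[1]
  called <- (is1 & carriers_n >= min_carriers) | (!is1 & carriers_n >= 1)
  calls <- data.frame(site = pat$site[called], chrom = pat$chrom[called],
                      pos = pat$pos[called], lineage = pat$donor[called],
                      n_carriers = carriers_n[called],
                      carriers = carrier_ids[called],
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  n1 <- sum(calls$lineage == lineages[1])
  n2 <- sum(calls$lineage == lineages[2])
  tot <- n1 + n2
  summary <- data.frame(lineage = lineages, n_sites = c(n1, n2),
                        pct = if (tot > 0) 100 * c(n1, n2) / tot else
                          c(NA_real_, NA_real_),
                        stringsAsFactors = FALSE)
  by_chrom <- as.data.frame.matrix(table(calls$chrom, factor(calls$lineage,
                                                             levels = lineages)))
  list(calls = calls, summary = summary, by_chromosome = by_chrom)
}
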