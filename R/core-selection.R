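# Diversity-maximizing core-collection selection: a greedy maximal-coverage
# set cover over observed allele classes (a surrogate for the advanced M
# "maximization" strategy of core-selection software), a quota-constrained
# phenotype-weighted reduction step, and capture metrics for assessing the
# selected subset.

#' Enumerate the allele-class universe of a panel
#'
#' One class per observed (site, allele) pair: the reference allele of a site
#' is a class when some sample carries it (dosage 0 or 1), the alternate when
#' some sample carries that (dosage 1 or 2); a monomorphic site therefore
#' yields a single class. When a phenotype table is supplied, every observed
#' (trait, category) pair is appended as an additional class.
#'
#' @param gm `geno_matrix`.
#' @param phenotypes Optional phenotype table ([read_phenotypes()]).
#' @return List of class `allele_class_universe`: `classes` (character ids
#'   such as `"S00001:alt"` or `"leaf_rust=R"`), `membership` (logical
#'   samples x classes matrix), and `pheno_classes` (the phenotype subset).
#' @export
allele_classes <- function(gm, phenotypes = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (n_sites(gm) == 0 || n_samples(gm) == 0) stop("empty genotype matrix")
  calls <- gm$calls
  carries_ref <- !is.na(calls) & calls <= 1L
  carries_alt <- !is.na(calls) & calls >= 1L
  ref_obs <- colSums(carries_ref) > 0
  alt_obs <- colSums(carries_alt) > 0
  membership <- cbind(carries_ref[, ref_obs, drop = FALSE],
                      carries_alt[, alt_obs, drop = FALSE])
  suffix <- function(ids, tag) if (length(ids)) paste0(ids, tag) else character(0)
  classes <- c(suffix(gm$sites$id[ref_obs], ":ref"),
               suffix(gm$sites$id[alt_obs], ":alt"))
  colnames(membership) <- classes
  pheno_classes <- character(0)
  if (!is.null(phenotypes)) {
    traits <- setdiff(names(phenotypes), "id")
    idx <- match(sample_ids(gm), phenotypes$id)
    for (tr in traits) {
      vals <- phenotypes[[tr]][idx]
      for (v in sort(unique(stats::na.omit(vals)))) {
        cl <- paste0(tr, "=", v)
        col <- !is.na(vals) & vals == v
        if (any(col)) {
          membership <- cbind(membership, col)
          colnames(membership)[ncol(membership)] <- cl
          pheno_classes <- c(pheno_classes, cl)
        }
      }
    }
    classes <- colnames(membership)
  }
  rownames(membership) <- sample_ids(gm)
  structure(list(classes = classes, membership = membership,
                 pheno_classes = pheno_classes),
            class = "allele_class_universe")
}

# deterministic greedy maximal coverage over a membership matrix;
# `weights` gives per-class scores, `candidates` the selectable samples,
# `quota`/`groups` optional per-group caps, `target_size` an optional stop
.greedy_cover <- function(membership, weights = NULL, candidates = NULL,
                          groups = NULL, quota = NULL, target_size = NULL) {
  weights <- weights %||% rep(1, ncol(membership))
  candidates <- sort(candidates %||% rownames(membership))
  covered <- rep(FALSE, ncol(membership))
  selected <- character(0)
  step_new <- integer(0)
  coverage <- numeric(0)
  remaining_quota <- quota
  repeat {
    if (!is.null(target_size) && length(selected) >= target_size) break
    avail <- setdiff(candidates, selected)
    if (!is.null(quota)) {
      open <- names(remaining_quota)[remaining_quota > 0]
      avail <- avail[groups[avail] %in% open]
    }
    if (length(avail) == 0) break
    gain <- vapply(avail, function(s) {
      sum(weights[membership[s, ] & !covered])
    }, numeric(1))
    if (is.null(target_size) && max(gain) <= 0) break
    pick <- avail[which.max(gain)]  # ties: first in sorted (lexicographic) order
    new_classes <- sum(membership[pick, ] & !covered)
    covered <- covered | membership[pick, ]
    selected <- c(selected, pick)
    step_new <- c(step_new, new_classes)
    coverage <- c(coverage, mean(covered))
    if (!is.null(quota)) {
      g <- groups[pick]
      remaining_quota[g] <- remaining_quota[g] - 1L
    }
  }
  list(selected = selected, step_new = step_new, coverage = coverage)
}

#' Greedy maximization-strategy core selection
#'
#' Repeatedly adds the sample covering the most uncovered allele (and
#' phenotype) classes, ties broken by lexicographic sample id, stopping at
#' full coverage of the coverable classes. As greedy set cover this inherits
#' the (1 - 1/e) worst-case coverage guarantee relative to the optimal
#' same-size subset.
#'
#' @param gm `geno_matrix`.
#' @param universe [allele_classes()] universe derived from `gm` (computed
#'   when `NULL`).
#' @param phenotypes Optional phenotype table, used when `universe` is
#'   computed here.
#' @return List of class `core_set`: `ids` (ordered selection), `step_new`
#'   (newly covered classes per step), `coverage` (cumulative fraction),
#'   `coverage_fraction` (final), and `capture` ([capture_metrics()] of the
#'   selection).
#' @export
greedy_m_selection <- function(gm, universe = NULL, phenotypes = NULL) {
  universe <- universe %||% allele_classes(gm, phenotypes)
  res <- .greedy_cover(universe$membership)
  structure(list(ids = res$selected, step_new = res$step_new,
                 coverage = res$coverage,
                 coverage_fraction = utils::tail(res$coverage, 1),
                 capture = capture_metrics(gm, res$selected)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d accessions, final class coverage %.1f%%\n",
              length(x$ids), 100 * x$coverage_fraction))
  cat(sprintf("  captures %.1f%% of segregating sites; Nei index %.4f\n",
              x$capture$pct_segregating, x$capture$nei_index))
  invisible(x)
}

#' Quota-constrained, phenotype-weighted core reduction
#'
#' Reduces a core to a target size by constrained greedy selection over its
#' members: each step adds the sample maximizing
#' `newly covered allele classes + w_pheno * newly covered resistant-trait
#' classes`, subject to per-group quotas. This formalizes a manually curated
#' reduction (phenotype-guided, geography-balanced) as a reproducible
#' procedure.
#'
#' @param core `core_set` from [greedy_m_selection()].
#' @param gm `geno_matrix`.
#' @param phenotypes Phenotype table; resistant classes are `trait=R`.
#' @param quotas Named integer vector, group -> count (e.g.
#'   `c(L1 = 29, L2 = 11)`).
#' @param partition Sample partition supplying the group of each member.
#' @param w_pheno Weight of a newly covered resistant-trait class relative
#'   to an allele class.
#' @param target_size Final size (default `sum(quotas)`).
#' @return A `core_set` of exactly `target_size` members honouring the
#'   quotas.
#' @export
reduce_core <- function(core, gm, phenotypes, quotas, partition,
                        w_pheno = 5, target_size = sum(quotas)) {
  stopifnot(inherits(core, "core_set"))
  partition <- as_partition(partition)
  if (target_size != sum(quotas)) stop("target_size must equal sum(quotas)")
  groups <- partition[core$ids]
  avail <- table(groups)
  for (g in names(quotas)) {
    have <- if (g %in% names(avail)) avail[[g]] else 0L
    if (quotas[[g]] > have) {
      stop("infeasible quota: group ", g, " has ", have,
           " core member(s), quota ", quotas[[g]])
    }
  }
  if (target_size > length(core$ids)) stop("target_size exceeds core size")
  universe <- allele_classes(gm, phenotypes)
  weights <- rep(1, ncol(universe$membership))
  resistant <- grepl("=R$", colnames(universe$membership))
  weights[resistant] <- w_pheno
  quota <- vapply(names(quotas), function(g) as.integer(quotas[[g]]),
                  integer(1))
  names(quota) <- names(quotas)
  res <- .greedy_cover(universe$membership, weights = weights,
                       candidates = core$ids, groups = partition,
                       quota = quota, target_size = target_size)
  if (length(res$selected) < target_size) {
    stop("quotas could not be filled from the core members")
  }
  structure(list(ids = res$selected, step_new = res$step_new,
                 coverage = res$coverage,
                 coverage_fraction = utils::tail(res$coverage, 1),
                 capture = capture_metrics(gm, res$selected)),
            class = "core_set")
}

#' Diversity captured by a sample subset
#'
#' @param gm `geno_matrix`.
#' @param subset Sample ids.
#' @return List with `pct_segregating` (percent of the panel's segregating
#'   sites that also segregate within the subset), `n_segregating_subset`,
#'   `n_segregating_full` and `nei_index` of the subset.
#' @export
capture_metrics <- function(gm, subset) {
  if (length(subset) == 0) stop("empty subset")
  if (!all(subset %in% sample_ids(gm))) stop("unknown sample id(s) in subset")
  seg <- function(calls) {
    af <- .allele_freq(calls)
    !is.na(af$freq) & af$freq > 0 & af$freq < 1
  }
  seg_full <- seg(gm$calls)
  seg_sub <- seg(gm$calls[subset, , drop = FALSE])
  n_full <- sum(seg_full)
  list(pct_segregating = if (n_full > 0) 100 * sum(seg_sub & seg_full) / n_full
         else NA_real_,
       n_segregating_subset = sum(seg_sub),
       n_segregating_full = n_full,
       nei_index = nei_diversity(gm, subset)$nei_index)
}
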